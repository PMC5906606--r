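test_that("a degenerate taxonomy yields one leaf with a full 7-rank lineage", {
  db <- build_reference_db(1, 1, 1, seq_length = 150, seed = 3)
  expect_equal(nrow(db$taxa), 1)
  expect_true(all(RANKS %in% names(db$taxa)))
  expect_false(any(is.na(db$taxa[, RANKS])))
  expect_false(grepl("[^ACGT]", db$sequences[[1]]))
})

test_that("invalid generator parameters are rejected", {
  expect_error(build_reference_db(0, 1, 1), "positive")
  expect_error(build_reference_db(2, 2, 2, seq_length = 100), "150")
  expect_error(build_reference_db(2, 2, 2,
                                  divergence_per_rank = rev(default_divergence())),
               "decrease")
})

test_that("identity decays with taxonomic distance in generated databases", {
  db <- build_reference_db(seed = 11)
  taxa <- db$taxa
  within_genus <- c(); cross_phylum <- c()
  for (i in seq_len(nrow(taxa) - 1)) for (j in (i + 1):nrow(taxa)) {
    id <- pairwise_identity(db$sequences[[i]], db$sequences[[j]])$identity
    if (taxa$genus[i] == taxa$genus[j]) within_genus <- c(within_genus, id)
    if (taxa$phylum[i] != taxa$phylum[j]) cross_phylum <- c(cross_phylum, id)
  }
  expect_gt(mean(within_genus), mean(cross_phylum))
  expect_gt(min(within_genus), max(cross_phylum))
})

test_that("identical seeds give byte-identical reference FASTA output", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(build_reference_db(seed = 9)$sequences, f1)
  write_fasta(build_reference_db(seed = 9)$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(build_reference_db(seed = 9)$sequences,
                         build_reference_db(seed = 10)$sequences))
})

test_that("the study database carries the expected structure", {
  db <- study_reference_db(seed = 2)
  expect_equal(nrow(db$taxa), 33)
  expect_equal(sum(db$taxa$is_host), 1)
  expect_false(anyDuplicated(db$taxa$id) > 0)
  host <- db$sequences[db$taxa$is_host]
  other_fish <- db$taxa$id[db$taxa$class == "Actinopterygii" & !db$taxa$is_host]
  for (id in other_fish) {
    dis <- 1 - pairwise_identity(db$sequences[[id]], host[[1]])$identity
    expect_gt(dis, 0.02) # real prey fish must survive the host-similarity filter
  }
})

test_that("profile validation enforces the simplex and positive concentration", {
  expect_error(community_profile(c(a = 0.6, b = 0.3)), "sum to 1")
  expect_error(community_profile(c(a = 1), overdispersion = 0), "overdispersion")
  expect_error(community_profile(c(0.5, 0.5)), "named")
  expect_silent(community_profile(c(a = 0.25, b = 0.75)))
})

test_that("count sampling respects degenerate profiles and read totals", {
  db <- study_reference_db(seed = 2)
  prof <- community_profile(c(Hydrozoa = 1), habitat = "gut")
  cm <- sample_counts(prof, db, n_samples = 6, reads_per_sample = 500, seed = 4)
  hydro <- study_lineages()$id[study_lineages()$class == "Hydrozoa"]
  expect_equal(colSums(cm$counts), setNames(rep(500, 6), colnames(cm$counts)))
  expect_equal(sum(cm$counts[!rownames(cm$counts) %in% hydro, ]), 0)
  expect_identical(sample_counts(prof, db, 3, 100, seed = 8)$counts,
                   sample_counts(prof, db, 3, 100, seed = 8)$counts)
})

test_that("default profiles are calibrated to the reported group means", {
  db <- study_reference_db(seed = 2)
  lin <- study_lineages()
  frac <- function(cm, ids) {
    mean(colSums(cm$counts[rownames(cm$counts) %in% ids, , drop = FALSE]) /
           colSums(cm$counts))
  }
  gut <- sample_counts(gut_profile(), db, 1000, 200, seed = 21)
  cn <- lin$id[lin$phylum == "Cnidaria"]
  expect_lt(abs(frac(gut, cn) - 0.76), 0.03)
  snow <- sample_counts(snow_profile(), db, 1000, 200, seed = 22)
  cr <- lin$id[lin$phylum == "Crustacea"]
  expect_lt(abs(frac(snow, cr) - 0.52), 0.04)
})

test_that("noiseless read emission copies references exactly and conserves counts", {
  db <- study_reference_db(seed = 2)
  cm <- sample_counts(gut_profile(), db, 4, 300, seed = 5)
  reads <- emit_reads(cm, db, error_rate = 0, host_fraction = 0, seed = 6)
  for (j in seq_along(reads)) {
    expect_equal(length(reads[[j]]), sum(cm$counts[, j]))
    expect_equal(attr(reads[[j]], "n_host"), 0L)
    expect_true(all(reads[[j]] %in% db$sequences))
  }
  expect_identical(unname(unlist(emit_reads(cm, db, seed = 9))),
                   unname(unlist(emit_reads(cm, db, seed = 9))))
})

test_that("host contamination matches the blocking-primer retention model", {
  db <- study_reference_db(seed = 2)
  m <- matrix(10000L, 1, 1, dimnames = list("hyd1", "GU001"))
  cm <- structure(list(counts = m,
                       samples = data.frame(sample_id = "GU001",
                                            habitat = "gut")),
                  class = "count_matrix")
  reads <- emit_reads(cm, db, error_rate = 0, host_fraction = 0.5,
                      blocking_efficiency = 0.9, seed = 31)
  n_host <- attr(reads[[1]], "n_host")
  # expected host count: n_prey * q/(1-q) with q = 0.05 -> 526, binomial sd ~22
  expect_lt(abs(n_host - 526), 5 * 23)
  expect_equal(length(reads[[1]]), 10000 + n_host)
  host_seq <- db$sequences[db$taxa$is_host][[1]]
  expect_equal(sum(reads[[1]] == host_seq), n_host)
  expect_error(emit_reads(cm, db, error_rate = 2), "\\[0, 1\\]")
})

test_that("larval cohorts honour truncation, moments and the mass anchor", {
  expect_error(draw_larvae(0), ">= 1")
  expect_error(draw_larvae(5, min_mm = 20, max_mm = 10), "smaller")
  fixed <- draw_larvae(50, sd_mm = 0, seed = 1)
  expect_true(all(fixed$length_mm == 15.2))
  coh <- draw_larvae(10000, seed = 12)
  expect_true(all(coh$length_mm >= 9.2 & coh$length_mm <= 24.7))
  expect_lt(abs(mean(coh$length_mm) - 15.2), 0.1)
  expect_lt(abs(sd(coh$length_mm) - 2.6), 0.1)
  expect_equal(length_to_wet_mass(15), 0.02)
  expect_true(all(diff(length_to_wet_mass(c(10, 15, 20, 24))) > 0))
})

test_that("hydrozoa fields integrate to their configured biomass", {
  one <- data.frame(top_m = 0, bottom_m = 200)
  exact <- draw_hydrozoa_field(5, strata = one, mean_integrated_mgC_m2 = 12,
                               cv = 0, seed = 3)
  b <- integrate_station(exact)
  expect_equal(b$biomass_mgC_m2, rep(12, 5), tolerance = 1e-9)
  big <- integrate_station(draw_hydrozoa_field(200, seed = 14))
  expect_lt(abs(mean(big$biomass_mgC_m2) - 16), 2)
  empty <- draw_hydrozoa_field(3, mean_integrated_mgC_m2 = 0, cv = 0, seed = 1)
  expect_equal(integrate_station(empty)$biomass_mgC_m2, rep(0, 3))
  expect_error(draw_hydrozoa_field(3, mean_integrated_mgC_m2 = -1), "non-negative")
})

test_that("FASTA, lineage and count-matrix files round-trip", {
  db <- build_reference_db(2, 2, 1, seq_length = 150, seed = 17)
  f <- tempfile(fileext = ".fasta")
  write_fasta(db$sequences, f)
  expect_identical(read_fasta(f), db$sequences)
  l <- tempfile(fileext = ".tsv")
  write_lineage_tsv(db, l)
  lin <- read_lineage_tsv(l)
  expect_identical(lin$id, db$taxa$id)
  expect_identical(lin$species, db$taxa$species)
  cm <- sample_counts(community_profile(c(P01 = 0.4, P02 = 0.6)), db, 3, 50,
                      seed = 18)
  ctsv <- tempfile(fileext = ".tsv")
  write_counts_tsv(cm$counts, ctsv)
  expect_identical(read_counts_tsv(ctsv), cm$counts)
})
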