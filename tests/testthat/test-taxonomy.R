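test_that("hit scoring ranks references like a brute-force sort", {
  db <- study_reference_db(seed = 2)
  q <- db$sequences[["cru2"]]
  hits <- score_hits(q, db)
  expect_equal(hits$ref_id[1], "cru2")
  expect_equal(hits$identity[1], 1)
  # oracle: sort all pairwise_identity results the same way
  oracle <- do.call(rbind, lapply(seq_len(nrow(db$taxa)), function(i) {
    r <- pairwise_identity(q, db$sequences[[i]])
    data.frame(ref_id = db$taxa$id[i], identity = r$identity,
               coverage = r$coverage)
  }))
  oracle <- oracle[order(-oracle$identity, -oracle$coverage, oracle$ref_id), ]
  expect_equal(hits$ref_id, oracle$ref_id)
  expect_equal(hits$identity, oracle$identity)
  expect_error(score_hits("", db), "non-empty")
})

test_that("identical references tie deterministically by reference id", {
  lin <- study_lineages()[1:2, ]
  s <- random_seq(200, seed = 30)
  db <- ref_db(lin, setNames(c(s, s), lin$id))
  hits <- score_hits(s, db)
  expect_equal(hits$ref_id, sort(lin$id))
  expect_equal(hits$identity, c(1, 1))
})

test_that("assignment applies the criteria conjunction, ties and fallback", {
  db <- tiny_refdb()
  # single passing hit at species level
  a <- assign_taxonomy(score_hits(db$sequences[["b1"]], db))
  expect_equal(a$assigned_rank, "species")
  expect_equal(a$lineage[7], "Limacina_inflata")

  # two congeneric references with identical sequences -> genus-level LCA
  lin <- tiny_refdb()$taxa[1:2, c("id", RANKS)]
  s <- random_seq(200, seed = 31)
  db2 <- ref_db(lin, setNames(c(s, s), lin$id))
  tie <- assign_taxonomy(score_hits(s, db2))
  expect_equal(tie$assigned_rank, "genus")
  expect_equal(tie$n_ties, 2L)
  expect_equal(tie$lineage[6], "Chelophyes")

  # good identity but poor coverage fails the conjunction -> unassigned
  fake <- data.frame(ref_id = "x", identity = 0.96, coverage = 0.90,
                     longest_perfect_run = 300,
                     kingdom = "Animalia", phylum = "Cnidaria",
                     class = "Hydrozoa", order = "Siphonophorae",
                     family = "Diphyidae", genus = "Chelophyes",
                     species = "Chelophyes_appendiculata")
  expect_equal(assign_taxonomy(fake)$assigned_rank, "unassigned")
  expect_length(assign_taxonomy(fake)$lineage, 0)

  # full coverage but sub-criteria identity takes the family-level fallback
  fake2 <- fake; fake2$coverage <- 1; fake2$identity <- 0.9
  fake2$longest_perfect_run <- 60
  fb <- assign_taxonomy(fake2)
  expect_equal(fb$assigned_rank, "family")
  expect_length(fb$lineage, 5)
  expect_equal(assign_taxonomy(fake2, fallback_identity = 1.5)$assigned_rank,
               "unassigned")
})

test_that("lca is the longest shared prefix, associative and order-invariant", {
  l1 <- c("Animalia", "Cnidaria", "Hydrozoa", "Siphonophorae", "Diphyidae",
          "Chelophyes", "Chelophyes_appendiculata")
  l2 <- l1; l2[7] <- "Chelophyes_contorta"
  l3 <- c("Animalia", "Mollusca", "Gastropoda", "Pteropoda", "Limacinidae",
          "Limacina", "Limacina_inflata")
  expect_equal(lca(list(l1)), l1)
  expect_length(lca(list(l1, l2)), 6)
  expect_length(lca(list(l1, l3)), 1)
  expect_error(lca(list()), "at least one")
  set.seed(32)
  for (i in 1:10) {
    perm <- sample(list(l1, l2, l3))
    expect_equal(lca(perm), lca(list(l1, l2, l3)))
    # associativity: lca(lca(a,b), c) == lca(a,b,c)
    expect_equal(lca(list(lca(perm[1:2]), perm[[3]])), lca(perm))
  }
})

test_that("assignments are never deeper than any tied hit's lineage", {
  lin <- study_lineages()[c(1, 2, 5), c("id", RANKS)]
  s <- random_seq(250, seed = 33)
  db <- ref_db(lin, setNames(rep(s, 3), lin$id))
  a <- assign_taxonomy(score_hits(s, db))
  expect_equal(a$n_ties, 3L)
  expect_equal(a$lineage, c("Animalia", "Cnidaria")) # LCA of 2 hydrozoans + 1 anthozoan
  expect_equal(a$assigned_rank, "phylum")
})

test_that("rank aggregation normalizes rows and pools shallow assignments", {
  counts <- matrix(c(10L, 5L, 5L, 0L, 5L, 15L), 3, 2,
                   dimnames = list(NULL, c("s1", "s2")))
  tab <- manual_otu_table(c("ACGT", "ACGA", "ACGC"), counts)
  asg <- data.frame(
    otu_id = rownames(tab$counts),
    assigned_rank = c("species", "species", "species"),
    lineage = c("Animalia;Cnidaria;Hydrozoa;o;f;g;s1",
                "Animalia;Cnidaria;Hydrozoa;o;f;g;s2",
                "Animalia;Mollusca;Gastropoda;o;f;g;s3"))
  comp <- aggregate_by_rank(tab, asg, "phylum")
  expect_equal(unname(rowSums(comp)), c(1, 1))
  expect_equal(comp["s1", "Cnidaria"], 0.75)
  expect_equal(comp["s2", "Mollusca"], 0.75)

  asg$lineage[3] <- "Animalia" # kingdom-only assignment pools as unassigned at phylum
  comp2 <- aggregate_by_rank(tab, asg, "phylum")
  expect_equal(comp2["s2", "unassigned"], 0.75)
  expect_error(aggregate_by_rank(tab, asg, "strain"), "rank must be")

  single <- aggregate_by_rank(tab, within(asg, lineage <-
    rep("Animalia;Cnidaria;Hydrozoa;o;f;g;s", 3)), "phylum")
  expect_equal(unname(single[, "Cnidaria"]), c(1, 1))
})

test_that("noiseless reads recover species and compositions exactly end-to-end", {
  db <- study_reference_db(seed = 2)
  cm <- sample_counts(gut_profile(), db, 5, 400, seed = 40)
  reads <- emit_reads(cm, db, error_rate = 0, host_fraction = 0, seed = 41)
  otus <- greedy_cluster(reads, 0.99)
  asg <- assign_all(otus, db)
  expect_true(all(asg$assigned_rank == "species"))
  expect_true(all(asg$identity == 1))
  # composition equals generator fractions exactly
  comp_counts <- aggregate_by_rank(otus, asg, "species", as = "count")
  species_of <- setNames(db$taxa$species, db$taxa$id)
  truth <- rowsum(cm$counts, species_of[rownames(cm$counts)])
  truth <- truth[rowSums(truth) > 0, , drop = FALSE]
  got <- t(comp_counts)[rownames(truth), colnames(truth)]
  expect_equal(unname(got), unname(truth))
})
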