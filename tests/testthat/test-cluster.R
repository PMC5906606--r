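test_that("greedy clustering handles the elementary cases", {
  a <- random_seq(200, seed = 1)
  same <- greedy_cluster(list(s1 = rep(a, 7)), 0.99)
  expect_equal(nrow(same$counts), 1)
  expect_equal(sum(same$counts), 7)

  b <- mutate_n(a, 20, seed = 2) # 10% diverged
  two <- greedy_cluster(list(s1 = c(rep(a, 5), rep(b, 3))), 0.99)
  expect_equal(nrow(two$counts), 2)

  c1 <- mutate_n(a, 1, seed = 3)
  exact <- greedy_cluster(list(s1 = c(a, a, b, c1)), threshold = 1)
  expect_equal(nrow(exact$counts), 3) # one OTU per distinct sequence

  empty <- greedy_cluster(list(), 0.99)
  expect_equal(nrow(empty$counts), 0)
  expect_error(greedy_cluster(list(s1 = a), threshold = 0), "\\(0, 1\\]")
})

test_that("hamming and alignment paths agree on substitution-only reads", {
  a <- random_seq(150, seed = 4)
  reads <- list(s1 = c(rep(a, 6), rep(mutate_n(a, 1, seed = 5), 3),
                       rep(mutate_n(a, 30, seed = 6), 4)))
  h <- greedy_cluster(reads, 0.99, method = "hamming")
  g <- greedy_cluster(reads, 0.99, method = "align")
  expect_identical(h$counts, g$counts)
  expect_identical(h$centroids, g$centroids)
})

test_that("clustering is invariant to input read order and conserves reads", {
  a <- random_seq(120, seed = 7)
  pool <- c(rep(a, 10), rep(mutate_n(a, 1, seed = 8), 4),
            rep(mutate_n(a, 40, seed = 9), 6),
            rep(mutate_n(a, 41, seed = 10), 2))
  set.seed(11)
  r1 <- list(s1 = pool[1:12], s2 = pool[13:22])
  shuffled <- sample(pool)
  r2 <- list(s1 = shuffled[1:12], s2 = shuffled[13:22])
  o1 <- greedy_cluster(r1, 0.99)
  o2 <- greedy_cluster(r2, 0.99)
  expect_identical(unname(o1$centroids), unname(o2$centroids))
  expect_equal(sum(o1$counts), length(pool))
  expect_equal(rowSums(o1$counts), rowSums(o2$counts))
})

test_that("member bookkeeping is consistent when requested", {
  a <- random_seq(100, seed = 12)
  reads <- list(s1 = setNames(c(a, a, mutate_n(a, 30, seed = 13)),
                              c("r1", "r2", "r3")))
  o <- greedy_cluster(reads, 0.99, keep_members = TRUE)
  expect_equal(sort(unlist(o$members, use.names = FALSE)), c("r1", "r2", "r3"))
  expect_equal(lengths(o$members)[order(names(o$members))],
               rowSums(o$counts)[order(rownames(o$counts))],
               ignore_attr = TRUE)
})

test_that("OTU filtering applies the abundance, host and fish rules", {
  base <- random_seq(300, seed = 14)
  host <- random_seq(300, seed = 15)
  cents <- c(base, mutate_n(base, 60, seed = 16),
             mutate_n(base, 90, seed = 17), mutate_n(base, 120, seed = 18))
  counts <- matrix(c(1L, 8L, 9L, 50L), 4, 1,
                   dimnames = list(NULL, "s1"))
  tab <- manual_otu_table(cents, counts)
  filt <- filter_otus(tab)
  expect_equal(nrow(filt$counts), 2)
  expect_equal(sort(unname(rowSums(filt$counts))), c(9, 50))
  removed <- attr(filt, "removed")
  expect_equal(lengths(removed)[c("singleton", "low_count")], c(singleton = 1L,
                                                               low_count = 1L))
  # idempotence
  again <- filter_otus(filt)
  expect_identical(filt$counts, again$counts)
  expect_identical(filt$centroids, again$centroids)

  # empty table passes through
  emptied <- filter_otus(manual_otu_table(character(0),
                                          matrix(0L, 0, 1,
                                                 dimnames = list(NULL, "s1"))))
  expect_equal(nrow(emptied$counts), 0)

  # host rules: exact host OTU removed; fish OTU at 1% dissimilarity removed;
  # non-fish OTU at the same 1% retained (rule is lineage-conditioned)
  near_host <- mutate_n(host, 3, seed = 19) # 1% of 300 nt
  tab2 <- manual_otu_table(c(host, near_host, near_host),
                           matrix(c(100L, 40L, 40L), 3, 1,
                                  dimnames = list(NULL, "s1")))
  cls <- c(OTU_0001 = "Actinopterygii", OTU_0002 = "Actinopterygii",
           OTU_0003 = "Gastropoda")
  filt2 <- filter_otus(tab2, host_sequence = host, otu_class = cls)
  expect_equal(attr(filt2, "removed")$host, "OTU_0001")
  expect_equal(attr(filt2, "removed")$host_like_fish, "OTU_0002")
  expect_equal(rownames(filt2$counts), "OTU_0003")
})

test_that("fish-lineage lookup against the reference database removes host-like OTUs", {
  db <- study_reference_db(seed = 2)
  host <- db$sequences[db$taxa$is_host][[1]]
  near_host <- mutate_n(host, 3, seed = 20)
  hydro <- db$sequences[["hyd1"]]
  tab <- manual_otu_table(c(near_host, hydro),
                          matrix(c(50L, 50L), 2, 1,
                                 dimnames = list(NULL, "s1")))
  filt <- filter_otus(tab, host_sequence = host, refdb = db)
  expect_equal(attr(filt, "removed")$host_like_fish, "OTU_0001")
  expect_equal(unname(filt$centroids), hydro)
})

test_that("sample depth enforcement drops thin samples and caps deep ones", {
  a <- random_seq(80, seed = 21)
  counts <- matrix(c(500L, 20000L, 5000L), 1, 3,
                   dimnames = list("OTU_0001", c("thin", "deep", "ok")))
  tab <- manual_otu_table(a, counts)
  out <- enforce_sample_depth(tab, min_reads = 1000, cap = 10000, seed = 22)
  expect_equal(attr(out, "dropped_samples"), "thin")
  expect_equal(unname(colSums(out$counts)), c(10000, 5000))
  out2 <- enforce_sample_depth(tab, min_reads = 1000, cap = 10000, seed = 22)
  expect_identical(out$counts, out2$counts)
  expect_error(enforce_sample_depth(tab, min_reads = 2, cap = 1), "exceed")
})

test_that("closed-reference clustering assigns by best reference above threshold", {
  db <- tiny_refdb()
  reads <- list(s1 = c(db$sequences[["a1"]], db$sequences[["a1"]],
                       db$sequences[["b1"]]))
  cm <- closed_reference_cluster(reads, db, 0.97)
  expect_equal(sum(cm$counts), 3)
  expect_equal(attr(cm, "discarded")[["s1"]], 0)
  expect_equal(cm$counts["a1", "s1"], 2)

  far <- mutate_n(db$sequences[["a1"]], 20, seed = 23) # 90% identity
  cm2 <- closed_reference_cluster(list(s1 = far), db, 0.97)
  expect_equal(sum(cm2$counts), 0)
  expect_equal(attr(cm2, "discarded")[["s1"]], 1)
  expect_error(closed_reference_cluster(reads, ref_db(study_lineages()[0, ],
                                                      character(0))),
               "non-empty")
})

test_that("trimming to a common length truncates and drops short reads", {
  out <- trim_to_length(c("ACGTACGT", "ACG", "ACGTA"), 5)
  expect_equal(out, c("ACGTA", "ACGTA"))
})
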