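test_that("median-of-ratios size factors satisfy their defining identities", {
  # two identical samples
  m <- matrix(c(5L, 10L, 3L, 5L, 10L, 3L), 3, 2,
              dimnames = list(paste0("o", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # doubling a sample doubles its factor
  a <- c(4L, 9L, 25L, 2L)
  m2 <- cbind(s1 = a, s2 = 2L * a)
  s <- size_factors(m2)
  expect_equal(unname(s["s2"] / s["s1"]), 2)

  # hand-computed 3x3 case
  m3 <- rbind(c(2, 4, 8), c(3, 9, 3), c(5, 10, 20))
  colnames(m3) <- c("s1", "s2", "s3")
  expect_equal(unname(size_factors(m3)), c(0.5, 1, 2))

  # error state: no all-positive OTU
  m4 <- rbind(c(0, 5), c(5, 0))
  colnames(m4) <- c("s1", "s2")
  expect_error(size_factors(m4), "no OTU is positive in every sample")
  # but the zero-robust variant is defined there
  expect_length(size_factors(m4, "poscounts"), 2)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(50)
  m <- matrix(rpois(200, lambda = 50) + 1L, 20, 10)
  colnames(m) <- paste0("s", 1:10)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("poscounts factors keep the scaling identity", {
  set.seed(51)
  a <- rpois(30, 20); a[sample(30, 8)] <- 0
  m <- cbind(s1 = a, s2 = 2 * a, s3 = a + (a > 0))
  s <- size_factors(m, "poscounts")
  expect_equal(unname(s["s2"] / s["s1"]), 2, tolerance = 1e-12)
})

test_that("PCA conserves variance and recovers eigenstructure", {
  set.seed(52)
  m <- matrix(rpois(600, 30), 30, 20)
  dimnames(m) <- list(paste0("o", 1:30), paste0("s", 1:20))
  sf <- size_factors(m, "poscounts")
  ord <- count_pca(m, sf)
  x <- t(log(sweep(m, 2, sf, "/") + 1))
  total_var <- sum(apply(x, 2, var))
  expect_lt(abs(sum(ord$sdev^2) - total_var), 1e-8)
  expect_equal(sum(ord$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(ord$variance_fraction) <= 1e-12))
  expect_true(all(abs(colMeans(ord$scores)) < 1e-10))

  # eigendecomposition oracle
  ev <- eigen(cov(x), symmetric = TRUE)
  k <- min(nrow(x) - 1, ncol(x))
  expect_equal(ord$sdev[1:k]^2, ev$values[1:k], tolerance = 1e-8)
  xc <- scale(x, center = TRUE, scale = FALSE)
  for (c_ in 1:3) {
    proj <- xc %*% ev$vectors[, c_]
    expect_equal(abs(drop(proj)), abs(ord$scores[, c_]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # rank-1 construction: first component captures essentially everything
  b <- seq(1, 3, length.out = 10); a_ <- runif(6)
  r1 <- exp(t(outer(b, a_))) - 1 # features x samples, log(x+1) = outer(a,b)
  colnames(r1) <- paste0("s", 1:10)
  ord1 <- count_pca(r1, sf = rep(1, 10))
  expect_gt(ord1$variance_fraction[1], 0.999)
  expect_error(count_pca(m[, 1, drop = FALSE]), "2 samples")
})

test_that("Holm adjustment matches its hand-applied definition", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  set.seed(53)
  for (i in 1:200) {
    p <- runif(sample(1:10, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, bf_holm(p))
    expect_equal(adj, p.adjust(p, "holm"))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("threshold prevalence counts strict exceedances", {
  comp <- rbind(c(0.004, 0.996), c(0.006, 0.994), c(0.3, 0.7), c(0.0, 1.0))
  colnames(comp) <- c("Cyanobacteria", "other")
  expect_equal(threshold_prevalence(comp, "Cyanobacteria", 0.005), 50)
  expect_equal(threshold_prevalence(comp, "other", 0), 100)
  zero <- comp; zero[, "Cyanobacteria"] <- 0
  expect_equal(threshold_prevalence(zero, "Cyanobacteria", 0.005), 0)
  expect_error(threshold_prevalence(comp, "Firmicutes", 0.1), "unknown group")
  expect_error(threshold_prevalence(comp, "other", 1), "\\[0, 1\\)")
})

test_that("the NB permutation test separates distinct communities and is label-symmetric", {
  db <- study_reference_db(seed = 2)
  gut <- sample_counts(gut_profile(), db, 8, 2000, seed = 54)
  snow <- sample_counts(snow_profile(), db, 8, 2000, seed = 55)
  m <- cbind(gut$counts, snow$counts)
  grp <- rep(c("gut", "snow"), each = 8)
  sf <- size_factors(m, "poscounts")
  res <- mv_nb_test(m, grp, n_perm = 99, seed = 56, sf = sf)
  expect_equal(res$p_global, 1 / 100) # minimum attainable
  expect_true(all(res$table$statistic >= 0))
  expect_true(all(res$table$p_holm >= res$table$p))
  expect_true(all(res$table$p >= 1 / 100 & res$table$p <= 1))

  flipped <- mv_nb_test(m, rep(c("snow", "gut"), each = 8), n_perm = 99,
                        seed = 56, sf = sf)
  expect_equal(res$p_global, flipped$p_global)
  expect_equal(res$global_stat, flipped$global_stat)

  expect_error(mv_nb_test(m, rep("gut", 16), sf = sf), "2 groups")
  expect_error(mv_nb_test(m[, 1:5], c("a", "a", "a", "b", "b"), sf = sf[1:5]),
               "at least 3")
  expect_error(mv_nb_test(m, grp, n_perm = 50, sf = sf), ">= 99")
})
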