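#' Median-of-ratios size factors
#'
#' The standard median-of-ratios normalization for overdispersed count
#' matrices: per feature, a geometric mean across samples is computed; the
#' size factor of sample j is the median over reference features of
#' count_ij / geomean_i. With `type = "ratio"` (the classic estimator) the
#' reference features are those with a positive count in every sample, and
#' the estimator is undefined — an error — when none exists. With
#' `type = "poscounts"` the geometric mean is taken over positive counts
#' only (zeros counted in the denominator), every feature with a positive
#' geometric mean is a reference, ratios are taken where the count is
#' positive, and factors are rescaled to geometric mean 1; this variant is
#' defined for the zero-rich tables typical of metabarcoding data.
#'
#' @param counts integer matrix, features x samples (or an `otu_table` /
#'   `count_matrix`).
#' @param type "ratio" or "poscounts".
#' @return named numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(counts, type = c("ratio", "poscounts")) {
  type <- match.arg(type)
  m <- if (inherits(counts, "otu_table")) counts$counts else as_count_matrix(counts)
  if (ncol(m) < 2) stop("size factors need at least 2 samples")
  if (type == "ratio") {
    ref <- rowSums(m > 0) == ncol(m)
    if (!any(ref))
      stop("normalization failure: no OTU is positive in every sample, so ",
           "median-of-ratios size factors are undefined (consider type = ",
           "\"poscounts\")")
    lgm <- rowMeans(log(m[ref, , drop = FALSE]))
    # median taken on the log scale (geometric interpolation for even counts)
    s <- exp(apply(log(m[ref, , drop = FALSE]) - lgm, 2, median))
  } else {
    lg <- log(m)
    lg[!is.finite(lg)] <- 0
    gm <- exp(rowSums(lg) / ncol(m))
    ref <- gm > 0 & rowSums(m > 0) > 0
    if (!any(ref)) stop("normalization failure: all-zero count matrix")
    s <- vapply(seq_len(ncol(m)), function(j) {
      r <- log(m[ref, j]) - log(gm[ref])
      exp(median(r[m[ref, j] > 0]))
    }, numeric(1))
    s <- s / exp(mean(log(s)))
  }
  if (any(!is.finite(s) | s <= 0))
    stop("normalization failure: non-positive size factor")
  names(s) <- colnames(m)
  s
}

#' Principal component analysis of normalized counts
#'
#' Counts are transformed to log(count / size_factor + 1), columns (features)
#' are centred, and the matrix is decomposed by singular values. Components
#' are ordered by variance; variance fractions are reported relative to the
#' total variance of the transformed matrix.
#'
#' @param counts features x samples matrix (or `otu_table` / `count_matrix`).
#' @param sf per-sample size factors; computed with
#'   `size_factors(counts, "poscounts")` when omitted.
#' @return list of class `ordination` with `scores` (samples x components,
#'   zero column means), `variance_fraction`, `loadings` and `sdev`.
#' @export
count_pca <- function(counts, sf = NULL) {
  m <- if (inherits(counts, "otu_table")) counts$counts else as_count_matrix(counts)
  if (ncol(m) < 2) stop("PCA needs at least 2 samples")
  if (is.null(sf)) sf <- size_factors(m, "poscounts")
  x <- t(log(sweep(m, 2, sf, "/") + 1))
  if (any(!is.finite(x))) stop("normalized matrix must be finite")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(scores = p$x,
                 variance_fraction = p$sdev^2 / sum(p$sdev^2),
                 loadings = p$rotation, sdev = p$sdev),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  vf <- round(100 * x$variance_fraction[1:min(3, length(x$variance_fraction))], 1)
  cat(sprintf("ordination of %d samples; leading components explain %s%% \n",
              nrow(x$scores), paste(vf, collapse = " / ")))
  invisible(x)
}

#' Multivariate negative-binomial permutation test
#'
#' Tests for a compositional difference between two groups of samples, in
#' the spirit of multivariate GLM analyses of abundance tables. Per OTU, an
#' intercept-only negative-binomial regression (log link, offset log s_j,
#' per-OTU dispersion estimated by method-of-moments on normalized counts
#' and floored at 1e-8, i.e. the Poisson limit) is compared with a two-group
#' model by a likelihood-ratio statistic; the global statistic is the sum
#' over OTUs. The null distribution comes from permuting group labels:
#' p = (1 + #permutations with statistic >= observed) / (1 + n_perm).
#' Per-OTU p-values use the same permutations and are Holm-adjusted.
#' Dispersions are estimated without reference to the labels, so they are
#' permutation-invariant and the test is exact under exchangeability.
#'
#' @param counts features x samples matrix (or `otu_table` / `count_matrix`).
#' @param groups factor (or coercible) with exactly 2 levels, each with at
#'   least 3 samples.
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @param sf optional per-sample size factors; defaults to the strict
#'   median-of-ratios estimator of [size_factors()] (which errors on tables
#'   with no all-positive OTU — pass poscounts factors for those).
#' @return list of class `mv_nb_test`: `global_stat`, `p_global`, `table`
#'   (per-OTU statistic, raw and Holm-adjusted p-values), `n_perm`, `seed`.
#' @export
mv_nb_test <- function(counts, groups, n_perm = 999, seed = 1, sf = NULL) {
  m <- if (inherits(counts, "otu_table")) counts$counts else as_count_matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly 2 groups are required")
  if (length(groups) != ncol(m))
    stop("groups must have one label per sample")
  if (any(table(groups) < 3)) stop("each group needs at least 3 samples")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (is.null(sf)) sf <- size_factors(m)
  g <- as.integer(groups) - 1L
  z <- sweep(m, 2, sf, "/")
  mu <- rowMeans(z)
  v <- apply(z, 1, var)
  disp <- pmax((v - mu) / pmax(mu^2, 1e-300), 1e-8)
  perms <- with_seed(seed, {
    t(replicate(n_perm, sample(g)))
  })
  res <- cpp_nb_lr(m, unname(sf), g, perms, disp)
  p_global <- (1 + sum(res$perm_sums >= res$obs_sum - 1e-12)) / (1 + n_perm)
  p_otu <- (1 + res$exceed) / (1 + n_perm)
  tab <- data.frame(otu_id = rownames(m) %||% paste0("f", seq_len(nrow(m))),
                    statistic = res$obs, p = p_otu,
                    p_holm = holm_adjust(p_otu))
  rownames(tab) <- NULL
  structure(list(global_stat = res$obs_sum, p_global = p_global, table = tab,
                 n_perm = n_perm, seed = seed), class = "mv_nb_test")
}

#' @export
print.mv_nb_test <- function(x, ...) {
  cat(sprintf(
    "multivariate NB permutation test: LR = %.2f, p = %.4g (%d permutations)\n",
    x$global_stat, x$p_global, x$n_perm))
  sig <- sum(x$table$p_holm <= 0.05)
  cat(sprintf("%d of %d OTUs significant at Holm-adjusted p <= 0.05\n",
              sig, nrow(x$table)))
  invisible(x)
}

#' Holm stepdown adjustment
#'
#' Classic stepdown familywise-error control: sort the p-values increasingly,
#' multiply the i-th by (n - i + 1), enforce monotonicity by a running
#' maximum, and cap at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the original order; elementwise >= `p`.
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  adj <- pmin(cummax((n - seq_len(n) + 1) * p[o]), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Prevalence of a group above a compositional threshold
#'
#' The percentage of samples in which a taxonomic group accounts for
#' strictly more than `threshold` of the reads — the summary used for, e.g.,
#' "proportion of samples where Cyanobacteria account for >0.5% of reads".
#'
#' @param composition samples x groups fraction matrix (rows sum to 1), as
#'   from [aggregate_by_rank()].
#' @param group_label column to summarize.
#' @param threshold fraction in [0, 1).
#' @return percentage of samples in [0, 100].
#' @export
threshold_prevalence <- function(composition, group_label, threshold) {
  if (!(threshold >= 0 && threshold < 1)) stop("threshold must be in [0, 1)")
  if (!group_label %in% colnames(composition))
    stop("unknown group label: ", group_label)
  100 * mean(composition[, group_label] > threshold)
}
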