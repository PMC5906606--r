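#' Simulate a leptocephalus length cohort
#'
#' Lengths are drawn from a truncated normal on `[min_mm, max_mm]` whose
#' parent parameters are moment-matched so that the *truncated* distribution
#' has mean `mean_mm` and standard deviation `sd_mm` (the reported cohort
#' statistics are sample moments of truncated data). Wet mass follows the
#' isometric power law W = c L^3 with c fixed by the anchor point
#' 15 mm -> 0.02 g.
#'
#' @param n cohort size (>= 1).
#' @param mean_mm,sd_mm target mean and standard deviation of length (mm);
#'   defaults 15.2 and 2.6.
#' @param min_mm,max_mm truncation bounds (mm); defaults 9.2 and 24.7.
#' @param n_stations stations to assign larvae to (round-robin labels only).
#' @param seed integer seed.
#' @return data.frame with columns `length_mm`, `wet_mass_g`, `station`.
#' @export
draw_larvae <- function(n, mean_mm = 15.2, sd_mm = 2.6, min_mm = 9.2,
                        max_mm = 24.7, n_stations = 5, seed = 1) {
  if (n < 1) stop("cohort size must be >= 1")
  if (!(min_mm < max_mm)) stop("min_mm must be smaller than max_mm")
  if (sd_mm < 0) stop("sd_mm must be non-negative")
  if (mean_mm <= min_mm || mean_mm >= max_mm)
    stop("mean_mm must lie inside the truncation bounds")
  lengths <- with_seed(seed, {
    if (sd_mm == 0) rep(mean_mm, n)
    else {
      par <- truncnorm_match(mean_mm, sd_mm, min_mm, max_mm)
      lo <- pnorm(min_mm, par[1], par[2])
      hi <- pnorm(max_mm, par[1], par[2])
      qnorm(lo + runif(n) * (hi - lo), par[1], par[2])
    }
  })
  data.frame(length_mm = lengths,
             wet_mass_g = length_to_wet_mass(lengths),
             station = sprintf("st%02d", 1 + (seq_len(n) - 1) %% n_stations))
}

# mean/sd of a normal(mu, sigma) truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  dz <- dnorm(al) - dnorm(be)
  m <- mu + sigma * dz / z
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z - (dz / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# solve for parent (mu, sigma) whose truncated moments hit the targets
truncnorm_match <- function(mean_t, sd_t, a, b) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), a, b)
    (mo[1] - mean_t)^2 + (mo[2] - sd_t)^2
  }
  fit <- stats::optim(c(mean_t, log(sd_t)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(fit$par[1], exp(fit$par[2]))
}

#' Length to wet mass for leptocephali
#'
#' Isometric scaling W = c L^3 with the coefficient fixed so a 15 mm larva
#' weighs 0.02 g wet mass.
#'
#' @param length_mm length in mm (> 0).
#' @param coef coefficient c in g mm^-3; default 0.02 / 15^3.
#' @return wet mass in g.
#' @export
length_to_wet_mass <- function(length_mm, coef = 0.02 / 15^3) {
  if (any(length_mm <= 0)) stop("length must be positive")
  coef * length_mm^3
}

#' @importFrom stats dnorm pbeta qbeta
NULL
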