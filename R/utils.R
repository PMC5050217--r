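# Internal helpers shared across modules.

# All infection timing arithmetic goes through these two converters so the
# hours-vs-days convention (draw/admission in hours since injury, infection
# records in fractional days since injury) lives in exactly one place.
days_to_hours <- function(days) days * 24
hours_to_days <- function(hours) hours / 24

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated normal sampler by inverse-CDF; support [lo, hi].
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-10) {
    stop("infeasible truncation: mean ", mean, " with sd ", sd,
         " has essentially no mass on [", lo, ", ", hi, "]")
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Mean and SD of a normal(mu, sd) truncated to [lo, hi].
truncnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sd * (da - db) / Z
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying normal parameters such that the [lo, hi]-truncated normal has
# the requested mean and SD (so configured group moments are recovered in
# the sample, not shifted by the truncation).
truncnorm_match <- function(mean, sd, lo, hi) {
  if (mean <= lo || (is.finite(hi) && mean >= hi)) {
    stop("infeasible truncation: target mean ", mean,
         " outside the open support (", lo, ", ", hi, ")")
  }
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (m[["mean"]] - mean)^2 / sd^2 + (m[["sd"]] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sd = exp(fit$par[2]), objective = fit$value)
}

# Truncated normal sample whose post-truncation moments match (mean, sd)
# where feasible; falls back to nominal parameters when the target SD is
# not achievable on the support.
rtruncnorm_matched <- function(n, mean, sd, lo, hi) {
  par <- truncnorm_match(mean, sd, lo, hi)
  if (par[["objective"]] > 1e-4) {
    return(rtruncnorm(n, mean, sd, lo, hi))
  }
  rtruncnorm(n, par[["mu"]], par[["sd"]], lo, hi)
}

# Log-normal parameters (meanlog, sdlog) matching a target mean and SD.
lognormal_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Sample standard error of the mean.
se_mean <- function(x) stats::sd(x) / sqrt(length(x))

assert_flag_vec <- function(x, name) {
  if (!is.logical(x) || anyNA(x)) {
    stop("'", name, "' must be a logical vector without missing values")
  }
  invisible(x)
}
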