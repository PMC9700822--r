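# Core probability model: process model, route-count (BBS-style) observation
# model, checklist (eBird-style) observation model, priors.
#
# Convention used throughout the package: every dispersion parameter named
# sigma_* or tau_* is a VARIANCE (the model's hierarchy writes N(mean, variance)),
# with InvGamma(0.01, 0.01) priors; the fixed hyperpriors on mean parameters
# ("standard deviation 10") are N(0, variance 100).

# Effective area surveyed by one BBS-style route: 50 stops, each a 3-minute
# point count with a 400-m detection radius; 50 * pi * 0.4^2 = 25.13 km^2,
# rounded to 25 km^2 in the offset.
.route_area_exact <- function() 50 * pi * 0.4^2

#' Survey-geometry constants
#'
#' `effective_route_area()` returns the effective area surveyed by one
#' 50-stop roadside route (each stop a point count with a 400-m radius),
#' rounded to the whole-km^2 value used in the model offset;
#' `cell_area_km2()` returns the area of one square grid cell.
#'
#' @param rounded If `TRUE` (default) return the rounded 25 km^2 used in the
#'   offset; otherwise the exact `50 * pi * 0.4^2`.
#' @param cell_size_km Grid-cell side length in km (default 111).
#' @return A single number (km^2).
#' @examples
#' effective_route_area()        # 25
#' cell_area_km2()               # 12321
#' log(effective_route_area() / cell_area_km2())  # the offset, about -6.2002
#' @export
effective_route_area <- function(rounded = TRUE) {
  if (rounded) round(.route_area_exact()) else .route_area_exact()
}

#' @rdname effective_route_area
#' @export
cell_area_km2 <- function(cell_size_km = 111) {
  stopifnot(cell_size_km > 0)
  cell_size_km^2
}

#' Log of the route-to-cell area offset
#'
#' The route observation model offsets cell-level relative abundance by the
#' ratio of effective route area (25 km^2) to grid-cell area (12,321 km^2),
#' so that `gamma` is interpreted on the grid-cell scale.
#'
#' @return `log(25/12321)`, about -6.2002.
#' @export
bbs_offset <- function() log(effective_route_area() / cell_area_km2())

#' Center years at the study-period midpoint
#'
#' Returns `year - (min + max)/2` so that the midpoint of the study period is
#' 0 (e.g. 2010--2019 maps to -4.5 ... 4.5, with 0 falling between 2014 and
#' 2015). With centered years, `exp(alpha)` is the mean relative abundance
#' over the study period and `beta` the trend of log relative abundance.
#'
#' @param years Integer (or numeric) vector of at least 2 distinct years.
#' @return Numeric vector of centered years, same length and order.
#' @examples
#' center_years(2010:2019)
#' @export
center_years <- function(years) {
  if (length(years) == 0) stop("empty year set")
  if (length(unique(years)) < 2) stop("need at least 2 distinct years")
  years - (min(years) + max(years)) / 2
}

#' Process-model mean of log relative abundance
#'
#' `mu_gamma = alpha + beta * year_c`, the linear-in-time mean of
#' `log(gamma)` for one cell. Vectorized over all arguments.
#'
#' @param alpha Cell intercept (log mean relative abundance).
#' @param beta Cell slope (trend of log relative abundance per year).
#' @param year_c Centered year (see [center_years()]).
#' @return `alpha + beta * year_c`.
#' @export
process_mean <- function(alpha, beta, year_c) alpha + beta * year_c

#' Log-density of log year-specific relative abundance
#'
#' Normal log-density of `log(gamma)` around the process mean with variance
#' `sigma_gamma` (the overdispersion of year-specific relative abundance).
#'
#' @param log_gamma Value of `log(gamma)` at which to evaluate.
#' @param mu Process mean (see [process_mean()]).
#' @param sigma_gamma Variance (not sd) of the Gaussian year noise; > 0.
#' @return Log-density (vectorized).
#' @export
log_gamma_density <- function(log_gamma, mu, sigma_gamma) {
  if (any(sigma_gamma <= 0)) stop("sigma_gamma must be a positive variance")
  dnorm(log_gamma, mu, sqrt(sigma_gamma), log = TRUE)
}

# InvGamma(shape a, rate b) log-density at variance v.
.dinvgamma_log <- function(v, a = 0.01, b = 0.01) {
  if (any(v <= 0)) stop("variance must be positive")
  a * log(b) - lgamma(a) - (a + 1) * log(v) - b / v
}

#' Log-density of the process-model hierarchy
#'
#' Sums the hierarchical Normal terms for cell intercepts and slopes around
#' their ecoregion (BCR) means, the BCR means around the grand means, the
#' fixed N(0, 100) hyperpriors on the grand means (sd 10), and
#' InvGamma(0.01, 0.01) priors on each of the five variances.
#'
#' @param params A parameter list with elements `alpha`, `beta` (per cell),
#'   `mu_alpha_bcr`, `mu_beta_bcr` (per BCR), `mu_alpha`, `mu_beta` (grand
#'   means), variances `sigma_alpha`, `sigma_beta`, `tau_alpha`, `tau_beta`,
#'   `sigma_gamma`, and the integer vector `bcr` giving each cell's BCR index.
#' @return Scalar log-density.
#' @export
hierarchy_log_density <- function(params) {
  p <- params
  vs <- c(p$sigma_alpha, p$sigma_beta, p$tau_alpha, p$tau_beta, p$sigma_gamma)
  if (any(vs <= 0)) stop("all variance parameters must be positive")
  k <- p$bcr
  sum(dnorm(p$alpha, p$mu_alpha_bcr[k], sqrt(p$sigma_alpha), log = TRUE)) +
    sum(dnorm(p$beta, p$mu_beta_bcr[k], sqrt(p$sigma_beta), log = TRUE)) +
    sum(dnorm(p$mu_alpha_bcr, p$mu_alpha, sqrt(p$tau_alpha), log = TRUE)) +
    sum(dnorm(p$mu_beta_bcr, p$mu_beta, sqrt(p$tau_beta), log = TRUE)) +
    dnorm(p$mu_alpha, 0, 10, log = TRUE) +
    dnorm(p$mu_beta, 0, 10, log = TRUE) +
    sum(.dinvgamma_log(vs))
}

#' Log intensity of a route count
#'
#' `log(lambda) = log(gamma) + log(25/12321) + eps + eta * I`: cell relative
#' abundance scaled by the effective-area offset, plus a route-by-observer
#' random effect and a first-year observer effect.
#'
#' @param log_gamma Log year-specific relative abundance of the record's
#'   cell-year.
#' @param eps Route-by-observer random effect.
#' @param eta First-year observer effect.
#' @param first_year 0/1 indicator for the observer's first survey year.
#' @return Log expected count (vectorized).
#' @export
bbs_log_intensity <- function(log_gamma, eps = 0, eta = 0, first_year = 0) {
  stopifnot(all(first_year %in% c(0, 1)))
  log_gamma + bbs_offset() + eps + eta * first_year
}

#' Log intensity of a checklist count
#'
#' `log(lambda) = log(gamma) + b0 + b1*TYPE + b2*DIST + b3*COSTIME +
#' b4*SINTIME + b5*DURA + b6*NOOB + eps`. `b0` is the free scaling intercept
#' relating checklist-level counts to cell-level relative abundance (the
#' effective area of a checklist is unknown); `eps` is an observer random
#' effect.
#'
#' @param log_gamma Log year-specific relative abundance of the record's
#'   cell-year.
#' @param b Numeric vector of length 7: the scaling intercept `b0` followed
#'   by the effort coefficients `b1..b6`.
#' @param type 1 for a stationary point count, 0 for a travelling transect.
#' @param dist Distance travelled (km; 0 for stationary counts).
#' @param costime,sintime Solar-time-of-day covariates
#'   (see [solar_time_covariates()]).
#' @param dura Survey duration (minutes, or any documented working scale).
#' @param noob Number of observers.
#' @param eps Observer random effect.
#' @return Log expected count (vectorized over records).
#' @export
ebird_log_intensity <- function(log_gamma, b, type, dist, costime, sintime,
                                dura, noob, eps = 0) {
  stopifnot(length(b) == 7)
  log_gamma + b[1] + b[2] * type + b[3] * dist + b[4] * costime +
    b[5] * sintime + b[6] * dura + b[7] * noob + eps
}

#' Zero-inflated Poisson log-probability
#'
#' Marginalized over the latent structural-zero indicator `z ~ Bernoulli(omega)`:
#' `P(y=0) = omega + (1-omega) exp(-lambda)`; for `y > 0`,
#' `P(y) = (1-omega) * Poisson(y; lambda)`. Computed on the log scale with a
#' numerically stable log-sum-exp for the zero branch.
#'
#' @param y Non-negative integer count(s).
#' @param lambda Poisson intensity, > 0.
#' @param omega Structural-zero probability in \[0, 1\].
#' @return Log-probability (vectorized; `-Inf` where the outcome is impossible).
#' @examples
#' zip_log_pmf(0, 1, 0.5)  # log(0.5 + 0.5 * exp(-1))
#' zip_log_pmf(3, 2, 0)    # dpois(3, 2, log = TRUE)
#' @export
zip_log_pmf <- function(y, lambda, omega) {
  n <- max(length(y), length(lambda), length(omega))
  y <- rep_len(y, n); lambda <- rep_len(lambda, n); omega <- rep_len(omega, n)
  if (any(y < 0) || any(y != floor(y))) stop("y must be non-negative integers")
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(omega < 0 | omega > 1)) stop("omega must lie in [0, 1]")
  out <- numeric(n)
  z0 <- y == 0
  if (any(z0)) {
    # log(omega + (1-omega) e^{-lambda}) via log-sum-exp; handles omega in {0,1}
    # m is always finite: omega = 0 gives b = -lambda, omega = 1 gives a = 0
    a <- log(omega[z0]); b <- log1p(-omega[z0]) - lambda[z0]
    m <- pmax(a, b)
    out[z0] <- m + log(exp(a - m) + exp(b - m))
  }
  if (any(!z0)) {
    out[!z0] <- log1p(-omega[!z0]) + dpois(y[!z0], lambda[!z0], log = TRUE)
  }
  out
}

#' Joint log-posterior of the BBS-only or joint model
#'
#' Evaluates, up to nothing (all constants included), the sum of the
#' process-model hierarchy, the log-density of every `log(gamma)`, the
#' zero-inflated Poisson log-probability of every route count, and -- for the
#' joint model -- every checklist count plus the checklist observation-model
#' priors (N(0, 100) on `b0..b6`, N(0, sigma_ebird) on the observer effects,
#' InvGamma(0.01, 0.01) on `sigma_ebird`, flat U(0,1) on `omega_ebird`).
#' The BBS observation-model priors (N(0, sigma_bbs) on the route-by-observer
#' effects, InvGamma on `sigma_bbs`, N(0, 100) on `eta`, U(0,1) on
#' `omega_bbs`) are always included. This function defines the target
#' distribution that [fit_abundance()] samples from.
#'
#' @param data A model-data object from [abund_model_data()].
#' @param params Parameter list; see [hierarchy_log_density()] for the process
#'   block, plus `log_gamma` (cell x year matrix), `eps_bbs` (per
#'   route-by-observer pair), `eta`, `sigma_bbs`, `omega_bbs`, and for the
#'   joint model `b` (length 7), `eps_ebird` (per observer), `sigma_ebird`,
#'   `omega_ebird`.
#' @param model `"bbs"` or `"joint"`.
#' @return Scalar log-posterior density.
#' @export
joint_log_posterior <- function(data, params, model = c("joint", "bbs")) {
  model <- match.arg(model)
  p <- params
  d <- data
  need <- c("alpha", "beta", "mu_alpha_bcr", "mu_beta_bcr", "mu_alpha",
            "mu_beta", "sigma_alpha", "sigma_beta", "tau_alpha", "tau_beta",
            "sigma_gamma", "log_gamma", "eps_bbs", "eta", "sigma_bbs",
            "omega_bbs")
  if (model == "joint")
    need <- c(need, "b", "eps_ebird", "sigma_ebird", "omega_ebird")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing parameter blocks for the ", model, " model: ",
         paste(miss, collapse = ", "))
  p$bcr <- d$bcr
  lp <- hierarchy_log_density(p)
  mu <- outer(p$alpha, rep(1, d$n_years)) + outer(p$beta, d$year_c)
  lp <- lp + sum(log_gamma_density(p$log_gamma, mu, p$sigma_gamma))
  # BBS stream
  if (p$sigma_bbs <= 0) stop("sigma_bbs must be a positive variance")
  lp <- lp + sum(dnorm(p$eps_bbs, 0, sqrt(p$sigma_bbs), log = TRUE)) +
    .dinvgamma_log(p$sigma_bbs) + dnorm(p$eta, 0, 10, log = TRUE)
  if (p$omega_bbs < 0 || p$omega_bbs > 1) stop("omega_bbs outside [0, 1]")
  if (d$bbs$n > 0) {
    lg <- p$log_gamma[cbind(d$bbs$cell, d$bbs$year)]
    ll <- bbs_log_intensity(lg, p$eps_bbs[d$bbs$pair], p$eta, d$bbs$first_year)
    lp <- lp + sum(zip_log_pmf(d$bbs$y, exp(ll), p$omega_bbs))
  }
  if (model == "joint") {
    if (p$sigma_ebird <= 0) stop("sigma_ebird must be a positive variance")
    lp <- lp + sum(dnorm(p$eps_ebird, 0, sqrt(p$sigma_ebird), log = TRUE)) +
      .dinvgamma_log(p$sigma_ebird) + sum(dnorm(p$b, 0, 10, log = TRUE))
    if (p$omega_ebird < 0 || p$omega_ebird > 1) stop("omega_ebird outside [0, 1]")
    if (d$ebird$n > 0) {
      lg <- p$log_gamma[cbind(d$ebird$cell, d$ebird$year)]
      X <- d$ebird$X
      ll <- ebird_log_intensity(lg, p$b, X[, 1], X[, 2], X[, 3], X[, 4],
                                X[, 5], X[, 6], p$eps_ebird[d$ebird$obs])
      lp <- lp + sum(zip_log_pmf(d$ebird$y, exp(ll), p$omega_ebird))
    }
  }
  lp
}
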