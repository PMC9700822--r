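# Model fitting: data indexing, initialization, the Gibbs sampler driver,
# and the "abund_fit" S3 class with its methods.

#' MCMC settings
#'
#' Defaults are conservative: 3 chains, 9000 iterations, 5000 burn-in, no
#' thinning (at least 4000 retained draws per chain). The
#' `"test"` profile (3 x 1500 iterations, 500 burn-in) is a fast setting for
#' development-scale runs.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations discarded per chain; < `n_iter`.
#' @param thin Thinning interval (must divide `n_iter - n_burnin`).
#' @param seed Integer seed; chain `c` uses `seed * 1e6 + c`.
#' @param profile `"full"` (the defaults) or `"test"` (1500/500).
#' @return A list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_chains = 3, n_iter = 9000, n_burnin = 5000,
                         thin = 1, seed = 1, profile = c("full", "test")) {
  profile <- match.arg(profile)
  if (profile == "test" && missing(n_iter) && missing(n_burnin)) {
    n_iter <- 1500; n_burnin <- 500
  }
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  if (n_chains < 1) stop("need at least one chain")
  if ((n_iter - n_burnin) %% thin != 0)
    stop("thin must divide n_iter - n_burnin")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Index survey records against the model's cells and years
#'
#' Builds the internal model-data structure: cells are the grid's in-range
#' cells (all cells if no `in_range` column), each with a BCR; records are
#' indexed to cell and year, route records to route-by-observer pairs and
#' checklist records to observers. Checklist effort covariates are assembled
#' with [effort_covariates()]; by default the continuous ones (DIST, DURA,
#' NOOB) are centered and scaled to unit variance (the transform is stored
#' for back-conversion of coefficients).
#'
#' @param bbs Route-count records: `cell_id` (or `x_km`/`y_km`), `route_id`,
#'   `observer_id`, `year`, `species_count`, `first_year` (0/1; see
#'   [flag_first_year()]).
#' @param ebird Optional checklist records: `cell_id` (or `x_km`/`y_km`),
#'   `observer_id`, `year`, `species_count` and the effort fields of
#'   [effort_covariates()].
#' @param grid An `"abund_grid"` with `bcr_id` (and optionally `in_range`).
#' @param years Study years; default `sort(unique())` of the record years.
#' @param scale_covariates Center/scale DIST, DURA, NOOB? (default `TRUE`).
#' @return A list of class `"abund_model_data"`.
#' @export
abund_model_data <- function(bbs, ebird = NULL, grid, years = NULL,
                             scale_covariates = TRUE) {
  cells <- if (!is.null(grid$in_range)) grid[grid$in_range, , drop = FALSE]
    else grid
  if (is.null(cells$bcr_id) || any(is.na(cells$bcr_id)))
    stop("every modelled cell needs a bcr_id (see assign_bcr)")
  if (is.null(years))
    years <- sort(unique(c(bbs$year, if (!is.null(ebird)) ebird$year)))
  year_c <- center_years(years)
  bcr_levels <- sort(unique(cells$bcr_id))
  bcr <- match(cells$bcr_id, bcr_levels)
  locate <- function(d, what) {
    if (is.null(d$cell_id)) d$cell_id <- assign_cells(d$x_km, d$y_km, grid)
    ci <- match(d$cell_id, cells$cell_id)
    if (any(is.na(ci)))
      stop(what, " records fall in cells outside the modelled set")
    ti <- match(d$year, years)
    if (any(is.na(ti))) stop(what, " records outside the study years")
    list(cell = ci, year = ti)
  }
  ix <- locate(bbs, "route")
  if (is.null(bbs$first_year))
    stop("route records need a first_year flag (see flag_first_year)")
  pair_lab <- paste(bbs$route_id, bbs$observer_id, sep = ":")
  pairs <- unique(pair_lab)
  bbs_d <- list(n = nrow(bbs), cell = ix$cell, year = ix$year,
                pair = match(pair_lab, pairs),
                first_year = as.integer(bbs$first_year),
                y = as.integer(bbs$species_count), pair_labels = pairs)
  ebird_d <- list(n = 0L)
  if (!is.null(ebird)) {
    scaling <- NULL
    if (nrow(ebird) > 0) {
      ix_e <- locate(ebird, "checklist")
      X <- effort_covariates(ebird)
      scaling <- list(center = c(0, 0, 0, 0, 0, 0), scale = rep(1, 6))
      names(scaling$center) <- names(scaling$scale) <- colnames(X)
      if (scale_covariates) {
        for (j in c(2, 5, 6)) {  # DIST, DURA, NOOB
          mu <- mean(X[, j]); s <- stats::sd(X[, j])
          if (!is.finite(s) || s == 0) s <- 1
          scaling$center[j] <- mu; scaling$scale[j] <- s
          X[, j] <- (X[, j] - mu) / s
        }
      }
      obs_lab <- sort(unique(ebird$observer_id))
      ebird_d <- list(n = nrow(ebird), cell = ix_e$cell, year = ix_e$year,
                      obs = match(ebird$observer_id, obs_lab),
                      y = as.integer(ebird$species_count), X = X,
                      obs_labels = obs_lab, scaling = scaling)
    } else {
      ebird_d <- list(n = 0L, cell = integer(0), year = integer(0),
                      obs = integer(0), y = integer(0),
                      X = matrix(0, 0, 6), obs_labels = character(0),
                      scaling = NULL)
    }
  }
  structure(list(n_cells = nrow(cells), n_years = length(years),
                 n_bcrs = length(bcr_levels), bcr = bcr,
                 bcr_levels = bcr_levels, cell_ids = cells$cell_id,
                 years = years, year_c = year_c, bbs = bbs_d,
                 ebird = ebird_d, has_ebird = !is.null(ebird)),
            class = "abund_model_data")
}

# Data-driven starting values: log gamma at the offset-corrected log of the
# cell-year mean route count (global mean where a cell-year has no routes),
# cell intercepts/slopes from per-cell least squares on that surface, BCR and
# grand means by averaging, variances at 1, omegas at 0.1, random effects at
# 0; chain-specific Gaussian jitter disperses the chains.
.abund_inits <- function(data, model, chain, seed, fixed_vals) {
  d <- data
  .with_seed(seed + 97L * chain, {
  mean_y <- matrix(NA_real_, d$n_cells, d$n_years)
  cnt <- matrix(0, d$n_cells, d$n_years)
  sums <- matrix(0, d$n_cells, d$n_years)
  if (d$bbs$n > 0) for (n in seq_len(d$bbs$n)) {
    i <- d$bbs$cell[n]; t <- d$bbs$year[n]
    cnt[i, t] <- cnt[i, t] + 1; sums[i, t] <- sums[i, t] + d$bbs$y[n]
  }
  mean_y[cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
  gmean <- if (any(cnt > 0)) sum(sums) / sum(cnt) else 1
  mean_y[cnt == 0] <- gmean
  lg0 <- log(mean_y + 0.5) - bbs_offset()
  jit <- if (chain == 1) 0 else 0.1
  lg <- lg0 + matrix(rnorm(length(lg0), 0, jit), nrow(lg0))
  alpha <- rowMeans(lg)
  syc2 <- sum(d$year_c^2)
  beta <- as.vector((lg %*% d$year_c) / syc2)
  muA <- as.vector(tapply(alpha, d$bcr, mean))
  muB <- as.vector(tapply(beta, d$bcr, mean))
  init <- list(alpha = alpha, beta = beta, log_gamma = lg,
               mu_alpha_bcr = muA, mu_beta_bcr = muB,
               mu_alpha = mean(muA), mu_beta = mean(muB),
               sigma_alpha = 1, sigma_beta = 1, tau_alpha = 1, tau_beta = 1,
               sigma_gamma = 1, omega_bbs = 0.1, sigma_bbs = 1, eta = 0,
               eps_bbs = rep(0, length(d$bbs$pair_labels)))
  if (model == "joint") {
    b0 <- if (d$ebird$n > 0)
      log(mean(d$ebird$y) + 0.5) - mean(lg) + rnorm(1, 0, 2 * jit) else 0
    init <- c(init, list(b = c(b0, rep(0, 6)), omega_ebird = 0.1,
                         sigma_ebird = 1,
                         eps_ebird = rep(0, length(d$ebird$obs_labels))))
  }
  # user-fixed values override the defaults (and are never jittered)
  for (nm in names(fixed_vals)) {
    v <- fixed_vals[[nm]]
    if (nm %in% c("alpha", "beta", "eps_bbs", "eps_ebird"))
      v <- rep_len(v, length(init[[nm]]))
    if (nm == "log_gamma" && !is.matrix(v))
      v <- matrix(v, d$n_cells, d$n_years)
    init[[nm]] <- v
  }
  init
  })
}

.param_names <- function(data, model) {
  d <- data
  nm <- c("mu_alpha", "mu_beta", "tau_alpha", "tau_beta", "sigma_alpha",
          "sigma_beta", "sigma_gamma",
          paste0("mu_alpha_bcr[", d$bcr_levels, "]"),
          paste0("mu_beta_bcr[", d$bcr_levels, "]"),
          paste0("alpha[", d$cell_ids, "]"),
          paste0("beta[", d$cell_ids, "]"),
          paste0("log_gamma[", rep(d$cell_ids, d$n_years), ",",
                 rep(d$years, each = d$n_cells), "]"),
          "omega_bbs", "sigma_bbs", "eta",
          paste0("eps_bbs[", d$bbs$pair_labels, "]"))
  if (model == "joint")
    nm <- c(nm, paste0("b", 0:6), "omega_ebird", "sigma_ebird",
            paste0("eps_ebird[", d$ebird$obs_labels, "]"))
  nm
}

# Evaluate the log-posterior term by term and name the first non-finite one.
.check_init_finite <- function(data, params, model) {
  terms <- list(
    hierarchy = function() {
      p <- params; p$bcr <- data$bcr; hierarchy_log_density(p)
    },
    process = function() {
      mu <- outer(params$alpha, rep(1, data$n_years)) +
        outer(params$beta, data$year_c)
      sum(log_gamma_density(params$log_gamma, mu, params$sigma_gamma))
    },
    bbs_likelihood = function() {
      if (data$bbs$n == 0) return(0)
      lg <- params$log_gamma[cbind(data$bbs$cell, data$bbs$year)]
      ll <- bbs_log_intensity(lg, params$eps_bbs[data$bbs$pair], params$eta,
                              data$bbs$first_year)
      sum(zip_log_pmf(data$bbs$y, exp(ll), params$omega_bbs))
    })
  if (model == "joint") terms$ebird_likelihood <- function() {
    if (data$ebird$n == 0) return(0)
    lg <- params$log_gamma[cbind(data$ebird$cell, data$ebird$year)]
    X <- data$ebird$X
    ll <- ebird_log_intensity(lg, params$b, X[, 1], X[, 2], X[, 3], X[, 4],
                              X[, 5], X[, 6], params$eps_ebird[data$ebird$obs])
    sum(zip_log_pmf(data$ebird$y, exp(ll), params$omega_ebird))
  }
  for (nm in names(terms)) {
    v <- terms[[nm]]()
    if (!is.finite(v))
      stop("non-finite log-posterior at initialization (term: ", nm, ")")
  }
  invisible(TRUE)
}

#' Fit the BBS-only or joint abundance model
#'
#' Samples the joint posterior defined by [joint_log_posterior()] with a
#' Gibbs sampler (conjugate updates for the Gaussian/inverse-gamma/Beta
#' blocks and latent zero-inflation indicators; slice sampling for the
#' log-concave Poisson-linked nodes). Fits are reproducible for a fixed
#' `mcmc_control()` seed.
#'
#' Parameters may be held fixed via `fixed` (a named list, e.g.
#' `list(omega_bbs = 0)` for a plain-Poisson observation model, or
#' `list(eps_bbs = 0, sigma_bbs = 1)` to drop the route random effects);
#' fixed parameters keep the given value in every draw. Fixing `log_gamma`
#' conditions on a known abundance surface (used by the conjugate
#' closed-form checks).
#'
#' @param bbs,ebird,grid,years,scale_covariates See [abund_model_data()].
#' @param model `"bbs"` or `"joint"`; default joint when `ebird` is given.
#' @param mcmc An [mcmc_control()].
#' @param fixed Named list of parameters to hold fixed at the given values.
#' @return An object of class `"abund_fit"`: draws (one iterations x
#'   parameters matrix per chain, named columns), the model-data object, the
#'   control settings and the covariate scaling. Methods: `print`,
#'   `summary`, `coef`, `predict`, `simulate`, `residuals`, `plot`.
#' @seealso [summary.abund_fit()], [gelman_rubin()], [ppc_zero_fraction()]
#' @export
fit_abundance <- function(bbs, ebird = NULL, grid, years = NULL,
                          model = NULL, mcmc = mcmc_control(),
                          fixed = list(), scale_covariates = TRUE) {
  if (is.null(model)) model <- if (is.null(ebird)) "bbs" else "joint"
  model <- match.arg(model, c("bbs", "joint"))
  if (model == "joint" && is.null(ebird))
    stop("the joint model needs checklist data ",
         "(an empty data frame gives the prior-only checklist block)")
  data <- abund_model_data(bbs, if (model == "joint") ebird else NULL,
                           grid, years, scale_covariates)
  fixed_flags <- as.list(stats::setNames(rep(TRUE, length(fixed)),
                                         names(fixed)))
  draws <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    init <- .abund_inits(data, model, ch, mcmc$seed, fixed)
    if (ch == 1) {
      chk <- init; chk$bcr <- data$bcr
      .check_init_finite(data, chk, model)
    }
    cd <- list(ncell = data$n_cells, nyear = data$n_years,
               nbcr = data$n_bcrs, bcr = data$bcr - 1L, yearc = data$year_c,
               off = bbs_offset(), nB = data$bbs$n,
               npair = length(data$bbs$pair_labels),
               bc = data$bbs$cell - 1L, bt = data$bbs$year - 1L,
               bp = data$bbs$pair - 1L, bI = data$bbs$first_year,
               by = data$bbs$y, has_e = (model == "joint"),
               nE = data$ebird$n,
               nobs = length(data$ebird$obs_labels %||% character(0)))
    if (model == "joint") {
      cd$ec <- data$ebird$cell - 1L; cd$et <- data$ebird$year - 1L
      cd$eo <- data$ebird$obs - 1L; cd$ey <- data$ebird$y
      cd$X <- data$ebird$X
    }
    m <- .run_abund_chain(cd, init, fixed_flags, mcmc$n_iter, mcmc$n_burnin,
                          mcmc$thin, as.numeric(mcmc$seed) * 1e6 + ch)
    colnames(m) <- .param_names(data, model)
    draws[[ch]] <- m
  }
  structure(list(draws = draws, model = model, data = data, mcmc = mcmc,
                 fixed = fixed, call = match.call()),
            class = "abund_fit")
}

#' Gelman-Rubin convergence diagnostic
#'
#' The classic (non-split) potential scale reduction factor:
#' `Rhat = sqrt((((n-1)/n) W + B/n) / W)` with `W` the mean within-chain
#' variance and `B/n` the between-chain variance of chain means. Values
#' below 1.2 were taken as converged in this analysis. Parameters with zero
#' total variance (e.g. fixed parameters) return 1.
#'
#' @param x An `"abund_fit"` or a list of iterations x parameters draw
#'   matrices (>= 2 chains, >= 10 draws each).
#' @param pars Optional character vector restricting the parameters.
#' @return Named numeric vector of Rhat values.
#' @export
gelman_rubin <- function(x, pars = NULL) {
  draws <- if (inherits(x, "abund_fit")) x$draws else x
  if (length(draws) < 2) stop("Gelman-Rubin needs at least 2 chains")
  n <- nrow(draws[[1]])
  if (n < 10) stop("need at least 10 draws per chain")
  if (!is.null(pars)) draws <- lapply(draws, function(m) m[, pars, drop = FALSE])
  means <- sapply(draws, colMeans)
  vars <- sapply(draws, function(m) apply(m, 2, stats::var))
  if (is.null(dim(means))) { means <- t(means); vars <- t(vars) }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, stats::var)
  rhat <- sqrt(((n - 1) / n * W + B_over_n) / W)
  rhat[W == 0 & B_over_n == 0] <- 1
  stats::setNames(rhat, colnames(draws[[1]]))
}

#' Posterior summary: quantiles and Rhat
#'
#' Pools draws across chains and reports the 2.5%, 50% and 97.5% empirical
#' quantiles (linear interpolation, `stats::quantile` type 7 -- the interval
#' convention behind all CV computations) together with the Gelman-Rubin
#' statistic per parameter.
#'
#' @param object An `"abund_fit"`.
#' @param pars Optional character vector restricting the parameters.
#' @param ... Unused.
#' @return A data frame of class `"summary.abund_fit"` with columns
#'   `parameter`, `q025`, `q50`, `q975`, `rhat`.
#' @export
summary.abund_fit <- function(object, pars = NULL, ...) {
  summarize_posterior(object$draws, pars = pars,
                      rhat = object$mcmc$n_chains >= 2)
}

#' @rdname summary.abund_fit
#' @param draws A list of draw matrices (or an `"abund_fit"`).
#' @param rhat Attach the Gelman-Rubin statistic? (needs >= 2 chains)
#' @export
summarize_posterior <- function(draws, pars = NULL, rhat = TRUE) {
  if (inherits(draws, "abund_fit")) draws <- draws$draws
  if (length(draws) == 0 || nrow(draws[[1]]) == 0) stop("empty draws")
  pooled <- do.call(rbind, draws)
  if (!is.null(pars)) pooled <- pooled[, pars, drop = FALSE]
  q <- t(apply(pooled, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE, type = 7))
  out <- data.frame(parameter = colnames(pooled), q025 = q[, 1],
                    q50 = q[, 2], q975 = q[, 3], row.names = NULL,
                    stringsAsFactors = FALSE)
  out$rhat <- if (rhat && length(draws) >= 2) {
    r <- gelman_rubin(draws)
    unname(r[match(out$parameter, names(r))])
  } else NA_real_
  class(out) <- c("summary.abund_fit", "data.frame")
  out
}

#' @export
print.summary.abund_fit <- function(x, ...) {
  cat("Posterior summary (", nrow(x), " parameters)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 20), digits = 4)
  if (nrow(x) > 20) cat("... (", nrow(x) - 20, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
print.abund_fit <- function(x, ...) {
  d <- x$data
  cat("Hierarchical ZIP state-space abundance model (",
      if (x$model == "joint") "joint route + checklist" else "route-count only",
      ")\n", sep = "")
  cat("  cells: ", d$n_cells, " in ", d$n_bcrs, " BCRs; years ",
      min(d$years), "-", max(d$years), "\n", sep = "")
  cat("  route records: ", d$bbs$n, "; checklist records: ",
      if (d$has_ebird) d$ebird$n else 0, "\n", sep = "")
  cat("  chains: ", x$mcmc$n_chains, "; retained draws per chain: ",
      nrow(x$draws[[1]]), "\n", sep = "")
  hyper <- c("mu_alpha", "mu_beta", "sigma_gamma", "omega_bbs")
  if (x$mcmc$n_chains >= 2) {
    r <- gelman_rubin(x, pars = intersect(hyper, colnames(x$draws[[1]])))
    cat("  max Rhat (hyperparameters): ", round(max(r), 3), "\n", sep = "")
  }
  invisible(x)
}

# Back-transform checklist coefficients from the scaled working scale.
.coef_original_scale <- function(b, scaling) {
  if (is.null(scaling)) return(b)
  bo <- b
  bo[2:7] <- b[2:7] / scaling$scale
  bo[1] <- b[1] - sum(b[2:7] * scaling$center / scaling$scale)
  bo
}

#' @export
#' @method coef abund_fit
coef.abund_fit <- function(object, scale = c("original", "working"), ...) {
  scale <- match.arg(scale)
  s <- summary(object)
  med <- stats::setNames(s$q50, s$parameter)
  keep <- c("mu_alpha", "mu_beta", "tau_alpha", "tau_beta", "sigma_alpha",
            "sigma_beta", "sigma_gamma", "omega_bbs", "sigma_bbs", "eta")
  out <- med[keep]
  if (object$model == "joint") {
    b <- med[paste0("b", 0:6)]
    if (scale == "original")
      b <- stats::setNames(.coef_original_scale(unname(b),
                                                object$data$ebird$scaling),
                           paste0("b", 0:6))
    out <- c(out, b, med[c("omega_ebird", "sigma_ebird")])
  }
  out
}

#' Posterior estimates of abundance and trend
#'
#' `type = "alpha"` returns per-cell mean relative abundance intercepts,
#' `"beta"` per-cell trends, `"gamma"` year-specific relative abundance per
#' cell-year (on the natural scale, `exp(log_gamma)` draws summarized).
#'
#' @param object An `"abund_fit"`.
#' @param type One of `"alpha"`, `"beta"`, `"gamma"`.
#' @param ... Unused.
#' @return Data frame with `cell_id` (and `year` for `"gamma"`), posterior
#'   `q025`, `q50`, `q975`.
#' @export
#' @method predict abund_fit
predict.abund_fit <- function(object, type = c("alpha", "beta", "gamma"), ...) {
  type <- match.arg(type)
  d <- object$data
  pooled <- do.call(rbind, object$draws)
  if (type %in% c("alpha", "beta")) {
    cols <- paste0(type, "[", d$cell_ids, "]")
    q <- t(apply(pooled[, cols, drop = FALSE], 2, stats::quantile,
                 probs = c(0.025, 0.5, 0.975), names = FALSE))
    data.frame(cell_id = d$cell_ids, q025 = q[, 1], q50 = q[, 2],
               q975 = q[, 3], row.names = NULL)
  } else {
    cols <- paste0("log_gamma[", rep(d$cell_ids, d$n_years), ",",
                   rep(d$years, each = d$n_cells), "]")
    q <- t(apply(exp(pooled[, cols, drop = FALSE]), 2, stats::quantile,
                 probs = c(0.025, 0.5, 0.975), names = FALSE))
    data.frame(cell_id = rep(d$cell_ids, d$n_years),
               year = rep(d$years, each = d$n_cells),
               q025 = q[, 1], q50 = q[, 2], q975 = q[, 3], row.names = NULL)
  }
}

# lambda for every record of a stream under one posterior draw (named vector)
.record_lambda <- function(fit, draw, stream) {
  d <- fit$data
  if (stream == "bbs") {
    lg <- draw[paste0("log_gamma[", d$cell_ids[d$bbs$cell], ",",
                      d$years[d$bbs$year], "]")]
    eps <- draw[paste0("eps_bbs[", d$bbs$pair_labels[d$bbs$pair], "]")]
    exp(bbs_log_intensity(lg, eps, draw["eta"], d$bbs$first_year))
  } else {
    lg <- draw[paste0("log_gamma[", d$cell_ids[d$ebird$cell], ",",
                      d$years[d$ebird$year], "]")]
    eps <- draw[paste0("eps_ebird[", d$ebird$obs_labels[d$ebird$obs], "]")]
    X <- d$ebird$X
    b <- unname(draw[paste0("b", 0:6)])
    exp(ebird_log_intensity(lg, b, X[, 1], X[, 2], X[, 3], X[, 4], X[, 5],
                            X[, 6], eps))
  }
}

#' Simulate replicate datasets from the posterior
#'
#' Draws `nsim` posterior parameter vectors (uniformly over retained draws,
#' all chains pooled) and generates a zero-inflated Poisson replicate of the
#' requested data stream from each.
#'
#' @param object An `"abund_fit"`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional RNG seed.
#' @param stream `"bbs"` or `"ebird"`.
#' @param ... Unused.
#' @return A matrix (records x nsim) of replicated counts.
#' @export
#' @method simulate abund_fit
simulate.abund_fit <- function(object, nsim = 1, seed = NULL,
                               stream = c("bbs", "ebird"), ...) {
  stream <- match.arg(stream)
  if (stream == "ebird" && object$model != "joint")
    stop("the BBS-only model has no checklist stream")
  if (!is.null(seed)) set.seed(seed)
  pooled <- do.call(rbind, object$draws)
  om_name <- if (stream == "bbs") "omega_bbs" else "omega_ebird"
  nrec <- if (stream == "bbs") object$data$bbs$n else object$data$ebird$n
  idx <- sample.int(nrow(pooled), nsim, replace = TRUE)
  out <- matrix(0L, nrec, nsim)
  for (r in seq_len(nsim)) {
    draw <- pooled[idx[r], ]
    lam <- .record_lambda(object, draw, stream)
    z <- rbinom(nrec, 1, draw[om_name])
    out[, r] <- rpois(nrec, ifelse(z == 1, 0, lam))
  }
  out
}

#' Posterior predictive check of the zero fraction
#'
#' Compares the observed fraction of zero counts in a stream to its
#' distribution over replicate datasets simulated from the fitted model. A
#' tail probability near 0 or 1 flags a model that cannot reproduce the
#' observed number of non-detections (the motivation for the zero-inflated
#' observation models).
#'
#' @param fit An `"abund_fit"`.
#' @param stream `"bbs"` or `"ebird"`.
#' @param n_rep Number of replicate datasets (>= 2).
#' @param seed RNG seed for the replicates.
#' @return A list of class `"abund_ppc"`: `observed` (zero fraction),
#'   `replicated` (vector of replicate zero fractions), `p_value`
#'   (`mean(replicated >= observed)`).
#' @export
ppc_zero_fraction <- function(fit, stream = c("bbs", "ebird"), n_rep = 200,
                              seed = 1) {
  stream <- match.arg(stream)
  if (n_rep < 2) stop("n_rep must be at least 2")
  y <- if (stream == "bbs") fit$data$bbs$y else fit$data$ebird$y
  reps <- simulate(fit, nsim = n_rep, seed = seed, stream = stream)
  repfrac <- colMeans(reps == 0)
  obs <- mean(y == 0)
  structure(list(observed = obs, replicated = repfrac,
                 p_value = mean(repfrac >= obs), stream = stream),
            class = "abund_ppc")
}

#' @export
print.abund_ppc <- function(x, ...) {
  cat("Zero-fraction posterior predictive check (", x$stream, ")\n", sep = "")
  cat("  observed: ", round(x$observed, 4), "; replicated 2.5-97.5%: ",
      paste(round(stats::quantile(x$replicated, c(0.025, 0.975)), 4),
            collapse = " - "),
      "; Pr(rep >= obs) = ", round(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Pearson residuals at the posterior median
#'
#' `(y - E[y]) / sd(y)` under the zero-inflated Poisson with every parameter
#' at its posterior median: `E[y] = lambda (1 - omega)`,
#' `Var[y] = lambda (1 - omega) (1 + lambda omega)`.
#'
#' @param object An `"abund_fit"`.
#' @param stream `"bbs"` or `"ebird"`.
#' @param ... Unused.
#' @return Numeric vector of residuals, one per record.
#' @export
#' @method residuals abund_fit
residuals.abund_fit <- function(object, stream = c("bbs", "ebird"), ...) {
  stream <- match.arg(stream)
  s <- summary(object)
  med <- stats::setNames(s$q50, s$parameter)
  lam <- .record_lambda(object, med, stream)
  om <- med[if (stream == "bbs") "omega_bbs" else "omega_ebird"]
  y <- if (stream == "bbs") object$data$bbs$y else object$data$ebird$y
  mu <- lam * (1 - om)
  v <- mu * (1 + lam * om)
  unname((y - mu) / sqrt(v))
}

#' Trace plots of monitored parameters
#'
#' @param x An `"abund_fit"`.
#' @param pars Parameters to plot (default the grand means and the
#'   zero-inflation probabilities).
#' @param ... Passed to [graphics::plot()].
#' @export
#' @method plot abund_fit
plot.abund_fit <- function(x, pars = NULL, ...) {
  if (is.null(pars)) {
    pars <- intersect(c("mu_alpha", "mu_beta", "omega_bbs", "omega_ebird"),
                      colnames(x$draws[[1]]))
  }
  old <- par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(par(old))
  for (p in pars) {
    rng <- range(sapply(x$draws, function(m) range(m[, p])))
    plot(x$draws[[1]][, p], type = "l", ylab = p, ylim = rng, ...)
    if (length(x$draws) > 1)
      for (ch in 2:length(x$draws))
        lines(x$draws[[ch]][, p], col = ch)
  }
  invisible(x)
}
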