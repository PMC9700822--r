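# Forward simulator with the exact generative structure of the model:
# BCR-nested cell intercepts/slopes, lognormal year noise, zero-inflated
# Poisson route counts with route-by-observer effects and the effective-area
# offset, and effort-driven zero-inflated Poisson checklist counts with an
# unknown scaling intercept. Known truth makes every downstream stage
# testable.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Collects every generative "truth" hyperparameter of the process and
#' observation models, plus survey-design settings, with validation. All
#' `sigma_*`/`tau_*` parameters are variances (the package-wide convention);
#' zero variances are allowed and give degenerate (exact) draws.
#'
#' Defaults define the package's reference study conditions: an 8 x 6 cell
#' landscape in 4 ecoregions over 2010-2019, a cell-scale abundance index of
#' `exp(7)` (about 1100 birds per 12,321 km^2 cell, i.e. a mean route count
#' of `exp(7) * 25/12321`, about 2.2 -- typical for a moderately common
#' species), weak positive trend (`mu_beta = 0.05`), modest heterogeneity
#' (all variances 0.05, year noise 0.01), 30% zero inflation in both
#' streams, two routes per cell and on average five checklists per
#' cell-year.
#'
#' @param n_cells_x,n_cells_y Grid dimensions (cells).
#' @param n_bcrs Number of ecoregions (contiguous column strips when
#'   possible); must not exceed the number of cells.
#' @param years Inclusive study years (at least 2).
#' @param mu_alpha,mu_beta Grand means of cell intercepts and slopes.
#' @param tau_alpha,tau_beta Variances of BCR means around the grand means.
#' @param sigma_alpha,sigma_beta Variances of cell parameters around their
#'   BCR means.
#' @param sigma_gamma Variance of the lognormal year noise on `log(gamma)`.
#' @param bbs List of route-survey design settings:
#'   `routes_per_cell` (fixed count, or Poisson mean if `routes_poisson`),
#'   `routes_poisson` (logical), `turnover` (per-year probability a route
#'   changes observer), `first_year_fraction` (probability an incoming
#'   observer is new to the archive), `eta` (first-year effect), `sigma_bbs`
#'   (variance of route-by-observer effects), `omega_bbs` (zero inflation).
#' @param ebird List of checklist design settings:
#'   `checklists_per_cell_year` (Poisson mean), `n_observers` (pool size),
#'   `b` (length-7 truth: scaling intercept then TYPE, DIST, COSTIME,
#'   SINTIME, DURA, NOOB coefficients), `sigma_ebird` (observer-effect
#'   variance), `omega_ebird` (zero inflation), `violating_fraction`
#'   (fraction of checklists drawn to breach at least one of the three
#'   effort filter bounds, for filter testing).
#' @param seed Integer seed; the truth, route and checklist stages use
#'   `seed`, `seed + 1`, `seed + 2` respectively.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_cells_x = 8, n_cells_y = 6, n_bcrs = 4,
                       years = 2010:2019,
                       mu_alpha = 7, mu_beta = 0.05,
                       tau_alpha = 0.05, tau_beta = 0.05,
                       sigma_alpha = 0.05, sigma_beta = 0.05,
                       sigma_gamma = 0.01,
                       bbs = list(), ebird = list(), seed = 1) {
  bbs_def <- list(routes_per_cell = 2, routes_poisson = FALSE,
                  turnover = 0.1, first_year_fraction = 0.5,
                  eta = -0.2, sigma_bbs = 0.05, omega_bbs = 0.3)
  ebird_def <- list(checklists_per_cell_year = 5, n_observers = 30,
                    b = c(bbs_offset(), 0.3, 0.05, -0.3, 0.2, 0.002, 0.05),
                    sigma_ebird = 0.05, omega_ebird = 0.3,
                    violating_fraction = 0)
  bad <- setdiff(names(bbs), names(bbs_def))
  if (length(bad)) stop("unknown bbs design fields: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(ebird), names(ebird_def))
  if (length(bad)) stop("unknown ebird design fields: ", paste(bad, collapse = ", "))
  bbs <- utils::modifyList(bbs_def, bbs)
  ebird <- utils::modifyList(ebird_def, ebird)
  vs <- c(tau_alpha = tau_alpha, tau_beta = tau_beta,
          sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
          sigma_gamma = sigma_gamma, sigma_bbs = bbs$sigma_bbs,
          sigma_ebird = ebird$sigma_ebird)
  if (any(vs < 0))
    stop("negative variance parameter(s): ",
         paste(names(vs)[vs < 0], collapse = ", "))
  if (length(unique(years)) < 2) stop("years must span at least 2 years")
  if (n_bcrs > n_cells_x * n_cells_y) stop("n_bcrs exceeds the number of cells")
  if (n_bcrs < 1) stop("need at least one BCR")
  om <- c(omega_bbs = bbs$omega_bbs, omega_ebird = ebird$omega_ebird)
  if (any(om < 0 | om > 1)) stop("omega parameters must lie in [0, 1]")
  if (length(ebird$b) != 7) stop("ebird$b must have length 7 (b0..b6)")
  if (ebird$violating_fraction < 0 || ebird$violating_fraction > 1)
    stop("violating_fraction must lie in [0, 1]")
  structure(list(n_cells_x = n_cells_x, n_cells_y = n_cells_y,
                 n_bcrs = n_bcrs, years = sort(unique(years)),
                 mu_alpha = mu_alpha, mu_beta = mu_beta,
                 tau_alpha = tau_alpha, tau_beta = tau_beta,
                 sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
                 sigma_gamma = sigma_gamma, bbs = bbs, ebird = ebird,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the true abundance surface
#'
#' Draws BCR means from the grand means (`N(mu, tau)`), cell intercepts and
#' slopes from their BCR means (`N(mu_k, sigma)`), and
#' `log(gamma[i, t]) ~ N(alpha_i + beta_i * year_c[t], sigma_gamma)` over a
#' square grid of 111-km cells partitioned into contiguous ecoregions.
#' Reproducible: the same config (seed) gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `"abund_truth"`: `grid` (an `"abund_grid"` with
#'   `bcr_id` and `in_range`), `bcr`, `alpha`, `beta`, `mu_alpha_bcr`,
#'   `mu_beta_bcr`, `log_gamma` and `gamma` (cell x year matrices), `years`,
#'   `year_c`, `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  grid <- build_grid(c(0, cf$n_cells_x * 111, 0, cf$n_cells_y * 111))
  ncell <- nrow(grid)
  # contiguous column strips when they fit, else row-major index blocks
  if (cf$n_bcrs <= cf$n_cells_x) {
    bcr <- as.integer(ceiling(grid$col * cf$n_bcrs / cf$n_cells_x))
  } else {
    bcr <- as.integer(ceiling(seq_len(ncell) * cf$n_bcrs / ncell))
  }
  grid$bcr_id <- bcr
  grid$in_range <- rep(TRUE, ncell)
  year_c <- center_years(cf$years)
  .with_seed(cf$seed, {
    mu_a_k <- rnorm(cf$n_bcrs, cf$mu_alpha, sqrt(cf$tau_alpha))
    mu_b_k <- rnorm(cf$n_bcrs, cf$mu_beta, sqrt(cf$tau_beta))
    alpha <- rnorm(ncell, mu_a_k[bcr], sqrt(cf$sigma_alpha))
    beta <- rnorm(ncell, mu_b_k[bcr], sqrt(cf$sigma_beta))
    mu <- outer(alpha, rep(1, length(cf$years))) + outer(beta, year_c)
    lgam <- matrix(rnorm(length(mu), mu, sqrt(cf$sigma_gamma)),
                   nrow = ncell, dimnames = list(NULL, cf$years))
    structure(list(grid = grid, bcr = bcr, alpha = alpha, beta = beta,
                   mu_alpha_bcr = mu_a_k, mu_beta_bcr = mu_b_k,
                   log_gamma = lgam, gamma = exp(lgam), years = cf$years,
                   year_c = year_c, config = cf),
              class = "abund_truth")
  })
}

#' Simulate route-count (BBS-style) survey data
#'
#' Places routes uniformly within cells, simulates observer tenures
#' (observers may be new to the archive or experienced when they take over a
#' route; the first-year flag derives from each observer's simulated career
#' start exactly as [flag_first_year()] computes it), draws one
#' route-by-observer effect `N(0, sigma_bbs)` per pair (reused across that
#' pair's years), and generates counts
#' `y ~ Poisson(lambda (1 - z))`, `z ~ Bernoulli(omega_bbs)`,
#' `log lambda = log(gamma * 25/12321) + eps + eta * I`.
#'
#' @param truth An `"abund_truth"` from [simulate_truth()].
#' @param config The same [sim_config()]; its `bbs` block holds the design.
#' @param seed RNG seed (default `config$seed + 1`).
#' @return Data frame with `route_id`, `observer_id`, `x_km`, `y_km`,
#'   `cell_id`, `year`, `species_count`, `first_year` (flag), plus
#'   attributes `observers` (archive history: `observer_id`, `first_year`)
#'   and `eps_bbs` (the true pair effects).
#' @export
simulate_bbs <- function(truth, config = truth$config,
                         seed = config$seed + 1L) {
  stopifnot(inherits(truth, "abund_truth"))
  cf <- config$bbs
  grid <- truth$grid
  years <- truth$years
  if (!all(grid$cell_id %in% truth$grid$cell_id))
    stop("route assigned to a cell without truth")
  .with_seed(seed, {
    nr_cell <- if (cf$routes_poisson)
      rpois(nrow(grid), cf$routes_per_cell)
    else rep(round(cf$routes_per_cell), nrow(grid))
    cell_of_route <- rep(grid$cell_id, nr_cell)
    n_routes <- length(cell_of_route)
    if (n_routes == 0) stop("design places no routes")
    s <- attr(grid, "cell_size")
    rx <- grid$x[cell_of_route] + runif(n_routes, -s / 2, s / 2)
    ry <- grid$y[cell_of_route] + runif(n_routes, -s / 2, s / 2)
    route_id <- sprintf("R%03d", seq_len(n_routes))
    # observer tenures: one observer per route at a time, geometric stints
    obs_first <- integer(0)        # archive first year per observer
    new_obs <- function(year) {
      rookie <- runif(1) < cf$first_year_fraction
      start <- if (rookie) year else min(years) - sample.int(10, 1)
      obs_first[length(obs_first) + 1L] <<- start
      length(obs_first)
    }
    recs <- vector("list", n_routes)
    eps_key <- character(0); eps_val <- numeric(0)
    for (r in seq_len(n_routes)) {
      ob <- new_obs(years[1])
      rows <- data.frame(year = years, observer = NA_integer_)
      for (ti in seq_along(years)) {
        if (ti > 1 && runif(1) < cf$turnover) ob <- new_obs(years[ti])
        rows$observer[ti] <- ob
      }
      recs[[r]] <- rows
    }
    obs_id <- sprintf("O%03d", seq_along(obs_first))
    out <- do.call(rbind, lapply(seq_len(n_routes), function(r) {
      data.frame(route_id = route_id[r],
                 observer_id = obs_id[recs[[r]]$observer],
                 x_km = rx[r], y_km = ry[r],
                 cell_id = cell_of_route[r],
                 year = recs[[r]]$year)
    }))
    observers <- data.frame(observer_id = obs_id, first_year = obs_first)
    out$first_year <- flag_first_year(out, observers)
    # one effect per route x observer pair, reused across its years
    pair <- paste(out$route_id, out$observer_id)
    upair <- unique(pair)
    eps <- rnorm(length(upair), 0, sqrt(cf$sigma_bbs))
    names(eps) <- upair
    ti <- match(out$year, years)
    ci <- match(out$cell_id, grid$cell_id)
    loglam <- truth$log_gamma[cbind(ci, ti)] + bbs_offset() +
      eps[pair] + cf$eta * out$first_year
    z <- rbinom(nrow(out), 1, cf$omega_bbs)
    out$species_count <- rpois(nrow(out), exp(loglam) * (1 - z))
    rownames(out) <- NULL
    attr(out, "observers") <- observers
    attr(out, "eps_bbs") <- eps
    out
  })
}

#' Simulate checklist (eBird-style) survey data
#'
#' Checklist counts per cell-year are Poisson around the configured
#' intensity; effort covariates are drawn to span the filter-compliant space
#' (TYPE ~ Bernoulli(0.5); DIST ~ U(0, 5) km, 0 when stationary;
#' DURA ~ U(5, 300) min; NOOB ~ 1 + Binomial(9, 0.2); start seconds
#' ~ U(0, 86400)), with a configured fraction instead drawn to breach at
#' least one of the three effort filter bounds. Counts follow
#' `y ~ ZIP(lambda, omega_ebird)` with
#' `log lambda = log(gamma) + b0 + b'x + eps_s`, one observer effect
#' `N(0, sigma_ebird)` per observer.
#'
#' @inheritParams simulate_bbs
#' @param seed RNG seed (default `config$seed + 2`).
#' @return Data frame with `checklist_id`, `observer_id`, `x_km`, `y_km`,
#'   `date`, `start_seconds`, `protocol`, `distance_km`, `duration_min`,
#'   `n_observers`, `all_species_reported`, `species_count`, `cell_id`,
#'   `year`; attribute `eps_ebird` holds the true observer effects.
#' @export
simulate_ebird <- function(truth, config = truth$config,
                           seed = config$seed + 2L) {
  stopifnot(inherits(truth, "abund_truth"))
  cf <- config$ebird
  grid <- truth$grid
  years <- truth$years
  .with_seed(seed, {
    ncell <- nrow(grid)
    nyr <- length(years)
    n_ct <- rpois(ncell * nyr, cf$checklists_per_cell_year)
    ci <- rep(rep(seq_len(ncell), nyr), n_ct)
    ti <- rep(rep(seq_len(nyr), each = ncell), n_ct)
    n <- length(ci)
    if (n == 0) {
      empty <- data.frame(checklist_id = character(0),
                          observer_id = character(0), x_km = numeric(0),
                          y_km = numeric(0), date = as.Date(character(0)),
                          start_seconds = numeric(0), protocol = character(0),
                          distance_km = numeric(0), duration_min = numeric(0),
                          n_observers = integer(0),
                          all_species_reported = logical(0),
                          species_count = integer(0), cell_id = integer(0),
                          year = integer(0))
      return(structure(empty, eps_ebird = numeric(0)))
    }
    s <- attr(grid, "cell_size")
    x <- grid$x[ci] + runif(n, -s / 2, s / 2)
    y <- grid$y[ci] + runif(n, -s / 2, s / 2)
    day <- sample.int(61, n, replace = TRUE) - 1L   # June 1 .. July 31
    date <- as.Date(paste0(years[ti], "-06-01")) + day
    type <- rbinom(n, 1, 0.5)
    dist <- ifelse(type == 1, 0, runif(n, 0, 5))
    dura <- runif(n, 5, 300)
    noob <- 1 + rbinom(n, 9, 0.2)
    start <- runif(n, 0, 86400)
    complete <- rep(TRUE, n)
    viol <- runif(n) < cf$violating_fraction
    if (any(viol)) {
      which_rule <- sample.int(3, sum(viol), replace = TRUE)
      vi <- which(viol)
      for (j in seq_along(vi)) {
        k <- vi[j]
        if (which_rule[j] == 1) dura[k] <- runif(1, 300, 600)
        else if (which_rule[j] == 2) { type[k] <- 0; dist[k] <- runif(1, 5, 20) }
        else noob[k] <- sample(10:20, 1)
      }
    }
    obs <- sample.int(cf$n_observers, n, replace = TRUE)
    eps <- rnorm(cf$n_observers, 0, sqrt(cf$sigma_ebird))
    st <- solar_time_covariates(start)
    loglam <- ebird_log_intensity(truth$log_gamma[cbind(ci, ti)], cf$b,
                                  type, dist, st$costime, st$sintime,
                                  dura, noob, eps[obs])
    z <- rbinom(n, 1, cf$omega_ebird)
    cnt <- rpois(n, exp(loglam) * (1 - z))
    out <- data.frame(
      checklist_id = sprintf("C%06d", seq_len(n)),
      observer_id = sprintf("E%03d", obs),
      x_km = x, y_km = y, date = date, start_seconds = start,
      protocol = ifelse(type == 1, "stationary", "traveling"),
      distance_km = dist, duration_min = dura, n_observers = noob,
      all_species_reported = complete, species_count = cnt,
      cell_id = grid$cell_id[ci], year = years[ti])
    attr(out, "eps_ebird") <- stats::setNames(eps, sprintf("E%03d",
                                              seq_len(cf$n_observers)))
    out
  })
}

#' Write a simulated study to delimited-text files
#'
#' Writes `bbs.csv`, `bbs_observers.csv`, `ebird.csv`, `grid.csv`,
#' `truth.csv` (`cell, bcr, alpha, beta`) and `truth_gamma.csv`
#' (`cell, year, gamma`) under `dir`; the files round-trip through
#' [read_survey_fixture()].
#'
#' @param truth An `"abund_truth"`.
#' @param bbs,ebird Data frames from [simulate_bbs()] / [simulate_ebird()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_fixture <- function(truth, bbs, ebird, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  w(as.data.frame(bbs), "bbs.csv")
  w(attr(bbs, "observers") %||% data.frame(observer_id = character(0),
                                           first_year = integer(0)),
    "bbs_observers.csv")
  w(as.data.frame(ebird), "ebird.csv")
  write_grid(truth$grid, file.path(dir, "grid.csv"))
  w(data.frame(cell = truth$grid$cell_id, bcr = truth$bcr,
               alpha = truth$alpha, beta = truth$beta), "truth.csv")
  gam <- truth$gamma
  w(data.frame(cell = rep(truth$grid$cell_id, ncol(gam)),
               year = rep(truth$years, each = nrow(gam)),
               gamma = as.vector(gam)), "truth_gamma.csv")
  invisible(dir)
}

#' Read a simulated study back from delimited-text files
#'
#' @param dir Directory written by [write_survey_fixture()].
#' @return A list with `bbs` (with the `observers` attribute restored),
#'   `ebird`, `grid`, `truth` and `truth_gamma` data frames.
#' @export
read_survey_fixture <- function(dir) {
  r <- function(f) utils::read.csv(file.path(dir, f))
  bbs <- r("bbs.csv")
  attr(bbs, "observers") <- r("bbs_observers.csv")
  list(bbs = bbs, ebird = r("ebird.csv"), grid = r("grid.csv"),
       truth = r("truth.csv"), truth_gamma = r("truth_gamma.csv"))
}
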