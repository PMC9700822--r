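# Core model components: year centering, process mean, densities,
# intensities, the ZIP pmf and the assembled log-posterior.

test_that("years are centered at the study-period midpoint", {
  yc <- center_years(2010:2019)
  expect_equal(yc[1], -4.5)
  expect_equal(yc[10], 4.5)
  expect_equal(center_years(2014:2015), c(-0.5, 0.5))
  expect_equal(sum(center_years(2011:2021)), 0)
  expect_error(center_years(integer(0)), "empty")
  expect_error(center_years(2015), "2 distinct")
})

test_that("process mean is the linear trend in centered time", {
  expect_equal(process_mean(1.0, 0.1, 0), 1.0)
  expect_equal(process_mean(0, 0.2, -4.5), -0.9)
  expect_equal(process_mean(0.7, 0, center_years(2010:2019)), rep(0.7, 10))
})

test_that("log gamma density matches the normal density and integrates to 1", {
  expect_equal(log_gamma_density(2, 2, 1), -0.5 * log(2 * pi))
  expect_equal(log_gamma_density(2, 2, 1), -0.918939, tolerance = 1e-6)
  # variance (not sd) convention, checked against the quadrature oracle
  v <- 0.35
  total <- stats::integrate(function(x) exp(log_gamma_density(x, 1.3, v)),
                            -20, 20, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  expect_equal(log_gamma_density(1.5, 1.3, v),
               dnorm(1.5, 1.3, sqrt(v), log = TRUE))
  expect_error(log_gamma_density(0, 0, 0), "positive")
})

test_that("hierarchy log density attains its Normal maxima at the means and is additive", {
  base <- list(mu_alpha = 0.4, mu_beta = 0.05,
               mu_alpha_bcr = c(0.4, 0.4), mu_beta_bcr = c(0.05, 0.05),
               alpha = c(0.4, 0.4, 0.4), beta = c(0.05, 0.05, 0.05),
               bcr = c(1, 1, 2), sigma_alpha = 0.3, sigma_beta = 0.2,
               tau_alpha = 0.1, tau_beta = 0.15, sigma_gamma = 0.05)
  got <- hierarchy_log_density(base)
  # independent longhand sum: Normal terms at their modes plus hyperpriors
  mode_term <- function(v) -0.5 * log(2 * pi * v)
  ig <- function(v) dgamma(1 / v, 0.01, rate = 0.01, log = TRUE) - 2 * log(v)
  want <- 3 * mode_term(0.3) + 3 * mode_term(0.2) +
    2 * mode_term(0.1) + 2 * mode_term(0.15) +
    dnorm(0.4, 0, 10, log = TRUE) + dnorm(0.05, 0, 10, log = TRUE) +
    ig(0.3) + ig(0.2) + ig(0.1) + ig(0.15) + ig(0.05)
  expect_equal(got, want, tolerance = 1e-12)
  # adding one cell at its BCR means adds exactly two Normal mode terms
  more <- base
  more$alpha <- c(more$alpha, 0.4); more$beta <- c(more$beta, 0.05)
  more$bcr <- c(more$bcr, 2)
  expect_equal(hierarchy_log_density(more) - got,
               mode_term(0.3) + mode_term(0.2), tolerance = 1e-12)
  expect_error(hierarchy_log_density(utils::modifyList(base,
               list(sigma_alpha = -1))), "positive")
})

test_that("the inverse-gamma prior density matches the stats oracle", {
  # at v = 1 the InvGamma(a, b) and Gamma(a, b) densities coincide
  p <- list(mu_alpha = 0, mu_beta = 0, mu_alpha_bcr = 0, mu_beta_bcr = 0,
            alpha = numeric(0), beta = numeric(0), bcr = integer(0),
            sigma_alpha = 1, sigma_beta = 1, tau_alpha = 1, tau_beta = 1,
            sigma_gamma = 1)
  got <- hierarchy_log_density(p)
  want <- 2 * dnorm(0, 0, 10, log = TRUE) +
    2 * dnorm(0, 0, sqrt(1), log = TRUE) +  # BCR means at grand mean 0
    5 * dgamma(1, 0.01, rate = 0.01, log = TRUE)
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(dgamma(1, 0.01, rate = 0.01, log = TRUE),
               0.01 * log(0.01) - lgamma(0.01) - 0.01, tolerance = 1e-9)
  expect_equal(dgamma(1, 0.01, rate = 0.01, log = TRUE), -4.655532,
               tolerance = 1e-6)
})

test_that("route log intensity applies the effective-area offset", {
  expect_equal(bbs_log_intensity(0), log(25 / 12321))
  expect_equal(bbs_log_intensity(0), -6.2002, tolerance = 1e-4)
  expect_equal(bbs_log_intensity(log(12321 / 25)), 0)
  expect_equal(bbs_log_intensity(0, eps = 0, eta = 0.5, first_year = 1),
               log(25 / 12321) + 0.5)
  expect_error(bbs_log_intensity(0, first_year = 2), "first_year")
})

test_that("checklist log intensity is the linear effort model", {
  lg <- 1.7
  expect_equal(ebird_log_intensity(lg, rep(0, 7), 1, 0, 0.5, 0.5, 60, 2), lg)
  # with b0 equal to the route offset and no effort effects the two streams
  # have identical intensity
  b <- c(bbs_offset(), rep(0, 6))
  expect_equal(ebird_log_intensity(0, b, 0, 2, 0.1, 0.9, 120, 3),
               bbs_log_intensity(0))
  b5 <- 0.004
  b <- c(0, 0, 0, 0, 0, b5, 0)
  d1 <- ebird_log_intensity(lg, b, 0, 0, 0, 0, 100, 1)
  d2 <- ebird_log_intensity(lg, b, 0, 0, 0, 0, 250, 1)
  expect_equal(d2 - d1, b5 * 150)
})

test_that("ZIP log pmf equals explicit enumeration over the latent indicator", {
  expect_equal(zip_log_pmf(0, 1, 0.5), log(0.5 + 0.5 * exp(-1)))
  expect_equal(zip_log_pmf(0, 1, 0.5), -0.37989, tolerance = 1e-4)
  expect_equal(zip_log_pmf(3, 2, 0), dpois(3, 2, log = TRUE))
  expect_equal(zip_log_pmf(3, 2, 0), -1.71232, tolerance = 1e-4)
  expect_identical(zip_log_pmf(5, 3, 1), -Inf)
  for (lam in c(0.1, 1, 5, 20)) {
    for (om in c(0, 0.17, 0.5, 0.93, 1)) {
      got <- zip_log_pmf(0:50, lam, om)
      want <- vapply(0:50, zip_oracle, numeric(1), lambda = lam, omega = om)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
  expect_error(zip_log_pmf(-1, 1, 0.5), "non-negative")
  expect_error(zip_log_pmf(1, 0, 0.5), "positive")
  expect_error(zip_log_pmf(1, 1, 1.5), "omega")
})

test_that("ZIP probabilities sum to one", {
  for (lam in c(0.5, 2, 20)) {
    for (om in c(0, 0.3, 1)) {
      expect_equal(sum(exp(zip_log_pmf(0:200, lam, om))), 1,
                   tolerance = 1e-10)
    }
  }
})

# small two-cell fixture shared by the log-posterior tests
.lp_fixture <- function() {
  g <- mini_grid(2, 1, n_bcrs = 2)
  years <- 2014:2015
  bbs <- data.frame(route_id = c("A", "A", "B", "B"),
                    observer_id = c("o1", "o1", "o2", "o2"),
                    cell_id = c(1, 1, 2, 2), year = c(2014, 2015, 2014, 2015),
                    species_count = c(3L, 0L, 1L, 2L),
                    first_year = c(1L, 0L, 0L, 0L))
  eb <- data.frame(checklist_id = sprintf("c%d", 1:3),
                   observer_id = c("e1", "e2", "e1"),
                   cell_id = c(1, 2, 2), year = c(2014, 2014, 2015),
                   species_count = c(0L, 4L, 1L),
                   protocol = c("stationary", "traveling", "traveling"),
                   distance_km = c(0, 2.5, 1), duration_min = c(30, 120, 60),
                   n_observers = c(1, 2, 1),
                   start_seconds = c(21600, 30000, 50000),
                   all_species_reported = TRUE)
  data <- abund_model_data(bbs, eb, g, years, scale_covariates = FALSE)
  params <- list(mu_alpha = 1, mu_beta = 0.1, mu_alpha_bcr = c(0.8, 1.1),
                 mu_beta_bcr = c(0.05, 0.12), alpha = c(0.9, 1.2),
                 beta = c(0.0, 0.15),
                 log_gamma = matrix(c(1.0, 1.3, 0.8, 1.4), 2, 2),
                 sigma_alpha = 0.2, sigma_beta = 0.1, tau_alpha = 0.3,
                 tau_beta = 0.25, sigma_gamma = 0.05,
                 eps_bbs = c(0.1, -0.2), eta = -0.3, sigma_bbs = 0.15,
                 omega_bbs = 0.25, b = c(-6, 0.2, 0.1, -0.4, 0.3, 0.01, 0.05),
                 eps_ebird = c(0.05, -0.1), sigma_ebird = 0.2,
                 omega_ebird = 0.4)
  list(data = data, params = params)
}

test_that("joint log posterior matches an independent term-by-term oracle", {
  fx <- .lp_fixture()
  expect_equal(joint_log_posterior(fx$data, fx$params, "joint"),
               longhand_log_posterior(fx$data, fx$params, "joint"),
               tolerance = 1e-10)
  expect_equal(joint_log_posterior(fx$data, fx$params, "bbs"),
               longhand_log_posterior(fx$data, fx$params, "bbs"),
               tolerance = 1e-10)
})

test_that("joint log posterior is additive over records and order invariant", {
  fx <- .lp_fixture()
  full <- joint_log_posterior(fx$data, fx$params, "joint")
  # drop the first route record: the value changes by exactly its ZIP term
  d2 <- fx$data
  keep <- 2:4
  d2$bbs <- utils::modifyList(d2$bbs, list(
    n = 3L, cell = d2$bbs$cell[keep], year = d2$bbs$year[keep],
    pair = d2$bbs$pair[keep], first_year = d2$bbs$first_year[keep],
    y = d2$bbs$y[keep]))
  lam1 <- exp(fx$params$log_gamma[1, 1] + log(25 / 12321) +
              fx$params$eps_bbs[1] + fx$params$eta)
  expect_equal(full - joint_log_posterior(d2, fx$params, "joint"),
               zip_oracle(3, lam1, 0.25), tolerance = 1e-10)
  # permuting record order leaves the value unchanged
  d3 <- fx$data
  perm <- c(3, 1, 4, 2)
  d3$bbs <- utils::modifyList(d3$bbs, list(
    cell = d3$bbs$cell[perm], year = d3$bbs$year[perm],
    pair = d3$bbs$pair[perm], first_year = d3$bbs$first_year[perm],
    y = d3$bbs$y[perm]))
  expect_equal(joint_log_posterior(d3, fx$params, "joint"), full,
               tolerance = 1e-12)
})

test_that("joint model with zero checklists equals BBS-only plus checklist priors", {
  fx <- .lp_fixture()
  d0 <- fx$data
  d0$ebird <- utils::modifyList(d0$ebird, list(
    n = 0L, cell = integer(0), year = integer(0), obs = integer(0),
    y = integer(0), X = matrix(0, 0, 6)))
  p <- fx$params
  prior_only <- sum(dnorm(p$b, 0, 10, log = TRUE)) +
    sum(dnorm(p$eps_ebird, 0, sqrt(p$sigma_ebird), log = TRUE)) +
    dgamma(1 / p$sigma_ebird, 0.01, rate = 0.01, log = TRUE) -
    2 * log(p$sigma_ebird)
  expect_equal(joint_log_posterior(d0, p, "joint"),
               joint_log_posterior(d0, p, "bbs") + prior_only,
               tolerance = 1e-10)
  expect_error(joint_log_posterior(fx$data, p[setdiff(names(p), "b")],
                                   "joint"), "missing parameter")
})

test_that("with no zero inflation the ML of gamma is the offset-corrected mean count", {
  # one cell-year, n routes, omega = 0, no random effects: the likelihood is
  # Poisson with offset 25/12321, so gamma_hat = sum(y) / (n * 25/12321)
  y <- c(3L, 1L, 4L, 0L, 2L)
  nll <- function(lg) -sum(zip_log_pmf(y, exp(lg + bbs_offset()), 0))
  opt <- stats::optimize(nll, c(-5, 15), tol = 1e-10)
  closed <- sum(y) / (length(y) * 25 / 12321)
  expect_equal(exp(opt$minimum), closed, tolerance = 1e-6)
})
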