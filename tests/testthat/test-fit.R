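# Inference: conjugate closed forms, sampler determinism, an independent
# JAGS cross-check of the posterior, convergence diagnostics, posterior
# summaries, the zero-fraction predictive check and the fit methods.

test_that("conditioned on a known abundance surface the intercept posterior is Normal-Normal", {
  # one cell, log gamma observed (fixed), variances known: alpha | log_gamma
  # is conjugate with prior variance sigma_alpha + tau_alpha + 100 through
  # the alpha <- mu_bcr <- grand-mean chain
  set.seed(42)
  g <- mini_grid(1, 1)
  years <- 2010:2019
  vg <- 0.25; va <- 0.3; ta <- 0.2
  lg <- matrix(rnorm(10, 2, sqrt(vg)), 1, 10)
  bbs <- mini_bbs(g, years)
  fit <- fit_abundance(bbs, grid = g, years = years,
                       mcmc = mcmc_control(n_chains = 3, n_iter = 5000,
                                           n_burnin = 1000, seed = 5),
                       fixed = list(log_gamma = lg, sigma_gamma = vg,
                                    sigma_alpha = va, tau_alpha = ta,
                                    beta = 0, sigma_beta = 1, tau_beta = 1,
                                    eps_bbs = 0, sigma_bbs = 1, eta = 0))
  dr <- do.call(rbind, fit$draws)[, "alpha[1]"]
  post_var <- 1 / (10 / vg + 1 / (va + ta + 100))
  post_mean <- post_var * sum(lg) / vg
  mc_se <- sd(dr) / sqrt(400)  # conservative effective sample size
  expect_lt(abs(mean(dr) - post_mean), 4 * mc_se)
  expect_equal(var(dr), post_var, tolerance = 0.15)
  # fixed parameters keep their values in every draw
  pooled <- do.call(rbind, fit$draws)
  expect_true(all(pooled[, "sigma_gamma"] == vg))
  expect_true(all(pooled[, "eta"] == 0))
})

test_that("fits are reproducible for a seed and differ across seeds", {
  g <- mini_grid(2, 1)
  bbs <- mini_bbs(g, 2013:2016, counts = c(0L, 2L, 1L, 0L, 3L, 1L, 0L, 0L))
  ctl <- mcmc_control(n_chains = 2, n_iter = 400, n_burnin = 100, seed = 3)
  f1 <- fit_abundance(bbs, grid = g, mcmc = ctl)
  f2 <- fit_abundance(bbs, grid = g, mcmc = ctl)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_abundance(bbs, grid = g,
                      mcmc = mcmc_control(n_chains = 2, n_iter = 400,
                                          n_burnin = 100, seed = 4))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the sampler agrees with an independent JAGS fit of the same posterior", {
  library(rjags)
  cf <- sim_config(n_cells_x = 3, n_cells_y = 2, n_bcrs = 2,
                   years = 2012:2016, seed = 11,
                   bbs = list(routes_per_cell = 1, sigma_bbs = 0),
                   ebird = list(checklists_per_cell_year = 3,
                                n_observers = 10, sigma_ebird = 0))
  tr <- simulate_truth(cf)
  bbs <- simulate_bbs(tr, cf)
  eb <- simulate_ebird(tr, cf)
  fit <- fit_abundance(bbs, eb, tr$grid, years = cf$years,
                       scale_covariates = FALSE,
                       mcmc = mcmc_control(n_chains = 3, n_iter = 6000,
                                           n_burnin = 1500, seed = 2),
                       fixed = list(eps_bbs = 0, sigma_bbs = 1,
                                    eps_ebird = 0, sigma_ebird = 1))
  s <- summary(fit)
  own <- s$q50[match(c("mu_alpha", "omega_bbs", "omega_ebird", "b0", "b1",
                       "eta", "sigma_gamma"), s$parameter)]
  d <- fit$data
  model_string <- "model {
    for (k in 1:Nb) { muA[k] ~ dnorm(gmA, 1/tA); muB[k] ~ dnorm(gmB, 1/tB) }
    for (i in 1:Nc) {
      a[i] ~ dnorm(muA[bcr[i]], 1/vA); bb[i] ~ dnorm(muB[bcr[i]], 1/vB2)
      for (t in 1:Nt) { lgam[i,t] ~ dnorm(a[i] + bb[i]*yr[t], 1/vG) }
    }
    gmA ~ dnorm(0, .01); gmB ~ dnorm(0, .01)
    pA2 ~ dgamma(.01,.01); vA <- 1/pA2
    pB2 ~ dgamma(.01,.01); vB2 <- 1/pB2
    pTA ~ dgamma(.01,.01); tA <- 1/pTA
    pTB ~ dgamma(.01,.01); tB <- 1/pTB
    pG ~ dgamma(.01,.01); vG <- 1/pG
    eta ~ dnorm(0,.01); omB ~ dunif(0,1)
    for (n in 1:NB) {
      zB[n] ~ dbern(omB)
      log(lamB[n]) <- lgam[cb[n], tb[n]] + off + eta*fy[n]
      yB[n] ~ dpois(lamB[n]*(1-zB[n]) + 1e-10)
    }
    omE ~ dunif(0,1)
    for (m in 1:7) { bcoef[m] ~ dnorm(0, .01) }
    for (n in 1:NE) {
      zE[n] ~ dbern(omE)
      log(lamE[n]) <- lgam[ce[n], te[n]] + bcoef[1] + inprod(X[n,], bcoef[2:7])
      yE[n] ~ dpois(lamE[n]*(1-zE[n]) + 1e-10)
    }
  }"
  dat <- list(Nb = d$n_bcrs, Nc = d$n_cells, Nt = d$n_years, bcr = d$bcr,
              yr = d$year_c, NB = d$bbs$n, cb = d$bbs$cell, tb = d$bbs$year,
              fy = d$bbs$first_year, yB = d$bbs$y, off = bbs_offset(),
              NE = d$ebird$n, ce = d$ebird$cell, te = d$ebird$year,
              X = d$ebird$X, yE = d$ebird$y)
  jm <- jags.model(textConnection(model_string), dat, n.chains = 3,
                   n.adapt = 500, quiet = TRUE)
  update(jm, 1000)
  sm <- coda.samples(jm, c("gmA", "omB", "omE", "bcoef", "eta", "vG"), 3000)
  q <- summary(sm)$quantiles
  jags <- q[c("gmA", "omB", "omE", "bcoef[1]", "bcoef[2]", "eta", "vG"),
            "50%"]
  tol <- c(0.25, 0.05, 0.05, 0.25, 0.15, 0.15, 0.01)
  expect_true(all(abs(own - jags) < tol),
              info = paste(round(own - jags, 4), collapse = " "))
})

test_that("the Gelman-Rubin statistic behaves as the classic formula", {
  set.seed(8)
  m1 <- cbind(p = rnorm(200))
  # identical sample paths in every chain: B = 0, Rhat just below 1
  r <- gelman_rubin(list(m1, m1, m1))
  expect_lt(abs(r - 1), 0.01)
  # chains centered at 0 and 100: far beyond the 1.2 threshold
  far <- list(cbind(p = rnorm(200, 0, 1)), cbind(p = rnorm(200, 100, 1)))
  expect_gt(gelman_rubin(far)["p"], 10)
  # location invariance
  shifted <- lapply(far, function(m) m + 17)
  expect_equal(gelman_rubin(far), gelman_rubin(shifted), tolerance = 1e-12)
  expect_error(gelman_rubin(list(m1)), "2 chains")
  # close agreement with the coda implementation on generic chains (coda
  # applies an extra degrees-of-freedom correction, so only near-equality)
  ch <- lapply(1:3, function(i) cbind(x = rnorm(500, i * 0.1), y = rnorm(500)))
  ours <- gelman_rubin(ch)
  cd <- coda::gelman.diag(coda::as.mcmc.list(lapply(ch, coda::mcmc)),
                          autoburnin = FALSE, multivariate = FALSE)
  expect_equal(unname(ours), unname(cd$psrf[, 1]), tolerance = 0.01)
})

test_that("posterior summaries use pooled type-7 quantiles", {
  d <- list(cbind(p = c(1, 2, 3)), cbind(p = c(1, 2, 3)))
  s <- summarize_posterior(d, rhat = FALSE)
  expect_equal(s$q50, 2)
  dc <- list(cbind(p = rep(4, 50)), cbind(p = rep(4, 50)))
  sc <- summarize_posterior(dc, rhat = FALSE)
  expect_equal(c(sc$q025, sc$q50, sc$q975), c(4, 4, 4))
  set.seed(3)
  dn <- list(cbind(p = rnorm(25000)), cbind(p = rnorm(25000)))
  sn <- summarize_posterior(dn, rhat = FALSE)
  expect_equal(sn$q025, -1.96, tolerance = 0.04)
  expect_equal(sn$q50, 0, tolerance = 0.04)
  expect_equal(sn$q975, 1.96, tolerance = 0.04)
  expect_true(all(sn$q025 <= sn$q50 & sn$q50 <= sn$q975))
})

# one small joint fit shared by the remaining blocks
.small_fit_env <- new.env(parent = emptyenv())
.small_fit <- function() {
  if (is.null(.small_fit_env$val)) {
    cf <- sim_config(n_cells_x = 3, n_cells_y = 2, n_bcrs = 2,
                     years = 2012:2016, seed = 19,
                     ebird = list(checklists_per_cell_year = 3))
    tr <- simulate_truth(cf)
    bbs <- simulate_bbs(tr, cf)
    eb <- simulate_ebird(tr, cf)
    fit <- fit_abundance(bbs, eb, tr$grid, years = cf$years,
                         mcmc = mcmc_control(n_chains = 2, n_iter = 1200,
                                             n_burnin = 400, seed = 6))
    .small_fit_env$val <- list(truth = tr, bbs = bbs, ebird = eb, cf = cf,
                               fit = fit)
  }
  .small_fit_env$val
}

test_that("the zero-fraction predictive check is calibrated on self-generated data", {
  fx <- .small_fit()
  ppc <- ppc_zero_fraction(fx$fit, "bbs", n_rep = 200, seed = 2)
  expect_gte(ppc$p_value, 0.05)
  expect_lte(ppc$p_value, 0.95)
  ppc2 <- ppc_zero_fraction(fx$fit, "bbs", n_rep = 200, seed = 2)
  expect_identical(ppc$replicated, ppc2$replicated)
  expect_error(ppc_zero_fraction(fx$fit, "bbs", n_rep = 1), "at least 2")
})

test_that("a plain-Poisson fit fails the zero-fraction check on zero-inflated data", {
  # heavily zero-inflated counts; the Poisson observation model (omega
  # pinned at 0, with the overdispersion terms that could masquerade as
  # inflation also pinned) cannot reproduce the observed zeros
  cf <- sim_config(n_cells_x = 2, n_cells_y = 2, n_bcrs = 1, seed = 23,
                   bbs = list(routes_per_cell = 5, omega_bbs = 0.5,
                              sigma_bbs = 0))
  tr <- simulate_truth(cf)
  bbs <- simulate_bbs(tr, cf)
  pois <- fit_abundance(bbs, grid = tr$grid, years = cf$years,
                        mcmc = mcmc_control(n_chains = 2, n_iter = 1200,
                                            n_burnin = 400, seed = 6),
                        fixed = list(omega_bbs = 0, sigma_gamma = 0.01,
                                     eps_bbs = 0, sigma_bbs = 1))
  ppc <- ppc_zero_fraction(pois, "bbs", n_rep = 200, seed = 3)
  expect_gt(ppc$observed, quantile(ppc$replicated, 0.975))
  # refitting with free zero inflation restores calibration
  zip <- fit_abundance(bbs, grid = tr$grid, years = cf$years,
                       mcmc = mcmc_control(n_chains = 2, n_iter = 1200,
                                           n_burnin = 400, seed = 6),
                       fixed = list(eps_bbs = 0, sigma_bbs = 1))
  ppc2 <- ppc_zero_fraction(zip, "bbs", n_rep = 200, seed = 3)
  expect_gte(ppc2$p_value, 0.05)
  expect_lte(ppc2$p_value, 0.95)
})

test_that("a fully zero-inflated model replicates only zeros", {
  g <- mini_grid(1, 1)
  bbs <- mini_bbs(g, 2014:2015, counts = 0L)
  fit <- fit_abundance(bbs, grid = g,
                       mcmc = mcmc_control(n_chains = 2, n_iter = 300,
                                           n_burnin = 100, seed = 1),
                       fixed = list(omega_bbs = 1))
  ppc <- ppc_zero_fraction(fit, "bbs", n_rep = 50, seed = 4)
  expect_true(all(ppc$replicated == 1))
})

test_that("a structurally impossible initialization is reported with its term", {
  g <- mini_grid(1, 1)
  bbs <- mini_bbs(g, 2014:2015, counts = 3L)  # non-zero counts
  expect_error(
    fit_abundance(bbs, grid = g,
                  mcmc = mcmc_control(n_chains = 1, n_iter = 100,
                                      n_burnin = 50, seed = 1),
                  fixed = list(omega_bbs = 1)),
    "non-finite log-posterior.*bbs_likelihood")
})

test_that("fit methods expose estimates in the expected shapes", {
  fx <- .small_fit()
  fit <- fx$fit
  co <- coef(fit)
  expect_true(all(c("mu_alpha", "mu_beta", "omega_bbs", "b0") %in% names(co)))
  # scaled-covariate coefficients back-transform to the original scale
  co_w <- coef(fit, scale = "working")
  sc <- fit$data$ebird$scaling
  expect_equal(unname(co["b5"]), unname(co_w["b5"] / sc$scale["DURA"]))
  pa <- predict(fit, "alpha")
  expect_equal(nrow(pa), 6)
  expect_true(all(pa$q025 <= pa$q50 & pa$q50 <= pa$q975))
  pg <- predict(fit, "gamma")
  expect_equal(nrow(pg), 6 * 5)
  expect_true(all(pg$q025 > 0))
  sims <- simulate(fit, nsim = 3, seed = 1, stream = "bbs")
  expect_equal(dim(sims), c(fit$data$bbs$n, 3))
  res <- residuals(fit, "bbs")
  expect_equal(length(res), fit$data$bbs$n)
  expect_true(all(is.finite(res)))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("control validation catches inconsistent settings", {
  expect_error(mcmc_control(n_iter = 100, n_burnin = 200), "smaller")
  expect_error(mcmc_control(n_iter = 101, n_burnin = 50, thin = 2), "divide")
  ctl <- mcmc_control(profile = "test")
  expect_equal(ctl$n_iter, 1500)
  expect_equal(ctl$n_burnin, 500)
})
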