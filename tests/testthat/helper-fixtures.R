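# Shared fixture builders. Everything is generated in code at test time.

# A small single-BCR grid of the given dimensions (cells are 111 km).
mini_grid <- function(nx = 2, ny = 2, n_bcrs = 1) {
  g <- build_grid(c(0, nx * 111, 0, ny * 111))
  g$bcr_id <- as.integer(ceiling(g$col * n_bcrs / nx))
  g$in_range <- rep(TRUE, nrow(g))
  g
}

# Hand-built route records over a mini grid (already zero-filled, flagged).
mini_bbs <- function(grid, years = 2012:2016, counts = NULL) {
  n <- nrow(grid) * length(years)
  d <- data.frame(route_id = rep(sprintf("R%02d", seq_len(nrow(grid))),
                                 each = length(years)),
                  observer_id = rep(sprintf("O%02d", seq_len(nrow(grid))),
                                    each = length(years)),
                  cell_id = rep(grid$cell_id, each = length(years)),
                  year = rep(years, nrow(grid)))
  d$first_year <- 0L
  d$species_count <- if (is.null(counts)) rep(1L, n) else rep_len(counts, n)
  d
}

# Independent enumeration oracle for the zero-inflated Poisson pmf:
# marginalize the structural-zero indicator by explicit two-branch summation.
zip_oracle <- function(y, lambda, omega) {
  p_z1 <- if (y == 0) omega else 0
  p_z0 <- (1 - omega) * stats::dpois(y, lambda)
  log(p_z1 + p_z0)
}

# Term-by-term longhand log-posterior for a fixture, written independently
# of joint_log_posterior (plain loops, stats:: densities).
longhand_log_posterior <- function(data, p, model) {
  d <- data
  total <- dnorm(p$mu_alpha, 0, 10, log = TRUE) +
    dnorm(p$mu_beta, 0, 10, log = TRUE)
  ig <- function(v) 0.01 * log(0.01) - lgamma(0.01) - 1.01 * log(v) - 0.01 / v
  for (v in c(p$sigma_alpha, p$sigma_beta, p$tau_alpha, p$tau_beta,
              p$sigma_gamma, p$sigma_bbs,
              if (model == "joint") p$sigma_ebird)) total <- total + ig(v)
  for (k in seq_along(p$mu_alpha_bcr)) {
    total <- total +
      dnorm(p$mu_alpha_bcr[k], p$mu_alpha, sqrt(p$tau_alpha), log = TRUE) +
      dnorm(p$mu_beta_bcr[k], p$mu_beta, sqrt(p$tau_beta), log = TRUE)
  }
  for (i in seq_len(d$n_cells)) {
    k <- d$bcr[i]
    total <- total +
      dnorm(p$alpha[i], p$mu_alpha_bcr[k], sqrt(p$sigma_alpha), log = TRUE) +
      dnorm(p$beta[i], p$mu_beta_bcr[k], sqrt(p$sigma_beta), log = TRUE)
    for (t in seq_len(d$n_years)) {
      total <- total + dnorm(p$log_gamma[i, t],
                             p$alpha[i] + p$beta[i] * d$year_c[t],
                             sqrt(p$sigma_gamma), log = TRUE)
    }
  }
  for (j in seq_along(p$eps_bbs))
    total <- total + dnorm(p$eps_bbs[j], 0, sqrt(p$sigma_bbs), log = TRUE)
  total <- total + dnorm(p$eta, 0, 10, log = TRUE)
  for (n in seq_len(d$bbs$n)) {
    lam <- exp(p$log_gamma[d$bbs$cell[n], d$bbs$year[n]] + log(25 / 12321) +
               p$eps_bbs[d$bbs$pair[n]] + p$eta * d$bbs$first_year[n])
    total <- total + zip_oracle(d$bbs$y[n], lam, p$omega_bbs)
  }
  if (model == "joint") {
    for (j in seq_along(p$b))
      total <- total + dnorm(p$b[j], 0, 10, log = TRUE)
    for (s in seq_along(p$eps_ebird))
      total <- total + dnorm(p$eps_ebird[s], 0, sqrt(p$sigma_ebird), log = TRUE)
    for (n in seq_len(d$ebird$n)) {
      x <- d$ebird$X[n, ]
      lam <- exp(p$log_gamma[d$ebird$cell[n], d$ebird$year[n]] + p$b[1] +
                 sum(p$b[2:7] * x) + p$eps_ebird[d$ebird$obs[n]])
      total <- total + zip_oracle(d$ebird$y[n], lam, p$omega_ebird)
    }
  }
  total
}
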