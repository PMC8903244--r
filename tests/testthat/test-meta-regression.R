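# Gibbs sampler correctness: conjugate closed-form oracles, GLS limit,
# diagnostics, posterior summaries.

# Small dataset reused across fits in this file.
sim_mr <- simulate_dataset(generator_config(n_obs = 150L, n_cities = 100L, seed = 31L))
cur_mr <- curate_records(filter_records(sim_mr$records))
dm_mr <- build_design(cur_mr)

test_that("with known covariance the sampler matches the closed-form posterior", {
  # single informative equation: y1 on one covariate, second equation
  # intercept-only; Sigma fixed and diagonal, so the traffic-equation
  # posterior is exactly normal with moments computable by direct linear
  # algebra (the independent oracle below)
  set.seed(71)
  n <- 40L
  x <- stats::rnorm(n)
  s1 <- 0.3^2
  sigma <- diag(c(s1, 0.5^2))
  y1 <- 1.5 + 0.8 * x + stats::rnorm(n, 0, sqrt(s1))
  y2 <- stats::rnorm(n, 2, 0.5)

  dm <- structure(list(
    y1 = y1, y2 = y2,
    X1 = matrix(x, ncol = 1, dimnames = list(NULL, "lat10")),
    X2 = matrix(numeric(0), nrow = n, ncol = 0),
    city_index = as.character(seq_len(n)), n = n
  ), class = "pm_design")

  n_keep <- 10000L
  fit <- fit_joint_model(
    dm, pm_priors(),
    mcmc_config(n_chains = 1L, n_iter = n_keep + 500L, n_burn = 500L,
                seed = 72L, fixed_sigma = sigma)
  )

  # oracle: posterior precision A = I/v0 + Z'Z/s1, mean A^{-1} Z'y/s1
  Z <- cbind(1, x)
  A <- diag(2) / 100 + crossprod(Z) / s1
  V <- solve(A)
  m <- V %*% crossprod(Z, y1) / s1

  draws <- fit$beta[, c("traffic:(Intercept)", "traffic:lat10")]
  for (j in 1:2) {
    mcse <- stats::sd(draws[, j]) / sqrt(n_keep)
    expect_lt(abs(mean(draws[, j]) - m[j]), 3 * mcse)
    # sampling variance of a variance estimate: var(s^2) ~ 2 sigma^4 / n
    mcse_var <- sqrt(2 / n_keep) * V[j, j]
    expect_lt(abs(stats::var(draws[, j]) - V[j, j]), 3 * mcse_var)
  }
})

test_that("with flat priors and fixed covariance the fit approaches GLS", {
  sigma <- matrix(c(0.25, 0.12, 0.12, 0.16), 2, 2)
  n_keep <- 4000L
  fit <- fit_joint_model(
    dm_mr, pm_priors(coef_var = 1e8),
    mcmc_config(n_chains = 1L, n_iter = n_keep + 500L, n_burn = 500L,
                seed = 73L, fixed_sigma = sigma)
  )
  # oracle: direct generalized-least-squares solve of the stacked system
  Z1 <- cbind(1, dm_mr$X1); Z2 <- cbind(1, dm_mr$X2)
  n <- dm_mr$n
  Zs <- rbind(cbind(Z1, matrix(0, n, ncol(Z2))),
              cbind(matrix(0, n, ncol(Z1)), Z2))
  Om <- solve(sigma) %x% diag(n)
  beta_gls <- solve(t(Zs) %*% Om %*% Zs, t(Zs) %*% Om %*% c(dm_mr$y1, dm_mr$y2))
  est <- colMeans(fit$beta)
  mcse <- apply(fit$beta, 2, stats::sd) / sqrt(n_keep)
  expect_true(all(abs(est - as.numeric(beta_gls)) < 4 * mcse))
})

test_that("degenerate or deficient designs are rejected with informative errors", {
  dm_bad <- dm_mr
  dm_bad$y2 <- rep(1, dm_bad$n)
  expect_error(fit_joint_model(dm_bad), class = "pm_fit_error")

  dm_rank <- dm_mr
  dm_rank$X1 <- cbind(dm_rank$X1, lat10_copy = dm_rank$X1[, "lat10"])
  err <- expect_error(fit_joint_model(dm_rank), class = "pm_fit_error")
  expect_match(conditionMessage(err), "lat10")

  few <- structure(list(y1 = stats::rnorm(5), y2 = stats::rnorm(5),
                        X1 = dm_mr$X1[1:5, , drop = FALSE],
                        X2 = dm_mr$X2[1:5, , drop = FALSE],
                        city_index = letters[1:5], n = 5L),
                   class = "pm_design")
  expect_error(fit_joint_model(few), class = "pm_fit_error")
})

fit_small <- fit_joint_model(
  dm_mr, pm_priors(),
  mcmc_config(n_chains = 2L, n_iter = 1500L, n_burn = 500L, seed = 74L)
)

test_that("covariance draws are symmetric positive definite with valid correlation", {
  n_draws <- dim(fit_small$sigma)[3]
  expect_equal(n_draws, 2L * 1000L)
  dets <- apply(fit_small$sigma, 3, function(S) S[1, 1] * S[2, 2] - S[1, 2]^2)
  expect_true(all(apply(fit_small$sigma, 3, function(S) S[1, 2] == S[2, 1])))
  expect_true(all(apply(fit_small$sigma, 3, diag) > 0))
  expect_true(all(dets > 0))
  rho <- posterior_correlation(fit_small)
  expect_true(all(rho$draws > -1 & rho$draws < 1))
  expect_equal(rho$mean, mean(rho$draws))
})

test_that("the fit is reproducible from its seed and stable under row permutation", {
  cfg <- mcmc_config(n_chains = 1L, n_iter = 800L, n_burn = 300L, seed = 75L)
  f1 <- fit_joint_model(dm_mr, pm_priors(), cfg)
  f2 <- fit_joint_model(dm_mr, pm_priors(), cfg)
  expect_identical(f1$beta, f2$beta)

  set.seed(76)
  perm <- sample(nrow(cur_mr))
  dmp <- build_design(cur_mr[perm, , drop = FALSE])
  fp <- fit_joint_model(dmp, pm_priors(), cfg)
  mcse <- apply(f1$beta, 2, stats::sd) / sqrt(500)
  expect_true(all(abs(colMeans(fp$beta) - colMeans(f1$beta)) < 4 * mcse))
})

test_that("Gelman-Rubin is ~1 for identical chains and large for disjoint modes", {
  m <- 500L
  set.seed(77)
  one <- stats::rnorm(m)
  beta <- cbind(`traffic:(Intercept)` = c(one, one),
                `overall:(Intercept)` = c(one, one))
  sig <- array(rep(diag(2), 2L * m), c(2, 2, 2L * m))
  fake <- make_fake_posterior(beta, sig, chain = rep(1:2, each = m),
                              columns = list(traffic = "(Intercept)",
                                             overall = "(Intercept)"),
                              sigma_fixed = TRUE)
  gr <- gelman_rubin(fake)
  expect_true(all(gr$rhat <= 1.01))
  expect_false(any(gr$flagged))

  # disjoint modes: N(0,1) and N(10,1); oracle from the B/W identities
  two <- stats::rnorm(m) + 10
  beta2 <- cbind(`traffic:(Intercept)` = c(one, two),
                 `overall:(Intercept)` = c(one, two))
  fake2 <- make_fake_posterior(beta2, sig, chain = rep(1:2, each = m),
                               columns = list(traffic = "(Intercept)",
                                              overall = "(Intercept)"),
                               sigma_fixed = TRUE)
  gr2 <- gelman_rubin(fake2)
  W <- (stats::var(one) + stats::var(two)) / 2
  B <- m * stats::var(c(mean(one), mean(two)))
  rhat_oracle <- sqrt(((m - 1) / m * W + B / m) / W)
  expect_gt(min(gr2$rhat), 3)
  expect_equal(gr2$rhat[1], rhat_oracle, tolerance = 1e-10)
})

test_that("Gelman-Rubin agrees with the coda reference implementation", {
  dm <- draws_matrix_for_test(fit_small)
  ours <- gelman_rubin(fit_small)
  for (p in c("traffic:ln_population", "overall:(Intercept)", "sigma[1,2]")) {
    x <- dm[, p]
    mcl <- coda::mcmc.list(lapply(split(x, fit_small$chain), coda::mcmc))
    ref <- as.numeric(coda::gelman.diag(mcl, autoburnin = FALSE)$psrf[1, 1])
    expect_equal(ours$rhat[ours$parameter == p], ref, tolerance = 0.01)
  }
  expect_error(gelman_rubin(fit_joint_model(
    dm_mr, pm_priors(),
    mcmc_config(n_chains = 1L, n_iter = 300L, n_burn = 100L, seed = 78L)
  )), class = "pm_diagnostic_error")
})

test_that("posterior_summary reports moments and equal-tailed intervals", {
  m <- 200L
  beta <- cbind(`traffic:(Intercept)` = rep(3.2, m),
                `overall:(Intercept)` = rep(-1, m))
  sig <- array(rep(diag(2), m), c(2, 2, m))
  fake <- make_fake_posterior(beta, sig,
                              columns = list(traffic = "(Intercept)",
                                             overall = "(Intercept)"),
                              sigma_fixed = TRUE)
  s <- posterior_summary(fake)
  expect_equal(nrow(s), 2L)  # one row per scalar parameter
  expect_equal(s$mean[1], 3.2)
  expect_equal(s$sd[1], 0)
  expect_equal(s$lower[1], 3.2)
  expect_equal(s$upper[1], 3.2)

  set.seed(79)
  big <- cbind(`traffic:(Intercept)` = stats::rnorm(1e5),
               `overall:(Intercept)` = stats::rnorm(1e5))
  fake2 <- make_fake_posterior(big, array(rep(diag(2), 1e5), c(2, 2, 1e5)),
                               columns = list(traffic = "(Intercept)",
                                              overall = "(Intercept)"),
                               sigma_fixed = TRUE)
  s2 <- posterior_summary(fake2)
  expect_equal(s2$lower[1], -1.96, tolerance = 0.02)
  expect_equal(s2$upper[1], 1.96, tolerance = 0.02)

  s_full <- posterior_summary(fit_small)
  expect_equal(nrow(s_full), 14L + 3L)  # coefficients plus Sigma entries
})

test_that("posterior_correlation handles forced covariance draws exactly", {
  m <- 50L
  beta <- cbind(`traffic:(Intercept)` = numeric(m),
                `overall:(Intercept)` = numeric(m))
  cols <- list(traffic = "(Intercept)", overall = "(Intercept)")
  diag_sig <- array(rep(diag(c(2, 3)), m), c(2, 2, m))
  expect_equal(posterior_correlation(
    make_fake_posterior(beta, diag_sig, columns = cols))$mean, 0)
  eq_sig <- array(rep(matrix(c(4, 2, 2, 4), 2, 2), m), c(2, 2, m))
  rho <- posterior_correlation(make_fake_posterior(beta, eq_sig, columns = cols))
  expect_equal(rho$mean, 0.5)
  expect_equal(rho$sd, 0)
})

test_that("prior and MCMC configuration objects validate their invariants", {
  expect_error(pm_priors(coef_var = 0), class = "pm_config_error")
  expect_error(pm_priors(wishart_df = 1), class = "pm_config_error")
  expect_error(pm_priors(wishart_scale = matrix(c(1, 2, 2, 1), 2, 2)),
               class = "pm_config_error")
  expect_error(mcmc_config(n_iter = 100L, n_burn = 100L),
               class = "pm_config_error")
  expect_error(mcmc_config(n_chains = 0L), class = "pm_config_error")
})
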