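sim_data <- function(sd = 0.5, seed = 1, ...) {
  ds <- generate_dataset(simulation_scenario(obs_error_sd = sd, seed = seed,
                                             ...), 1)
  list(ds = ds, pd = plume_data(ds$y, ds$distances, ds$groups))
}

test_that("identical seeds give bit-identical chains", {
  d <- sim_data()
  f1 <- sample_posterior(d$pd, n_iter = 600, n_burn = 200, seed = 99)
  f2 <- sample_posterior(d$pd, n_iter = 600, n_burn = 200, seed = 99)
  expect_identical(f1$chains, f2$chains)
  f3 <- sample_posterior(d$pd, n_iter = 600, n_burn = 200, seed = 100)
  expect_false(identical(f1$chains, f3$chains))
})

test_that("prior-only sampling reproduces prior moments", {
  pr <- default_priors(tau_y_shape = 2, tau_y_rate = 1,
                       tau_nu_shape = 2, tau_nu_rate = 1,
                       alpha_shape = 2, alpha_rate = 1,
                       theta_logmean = 0, theta_logsd = 1)
  d <- sim_data()
  fit <- sample_posterior(d$pd, model_spec(priors = pr), n_chains = 2,
                          n_iter = 21000, n_burn = 1000, thin = 4,
                          seed = 5, likelihood = FALSE, gr_threshold = 1.2)
  dr <- pooled_draws(fit)
  # alpha ~ gamma(2, 1): mean 2, sd sqrt(2)
  expect_equal(mean(dr[, "alpha[1]"]), 2, tolerance = 0.1)
  expect_equal(sd(dr[, "alpha[1]"]), sqrt(2), tolerance = 0.15)
  # log theta ~ N(0, 1)
  expect_equal(mean(log(dr[, "theta"])), 0, tolerance = 0.1)
  expect_equal(sd(log(dr[, "theta"])), 1, tolerance = 0.1)
  # tau_y ~ gamma(2, 1) drawn exactly
  expect_equal(mean(dr[, "tau_y"]), 2, tolerance = 0.1)
})

test_that("parameters are recovered from low-noise simulated data", {
  d <- sim_data(sd = 0.1, seed = 4)
  fit <- sample_posterior(d$pd, n_iter = 3000, n_burn = 1000, seed = 4)
  expect_true(fit$converged)
  s <- summary(fit)
  a <- s$mean[s$parameter == "alpha[1]"]
  th <- s$mean[s$parameter == "theta"]
  expect_lt(abs(a - 1.25) / 1.25, 0.05)
  expect_lt(abs(th - 1), 0.1)
  # observation precision: truth 1/0.1^2 = 100
  expect_lt(abs(s$mean[s$parameter == "tau_y"] - 100) / 100, 0.25)
})

test_that("the exponential-kernel configuration changes the fitted model", {
  d <- sim_data(sd = 0.3, seed = 6)
  fp <- sample_posterior(d$pd, model_spec("power"),
                         n_iter = 1500, n_burn = 600, seed = 6)
  fe <- sample_posterior(d$pd, model_spec("exponential"),
                         n_iter = 1500, n_burn = 600, seed = 6)
  # data were generated by the power kernel; it must fit better
  expect_lt(mean(unlist(fp$deviance)), mean(unlist(fe$deviance)))
})

test_that("non-convergence is flagged, not silently accepted", {
  d <- sim_data()
  fit <- sample_posterior(d$pd, n_iter = 220, n_burn = 200, seed = 2)
  expect_false(isTRUE(fit$converged) && any(fit$gelman_rubin >= 1.05))
  expect_type(fit$converged, "logical")
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  d <- sim_data(sd = 0.3, seed = 8)
  fit <- sample_posterior(d$pd, n_iter = 4000, n_burn = 1500, seed = 8)
  s <- summary(fit)
  model <- "model {
    for (i in 1:n) {
      for (j in 1:m) { W[i, j] <- pow(D[i, j], -alpha) }
      logy[i] ~ dnorm(log(inprod(beta[], W[i, ])), tau_y)
    }
    for (j in 1:m) {
      beta[j] <- theta * S[j] * exp(nu[j])
      nu[j] ~ dnorm(0, tau_nu)
    }
    alpha ~ dgamma(1, 0.1)
    theta ~ dlnorm(0, 0.1)
    tau_y ~ dgamma(0.01, 0.01)
    tau_nu ~ dgamma(0.01, 0.01)
  }"
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(logy = log(d$pd$y), D = d$pd$D, S = d$pd$S,
                n = length(d$pd$y), m = length(d$pd$S)),
    inits = list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 8),
    n.chains = 1, n.adapt = 500, quiet = TRUE)
  js <- rjags::coda.samples(jm, c("alpha", "theta", "tau_y"), 4000)
  jref <- colMeans(as.matrix(js))
  expect_equal(s$mean[s$parameter == "alpha[1]"], unname(jref["alpha"]),
               tolerance = 0.05)
  expect_equal(s$mean[s$parameter == "tau_y"], unname(jref["tau_y"]),
               tolerance = 0.1)
})

test_that("hold-out pixels are withheld from fitting and scored", {
  d <- sim_data(seed = 9)
  sp <- model_spec(holdout_frac = 0.2)
  fit <- sample_posterior(d$pd, sp, n_iter = 2000, n_burn = 800, seed = 9)
  expect_length(fit$holdout, 60)
  expect_length(intersect(fit$train, fit$holdout), 0)
  st <- model_selection_stats(fit)
  expect_true(is.finite(st$holdout_rmse) && st$holdout_rmse >= 0)
  expect_true(is.finite(st$dic))
  expect_true(is.finite(st$predictive_loss))
  expect_gt(st$pl_penalty, 0)
  # no hold-out: RMSE omitted with a warning
  fit0 <- sample_posterior(d$pd, n_iter = 800, n_burn = 400, seed = 9)
  expect_warning(st0 <- model_selection_stats(fit0), "hold-out")
  expect_true(is.na(st0$holdout_rmse))
})

test_that("adding an unneeded dispersion parameter raises the DIC penalty", {
  sc <- simulation_scenario(coast_label = c("a", "a", "b"), seed = 12)
  ds <- generate_dataset(sc, 1)
  pd <- plume_data(ds$y, ds$distances, ds$groups)
  f1 <- sample_posterior(pd, model_spec(alpha_groups = c(a = 1, b = 1)),
                         n_iter = 3000, n_burn = 1200, seed = 12)
  f2 <- sample_posterior(pd, model_spec(alpha_groups = c(a = 1, b = 2)),
                         n_iter = 3000, n_burn = 1200, seed = 12)
  pD <- suppressWarnings(  # no hold-out set here; RMSE is not the point
    c(model_selection_stats(f1)$pD, model_selection_stats(f2)$pD))
  expect_gt(pD[2], pD[1])
})
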