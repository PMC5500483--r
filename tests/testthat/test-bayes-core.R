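test_that("source influence follows the configured kernel", {
  expect_equal(source_influence(1e-12, 1, 7), 1, tolerance = 1e-9)
  expect_equal(source_influence(1.25, 2, 1), 2)
  expect_equal(source_influence(1.25, 1, 2), 2^(-1.25))
  expect_equal(source_influence(1.25, 1, 2), 0.42045, tolerance = 1e-4)
  d <- sort(runif(20, 0.5, 80))
  expect_true(all(diff(source_influence(1.25, 1, d)) < 0))
  # exponential kernel is a different function, not a reparameterization
  expect_equal(source_influence(0.1, 3, 10, kernel = "exponential"),
               3 * exp(-1))
  dd <- c(1, 2, 5, 20)
  expect_false(isTRUE(all.equal(source_influence(1, 1, dd),
                                source_influence(1, 1, dd, "exponential"))))
  expect_error(source_influence(1, 1, 0), "positive")
})

test_that("mean turbidity sums kernel influences over sources", {
  D <- cbind(c(1, 2), c(2, 1))
  state <- list(alpha = 1.25, theta = 1)
  mu <- predict_mean_turbidity(state, c(1, 1), D)
  expect_equal(mu, rep(1 + 2^(-1.25), 2))
  # single source equals the kernel elementwise
  D1 <- matrix(c(1, 3, 7), 3)
  expect_equal(predict_mean_turbidity(state, 1, D1),
               source_influence(1.25, 1, c(1, 3, 7)))
  # linear in theta
  expect_equal(predict_mean_turbidity(list(alpha = 1.25, theta = 2),
                                      c(1, 1), D), 2 * mu)
  expect_error(predict_mean_turbidity(state, c(1, 1, 1), D), "columns")
})

test_that("forward model is additive over source partitions and label-invariant", {
  set.seed(42)
  for (case in 1:5) {
    m <- sample(2:10, 1); n <- sample(5:50, 1)
    D <- matrix(runif(n * m, 0.5, 100), n, m)
    S <- runif(m, 0.1, 1)
    st <- list(alpha = runif(1, 0.3, 2.5), theta = runif(1, 0.5, 2),
               nu = rnorm(m, 0, 0.2))
    all_mu <- predict_mean_turbidity(st, S, D)
    split <- sample(m, floor(m / 2))
    mu_a <- predict_mean_turbidity(
      list(alpha = st$alpha, theta = st$theta, nu = st$nu[split]),
      S[split], D[, split, drop = FALSE])
    rest <- setdiff(seq_len(m), split)
    mu_b <- predict_mean_turbidity(
      list(alpha = st$alpha, theta = st$theta, nu = st$nu[rest]),
      S[rest], D[, rest, drop = FALSE])
    expect_equal(all_mu, mu_a + mu_b)
    # permuting source labels with their distance columns changes nothing
    perm <- sample(m)
    mu_p <- predict_mean_turbidity(
      list(alpha = st$alpha, theta = st$theta, nu = st$nu[perm]),
      S[perm], D[, perm, drop = FALSE])
    expect_equal(mu_p, all_mu)
  }
})

test_that("log likelihood is the exact Gaussian density of log observations", {
  y <- c(1, 2, 5); tau <- 2.5
  expect_equal(log_likelihood(y, y, tau), 3 * 0.5 * log(tau / (2 * pi)))
  expect_equal(log_likelihood(exp(1), 1, 1), 0.5 * log(1 / (2 * pi)) - 0.5)
  # halving the precision halves the residual term
  resid_term <- function(tau) log_likelihood(exp(1), 1, tau) -
    0.5 * log(tau / (2 * pi))
  expect_equal(resid_term(0.5), 0.5 * resid_term(1))
  expect_error(log_likelihood(c(-1, 1), c(1, 1), 1), "positive")
  expect_error(log_likelihood(c(1, 1), c(0, 1), 1), "positive")
})

test_that("rescaling anchors the minimum at epsilon and refuses double application", {
  expect_equal(rescale_observations(c(5, 6, 7), eps = 0.01),
               c(0.01, 1.01, 2.01))
  set.seed(3)
  raw <- rnorm(50, 10, 4)
  out <- rescale_observations(raw)
  expect_true(all(out > 0))
  expect_equal(min(out), 1e-3 * mean(raw))
  # not idempotent by design: the field flag guards re-application
  expect_false(isTRUE(all.equal(rescale_observations(out), out)))
  f <- gradient_field()
  f$rescaled <- FALSE
  f2 <- rescale_observations(f)
  expect_true(f2$rescaled)
  expect_error(rescale_observations(f2), "already rescaled")
  expect_error(rescale_observations(rep(2, 5)), "constant")
})

test_that("Gelman-Rubin matches the between/within variance formula", {
  # hand toy: 2 chains x 4 draws, one parameter
  c1 <- matrix(c(1, 2, 3, 4), ncol = 1)
  c2 <- matrix(c(2, 3, 4, 9), ncol = 1)
  nit <- 4
  W <- mean(c(var(c1[, 1]), var(c2[, 1])))
  B_over_n <- var(c(mean(c1), mean(c2)))
  expected <- sqrt(((nit - 1) / nit * W + B_over_n) / W)
  expect_equal(unname(gelman_rubin(list(c1, c2))), expected)
  expect_equal(expected, 1.0502101, tolerance = 1e-6)
  # identical chains sit at the floor of 1
  expect_equal(unname(gelman_rubin(list(c1, c1))), 1)
  # disjoint supports blow up
  far <- list(matrix(rnorm(100, 0, 0.1), ncol = 1),
              matrix(rnorm(100, 50, 0.1), ncol = 1))
  expect_gt(gelman_rubin(far), 10)
  expect_error(gelman_rubin(list(c1)), "two chains")
  expect_error(gelman_rubin(list(c1, matrix(1:3, ncol = 1))), "equal")
})

test_that("Gelman-Rubin agrees with coda on well-behaved chains", {
  set.seed(11)
  ch <- lapply(1:3, function(i) matrix(rnorm(600), ncol = 2))
  mine <- gelman_rubin(ch)
  ref <- coda::gelman.diag(coda::as.mcmc.list(lapply(ch, coda::as.mcmc)),
                           autoburnin = FALSE)$psrf[, 1]
  expect_equal(unname(mine), unname(ref), tolerance = 0.03)
})

test_that("model spec validates its label map and priors", {
  expect_error(model_spec(alpha_groups = c(1, 2)), "named")
  expect_error(model_spec(alpha_groups = c(a = 1, b = 3)), "1..G")
  expect_error(default_priors(alpha_shape = -1), "positive")
  sp <- model_spec(alpha_groups = c(south = 1, north = 2))
  expect_equal(sp$kernel, "power")
})
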