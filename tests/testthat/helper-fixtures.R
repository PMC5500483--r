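# shared fixtures built in code at test time

# fitting settings small enough for unit tests but long enough to converge
quick_fit <- list(n_iter = 2500, n_burn = 1000)

# a tiny catchment with one land use, handy for loading arithmetic
one_use_catchment <- function(s = 1, p = 0.5, r = 10, id = "c1",
                              xy = c(0, 0)) {
  source_catchment(id, xy, c(forest = 1), rainfall_total = r,
                   landuse_yields = c(forest = s),
                   runoff_proportions = c(forest = p))
}

# n catchments with unit loadings at given mouth coordinates
unit_catchments <- function(xy) {
  lapply(seq_len(nrow(xy)), function(i)
    one_use_catchment(s = 1, p = 1, r = 1, id = paste0("c", i),
                      xy = xy[i, ]))
}

# small all-ocean field with a linear turbidity gradient
gradient_field <- function(nr = 12, nc = 14, cell = 1) {
  x <- (seq_len(nc) - 0.5) * cell
  y <- (seq_len(nr) - 0.5) * cell
  vals <- outer(y, x, function(yy, xx) 0.2 + 0.1 * xx)
  turbidity_field(vals, x, y, standardized = TRUE, rescaled = TRUE)
}

# brute-force forward model: explicit per-source per-pixel loops
brute_force_mu <- function(alpha_by_source, beta, D, kernel = "power") {
  n <- nrow(D); m <- ncol(D)
  mu <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    k <- if (kernel == "power") D[i, j]^(-alpha_by_source[j]) else
      exp(-alpha_by_source[j] * D[i, j])
    mu[i] <- mu[i] + beta[j] * k
  }
  mu
}
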