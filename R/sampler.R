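#' Bundle observations, distances and sources for fitting
#'
#' @param y Positive observation vector (standardized/rescaled turbidity),
#'   one value per pixel.
#' @param distances n x m matrix from [build_distance_matrix()], km.
#' @param groups List of `source_group`s with relative loadings (max 1),
#'   or a plain numeric loading vector (coast label `"all"`).
#' @return A `plume_data` object.
#' @export
plume_data <- function(y, distances, groups) {
  if (is.numeric(groups))
    groups <- lapply(seq_along(groups), function(j)
      structure(list(group_id = paste0("g", j), member_ids = character(),
                     loading = groups[j], mouth_xy = matrix(NA, 0, 2),
                     coast_label = "all"), class = "source_group"))
  S <- vapply(groups, `[[`, numeric(1), "loading")
  distances <- as.matrix(distances)
  if (any(y <= 0)) stop("observations must be positive; rescale first")
  if (any(distances <= 0)) stop("distances must be positive (0.5 km floor)")
  if (length(y) != nrow(distances) || length(S) != ncol(distances))
    stop("dimension mismatch between y, distances and groups")
  if (any(S < 0) || max(S) <= 0) stop("invalid loadings")
  structure(list(y = as.numeric(y), D = distances, groups = groups, S = S),
            class = "plume_data")
}

#' Sample the posterior by adaptive Metropolis-within-Gibbs
#'
#' Runs `n_chains` independent chains (sequentially, from a single seeded
#' RNG stream with overdispersed initial values), computes the
#' Gelman-Rubin statistic per parameter, and flags the fit as converged
#' only if every statistic is < `gr_threshold`. Non-convergence is
#' reported, never silently accepted.
#'
#' @param data A [plume_data()].
#' @param spec A [model_spec()].
#' @param n_chains Number of chains, at least 2 (needed for Gelman-Rubin).
#' @param n_iter Total iterations per chain, including burn-in.
#' @param n_burn Burn-in iterations (adaptation happens only here).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; identical seeds give bit-identical chains.
#' @param gr_threshold Convergence acceptance bound (default 1.05).
#' @param likelihood Set `FALSE` to sample the prior only (sampler
#'   correctness checks).
#' @param update_nu Set `FALSE` to pin the loading deviations `nu` at 0
#'   (collapses the hierarchy to `beta_j = theta * S_j`).
#' @return A `posterior_samples` object: per-chain draw matrices, stored
#'   training deviance, Gelman-Rubin statistics, hold-out indices, and
#'   the data/spec needed to recompute predictions from the chains.
#' @export
sample_posterior <- function(data, spec = model_spec(), n_chains = 2,
                             n_iter = 3000, n_burn = 1000, thin = 1,
                             seed = 1, gr_threshold = 1.05,
                             likelihood = TRUE, update_nu = TRUE) {
  stopifnot(inherits(data, "plume_data"), inherits(spec, "model_spec"),
            n_chains >= 2, n_burn < n_iter)
  ag <- alpha_index(data$groups, spec)
  G <- max(ag)
  m <- length(data$S)
  n <- length(data$y)
  K <- if (spec$kernel == "power") log(data$D) else data$D
  set.seed(as.integer(seed))
  holdout <- integer(0)
  if (spec$holdout_frac > 0)
    holdout <- sort(sample.int(n, max(1, round(spec$holdout_frac * n))))
  train <- setdiff(seq_len(n), holdout)

  pnames <- c(paste0("alpha[", seq_len(G), "]"), "theta",
              paste0("nu[", seq_len(m), "]"), "tau_y", "tau_nu")
  chains <- vector("list", n_chains)
  devs <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    a0 <- stats::runif(G, 0.5, 2.5)
    W0 <- exp(-K[train, , drop = FALSE] %*% diag(a0[ag], m, m))
    base <- mean(as.numeric(W0 %*% data$S))
    th0 <- max(1e-6, mean(data$y[train]) / base) * exp(stats::rnorm(1, 0, 0.3))
    init <- list(alpha = a0, theta = th0, nu = rep(0, m),
                 tau_y = exp(stats::rnorm(1, 0, 0.3)), tau_nu = 1)
    res <- mcmc_plume(log(data$y[train]), K[train, , drop = FALSE], data$S,
                      as.integer(ag), spec$priors, init,
                      as.integer(n_iter), as.integer(n_burn),
                      as.integer(thin), likelihood, update_nu)
    colnames(res$draws) <- pnames
    chains[[ch]] <- res$draws
    devs[[ch]] <- res$deviance
  }
  gr <- gelman_rubin(chains)
  # tau_nu and nu are not updated when the hierarchy is pinned; drop them
  # from the convergence check in that case
  chk <- if (update_nu) gr else gr[!grepl("^nu\\[|^tau_nu$", names(gr))]
  structure(list(chains = chains, deviance = devs, param_names = pnames,
                 n_burn = n_burn, thin = thin, spec = spec,
                 alpha_group = ag, n_groups = G, data = data,
                 train = train, holdout = holdout,
                 gelman_rubin = gr, converged = all(chk < gr_threshold),
                 seed = seed),
            class = "posterior_samples")
}

#' Gelman-Rubin potential scale reduction
#'
#' For each parameter, with m chains of n draws, W the mean within-chain
#' variance and B/n the variance of the chain means, the statistic is
#' `sqrt(((n-1)/n * W + B/n) / W)`, floored at 1 (the raw formula dips to
#' `sqrt((n-1)/n)` for identical chains). Values near 1 indicate the
#' chains are mixing over the same distribution.
#'
#' @param chains List (>= 2) of equal-size draw matrices, or a
#'   `posterior_samples` object.
#' @return Named vector of statistics, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "posterior_samples")) chains <- chains$chains
  if (!is.list(chains) || length(chains) < 2)
    stop("Gelman-Rubin needs at least two chains")
  nit <- unique(vapply(chains, nrow, 0L))
  if (length(nit) != 1) stop("chains must have equal lengths")
  p <- ncol(chains[[1]])
  out <- vapply(seq_len(p), function(k) {
    x <- vapply(chains, function(ch) ch[, k], numeric(nit))
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W == 0) return(1)
    max(1, sqrt(((nit - 1) / nit * W + B_over_n) / W))
  }, 0)
  names(out) <- colnames(chains[[1]])
  out
}

#' Pooled posterior draws
#'
#' @param samples A `posterior_samples` object.
#' @return One matrix, chains stacked.
#' @export
pooled_draws <- function(samples) {
  do.call(rbind, samples$chains)
}

#' Posterior draws of the mean-turbidity field
#'
#' Recomputes `mu_i` for stored parameter draws — predictions are a pure
#' function of the chains, so reports never need a refit.
#'
#' @param samples A `posterior_samples` object.
#' @param pixels `"all"`, `"train"`, or `"holdout"`.
#' @param max_draws Thin to at most this many draws (default 500).
#' @return Matrix, rows = draws, cols = pixels.
#' @export
posterior_mu <- function(samples, pixels = c("all", "train", "holdout"),
                         max_draws = 500) {
  pixels <- match.arg(pixels)
  idx <- switch(pixels, all = seq_along(samples$data$y),
                train = samples$train, holdout = samples$holdout)
  if (length(idx) == 0) stop("no ", pixels, " pixels")
  dr <- pooled_draws(samples)
  stride <- max(1L, nrow(dr) %/% max_draws)
  K <- if (samples$spec$kernel == "power") log(samples$data$D) else
    samples$data$D
  mu_from_draws(dr, K[idx, , drop = FALSE], samples$data$S,
                as.integer(samples$alpha_group), samples$n_groups,
                as.integer(stride))
}

#' Posterior draws of source contribution shares
#'
#' Per draw, `beta_j = theta * S_j * exp(nu_j)` normalized to sum to 1:
#' each source's share of total at-origin influence.
#'
#' @param samples A `posterior_samples` object.
#' @return Matrix, rows = draws, cols = sources.
#' @export
posterior_shares <- function(samples) {
  dr <- pooled_draws(samples)
  G <- samples$n_groups
  m <- length(samples$data$S)
  nu <- dr[, G + 1 + seq_len(m), drop = FALSE]
  beta <- dr[, G + 1] * sweep(exp(nu), 2, samples$data$S, `*`)
  sh <- beta / rowSums(beta)
  colnames(sh) <- vapply(samples$data$groups, `[[`, character(1), "group_id")
  sh
}

#' Posterior summary table
#'
#' @param object A `posterior_samples` object.
#' @param ... Unused.
#' @return `data.frame` with mean, sd, 2.5/50/97.5 percentiles and
#'   Gelman-Rubin statistic per parameter.
#' @export
summary.posterior_samples <- function(object, ...) {
  dr <- pooled_draws(object)
  qs <- t(apply(dr, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  data.frame(parameter = colnames(dr), mean = colMeans(dr),
             sd = apply(dr, 2, stats::sd),
             q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
             gelman_rubin = object$gelman_rubin, row.names = NULL)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Hierarchical plume model posterior (", length(x$chains), " chains x ",
      nrow(x$chains[[1]]), " draws, kernel = ", x$spec$kernel, ")\n",
      "converged (all Gelman-Rubin < 1.05): ", x$converged, "\n", sep = "")
  print(utils::head(summary(x), 12), digits = 3)
  invisible(x)
}
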