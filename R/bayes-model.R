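#' Default prior hyperparameters
#'
#' Vague priors: gamma(0.01, 0.01) on the observation and loading-deviation
#' precisions, gamma(1, 0.1) on each dispersion parameter (positive,
#' weakly informative), and a lognormal with log-scale mean 0 and variance
#' 10 on the loading-to-turbidity scale.
#'
#' @param tau_y_shape,tau_y_rate Gamma prior on the observation precision.
#' @param tau_nu_shape,tau_nu_rate Gamma prior on the loading-deviation
#'   precision.
#' @param alpha_shape,alpha_rate Gamma prior on each dispersion parameter.
#' @param theta_logmean,theta_logsd Normal prior on log(theta).
#' @return Named list of hyperparameters (all positive).
#' @export
default_priors <- function(tau_y_shape = 0.01, tau_y_rate = 0.01,
                           tau_nu_shape = 0.01, tau_nu_rate = 0.01,
                           alpha_shape = 1, alpha_rate = 0.1,
                           theta_logmean = 0, theta_logsd = sqrt(10)) {
  pr <- list(tau_y_shape = tau_y_shape, tau_y_rate = tau_y_rate,
             tau_nu_shape = tau_nu_shape, tau_nu_rate = tau_nu_rate,
             alpha_shape = alpha_shape, alpha_rate = alpha_rate,
             theta_logmean = theta_logmean, theta_logsd = theta_logsd)
  if (any(unlist(pr[setdiff(names(pr), "theta_logmean")]) <= 0))
    stop("prior hyperparameters must be positive")
  pr
}

#' Model specification
#'
#' Fixes the dispersion kernel, how coast labels map to dispersion
#' parameters, the priors, and the hold-out scheme. The dispersion
#' parameter is stored as a positive magnitude `alpha` and applied as the
#' exponent `-alpha`, so influence declines with distance.
#'
#' @param kernel `"power"` (influence = beta * d^-alpha) or
#'   `"exponential"` (influence = beta * exp(-alpha d)).
#' @param alpha_groups Named integer vector mapping each coast label to a
#'   dispersion-parameter index, e.g. `c(all = 1)` or
#'   `c(south = 1, north = 2)`.
#' @param priors See [default_priors()].
#' @param holdout_frac Fraction of pixels withheld from fitting for
#'   out-of-sample RMSE (0 disables).
#' @return A `model_spec` object.
#' @export
model_spec <- function(kernel = c("power", "exponential"),
                       alpha_groups = c(all = 1L),
                       priors = default_priors(),
                       holdout_frac = 0) {
  kernel <- match.arg(kernel)
  stopifnot(holdout_frac >= 0, holdout_frac < 1)
  ag <- as.integer(alpha_groups)
  names(ag) <- names(alpha_groups)
  if (is.null(names(ag)) || any(!nzchar(names(ag))))
    stop("alpha_groups must be a named label -> index map")
  if (!setequal(ag, seq_len(max(ag))))
    stop("alpha group indices must be 1..G")
  structure(list(kernel = kernel, alpha_groups = ag, priors = priors,
                 holdout_frac = holdout_frac),
            class = "model_spec")
}

#' Influence of a single source at a distance
#'
#' Power kernel: `z = beta * d^-alpha`; exponential kernel:
#' `z = beta * exp(-alpha d)`. Strictly decreasing in `d` for
#' `alpha > 0`.
#'
#' @param alpha Positive dispersion magnitude.
#' @param beta Positive influence at the kernel's origin.
#' @param d Distance, km; must be > 0 (callers enforce a 0.5 km floor).
#' @param kernel Kernel family.
#' @return Influence `z`, vectorized over `d`.
#' @export
source_influence <- function(alpha, beta, d, kernel = c("power", "exponential")) {
  kernel <- match.arg(kernel)
  if (any(d <= 0)) stop("distance must be strictly positive")
  stopifnot(alpha >= 0, beta > 0)
  if (kernel == "power") beta * d^(-alpha) else beta * exp(-alpha * d)
}

#' Source influences combined into mean turbidity
#'
#' The expected turbidity at pixel i is the sum over source groups of
#' their influences, `mu_i = sum_j beta_j * k(d_ij; alpha_g(j))` with
#' `beta_j = theta * S_j * exp(nu_j)`.
#'
#' @param state Named list with `alpha` (length-G positive vector),
#'   `theta`, and optionally `nu` (length-m, default 0).
#' @param groups List of `source_group`s (relative loadings) or a numeric
#'   vector of loadings `S_j`.
#' @param distances n x m matrix, km.
#' @param spec A [model_spec()]; supplies the kernel and the coast-label
#'   to alpha-group map.
#' @return Numeric vector of length n, strictly positive.
#' @export
predict_mean_turbidity <- function(state, groups, distances, spec = model_spec()) {
  S <- if (is.numeric(groups)) groups
       else vapply(groups, `[[`, numeric(1), "loading")
  m <- length(S)
  if (ncol(distances) != m)
    stop("distance matrix has ", ncol(distances), " columns but ", m,
         " source groups")
  ag <- alpha_index(groups, spec)
  nu <- if (is.null(state$nu)) rep(0, m) else state$nu
  stopifnot(length(nu) == m, all(state$alpha > 0), state$theta > 0)
  beta <- state$theta * S * exp(nu)
  K <- if (spec$kernel == "power") log(distances) else distances
  W <- exp(-sweep(K, 2, state$alpha[ag], `*`))
  as.numeric(W %*% beta)
}

# coast labels -> 1..G alpha indices, validated against the spec map
alpha_index <- function(groups, spec) {
  if (is.numeric(groups)) return(rep(1L, length(groups)))
  labs <- vapply(groups, `[[`, character(1), "coast_label")
  if (!all(labs %in% names(spec$alpha_groups)))
    stop("coast labels without an alpha group: ",
         paste(setdiff(labs, names(spec$alpha_groups)), collapse = ", "))
  unname(spec$alpha_groups[labs])
}

#' Log likelihood of observed turbidity
#'
#' Multiplicative lognormal observation error: `y_i = mu_i * exp(e_i)`
#' with `e_i ~ Normal(0, 1/tau_y)`, evaluated exactly as a Gaussian
#' density on `log y` (no approximation).
#'
#' @param y Positive observations.
#' @param mu Positive predicted means.
#' @param tau_y Observation precision.
#' @return Scalar log likelihood (of `log y`; omits the fixed `-sum(log y)`
#'   Jacobian, which cancels in all model comparisons).
#' @export
log_likelihood <- function(y, mu, tau_y) {
  if (any(y <= 0) || any(mu <= 0)) stop("y and mu must be positive")
  stopifnot(length(y) == length(mu), tau_y > 0)
  n <- length(y)
  0.5 * n * log(tau_y / (2 * pi)) - 0.5 * tau_y * sum((log(y) - log(mu))^2)
}

#' Rescale raw turbidity to a positive anchored scale
#'
#' Subtracts the minimum and adds a small positive epsilon so the
#' smallest observation equals epsilon and an additive background term
#' need not be estimated. Not idempotent by design — a second application
#' shifts again — so fields carry a `rescaled` flag and re-application to
#' a flagged field is an error.
#'
#' @param raw Numeric vector, or a [turbidity_field()].
#' @param eps Positive offset; default `1e-3 * mean(raw)`.
#' @return Same type as `raw`, strictly positive, minimum = `eps`.
#' @export
rescale_observations <- function(raw, eps = NULL) {
  if (inherits(raw, "turbidity_field")) {
    if (raw$rescaled) stop("field already rescaled; refusing to shift again")
    v <- raw$values[!raw$mask]
    raw$values[!raw$mask] <- rescale_observations(v, eps)
    raw$rescaled <- TRUE
    return(raw)
  }
  stopifnot(all(is.finite(raw)))
  if (max(raw) == min(raw)) stop("constant observations: no contrast to fit")
  if (is.null(eps)) eps <- 1e-3 * mean(raw)
  stopifnot(eps > 0)
  raw - min(raw) + eps
}
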