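#' Model-selection and fit statistics
#'
#' Computes, from stored chains:
#' \itemize{
#'   \item DIC = Dbar + pD with pD = Dbar - D(plug-in), where the
#'     deviance is the Gaussian deviance of log-turbidity on the fitting
#'     pixels and the plug-in point is the posterior median of each
#'     parameter (robust to the strong skew of the positive-scale
#'     parameters, for which the posterior-mean plug-in can land far from
#'     the bulk of the posterior and produce large negative pD);
#'   \item Gelfand-Ghosh predictive loss (squared-error form, k -> inf) on
#'     the log scale: sum over fitting pixels of the squared deviation of
#'     the posterior-predictive mean from the observation (goodness of
#'     fit) plus the posterior-predictive variance (penalty);
#'   \item hold-out RMSE: root-mean-square difference between withheld
#'     observations and the posterior-mean turbidity field, on the
#'     natural (standardized-turbidity) scale.
#' }
#' Lower values of all three indicate a more parsimonious/accurate model.
#'
#' @param samples A `posterior_samples` object from [sample_posterior()].
#' @param max_draws Cap on draws used for posterior-predictive moments.
#' @return A `fit_statistics` list: `dic`, `pD`, `dbar`, `predictive_loss`,
#'   `pl_gof`, `pl_penalty`, `holdout_rmse` (NA with a warning if no
#'   hold-out pixels).
#' @export
model_selection_stats <- function(samples, max_draws = 500) {
  stopifnot(inherits(samples, "posterior_samples"))
  data <- samples$data
  y_tr <- data$y[samples$train]
  dev <- unlist(samples$deviance)
  dbar <- mean(dev)

  # plug-in deviance at the posterior medians
  dr <- pooled_draws(samples)
  pm <- apply(dr, 2, stats::median)
  G <- samples$n_groups
  m <- length(data$S)
  state <- list(alpha = pm[seq_len(G)], theta = pm[G + 1],
                nu = pm[G + 1 + seq_len(m)])
  mu_hat <- predict_mean_turbidity(state, data$groups,
                                   data$D[samples$train, , drop = FALSE],
                                   samples$spec)
  tau_hat <- pm["tau_y"]
  dhat <- -2 * log_likelihood(y_tr, mu_hat, tau_hat)
  pD <- dbar - dhat
  dic <- dbar + pD

  # Gelfand-Ghosh on log scale
  mu_dr <- posterior_mu(samples, "train", max_draws = max_draws)
  lmu <- log(mu_dr)
  em <- colMeans(lmu)
  vm <- apply(lmu, 2, stats::var) + mean(1 / dr[, "tau_y"])
  gof <- sum((log(y_tr) - em)^2)
  pen <- sum(vm)

  rmse <- NA_real_
  if (length(samples$holdout) > 0) {
    pred <- colMeans(posterior_mu(samples, "holdout", max_draws = max_draws))
    rmse <- sqrt(mean((data$y[samples$holdout] - pred)^2))
  } else {
    warning("no hold-out pixels; hold-out RMSE omitted")
  }
  structure(list(dic = dic, pD = pD, dbar = dbar,
                 predictive_loss = gof + pen, pl_gof = gof, pl_penalty = pen,
                 holdout_rmse = rmse),
            class = "fit_statistics")
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf("DIC %.1f (pD %.1f) | predictive loss %.1f | hold-out RMSE %s\n",
              x$dic, x$pD, x$predictive_loss,
              ifelse(is.na(x$holdout_rmse), "-",
                     sprintf("%.4f", x$holdout_rmse))))
  invisible(x)
}
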