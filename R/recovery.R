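#' Recovery metrics
#'
#' Bias, precision and prediction-error summaries for batches of fits to
#' simulated data with known truth:
#' \itemize{
#'   \item `mre()` — mean relative error, a bias measure: the mean over
#'     replicates of (estimate - truth)/truth x 100. Sign is preserved
#'     (negative = under-estimation).
#'   \item `mean_cv()` — mean coefficient of variation, a precision
#'     measure: the mean over replicates of posterior sd / posterior
#'     mean x 100.
#'   \item `prediction_rmse()` — RMSE of predicted vs noiseless
#'     turbidity, absolute and as a percent of the mean true value.
#' }
#'
#' @param estimates Posterior point estimates (posterior means), one per
#'   replicate.
#' @param truth True scalar value (nonzero).
#' @return `mre()`: percent (signed).
#' @export
mre <- function(estimates, truth) {
  if (truth == 0) stop("truth must be nonzero for a relative error")
  mean((estimates - truth) / truth) * 100
}

#' @rdname mre
#' @param posterior_sds,posterior_means Per-replicate posterior sds and
#'   means (means positive).
#' @export
mean_cv <- function(posterior_sds, posterior_means) {
  stopifnot(length(posterior_sds) == length(posterior_means))
  if (any(posterior_means <= 0)) stop("posterior means must be positive")
  mean(posterior_sds / posterior_means) * 100
}

#' @rdname mre
#' @param predicted_mu,true_mu Equal-length vectors of predicted and
#'   noiseless turbidity.
#' @export
prediction_rmse <- function(predicted_mu, true_mu) {
  if (length(predicted_mu) != length(true_mu)) stop("length mismatch")
  r <- sqrt(mean((predicted_mu - true_mu)^2))
  list(absolute = r, percent_of_mean = r / mean(true_mu) * 100)
}

#' Fit a batch of simulated replicates and score recovery
#'
#' Generates each replicate of the scenario, fits the hierarchical model,
#' discards (and counts) replicates whose chains fail the Gelman-Rubin
#' acceptance bound, and aggregates bias (MRE), precision (mean CV) and
#' prediction RMSE against the noiseless truth. A batch with more than
#' half its replicates non-converged is flagged as failed.
#'
#' @param scenario A [simulation_scenario()].
#' @param fit Named list of fitting settings: `n_chains`, `n_iter`,
#'   `n_burn`, `thin`, `priors`, `gr_threshold`, `update_nu`.
#' @param n_replicates Overrides the scenario's replicate count.
#' @param spec_kernel Kernel used in fitting (simulation always uses the
#'   power form).
#' @return A `recovery_report`: per-parameter MRE and mean CV for the
#'   dispersion parameter(s) and contribution shares, prediction RMSE,
#'   convergence counts, and the per-replicate table.
#' @export
run_recovery_batch <- function(scenario, fit = list(), n_replicates = NULL,
                               spec_kernel = "power") {
  stopifnot(inherits(scenario, "simulation_scenario"))
  f <- utils::modifyList(list(n_chains = 2, n_iter = 3000, n_burn = 1000,
                              thin = 1, priors = default_priors(),
                              gr_threshold = 1.05, update_nu = TRUE), fit)
  R <- if (is.null(n_replicates)) scenario$n_replicates else n_replicates
  labs <- unique(scenario$coast_label)
  spec <- model_spec(kernel = spec_kernel,
                     alpha_groups = stats::setNames(seq_along(labs), labs),
                     priors = f$priors)
  m <- length(scenario$source_positions_km)
  G <- length(labs)
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    ds <- generate_dataset(scenario, r)
    fitted <- sample_posterior(plume_data(ds$y, ds$distances, ds$groups),
                               spec, n_chains = f$n_chains,
                               n_iter = f$n_iter, n_burn = f$n_burn,
                               thin = f$thin,
                               seed = replicate_seed(scenario$seed + 7L, r),
                               gr_threshold = f$gr_threshold,
                               update_nu = f$update_nu)
    if (!fitted$converged) {
      rows[[r]] <- list(converged = FALSE)
      next
    }
    dr <- pooled_draws(fitted)
    a_mean <- colMeans(dr[, seq_len(G), drop = FALSE])
    a_sd <- apply(dr[, seq_len(G), drop = FALSE], 2, stats::sd)
    sh <- posterior_shares(fitted)
    pred <- colMeans(posterior_mu(fitted, "all"))
    rows[[r]] <- list(converged = TRUE, alpha_mean = a_mean, alpha_sd = a_sd,
                      share_mean = colMeans(sh),
                      share_sd = apply(sh, 2, stats::sd),
                      rmse = prediction_rmse(pred, ds$mu),
                      pred = pred, mu_true = ds$mu,
                      truth = ds$truth)
  }
  ok <- vapply(rows, `[[`, TRUE, "converged")
  if (!any(ok)) stop("no replicate converged")
  kept <- rows[ok]
  tr1 <- kept[[1]]$truth
  as_rows <- function(fld, k) matrix(unlist(lapply(kept, `[[`, fld)),
                                     ncol = k, byrow = TRUE)
  alpha_mat <- as_rows("alpha_mean", G)
  alpha_sd <- as_rows("alpha_sd", G)
  share_mat <- as_rows("share_mean", m)
  share_sd <- as_rows("share_sd", m)
  mre_alpha <- vapply(seq_len(G), function(g)
    mre(alpha_mat[, g], tr1$alpha[g]), 0)
  cv_alpha <- vapply(seq_len(G), function(g)
    mean_cv(alpha_sd[, g], alpha_mat[, g]), 0)
  mre_share <- vapply(seq_len(m), function(j)
    mre(share_mat[, j], tr1$shares[j]), 0)
  cv_share <- vapply(seq_len(m), function(j)
    mean_cv(share_sd[, j], share_mat[, j]), 0)
  rmse_pct <- vapply(kept, function(r) r$rmse$percent_of_mean, 0)
  rmse_abs <- vapply(kept, function(r) r$rmse$absolute, 0)
  # RMSE of the across-replicate mean prediction: isolates systematic
  # prediction bias from per-replicate observation noise (true fields are
  # identical across replicates when no loading noise is injected)
  np <- length(kept[[1]]$pred)
  mean_pred <- colMeans(matrix(unlist(lapply(kept, `[[`, "pred")),
                               ncol = np, byrow = TRUE))
  bias_rmse <- prediction_rmse(mean_pred, kept[[1]]$mu_true)
  structure(list(
    scenario = scenario, n_replicates = R, n_converged = sum(ok),
    failed = mean(!ok) > 0.5,
    mre_alpha = stats::setNames(mre_alpha, names(tr1$alpha)),
    cv_alpha = stats::setNames(cv_alpha, names(tr1$alpha)),
    mre_shares = mre_share, cv_shares = cv_share,
    rmse_percent = mean(rmse_pct), rmse_absolute = mean(rmse_abs),
    bias_rmse_percent = bias_rmse$percent_of_mean,
    bias_rmse_absolute = bias_rmse$absolute,
    per_replicate = list(alpha = alpha_mat, shares = share_mat,
                         rmse_percent = rmse_pct),
    truth = tr1), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "Recovery over %d/%d converged replicates%s\n", x$n_converged,
    x$n_replicates, if (x$failed) " [FAILED: >50% non-converged]" else ""))
  cat(sprintf("  MRE(alpha): %s %%  | mean CV(alpha): %s %%\n",
              paste(sprintf("%.2f", x$mre_alpha), collapse = ", "),
              paste(sprintf("%.2f", x$cv_alpha), collapse = ", ")))
  cat(sprintf("  MRE(shares): %s %%\n",
              paste(sprintf("%.2f", x$mre_shares), collapse = ", ")))
  cat(sprintf("  prediction RMSE: %.3f%% of mean true turbidity\n",
              x$rmse_percent))
  invisible(x)
}

#' Flatten recovery reports into a table
#'
#' One row per report, mirroring a bias/variance summary table: scenario
#' descriptor, worst-source and dispersion bias, precision, RMSE.
#'
#' @param reports Named list of `recovery_report`s.
#' @return `data.frame`.
#' @export
recovery_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(scenario = nm, n_converged = r$n_converged,
               mre_alpha = max(abs(r$mre_alpha)),
               cv_alpha = mean(r$cv_alpha),
               mre_shares_worst = max(abs(r$mre_shares)),
               cv_shares = mean(r$cv_shares),
               rmse_percent = r$rmse_percent)
  }))
}
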