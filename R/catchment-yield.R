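#' Per-catchment sediment loading from land use and rainfall
#'
#' The wet-season sediment loading of a catchment is the sum over its
#' land-use classes of (yield per unit rainfall) x (runoff proportion) x
#' (total rainfall volume) x (areal fraction under that land use):
#' \deqn{S_k = \sum_l s_l \, p_{l,k} \, r_k \, f_{l,k}}
#' with \eqn{s_l} in mg/L, \eqn{p_{l,k}} dimensionless in (0, 1],
#' \eqn{r_k} in litres and \eqn{\sum_l f_{l,k} = 1}.
#'
#' @param catchment A `source_catchment` object, see [source_catchment()].
#' @return Loading in mg (scalar).
#' @examples
#' ct <- source_catchment("c1", mouth_xy = c(0, 0),
#'                        landuse_fractions = c(forested = 0.25, deforested = 0.75),
#'                        rainfall_total = 100,
#'                        landuse_yields = c(forested = 2, deforested = 1),
#'                        runoff_proportions = c(forested = 0.4, deforested = 0.8))
#' compute_loading(ct)  # 2*0.4*100*0.25 + 1*0.8*100*0.75 = 80
#' @export
compute_loading <- function(catchment) {
  stopifnot(inherits(catchment, "source_catchment"))
  f <- catchment$landuse_fractions
  s <- catchment$landuse_yields[names(f)]
  p <- catchment$runoff_proportions[names(f)]
  r <- catchment$rainfall_total
  sum(s * p * r * f)
}

#' Construct a sediment-source catchment
#'
#' @param id Catchment identifier.
#' @param mouth_xy Numeric length-2, river-mouth planar coordinates in km.
#' @param landuse_fractions Named numeric, areal fraction per land use;
#'   must sum to 1 (tolerance 1e-9).
#' @param rainfall_total Total wet-season rainfall volume over the
#'   catchment, in litres.
#' @param landuse_yields Named numeric, sediment yield per land use in
#'   mg per litre of runoff; names must cover those of
#'   `landuse_fractions`.
#' @param runoff_proportions Named numeric in (0, 1], proportion of
#'   rainfall that runs off each land use, or a single number recycled.
#' @param coast_label Optional categorical tag (e.g. "north"/"south")
#'   selecting which dispersion parameter applies downstream.
#' @return A `source_catchment` list with a `loading` field (mg).
#' @export
source_catchment <- function(id, mouth_xy, landuse_fractions, rainfall_total,
                             landuse_yields, runoff_proportions,
                             coast_label = "all") {
  stopifnot(length(mouth_xy) == 2, all(is.finite(mouth_xy)))
  if (abs(sum(landuse_fractions) - 1) > 1e-9)
    stop("land-use fractions must sum to 1 (got ", sum(landuse_fractions), ")")
  if (any(landuse_fractions < 0) || rainfall_total < 0 ||
      any(landuse_yields < 0))
    stop("negative catchment inputs are not allowed")
  if (length(runoff_proportions) == 1 && is.null(names(runoff_proportions)))
    runoff_proportions <- stats::setNames(
      rep(runoff_proportions, length(landuse_fractions)),
      names(landuse_fractions))
  if (!all(names(landuse_fractions) %in% names(landuse_yields)) ||
      !all(names(landuse_fractions) %in% names(runoff_proportions)))
    stop("landuse_yields and runoff_proportions must name every land use")
  if (any(runoff_proportions <= 0) || any(runoff_proportions > 1))
    stop("runoff proportions must lie in (0, 1]")
  out <- structure(list(
    id = as.character(id), mouth_xy = as.numeric(mouth_xy),
    landuse_fractions = landuse_fractions, rainfall_total = rainfall_total,
    landuse_yields = landuse_yields, runoff_proportions = runoff_proportions,
    coast_label = as.character(coast_label), loading = NA_real_),
    class = "source_catchment")
  out$loading <- compute_loading(out)
  out
}

#' Runoff-proportion curves
#'
#' The proportion of rainfall that runs off a catchment increases with the
#' catchment's spatially averaged wet-season rainfall. Two monotone forms
#' are provided: `"linear_capped"`, \eqn{p = \min(1, c\,r)}, and
#' `"saturating_exp"`, \eqn{p = p_{max}(1 - e^{-k r})}.
#'
#' @param form Curve family.
#' @param coef Slope `c` (1/mm) for the linear form; rate `k` (1/mm) for
#'   the saturating form.
#' @param ceiling Upper asymptote in (0, 1]; only the saturating form
#'   uses it (the linear form caps at 1).
#' @return A `runoff_curve` object usable with [runoff_proportion()].
#' @export
runoff_curve <- function(form = c("linear_capped", "saturating_exp"),
                         coef = 0.001, ceiling = 1) {
  form <- match.arg(form)
  if (coef <= 0) stop("curve coefficient must be positive")
  if (ceiling <= 0 || ceiling > 1) stop("ceiling must lie in (0, 1]")
  structure(list(form = form, coef = coef, ceiling = ceiling),
            class = "runoff_curve")
}

#' Evaluate a runoff curve
#'
#' @param mean_rainfall_mm Spatially averaged wet-season rainfall, mm;
#'   vectorized.
#' @param curve A [runoff_curve()].
#' @return Runoff proportions in (0, 1]; monotone non-decreasing in
#'   rainfall.
#' @export
runoff_proportion <- function(mean_rainfall_mm, curve) {
  stopifnot(inherits(curve, "runoff_curve"), all(mean_rainfall_mm >= 0))
  p <- switch(curve$form,
    linear_capped  = pmin(1, curve$coef * mean_rainfall_mm),
    saturating_exp = curve$ceiling * (1 - exp(-curve$coef * mean_rainfall_mm)))
  if (any(p < 0) || any(p > 1))
    stop("runoff curve produced proportions outside [0, 1]")
  p
}

#' Aggregate nearby river mouths into source groups
#'
#' River mouths whose pairwise straight-line separation is within
#' `threshold_km` (transitively, single-linkage closure) are merged into
#' one source group: loadings are summed and the group keeps every member
#' mouth so that group-to-pixel distances can later be taken as the mean
#' over members. Mouths close together are not separately identifiable by
#' the dispersion model, which is why they are pooled before fitting.
#'
#' @param catchments List of [source_catchment()] objects.
#' @param threshold_km Grouping distance, km (default 5).
#' @return List of `source_group` objects with fields `group_id`,
#'   `member_ids`, `loading` (summed, mg), `mouth_xy` (matrix of member
#'   mouths), `coast_label`.
#' @export
aggregate_sources <- function(catchments, threshold_km = 5) {
  if (length(catchments) == 0) stop("no catchments supplied")
  stopifnot(all(vapply(catchments, inherits, TRUE, "source_catchment")))
  xy <- t(vapply(catchments, `[[`, numeric(2), "mouth_xy"))
  if (nrow(xy) == 1) {
    memb <- 1L
  } else {
    # single linkage + cut at threshold = transitive closure of the
    # within-threshold graph
    hc <- stats::hclust(stats::dist(xy), method = "single")
    memb <- stats::cutree(hc, h = threshold_km)
  }
  ids <- vapply(catchments, `[[`, character(1), "id")
  lapply(sort(unique(memb)), function(g) {
    k <- which(memb == g)
    labs <- unique(vapply(catchments[k], `[[`, character(1), "coast_label"))
    structure(list(
      group_id = paste0("g", g),
      member_ids = ids[k],
      loading = sum(vapply(catchments[k], `[[`, numeric(1), "loading")),
      mouth_xy = xy[k, , drop = FALSE],
      coast_label = labs[[1]]), class = "source_group")
  })
}

#' Rescale group loadings relative to the largest
#'
#' Loadings enter the Bayesian model in relative units: each group's
#' loading is divided by the maximum so the largest group has loading 1
#' and ratios are preserved.
#'
#' @param groups List of `source_group` objects.
#' @return The groups with `loading` replaced by relative loading.
#' @export
normalize_loadings <- function(groups) {
  L <- vapply(groups, `[[`, numeric(1), "loading")
  if (all(L == 0)) stop("all loadings are zero; nothing to normalize")
  if (any(L < 0)) stop("negative loadings")
  mx <- max(L)
  lapply(groups, function(g) { g$loading <- g$loading / mx; g })
}

#' Read a catchment table from CSV
#'
#' Expected columns: `id`, `mouth_x`, `mouth_y`, `rainfall_total_L`,
#' `mean_rainfall_mm`, one `f_<landuse>` column per land use, and
#' optionally `coast_label`. Runoff proportions are computed from
#' `mean_rainfall_mm` through `curve` and shared across land uses.
#'
#' @param path CSV path.
#' @param landuse_yields Named numeric, mg/L per land use; names must
#'   match the `f_<landuse>` columns.
#' @param curve A [runoff_curve()].
#' @return List of [source_catchment()] objects.
#' @export
read_catchment_table <- function(path, landuse_yields,
                                 curve = runoff_curve()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f_", names(tab), value = TRUE)
  if (length(fcols) == 0) stop("no f_<landuse> columns in ", path)
  uses <- sub("^f_", "", fcols)
  if (!all(uses %in% names(landuse_yields)))
    stop("landuse_yields missing classes: ",
         paste(setdiff(uses, names(landuse_yields)), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    p <- runoff_proportion(tab$mean_rainfall_mm[i], curve)
    source_catchment(
      id = tab$id[i], mouth_xy = c(tab$mouth_x[i], tab$mouth_y[i]),
      landuse_fractions = stats::setNames(as.numeric(tab[i, fcols]), uses),
      rainfall_total = tab$rainfall_total_L[i],
      landuse_yields = landuse_yields[uses],
      runoff_proportions = stats::setNames(rep(p, length(uses)), uses),
      coast_label = if ("coast_label" %in% names(tab))
        tab$coast_label[i] else "all")
  })
}
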