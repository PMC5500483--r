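#' Gridded turbidity containers
#'
#' A `turbidity_scene` is one satellite image on a regular planar grid:
#' a value matrix (rows follow `y`, columns follow `x`, both cell-center
#' coordinates in km), an optional quality-flag matrix of the same shape,
#' and an acquisition date. A `turbidity_field` is a temporal summary of
#' scenes, carrying a logical exclusion mask (`TRUE` = masked), the number
#' of scenes summarized, the summary statistic used, and flags recording
#' whether the field has been mean-standardized and min-rescaled.
#'
#' @param values Numeric matrix of turbidity values (NA = missing).
#' @param x,y Cell-center coordinate vectors, km; lengths must match
#'   `ncol(values)` and `nrow(values)`.
#' @param flags Optional quality-flag matrix, same shape as `values`.
#' @param date Acquisition date (`Date` or parseable string).
#' @return A `turbidity_scene` object.
#' @export
turbidity_scene <- function(values, x, y, flags = NULL, date = NULL) {
  values <- as.matrix(values)
  stopifnot(length(x) == ncol(values), length(y) == nrow(values))
  if (!is.null(flags)) {
    flags <- as.matrix(flags)
    if (!all(dim(flags) == dim(values)))
      stop("quality-flag grid is not aligned with the scene")
  }
  if (!is.null(date)) date <- as.Date(date)
  structure(list(values = values, x = as.numeric(x), y = as.numeric(y),
                 flags = flags, date = date),
            class = "turbidity_scene")
}

#' @rdname turbidity_scene
#' @param mask Logical matrix, `TRUE` = excluded cell.
#' @param n_images Number of scenes behind the summary.
#' @param summary_kind One of `"geometric_mean"`, `"max"`, `"min"`,
#'   `"exceedance_freq"`.
#' @param standardized Has the field been divided by its unmasked mean?
#' @param rescaled Has [rescale_observations()] been applied?
#' @export
turbidity_field <- function(values, x, y, mask = NULL, n_images = 1L,
                            summary_kind = "geometric_mean",
                            standardized = FALSE, rescaled = FALSE) {
  values <- as.matrix(values)
  stopifnot(length(x) == ncol(values), length(y) == nrow(values))
  if (is.null(mask)) mask <- is.na(values)
  mask <- mask | is.na(values)
  structure(list(values = values, x = as.numeric(x), y = as.numeric(y),
                 mask = mask, n_images = as.integer(n_images),
                 summary_kind = summary_kind, standardized = standardized,
                 rescaled = rescaled),
            class = "turbidity_field")
}

#' Mask low-quality pixels in a scene
#'
#' Cells whose quality flag falls below `threshold` are set to `NA`; all
#' other cells are untouched. Flag semantics are product-specific; any
#' flag band where larger means better works.
#'
#' @param scene A [turbidity_scene()] with a flag grid (or `flag_grid`
#'   supplied separately).
#' @param flag_grid Optional flag matrix overriding `scene$flags`.
#' @param threshold Flags strictly below this are masked (default 0.01).
#' @return The scene with low-quality cells set to `NA`.
#' @export
quality_filter <- function(scene, flag_grid = NULL, threshold = 0.01) {
  stopifnot(inherits(scene, "turbidity_scene"))
  fl <- if (is.null(flag_grid)) scene$flags else as.matrix(flag_grid)
  if (is.null(fl)) stop("no quality-flag grid available")
  if (!all(dim(fl) == dim(scene$values)))
    stop("quality-flag grid is not aligned with the scene")
  scene$values[fl < threshold] <- NA
  scene
}

#' Mask reef cells and their neighbours
#'
#' Returns a logical mask covering the given reef/shallow cells plus all
#' of their 8-connected neighbours, clipped at the grid boundary. Cells
#' on or next to reefs are excluded to limit benthic-reflectance
#' contamination of the turbidity signal.
#'
#' @param dim Grid dimension `c(nrow, ncol)` or an object with a `values`
#'   matrix.
#' @param reef_cells Two-column matrix/data.frame of (row, col) indices;
#'   may be empty.
#' @return Logical matrix, `TRUE` = masked.
#' @export
mask_reef_adjacent <- function(dim, reef_cells) {
  if (is.list(dim) && !is.null(dim$values)) dim <- base::dim(dim$values)
  msk <- matrix(FALSE, dim[1], dim[2])
  reef_cells <- as.matrix(reef_cells)
  if (nrow(reef_cells) == 0) return(msk)
  if (any(reef_cells[, 1] < 1 | reef_cells[, 1] > dim[1] |
          reef_cells[, 2] < 1 | reef_cells[, 2] > dim[2]))
    stop("reef cells outside grid bounds")
  for (k in seq_len(nrow(reef_cells))) {
    r <- max(1, reef_cells[k, 1] - 1):min(dim[1], reef_cells[k, 1] + 1)
    c <- max(1, reef_cells[k, 2] - 1):min(dim[2], reef_cells[k, 2] + 1)
    msk[r, c] <- TRUE
  }
  msk
}

#' Is a date in the (southern-hemisphere) wet season?
#'
#' November through April inclusive.
#' @param date `Date` vector.
#' @return Logical vector.
#' @export
is_wet_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  m >= 11 | m <= 4
}

#' Summarize a stack of scenes into one field
#'
#' Cellwise temporal summary over co-registered scenes: geometric mean
#' (default), max, min, or the frequency of exceedance of a high-turbidity
#' threshold (scene mean + 2 SD by default). A cell is summarized over the
#' scenes in which it is unmasked; cells missing everywhere stay masked.
#' The summary is then standardized by its unmasked mean so the field has
#' mean 1 (spatial pattern, not absolute units, is what the model uses).
#'
#' @param scenes List of [turbidity_scene()]s, identical grids.
#' @param kind Summary statistic.
#' @param wet_season_only Drop scenes dated outside November-April
#'   (scenes without dates are kept).
#' @param mask Optional extra logical mask applied to the result (e.g.
#'   from [mask_reef_adjacent()]).
#' @param standardize Divide by the unmasked mean (default `TRUE`).
#' @param exceed_threshold Threshold for `kind = "exceedance_freq"`;
#'   default mean + 2 SD over all unmasked scene values.
#' @return A [turbidity_field()].
#' @export
summarize_scenes <- function(scenes,
                             kind = c("geometric_mean", "max", "min",
                                      "exceedance_freq"),
                             wet_season_only = TRUE, mask = NULL,
                             standardize = TRUE, exceed_threshold = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(scenes) >= 1,
            all(vapply(scenes, inherits, TRUE, "turbidity_scene")))
  if (wet_season_only) {
    dated <- !vapply(scenes, function(s) is.null(s$date), TRUE)
    keep <- !dated | vapply(scenes, function(s)
      is.null(s$date) || is_wet_season(s$date), TRUE)
    scenes <- scenes[keep]
    if (length(scenes) == 0) stop("no wet-season scenes left")
  }
  d <- dim(scenes[[1]]$values)
  for (s in scenes) if (!all(dim(s$values) == d))
    stop("scenes are not co-registered")
  arr <- array(unlist(lapply(scenes, `[[`, "values")),
               dim = c(d, length(scenes)))
  if (kind %in% c("geometric_mean") && any(arr <= 0, na.rm = TRUE))
    stop("geometric mean requires strictly positive values")
  if (kind == "exceedance_freq" && is.null(exceed_threshold))
    exceed_threshold <- mean(arr, na.rm = TRUE) + 2 * stats::sd(arr, na.rm = TRUE)
  f <- switch(kind,
    geometric_mean = function(v) exp(mean(log(v))),
    max = max, min = min,
    exceedance_freq = function(v) mean(v > exceed_threshold))
  vals <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else f(v)
  })
  if (!is.null(mask)) vals[mask] <- NA
  if (standardize) {
    mu <- mean(vals, na.rm = TRUE)
    if (!is.finite(mu) || mu == 0) stop("cannot standardize: mean is 0 or NA")
    vals <- vals / mu
  }
  turbidity_field(vals, scenes[[1]]$x, scenes[[1]]$y,
                  n_images = length(scenes), summary_kind = kind,
                  standardized = standardize)
}

#' Block-average a field to coarser resolution
#'
#' Aggregates `factor x factor` blocks (or `c(row, col)` factors) by the
#' arithmetic mean of unmasked member cells; a block with every member
#' masked stays masked. Block means preserve regional averages over
#' fully-unmasked areas. Trailing rows/columns that do not fill a block
#' are dropped.
#'
#' @param field A [turbidity_field()].
#' @param factor Integer aggregation factor(s) >= 1.
#' @return A coarser [turbidity_field()].
#' @export
resample_field <- function(field, factor) {
  stopifnot(inherits(field, "turbidity_field"))
  factor <- rep(as.integer(factor), length.out = 2)
  if (any(factor < 1)) stop("factor must be >= 1")
  d <- dim(field$values)
  if (any(factor > d)) stop("factor larger than the grid")
  if (all(factor == 1)) return(field)
  nr <- d[1] %/% factor[1]; nc <- d[2] %/% factor[2]
  vals <- matrix(NA_real_, nr, nc)
  v <- field$values
  v[field$mask] <- NA
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- v[((i - 1) * factor[1] + 1):(i * factor[1]),
             ((j - 1) * factor[2] + 1):(j * factor[2])]
    if (any(!is.na(blk))) vals[i, j] <- mean(blk, na.rm = TRUE)
  }
  bx <- vapply(seq_len(nc), function(j)
    mean(field$x[((j - 1) * factor[2] + 1):(j * factor[2])]), 0)
  by <- vapply(seq_len(nr), function(i)
    mean(field$y[((i - 1) * factor[1] + 1):(i * factor[1])]), 0)
  turbidity_field(vals, bx, by, n_images = field$n_images,
                  summary_kind = field$summary_kind,
                  standardized = field$standardized,
                  rescaled = field$rescaled)
}

#' Unmasked pixels of a field as a table
#'
#' @param field A [turbidity_field()].
#' @return `data.frame(row, col, x, y, value)` for unmasked cells, in
#'   column-major order.
#' @export
field_pixels <- function(field) {
  stopifnot(inherits(field, "turbidity_field"))
  keep <- which(!field$mask)
  rc <- arrayInd(keep, dim(field$values))
  data.frame(row = rc[, 1], col = rc[, 2],
             x = field$x[rc[, 2]], y = field$y[rc[, 1]],
             value = field$values[keep])
}

#' Pixel-to-source-group distance matrix
#'
#' Entry (i, j) is the mean, over the member river mouths of group j, of
#' the distance from pixel i to the mouth, floored at `floor_km` to keep
#' the power kernel away from its d = 0 singularity. Distances are
#' straight-line in the planar km coordinates by default; the
#' `"overwater"` metric routes around masked (land/reef) cells via
#' 8-connected shortest paths on the unmasked lattice.
#'
#' @param pixels `data.frame` with `x`, `y` columns (e.g.
#'   [field_pixels()]) or a [turbidity_field()].
#' @param groups List of `source_group`s from [aggregate_sources()].
#' @param metric `"euclidean"` or `"overwater"`.
#' @param floor_km Minimum distance, km (default 0.5).
#' @param field Required for `"overwater"`: the [turbidity_field()]
#'   providing the lattice and mask.
#' @return Numeric matrix, rows = pixels, cols = groups, km.
#' @export
build_distance_matrix <- function(pixels, groups,
                                  metric = c("euclidean", "overwater"),
                                  floor_km = 0.5, field = NULL) {
  metric <- match.arg(metric)
  if (inherits(pixels, "turbidity_field")) {
    field <- pixels
    pixels <- field_pixels(pixels)
  }
  stopifnot(all(c("x", "y") %in% names(pixels)), length(groups) >= 1)
  if (metric == "euclidean") {
    D <- vapply(groups, function(g) {
      dm <- vapply(seq_len(nrow(g$mouth_xy)), function(k)
        sqrt((pixels$x - g$mouth_xy[k, 1])^2 +
             (pixels$y - g$mouth_xy[k, 2])^2), numeric(nrow(pixels)))
      rowMeans(matrix(dm, nrow = nrow(pixels)))
    }, numeric(nrow(pixels)))
  } else {
    if (is.null(field)) stop("overwater metric needs the lattice field")
    D <- overwater_distances(field, pixels, groups)
  }
  D <- matrix(pmax(D, floor_km), nrow = nrow(pixels))
  colnames(D) <- vapply(groups, `[[`, character(1), "group_id")
  D
}

# Shortest over-water path lengths on the unmasked 8-connected lattice.
# Each river mouth is snapped to its nearest unmasked cell; the snap
# offset is added so distances stay comparable with the Euclidean metric.
overwater_distances <- function(field, pixels, groups) {
  px <- field_pixels(field)
  n <- nrow(px)
  idx <- matrix(0L, nrow(field$values), ncol(field$values))
  idx[cbind(px$row, px$col)] <- seq_len(n)
  ee <- list(); ww <- list()
  for (dr in -1:1) for (dc in -1:1) {
    if (dr < 0 || (dr == 0 && dc <= 0)) next  # each undirected edge once
    r2 <- px$row + dr; c2 <- px$col + dc
    ok <- r2 >= 1 & r2 <= nrow(idx) & c2 >= 1 & c2 <= ncol(idx)
    ok[ok] <- idx[cbind(r2[ok], c2[ok])] > 0
    if (!any(ok)) next
    a <- which(ok); b <- idx[cbind(r2[a], c2[a])]
    w <- sqrt((px$x[a] - px$x[b])^2 + (px$y[a] - px$y[b])^2)
    ee[[length(ee) + 1]] <- rbind(a, b)
    ww[[length(ww) + 1]] <- w
  }
  g <- igraph::make_graph(as.vector(do.call(cbind, ee)), directed = FALSE,
                          n = n)
  igraph::E(g)$weight <- unlist(ww)
  # distances between the requested pixels and every lattice cell
  pix_id <- idx[cbind(
    vapply(pixels$y, function(y) which.min(abs(field$y - y)), 0L),
    vapply(pixels$x, function(x) which.min(abs(field$x - x)), 0L))]
  if (any(pix_id == 0)) stop("a requested pixel falls on a masked cell")
  dall <- igraph::distances(g, v = pix_id)
  vapply(groups, function(gr) {
    dm <- vapply(seq_len(nrow(gr$mouth_xy)), function(k) {
      snap <- which.min((px$x - gr$mouth_xy[k, 1])^2 +
                        (px$y - gr$mouth_xy[k, 2])^2)
      off <- sqrt((px$x[snap] - gr$mouth_xy[k, 1])^2 +
                  (px$y[snap] - gr$mouth_xy[k, 2])^2)
      dall[, snap] + off
    }, numeric(nrow(pixels)))
    rowMeans(matrix(dm, nrow = nrow(pixels)))
  }, numeric(nrow(pixels)))
}

#' Read/write a turbidity field as plain-text CSV
#'
#' The on-disk format is a value matrix in CSV with the `x` coordinates
#' as the header row and the `y` coordinates as the first column; masked
#' cells are empty. Small, diffable, and round-trips exactly at full
#' double precision.
#'
#' @param field A [turbidity_field()].
#' @param path Output path.
#' @export
write_field_csv <- function(field, path) {
  v <- field$values
  v[field$mask] <- NA
  tab <- cbind(y = field$y, as.data.frame(v))
  names(tab) <- c("y", format(field$x, digits = 17, trim = TRUE))
  utils::write.csv(tab, path, row.names = FALSE, na = "")
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  y <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  turbidity_field(unname(vals), x = as.numeric(names(tab)[-1]), y = y)
}
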