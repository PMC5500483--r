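mk_scene <- function(vals, flags = NULL, date = NULL) {
  turbidity_scene(vals, x = seq_len(ncol(as.matrix(vals))),
                  y = seq_len(nrow(as.matrix(vals))), flags = flags,
                  date = date)
}

test_that("quality filter masks exactly the sub-threshold cells", {
  v <- matrix(1:9, 3, 3)
  ok <- mk_scene(v, flags = matrix(1, 3, 3))
  expect_equal(quality_filter(ok)$values, v)
  none <- mk_scene(v, flags = matrix(0, 3, 3))
  expect_true(all(is.na(quality_filter(none)$values)))
  fl <- matrix(1, 3, 3); fl[1, 2] <- 0.005; fl[3, 3] <- 0
  mixed <- quality_filter(mk_scene(v, flags = fl))
  expect_equal(which(is.na(mixed$values)), which(fl < 0.01))
  expect_equal(mixed$values[fl >= 0.01], v[fl >= 0.01])
  expect_error(quality_filter(mk_scene(v, flags = matrix(1, 2, 2))),
               "aligned")
  expect_error(quality_filter(mk_scene(v)), "flag")
})

test_that("reef mask covers reefs plus 8-neighbours, clipped at edges", {
  expect_equal(sum(mask_reef_adjacent(c(5, 5), cbind(3, 3))), 9)
  expect_equal(sum(mask_reef_adjacent(c(5, 5), cbind(1, 1))), 4)
  expect_equal(sum(mask_reef_adjacent(c(5, 5), cbind(1, 3))), 6)
  expect_equal(sum(mask_reef_adjacent(c(5, 5), matrix(0, 0, 2))), 0)
  expect_error(mask_reef_adjacent(c(5, 5), cbind(6, 3)), "bounds")
})

test_that("geometric-mean summary averages on the log scale and standardizes", {
  s1 <- mk_scene(matrix(1, 2, 2)); s2 <- mk_scene(matrix(100, 2, 2))
  raw <- summarize_scenes(list(s1, s2), standardize = FALSE)
  expect_equal(raw$values, matrix(10, 2, 2))
  expect_equal(raw$n_images, 2L)
  std <- summarize_scenes(list(s1, s2))
  expect_equal(mean(std$values[!std$mask]), 1, tolerance = 1e-9)
  one <- summarize_scenes(list(mk_scene(matrix(c(1, 2, 3, 4), 2)))) # single scene
  expect_equal(mean(one$values), 1, tolerance = 1e-9)
  expect_error(summarize_scenes(list(mk_scene(matrix(c(-1, 2, 3, 4), 2)))),
               "positive")
})

test_that("summaries ignore scene order and handle partial missingness", {
  set.seed(1)
  scenes <- lapply(1:4, function(i) {
    v <- matrix(exp(rnorm(12)), 3, 4)
    if (i == 2) v[1, 1] <- NA  # cell missing in one scene only
    mk_scene(v)
  })
  a <- summarize_scenes(scenes, standardize = FALSE)
  b <- summarize_scenes(rev(scenes), standardize = FALSE)
  expect_equal(a$values, b$values)
  expect_false(is.na(a$values[1, 1]))  # summarized over remaining scenes
})

test_that("exceedance summary counts scenes above threshold", {
  vals <- list(matrix(c(1, 1, 5, 1), 2), matrix(c(1, 1, 5, 5), 2),
               matrix(c(1, 1, 1, 5), 2))
  scenes <- lapply(vals, mk_scene)
  f <- summarize_scenes(scenes, kind = "exceedance_freq",
                        standardize = FALSE, exceed_threshold = 3)
  expect_equal(f$values, matrix(c(0, 0, 2 / 3, 2 / 3), 2))
})

test_that("wet-season filter drops dry-season scenes before summarizing", {
  wet <- mk_scene(matrix(2, 2, 2), date = "2008-01-15")
  dry <- mk_scene(matrix(1000, 2, 2), date = "2008-07-15")
  out <- summarize_scenes(list(wet, dry), standardize = FALSE)
  expect_equal(out$values, matrix(2, 2, 2))
  expect_equal(out$n_images, 1L)
  expect_true(all(is_wet_season(as.Date(c("2007-11-01", "2008-04-30")))))
  expect_false(any(is_wet_season(as.Date(c("2008-05-10", "2008-10-31")))))
})

test_that("block resampling averages unmasked cells and preserves means", {
  f <- turbidity_field(matrix(as.numeric(1:16), 4, 4, byrow = TRUE),
                       x = 1:4, y = 1:4)
  expect_equal(resample_field(f, 1), f)
  r <- resample_field(f, 2)
  expect_equal(r$values[1, 1], mean(c(1, 2, 5, 6)))
  expect_equal(mean(r$values), mean(f$values))  # regional mean preserved
  # one masked cell in a block: mean of the remaining three
  v <- matrix(c(1, 3, 2, NA), 2, 2)
  r1 <- resample_field(turbidity_field(v, 1:2, 1:2), 2)
  expect_equal(r1$values[1, 1], 2)
  # fully masked block stays masked
  v2 <- matrix(NA_real_, 2, 2)
  expect_true(resample_field(turbidity_field(v2, 1:2, 1:2), 2)$mask[1, 1])
  expect_error(resample_field(f, 5), "factor")
})

test_that("distance matrix uses mouth means and the 0.5-km floor", {
  px <- data.frame(x = 3, y = 4)
  g1 <- aggregate_sources(list(one_use_catchment(xy = c(0, 0))))
  expect_equal(unname(build_distance_matrix(px, g1)[1, 1]), 5)
  # group of two mouths at distances 4 and 6 from the pixel -> mean 5
  g2 <- aggregate_sources(unit_catchments(rbind(c(0, 0), c(0, 2))))
  expect_length(g2, 1)
  expect_equal(unname(build_distance_matrix(data.frame(x = 0, y = -4), g2)[1, 1]), 5)
  near <- data.frame(x = 0.1, y = 0)
  expect_equal(unname(build_distance_matrix(near, g1)[1, 1]), 0.5)
})

test_that("over-water distances route around land and never undercut straight lines", {
  x <- seq(0.5, 9.5); y <- seq(0.5, 9.5)
  wall <- outer(y, x, function(yy, xx) xx > 4 & xx < 6 & yy < 8)
  f <- turbidity_field(matrix(1, 10, 10), x, y, mask = wall)
  g <- aggregate_sources(list(one_use_catchment(xy = c(1.5, 1.5))))
  px <- data.frame(x = 8.5, y = 1.5)
  d_euc <- build_distance_matrix(px, g)
  d_sea <- build_distance_matrix(px, g, metric = "overwater", field = f)
  expect_gt(d_sea[1, 1], d_euc[1, 1] + 3)  # detour over the wall
  # open water: lattice path equals straight line along a grid axis
  open <- turbidity_field(matrix(1, 10, 10), x, y)
  d_open <- build_distance_matrix(px, g, metric = "overwater", field = open)
  expect_equal(unname(d_open[1, 1]), 7)
})

test_that("field CSV round-trips values, mask and coordinates", {
  f <- gradient_field(5, 6)
  f$values[2, 3] <- NA
  f <- turbidity_field(f$values, f$x, f$y)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, path)
  g <- read_field_csv(path)
  expect_equal(g$values, f$values)
  expect_equal(g$mask, f$mask)
  expect_equal(g$x, f$x)
  expect_equal(g$y, f$y)
})
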