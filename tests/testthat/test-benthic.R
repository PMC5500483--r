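test_that("site extraction takes the containing cell with nearest-unmasked fallback", {
  f <- gradient_field(6, 8)
  sites <- data.frame(site_id = "s1", x = f$x[3], y = f$y[2])
  out <- extract_turbidity_at_sites(f, sites)
  expect_equal(out$turbidity, f$values[2, 3])
  # masked cell with unmasked neighbours -> neighbour value
  f2 <- f
  f2$mask[2, 3] <- TRUE
  out2 <- extract_turbidity_at_sites(f2, sites)
  expect_true(out2$turbidity %in%
                f2$values[1:3, 2:4][!f2$mask[1:3, 2:4]])
  # site far outside the grid is dropped with a warning
  far <- data.frame(site_id = "s2", x = 999, y = 999)
  expect_warning(out3 <- extract_turbidity_at_sites(f, rbind(sites, far)),
                 "dropped")
  expect_equal(nrow(out3), 1)
})

test_that("survey fixtures are seed-reproducible with the requested inflation", {
  f <- gradient_field(20, 25, 0.5)
  s1 <- generate_survey_fixture(f, n_sites = 168, seed = 3)
  s2 <- generate_survey_fixture(f, n_sites = 168, seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 168)
  expect_true(all(s1$cover_silt >= 0 & s1$cover_silt <= 100))
  expect_true(all(s1$n_transects %in% 2:6))
  # ~30% structural zeros for algae over many sites
  big <- do.call(rbind, lapply(1:6, function(sd)
    generate_survey_fixture(f, n_sites = 168, seed = sd)))
  expect_equal(mean(big$cover_algae == 0), 0.3, tolerance = 0.05)
  expect_error(generate_survey_fixture(gradient_field(2, 2), n_sites = 99),
               "fewer unmasked")
})

test_that("noise-free, inflation-free fixtures fall on the generating curve", {
  f <- gradient_field(20, 25, 0.5)
  p <- survey_fixture_params()
  p$silt$sd <- 0; p$silt$zero_prob <- 0
  p$coral$sd <- 0
  s <- generate_survey_fixture(f, n_sites = 50, params = p, seed = 1)
  expect_equal(s$cover_silt,
               pmin(100, exp(p$silt$intercept + p$silt$slope * s$turbidity)))
  expect_equal(s$cover_coral_sensitive,
               100 / (1 + exp(-(p$coral$intercept +
                                  p$coral$slope * s$turbidity))))
})

test_that("habitat fits recover generated slopes and report significance", {
  f <- gradient_field(20, 25, 0.5)
  s <- generate_survey_fixture(f, n_sites = 168, seed = 7)
  p <- survey_fixture_params()
  silt <- fit_habitat_model(s$turbidity, s$cover_silt, "silt")
  expect_equal(silt$model_form, "zero_inflated_log_linear")
  expect_gt(silt$slope, 0)
  expect_true(silt$significant)
  expect_lt(abs(silt$slope - p$silt$slope), 3 * silt$slope_se)
  coral <- fit_habitat_model(s$turbidity, s$cover_coral_sensitive, "coral")
  expect_equal(coral$model_form, "logit_linear")
  expect_lt(coral$slope, 0)
  expect_true(coral$significant)
  algae <- fit_habitat_model(s$turbidity, s$cover_algae, "algae")
  expect_equal(algae$model_form, "zero_inflated_logit")
  expect_true(all(c("turbidity", "fit", "lwr", "upr") %in%
                    names(algae$curve)))
  expect_true(all(algae$curve$lwr <= algae$curve$upr))
})

test_that("covers unrelated to turbidity are usually not significant", {
  f <- gradient_field(20, 25, 0.5)
  set.seed(31)
  hits <- 0
  for (k in 1:10) {
    cover <- exp(rnorm(168, 1, 0.6))  # independent of turbidity
    turb <- sample(field_pixels(f)$value, 168, replace = TRUE)
    fit <- fit_habitat_model(turb, pmin(cover, 100), "silt")
    hits <- hits + fit$significant
  }
  expect_lte(hits, 2)  # ~5% type-I rate
})

test_that("degenerate all-zero cover is flagged instead of fitted", {
  f <- gradient_field(10, 10)
  turb <- field_pixels(f)$value[1:20]
  fit <- fit_habitat_model(turb, rep(0, 20), "silt")
  expect_equal(fit$degenerate, "all_zero")
  expect_false(fit$significant)
  expect_true(all(fit$curve$fit == 0))
})

test_that("a fixture calibrated to silt 2-19% and coral 21-0.4% endpoints refits them", {
  f <- gradient_field(20, 25, 0.5)
  turb <- field_pixels(f)$value
  lo <- min(turb); hi <- max(turb)
  p <- survey_fixture_params()
  # log-linear silt through (lo, 2%) and (hi, 19%)
  p$silt$slope <- log(19 / 2) / (hi - lo)
  p$silt$intercept <- log(2) - p$silt$slope * lo
  p$silt$zero_prob <- 0; p$silt$sd <- 0.4
  # logit-linear coral through (lo, 21%) and (hi, 0.4%)
  lgt <- function(q) log(q / (1 - q))
  p$coral$slope <- (lgt(0.004) - lgt(0.21)) / (hi - lo)
  p$coral$intercept <- lgt(0.21) - p$coral$slope * lo
  p$coral$sd <- 0.5
  s <- generate_survey_fixture(f, n_sites = 168, params = p, seed = 2)
  silt <- fit_habitat_model(s$turbidity, s$cover_silt, "silt")
  ends <- silt$curve[c(1, nrow(silt$curve)), ]
  expect_true(ends$lwr[1] < 2 * exp(0.4^2 / 2) && 2 < ends$upr[1] * 1.5)
  expect_true(ends$lwr[2] < 19 * exp(0.4^2 / 2) && 19 < ends$upr[2] * 1.5)
  coral <- fit_habitat_model(s$turbidity, s$cover_coral_sensitive, "coral")
  cends <- coral$curve[c(1, nrow(coral$curve)), ]
  expect_lt(abs(cends$fit[1] - 21), 6)
  expect_lt(abs(cends$fit[2] - 0.4), 1.5)
})

test_that("the extreme-turbidity filter drops high sites before fitting", {
  f <- gradient_field(20, 25, 0.5)
  s <- generate_survey_fixture(f, n_sites = 168, seed = 5)
  cutoff <- quantile(s$turbidity, 0.8)
  fit <- fit_habitat_model(s$turbidity, s$cover_silt, "silt",
                           turbidity_cutoff = cutoff)
  expect_lte(max(fit$curve$turbidity), cutoff)
  expect_lt(fit$n, 168)
})
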