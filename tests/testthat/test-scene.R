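test_that("rendered disc matches the requested base color", {
  lay <- test_layout()
  p <- test_params(seed = 7)
  img <- render_scene(lay, p)
  dm <- visionqc:::disc_mask(lay)
  # the correlated texture field dominates the disc-mean uncertainty: its
  # effective sample size is ~ area / (4 pi sigma^2)
  neff <- max(1, sum(dm) / (4 * pi * p$texture_correlation_length^2))
  tol <- 2 * (p$texture_amplitude / sqrt(neff) +
                p$color_noise_sd / sqrt(sum(dm))) + 0.5
  for (ch in 1:3) {
    expect_lt(abs(mean(img[, , ch][dm]) - p$base_color[ch]), tol)
  }
})

test_that("full whitening turns the disc into the white reference color", {
  lay <- test_layout()
  img <- render_scene(lay, test_params(seed = 3, whitening_fraction = 1))
  dm <- visionqc:::disc_mask(lay)
  for (ch in 1:3) {
    expect_equal(mean(img[, , ch][dm]), lay$white_level)
  }
})

test_that("rendering is deterministic given the seed and 8-bit", {
  lay <- test_layout(96)
  a <- render_scene(lay, test_params(seed = 11))
  b <- render_scene(lay, test_params(seed = 11))
  d <- render_scene(lay, test_params(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_true(all(a == round(a)))
  expect_gte(min(a), 0)
  expect_lte(max(a), 255)
})

test_that("invalid layouts are rejected", {
  expect_error(
    scene_layout(128, 128,
                 white_ref = rect_region(100, 8, 20, 28)),  # hits indicator
    class = "visionqc_layout")
  expect_error(
    scene_layout(128, 128, disc_center = c(64, 5), disc_radius = 30),
    class = "visionqc_layout")
  expect_error(appearance_params(whitening_fraction = 1.2),
               class = "visionqc_params")
  expect_error(appearance_params(illumination_gain = 0),
               class = "visionqc_params")
})

test_that("the default design reproduces the full study inventory", {
  inv <- enumerate_design(study_design())
  expect_equal(sum(inv$packages$state == "treated"), 168)
  expect_equal(sum(inv$packages$state == "control"), 9)
  expect_equal(nrow(inv$images), 708)
  expect_equal(sum(inv$images$state == "fresh"), 336)
  expect_equal(sum(inv$images$state == "treated"), 336)
  expect_equal(sum(inv$images$state == "control"), 36)
})

test_that("a minimal design yields one package and four images", {
  d <- study_design(maps = "MAP1",
                    conditions = treatment_condition("TC2", 40, 6, 15),
                    center_replicates = 1, control_times = 0,
                    replicates = 1, controls = FALSE)
  inv <- enumerate_design(d)
  expect_equal(nrow(inv$packages), 1)
  expect_equal(nrow(inv$images), 4)  # 2 slices x 2 events
})

test_that("inventory counts factorize over the design dimensions", {
  for (cfg in list(list(m = 2, ct = c(0, 5), r = 3),
                   list(m = 3, ct = c(0, 3, 7, 14), r = 1))) {
    d <- study_design(maps = paste0("MAP", seq_len(cfg$m)),
                      control_times = cfg$ct, replicates = cfg$r)
    inv <- enumerate_design(d)
    runs <- nrow(visionqc:::design_runs(d))
    n_treated <- cfg$m * runs * length(cfg$ct) * cfg$r
    n_ctrl <- cfg$m * sum(cfg$ct > 0)
    expect_equal(sum(inv$packages$state == "treated"), n_treated)
    expect_equal(sum(inv$packages$state == "control"), n_ctrl)
    expect_equal(nrow(inv$images), (n_treated + n_ctrl) * 2 * 2)
  }
})

test_that("treatment conditions outside the apparatus envelope error", {
  expect_error(treatment_condition("bad", 60, 9, 30),
               class = "visionqc_condition")
  expect_error(treatment_condition("bad", 40, 2, 30),
               class = "visionqc_condition")
})

test_that("simulated cohorts match the enumerated inventory and seed contract", {
  d <- small_design()
  lay <- test_layout(64)
  sim1 <- simulate_cohort(d, layout = lay, seed = 5)
  sim2 <- simulate_cohort(d, layout = lay, seed = 5)
  sim3 <- simulate_cohort(d, layout = lay, seed = 6)
  inv <- enumerate_design(d)
  expect_equal(length(sim1$images), nrow(inv$images))
  expect_identical(sim1$images, sim2$images)
  # different seed: same inventory identity, different pixels
  expect_identical(sim1$inventory$image_id, sim3$inventory$image_id)
  expect_false(identical(sim1$images[[1]], sim3$images[[1]]))
})

test_that("a null effect model leaves treated appearance parameters at fresh values", {
  d <- small_design()
  eff <- effect_model_null(days = c(0, 3), conditions = c("TC2", "control"))
  cp <- visionqc:::cohort_params(d, eff, appearance_population(), seed = 2)
  img <- cp$images
  for (key in unique(paste(img$package_id, img$slice))) {
    rows <- img[paste(img$package_id, img$slice) == key, ]
    expect_equal(rows$base_r[1], rows$base_r[2])
    expect_equal(rows$whitening_fraction, rep(0, nrow(rows)))
  }
})

test_that("out-of-bounds effect severity is clipped with a warning", {
  d <- small_design(control_times = c(0, 3), replicates = 1)
  eff <- effect_model_linear("TC2", days = c(0, 3), whitening0 = 0.9,
                             whitening_per_day = 0.2)
  expect_warning(
    cp <- visionqc:::cohort_params(d, eff, appearance_population(), seed = 1),
    class = "visionqc_effects_clipped")
  expect_true(all(cp$images$whitening_fraction <= 1))
})

test_that("disc mean is an unbiased estimator of base color across seeds", {
  lay <- test_layout(96)
  p <- test_params()
  dm <- visionqc:::disc_mask(lay)
  means <- vapply(1:50, function(s) {
    img <- render_scene(lay, test_params(seed = s))
    mean(img[, , 1][dm])
  }, numeric(1))
  neff <- max(1, sum(dm) / (4 * pi * p$texture_correlation_length^2))
  se <- p$texture_amplitude / sqrt(neff) / sqrt(50)
  expect_lt(abs(mean(means) - p$base_color[1]), 4 * se + 0.5)
})

test_that("monotone effects produce monotone color drift with storage", {
  d <- study_design(maps = "MAP1",
                    conditions = treatment_condition("TC2", 40, 6, 15),
                    center_replicates = 1, control_times = c(0, 3, 7),
                    replicates = 2, controls = FALSE)
  lay <- test_layout(64)
  eff <- effect_model_linear("TC2", days = c(0, 3, 7),
                             whitening0 = 0.05, whitening_per_day = 0.06)
  sim <- simulate_cohort(d, eff, layout = lay, seed = 9)
  dm <- visionqc:::disc_mask(lay)
  base <- appearance_population()$base$base_color
  treated <- dplyr::filter(sim$inventory, state == "treated")
  drift <- vapply(split(treated$image_id, treated$storage_day), function(ids) {
    mean(vapply(ids, function(id) {
      img <- sim$images[[id]]
      sqrt(sum((vapply(1:3, function(ch) mean(img[, , ch][dm]),
                       numeric(1)) - base)^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(drift[order(as.numeric(names(drift)))]) > 0))
})

test_that("non-monotone effect tables trigger a warning", {
  tab <- tibble::tibble(condition = "TC2", storage_day = c(0, 3),
                        dr = 0, dg = 0, db = 0,
                        whitening_delta = c(0.4, 0.1), texture_delta = 0)
  expect_warning(effect_model(tab), class = "visionqc_effects_nonmonotone")
})
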