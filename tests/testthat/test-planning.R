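test_that("strategies expand to the published scenario counts", {
  counts <- c("photon3D-PS" = 15L, "photon3D-BH" = 15L,
              "proton3D-PS" = 45L, "proton3D-BH" = 45L,
              "photon4D-BH" = 105L, "proton4D-BH" = 315L)
  for (nm in names(counts)) {
    bs <- build_strategy(nm)
    expect_equal(nrow(bs$scenarios), unname(counts[nm]), label = nm)
  }
  bs <- build_strategy("photon3D-BH")
  expect_equal(bs$strategy$setup_radius, 7.0)
  expect_equal(bs$strategy$planning_images, 1L)
  bs <- build_strategy("proton4D-BH")
  expect_equal(bs$strategy$setup_radius, 5.7)
  expect_equal(bs$strategy$tumor_shift_radius, 4.1)
  expect_equal(length(unique(bs$scenarios$image_id)), 7L)
  expect_error(build_strategy("carbon3D"), "unknown strategy")
})

test_that("single-objective toy problem scales dose to the prescription", {
  # only the CTV D50% objective active, nominal-only scenarios (zero SDs):
  # the optimum scales the beam weight so soft-D50% sits at 54 Gy
  wat <- box_phantom(shape = c(36L, 36L, 20L), spacing = c(5, 5, 5), hu_value = 0)
  wat$structures$CTV[16:20, 16:20, 9:12] <- TRUE
  wat$structures$lung_ipsi <- wat$structures$CTV
  um0 <- uncertainty_model(Sigma_PS = rep(0, 3), sigma_PS = rep(0, 3),
                           Sigma_BH_A = rep(0, 3), sigma_BH_A = rep(0, 3),
                           Sigma_BH_B = rep(0, 3), sigma_BH_B = rep(0, 3))
  # sharp soft-quantile (gamma = 10/Gy) so soft and exact D50% agree closely;
  # start well below prescription: the one-sided coverage penalty must pull
  # the single effective scale up until D50% sits at 54 Gy
  obj <- objective_config(w_under = 0, w_hot = 0, w_shell = 0, w_cw = 0,
                          gamma = 10)
  suppressWarnings(
    p <- robust_optimize(wat, "photon3D-PS", um = um0, obj = obj,
                         angles = c(0, 90), maxit = 60, start_scale = 0.5)
  )
  ev <- robust_evaluate(p)
  expect_lt(abs(min(ev$ctv_d50) - 54), 1.0)  # soft vs exact quantile slack
})

test_that("optimization descends from the uniform start", {
  for (p in study_plans()) {
    lg <- p$opt_log
    expect_lte(lg$objective[nrow(lg)], lg$objective[1])
    expect_true(all(p$weights >= 0))
  }
})

test_that("normalization pins the worst robust scenario at 54 Gy", {
  # synthetic table: linearity of the scale factor
  plans <- study_plans()
  p <- plans[["photon3D-PS"]]
  fake <- p$robust_eval
  fake$ctv_d50 <- fake$ctv_d50 / min(fake$ctv_d50) * 60  # min 60 Gy
  p2 <- normalize_plan(p, fake)
  expect_equal(p2$normalization_scale / p$normalization_scale, 54 / 60)
  fake$ctv_d50 <- fake$ctv_d50 / min(fake$ctv_d50) * 54  # min already 54
  p3 <- normalize_plan(p, fake)
  expect_equal(p3$normalization_scale, p$normalization_scale)
  fake$ctv_d50[1] <- -1
  expect_error(normalize_plan(p, fake), "not positive")
})

test_that("enlarging the setup radius does not ease the worst case", {
  # nested-stress comparison on a fixed phantom: the optimized plan built
  # for 5.7 mm shifts, when robust-evaluated at 7.0 mm shifts, cannot beat
  # its own 5.7 mm evaluation (worst-case D50 deficit is monotone in radius)
  plans <- study_plans()
  p <- plans[["photon3D-PS"]]   # built at 5.7 mm
  ev57 <- robust_evaluate(p)
  p70 <- p
  st <- setup_shift_samples(7.0)
  sc <- p$scenarios
  sc$dx <- st$dx[sc$setup_id]; sc$dy <- st$dy[sc$setup_id]; sc$dz <- st$dz[sc$setup_id]
  p70$scenarios <- sc
  ev70 <- robust_evaluate(p70)
  expect_lte(min(ev70$ctv_d50), min(ev57$ctv_d50) + 1e-6)
})

test_that("plans tidy and glance into well-formed tibbles", {
  p <- study_plans()[["proton3D-PS"]]
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(p$weights))
  expect_true(all(td$weight >= 0))
  gl <- glance(p)
  expect_equal(gl$n_scenarios, 45L)
  expect_equal(gl$min_robust_ctv_d50, 54, tolerance = 0.1 / 54)
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(p, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$name, "proton3D-PS")
  expect_equal(length(obj$weights), length(p$weights))
})
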