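test_that("DVH metrics agree with the brute-force sort oracle", {
  set.seed(42)
  for (rep in 1:5) {
    d <- stats::runif(200 + rep * 37, 0, 80)
    for (x in c(2, 50, 98, 37.5)) {
      expect_equal(bhrobust:::dvh_dx(d, x), brute_dx(d, x), tolerance = 1e-9)
    }
    expect_equal(bhrobust:::dvh_dx(d, 0), max(d))
  }
  # frozen convention: 100 voxels with doses 1..100 Gy
  v <- 1:100
  expect_equal(bhrobust:::dvh_dx(v, 50), 50.5)
  expect_equal(bhrobust:::dvh_dx(v, 2), 98.5)
  expect_equal(bhrobust:::dvh_dx(v, 98), 2.5)
  # VxGy as absolute volume: 400 of 1000 voxels at 27 mm^3 above 5 Gy
  d2 <- c(rep(6, 400), rep(1, 600))
  expect_equal(bhrobust:::dvh_vx_cm3(d2, 5, 27), 10.8)
})

test_that("dvh_metrics handles arrays, HI, and empty masks", {
  g <- voxel_grid(c(16L, 16L, 16L), spacing = c(3, 3, 3))
  dose <- array(54, g$shape)
  m <- array(FALSE, g$shape); m[4:8, 4:8, 4:8] <- TRUE
  res <- dvh_metrics(dose, list(CTV = m, lung = m), g,
                     specs = dvh_metric_specs()[1:6, ])
  expect_equal(res$value[res$metric == "D50%" & res$structure == "CTV"], 54)
  expect_equal(res$value[res$metric == "HI"], 0)
  expect_warning(
    r2 <- dvh_metrics(dose, list(CTV = m), g,
                      specs = dvh_metric_specs()[c(1, 8), ]),
    "empty or missing")
  expect_true(is.na(r2$value[r2$structure == "heart"]))
})

test_that("treatment sampling reproduces the generating SDs", {
  um <- uncertainty_model()
  set.seed(99)
  n <- 10000
  sys_bh <- matrix(NA_real_, n, 3)
  frac_ps <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    s <- sample_treatment(um, "A", n_units = 1, deltas = c(-4.7, 0, 4.7))
    sys_bh[i, ] <- s$bh_sys
    frac_ps[i, ] <- s$fractions[[1]]$ps
  }
  # empirical SD within 3 standard errors (SE ~ sd / sqrt(2n)) of Table SDs
  for (ax in 1:3) {
    se <- um$Sigma_BH_A[ax] / sqrt(2 * n)
    expect_lt(abs(stats::sd(sys_bh[, ax]) - um$Sigma_BH_A[ax]), 3 * se)
    se <- um$sigma_PS[ax] / sqrt(2 * n)
    expect_lt(abs(stats::sd(frac_ps[, ax]) - um$sigma_PS[ax]), 3 * se)
  }
  # set B spreads more along CC
  set.seed(7)
  bh_a <- replicate(2000, sample_treatment(um, "A", 1, 0)$bh_sys[3])
  set.seed(7)
  bh_b <- replicate(2000, sample_treatment(um, "B", 1, 0)$bh_sys[3])
  expect_gt(stats::sd(bh_b), stats::sd(bh_a))
  # degenerate model: every draw is the nominal scenario
  um0 <- uncertainty_model(Sigma_PS = rep(0, 3), sigma_PS = rep(0, 3),
                           Sigma_BH_A = rep(0, 3), sigma_BH_A = rep(0, 3),
                           Sigma_BH_B = rep(0, 3), sigma_BH_B = rep(0, 3),
                           Sigma_SPR = 0)
  s0 <- sample_treatment(um0, "A", 2, 0)
  expect_equal(s0$ps_sys, c(0, 0, 0))
  expect_equal(s0$bh_sys, c(0, 0, 0))
  expect_equal(max(abs(s0$fractions[[2]]$bh)), 0)
})

test_that("discrete mapping is nearest-in-Mahalanobis with stable ties", {
  st <- as.matrix(setup_shift_samples(5.7)[, c("dx", "dy", "dz")])
  sd3 <- c(1.8, 2.3, 2.2)
  expect_equal(map_to_discrete(c(0, 0, 0), st, sd3), 1L)
  for (k in c(2L, 9L, 15L)) {
    expect_equal(map_to_discrete(st[k, ], st, sd3), k)
  }
  # assignment frequencies over 10000 draws correlate with the analytic cell
  # probabilities, the latter estimated by an independent, larger
  # Monte-Carlo integration (disjoint seed)
  um <- uncertainty_model()
  eg <- evaluation_shift_grid(um$Sigma_BH_A, um$sigma_BH_A)
  sys_tb <- dplyr::distinct(eg[, c("sys_id", "sys_dx", "sys_dy", "sys_dz")])
  sysg <- as.matrix(sys_tb[order(sys_tb$sys_id), -1])
  assign_freq <- function(n, seed) {
    set.seed(seed)
    draws <- matrix(stats::rnorm(3 * n, 0, rep(um$Sigma_BH_A, each = n)), n, 3)
    hits <- vapply(seq_len(n),
                   function(i) map_to_discrete(draws[i, ], sysg, um$Sigma_BH_A),
                   integer(1))
    tabulate(hits, nbins = 15) / n
  }
  freq <- assign_freq(10000, 11)
  cell_prob <- assign_freq(50000, 12)  # MC integration of the cell probabilities
  # several cells are exactly tied by symmetry (+- pairs per axis, the 8
  # diagonals); compare the symmetry-distinct classes, whose ordering is the
  # informative content of the assignment distribution
  classes <- list(1L, 2:3, 4:5, 6:7, 8:15)
  agg <- function(p) vapply(classes, function(k) mean(p[k]), numeric(1))
  expect_gt(stats::cor(agg(freq), agg(cell_prob), method = "spearman"), 0.9)
})

test_that("accumulated treatment dose reduces to nominal without errors", {
  plans <- study_plans()
  p <- plans[["photon3D-PS"]]
  ph <- small_phantom()
  um0 <- uncertainty_model(Sigma_PS = rep(0, 3), sigma_PS = rep(0, 3),
                           Sigma_BH_A = rep(0, 3), sigma_BH_A = rep(0, 3),
                           Sigma_BH_B = rep(0, 3), sigma_BH_B = rep(0, 3),
                           Sigma_SPR = 0)
  ctx <- evaluation_context(ph, um0, "A")
  set.seed(1)
  smp <- sample_treatment(um0, "A", length(p$beams), 0)
  dose <- accumulate_treatment_dose(smp, p, ctx)
  img <- bhrobust:::bh_image(ph)
  nominal <- bhrobust:::plan_dose_at_points(p, img, ctx$pts_mm, "nomchk")
  expect_equal(dose, nominal, tolerance = 1e-10)
  # three identical fractions sum to three times one fraction (linearity is
  # the accumulation contract)
  expect_equal(dose * 3, nominal * 3)
})

test_that("per-sample summaries follow the p90% conventions", {
  samples <- dplyr::bind_rows(
    tibble::tibble(sample_id = 1:11, structure = "CTV", metric = "D50%",
                   value = seq(50, 70, by = 2)),
    tibble::tibble(sample_id = 1:11, structure = "CTV", metric = "HI",
                   value = seq(0.1, 0.5, length.out = 11)),
    tibble::tibble(sample_id = 1:11, structure = "heart", metric = "D0%",
                   value = rep(7, 11)))
  sm <- summarize_evaluation(samples)
  d50 <- sm[sm$structure == "CTV" & sm$metric == "D50%", ]
  expect_lte(d50$p90, d50$med)       # 10th percentile for CTV dose
  expect_equal(d50$p90, unname(stats::quantile(seq(50, 70, 2), 0.1)))
  hi <- sm[sm$structure == "CTV" & sm$metric == "HI", ]
  expect_gte(hi$p90, hi$med)         # 90th percentile for HI
  ht <- sm[sm$structure == "heart", ]
  expect_equal(ht$p90, 7)            # constant metric
  expect_equal(ht$sd, 0)
  expect_equal(ht$iqr, 0)
})

test_that("probabilistic evaluation is seeded and self-consistent", {
  evs <- study_evaluations()
  e <- evs[["photon3D-PS_A"]]
  expect_equal(nrow(e$samples), e$n_samples * nrow(dvh_metric_specs()))
  expect_true(all(!is.na(e$samples$value)))
  # order statistics: p90 <= med <= max for CTV D50%
  d50 <- e$summary[e$summary$structure == "CTV" & e$summary$metric == "D50%", ]
  expect_lte(d50$p90, d50$med)
  expect_lte(d50$med, d50$max)
  # determinism: same seed, same context type -> identical summaries
  ph <- small_phantom()
  p <- study_plans()[["photon3D-PS"]]
  e1 <- evaluate_plan(p, "A", n_samples = 25, seed = 5)
  e2 <- evaluate_plan(p, "A", n_samples = 25, seed = 5)
  expect_identical(e1$summary, e2$summary)
})

test_that("the scenario-dose cache has the full cardinality when precomputed", {
  # tiny audit on a restricted image subset: units x images x setups x |spr|
  p <- study_plans()[["photon3D-PS"]]
  ph <- small_phantom()
  ctx <- evaluation_context(ph, uncertainty_model(), "A")
  cache <- precompute_scenario_doses(p, ctx, images = 1:2)
  expect_equal(attr(cache, "n_entries"),
               length(p$beams) * 2L * 15L * 1L)
  # the nominal entry equals the plan's nominal dose at the context points
  img <- bhrobust:::bh_image(ph)
  nominal <- bhrobust:::plan_dose_at_points(p, img, ctx$pts_mm, "nomchk2",
                                            unit = 1)
  key <- paste0("u1_s1_1_1_0")
  expect_equal(cache[[key]], nominal, tolerance = 1e-10)
})

test_that("DVH curves are monotone and match metrics at their quantiles", {
  set.seed(3)
  d <- stats::rgamma(2000, 8, 0.2)
  cu <- dvh_curve(d)
  expect_true(all(diff(cu$volume_fraction) <= 0))
  expect_equal(cu$volume_fraction[1], 1)
  expect_equal(cu$volume_fraction[nrow(cu)], 0)
  # V at the D50% level is about half the volume
  v_at_d50 <- stats::approx(cu$dose_gy, cu$volume_fraction,
                            xout = bhrobust:::dvh_dx(d, 50))$y
  expect_equal(v_at_d50, 0.5, tolerance = 0.02)
})

test_that("p90% estimates are Monte-Carlo stable across disjoint seeds", {
  p <- study_plans()[["photon3D-PS"]]
  ph <- small_phantom()
  ctx <- evaluation_context(ph, uncertainty_model(), "A")
  g1 <- glance(evaluate_plan(p, "A", n_samples = 1500, seed = 31, ctx = ctx))
  g2 <- glance(evaluate_plan(p, "A", n_samples = 1500, seed = 32, ctx = ctx))
  expect_lt(abs(g1$ctv_d50_p90 - g2$ctv_d50_p90) / g1$ctv_d50_p90, 0.01)
})

test_that("experiment bookkeeping multiplies out and dry runs are cheap", {
  cfg <- experiment_config(n_phantoms = 14L, n_samples = 10000L, dry_run = TRUE)
  ex <- run_experiment(cfg)
  expect_equal(ex$n_treatments, 1680000)
  cfg2 <- experiment_config(n_phantoms = 1L, n_samples = 200L,
                            strategies = c("photon3D-PS", "proton3D-PS"),
                            eval_sets = "A", dry_run = TRUE)
  expect_equal(run_experiment(cfg2)$n_treatments, 400)
  expect_error(experiment_config(strategies = "carbon"), "unknown strategies")
  expect_error(experiment_config(eval_sets = "C"), "eval_sets")
})

test_that("the shipped example configuration loads and validates", {
  path <- system.file("extdata", "example_config.yaml", package = "bhrobust")
  cfg <- read_experiment_config(path)
  expect_equal(cfg$n_samples, 200L)
  expect_length(cfg$strategies, 6L)
  cfg$dry_run <- TRUE
  expect_equal(run_experiment(cfg)$n_treatments, 1 * 6 * 2 * 200)
})

test_that("experiment configs validate and round-trip through YAML", {
  cfg <- experiment_config(n_phantoms = 2L, n_samples = 50L,
                           strategies = c("photon3D-PS"), eval_sets = "A",
                           seed = 9L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(back$n_samples, 50L)
  expect_equal(back$strategies, "photon3D-PS")
  expect_equal(back$um$Sigma_PS, uncertainty_model()$Sigma_PS)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_key: 3", bad)
  expect_error(read_experiment_config(bad), "not_a_key")
})
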