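test_that("radiological path is water-equivalent depth in uniform water", {
  wat <- box_phantom(shape = c(50L, 20L, 20L), spacing = c(2, 2, 2), hu_value = 0)
  entry <- c(wat$grid$origin[1], 0, 0)
  rp <- radiological_path(wat, entry, c(1, 0, 0))
  # inside the box, WEPL equals geometric depth within half a voxel
  inb <- rp$t_mm < 90
  expect_lt(max(abs(rp$wepl_mm[inb] - rp$t_mm[inb])), 1.01)

  # a 40 mm lung segment (SPR ~ 0.25) contributes ~10 mm WEPL
  lng <- box_phantom(shape = c(50L, 20L, 20L), spacing = c(2, 2, 2), hu_value = -750)
  rl <- radiological_path(lng, entry, c(1, 0, 0))
  w40 <- rl$wepl_mm[which.min(abs(rl$t_mm - 40))]
  expect_lt(abs(w40 - 10), 1.0)
})

test_that("photon depth dose has build-up and beams superpose symmetrically", {
  pars <- dose_engine_params()
  z <- seq(0, 300, by = 1)
  pdd <- bhrobust:::pdd_photon(z, pars)
  expect_lt(pdd[1], max(pdd))            # build-up region exists
  expect_gt(which.max(pdd), 5)
  expect_lt(max(pdd), 1 + 1e-9)

  wat <- box_phantom(shape = c(40L, 40L, 24L), spacing = c(4, 4, 4), hu_value = 0)
  wat$structures$CTV[19:22, 19:22, 11:14] <- TRUE
  wat$structures$lung_ipsi <- wat$structures$CTV | wat$structures$lung_ipsi
  b <- make_beams(wat, "photon", angles = c(0, 180), pars = pars)
  d1 <- photon_beam_dose(wat, b[[1]], 1, pars)
  d2 <- photon_beam_dose(wat, b[[2]], 1, pars)
  tot <- d1 + d2
  # opposed beams: profile along the beam axis is symmetric about midline
  prof <- tot[, 20, 12]
  expect_lt(max(abs(prof - rev(prof))), 0.02 * max(prof))
  # linearity: doubling the weight doubles dose everywhere
  expect_equal(photon_beam_dose(wat, b[[1]], 2, pars), 2 * d1)
})

test_that("proton Bragg peak sits at the nominal range and responds to SPR", {
  pars <- dose_engine_params()
  z <- seq(0, 200, by = 0.05)
  R <- 120
  bc <- bhrobust:::bragg_curve(z, R, pars)
  expect_equal(z[which.max(bc)], R)
  expect_true(all(diff(bc[z <= R]) >= -1e-12))  # monotone rise to the peak
  expect_lt(bc[1], 0.5)                         # entrance plateau below peak

  # +4.7% SPR pulls the peak proximally by R (1 - 1/1.047): argmax oracle on
  # the perturbed depth-dose in uniform water (WEPL = depth)
  bp <- bhrobust:::bragg_curve(z * 1.047, R, pars)
  shift <- z[which.max(bc)] - z[which.max(bp)]
  expect_equal(shift, R * (1 - 1 / 1.047), tolerance = 0.02)
})

test_that("proton dose is deterministic, linear, and RBE-weighted once", {
  ph <- small_phantom()
  pars <- test_pars()
  b <- make_beams(ph, "proton", pars = pars)[[1]]
  nw <- bhrobust:::n_beam_weights(b)
  w <- rep(1, nw)
  d1 <- proton_dose(ph, b, w, 0, pars = pars)
  d2 <- proton_dose(ph, b, w, 0, pars = pars)
  expect_identical(d1, d2)
  expect_equal(proton_dose(ph, b, 2 * w, 0, pars = pars), 2 * d1)
  expect_equal(max(proton_dose(ph, b, rep(0, nw), 0, pars = pars)), 0)
  # RBE: the 1.1 factor relative to rbe = 1
  d_phys <- proton_dose(ph, b, w, 0, rbe = 1, pars = pars)
  expect_equal(d1, 1.1 * d_phys)
  # range perturbation changes the dose
  expect_gt(max(abs(proton_dose(ph, b, w, 4.7, pars = pars) - d1)), 0.01 * max(d1))
})

test_that("energy-layer splitting follows the ten-layer breath-hold rule", {
  ph <- small_phantom()
  b <- make_beams(ph, "proton", pars = test_pars())[[1]]
  with_n <- function(n) {
    b$layers <- rep(b$layers[1], n)
    b
  }
  expect_length(split_energy_layers(with_n(10)), 1L)
  s12 <- split_energy_layers(with_n(12))
  expect_equal(vapply(s12, function(x) length(x$layers), integer(1)), c(6L, 6L))
  s11 <- split_energy_layers(with_n(11))
  expect_equal(vapply(s11, function(x) length(x$layers), integer(1)), c(6L, 5L))
  # deepest-first order preserved across the split
  bb <- make_beams(ph, "proton",
                   pars = dose_engine_params(layer_spacing_mm = 2))[[1]]
  sp <- split_energy_layers(bb)
  rng <- unlist(lapply(sp, function(x)
    vapply(x$layers, `[[`, numeric(1), "nominal_range")))
  expect_equal(rng, vapply(bb$layers, `[[`, numeric(1), "nominal_range"))
  expect_true(all(diff(rng) < 0))
})

test_that("scenario dose honours shifts, SPR invariance, and deformation", {
  ph <- small_phantom()
  pars <- test_pars()
  obj <- test_obj()
  plans <- study_plans()
  pphot <- plans[["photon3D-PS"]]
  pprot <- plans[["proton3D-PS"]]

  nom <- compute_scenario_dose(pphot, ph)
  expect_true(all(nom >= 0) && all(is.finite(nom)))
  # photon dose is invariant to SPR perturbation; proton dose is not
  expect_equal(compute_scenario_dose(pphot, ph, spr_perturbation = 4.7), nom)
  pnom <- compute_scenario_dose(pprot, ph)
  expect_gt(max(abs(compute_scenario_dose(pprot, ph, spr_perturbation = 4.7) - pnom)),
            0.01 * max(pnom))

  # lateral setup shift in a uniform water tank translates the photon dose
  # (shift-and-compare oracle): shift one voxel along the in-plane lateral
  # axis of a 0-degree beam (the LR/AP plane), compare to the rolled array
  wat <- box_phantom(shape = c(40L, 40L, 24L), spacing = c(4, 4, 4), hu_value = 0)
  wat$structures$CTV[19:22, 19:22, 11:14] <- TRUE
  wat$structures$lung_ipsi <- wat$structures$CTV
  wplan <- plan_strategy(wat, "photon3D-PS", pars = pars, obj = obj,
                         angles = c(0, 180), maxit = 10)
  d0 <- compute_scenario_dose(wplan, wat)
  dy <- compute_scenario_dose(wplan, wat, setup_shift = c(0, 4, 0))
  # dose under the shift, sampled one voxel back along y, matches nominal
  expect_lt(max(abs(dy[, 1:39, ] - d0[, 2:40, ])), 1e-6 * max(d0))

  # deformed image: dose differs from nominal and stays finite
  f <- invert_dvf(solve_laplacian_dvf(ph, c(0, 0, 4)))
  dd <- compute_scenario_dose(pprot, ph, field = f)
  expect_true(all(is.finite(dd)))
  expect_gt(max(abs(dd - pnom)), 0.005 * max(pnom))
})
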