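test_that("slab geometry reproduces the linear 1D harmonic solution", {
  # lung slab spanning the full cross-section: lateral array edges are
  # zero-flux, so the harmonic displacement between the tumor plane and the
  # lung wall is exactly linear
  ph <- box_phantom(shape = c(40L, 16L, 16L), spacing = c(2, 2, 2),
                    lung_x = 5:36, tumor_x = 5:10)
  s <- 4
  f <- solve_laplacian_dvf(ph, c(0, 0, s), clamp = FALSE)
  u <- f$vectors[, 8, 8, 3]
  # Dirichlet data: tumor plane at x-index 10 holds s, wall (index 37) holds 0
  expected <- s * (37 - (11:36)) / (37 - 10)
  expect_lt(max(abs(u[11:36] - expected)), 0.01 * s)
  expect_equal(u[5:10], rep(s, 6))   # tumor voxels exactly s
  expect_equal(u[37:40], rep(0, 4))  # outside the lung exactly 0
})

test_that("solved fields are discretely harmonic with exact Dirichlet data", {
  ph <- small_phantom()
  sh <- c(2, -1, 3)
  f <- solve_laplacian_dvf(ph, sh)
  lung <- ph$structures$lung_ipsi | ph$structures$CTV
  tumor <- ph$structures$CTV
  domain <- lung & !tumor
  d <- ph$grid$shape
  for (c_ in 1:3) {
    comp <- f$vectors[, , , c_]
    # boundary fidelity
    expect_equal(unname(comp[tumor]), rep(f$shift[c_], sum(tumor)))
    expect_equal(unname(comp[!lung]), rep(0, sum(!lung)))
    # interior voxels equal the mean of their 6 neighbours (isotropic grid)
    interior <- bhrobust:::erode6(domain) &
      bhrobust:::erode6(array(TRUE, d))  # defensive: off array edges
    idx <- which(interior)
    if (length(idx)) {
      n12 <- d[1] * d[2]
      nb_mean <- (comp[idx - 1] + comp[idx + 1] + comp[idx - d[1]] +
                  comp[idx + d[1]] + comp[idx - n12] + comp[idx + n12]) / 6
      expect_lt(max(abs(comp[idx] - nb_mean)), 1e-3)
    }
  }
  # linearity of the Laplace solve in the boundary data
  f2 <- solve_laplacian_dvf(ph, sh / 2)
  expect_lt(max(abs(f$vectors - 2 * f2$vectors)), 1e-3)
  # zero shift gives the identically zero field
  f0 <- solve_laplacian_dvf(ph, c(0, 0, 0))
  expect_equal(max(abs(f0$vectors)), 0)
})

test_that("field inversion is consistent and handles special cases", {
  ph <- small_phantom()
  # zero field -> zero inverse
  f0 <- invert_dvf(solve_laplacian_dvf(ph, c(0, 0, 0)))
  expect_equal(max(abs(f0$inverse)), 0)

  # pure translation over a large domain: inverse is the negated translation
  # in the deep interior
  bx <- box_phantom(shape = c(24L, 24L, 24L), spacing = c(3, 3, 3))
  g <- bx$grid
  tr <- array(0, c(g$shape, 3))
  tr[, , , 1] <- 4
  fld <- structure(list(grid = g, vectors = tr, shift = c(4, 0, 0),
                        inverse = NULL, domain = array(TRUE, g$shape)),
                   class = "bh_dvf")
  fld <- suppressWarnings(invert_dvf(fld))
  core <- fld$inverse[8:16, 8:16, 8:16, 1]
  expect_lt(max(abs(core + 4)), 1e-6)

  # Laplacian field from a 4 mm shift: composition residual below 1/4 voxel
  f <- invert_dvf(solve_laplacian_dvf(ph, c(0, 0, 4)))
  expect_lt(attr(f$inverse, "residual_rms"), 0.25 * min(ph$grid$spacing))
})

test_that("warping moves structures by the shift and round-trips", {
  ph <- small_phantom()
  sh <- c(0, 3, -4)
  f <- invert_dvf(solve_laplacian_dvf(ph, sh))

  # zero field: value-identical warp
  f0 <- solve_laplacian_dvf(ph, c(0, 0, 0))
  expect_equal(warp_image(ph$hu, f0, "linear"), ph$hu)

  # tumor centroid moves by the clamped shift within half a voxel
  wm <- warp_image(ph$structures$CTV, f, "nearest")
  c0 <- colMeans(bhrobust:::grid_points(ph$grid, which(ph$structures$CTV)))
  c1 <- colMeans(bhrobust:::grid_points(ph$grid, which(wm > 0.5)))
  expect_lt(max(abs((c1 - c0) - f$shift)), 0.5 * max(ph$grid$spacing))

  # smooth-volume round trip: bounded interpolation error
  co <- bhrobust:::grid_coords(ph$grid)
  smooth <- array(sin(co$x / 20) + cos(co$y / 25) + sin(co$z / 30), ph$grid$shape)
  rt <- warp_image(warp_image(smooth, f, "linear"), f, "linear", inverse = TRUE)
  rms <- sqrt(mean((rt - smooth)^2))
  expect_lt(rms, 0.05)  # units of a signal with O(1) amplitude
})

test_that("dose accumulation preserves integral dose and maps the maximum back", {
  ph <- small_phantom()
  f <- invert_dvf(solve_laplacian_dvf(ph, c(0, 0, 4)))
  g <- ph$grid
  # smooth dose blob centred on the *shifted* tumor position
  co <- bhrobust:::grid_coords(g)
  ctr <- ph$meta$tumor_center_mm + f$shift
  dose <- array(exp(-((co$x - ctr[1])^2 + (co$y - ctr[2])^2 +
                        (co$z - ctr[3])^2) / (2 * 15^2)), g$shape)
  acc <- accumulate_dose_on_reference(dose, f)
  expect_lt(abs(sum(acc) - sum(dose)) / sum(dose), 0.02)
  # the maximum maps back by about -shift
  am0 <- bhrobust:::grid_points(g, which.max(dose))
  am1 <- bhrobust:::grid_points(g, which.max(acc))
  expect_lt(max(abs((am1 - am0) + f$shift)), 1.5 * max(g$spacing))
  # zero field: identity
  f0 <- invert_dvf(solve_laplacian_dvf(ph, c(0, 0, 0)))
  expect_equal(accumulate_dose_on_reference(dose, f0), dose)
  # missing inverse errors
  fni <- solve_laplacian_dvf(ph, c(0, 0, 2))
  expect_error(accumulate_dose_on_reference(dose, fni), "inverse")
})

test_that("lung-wall clamping scales infeasible shifts, direction preserved", {
  ph <- small_phantom()
  tumor <- ph$structures$CTV
  lung <- ph$structures$lung_ipsi | tumor
  g <- ph$grid

  expect_equal(as.numeric(clamp_shift_to_lung_wall(c(0, 0, 0), tumor, lung, g)),
               c(0, 0, 0))
  # small shift toward a distant wall: unchanged
  s3 <- clamp_shift_to_lung_wall(c(3, 0, 0), tumor, lung, g)
  expect_equal(as.numeric(s3), c(3, 0, 0))

  # large shift: scaled, and the shifted tumor must stay inside the lung
  # (binary-search feasibility oracle: shift voxel centres and test
  # containment in the eroded lung)
  big <- c(40, 0, 0)
  cl <- clamp_shift_to_lung_wall(big, tumor, lung, g)
  expect_lt(sqrt(sum(cl^2)), sqrt(sum(big^2)))
  expect_equal(as.numeric(cl / sqrt(sum(cl^2))), big / sqrt(sum(big^2)))
  interior <- bhrobust:::erode6(lung)
  tpts <- bhrobust:::grid_points(g, which(tumor))
  shifted <- sweep(tpts, 2, as.numeric(cl), "+")
  inside <- bhrobust:::interp_volume(interior + 0,
                                     bhrobust:::world_to_index(g, shifted),
                                     "nearest")
  expect_true(all(inside > 0))
  # tumor outside lung errors
  expect_error(clamp_shift_to_lung_wall(c(1, 0, 0), tumor,
                                        ph$structures$lung_contra, g),
               "not contained")
})
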