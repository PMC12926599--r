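#' The six planning strategies
#'
#' One row per strategy: modality, isotropic setup-shift radius used in
#' robust optimization (the 5.7 mm patient-setup radius, or the enlarged
#' 7.0 mm radius absorbing breath-hold variability for the 3D-BH plans),
#' number of planning images (1, or 7 deformed breath-hold images for the
#' 4D-BH plans), tumor-shift radius of the deformed planning images (4.1 mm),
#' and the SPR perturbation set (protons only). All radii are computed from
#' the uncertainty model via the 90% containment radius, not hard-coded.
#'
#' @param um An [uncertainty_model()].
#' @param spr_perturbations Percent SPR triple for protons.
#' @return Tibble with one row per strategy and an `n_scenarios` column
#'   (15/45 for the 3D plans, 105/315 for the 4D plans).
#' @export
planning_strategies <- function(um = uncertainty_model(),
                                spr_perturbations = c(-4.7, 0, 4.7)) {
  r_ps <- round(ci90_radius(max(um$Sigma_PS), max(um$sigma_PS)), 1)
  r_bh <- round(ci90_radius_combined(c(max(um$Sigma_PS), max(um$sigma_PS)),
                                     c(max(um$Sigma_BH_A), max(um$sigma_BH_A))), 1)
  r_tm <- round(ci90_radius(max(um$Sigma_BH_A), max(um$sigma_BH_A)), 1)
  tb <- tibble::tibble(
    name = c("proton3D-PS", "proton3D-BH", "proton4D-BH",
             "photon3D-PS", "photon3D-BH", "photon4D-BH"),
    modality = rep(c("proton", "photon"), each = 3),
    setup_radius = c(r_ps, r_bh, r_ps, r_ps, r_bh, r_ps),
    planning_images = c(1L, 1L, 7L, 1L, 1L, 7L),
    tumor_shift_radius = c(0, 0, r_tm, 0, 0, r_tm))
  tb$n_spr <- ifelse(tb$modality == "proton", length(spr_perturbations), 1L)
  tb$n_scenarios <- tb$planning_images * 15L * tb$n_spr
  tb
}

#' Build a planning strategy and its robust scenario set
#'
#' Expands one strategy into its full robust-optimization scenario list:
#' planning image x setup position x SPR perturbation. Scenario counts are
#' 15 for photon3D-PS/photon3D-BH, 45 (3x15) for proton3D-PS/proton3D-BH,
#' 105 (15x7) for photon4D-BH and 315 (3x15x7) for proton4D-BH.
#'
#' @param name Strategy name (see [planning_strategies()]).
#' @param um An [uncertainty_model()].
#' @param spr_perturbations Percent SPR triple for protons.
#' @return List with `strategy` (one-row tibble) and `scenarios` (tibble with
#'   `scenario_id`, `image_id`, `setup_id`, setup shift components in mm, and
#'   `delta` in percent).
#' @export
build_strategy <- function(name, um = uncertainty_model(),
                           spr_perturbations = c(-4.7, 0, 4.7)) {
  strat <- planning_strategies(um, spr_perturbations)
  strat <- strat[strat$name == name, ]
  if (nrow(strat) != 1L) {
    stop("build_strategy: unknown strategy '", name, "'; valid names: ",
         paste(planning_strategies(um)$name, collapse = ", "))
  }
  setup <- setup_shift_samples(strat$setup_radius)
  deltas <- spr_scenarios(strat$modality, spr_perturbations)
  sc <- tidyr::expand_grid(image_id = seq_len(strat$planning_images),
                           setup_id = setup$sample_id,
                           delta = deltas) |>
    dplyr::left_join(dplyr::rename(setup[, c("sample_id", "dx", "dy", "dz")],
                                   setup_id = "sample_id"),
                     by = "setup_id") |>
    dplyr::mutate(scenario_id = dplyr::row_number(), .before = 1)
  stopifnot(nrow(sc) == strat$n_scenarios)
  list(strategy = strat, scenarios = sc)
}

# differentiable soft D50%: t solves sum(sigmoid(gamma (d - t))) = n/2.
# Returns t and the gradient weights dt/dd_i (softmax of sigmoid slopes).
soft_d50 <- function(d, gamma = 2) {
  f <- function(t) sum(stats::plogis(gamma * (d - t))) - length(d) / 2
  lo <- min(d) - 10; hi <- max(d) + 10
  if (lo == hi) return(list(t = lo, dt = rep(1 / length(d), length(d))))
  t <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  s <- stats::plogis(gamma * (d - t))
  sl <- s * (1 - s)
  if (sum(sl) <= 0) sl <- rep(1, length(d))
  list(t = t, dt = sl / sum(sl))
}

#' Planning objective configuration
#'
#' Weights and parameters of the composite robust objective: (i) penalty when
#' the CTV soft-D50% of a scenario falls below the prescription, plus a CTV
#' hot-spot cap; (ii) quadratic penalty on dose outside the CTV exceeding a
#' distance-based fall-off envelope; (iii) chest-wall max-dose penalty. The
#' worst case over scenarios is smoothed with a log-sum-exp of sharpness
#' `beta`. Weights were fixed once on the default phantom and are
#' configuration, not fitted quantities.
#'
#' @param d_presc Prescription dose (Gy), CTV D50% target per scenario.
#' @param falloff_tau Fall-off envelope length scale (mm).
#' @param falloff_floor Envelope floor as a fraction of prescription.
#' @param cw_limit Chest-wall max-dose limit (Gy).
#' @param hot_cap CTV hot-spot cap (Gy).
#' @param under_frac Per-voxel CTV underdose threshold as a fraction of the
#'   prescription (uniformity term keeping cold spots up per scenario).
#' @param w_ctv,w_under,w_hot,w_shell,w_cw Objective weights.
#' @param beta Log-sum-exp sharpness of the worst-case smoothing.
#' @param gamma Soft-D50% sigmoid sharpness (per Gy).
#' @param n_shell,n_cw Maximum fall-off / chest-wall voxel samples.
#' @return Named list.
#' @export
objective_config <- function(d_presc = 54, falloff_tau = 15, falloff_floor = 0.1,
                             cw_limit = 30, hot_cap = 70, under_frac = 0.97,
                             w_ctv = 200, w_under = 80, w_hot = 40,
                             w_shell = 30, w_cw = 10,
                             beta = 5, gamma = 2,
                             n_shell = 600, n_cw = 300) {
  as.list(environment())
}

# optimization voxel sets: all CTV voxels, a sampled fall-off shell (distance
# from the CTV surface up to 30 mm), and sampled chest-wall voxels near the
# target. Deterministic striding, no RNG.
planning_points <- function(phantom, obj) {
  grid <- phantom$grid
  ctv <- phantom$structures$CTV
  ctv_idx <- which(ctv)
  surf <- mask_surface(ctv)
  d <- grid$shape
  ar <- arrayInd(which(ctv), d)
  pad <- ceiling(30 / min(grid$spacing))
  lo <- pmax(apply(ar, 2, min) - pad, 1L); hi <- pmin(apply(ar, 2, max) + pad, d)
  cand <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  lin <- (cand[, 3] - 1L) * (d[1] * d[2]) + (cand[, 2] - 1L) * d[1] + cand[, 1]
  keep <- phantom$structures$body[lin] & !ctv[lin]
  lin <- lin[keep]
  dist <- dist_to_mask(grid, grid_points(grid, lin), surf)
  shell <- lin[dist <= 30]
  shell_dist <- dist[dist <= 30]
  if (length(shell) > obj$n_shell) {
    take <- unique(round(seq(1, length(shell), length.out = obj$n_shell)))
    shell <- shell[take]; shell_dist <- shell_dist[take]
  }
  iso <- colMeans(grid_points(grid, ctv_idx))
  cw_idx <- which(phantom$structures$chest_wall)
  cw_pts <- grid_points(grid, cw_idx)
  near <- sqrt(rowSums(sweep(cw_pts, 2, iso, "-")^2)) <= 80
  cw_idx <- cw_idx[near]
  if (length(cw_idx) > obj$n_cw) {
    cw_idx <- cw_idx[unique(round(seq(1, length(cw_idx), length.out = obj$n_cw)))]
  }
  idx <- c(ctv_idx, shell, cw_idx)
  list(idx = idx,
       pts = grid_points(grid, idx),
       i_ctv = seq_along(ctv_idx),
       i_shell = length(ctv_idx) + seq_along(shell),
       i_cw = length(ctv_idx) + length(shell) + seq_along(cw_idx),
       shell_bound = obj$d_presc * pmax(exp(-shell_dist / obj$falloff_tau),
                                        obj$falloff_floor))
}

# planning images for a strategy: the reference image plus, for 4D plans,
# the 7-shift deformed set at the tumor-shift radius (clamped to the lung
# wall, inverses populated)
planning_images <- function(phantom, strat) {
  if (strat$planning_images == 1L) return(list(bh_image(phantom, id = "plan1")))
  shifts <- planning_axis_samples(strat$tumor_shift_radius)
  lapply(seq_len(nrow(shifts)), function(i) {
    sh <- c(shifts$dx[i], shifts$dy[i], shifts$dz[i])
    if (all(sh == 0)) return(bh_image(phantom, id = paste0("plan", i)))
    f <- invert_dvf(solve_laplacian_dvf(phantom, sh))
    bh_image(phantom, f, id = paste0("plan", i))
  })
}

# per-scenario composite objective value and gradient wrt the dose vector
scenario_objective <- function(d, pp, obj) {
  g <- numeric(length(d))
  dctv <- d[pp$i_ctv]
  sq <- soft_d50(dctv, obj$gamma)
  deficit <- max(obj$d_presc - sq$t, 0) / obj$d_presc
  f <- obj$w_ctv * deficit^2
  if (deficit > 0) {
    g[pp$i_ctv] <- g[pp$i_ctv] -
      obj$w_ctv * 2 * deficit / obj$d_presc * sq$dt
  }
  hot <- pmax(dctv - obj$hot_cap, 0) / obj$d_presc
  f <- f + obj$w_hot * mean(hot^2)
  g[pp$i_ctv] <- g[pp$i_ctv] +
    obj$w_hot * 2 * hot / obj$d_presc / length(dctv)
  under <- pmax(obj$under_frac * obj$d_presc - dctv, 0) / obj$d_presc
  f <- f + obj$w_under * mean(under^2)
  g[pp$i_ctv] <- g[pp$i_ctv] -
    obj$w_under * 2 * under / obj$d_presc / length(dctv)
  if (length(pp$i_shell)) {
    ex <- pmax(d[pp$i_shell] - pp$shell_bound, 0) / obj$d_presc
    f <- f + obj$w_shell * mean(ex^2)
    g[pp$i_shell] <- g[pp$i_shell] +
      obj$w_shell * 2 * ex / obj$d_presc / length(pp$i_shell)
  }
  if (length(pp$i_cw)) {
    ex <- pmax(d[pp$i_cw] - obj$cw_limit, 0) / obj$d_presc
    f <- f + obj$w_cw * mean(ex^2)
    g[pp$i_cw] <- g[pp$i_cw] +
      obj$w_cw * 2 * ex / obj$d_presc / length(pp$i_cw)
  }
  list(f = f, g = g)
}

#' Robustly optimize a plan for one strategy
#'
#' Scenario-based minimax optimization: nonnegative beam/spot weights
#' minimizing a log-sum-exp-smoothed worst case, over the strategy's robust
#' scenarios, of a composite objective prioritising per-scenario CTV coverage
#' (soft D50% at the prescription), a sharp dose fall-off outside the CTV and
#' a chest-wall max-dose penalty. Organs of interest are deliberately not
#' objectives — their sparing comes from the beam-angle arrangement — and are
#' only reported at evaluation time. Deterministic given the configuration.
#'
#' @param phantom A `bh_phantom`.
#' @param name Strategy name, e.g. `"proton4D-BH"`.
#' @param um An [uncertainty_model()].
#' @param pars Engine parameters ([dose_engine_params()]).
#' @param obj Objective configuration ([objective_config()]).
#' @param angles Optional beam entry angles (degrees).
#' @param spr_perturbations Percent SPR triple for protons.
#' @param maxit L-BFGS-B iteration cap.
#' @param start_scale Starting-point factor: uniform weights scaled so the
#'   nominal CTV mean dose is `start_scale` times the prescription.
#' @param seed Integer seed (reserved for stochastic engine options; the
#'   default optimization is deterministic).
#' @return A `bh_plan`: beams (sub-beams after energy-layer splitting),
#'   weights, strategy and scenario tables, planning images, optimization
#'   log, `n_fractions = 3`, `rbe` (1.1 proton / 1.0 photon) and
#'   `normalization_scale` (1 until [normalize_plan()]).
#' @export
robust_optimize <- function(phantom, name, um = uncertainty_model(),
                            pars = dose_engine_params(),
                            obj = objective_config(),
                            angles = NULL,
                            spr_perturbations = c(-4.7, 0, 4.7),
                            maxit = 120L, start_scale = 1.05, seed = 1L) {
  bs <- build_strategy(name, um, spr_perturbations)
  strat <- bs$strategy
  modality <- strat$modality
  beams <- make_beams(phantom, modality, angles, pars)
  if (modality == "proton") {
    beams <- unlist(lapply(beams, split_energy_layers,
                           max_layers = pars$max_layers_per_bh),
                    recursive = FALSE)
  }
  nw <- vapply(beams, n_beam_weights, integer(1))
  weight_beam <- rep(seq_along(beams), nw)
  rbe <- if (modality == "proton") 1.1 else 1.0

  images <- planning_images(phantom, strat)
  pp <- planning_points(phantom, obj)

  # per-scenario influence matrices (dose per unit weight, RBE included)
  sc <- bs$scenarios
  infl <- vector("list", nrow(sc))
  for (k in seq_len(nrow(sc))) {
    img <- images[[sc$image_id[k]]]
    s <- c(sc$dx[k], sc$dy[k], sc$dz[k])
    cols <- lapply(beams, function(bm) {
      pd <- image_point_data(img, bm, pp$pts, "opt")
      beam_influence(bm, pd, s = s, delta = sc$delta[k], pars = pars)
    })
    infl[[k]] <- do.call(cbind, cols) * rbe
  }

  # starting weights: uniform, scaled so the nominal CTV mean slightly
  # exceeds the prescription
  w1 <- rep(1, sum(nw))
  nominal <- which(sc$setup_id == 1 & sc$delta == 0 & sc$image_id == 1)[1]
  mean0 <- mean((infl[[nominal]] %*% w1)[pp$i_ctv, 1])
  if (mean0 <= 0) stop("robust_optimize: infeasible geometry, no CTV dose")
  w0 <- w1 * start_scale * obj$d_presc / mean0

  log_env <- new.env(parent = emptyenv())
  log_env$it <- 0L; log_env$rows <- list()
  fn_gr <- function(w) {
    fs <- numeric(length(infl))
    gs <- matrix(0, length(w), length(infl))
    for (k in seq_along(infl)) {
      d <- as.numeric(infl[[k]] %*% w)
      so <- scenario_objective(d, pp, obj)
      fs[k] <- so$f
      gs[, k] <- as.numeric(crossprod(infl[[k]], so$g))
    }
    b <- obj$beta
    m <- max(b * fs)
    p <- exp(b * fs - m); p <- p / sum(p)
    F <- (m + log(sum(exp(b * fs - m))) - log(length(fs))) / b
    list(F = F, grad = as.numeric(gs %*% p), worst = max(fs))
  }
  last <- NULL
  fwrap <- function(w) {
    last <<- fn_gr(w)
    log_env$it <- log_env$it + 1L
    log_env$rows[[log_env$it]] <- c(F = last$F, worst = last$worst)
    last$F
  }
  gwrap <- function(w) last$grad
  opt <- stats::optim(w0, fwrap, gwrap, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = maxit))
  w <- pmax(opt$par, 0)

  plan <- structure(
    list(name = name, modality = modality, beams = beams, weights = w,
         weight_beam = weight_beam, n_fractions = 3L, rbe = rbe,
         normalization_scale = 1,
         strategy = strat, scenarios = sc, planning_images = images,
         phantom = phantom, pars = pars, obj = obj, um = um,
         spr_perturbations = spr_perturbations,
         opt_log = tibble::tibble(
           iter = seq_along(log_env$rows),
           objective = vapply(log_env$rows, `[[`, numeric(1), "F"),
           worst_scenario = vapply(log_env$rows, `[[`, numeric(1), "worst")),
         opt_convergence = opt$convergence),
    class = "bh_plan")
  plan
}

#' @export
print.bh_plan <- function(x, ...) {
  cat("<bh_plan> ", x$name, ": ", length(x$beams), " beams/sub-beams, ",
      length(x$weights), " weights, ", nrow(x$scenarios), " robust scenarios\n",
      "  normalization scale ", signif(x$normalization_scale, 4),
      ", RBE ", x$rbe, ", ", x$n_fractions, " fractions\n", sep = "")
  invisible(x)
}

#' Robustly evaluate a plan
#'
#' Recomputes the CTV D50% for every robust-optimization scenario of the
#' plan's strategy (one planning image for the 3D plans, seven for the 4D
#' plans), using the exact interpolated-quantile D50% on the reference-
#' geometry CTV voxels.
#'
#' @param plan A `bh_plan`.
#' @return Tibble with one row per robust scenario: `scenario_id`,
#'   `image_id`, `setup_id`, `delta` and `ctv_d50`.
#' @export
robust_evaluate <- function(plan) {
  phantom <- plan$phantom
  ctv_idx <- which(phantom$structures$CTV)
  pts <- grid_points(phantom$grid, ctv_idx)
  sc <- plan$scenarios
  d50 <- numeric(nrow(sc))
  for (k in seq_len(nrow(sc))) {
    img <- plan$planning_images[[sc$image_id[k]]]
    dose <- plan_dose_at_points(plan, img, pts, "ctv",
                                setup_shift = c(sc$dx[k], sc$dy[k], sc$dz[k]),
                                delta = sc$delta[k])
    d50[k] <- dvh_dx(dose, 50)
  }
  dplyr::mutate(sc[, c("scenario_id", "image_id", "setup_id", "delta")],
                ctv_d50 = d50)
}

#' Normalize a plan to the worst robust scenario
#'
#' Scales all weights so the robust scenario with the lowest CTV D50% equals
#' the prescription (54 Gy): every robust scenario is then guaranteed to meet
#' the robust CTV prescription. Dose is linear in the weights, so the
#' normalization is exact up to dose-grid interpolation.
#'
#' @param plan A `bh_plan`.
#' @param robust_eval Optional result of [robust_evaluate()]; computed if
#'   missing.
#' @param d_presc Prescription dose (Gy, default 54).
#' @return The plan with scaled weights, updated `normalization_scale` and a
#'   `robust_eval` table (post-normalization).
#' @export
normalize_plan <- function(plan, robust_eval = NULL, d_presc = 54) {
  if (is.null(robust_eval)) robust_eval <- robust_evaluate(plan)
  mn <- min(robust_eval$ctv_d50)
  if (mn <= 0) stop("normalize_plan: minimum scenario CTV D50% is not positive")
  scale <- d_presc / mn
  plan$weights <- plan$weights * scale
  plan$normalization_scale <- plan$normalization_scale * scale
  robust_eval$ctv_d50 <- robust_eval$ctv_d50 * scale
  plan$robust_eval <- robust_eval
  plan
}

#' Build, optimize and normalize one strategy's plan
#'
#' Convenience wrapper: [robust_optimize()], [robust_evaluate()],
#' [normalize_plan()].
#'
#' @inheritParams robust_optimize
#' @return A normalized `bh_plan` with its `robust_eval` table.
#' @export
plan_strategy <- function(phantom, name, um = uncertainty_model(),
                          pars = dose_engine_params(),
                          obj = objective_config(), angles = NULL,
                          spr_perturbations = c(-4.7, 0, 4.7),
                          maxit = 120L, seed = 1L) {
  plan <- robust_optimize(phantom, name, um, pars, obj, angles,
                          spr_perturbations, maxit, seed)
  normalize_plan(plan)
}

#' Tidy a plan's weights
#' @param x A `bh_plan`.
#' @param ... Unused.
#' @return Tibble with one row per weight: beam id, modality and weight.
#' @export
tidy.bh_plan <- function(x, ...) {
  tibble::tibble(
    beam = vapply(x$beams, `[[`, character(1), "id")[x$weight_beam],
    modality = x$modality,
    weight = x$weights)
}

#' One-row summary of a plan
#' @param x A `bh_plan`.
#' @param ... Unused.
#' @return Tibble with strategy name, counts, normalization scale and the
#'   minimum robust-scenario CTV D50% (if evaluated).
#' @export
glance.bh_plan <- function(x, ...) {
  tibble::tibble(
    name = x$name, modality = x$modality,
    n_beams = length(x$beams), n_weights = length(x$weights),
    n_scenarios = nrow(x$scenarios),
    normalization_scale = x$normalization_scale,
    min_robust_ctv_d50 = if (!is.null(x$robust_eval)) min(x$robust_eval$ctv_d50) else NA_real_)
}

#' Serialize a plan to JSON
#'
#' Writes beams (direction, aperture or layer ranges), weights, strategy and
#' normalization scale for audit; dose arrays are not serialized.
#'
#' @param plan A `bh_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  beams <- lapply(plan$beams, function(b) {
    out <- list(id = b$id, modality = b$modality, theta_deg = b$theta_deg)
    if (b$modality == "photon") out$aperture <- b$aperture
    else out$nominal_ranges <- vapply(b$layers, `[[`, numeric(1), "nominal_range")
    out
  })
  jsonlite::write_json(
    list(name = plan$name, modality = plan$modality,
         n_fractions = plan$n_fractions, rbe = plan$rbe,
         normalization_scale = plan$normalization_scale,
         beams = beams, weights = plan$weights,
         weight_beam = plan$weight_beam),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
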