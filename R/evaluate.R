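# ---- DVH metrics ------------------------------------------------------------

# Dx%: dose exceeded by x% of the structure's voxels, interpolated-quantile
# convention (type 5: for 100 voxels with doses 1..100, D50% = 50.5,
# D2% = 98.5, D98% = 2.5). D0% is the voxel-wise maximum.
dvh_dx <- function(dose, x) {
  if (x <= 0) return(max(dose))
  unname(stats::quantile(dose, probs = 1 - x / 100, type = 5))
}

dvh_vx_cm3 <- function(dose, threshold_gy, voxel_volume_mm3) {
  sum(dose >= threshold_gy) * voxel_volume_mm3 / 1000
}

#' Default DVH metric specification
#'
#' The metric panel reported per simulated treatment: CTV D50%/D2%/D98%/D0%
#' and homogeneity index HI = (D2% - D98%)/D50%; lung (both lungs) V5Gy and
#' V20Gy in cm^3; heart D0% and Dmean; esophagus, aorta and spinal cord D0%.
#'
#' @return Tibble with columns `structure`, `metric`, `x` (the Dx percentage
#'   or VxGy threshold, NA otherwise).
#' @export
dvh_metric_specs <- function() {
  tibble::tribble(
    ~structure,    ~metric,  ~x,
    "CTV",         "D50%",   50,
    "CTV",         "D2%",    2,
    "CTV",         "D98%",   98,
    "CTV",         "D0%",    0,
    "CTV",         "HI",     NA,
    "lung",        "V5Gy",   5,
    "lung",        "V20Gy",  20,
    "heart",       "D0%",    0,
    "heart",       "Dmean",  NA,
    "esophagus",   "D0%",    0,
    "aorta",       "D0%",    0,
    "spinal_cord", "D0%",    0)
}

#' Dose-volume-histogram metrics of a dose grid
#'
#' Computes Dx% (interpolated-quantile dose exceeded by x% of the structure,
#' with D0% the voxel-wise maximum), Dmean, VxGy (absolute volume in cm^3
#' receiving at least x Gy) and CTV HI = (D2% - D98%)/D50% for the requested
#' structures. An empty structure mask yields `NA` with a warning and is
#' excluded from downstream summaries.
#'
#' @param dose 3D dose array (Gy).
#' @param structures Named list of logical masks on the same grid. A `lung`
#'   entry may be supplied directly or is formed as the union of `lung_ipsi`
#'   and `lung_contra` if present.
#' @param grid The [voxel_grid()] (for absolute volumes).
#' @param specs Metric specification tibble (default [dvh_metric_specs()]).
#' @return Tibble `structure`, `metric`, `value`.
#' @export
dvh_metrics <- function(dose, structures, grid, specs = dvh_metric_specs()) {
  if (!("lung" %in% names(structures)) &&
      all(c("lung_ipsi", "lung_contra") %in% names(structures))) {
    structures$lung <- structures$lung_ipsi | structures$lung_contra
  }
  vv <- voxel_volume(grid)
  vals <- numeric(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    st <- specs$structure[i]
    if (!st %in% names(structures) || !any(structures[[st]])) {
      warning("dvh_metrics: structure '", st, "' empty or missing; metric NA")
      vals[i] <- NA_real_
      next
    }
    d <- dose[structures[[st]]]
    vals[i] <- switch(
      specs$metric[i],
      "Dmean" = mean(d),
      "HI" = (dvh_dx(d, 2) - dvh_dx(d, 98)) / dvh_dx(d, 50),
      if (startsWith(specs$metric[i], "V")) dvh_vx_cm3(d, specs$x[i], vv)
      else dvh_dx(d, specs$x[i]))
  }
  dplyr::mutate(specs[, c("structure", "metric")], value = vals)
}

#' Cumulative dose-volume histogram of a structure
#'
#' Fraction of the structure receiving at least each dose level.
#'
#' @param dose 3D dose array or dose vector (Gy).
#' @param mask Logical mask (same shape as `dose`), or `NULL` if `dose` is
#'   already restricted to the structure.
#' @param n_bins Number of dose levels.
#' @return Tibble with `dose_gy` and `volume_fraction` (from 1 at 0 Gy down
#'   to 0 above the maximum dose).
#' @export
dvh_curve <- function(dose, mask = NULL, n_bins = 200L) {
  d <- if (is.null(mask)) as.numeric(dose) else dose[mask]
  if (!length(d)) stop("dvh_curve: empty structure")
  lv <- seq(0, max(d) * 1.02 + 1e-9, length.out = n_bins)
  frac <- vapply(lv, function(t) mean(d >= t), numeric(1))
  tibble::tibble(dose_gy = lv, volume_fraction = frac)
}

# fast path: metrics from a dose vector on the evaluation point subset
metrics_from_vector <- function(dose_vec, sidx, vv, specs) {
  vals <- numeric(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    d <- dose_vec[sidx[[specs$structure[i]]]]
    vals[i] <- switch(
      specs$metric[i],
      "Dmean" = mean(d),
      "HI" = (dvh_dx(d, 2) - dvh_dx(d, 98)) / dvh_dx(d, 50),
      if (startsWith(specs$metric[i], "V")) sum(d >= specs$x[i]) * vv / 1000
      else dvh_dx(d, specs$x[i]))
  }
  vals
}

# ---- discrete mapping -------------------------------------------------------

#' Map a continuous shift to its nearest discrete scenario
#'
#' Nearest-neighbour assignment in Mahalanobis distance (per-axis SDs of the
#' generating Gaussian); ties break deterministically to the lowest scenario
#' id.
#'
#' @param shift Length-3 continuous shift (mm).
#' @param grid_shifts n x 3 matrix of discrete shifts (mm).
#' @param sd3 Per-axis SDs (mm) defining the metric; axes with SD 0 use a
#'   unit metric.
#' @return Integer row index into `grid_shifts`.
#' @export
map_to_discrete <- function(shift, grid_shifts, sd3) {
  s <- ifelse(sd3 > 0, sd3, 1)
  d2 <- colSums((t(grid_shifts) - shift)^2 / s^2)
  which.min(d2)  # first minimum = lowest id
}

# ---- treatment sampling -----------------------------------------------------

#' Sample one simulated treatment from the hierarchical error model
#'
#' Draws the systematic components (SPR perturbation from the discrete set
#' weighted by the N(0, Sigma_SPR) density; patient-setup and breath-hold
#' systematic shifts from per-axis zero-mean Gaussians) and, per fraction,
#' a random patient-setup shift plus one breath-hold shift per delivery unit
#' (beam or sub-beam). Uses the current RNG state — seed the caller.
#'
#' @param um An [uncertainty_model()].
#' @param eval_set `"A"` or `"B"` (breath-hold SD set).
#' @param n_units Breath-hold delivery units per fraction.
#' @param deltas Discrete SPR perturbations (percent); `0` for photons.
#' @param n_fractions Number of fractions (default 3).
#' @return List with `delta`, `ps_sys`, `bh_sys` and `fractions` (each with
#'   `ps` and an `n_units` x 3 matrix `bh`).
#' @export
sample_treatment <- function(um, eval_set = c("A", "B"), n_units,
                             deltas = 0, n_fractions = 3L) {
  eval_set <- match.arg(eval_set)
  Sbh <- if (eval_set == "A") um$Sigma_BH_A else um$Sigma_BH_B
  sbh <- if (eval_set == "A") um$sigma_BH_A else um$sigma_BH_B
  if (length(deltas) > 1L) {
    wts <- stats::dnorm(deltas, 0, max(um$Sigma_SPR, 1e-9))
    delta <- sample(deltas, 1L, prob = wts / sum(wts))
  } else delta <- deltas
  list(
    delta = delta,
    ps_sys = stats::rnorm(3, 0, um$Sigma_PS),
    bh_sys = stats::rnorm(3, 0, Sbh),
    fractions = lapply(seq_len(n_fractions), function(f) {
      list(ps = stats::rnorm(3, 0, um$sigma_PS),
           bh = matrix(stats::rnorm(3 * n_units, 0,
                                    rep(sbh, each = n_units)),
                       n_units, 3))
    }))
}

# ---- evaluation context -----------------------------------------------------

#' Build the evaluation context for one breath-hold reproducibility set
#'
#' Precomputes everything shared across plans for a probabilistic evaluation:
#' the 105-image combined-shift grid (15 systematic x 7 per-breath-hold
#' shifts, probability weighted), the 15-point discrete setup grid at the
#' patient-setup 90% radius, the evaluation voxel subset (union of all scored
#' structures) and a lazy store of deformed images (Laplacian field, inverse,
#' warped SPR) built on first use and shared across plans.
#'
#' @param phantom A `bh_phantom`.
#' @param um An [uncertainty_model()].
#' @param eval_set `"A"` or `"B"`.
#' @return An environment of class `bh_eval_context`.
#' @export
evaluation_context <- function(phantom, um = uncertainty_model(),
                               eval_set = c("A", "B")) {
  eval_set <- match.arg(eval_set)
  ctx <- new.env(parent = emptyenv())
  ctx$phantom <- phantom
  ctx$um <- um
  ctx$eval_set <- eval_set
  ctx$Sigma_BH <- if (eval_set == "A") um$Sigma_BH_A else um$Sigma_BH_B
  ctx$sigma_BH <- if (eval_set == "A") um$sigma_BH_A else um$sigma_BH_B
  ctx$grid105 <- evaluation_shift_grid(ctx$Sigma_BH, ctx$sigma_BH,
                                       paste0("eval", eval_set, "_105"))
  sys_tb <- dplyr::distinct(ctx$grid105[, c("sys_id", "sys_dx", "sys_dy", "sys_dz")])
  bh_tb <- dplyr::distinct(ctx$grid105[, c("bh_id", "bh_dx", "bh_dy", "bh_dz")])
  ctx$sys_grid <- as.matrix(sys_tb[order(sys_tb$sys_id), -1])
  ctx$bh_grid <- as.matrix(bh_tb[order(bh_tb$bh_id), -1])
  r_setup <- ci90_radius(max(um$Sigma_PS), max(um$sigma_PS))
  st <- setup_shift_samples(r_setup)
  ctx$setup_grid <- as.matrix(st[, c("dx", "dy", "dz")])
  ctx$setup_sd <- sqrt(um$Sigma_PS^2 + um$sigma_PS^2)

  structures <- phantom$structures
  structures$lung <- structures$lung_ipsi | structures$lung_contra
  score <- c("CTV", "lung", "heart", "esophagus", "aorta", "spinal_cord")
  uni <- Reduce(`|`, structures[score])
  ctx$pts_idx <- which(uni)
  ctx$pts_mm <- grid_points(phantom$grid, ctx$pts_idx)
  pos <- integer(prod(phantom$grid$shape)); pos[ctx$pts_idx] <- seq_along(ctx$pts_idx)
  ctx$sidx <- lapply(structures[score], function(m) pos[which(m)])
  ctx$images <- new.env(parent = emptyenv())
  class(ctx) <- "bh_eval_context"
  ctx
}

# deformed image for a (sys_id, bh_id) cell, built lazily; combined shift is
# clamped to the lung wall before solving
context_image <- function(ctx, sys_id, bh_id) {
  key <- paste0("i", sys_id, "_", bh_id)
  img <- ctx$images[[key]]
  if (!is.null(img)) return(img)
  sh <- ctx$sys_grid[sys_id, ] + ctx$bh_grid[bh_id, ]
  img <- if (all(abs(sh) < 1e-9)) {
    bh_image(ctx$phantom, id = key)
  } else {
    f <- invert_dvf(solve_laplacian_dvf(ctx$phantom, sh))
    bh_image(ctx$phantom, f, id = key)
  }
  ctx$images[[key]] <- img
  img
}

#' Accumulate the total dose of one simulated treatment
#'
#' Maps each fraction's combined setup shift and each delivery unit's
#' combined breath-hold shift to the discrete scenario grids (Mahalanobis
#' nearest neighbour), looks up (or computes and caches) the unit's
#' reference-geometry dose for that discrete scenario, and sums over the
#' plan's fractions and units with each fraction contributing 1/n_fractions
#' of its units' dose.
#'
#' @param sample A treatment sample from [sample_treatment()].
#' @param plan A normalized `bh_plan`.
#' @param ctx A `bh_eval_context` for the same phantom.
#' @param cache Environment of cached unit dose vectors (per plan).
#' @return Dose vector (Gy) on the context's evaluation points.
#' @export
accumulate_treatment_dose <- function(sample, plan, ctx, cache = new.env()) {
  n_units <- length(plan$beams)
  sys_id <- map_to_discrete(sample$bh_sys, ctx$sys_grid, ctx$Sigma_BH)
  total <- numeric(nrow(ctx$pts_mm))
  for (fr in sample$fractions) {
    setup_id <- map_to_discrete(sample$ps_sys + fr$ps, ctx$setup_grid, ctx$setup_sd)
    s <- ctx$setup_grid[setup_id, ]
    for (u in seq_len(n_units)) {
      bh_id <- map_to_discrete(sample$bh_sys + fr$bh[u, ], ctx$bh_grid, ctx$sigma_BH)
      key <- paste0("u", u, "_s", sys_id, "_", bh_id, "_", setup_id, "_", sample$delta)
      dv <- cache[[key]]
      if (is.null(dv)) {
        img <- context_image(ctx, sys_id, bh_id)
        dv <- plan_dose_at_points(plan, img, ctx$pts_mm, "eval",
                                  setup_shift = s, delta = sample$delta,
                                  unit = u)
        cache[[key]] <- dv
      }
      total <- total + dv
    }
  }
  total / plan$n_fractions
}

#' Probabilistically evaluate a plan
#'
#' Samples `n_samples` simulated treatments from the hierarchical error
#' model, accumulates each treatment's dose on the reference geometry from
#' the discrete scenario-dose cache, computes the DVH metric panel per
#' treatment and attaches grouped summary statistics including p90%.
#'
#' @param plan A normalized `bh_plan`.
#' @param eval_set `"A"` or `"B"`.
#' @param n_samples Simulated treatments (study default 10000; scale down for
#'   quick runs).
#' @param seed Integer seed.
#' @param ctx Optional shared [evaluation_context()] (built if missing).
#' @param specs Metric panel (default [dvh_metric_specs()]).
#' @return A `bh_eval` object: `samples` (long tibble: sample_id, structure,
#'   metric, value), `summary` (see [summarize_evaluation()]) and metadata.
#' @export
evaluate_plan <- function(plan, eval_set = c("A", "B"), n_samples = 1000L,
                          seed = 1L, ctx = NULL, specs = dvh_metric_specs()) {
  eval_set <- match.arg(eval_set)
  if (is.null(ctx)) ctx <- evaluation_context(plan$phantom, plan$um, eval_set)
  stopifnot(identical(ctx$eval_set, eval_set))
  deltas <- spr_scenarios(plan$modality, plan$spr_perturbations)
  n_units <- length(plan$beams)
  vv <- voxel_volume(plan$phantom$grid)
  cache <- new.env(parent = emptyenv())

  old <- .Random.seed_get()
  set.seed(as.integer(seed))
  nmet <- nrow(specs)
  vals <- matrix(NA_real_, n_samples, nmet)
  for (i in seq_len(n_samples)) {
    smp <- sample_treatment(ctx$um, eval_set, n_units, deltas,
                            plan$n_fractions)
    dose <- accumulate_treatment_dose(smp, plan, ctx, cache)
    vals[i, ] <- metrics_from_vector(dose, ctx$sidx, vv, specs)
  }
  .Random.seed_restore(old)

  samples <- tidyr::expand_grid(sample_id = seq_len(n_samples),
                                idx = seq_len(nmet)) |>
    dplyr::mutate(structure = specs$structure[.data$idx],
                  metric = specs$metric[.data$idx],
                  value = as.numeric(t(vals))) |>
    dplyr::select(-"idx")
  res <- structure(
    list(samples = samples,
         summary = summarize_evaluation(samples),
         plan_name = plan$name, eval_set = eval_set,
         n_samples = n_samples, seed = seed,
         n_cache_entries = length(ls(cache))),
    class = "bh_eval")
  res
}

#' Summarize per-treatment DVH metrics
#'
#' Per metric: Avg, SD, Med, IQR, min, max and p90%. For CTV dose metrics
#' p90% is the 10th percentile (the value reached with 90% probability); for
#' CTV HI and all organ-of-interest metrics it is the 90th percentile (the
#' value not exceeded with 90% probability).
#'
#' @param samples Long tibble of per-sample metrics (`structure`, `metric`,
#'   `value`).
#' @return Tibble with one row per structure x metric.
#' @export
summarize_evaluation <- function(samples) {
  samples |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$structure, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      avg = mean(.data$value),
      sd = stats::sd(.data$value),
      med = stats::median(.data$value),
      iqr = stats::IQR(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      p90 = unname(stats::quantile(
        .data$value,
        probs = if (.data$structure[1] == "CTV" && .data$metric[1] != "HI") 0.1 else 0.9)),
      .groups = "drop")
}

#' @export
print.bh_eval <- function(x, ...) {
  cat("<bh_eval> ", x$plan_name, ", set ", x$eval_set, ", ",
      x$n_samples, " simulated treatments\n", sep = "")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Tidy a probabilistic evaluation
#' @param x A `bh_eval`.
#' @param ... Unused.
#' @return The per-sample long tibble.
#' @export
tidy.bh_eval <- function(x, ...) x$samples

#' One-row summary of a probabilistic evaluation
#' @param x A `bh_eval`.
#' @param ... Unused.
#' @return Tibble with plan, set, sample count and CTV D50% p90%.
#' @export
glance.bh_eval <- function(x, ...) {
  d50 <- dplyr::filter(x$summary, .data$structure == "CTV", .data$metric == "D50%")
  tibble::tibble(plan = x$plan_name, eval_set = x$eval_set,
                 n_samples = x$n_samples,
                 ctv_d50_p90 = d50$p90, ctv_d50_med = d50$med)
}

#' Precompute the full discrete scenario-dose cache for a plan
#'
#' Eagerly fills the cache [evaluate_plan()] normally fills lazily: one
#' reference-geometry dose vector per (delivery unit, evaluation image,
#' setup position, SPR perturbation). Mainly useful for audits and small
#' grids — the lazy path only computes cells that are actually drawn.
#'
#' @param plan A normalized `bh_plan`.
#' @param ctx A [evaluation_context()].
#' @param images Restrict to these image cell indices (rows of the 105-grid);
#'   default all.
#' @return Environment mapping cache keys to dose vectors; its `"n_entries"`
#'   attribute equals units x images x setups x SPR members.
#' @export
precompute_scenario_doses <- function(plan, ctx, images = NULL) {
  deltas <- spr_scenarios(plan$modality, plan$spr_perturbations)
  cache <- new.env(parent = emptyenv())
  g <- ctx$grid105
  if (!is.null(images)) g <- g[g$sample_id %in% images, ]
  for (r in seq_len(nrow(g))) {
    img <- context_image(ctx, g$sys_id[r], g$bh_id[r])
    for (setup_id in seq_len(nrow(ctx$setup_grid))) {
      s <- ctx$setup_grid[setup_id, ]
      for (delta in deltas) {
        for (u in seq_along(plan$beams)) {
          key <- paste0("u", u, "_s", g$sys_id[r], "_", g$bh_id[r], "_",
                        setup_id, "_", delta)
          cache[[key]] <- plan_dose_at_points(plan, img, ctx$pts_mm, "eval",
                                              setup_shift = s, delta = delta,
                                              unit = u)
        }
      }
    }
  }
  attr(cache, "n_entries") <- length(ls(cache))
  cache
}

# ---- experiment driver ------------------------------------------------------

#' Run the full planning + evaluation experiment
#'
#' Loops phantoms x strategies x evaluation sets: builds and normalizes every
#' plan, evaluates each with `n_samples` simulated treatments per set, and
#' reports the total number of simulated treatments
#' (`n_phantoms x n_plans x n_sets x n_samples`). With `dry_run = TRUE` only
#' the bookkeeping is computed — use this to audit scenario and treatment
#' counts without dose computation.
#'
#' @param config An [experiment_config()].
#' @return A `bh_experiment`: `n_treatments`, `plans` (glance rows),
#'   `summaries` (stacked evaluation summaries with phantom/plan/set ids) and
#'   the config. For dry runs only the bookkeeping fields are populated.
#' @export
run_experiment <- function(config = experiment_config()) {
  validate_experiment_config(config)
  n_plans <- length(config$strategies)
  n_sets <- length(config$eval_sets)
  n_phantoms <- config$n_phantoms
  n_treatments <- n_phantoms * n_plans * n_sets * config$n_samples
  if (isTRUE(config$dry_run)) {
    return(structure(list(n_treatments = n_treatments,
                          n_phantoms = n_phantoms, n_plans = n_plans,
                          n_sets = n_sets, n_samples = config$n_samples,
                          dry_run = TRUE, config = config),
                     class = "bh_experiment"))
  }
  um <- config$um
  plans_rows <- list(); summaries <- list(); evals <- list()
  for (iph in seq_len(n_phantoms)) {
    ph_args <- config$phantom
    ph_args$seed <- config$seed + iph
    phantom <- do.call(generate_phantom, ph_args)
    plans <- lapply(config$strategies, function(nm) {
      plan_strategy(phantom, nm, um = um, pars = config$pars,
                    obj = config$obj, maxit = config$maxit,
                    seed = config$seed)
    })
    names(plans) <- config$strategies
    for (p in plans) {
      plans_rows[[length(plans_rows) + 1L]] <-
        dplyr::mutate(glance.bh_plan(p), phantom = iph, .before = 1)
    }
    for (set in config$eval_sets) {
      ctx <- evaluation_context(phantom, um, set)
      for (nm in config$strategies) {
        # the same seed across sets A and B (common random numbers) pairs
        # the draws, sharpening the A-vs-B comparison
        ev <- evaluate_plan(plans[[nm]], set, n_samples = config$n_samples,
                            seed = config$seed + 101 * iph +
                              match(nm, config$strategies),
                            ctx = ctx)
        evals[[paste(iph, nm, set, sep = "|")]] <- ev
        summaries[[length(summaries) + 1L]] <-
          dplyr::mutate(ev$summary, phantom = iph, plan = nm, eval_set = set,
                        .before = 1)
      }
    }
  }
  structure(list(n_treatments = n_treatments,
                 n_phantoms = n_phantoms, n_plans = n_plans, n_sets = n_sets,
                 n_samples = config$n_samples, dry_run = FALSE,
                 plans = dplyr::bind_rows(plans_rows),
                 summaries = dplyr::bind_rows(summaries),
                 evaluations = evals,
                 config = config),
            class = "bh_experiment")
}

#' @export
print.bh_experiment <- function(x, ...) {
  cat("<bh_experiment> ", x$n_phantoms, " phantom(s) x ", x$n_plans,
      " plan(s) x ", x$n_sets, " evaluation set(s) x ", x$n_samples,
      " samples = ", format(x$n_treatments, big.mark = ","),
      " simulated treatments", if (isTRUE(x$dry_run)) " (dry run)", "\n",
      sep = "")
  invisible(x)
}

#' Write experiment outputs
#'
#' Per-sample metric tables and summary tables as CSV plus a JSON mirror of
#' the summaries; every file records the seed and config.
#'
#' @param experiment A `bh_experiment` (not a dry run).
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_experiment <- function(experiment, dir) {
  if (isTRUE(experiment$dry_run)) stop("write_experiment: dry run has no outputs")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "summaries.csv")
  utils::write.csv(experiment$summaries, f, row.names = FALSE)
  files <- c(files, f)
  for (key in names(experiment$evaluations)) {
    ev <- experiment$evaluations[[key]]
    f <- file.path(dir, paste0("samples_", gsub("[^A-Za-z0-9]+", "_", key), ".csv"))
    utils::write.csv(ev$samples, f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "experiment.json")
  jsonlite::write_json(
    list(n_treatments = experiment$n_treatments,
         seed = experiment$config$seed,
         strategies = experiment$config$strategies,
         eval_sets = experiment$config$eval_sets,
         n_samples = experiment$n_samples),
    f, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f))
}
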