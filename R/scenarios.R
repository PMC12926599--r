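#' The systematic/random uncertainty model
#'
#' Container for every standard deviation of the error model: patient setup
#' (PS), breath-hold tumor position sets A and B, and the stopping-power-ratio
#' (SPR) uncertainty. `Sigma_*` are systematic SDs (drawn once per treatment
#' course), `sigma_*` are random SDs (redrawn per fraction or per breath-hold).
#' Positional SDs are per-axis (LR, AP, CC) in mm; `Sigma_SPR` is in percent.
#' Defaults are the literature values the study conditions prescribe.
#'
#' @param Sigma_PS,sigma_PS Patient-setup systematic/random SDs (mm, LR/AP/CC).
#' @param Sigma_BH_A,sigma_BH_A Breath-hold tumor position SDs, set A (mm).
#' @param Sigma_BH_B,sigma_BH_B Breath-hold tumor position SDs, set B (mm) —
#'   a larger-variability set used for evaluation only.
#' @param Sigma_SPR SPR systematic SD in percent.
#' @return An object of class `uncertainty_model`.
#' @examples
#' um <- uncertainty_model()
#' ci90_radius(max(um$Sigma_PS), max(um$sigma_PS))  # 5.7 mm
#' @export
uncertainty_model <- function(Sigma_PS  = c(1.1, 1.5, 1.4),
                              sigma_PS  = c(1.4, 1.7, 1.7),
                              Sigma_BH_A = c(1.3, 1.2, 1.1),
                              sigma_BH_A = c(0.9, 1.0, 1.0),
                              Sigma_BH_B = c(1.0, 1.2, 2.2),
                              sigma_BH_B = c(1.1, 1.6, 2.7),
                              Sigma_SPR = 3.8) {
  m <- list(Sigma_PS = Sigma_PS, sigma_PS = sigma_PS,
            Sigma_BH_A = Sigma_BH_A, sigma_BH_A = sigma_BH_A,
            Sigma_BH_B = Sigma_BH_B, sigma_BH_B = sigma_BH_B,
            Sigma_SPR = Sigma_SPR)
  for (nm in names(m)[1:6]) {
    if (length(m[[nm]]) != 3L || any(m[[nm]] < 0))
      stop("uncertainty_model: ", nm, " must be 3 nonnegative per-axis SDs")
  }
  if (Sigma_SPR < 0) stop("uncertainty_model: Sigma_SPR must be nonnegative")
  structure(m, class = "uncertainty_model")
}

#' @export
print.uncertainty_model <- function(x, ...) {
  tb <- tidy.uncertainty_model(x)
  cat("<uncertainty_model> per-axis SDs (mm; SPR in %)\n")
  print(tb, n = nrow(tb))
  invisible(x)
}

#' Tidy an uncertainty model into a tibble
#' @param x An `uncertainty_model`.
#' @param ... Unused.
#' @return One row per parameter with LR/AP/CC columns.
#' @export
tidy.uncertainty_model <- function(x, ...) {
  pos <- names(x)[1:6]
  dplyr::bind_rows(
    tibble::tibble(parameter = pos,
                   LR = vapply(x[pos], `[`, numeric(1), 1),
                   AP = vapply(x[pos], `[`, numeric(1), 2),
                   CC = vapply(x[pos], `[`, numeric(1), 3)),
    tibble::tibble(parameter = "Sigma_SPR", LR = x$Sigma_SPR, AP = NA_real_,
                   CC = NA_real_))
}

# sqrt of the 0.90 quantile of chi-squared with 3 df: the factor taking an
# isotropic 3D Gaussian's per-axis SD to its 90% containment radius.
chi3_90 <- function() sqrt(stats::qchisq(0.90, df = 3))

#' 90% containment radius of a combined systematic + random shift
#'
#' Radius `r` such that an isotropic 3D Gaussian with per-axis SD
#' `sqrt(Sigma^2 + sigma^2)` satisfies `P(||X|| <= r) = 0.90`:
#' `r = sqrt(Sigma^2 + sigma^2) * sqrt(qchisq(0.9, 3))`. With the maximum
#' per-axis patient-setup SDs this is the 5.7 mm planning shift; with the
#' breath-hold set-A maxima it is the 4.1 mm planning-image shift.
#'
#' @param Sigma Systematic SD in mm (>= 0).
#' @param sigma Random SD in mm (>= 0).
#' @return Radius in mm.
#' @export
ci90_radius <- function(Sigma, sigma) {
  if (Sigma < 0 || sigma < 0) stop("ci90_radius: SDs must be nonnegative")
  sqrt(Sigma^2 + sigma^2) * chi3_90()
}

#' 90% containment radius combining setup and breath-hold uncertainty
#'
#' As [ci90_radius()] but with per-axis SD
#' `sqrt(Sigma_ps^2 + sigma_ps^2 + Sigma_bh^2 + sigma_bh^2)`; with the
#' Table-of-defaults maxima (1.5, 1.7, 1.3, 1.0 mm) this gives the 7.0 mm
#' shift used by the 3D-BH strategies to absorb breath-hold variability into
#' an enlarged setup shift.
#'
#' @param ps Length-2 numeric `(Sigma, sigma)` patient-setup maxima (mm).
#' @param bh Length-2 numeric `(Sigma, sigma)` breath-hold maxima (mm).
#' @return Radius in mm.
#' @export
ci90_radius_combined <- function(ps, bh) {
  if (any(c(ps, bh) < 0)) stop("ci90_radius_combined: SDs must be nonnegative")
  sqrt(sum(ps^2) + sum(bh^2)) * chi3_90()
}

new_scenario_set <- function(label, tb) {
  stopifnot(all(c("sample_id", "dx", "dy", "dz", "weight") %in% names(tb)))
  tb$label <- label
  class(tb) <- c("scenario_set", class(tb))
  tb
}

#' Axis-sampled planning shift set (7 positions)
#'
#' The planning-image shift set: the zero shift plus the six on-axis shifts
#' at radius `r` (`{0, +-r e_LR, +-r e_AP, +-r e_CC}`), i.e. the seven
#' deformed planning images including one non-deformed.
#'
#' @param radius Shift magnitude in mm (>= 0).
#' @return A `scenario_set` tibble (`label = "planning_7"`) with columns
#'   `sample_id`, `dx`, `dy`, `dz` (mm) and uniform `weight`. With
#'   `radius = 0` the seven coincident shifts collapse to one with a warning.
#' @export
planning_axis_samples <- function(radius) {
  if (radius < 0) stop("planning_axis_samples: radius must be nonnegative")
  dirs <- rbind(c(0, 0, 0),
                c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  sh <- dirs * radius
  if (radius == 0) {
    warning("planning_axis_samples: radius 0 collapses the 7 shifts to 1")
    sh <- sh[1, , drop = FALSE]
  }
  tb <- tibble::tibble(sample_id = seq_len(nrow(sh)),
                       dx = sh[, 1], dy = sh[, 2], dz = sh[, 3],
                       weight = 1 / nrow(sh))
  new_scenario_set("planning_7", tb)
}

#' Setup shift set (15 positions)
#'
#' The 15-position isotropic setup-shift pattern: the zero shift, the six
#' on-axis shifts at radius `r`, and the eight body-diagonal directions
#' `(+-1, +-1, +-1)/sqrt(3)` scaled to norm `r` — the minimal symmetric
#' superset of the 7-point axis pattern reaching 15 positions.
#'
#' @param radius Shift magnitude in mm (>= 0).
#' @return A `scenario_set` tibble (`label = "setup_15"`), 15 rows, uniform
#'   `weight`.
#' @export
setup_shift_samples <- function(radius) {
  if (radius < 0) stop("setup_shift_samples: radius must be nonnegative")
  ax <- rbind(c(0, 0, 0),
              c(1, 0, 0), c(-1, 0, 0),
              c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  dg <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  dimnames(dg) <- NULL
  sh <- rbind(ax, dg) * radius
  tb <- tibble::tibble(sample_id = seq_len(15L),
                       dx = sh[, 1], dy = sh[, 2], dz = sh[, 3],
                       weight = 1 / 15)
  new_scenario_set("setup_15", tb)
}

#' Probability-weighted evaluation shift grid (105 combined shifts)
#'
#' Evaluation image sets A and B: 15 discrete systematic breath-hold shifts
#' (the 15-point pattern at the 90% radius of the systematic SD alone)
#' crossed with 7 discrete per-breath-hold shifts (the axis pattern at the
#' 90% radius of the random SD alone) — 105 combined shifts. Each sample is
#' weighted by the product of the anisotropic per-axis Gaussian densities of
#' its systematic and per-BH components, normalized to sum 1 (the zero-shift
#' sample carries the largest weight).
#'
#' @param Sigma_BH Per-axis systematic SD, mm (length 3).
#' @param sigma_BH Per-axis per-breath-hold SD, mm (length 3).
#' @param label Set label, e.g. `"evalA_105"`.
#' @return A `scenario_set` tibble with systematic (`sys_id`, `sys_dx` ...),
#'   per-BH (`bh_id`, `bh_dx` ...) and combined (`dx`, `dy`, `dz`) shifts
#'   plus normalized `weight`.
#' @export
evaluation_shift_grid <- function(Sigma_BH, sigma_BH, label = "evalA_105") {
  stopifnot(length(Sigma_BH) == 3L, length(sigma_BH) == 3L)
  if (any(c(Sigma_BH, sigma_BH) < 0)) stop("evaluation_shift_grid: SDs must be nonnegative")
  r_sys <- ci90_radius(max(Sigma_BH), 0)
  r_bh  <- ci90_radius(0, max(sigma_BH))
  sys <- setup_shift_samples(r_sys)
  bh  <- planning_axis_samples(max(r_bh, .Machine$double.eps))
  dens <- function(sh, sd3) {
    # anisotropic Gaussian density at a shift; degenerate axes (sd 0) ignored
    ok <- sd3 > 0
    apply(sh, 1, function(v) prod(stats::dnorm(v[ok], 0, sd3[ok])))
  }
  grid <- tidyr::expand_grid(sys_id = sys$sample_id, bh_id = bh$sample_id)
  grid <- grid |>
    dplyr::left_join(dplyr::rename(sys[, c("sample_id", "dx", "dy", "dz")],
                                   sys_id = "sample_id", sys_dx = "dx",
                                   sys_dy = "dy", sys_dz = "dz"),
                     by = "sys_id") |>
    dplyr::left_join(dplyr::rename(bh[, c("sample_id", "dx", "dy", "dz")],
                                   bh_id = "sample_id", bh_dx = "dx",
                                   bh_dy = "dy", bh_dz = "dz"),
                     by = "bh_id") |>
    dplyr::mutate(dx = .data$sys_dx + .data$bh_dx,
                  dy = .data$sys_dy + .data$bh_dy,
                  dz = .data$sys_dz + .data$bh_dz)
  w_sys <- dens(as.matrix(grid[, c("sys_dx", "sys_dy", "sys_dz")]), Sigma_BH)
  w_bh  <- dens(as.matrix(grid[, c("bh_dx", "bh_dy", "bh_dz")]), sigma_BH)
  w <- w_sys * w_bh
  grid$weight <- w / sum(w)
  grid$sample_id <- seq_len(nrow(grid))
  new_scenario_set(label, grid)
}

#' Stopping-power-ratio perturbation scenarios
#'
#' The discrete SPR perturbations applied to proton plans: a configured
#' triple, default (-4.7, 0, +4.7) percent. Photon dose does not depend on
#' SPR, so photon plans use the single 0 perturbation.
#'
#' @param modality `"proton"` or `"photon"`.
#' @param perturbations Percent triple for protons (default `c(-4.7, 0, 4.7)`).
#' @return Numeric vector of percent perturbations.
#' @export
spr_scenarios <- function(modality = c("proton", "photon"),
                          perturbations = c(-4.7, 0, 4.7)) {
  modality <- match.arg(modality)
  if (modality == "photon") return(0)
  as.numeric(perturbations)
}

#' Serialize a scenario set to JSON
#' @param set A `scenario_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_set <- function(set, path) {
  jsonlite::write_json(
    list(label = set$label[1],
         samples = as.data.frame(set[, setdiff(names(set), "label")])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scenario set from JSON
#' @param path Path written by [write_scenario_set()].
#' @return A `scenario_set` tibble.
#' @export
read_scenario_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_scenario_set(obj$label, tibble::as_tibble(obj$samples))
}
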