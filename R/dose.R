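#' Dose engine parameters
#'
#' Defaults for the simplified analytic dose engines. These engines replace a
#' clinical treatment planning system on purpose: the robustness questions the
#' package addresses need the correct *sensitivity structure* (range vs SPR,
#' lateral penumbra vs setup shift, depth dose vs anatomy), not clinical
#' dosimetric accuracy.
#'
#' @param photon_buildup_mm Photon depth-dose build-up constant (mm).
#' @param photon_mu_per_mm Photon exponential attenuation per mm of
#'   water-equivalent depth.
#' @param photon_penumbra_sigma Aperture penumbra sigma (mm).
#' @param photon_aperture_margin Aperture margin beyond the CTV projection (mm).
#' @param bragg_plateau Entrance plateau of the Bragg curve relative to peak.
#' @param bragg_sigma_prox Proximal Gaussian width of the Bragg peak (mm).
#' @param bragg_sigma_dist Distal fall-off sigma (mm), range straggling included.
#' @param spot_lateral_sigma Pencil-beam lateral Gaussian sigma (mm).
#' @param layer_spacing_mm Energy-layer spacing in WEPL (mm).
#' @param spot_spacing_mm Lateral spot grid spacing (mm).
#' @param spot_margin_mm Lateral spot grid margin beyond the CTV projection (mm).
#' @param range_margin_mm WEPL margin proximal/distal of the CTV (mm).
#' @param max_layers_per_bh Energy layers deliverable in one breath-hold; a
#'   beam with more layers is split into two sub-beams.
#' @param dose_noise_sd Optional relative Gaussian dose noise (e.g. 0.02 to
#'   mimic a 2% Monte-Carlo statistical uncertainty); 0 disables it.
#' @return Named list of engine parameters.
#' @export
dose_engine_params <- function(photon_buildup_mm = 15,
                               photon_mu_per_mm = 0.0045,
                               photon_penumbra_sigma = 4,
                               photon_aperture_margin = 8,
                               bragg_plateau = 0.35,
                               bragg_sigma_prox = 8,
                               bragg_sigma_dist = 3,
                               spot_lateral_sigma = 5,
                               layer_spacing_mm = 5,
                               spot_spacing_mm = 5,
                               spot_margin_mm = 5,
                               range_margin_mm = 4,
                               max_layers_per_bh = 10,
                               dose_noise_sd = 0) {
  as.list(environment())
}

# ---- depth-dose kernels -----------------------------------------------------

# Photon percentage depth dose vs water-equivalent depth z (mm): build-up then
# exponential attenuation, normalized to peak 1.
pdd_photon <- function(z, pars) {
  raw <- (1 - exp(-z / pars$photon_buildup_mm)) * exp(-pars$photon_mu_per_mm * z)
  zs <- seq(0, 400, by = 0.5)
  mx <- max((1 - exp(-zs / pars$photon_buildup_mm)) * exp(-pars$photon_mu_per_mm * zs))
  raw / mx
}

# Analytic Bragg curve: entrance plateau rising to a peak at residual range 0,
# sharp distal Gaussian fall-off. z and R in WEPL mm; peak value 1 at z = R.
bragg_curve <- function(z, R, pars) {
  out <- numeric(length(z))
  prox <- z <= R
  out[prox] <- pars$bragg_plateau +
    (1 - pars$bragg_plateau) * exp(-(R - z[prox])^2 / (2 * pars$bragg_sigma_prox^2))
  out[!prox] <- exp(-(z[!prox] - R)^2 / (2 * pars$bragg_sigma_dist^2))
  out
}

# erf via pnorm
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# 1D aperture edge transmission across [a, b] with penumbra sigma
aperture_edge <- function(x, a, b, sigma) {
  0.5 * (.erf((x - a) / (sqrt(2) * sigma)) - .erf((x - b) / (sqrt(2) * sigma)))
}

# ---- beam geometry ----------------------------------------------------------

# A beam frame in the axial plane: entry angle theta (degrees, measured in the
# LR/AP plane from +LR), beam direction d = -entry, lateral axes e1 (in-plane)
# and e2 (CC).
beam_frame <- function(theta_deg, iso) {
  th <- theta_deg * pi / 180
  e <- c(cos(th), sin(th), 0)           # direction the beam enters from
  d <- -e                               # propagation direction
  e1 <- c(-d[2], d[1], 0)               # in-plane lateral axis
  e2 <- c(0, 0, 1)                      # CC lateral axis
  list(theta_deg = theta_deg, direction = d, e1 = e1, e2 = e2, iso = iso)
}

# Default entry angles for a right-sided tumor (mirrored for left-sided).
# Photons: six spread entries over the ipsilateral hemithorax. Protons:
# near-sagittal anterior entries whose distal overshoot corridors (rays that
# miss the tumor and overshoot through low-density lung) end in posterior
# lung/chest wall rather than the mediastinal organs — organ sparing by beam
# angle arrangement, not by objective.
default_angles <- function(modality, laterality) {
  ang <- if (modality == "proton") c(-110, -90, -70) else c(-85, -55, -25, 25, 55, 85)
  if (laterality == "left") ang <- 180 - ang
  ang
}

#' Water-equivalent path length along a single ray
#'
#' Cumulative WEPL (mm) sampled at fixed steps along a ray through the
#' phantom, integrating the stopping-power ratio (`quantity = "spr"`) or the
#' same SPR volume used as a generic radiological density
#' (`quantity = "density"`).
#'
#' @param phantom A `bh_phantom`.
#' @param entry Length-3 world start point (mm).
#' @param direction Length-3 unit direction.
#' @param quantity `"spr"` or `"density"`.
#' @param step Step length in mm.
#' @param n_steps Number of steps (default: enough to traverse the volume).
#' @return Tibble with `t_mm` (geometric depth) and `wepl_mm` (cumulative).
#' @export
radiological_path <- function(phantom, entry, direction,
                              quantity = c("spr", "density"),
                              step = NULL, n_steps = NULL) {
  quantity <- match.arg(quantity)
  grid <- phantom$grid
  if (is.null(step)) step <- min(grid$spacing)
  if (is.null(n_steps)) {
    n_steps <- ceiling(sqrt(sum((grid$shape * grid$spacing)^2)) / step)
  }
  d <- direction / sqrt(sum(direction^2))
  t_mm <- (seq_len(n_steps) - 0.5) * step
  pts <- sweep(outer(t_mm, d), 2, entry, "+")
  spr <- hu_to_spr(phantom$hu)
  vals <- interp_volume(spr, world_to_index(grid, pts), "linear")
  tibble::tibble(t_mm = t_mm, wepl_mm = cumsum(vals) * step)
}

# WEPL volume for a whole grid and one beam direction: resample SPR onto a
# beam-aligned grid, cumulative-sum along depth, resample back.
wepl_volume <- function(spr, grid, frame, step = NULL) {
  if (is.null(step)) step <- min(grid$spacing)
  d <- frame$direction; e1 <- frame$e1; e2 <- frame$e2
  corners <- as.matrix(expand.grid(
    grid$origin[1] + c(0, (grid$shape[1] - 1) * grid$spacing[1]),
    grid$origin[2] + c(0, (grid$shape[2] - 1) * grid$spacing[2]),
    grid$origin[3] + c(0, (grid$shape[3] - 1) * grid$spacing[3])))
  ctr <- colMeans(corners)
  rel <- sweep(corners, 2, ctr, "-")
  tr <- range(rel %*% d); ur <- range(rel %*% e1); vr <- range(rel %*% e2)
  ts <- seq(tr[1], tr[2], by = step)
  us <- seq(ur[1] - step, ur[2] + step, by = step)
  vs <- seq(vr[1] - step, vr[2] + step, by = step)
  nb <- c(length(ts), length(us), length(vs))
  bt <- rep(ts, times = nb[2] * nb[3])
  bu <- rep(rep(us, each = nb[1]), times = nb[3])
  bv <- rep(vs, each = nb[1] * nb[2])
  pts <- cbind(ctr[1] + bt * d[1] + bu * e1[1] + bv * e2[1],
               ctr[2] + bt * d[2] + bu * e1[2] + bv * e2[2],
               ctr[3] + bt * d[3] + bu * e1[3] + bv * e2[3])
  sv <- interp_volume(spr, world_to_index(grid, pts), "linear")
  sb <- array(sv, nb)
  cw <- apply(sb, c(2, 3), cumsum) * step       # cumulative along depth
  cw <- cw - sb * step / 2                      # midpoint correction
  # sample back at the voxel centres
  co <- grid_coords(grid)
  px <- co$x - ctr[1]; py <- co$y - ctr[2]; pz <- co$z - ctr[3]
  tq <- (px * d[1] + py * d[2] + pz * d[3] - ts[1]) / step + 1
  uq <- (px * e1[1] + py * e1[2] + pz * e1[3] - us[1]) / step + 1
  vq <- (px * e2[1] + py * e2[2] + pz * e2[3] - vs[1]) / step + 1
  array(interp_volume(cw, cbind(tq, uq, vq), "linear"), grid$shape)
}

# ---- beam construction ------------------------------------------------------

# CTV projection extents and WEPL extent for one frame
ctv_beam_extent <- function(phantom, frame, wepl_ref) {
  idx <- which(phantom$structures$CTV)
  pts <- grid_points(phantom$grid, idx)
  rel <- sweep(pts, 2, frame$iso, "-")
  list(u = range(rel %*% frame$e1), v = range(rel %*% frame$e2),
       w = range(wepl_ref[idx]))
}

#' Construct the beams of a plan
#'
#' Photon beams get a rectangular aperture covering the CTV projection plus a
#' margin; proton beams get energy layers spaced in WEPL covering the CTV
#' depth extent plus a range margin, each layer carrying a lateral spot grid
#' over the CTV projection plus a margin. Beam entry angles default to an
#' arrangement avoiding contralateral-lung entry (overridable).
#'
#' @param phantom A `bh_phantom`.
#' @param modality `"photon"` or `"proton"`.
#' @param angles Entry angles in degrees in the axial plane, or `NULL` for
#'   defaults (6 photon / 3 proton beams).
#' @param pars Engine parameters from [dose_engine_params()].
#' @return List of beam objects (direction frame plus aperture or layers).
#' @export
make_beams <- function(phantom, modality = c("photon", "proton"),
                       angles = NULL, pars = dose_engine_params()) {
  modality <- match.arg(modality)
  if (is.null(angles)) angles <- default_angles(modality, phantom$meta$laterality)
  iso <- colMeans(grid_points(phantom$grid, which(phantom$structures$CTV)))
  spr_ref <- reference_spr(phantom)
  beams <- vector("list", length(angles))
  for (b in seq_along(angles)) {
    fr <- beam_frame(angles[b], iso)
    wep <- reference_wepl(phantom, fr)
    ext <- ctv_beam_extent(phantom, fr, wep)
    if (modality == "photon") {
      m <- pars$photon_aperture_margin
      beams[[b]] <- c(fr, list(
        modality = "photon",
        aperture = list(u = ext$u + c(-m, m), v = ext$v + c(-m, m)),
        id = paste0("ph", b)))
    } else {
      rngs <- seq(ext$w[2] + pars$range_margin_mm,
                  ext$w[1] - pars$range_margin_mm,
                  by = -pars$layer_spacing_mm)   # deepest first
      m <- pars$spot_margin_mm
      us <- seq(ext$u[1] - m, ext$u[2] + m, by = pars$spot_spacing_mm)
      vs <- seq(ext$v[1] - m, ext$v[2] + m, by = pars$spot_spacing_mm)
      spots <- as.matrix(expand.grid(u = us, v = vs))
      layers <- lapply(rngs, function(R) {
        list(nominal_range = R, spots = spots,
             lateral_sigma = pars$spot_lateral_sigma)
      })
      beams[[b]] <- c(fr, list(modality = "proton", layers = layers,
                               id = paste0("pr", b)))
    }
  }
  beams
}

#' Split a proton beam into breath-hold deliverable sub-beams
#'
#' A beam with more than `max_layers` energy layers is split into two
#' sub-beams, the first taking the first `ceiling(n/2)` successive layers
#' (deepest-first order preserved) and the second the remaining
#' `floor(n/2)`, so each sub-beam can be delivered within a single
#' breath-hold. Beams with at most `max_layers` layers are returned as-is.
#'
#' @param beam A proton beam from [make_beams()].
#' @param max_layers Split threshold (default 10).
#' @return List of one or two sub-beams.
#' @export
split_energy_layers <- function(beam, max_layers = 10L) {
  if (is.null(beam$layers)) stop("split_energy_layers: not a proton beam")
  n <- length(beam$layers)
  if (n <= max_layers) return(list(beam))
  k <- ceiling(n / 2)
  b1 <- beam; b1$layers <- beam$layers[seq_len(k)]; b1$id <- paste0(beam$id, "a")
  b2 <- beam; b2$layers <- beam$layers[(k + 1):n]; b2$id <- paste0(beam$id, "b")
  list(b1, b2)
}

# ---- cached reference volumes ----------------------------------------------

reference_spr <- function(phantom) {
  if (is.null(phantom$cache$spr)) phantom$cache$spr <- hu_to_spr(phantom$hu)
  phantom$cache$spr
}

reference_wepl <- function(phantom, frame) {
  key <- paste0("wepl_", frame$theta_deg)
  if (is.null(phantom$cache[[key]])) {
    phantom$cache[[key]] <- wepl_volume(reference_spr(phantom), phantom$grid, frame)
  }
  phantom$cache[[key]]
}

# ---- images (reference or deformed breath-hold geometry) -------------------

# A breath-hold image: the reference phantom plus an optional displacement
# field (inverse populated). Carries its own cache of warped SPR and per-beam
# WEPL volumes.
bh_image <- function(phantom, field = NULL, id = "ref") {
  cache <- new.env(parent = emptyenv())
  cache$field <- field
  structure(list(phantom = phantom, id = id, cache = cache),
            class = "bh_image")
}

image_field <- function(image) image$cache$field

image_spr <- function(image) {
  if (is.null(image_field(image))) return(reference_spr(image$phantom))
  if (is.null(image$cache$spr)) {
    image$cache$spr <- warp_image(reference_spr(image$phantom), image_field(image), "linear")
  }
  image$cache$spr
}

# WEPL volume for this image and beam. Photon attenuation uses the reference
# image (static-cloud approximation: lung-confined deformations barely change
# photon attenuation; deformation enters photon dose via the accumulation
# mapping). Proton WEPL is recomputed on the deformed image (range effects).
image_wepl <- function(image, beam) {
  if (beam$modality == "photon" || is.null(image_field(image))) {
    return(reference_wepl(image$phantom, beam))
  }
  key <- paste0("wepl_", beam$theta_deg)
  if (is.null(image$cache[[key]])) {
    image$cache[[key]] <- wepl_volume(image_spr(image), image$phantom$grid, beam)
  }
  image$cache[[key]]
}

# Per-beam point data at reference points pts_mm: WEPL and lateral coordinates
# evaluated at the deformed positions x(p) (identity when the image is the
# reference). `tag` keys the cache for a reusable point set.
image_point_data <- function(image, beam, pts_mm, tag) {
  key <- paste0("pd_", beam$id, "_", tag)
  if (!is.null(image$cache[[key]])) return(image$cache[[key]])
  fld <- image_field(image)
  x <- if (is.null(fld)) pts_mm else deformed_positions(fld, pts_mm)
  W <- interp_volume(image_wepl(image, beam), world_to_index(image$phantom$grid, x), "linear")
  rel <- sweep(x, 2, beam$iso, "-")
  out <- list(W = W,
              u = as.numeric(rel %*% beam$e1),
              v = as.numeric(rel %*% beam$e2))
  image$cache[[key]] <- out
  out
}

# ---- dose evaluation --------------------------------------------------------

# Dose-influence columns of one beam at point data `pd` under setup shift s
# (world mm) and SPR perturbation delta (%): n_points x n_weights matrix of
# dose per unit weight. RBE is NOT applied here.
beam_influence <- function(beam, pd, s = c(0, 0, 0), delta = 0,
                           pars = dose_engine_params()) {
  su <- sum(s * beam$e1); sv <- sum(s * beam$e2)
  if (beam$modality == "photon") {
    tr <- aperture_edge(pd$u + su, beam$aperture$u[1], beam$aperture$u[2],
                        pars$photon_penumbra_sigma) *
          aperture_edge(pd$v + sv, beam$aperture$v[1], beam$aperture$v[2],
                        pars$photon_penumbra_sigma)
    return(matrix(pdd_photon(pd$W, pars) * tr, ncol = 1))
  }
  Wp <- pd$W * (1 + delta / 100)
  ncol_tot <- sum(vapply(beam$layers, function(l) nrow(l$spots), integer(1)))
  out <- matrix(0, length(pd$W), ncol_tot)
  col <- 1L
  for (l in beam$layers) {
    bz <- bragg_curve(Wp, l$nominal_range, pars)
    s2 <- 2 * l$lateral_sigma^2
    for (j in seq_len(nrow(l$spots))) {
      g <- exp(-((pd$u + su - l$spots[j, 1])^2 + (pd$v + sv - l$spots[j, 2])^2) / s2)
      out[, col] <- bz * g
      col <- col + 1L
    }
  }
  out
}

n_beam_weights <- function(beam) {
  if (beam$modality == "photon") 1L
  else sum(vapply(beam$layers, function(l) nrow(l$spots), integer(1)))
}

#' Photon beam dose on the phantom grid
#'
#' Full-grid dose of a single photon beam at unit isocenter position:
#' depth dose (build-up then exponential attenuation of radiological depth)
#' times error-function aperture penumbra, scaled by `weight`. Deterministic.
#'
#' @param phantom A `bh_phantom`.
#' @param beam A photon beam from [make_beams()].
#' @param weight Nonnegative beam weight.
#' @param pars Engine parameters.
#' @return 3D dose array (arbitrary units until plan normalization).
#' @export
photon_beam_dose <- function(phantom, beam, weight = 1,
                             pars = dose_engine_params()) {
  img <- bh_image(phantom)
  pd <- image_point_data(img, beam, grid_points(phantom$grid), "full")
  array(as.numeric(beam_influence(beam, pd, pars = pars)) * weight,
        phantom$grid$shape)
}

#' Proton beam dose on the phantom grid
#'
#' Full-grid RBE-weighted dose of one proton beam: per spot, an analytic
#' Bragg curve in perturbed WEPL (`WEPL x (1 + delta/100)`) times a lateral
#' Gaussian, summed over spots and layers with the given weights and
#' multiplied by the constant RBE 1.1.
#'
#' @param phantom A `bh_phantom`.
#' @param beam A proton beam from [make_beams()].
#' @param weights Nonnegative spot weights (length = layers x spots), or a
#'   scalar applied to all spots.
#' @param spr_perturbation SPR perturbation in percent.
#' @param rbe Relative biological effectiveness (default 1.1).
#' @param pars Engine parameters.
#' @return 3D RBE-weighted dose array.
#' @export
proton_dose <- function(phantom, beam, weights = 1, spr_perturbation = 0,
                        rbe = 1.1, pars = dose_engine_params()) {
  nw <- n_beam_weights(beam)
  if (length(weights) == 1L) weights <- rep(weights, nw)
  stopifnot(length(weights) == nw, all(weights >= 0))
  img <- bh_image(phantom)
  pd <- image_point_data(img, beam, grid_points(phantom$grid), "full")
  infl <- beam_influence(beam, pd, delta = spr_perturbation, pars = pars)
  array(rbe * as.numeric(infl %*% weights), phantom$grid$shape)
}

# Dose at reference points for a plan under one scenario. `image` is a
# bh_image (reference or deformed, inverse populated); `unit` optionally
# restricts to one breath-hold delivery unit (sub-beam index).
plan_dose_at_points <- function(plan, image, pts_mm, tag, setup_shift = c(0, 0, 0),
                                delta = 0, unit = NULL) {
  beams <- plan$beams
  idxs <- if (is.null(unit)) seq_along(beams) else unit
  dose <- numeric(nrow(pts_mm))
  for (b in idxs) {
    beam <- beams[[b]]
    pd <- image_point_data(image, beam, pts_mm, tag)
    infl <- beam_influence(beam, pd, s = setup_shift,
                           delta = if (beam$modality == "proton") delta else 0,
                           pars = plan$pars)
    w <- plan$weights[plan$weight_beam == b]
    dose <- dose + as.numeric(infl %*% w)
  }
  dose * plan$rbe
}

#' Scenario dose accumulated on the reference geometry
#'
#' Computes the plan dose for one robust/evaluation scenario: the dose is
#' evaluated on the (possibly deformed) breath-hold image with the setup
#' shift applied as a rigid isocenter translation and the SPR perturbation
#' applied to proton WEPL, then mapped back to the reference geometry through
#' the image's inverse displacement field.
#'
#' @param plan A `bh_plan` (see [robust_optimize()]).
#' @param phantom The reference `bh_phantom`.
#' @param field Optional `bh_dvf` (inverse populated) describing the deformed
#'   breath-hold geometry; `NULL` for the reference image.
#' @param setup_shift Length-3 rigid setup shift in mm.
#' @param spr_perturbation SPR perturbation in percent (protons only;
#'   photon dose is invariant).
#' @param noise_seed Seed for the optional relative Gaussian dose noise
#'   (applied only when the plan's engine parameter `dose_noise_sd` > 0).
#' @return 3D dose array on the reference geometry (Gy after normalization).
#' @export
compute_scenario_dose <- function(plan, phantom, field = NULL,
                                  setup_shift = c(0, 0, 0), spr_perturbation = 0,
                                  noise_seed = 1L) {
  img <- bh_image(phantom, field, id = if (is.null(field)) "ref" else "def")
  pts <- grid_points(phantom$grid)
  dose <- plan_dose_at_points(plan, img, pts, "full", setup_shift, spr_perturbation)
  if (plan$pars$dose_noise_sd > 0) {
    old <- .Random.seed_get()
    set.seed(as.integer(noise_seed))
    dose <- pmax(dose * (1 + stats::rnorm(length(dose), 0, plan$pars$dose_noise_sd)), 0)
    .Random.seed_restore(old)
  }
  array(dose, phantom$grid$shape)
}
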