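#' Generate a synthetic breath-hold thorax phantom
#'
#' Builds the voxelised thorax CT and structure set used throughout the
#' pipeline as a stand-in for a patient breath-hold CT: an elliptical body
#' with a high-density chest wall shell, two low-density lungs, heart,
#' esophagus, aorta and spinal cord, and a spherical tumor (CTV) inside one
#' lung. Tissue HU values are fixed nominal constants (lung -750, soft tissue
#' ~40, chest wall 700, tumor 20) chosen for realistic density contrast —
#' proton range through lung is what makes the simulated plans sensitive to
#' breath-hold tumor-position variability.
#'
#' @param grid A [voxel_grid()]. Default: 3 mm isotropic covering a
#'   220 x 170 x 180 mm thorax centred on the world origin.
#' @param tumor_diameter_mm CTV sphere diameter in mm (default 25).
#' @param tumor_center_mm World coordinates (mm) of the tumor centre, or
#'   `NULL` for a default position well inside the ipsilateral lung.
#' @param laterality `"right"` or `"left"`: which lung hosts the tumor.
#'   The anatomy is mirrored in LR accordingly.
#' @param noise_sd Optional SD (HU) of seeded Gaussian texture noise added to
#'   the HU volume inside the body; 0 (default) disables it.
#' @param seed Integer seed for the texture noise; the geometry itself is
#'   deterministic. Same config + same seed is bit-identical.
#' @return An object of class `bh_phantom`: list with `grid`, `hu` (3D array),
#'   `structures` (named list of logical arrays: CTV, lung_ipsi, lung_contra,
#'   heart, esophagus, aorta, spinal_cord, chest_wall, body), and `meta`
#'   (config echo plus `tumor_wall_gap_mm`, the clearance between the CTV
#'   surface and the lung wall).
#' @examples
#' ph <- generate_phantom(grid = voxel_grid(c(40, 32, 34), spacing = c(5, 5, 5),
#'                                          origin = -c(39, 31, 33) * 5 / 2))
#' sapply(ph$structures, sum)
#' @export
generate_phantom <- function(grid = NULL,
                             tumor_diameter_mm = 25,
                             tumor_center_mm = NULL,
                             laterality = c("right", "left"),
                             noise_sd = 0,
                             seed = 1L) {
  laterality <- match.arg(laterality)
  s <- if (laterality == "right") 1 else -1
  if (is.null(grid)) {
    shape <- c(74L, 57L, 61L)
    grid <- voxel_grid(shape, spacing = c(3, 3, 3), origin = -(shape - 1) * 3 / 2)
  }
  if (tumor_diameter_mm <= max(grid$spacing)) {
    stop("generate_phantom: tumor diameter must exceed one voxel (",
         max(grid$spacing), " mm)")
  }
  if (is.null(tumor_center_mm)) tumor_center_mm <- c(s * 55, -5, 20)

  co <- grid_coords(grid)
  x <- s * co$x  # mirrored LR coordinate: anatomy is defined for a right-sided tumor
  y <- co$y; z <- co$z
  dims <- grid$shape
  as_mask <- function(v) array(v, dims)

  ellipse2 <- function(cx, cy, ax, ay) ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
  ellipsoid <- function(cx, cy, cz, ax, ay, az)
    ((x - cx) / ax)^2 + ((y - cy) / ay)^2 + ((z - cz) / az)^2 <= 1
  cylinder <- function(cx, cy, r) (x - cx)^2 + (y - cy)^2 <= r^2

  body       <- ellipse2(0, 0, 100, 75)
  body_inner <- ellipse2(0, 0, 88, 63)
  chest_wall <- body & !body_inner
  lung_ipsi  <- ellipsoid( 48, -5, 0, 36, 46, 65)
  lung_contra<- ellipsoid(-48, -5, 0, 36, 46, 65)
  esophagus  <- cylinder(0, 30, 5)
  aorta      <- cylinder(-15, 40, 9)
  spinal     <- cylinder(0, 52, 5)
  heart      <- ellipsoid(-14, -18, -25, 35, 30, 40) & !esophagus & !aorta & !spinal
  lung_ipsi  <- lung_ipsi  & !heart & !esophagus & !aorta & !spinal & body_inner
  lung_contra<- lung_contra & !heart & !esophagus & !aorta & !spinal & body_inner

  tc <- tumor_center_mm
  ctv <- ((co$x - tc[1])^2 + (y - tc[2])^2 + (z - tc[3])^2) <= (tumor_diameter_mm / 2)^2
  # uncarved geometric lung: the region the tumor is allowed to occupy
  lung_geom <- ellipsoid(48, -5, 0, 36, 46, 65)

  structures <- lapply(
    list(CTV = ctv, lung_ipsi = lung_ipsi, lung_contra = lung_contra,
         heart = heart, esophagus = esophagus & body_inner,
         aorta = aorta & body_inner, spinal_cord = spinal & body_inner,
         chest_wall = chest_wall, body = body),
    as_mask)
  lung_geom <- as_mask(lung_geom)

  if (!any(structures$CTV)) stop("generate_phantom: CTV is empty on this grid")
  center_in <- ((s * tc[1] - 48) / 36)^2 + ((tc[2] + 5) / 46)^2 + (tc[3] / 65)^2 <= 1
  if (!center_in) {
    stop("generate_phantom: tumor centre (", paste(tc, collapse = ", "),
         ") mm does not lie inside the ipsilateral lung")
  }
  if (any(structures$CTV & !lung_geom))
    stop("generate_phantom: CTV extends outside the ipsilateral lung")

  hu <- array(-1000, dims)
  hu[structures$body]        <- 40
  hu[structures$chest_wall]  <- 700
  hu[structures$lung_ipsi]   <- -750
  hu[structures$lung_contra] <- -750
  hu[structures$heart]       <- 45
  hu[structures$esophagus]   <- 35
  hu[structures$aorta]       <- 50
  hu[structures$spinal_cord] <- 40
  hu[structures$CTV]         <- 20

  if (noise_sd > 0) {
    old <- .Random.seed_get()
    set.seed(as.integer(seed))
    nb <- sum(structures$body)
    hu[structures$body] <- hu[structures$body] + stats::rnorm(nb, 0, noise_sd)
    .Random.seed_restore(old)
  }

  lung_for_gap <- structures$lung_ipsi | structures$CTV
  gap <- dist_to_mask(grid, grid_points(grid, which(mask_surface(structures$CTV))),
                      mask_surface(lung_for_gap) & !structures$CTV)
  ph <- structure(
    list(grid = grid, hu = hu, structures = structures,
         meta = list(tumor_diameter_mm = tumor_diameter_mm,
                     tumor_center_mm = tc, laterality = laterality,
                     noise_sd = noise_sd, seed = as.integer(seed),
                     tumor_wall_gap_mm = min(gap)),
         cache = new.env(parent = emptyenv())),
    class = "bh_phantom")
  ph
}

# save/restore global RNG state so phantom generation does not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' @export
print.bh_phantom <- function(x, ...) {
  cat("<bh_phantom> ", paste(x$grid$shape, collapse = "x"), " voxels @ ",
      paste(x$grid$spacing, collapse = "/"), " mm\n", sep = "")
  cat("  tumor: ", x$meta$tumor_diameter_mm, " mm diameter, ",
      x$meta$laterality, " lung, wall gap ",
      round(x$meta$tumor_wall_gap_mm, 1), " mm\n", sep = "")
  vv <- voxel_volume(x$grid) / 1000
  tb <- tibble::tibble(
    structure = names(x$structures),
    voxels = vapply(x$structures, sum, integer(1)),
    volume_cm3 = round(vapply(x$structures, sum, integer(1)) * vv, 1))
  print(tb, n = nrow(tb))
  invisible(x)
}

#' Structure volumes as a tibble
#' @param phantom A `bh_phantom`.
#' @return Tibble with structure name, voxel count and volume in cm^3.
#' @export
structure_volumes <- function(phantom) {
  vv <- voxel_volume(phantom$grid) / 1000
  tibble::tibble(
    structure = names(phantom$structures),
    voxels = vapply(phantom$structures, sum, integer(1))
  ) |> dplyr::mutate(volume_cm3 = .data$voxels * vv)
}

#' Convert Hounsfield units to stopping-power ratio
#'
#' Piecewise-linear monotone calibration with anchors at air
#' (SPR(-1000) = 0.001) and water (SPR(0) = 1.0), extended linearly into
#' bone-like densities. HU outside [-1024, 3000] are clamped. The curve is a
#' generic research calibration, not a scanner-specific one.
#'
#' @param hu Numeric vector or array of HU values.
#' @return SPR values with the same shape as `hu`.
#' @examples
#' hu_to_spr(c(-1000, -750, 0, 700))
#' @export
hu_to_spr <- function(hu) {
  knots_hu <- c(-1024, -1000, 0, 1600, 3000)
  knots_spr <- c(0.001, 0.001, 1.0, 1.85, 2.50)
  v <- pmin(pmax(as.vector(hu), -1024), 3000)
  out <- stats::approx(knots_hu, knots_spr, xout = v, rule = 2)$y
  if (is.array(hu)) array(out, dim(hu)) else out
}

#' Write a phantom to NIfTI volumes with a JSON sidecar
#'
#' Writes the HU volume and each structure mask as NIfTI files (requires the
#' RNifti package) plus a JSON sidecar recording structure names, grid
#' geometry and the generation config.
#'
#' @param phantom A `bh_phantom`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("write_phantom requires the RNifti package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$grid$spacing
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
    path
  }
  paths <- c(wr(phantom$hu, file.path(dir, "hu.nii.gz")))
  for (nm in names(phantom$structures)) {
    paths <- c(paths, wr(phantom$structures[[nm]] + 0,
                         file.path(dir, paste0("mask_", nm, ".nii.gz"))))
  }
  sidecar <- file.path(dir, "phantom.json")
  jsonlite::write_json(
    list(structures = names(phantom$structures),
         grid = phantom$grid[c("shape", "spacing", "origin")],
         meta = phantom$meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}
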