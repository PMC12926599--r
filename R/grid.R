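#' Voxel grid geometry
#'
#' A `voxel_grid` describes the regular 3D lattice shared by every volume and
#' structure mask of a phantom: array dimensions, voxel spacing and world
#' origin. World coordinates (mm) of voxel `(i, j, k)` (1-based indices) are
#' `origin + (index - 1) * spacing`. Axis order is LR (x), AP (y), CC (z).
#'
#' @param shape Integer vector of length 3, array dimensions (>= 16 each).
#' @param spacing Numeric vector of length 3, voxel spacing in mm (> 0).
#' @param origin Numeric vector of length 3, world position of voxel (1,1,1) in mm.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 16L)) stop("voxel_grid: shape must be at least 16 voxels per axis")
  if (any(spacing <= 0)) stop("voxel_grid: spacing must be positive on all axes")
  structure(
    list(shape = shape, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"),
      " mm, origin (", paste(x$origin, collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' Voxel volume in mm^3
#' @param grid A `voxel_grid`.
#' @return Scalar volume of one voxel in mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

# World-coordinate arrays of every voxel centre, one n-vector per axis.
grid_coords <- function(grid) {
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
  list(
    x = rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
    y = rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
    z = rep(ax[[3]], each = grid$shape[1] * grid$shape[2])
  )
}

# n x 3 matrix of world coordinates for linear voxel indices (default: all).
grid_points <- function(grid, idx = NULL) {
  co <- grid_coords(grid)
  p <- cbind(co$x, co$y, co$z)
  if (!is.null(idx)) p <- p[idx, , drop = FALSE]
  p
}

world_to_index <- function(grid, pts) {
  # continuous 1-based array indices for an n x 3 matrix of world points (mm)
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

#' Sample a volume at arbitrary points
#'
#' Trilinear or nearest-neighbour interpolation of a 3D array at continuous
#' 1-based array indices. Points outside the array are clamped to the edge
#' (the phantom border is air, so clamping reproduces the background value).
#'
#' @param vol 3D numeric array.
#' @param idx n x 3 matrix of continuous 1-based indices.
#' @param mode `"linear"` (HU, SPR, dose) or `"nearest"` (masks, labels).
#' @return Numeric vector of length n.
#' @export
interp_volume <- function(vol, idx, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(vol)
  cx <- pmin(pmax(idx[, 1], 1), d[1])
  cy <- pmin(pmax(idx[, 2], 1), d[2])
  cz <- pmin(pmax(idx[, 3], 1), d[3])
  if (mode == "nearest") {
    return(vol[cbind(round(cx), round(cy), round(cz))])
  }
  x0 <- pmin(floor(cx), d[1] - 1); y0 <- pmin(floor(cy), d[2] - 1); z0 <- pmin(floor(cz), d[3] - 1)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  n12 <- d[1] * d[2]
  base <- (z0 - 1) * n12 + (y0 - 1) * d[1] + x0  # linear index of (x0, y0, z0)
  v <- as.vector(vol)
  c000 <- v[base];               c100 <- v[base + 1]
  c010 <- v[base + d[1]];        c110 <- v[base + d[1] + 1]
  c001 <- v[base + n12];         c101 <- v[base + n12 + 1]
  c011 <- v[base + n12 + d[1]];  c111 <- v[base + n12 + d[1] + 1]
  w00 <- c000 * (1 - fx) + c100 * fx
  w10 <- c010 * (1 - fx) + c110 * fx
  w01 <- c001 * (1 - fx) + c101 * fx
  w11 <- c011 * (1 - fx) + c111 * fx
  (w00 * (1 - fy) + w10 * fy) * (1 - fz) + (w01 * (1 - fy) + w11 * fy) * fz
}

# Binary erosion with the 6-connected structuring element (face neighbours).
erode6 <- function(mask) {
  d <- dim(mask)
  m <- mask
  shift_and <- function(m, axis, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    n <- d[axis]
    if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
    else        { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  res <- mask
  for (axis in 1:3) for (by in c(-1L, 1L)) res <- res & shift_and(m, axis, by)
  res
}

# Distance (mm) from each of the points `pts` (n x 3 world mm) to the nearest
# voxel centre of `mask`. Brute force over mask voxels, chunked; masks here are
# small (structure surfaces).
dist_to_mask <- function(grid, pts, mask) {
  mp <- grid_points(grid, which(mask))
  if (nrow(mp) == 0L) stop("dist_to_mask: empty mask")
  out <- numeric(nrow(pts))
  chunk <- max(1L, floor(2e6 / nrow(mp)))
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(block[, 1], mp[, 1], "-")^2 +
          outer(block[, 2], mp[, 2], "-")^2 +
          outer(block[, 3], mp[, 3], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

# Surface voxels of a mask (mask voxels with at least one non-mask 6-neighbour).
mask_surface <- function(mask) mask & !erode6(mask)
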