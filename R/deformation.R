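#' Clamp a tumor shift to the lung wall
#'
#' Breath-hold tumor shifts are constrained by the lung wall: a requested
#' shift that would push the tumor outside the lung is scaled down (direction
#' preserved) until the shifted tumor stays inside the lung with at least one
#' voxel of clearance. Feasible shifts are returned unchanged.
#'
#' @param shift Numeric length-3 shift in mm (LR, AP, CC).
#' @param tumor_mask,lung_mask Logical 3D arrays on the same grid; the tumor
#'   must lie inside the lung (the lung mask should include the tumor voxels).
#' @param grid The shared [voxel_grid()].
#' @return A length-3 numeric shift (mm), scaled if necessary. The applied
#'   scale factor is attached as attribute `"scale"`.
#' @export
clamp_shift_to_lung_wall <- function(shift, tumor_mask, lung_mask, grid) {
  stopifnot(length(shift) == 3L, all(dim(tumor_mask) == dim(lung_mask)))
  if (!all(lung_mask[tumor_mask])) {
    stop("clamp_shift_to_lung_wall: tumor mask is not contained in the lung mask")
  }
  if (all(shift == 0)) return(structure(c(0, 0, 0), scale = 1))
  interior <- erode6(lung_mask)  # >= 1 voxel clearance
  tpts <- grid_points(grid, which(tumor_mask))
  feasible <- function(alpha) {
    idx <- world_to_index(grid, sweep(tpts, 2, alpha * shift, "+"))
    # reject points that leave the array entirely
    d <- grid$shape
    inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
              idx[, 2] >= 1 & idx[, 2] <= d[2] &
              idx[, 3] >= 1 & idx[, 3] <= d[3]
    if (!all(inside)) return(FALSE)
    all(interp_volume(interior + 0, idx, "nearest") > 0)
  }
  if (feasible(1)) return(structure(as.numeric(shift), scale = 1))
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  structure(lo * as.numeric(shift), scale = lo)
}

# Build (and cache on the phantom) the sparse 7-point Laplacian factorization
# for the harmonic DVF domain: ipsilateral lung minus tumor. Dirichlet data
# live on the tumor (value = shift) and on out-of-lung voxels (value = 0);
# array-edge faces are zero-flux (the lung never touches the array edge in
# practice, and the slab analogue relies on it).
dvf_factor <- function(phantom) {
  cache <- phantom$cache
  if (!is.null(cache$dvf_factor)) return(cache$dvf_factor)
  grid <- phantom$grid
  lung <- phantom$structures$lung_ipsi | phantom$structures$CTV
  tumor <- phantom$structures$CTV
  domain <- lung & !tumor
  d <- grid$shape
  id <- array(0L, d)
  nd <- sum(domain)
  if (nd == 0L) stop("dvf_factor: empty deformation domain")
  id[domain] <- seq_len(nd)
  w <- 1 / grid$spacing^2

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nd)
  # per-voxel tumor-neighbour count per axis weight: contributes to RHS with shift value
  tumor_rhs_w <- numeric(nd)
  dom_idx <- which(domain)
  ar <- arrayInd(dom_idx, d)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- ar
      nb[, axis] <- nb[, axis] + dir
      inb <- nb[, axis] >= 1L & nb[, axis] <= d[axis]
      # array-edge neighbours: zero-flux -> no coupling, no diagonal contribution
      nb_lin <- rep(NA_integer_, nd)
      nb_lin[inb] <- (nb[inb, 3] - 1L) * (d[1] * d[2]) + (nb[inb, 2] - 1L) * d[1] + nb[inb, 1]
      in_dom <- inb & domain[pmax(nb_lin, 1L)] & !is.na(nb_lin)
      in_tum <- inb & !in_dom & tumor[pmax(nb_lin, 1L)] & !is.na(nb_lin)
      # everything else inside array but outside domain/tumor: Dirichlet 0
      diag_acc[inb] <- diag_acc[inb] + w[axis]
      ii <- c(ii, which(in_dom)); jj <- c(jj, id[nb_lin[in_dom]])
      xx <- c(xx, rep(-w[axis], sum(in_dom)))
      tumor_rhs_w[in_tum] <- tumor_rhs_w[in_tum] + w[axis]
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nd)), j = c(jj, seq_len(nd)),
                            x = c(xx, diag_acc), dims = c(nd, nd))
  fac <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)
  out <- list(factor = fac, A = A, domain = domain, id = id,
              tumor_rhs_w = tumor_rhs_w, dom_idx = dom_idx)
  cache$dvf_factor <- out
  out
}

#' Solve a Laplacian displacement vector field for a tumor shift
#'
#' Each displacement component is harmonic (discrete Laplace equation) on the
#' ipsilateral lung minus the tumor, with Dirichlet values equal to the
#' (clamped) tumor shift on tumor voxels and zero on and outside the lung
#' boundary. This interpolates a rigid tumor displacement smoothly down to a
#' fixed lung wall — lung tissue between tumor and wall deforms, everything
#' outside the lung stays static.
#'
#' @param phantom A `bh_phantom`.
#' @param tumor_shift Length-3 shift in mm; clamped to the lung wall first
#'   (see [clamp_shift_to_lung_wall()]) unless `clamp = FALSE`.
#' @param tol Residual tolerance in mm for the max-norm of the discrete
#'   Laplacian over interior voxels (default 1e-3).
#' @param clamp Clamp the shift to the lung wall before solving (default TRUE).
#' @return An object of class `bh_dvf`: `grid`, `vectors` (4D array
#'   `shape x 3`, mm, zero outside the deformation domain), `shift` (the
#'   applied, possibly clamped shift) and `inverse` (`NULL` until
#'   [invert_dvf()] populates it).
#' @export
solve_laplacian_dvf <- function(phantom, tumor_shift, tol = 1e-3, clamp = TRUE) {
  stopifnot(tol > 0)
  grid <- phantom$grid
  lung <- phantom$structures$lung_ipsi | phantom$structures$CTV
  tumor <- phantom$structures$CTV
  shift <- as.numeric(tumor_shift)
  if (clamp) shift <- as.numeric(clamp_shift_to_lung_wall(shift, tumor, lung, grid))

  fac <- dvf_factor(phantom)
  d <- grid$shape
  vec <- array(0, c(d, 3L))
  if (any(shift != 0)) {
    for (c_ in 1:3) {
      if (shift[c_] == 0) next
      b <- fac$tumor_rhs_w * shift[c_]
      u <- as.numeric(Matrix::solve(fac$factor, b))
      comp <- array(0, d)
      comp[fac$dom_idx] <- u
      comp[tumor] <- shift[c_]
      vec[, , , c_] <- comp
      # residual check on interior voxels
      res <- max(abs(fac$A %*% u - b))
      if (res >= tol) {
        stop("solve_laplacian_dvf: solver residual ", signif(res, 3),
             " exceeds tol ", tol)
      }
    }
  }
  structure(list(grid = grid, vectors = vec, shift = shift, inverse = NULL,
                 domain = lung),
            class = "bh_dvf")
}

#' @export
print.bh_dvf <- function(x, ...) {
  cat("<bh_dvf> shift (", paste(round(x$shift, 2), collapse = ", "),
      ") mm; inverse ", if (is.null(x$inverse)) "not " else "", "populated\n",
      sep = "")
  invisible(x)
}

# Sample a displacement field (4D array) at continuous index positions.
sample_field <- function(vec, idx) {
  cbind(interp_volume(vec[, , , 1], idx, "linear"),
        interp_volume(vec[, , , 2], idx, "linear"),
        interp_volume(vec[, , , 3], idx, "linear"))
}

#' Invert a displacement field by fixed-point iteration
#'
#' Computes the inverse displacement `u_inv` satisfying
#' `u_inv(p) = -u(p - u_inv(p))`, so that warping with the field and then with
#' its inverse is the identity up to interpolation. The composition residual
#' (RMS of `u_inv(p) + u(p - u_inv(p))` over the deformation domain) is
#' attached as attribute `"residual_rms"` on the returned field's `inverse`.
#'
#' @param field A `bh_dvf`.
#' @param iters Fixed-point iterations (default 20).
#' @return The field with `inverse` populated (4D array, mm). Warns if the
#'   residual exceeds 0.25 x the smallest voxel spacing.
#' @export
invert_dvf <- function(field, iters = 20L) {
  grid <- field$grid
  d <- grid$shape
  # the inverse is nonzero only near the deformation domain: iterate on the
  # domain bounding box dilated by the maximum displacement
  pad <- ceiling(max(abs(field$shift), 1) / min(grid$spacing)) + 1L
  ar <- arrayInd(which(field$domain), d)
  lo <- pmax(apply(ar, 2, min) - pad, 1L)
  hi <- pmin(apply(ar, 2, max) + pad, d)
  sub <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  pts <- sub  # already 1-based index coordinates
  uinv <- matrix(0, nrow(pts), 3)
  for (it in seq_len(iters)) {
    q <- pts - sweep(uinv, 2, grid$spacing, "/")
    uinv <- -sample_field(field$vectors, q)
  }
  q <- pts - sweep(uinv, 2, grid$spacing, "/")
  resid <- uinv + sample_field(field$vectors, q)
  dom <- field$domain[sub]
  rms <- if (any(dom)) sqrt(mean(rowSums(resid[dom, , drop = FALSE]^2))) else 0
  thresh <- 0.25 * min(grid$spacing)
  if (rms >= thresh) {
    warning("invert_dvf: composition residual RMS ", signif(rms, 3),
            " mm exceeds ", signif(thresh, 3), " mm after ", iters, " iterations")
  }
  inv <- array(0, c(d, 3L))
  lin <- (sub[, 3] - 1L) * (d[1] * d[2]) + (sub[, 2] - 1L) * d[1] + sub[, 1]
  n3 <- prod(d)
  for (c_ in 1:3) inv[lin + (c_ - 1L) * n3] <- uinv[, c_]
  field$inverse <- structure(inv, residual_rms = rms)
  field
}

#' Warp a volume with a displacement field
#'
#' Pull-back resampling: the warped volume at voxel `x` takes the value of the
#' input at `x - u(x)`, so structures move by `+u`. Use linear interpolation
#' for HU/dose and nearest for masks. The field is zero outside the
#' deformation domain, so voxels there keep their reference values.
#'
#' @param volume 3D array (numeric or logical).
#' @param field A `bh_dvf` (uses `field$vectors`; pass `inverse = TRUE` to
#'   warp with the populated inverse field instead).
#' @param mode `"linear"` or `"nearest"`.
#' @param inverse Warp with the inverse field (requires [invert_dvf()]).
#' @return Warped 3D array (numeric).
#' @export
warp_image <- function(volume, field, mode = c("linear", "nearest"),
                       inverse = FALSE) {
  mode <- match.arg(mode)
  vec <- if (inverse) {
    if (is.null(field$inverse)) stop("warp_image: inverse field not populated")
    field$inverse
  } else field$vectors
  grid <- field$grid
  pts <- world_to_index(grid, grid_points(grid))
  u <- cbind(as.vector(vec[, , , 1]), as.vector(vec[, , , 2]), as.vector(vec[, , , 3]))
  q <- pts - sweep(u, 2, grid$spacing, "/")
  array(interp_volume(volume + 0, q, mode), grid$shape)
}

#' Accumulate a dose computed on deformed anatomy onto the reference geometry
#'
#' Resamples a dose grid computed on the deformed image back to the reference
#' geometry using the inverse displacement field (linear interpolation), so
#' doses from different breath-hold geometries can be summed voxel-wise.
#'
#' @param dose 3D dose array on the deformed geometry (Gy).
#' @param field A `bh_dvf` with the inverse populated.
#' @return 3D dose array on the reference geometry.
#' @export
accumulate_dose_on_reference <- function(dose, field) {
  if (is.null(field$inverse)) {
    stop("accumulate_dose_on_reference: inverse field missing; call invert_dvf() first")
  }
  warp_image(dose, field, mode = "linear", inverse = TRUE)
}

# Deformed positions of reference points: x(p) = p - u_inv(p) in world mm.
# Reference voxel p receives the dose delivered at x(p) on the deformed image.
deformed_positions <- function(field, pts_mm) {
  idx <- world_to_index(field$grid, pts_mm)
  uinv <- cbind(interp_volume(field$inverse[, , , 1], idx, "linear"),
                interp_volume(field$inverse[, , , 2], idx, "linear"),
                interp_volume(field$inverse[, , , 3], idx, "linear"))
  pts_mm - uinv
}
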