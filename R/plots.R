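#' Plot an axial phantom slice
#'
#' HU raster of the axial slice through a given CC position (default: the
#' tumor centre) with structure outlines.
#'
#' @param phantom A `bh_phantom`.
#' @param z_mm CC world coordinate of the slice (default tumor centre).
#' @param structures Structure names to outline.
#' @return A ggplot object.
#' @export
plot_phantom_slice <- function(phantom, z_mm = NULL,
                               structures = c("CTV", "lung_ipsi", "lung_contra",
                                              "heart", "spinal_cord")) {
  grid <- phantom$grid
  if (is.null(z_mm)) z_mm <- phantom$meta$tumor_center_mm[3]
  k <- round((z_mm - grid$origin[3]) / grid$spacing[3]) + 1
  k <- min(max(k, 1), grid$shape[3])
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  df <- tidyr::expand_grid(y = ys, x = xs)
  df$hu <- as.vector(phantom$hu[, , k])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hu)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "LR [mm]", y = "AP [mm]", fill = "HU",
                  title = paste0("Axial slice, CC = ", round(z_mm), " mm"))
  for (nm in intersect(structures, names(phantom$structures))) {
    m <- phantom$structures[[nm]][, , k]
    if (!any(m)) next
    dc <- df
    dc$v <- as.vector(m + 0)
    p <- p + ggplot2::geom_contour(
      data = dc, ggplot2::aes(z = .data$v), breaks = 0.5,
      colour = "red", linewidth = 0.3)
  }
  p
}

#' @export
autoplot.bh_phantom <- function(object, ...) plot_phantom_slice(object, ...)

#' Plot the distribution of a DVH metric over simulated treatments
#'
#' Histogram of a per-treatment metric with its median and p90% marked.
#'
#' @param object A `bh_eval`.
#' @param structure,metric Metric to plot (default CTV D50%).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bh_eval <- function(object, structure = "CTV", metric = "D50%", ...) {
  df <- dplyr::filter(object$samples, .data$structure == !!structure,
                      .data$metric == !!metric)
  sm <- dplyr::filter(object$summary, .data$structure == !!structure,
                      .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey30") +
    ggplot2::geom_vline(xintercept = sm$med, linetype = 1) +
    ggplot2::geom_vline(xintercept = sm$p90, linetype = 2, colour = "red") +
    ggplot2::labs(x = paste(structure, metric),
                  y = "simulated treatments",
                  title = paste0(object$plan_name, ", set ", object$eval_set,
                                 " (dashed: p90%)"))
}

#' DVH band of sampled treatments against the nominal curve
#'
#' Nominal DVH curve of one structure with a band spanning the
#' per-treatment DVH curves of a set of accumulated dose vectors.
#'
#' @param nominal_dose Dose vector of the nominal scenario for the structure.
#' @param sampled_doses List of dose vectors (one per simulated treatment)
#'   for the same structure.
#' @param structure Label for the plot.
#' @return A ggplot object.
#' @export
plot_dvh_band <- function(nominal_dose, sampled_doses, structure = "CTV") {
  nom <- dvh_curve(nominal_dose)
  curves <- lapply(sampled_doses, dvh_curve)
  lv <- nom$dose_gy
  at <- function(cu) stats::approx(cu$dose_gy, cu$volume_fraction, xout = lv,
                                   yleft = 1, yright = 0)$y
  m <- vapply(curves, at, numeric(length(lv)))
  band <- tibble::tibble(dose_gy = lv,
                         lo = apply(m, 1, min), hi = apply(m, 1, max))
  ggplot2::ggplot(band, ggplot2::aes(.data$dose_gy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(data = nom,
                       ggplot2::aes(y = .data$volume_fraction)) +
    ggplot2::labs(x = "dose [Gy]", y = "volume fraction",
                  title = paste(structure, "DVH: nominal and sampled range"))
}

#' Compare p90% CTV D50% across plans
#'
#' Dot plot of the p90% (and median) CTV D50% per plan and evaluation set
#' from an experiment's summary table.
#'
#' @param experiment A `bh_experiment` (not a dry run).
#' @return A ggplot object.
#' @export
plot_p90_comparison <- function(experiment) {
  df <- experiment$summaries |>
    dplyr::filter(.data$structure == "CTV", .data$metric == "D50%")
  ggplot2::ggplot(df, ggplot2::aes(.data$plan, .data$p90,
                                   colour = .data$eval_set)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$med), shape = 1, size = 3) +
    ggplot2::geom_hline(yintercept = 54, linetype = 3) +
    ggplot2::labs(x = NULL, y = "CTV D50% [Gy]",
                  title = "p90% (filled) and median (open) CTV D50%",
                  colour = "set") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
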