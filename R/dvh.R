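# Cumulative dose-volume histograms and the derived point metrics used in
# plan evaluation: D_x% (minimum dose to the hottest x% of a structure) and
# V_p% (absolute volume receiving at least p% of a reference dose).

#' Cumulative DVH of one or more structures
#'
#' @param dose a `dose_grid`.
#' @param ss the `structure_set` the dose was computed on.
#' @param structures character vector of structure names; an element may
#'   also be given as `"A-B"` for the set difference (e.g. `"PTV-Boost"`).
#' @param n_bins number of dose bins.
#' @return a `dvh` tibble with columns structure, dose_Gy, volume_cm3,
#'   volume_fraction; the per-structure voxel dose samples are kept in the
#'   `voxel_doses` attribute for exact metric lookups.
#' @export
compute_dvh <- function(dose, ss, structures = structure_names(ss),
                        n_bins = 256) {
  vox_cm3 <- dose$resolution^2 * dose$slice_thickness / 1000
  dmax <- max(dose$dose) * 1.0001
  bins <- seq(0, max(dmax, 1e-6), length.out = n_bins)
  voxel_doses <- list()
  rows <- purrr::map_dfr(structures, function(nm) {
    m <- structure_mask(ss, parse_structure_expr(nm), dose)
    d <- dose$dose[m]
    if (length(d) == 0) stop("structure has no voxels on the dose grid: ", nm)
    voxel_doses[[nm]] <<- d
    at_least <- vapply(bins, function(b) sum(d >= b), numeric(1))
    tibble::tibble(structure = nm, dose_Gy = bins,
                   volume_cm3 = at_least * vox_cm3,
                   volume_fraction = at_least / length(d))
  })
  tibble::new_tibble(rows, voxel_doses = voxel_doses, voxel_cm3 = vox_cm3,
                     class = "dvh")
}

parse_structure_expr <- function(nm) {
  if (grepl("-", nm, fixed = TRUE)) strsplit(nm, "-", fixed = TRUE)[[1]] else nm
}

#' DVH point metrics
#'
#' `D_x%` is the minimum dose received by the hottest x% of the structure
#' volume, read off the inverse cumulative curve with linear interpolation
#' (on the voxel dose samples when available, equivalent to a type-7
#' quantile at probability 1 - x/100). `V_p%` is the absolute volume in cm^3
#' receiving at least p% of `reference_dose`. `D_mean` is the voxel average.
#'
#' @param dvh a `dvh` from [compute_dvh()].
#' @param structure structure name as used in the DVH.
#' @param d_pct percentages x for D_x% (each in (0, 100]).
#' @param v_pct percentages p for V_p% (each in (0, 100]).
#' @param reference_dose reference for the V_p% isodose levels (Gy).
#' @return tibble with columns metric, value (D in Gy, V in cm^3).
#' @export
dvh_metrics <- function(dvh, structure, d_pct = c(99, 95, 1),
                        v_pct = numeric(0), reference_dose = 76.2) {
  if (any(c(d_pct, v_pct) <= 0) || any(c(d_pct, v_pct) > 100))
    stop("percentages must lie in (0, 100]")
  d <- attr(dvh, "voxel_doses")[[structure]]
  if (is.null(d)) {
    cur <- dvh[dvh$structure == structure, ]
    if (nrow(cur) == 0) stop("structure not in DVH: ", structure)
    d_of <- function(x) stats::approx(cur$volume_fraction, cur$dose_Gy,
                                      xout = x / 100, ties = "ordered")$y
    dx <- vapply(d_pct, d_of, numeric(1))
    vol <- max(cur$volume_cm3)
    vp <- vapply(v_pct, function(p) stats::approx(
      cur$dose_Gy, cur$volume_cm3, xout = p / 100 * reference_dose,
      yleft = vol, yright = 0)$y, numeric(1))
    dmean <- -sum(diff(cur$volume_fraction) *
                    (cur$dose_Gy[-1] + cur$dose_Gy[-nrow(cur)]) / 2)
  } else {
    dx <- vapply(d_pct, function(x)
      unname(stats::quantile(d, probs = 1 - x / 100, type = 7)), numeric(1))
    vox <- attr(dvh, "voxel_cm3")
    vp <- vapply(v_pct, function(p)
      sum(d >= p / 100 * reference_dose) * vox, numeric(1))
    dmean <- mean(d)
  }
  tibble::tibble(
    metric = c("D_mean",
               if (length(d_pct)) paste0("D_", d_pct, "%"),
               if (length(v_pct)) paste0("V_", v_pct, "%")),
    value = c(dmean, dx, vp))
}

#' Plot cumulative DVHs
#' @param object a `dvh`.
#' @param ... unused.
#' @method autoplot dvh
#' @export
autoplot.dvh <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$dose_Gy, 100 * .data$volume_fraction,
                               colour = .data$structure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose [Gy]", y = "Volume [%]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Export a DVH to CSV (columns structure, dose_Gy, volume_cm3,
#' volume_fraction)
#' @param dvh a `dvh`.
#' @param path output file.
#' @export
write_dvh_csv <- function(dvh, path) {
  utils::write.csv(tibble::as_tibble(dvh), path, row.names = FALSE)
  invisible(path)
}
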