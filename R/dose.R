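# Idealized exposure-fraction dose engine: unit primary fluence, no
# attenuation or scatter. A voxel receives a segment's monitor units
# whenever its parallel BEV projection at that segment's gantry angle lies
# inside the open leaf interval of the covering leaf pair; dose is the
# calibrated sum over segments. This is the discrete counterpart of the
# continuous blocked-rotation model in radial_dose_closed_form(), which it
# approaches as the number of beams grows.

#' Compute dose for a plan on a structure set
#'
#' @param plan an `rt_plan` (see [rt_plan()]).
#' @param ss a `structure_set`.
#' @param resolution dose-grid sampling step in-plane (mm).
#' @param calibration Gy per (MU x exposure). `NULL` calibrates the plan so
#'   the mean dose in `calibrate_to` equals its prescription; pass a number
#'   to reuse a calibration across plans (MU-preserving comparisons must
#'   share one calibration).
#' @param calibrate_to structure used for auto-calibration; default the
#'   highest-prescription target present.
#' @return a `dose_grid`: list with the dose array (Gy), grid coordinate
#'   vectors (mm), the calibration factor and the grid resolution.
#' @export
compute_dose <- function(plan, ss, resolution = 2, calibration = NULL,
                         calibrate_to = NULL) {
  beams <- attr(plan, "beams")
  bad <- setdiff(unique(plan$angle_deg), beams)
  if (length(bad) > 0)
    stop("segment at angle(s) not in the beam set: ", paste(bad, collapse = ", "))
  grid <- dose_sampling_grid(ss, resolution)
  iso <- plan_isocenter(plan, ss)
  w <- attr(plan, "mlc")$leaf_width_mm
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  xy <- expand.grid(x = grid$x, y = grid$y)
  dose <- array(0, c(nx, ny, nz))
  pair_of_slice <- pair_of_z(grid$z, iso[3], w)
  for (ang in unique(plan$angle_deg)) {
    p <- bev_axis_p(xy$x, xy$y, ang, iso)
    segs <- which(plan$angle_deg == ang)
    for (si in segs) {
      lv <- plan$leaves[[si]]
      mu <- plan$mu[si]
      if (is.null(lv) || nrow(lv) == 0 || mu == 0) next
      for (k in seq_len(nrow(lv))) {
        sl <- which(pair_of_slice == lv[k, "pair"])
        if (length(sl) == 0) next
        inside <- (p > lv[k, "lo"]) & (p < lv[k, "hi"])
        add <- mu * inside
        for (s in sl) dose[, , s] <- dose[, , s] + add
      }
    }
  }
  if (is.null(calibration)) {
    presc <- attr(plan, "prescription")
    if (is.null(calibrate_to)) {
      present <- intersect(names(presc), structure_names(ss))
      calibrate_to <- present[which.max(presc[present])]
    }
    m <- structure_mask(ss, calibrate_to, grid)
    mean_raw <- mean(dose[m])
    if (!is.finite(mean_raw) || mean_raw <= 0)
      stop("cannot calibrate: no dose in ", calibrate_to)
    calibration <- unname(presc[calibrate_to] / mean_raw)
  }
  structure(list(dose = dose * calibration, x = grid$x, y = grid$y, z = grid$z,
                 resolution = resolution, calibration = calibration,
                 slice_thickness = slice_thickness(ss)),
            class = "dose_grid")
}

plan_isocenter <- function(plan, ss) {
  iso <- attr(plan, "isocenter")
  if (is.null(iso)) iso <- isocenter(ss)
  iso
}

dose_sampling_grid <- function(ss, resolution) {
  ref <- if ("body" %in% structure_names(ss)) "body" else structure_names(ss)[1]
  bb <- apply(do.call(rbind, ss$poly[ss$structure == ref]), 2, range)
  list(x = seq(bb[1, 1], bb[2, 1], by = resolution),
       y = seq(bb[1, 2], bb[2, 2], by = resolution),
       z = sort(unique(ss$z)))
}

#' Voxel membership mask of a structure on a dose grid
#'
#' Membership is decided by even-odd point-in-polygon tests at voxel
#' centres, slice by slice.
#'
#' @param ss a `structure_set`.
#' @param structure structure name, or a character vector of two names
#'   `c(a, b)` meaning the set difference a minus b (e.g. PTV minus Boost).
#' @param grid a `dose_grid` or the list returned by the internal sampling
#'   grid constructor.
#' @return logical array with the grid's dimensions.
#' @export
structure_mask <- function(ss, structure, grid) {
  if (length(structure) == 2)
    return(structure_mask(ss, structure[1], grid) &
             !structure_mask(ss, structure[2], grid))
  pts <- as.matrix(expand.grid(x = grid$x, y = grid$y))
  m <- array(FALSE, c(length(grid$x), length(grid$y), length(grid$z)))
  for (s in seq_along(grid$z)) {
    rings <- slice_rings(ss, structure, grid$z[s])
    if (length(rings) == 0) next
    m[, , s] <- points_in_rings(rings, pts)
  }
  m
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels at %g mm, max %.2f Gy, calibration %.4g Gy/MU\n",
              length(x$x), length(x$y), length(x$z), x$resolution,
              max(x$dose), x$calibration))
  invisible(x)
}

#' Turn a dose grid into a tibble of voxels
#' @param x a `dose_grid`.
#' @param ... unused.
#' @method as_tibble dose_grid
#' @export
as_tibble.dose_grid <- function(x, ...) {
  g <- expand.grid(x = x$x, y = x$y, z = x$z)
  tibble::tibble(x = g$x, y = g$y, z = g$z, dose_Gy = as.vector(x$dose))
}

#' Closed-form radial dose of blocked rotations (concentric geometry)
#'
#' Continuous-rotation model on concentric circles, normalized radius
#' rho = r / R_PTV. The OAR-blocking rotation (S1 aperture open outside the
#' central block of half-width rho_oar) delivers
#' `D_S1(rho) = 1 - (2/pi) asin(min(1, rho_oar / rho))`; a strip rotation
#' open on `rho_oar <= |x| <= rho_oar + beta` delivers
#' `D_S2(rho) = (2/pi) (asin(min(1, (rho_oar + beta)/rho)) - asin(min(1, rho_oar/rho)))`.
#' The composite two-step dose is `D_S1 + omega * D_S2`.
#'
#' @param rho normalized radius (vectorized), 0 < rho <= 1. At rho = 0 with
#'   a block present the point is fully shadowed and D_S1 = 0.
#' @param rho_oar normalized OAR radius, `0 <= rho_oar < 1`.
#' @param beta normalized strip width (needed for S2 / total).
#' @param component `"S1"`, `"S2"` or `"total"`.
#' @param omega relative weight of the strip rotation (total only).
#' @return dimensionless dose (unit = dose of an unblocked rotation).
#' @export
radial_dose_closed_form <- function(rho, rho_oar, beta = NULL,
                                    component = c("S1", "S2", "total"),
                                    omega = 1) {
  component <- match.arg(component)
  stopifnot(rho_oar >= 0, rho_oar < 1, all(rho >= 0))
  s1 <- ifelse(rho <= 0, ifelse(rho_oar > 0, 0, 1),
               1 - (2 / pi) * asin(pmin(1, rho_oar / rho)))
  if (component == "S1") return(s1)
  stopifnot(!is.null(beta), beta >= 0)
  s2 <- ifelse(rho <= 0, 0,
               (2 / pi) * (asin(pmin(1, (rho_oar + beta) / rho)) -
                             asin(pmin(1, rho_oar / rho))))
  if (component == "S2") return(s2)
  s1 + omega * s2
}
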