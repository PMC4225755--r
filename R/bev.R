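# Beam's-eye-view projection. The gantry rotates coplanar in the axial
# plane; projection is parallel. Convention: at gantry angle 0 the BEV
# x-axis coincides with the patient x-axis, and the projected coordinate at
# angle theta is p = (x - iso_x) cos(theta) + (y - iso_y) sin(theta), in mm
# at the isocenter plane. MLC leaf pairs run along the patient z axis: pair
# i spans z in [iso_z + (i - 1/2) w, iso_z + (i + 1/2) w) with leaf width w,
# so pair 0 is centred on the isocenter.

#' MLC specification
#'
#' @param leaf_width_mm leaf width at the isocenter plane (mm).
#' @param field_half_mm maximum half-opening of a leaf pair (mm).
#' @export
mlc_spec <- function(leaf_width_mm = 4, field_half_mm = 200) {
  stopifnot(leaf_width_mm > 0, field_half_mm > 0)
  structure(list(leaf_width_mm = leaf_width_mm, field_half_mm = field_half_mm),
            class = "mlc_spec")
}

# leaf pair index covering height z (relative to isocenter z)
pair_of_z <- function(z, iso_z, w) as.integer(floor((z - iso_z) / w + 0.5))

# z range [lo, hi) of a pair
pair_z_range <- function(pair, iso_z, w) c(iso_z + (pair - 0.5) * w,
                                           iso_z + (pair + 0.5) * w)

bev_axis_p <- function(x, y, gantry_deg, iso) {
  th <- gantry_deg * pi / 180
  (x - iso[1]) * cos(th) + (y - iso[2]) * sin(th)
}

# merge a two-column matrix of [lo, hi] intervals
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2] + 1e-9) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else out <- rbind(out, iv[i, ])
  }
  out
}

# projected intervals of one structure on one slice: one interval per outer
# ring (holes are invisible in silhouette), merged
slice_projection <- function(ss, structure, z, gantry_deg) {
  rings <- slice_rings(ss, structure, z)
  if (length(rings) == 0) return(NULL)
  depth <- ring_depths(rings)
  iso <- isocenter(ss)
  iv <- do.call(rbind, lapply(rings[depth %% 2 == 0], function(r) {
    p <- bev_axis_p(r[, 1], r[, 2], gantry_deg, iso)
    c(min(p), max(p))
  }))
  merge_intervals(iv)
}

#' Project a structure set into the beam's eye view
#'
#' For every MLC leaf pair intersecting the slice grid, the projected
#' interval(s) of every structure on the BEV x-axis: the union over the
#' slices the pair spans, sorted and non-overlapping.
#'
#' @param ss a `structure_set`.
#' @param gantry_deg gantry angle (degrees).
#' @param mlc an [mlc_spec()].
#' @return a `bev_projection` tibble with columns structure, pair, x_lo,
#'   x_hi; attributes carry the gantry angle, the MLC spec and the pair
#'   z-spans.
#' @export
project_to_bev <- function(ss, gantry_deg, mlc = mlc_spec()) {
  iso <- isocenter(ss)
  w <- mlc$leaf_width_mm
  zs <- sort(unique(ss$z))
  pair_of_slice <- pair_of_z(zs, iso[3], w)
  pairs <- sort(unique(pair_of_slice))
  rows <- purrr::map_dfr(structure_names(ss), function(nm) {
    purrr::map_dfr(pairs, function(pr) {
      ivs <- do.call(rbind, lapply(zs[pair_of_slice == pr], function(z)
        slice_projection(ss, nm, z, gantry_deg)))
      if (is.null(ivs)) return(NULL)
      ivs <- merge_intervals(ivs)
      tibble::tibble(structure = nm, pair = pr,
                     x_lo = ivs[, 1], x_hi = ivs[, 2])
    })
  })
  pair_spans <- tibble::tibble(
    pair = pairs,
    z_lo = vapply(pairs, function(p) pair_z_range(p, iso[3], w)[1], numeric(1)),
    z_hi = vapply(pairs, function(p) pair_z_range(p, iso[3], w)[2], numeric(1)))
  tibble::new_tibble(rows, gantry_deg = gantry_deg, mlc = mlc,
                     isocenter = iso, pair_spans = pair_spans,
                     class = "bev_projection")
}

# outer hull interval [lo, hi] of a structure's projection on one pair
bev_hull <- function(bev, structure, pair) {
  sel <- bev$structure == structure & bev$pair == pair
  if (!any(sel)) return(NULL)
  c(min(bev$x_lo[sel]), max(bev$x_hi[sel]))
}

# pair index range covered by a structure in a BEV projection
bev_extent <- function(bev, structure) {
  prs <- bev$pair[bev$structure == structure]
  if (length(prs) == 0) return(NULL)
  range(prs)
}

#' Measure normalized geometry for a leaf pair
#'
#' In the CT layer(s) a leaf pair spans, the target half-width R_PTV and the
#' OAR half-width R_OAR are read off the BEV projection, and the OAR-target
#' gap g is the signed edge-to-edge distance between the OAR boundary and
#' the target (inner) boundary in the slice plane. Values from several
#' slices under one pair are averaged. Returned are the normalized OAR
#' radius rho_oar = R_OAR / R_PTV and normalized gap gamma = g / R_PTV.
#'
#' A pair with no OAR in view reports rho_oar = 0 and gamma NA with
#' `flagged = TRUE`; a negative gamma means the OAR bulges into the target
#' and is likewise flagged.
#'
#' @param ss a `structure_set`.
#' @param gantry_deg gantry angle (degrees).
#' @param pair leaf pair index (0 = centred on isocenter).
#' @param mlc an [mlc_spec()].
#' @param target,oar structure names.
#' @return one-row tibble: pair, rho_oar, gamma, r_ptv, gap_mm, flagged.
#' @export
measure_normalized_geometry <- function(ss, gantry_deg, pair, mlc = mlc_spec(),
                                        target = "PTV", oar = "OAR") {
  iso <- isocenter(ss)
  zr <- pair_z_range(pair, iso[3], mlc$leaf_width_mm)
  zs <- sort(unique(ss$z))
  zs <- zs[zs >= zr[1] - 1e-9 & zs < zr[2] - 1e-9]
  per_slice <- purrr::map_dfr(zs, function(z) {
    ti <- slice_projection(ss, target, z, gantry_deg)
    if (is.null(ti)) return(NULL)
    r_ptv <- (max(ti[, 2]) - min(ti[, 1])) / 2
    oi <- slice_projection(ss, oar, z, gantry_deg)
    if (is.null(oi)) {
      return(tibble::tibble(r_ptv = r_ptv, r_oar = 0, gap = NA_real_))
    }
    r_oar <- (max(oi[, 2]) - min(oi[, 1])) / 2
    gap <- boundary_gap(slice_rings(ss, oar, z), slice_rings(ss, target, z))
    tibble::tibble(r_ptv = r_ptv, r_oar = r_oar, gap = gap)
  })
  if (nrow(per_slice) == 0)
    stop("leaf pair ", pair, " does not intersect the target projection")
  r_ptv <- mean(per_slice$r_ptv)
  r_oar <- mean(per_slice$r_oar)
  gap <- if (all(is.na(per_slice$gap))) NA_real_ else
    mean(per_slice$gap, na.rm = TRUE)
  rho <- r_oar / r_ptv
  gamma <- if (rho == 0) NA_real_ else gap / r_ptv
  tibble::tibble(pair = pair, rho_oar = rho, gamma = gamma, r_ptv = r_ptv,
                 gap_mm = gap,
                 flagged = rho == 0 || (!is.na(gamma) && gamma < 0))
}

#' Normalized geometry for every leaf pair covering a target
#'
#' @inheritParams measure_normalized_geometry
#' @return tibble with one row per leaf pair intersecting the target.
#' @export
pairwise_geometry <- function(ss, gantry_deg, mlc = mlc_spec(),
                              target = "PTV", oar = "OAR") {
  bev <- project_to_bev(ss, gantry_deg, mlc)
  prs <- sort(unique(bev$pair[bev$structure == target]))
  purrr::map_dfr(prs, function(p)
    measure_normalized_geometry(ss, gantry_deg, p, mlc, target, oar))
}
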