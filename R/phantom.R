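# Horseshoe phantom generator: a nearly enclosed ring target around a central
# cylindrical organ at risk inside an elliptical body, the classic benchmark
# geometry for coplanar IMRT. The paired-geometry generator produces a
# planning geometry (CT1) and a geometry of the day (CT2) in which the OAR
# radius shrinks and the target inner edge follows it inwards while the
# target-OAR gap stays constant.

#' Specification of the horseshoe phantom
#'
#' Dimensions are configurable because no canonical print of the benchmark
#' phantom's sizes is used here; the defaults give a normalized OAR radius
#' rho_OAR = 24/60 = 0.4 and normalized gap gamma = 6/60 = 0.1.
#'
#' @param body_half_axes ellipse half-axes of the body outline (mm).
#' @param r_ptv outer radius of the ring target (mm).
#' @param r_oar radius of the central OAR cylinder (mm).
#' @param gap edge-to-edge gap between OAR and target inner edge (mm).
#' @param opening_deg angular opening of the horseshoe (degrees).
#' @param n_slices number of axial slices.
#' @param slice_thickness slice thickness (mm).
#' @param resolution in-plane resolution (mm).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(body_half_axes = c(150, 100), r_ptv = 60, r_oar = 24,
                         gap = 6, opening_deg = 60, n_slices = 8,
                         slice_thickness = 2.5, resolution = 1) {
  spec <- list(body_half_axes = body_half_axes, r_ptv = r_ptv, r_oar = r_oar,
               gap = gap, opening_deg = opening_deg, n_slices = n_slices,
               slice_thickness = slice_thickness, resolution = resolution)
  if (any(unlist(spec[1:4]) <= 0)) stop("phantom_spec: all lengths must be > 0")
  if (r_oar + gap >= r_ptv)
    stop("phantom_spec: r_oar + gap must be smaller than r_ptv")
  if (n_slices < 1 || slice_thickness <= 0)
    stop("phantom_spec: invalid slice grid")
  if (opening_deg < 0 || opening_deg >= 180)
    stop("phantom_spec: opening_deg must be in [0, 180)")
  class(spec) <- "phantom_spec"
  spec
}

phantom_geometry <- function(spec, r_oar) {
  zs <- (seq_len(spec$n_slices) - (spec$n_slices + 1) / 2) * spec$slice_thickness
  rows <- purrr::map_dfr(zs, function(z) tibble::tibble(
    structure = c("body", "OAR", "PTV"),
    z = z,
    poly = list(
      ellipse_poly(0, 0, spec$body_half_axes[1], spec$body_half_axes[2], n = 180),
      circle_poly(0, 0, r_oar, n = 120),
      horseshoe_poly(0, 0, r_oar + spec$gap, spec$r_ptv,
                     opening_deg = spec$opening_deg, n = 180)
    )
  ))
  structure_set(rows, spec$slice_thickness, spec$resolution,
                isocenter = c(0, 0, 0), validate = FALSE)
}

#' Generate a paired horseshoe-phantom geometry (CT1, CT2)
#'
#' CT2 differs from CT1 only in the OAR radius, reduced by
#' `delta_rho * r_ptv`; the target inner edge follows inwards so the
#' OAR-target gap is identical in both geometries and the target ring of CT2
#' strictly contains that of CT1. Isocenters coincide, so the relocation
#' shift between the two geometries is zero by construction.
#'
#' @param spec a [phantom_spec()].
#' @param delta_rho difference of normalized OAR radii between CT1 and CT2
#'   (dimensionless, `0 <= delta_rho < r_oar/r_ptv`); interfractional changes
#'   of the order of 0.05 are the regime the adaptation is designed for.
#' @return list with elements `ct1` and `ct2`, both `structure_set`s.
#' @export
generate_quasimodo <- function(spec = phantom_spec(), delta_rho = 0.05) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  rho1 <- spec$r_oar / spec$r_ptv
  if (delta_rho < 0 || delta_rho >= rho1)
    stop("delta_rho must satisfy 0 <= delta_rho < r_oar/r_ptv = ", round(rho1, 3))
  r_oar2 <- spec$r_oar - delta_rho * spec$r_ptv
  if (r_oar2 <= 0) stop("delta_rho leaves no OAR")
  list(ct1 = phantom_geometry(spec, spec$r_oar),
       ct2 = phantom_geometry(spec, r_oar2))
}
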