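# Synthetic deformable prostate cases. A planning geometry (CT1) holds a
# roughly spherical CTV (prostate plus base of the seminal vesicles) anterior
# to a tubular rectum inside an elliptical body. The geometry of the day
# (CT2) applies a parameterized deformation: the prostate is pushed
# posteriorly/inferiorly, the high-dose Boost shrinks by a prescribed volume
# fraction, and the rectum caliber changes with filling. Margins follow the
# clinical protocol: CTV + 10 mm (7 mm posterior) = PTV; CTV + 5 mm = Boost,
# overlap with the rectum not allowed.

#' Deformation parameters for the synthetic prostate generator
#'
#' @param shift_mm rigid displacement of the CTV from CT1 to CT2 (x, y, z in
#'   mm; negative y = posterior, e.g. the prostate pushed towards the rectum
#'   by increased bladder filling).
#' @param boost_shrink fractional volume loss of the Boost from CT1 to CT2
#'   (0.05 is a typical interfractional change; 0.25 is the hard regime at
#'   the limits of MU-preserving adaptation).
#' @param rectum_radius_delta_mm change of the rectum tube radius (mm).
#' @return a `prostate_deformation` list.
#' @export
prostate_deformation <- function(shift_mm = c(0, 0, 0), boost_shrink = 0,
                                 rectum_radius_delta_mm = 0) {
  stopifnot(length(shift_mm) == 3, boost_shrink >= 0, boost_shrink < 0.6)
  structure(list(shift_mm = as.numeric(shift_mm), boost_shrink = boost_shrink,
                 rectum_radius_delta_mm = rectum_radius_delta_mm),
            class = "prostate_deformation")
}

#' Preset deformations: small (~5%) and large (~25% Boost shrink) regimes
#' @rdname prostate_deformation
#' @export
small_deformation <- function() prostate_deformation(c(0, -2, 0), 0.05, 1)

#' @rdname prostate_deformation
#' @export
large_deformation <- function() prostate_deformation(c(0, -4, 0), 0.25, 3)

prostate_anatomy <- function(pars, ctv_scale = 1, ctv_shift = c(0, 0, 0),
                             rectum_delta = 0) {
  st <- pars$slice_thickness
  zs <- (seq_len(pars$n_slices) - (pars$n_slices + 1) / 2) * st
  cx <- pars$ctv_center[1] + ctv_shift[1]
  cy <- pars$ctv_center[2] + ctv_shift[2]
  cz <- pars$ctv_center[3] + ctv_shift[3]
  r <- pars$ctv_radius * ctv_scale
  rr <- pars$rectum_radius + rectum_delta
  rows <- purrr::map_dfr(zs, function(z) {
    polys <- list(body = ellipse_poly(0, 0, pars$body_half_axes[1],
                                      pars$body_half_axes[2], n = 150),
                  OAR = circle_poly(pars$rectum_center[1], pars$rectum_center[2],
                                    rr, n = 90))
    rz2 <- r^2 - (z - cz)^2
    if (rz2 > (2)^2) {  # skip sub-2mm caps: too small to contour
      rad <- sqrt(rz2)
      polys$CTV <- ellipse_poly(cx, cy, rad * pars$ctv_ax[1],
                                rad * pars$ctv_ax[2], n = 90)
    }
    tibble::tibble(structure = names(polys), z = z, poly = unname(polys))
  })
  ss <- structure_set(rows, st, pars$resolution, isocenter = pars$ctv_center,
                      validate = FALSE)
  ss <- expand_margin(ss, "CTV", 10, posterior_mm = 7, new_name = "PTV")
  ss <- expand_margin(ss, "CTV", 5, forbidden = "OAR", new_name = "Boost")
  ss
}

#' Generate a synthetic prostate adaptation case (CT1, CT2)
#'
#' Reproducible given `seed`: the base anatomy (CTV radius and ellipticity,
#' rectum radius, centres) is jittered once, then CT1 and CT2 are derived
#' deterministically. The Boost-shrink deformation solves for the CTV scale
#' factor on the discretized geometry, so the requested Boost volume ratio is
#' met on the contours as generated.
#'
#' @param seed integer RNG seed.
#' @param deformation a [prostate_deformation()].
#' @param n_slices,slice_thickness axial slice grid (mm).
#' @return list with `ct1`, `ct2` (structure sets) and `volumes`, a tibble of
#'   per-structure volumes in both geometries with their ratio.
#' @export
generate_prostate_case <- function(seed = 1L,
                                   deformation = prostate_deformation(),
                                   n_slices = 24, slice_thickness = 2.5) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  pars <- list(
    body_half_axes = c(160, 110),
    ctv_center = c(stats::runif(1, -2, 2), stats::runif(1, -1, 1), 0),
    ctv_radius = stats::runif(1, 20, 23),
    ctv_ax = c(1, 1) + stats::runif(2, -0.06, 0.06),
    rectum_center = c(stats::runif(1, -2, 2), stats::runif(1, -38, -34)),
    rectum_radius = stats::runif(1, 10, 12),
    n_slices = n_slices, slice_thickness = slice_thickness, resolution = 1
  )
  ct1 <- prostate_anatomy(pars)

  scale <- 1
  if (deformation$boost_shrink > 0) {
    v1 <- structure_volumes(ct1)
    b1 <- v1$volume_cm3[v1$structure == "Boost"]
    target <- (1 - deformation$boost_shrink) * b1
    # continuous-sphere initial guess, then bisection on discretized volume
    f <- function(s) {
      ss <- prostate_anatomy(pars, ctv_scale = s,
                             ctv_shift = deformation$shift_mm,
                             rectum_delta = deformation$rectum_radius_delta_mm)
      v <- structure_volumes(ss)
      v$volume_cm3[v$structure == "Boost"] - target
    }
    s0 <- ((1 - deformation$boost_shrink)^(1 / 3) * (pars$ctv_radius + 5) - 5) /
      pars$ctv_radius
    scale <- stats::uniroot(f, c(max(0.4, s0 - 0.1), min(1, s0 + 0.1)),
                            tol = 5e-4)$root
  }
  ct2 <- prostate_anatomy(pars, ctv_scale = scale,
                          ctv_shift = deformation$shift_mm,
                          rectum_delta = deformation$rectum_radius_delta_mm)
  validate_structure_set(ct2)
  v1 <- structure_volumes(ct1); v2 <- structure_volumes(ct2)
  vols <- dplyr::inner_join(v1, v2, by = "structure",
                            suffix = c("_ct1", "_ct2"))
  vols$ratio <- vols$volume_cm3_ct2 / vols$volume_cm3_ct1
  list(ct1 = ct1, ct2 = ct2, volumes = vols)
}
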