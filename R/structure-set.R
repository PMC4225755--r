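# Structure sets: per-slice closed polygon contours for the structures of
# interest (CTV, PTV, Boost, OAR/rectum, body) on a common axial slice grid.
# The container is a tibble with one row per contour ring, so the usual dplyr
# verbs apply; grid metadata travels in attributes.

#' Build a structure set
#'
#' @param contours tibble/data.frame with columns `structure` (character),
#'   `z` (slice position, mm) and `poly` (list of n x 2 vertex matrices, mm).
#'   Several rows with the same structure and z are combined with the even-odd
#'   rule, so an inner ring is a hole.
#' @param slice_thickness slice thickness in mm.
#' @param resolution in-plane resolution in mm (used for rasterized margin
#'   operations and as the default dose-sampling hint).
#' @param isocenter numeric length-3 (x, y, z) in mm.
#' @param validate check contour validity (at least 3 vertices, finite
#'   coordinates, no self-intersection, positive area).
#' @return a `structure_set` tibble.
#' @export
structure_set <- function(contours, slice_thickness, resolution = 1,
                          isocenter = c(0, 0, 0), validate = TRUE) {
  contours <- tibble::as_tibble(contours)
  stopifnot(all(c("structure", "z", "poly") %in% names(contours)),
            slice_thickness > 0, resolution > 0, length(isocenter) == 3)
  contours <- dplyr::arrange(contours, .data$structure, .data$z)
  ss <- tibble::new_tibble(contours, slice_thickness = slice_thickness,
                           resolution = resolution,
                           isocenter = as.numeric(isocenter),
                           class = "structure_set")
  if (validate) validate_structure_set(ss)
  ss
}

#' @export
slice_thickness <- function(ss) attr(ss, "slice_thickness")

#' @export
isocenter <- function(ss) attr(ss, "isocenter")

#' Validate a structure set
#'
#' Checks each contour ring: at least 3 vertices, finite coordinates, no
#' self-intersection and non-zero area; checks that all structures sit on a
#' common slice grid (z positions are multiples of the slice thickness apart).
#'
#' @param ss a `structure_set`.
#' @return `ss` invisibly; stops with a message naming the violated invariant.
#' @export
validate_structure_set <- function(ss) {
  st <- slice_thickness(ss)
  for (i in seq_len(nrow(ss))) {
    p <- ss$poly[[i]]
    lab <- sprintf("%s @ z=%g", ss$structure[i], ss$z[i])
    if (!is.matrix(p) || ncol(p) != 2) stop("contour ", lab, ": not an n x 2 matrix")
    if (nrow(p) < 3) stop("contour ", lab, ": fewer than 3 vertices")
    if (!all(is.finite(p))) stop("contour ", lab, ": non-finite vertex")
    if (abs(polygon_area(p)) <= 0) stop("contour ", lab, ": zero enclosed area")
    if (ring_self_intersects(p)) stop("contour ", lab, ": self-intersecting")
  }
  zr <- (ss$z - min(ss$z)) / st
  if (any(abs(zr - round(zr)) > 1e-6))
    stop("slices are not on a common grid with thickness ", st)
  invisible(ss)
}

#' Names of structures present in a set
#' @param ss a `structure_set`.
#' @export
structure_names <- function(ss) unique(ss$structure)

# rings (list of matrices) of one structure on one slice
slice_rings <- function(ss, structure, z, tol = 1e-6) {
  ss$poly[ss$structure == structure & abs(ss$z - z) < tol]
}

# z positions occupied by a structure
structure_zs <- function(ss, structure) sort(unique(ss$z[ss$structure == structure]))

#' Per-slice areas of every structure
#'
#' @param ss a `structure_set`.
#' @return tibble with columns structure, z, area_mm2 (even-odd area).
#' @export
structure_areas <- function(ss) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(ss), .data$structure, .data$z),
                   area_mm2 = rings_area(.data$poly), .groups = "drop")
}

#' Structure volumes
#'
#' Volume is the sum of per-slice areas times the slice thickness.
#'
#' @param ss a `structure_set`.
#' @return tibble with columns structure, volume_cm3.
#' @export
structure_volumes <- function(ss) {
  a <- structure_areas(ss)
  dplyr::summarise(dplyr::group_by(a, .data$structure),
                   volume_cm3 = sum(.data$area_mm2) * slice_thickness(ss) / 1000,
                   .groups = "drop")
}

#' Rigidly translate a structure set
#'
#' The z component is rounded to whole slices so the result stays on the
#' slice grid.
#'
#' @param ss a `structure_set`.
#' @param shift numeric length-3 (mm); applied to contours and isocenter.
#' @export
translate_structure_set <- function(ss, shift) {
  stopifnot(length(shift) == 3)
  st <- slice_thickness(ss)
  dz <- round(shift[3] / st) * st
  out <- tibble::as_tibble(ss)
  out$z <- out$z + dz
  out$poly <- lapply(out$poly, function(p) sweep(p, 2, shift[1:2], "+"))
  structure_set(out, st, attr(ss, "resolution"),
                isocenter(ss) + c(shift[1:2], dz), validate = FALSE)
}

#' Write a structure set to JSON
#'
#' Format: `{meta: {slice_thickness_mm, resolution_mm, isocenter_mm},
#' structures: {name: [{z_mm, points_mm: [[x, y], ...]}, ...]}}`.
#' Writing, reading and re-writing is byte-identical.
#'
#' @param ss a `structure_set`.
#' @param path output file.
#' @export
write_structure_set <- function(ss, path) {
  structures <- lapply(split(tibble::as_tibble(ss), ss$structure), function(df) {
    lapply(seq_len(nrow(df)), function(i)
      list(z_mm = df$z[i], points_mm = unname(df$poly[[i]])))
  })
  obj <- list(
    meta = list(slice_thickness_mm = slice_thickness(ss),
                resolution_mm = attr(ss, "resolution"),
                isocenter_mm = isocenter(ss)),
    structures = structures[order(names(structures))]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a structure set written by [write_structure_set()]
#' @param path JSON file.
#' @export
read_structure_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map_dfr(names(obj$structures), function(nm) {
    tibble::tibble(
      structure = nm,
      z = purrr::map_dbl(obj$structures[[nm]], "z_mm"),
      poly = purrr::map(obj$structures[[nm]], function(ct)
        do.call(rbind, lapply(ct$points_mm, unlist)))
    )
  })
  structure_set(rows, obj$meta$slice_thickness_mm, obj$meta$resolution_mm,
                unlist(obj$meta$isocenter_mm), validate = FALSE)
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d contours, %d structures, %d slices (dz = %g mm)\n",
              nrow(x), length(structure_names(x)), length(unique(x$z)),
              slice_thickness(x)))
  v <- structure_volumes(x)
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %-10s %7.1f cm^3\n", v$structure[i], v$volume_cm3[i]))
  invisible(x)
}
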