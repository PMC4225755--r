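# Margin expansion: per-slice 2D anisotropic dilation at the set's in-plane
# resolution plus cross-slice extension by the margin rounded to whole
# slices, optionally minus a forbidden structure. The dilation runs in
# raster space (shift-OR with a binary kernel) and the result is traced back
# to polygons with grDevices::contourLines at the 0.5 level, so boundary
# placement is accurate to about one in-plane resolution cell.

# anisotropic kernel offsets: circle of radius `margin` for dy >= 0, ellipse
# with posterior (negative y) half-axis `posterior` below
margin_kernel <- function(margin, posterior, res) {
  r <- ceiling(margin / res)
  ij <- expand.grid(di = -r:r, dj = -r:r)
  dx <- ij$di * res; dy <- ij$dj * res
  my <- ifelse(dy < 0, posterior, margin)
  keep <- (dx / margin)^2 + ifelse(my > 0, (dy / my)^2, ifelse(dy == 0, 0, Inf)) <= 1 + 1e-9
  ij[keep, , drop = FALSE]
}

# binary dilation of a logical matrix by kernel offsets (shift-OR)
dilate_mask <- function(mask, kernel) {
  nx <- nrow(mask); ny <- ncol(mask)
  out <- matrix(FALSE, nx, ny)
  for (k in seq_len(nrow(kernel))) {
    di <- kernel$di[k]; dj <- kernel$dj[k]
    xi <- max(1, 1 + di):min(nx, nx + di)
    yj <- max(1, 1 + dj):min(ny, ny + dj)
    out[xi, yj] <- out[xi, yj] | mask[xi - di, yj - dj]
  }
  out
}

rings_to_mask <- function(rings, xs, ys) {
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  matrix(points_in_rings(rings, pts), nrow = length(xs))
}

# trace a padded binary mask back to polygon rings
mask_to_rings <- function(mask, xs, ys) {
  res_x <- xs[2] - xs[1]; res_y <- ys[2] - ys[1]
  xs_p <- c(xs[1] - res_x, xs, xs[length(xs)] + res_x)
  ys_p <- c(ys[1] - res_y, ys, ys[length(ys)] + res_y)
  z <- matrix(0, length(xs_p), length(ys_p))
  z[2:(length(xs) + 1), 2:(length(ys) + 1)] <- mask * 1
  cl <- grDevices::contourLines(xs_p, ys_p, z, levels = 0.5)
  lapply(cl, function(ct) {
    p <- cbind(ct$x, ct$y)
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    p
  })
}

#' Expand a structure by a (possibly anisotropic) safety margin
#'
#' In-plane expansion is a 2D dilation of each slice: isotropic of
#' `margin_mm` except towards posterior (negative y), where `posterior_mm`
#' applies. Across slices the structure is extended by `margin_mm` rounded to
#' whole slices, copying the dilated end slices outward (a tractable stand-in
#' for a full 3D dilation at the native slice thickness). When `forbidden`
#' is given, that structure (grown by one raster cell so boundaries cannot
#' touch) is removed, so the result never overlaps it.
#'
#' @param ss a `structure_set`.
#' @param structure name of the base structure.
#' @param margin_mm isotropic margin (mm, >= 0).
#' @param posterior_mm margin towards negative y (mm); default `margin_mm`.
#' @param forbidden optional name of a structure the result must not overlap.
#' @param new_name name of the resulting structure; replaced if present.
#' @return the structure set with the expanded structure added.
#' @export
expand_margin <- function(ss, structure, margin_mm, posterior_mm = margin_mm,
                          forbidden = NULL, new_name = paste0(structure, "_exp")) {
  stopifnot(margin_mm >= 0, posterior_mm >= 0)
  res <- attr(ss, "resolution")
  st <- slice_thickness(ss)
  base_z <- structure_zs(ss, structure)
  if (length(base_z) == 0) stop("structure not found: ", structure)

  if (margin_mm == 0 && posterior_mm == 0 && is.null(forbidden)) {
    rows <- tibble::as_tibble(ss)[ss$structure == structure, ]
    rows$structure <- new_name
    return(replace_structure(ss, new_name, rows))
  }

  # dilate each occupied slice in raster space over the slice's local window
  kernel <- if (margin_mm > 0) margin_kernel(margin_mm, posterior_mm, res) else NULL
  dilated <- lapply(base_z, function(z) {
    rings <- slice_rings(ss, structure, z)
    bb <- apply(do.call(rbind, rings), 2, range)
    xs <- seq(floor(bb[1, 1] - margin_mm - 2 * res),
              ceiling(bb[2, 1] + margin_mm + 2 * res), by = res)
    ys <- seq(floor(bb[1, 2] - margin_mm - 2 * res),
              ceiling(bb[2, 2] + margin_mm + 2 * res), by = res)
    mask <- rings_to_mask(rings, xs, ys)
    if (!is.null(kernel)) mask <- dilate_mask(mask, kernel)
    list(z = z, xs = xs, ys = ys, mask = mask)
  })

  # cross-slice extension: copy end-slice dilations outward
  n_ext <- round(margin_mm / st)
  all_z <- sort(unique(ss$z))
  slices <- dilated
  if (n_ext > 0) {
    lo <- min(base_z); hi <- max(base_z)
    for (k in seq_len(n_ext)) {
      for (zn in c(lo - k * st, hi + k * st)) {
        if (any(abs(all_z - zn) < 1e-6)) {
          src <- if (zn < lo) dilated[[1]] else dilated[[length(dilated)]]
          slices <- c(slices, list(modifyList(src, list(z = zn))))
        }
      }
    }
  }

  rows <- purrr::map_dfr(slices, function(sl) {
    mask <- sl$mask
    if (!is.null(forbidden)) {
      frings <- slice_rings(ss, forbidden, sl$z)
      if (length(frings) > 0) {
        fmask <- rings_to_mask(frings, sl$xs, sl$ys)
        fmask <- dilate_mask(fmask, expand.grid(di = -1:1, dj = -1:1))
        mask <- mask & !fmask
      }
    }
    if (!any(mask)) {
      message("expand_margin: empty result on slice z = ", sl$z, "; omitted")
      return(NULL)
    }
    rings <- mask_to_rings(mask, sl$xs, sl$ys)
    tibble::tibble(structure = new_name, z = sl$z, poly = rings)
  })
  replace_structure(ss, new_name, rows)
}

replace_structure <- function(ss, name, rows) {
  out <- dplyr::bind_rows(tibble::as_tibble(ss)[ss$structure != name, ], rows)
  structure_set(out, slice_thickness(ss), attr(ss, "resolution"),
                isocenter(ss), validate = FALSE)
}
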