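# Two-step segment generation. From a BEV projection three fluence steps
# are built per gantry angle and target: S0 conformal to the target, S1
# sparing the OAR (the OAR shadow removed from the target opening; an
# interior block yields a left and a right one-sided segment, because one
# MLC leaf pair carries a single open interval), and S2, narrow strips of
# normalized width beta adjacent to the block edges that compensate the
# target underdosage caused by the sparing. The strip width comes from the
# beta* = omega_opt * beta_opt characteristic of the concentric
# blocked-rotation model, evaluated per leaf pair at that pair's measured
# (gamma, rho_oar).

segment_row <- function(angle, type, target, side, leaves, mu = NA_real_) {
  tibble::tibble(angle_deg = angle, step_type = type, target = target,
                 side = side, mu = mu, leaves = list(leaves))
}

leaf_matrix <- function(pair, lo, hi) {
  m <- cbind(pair = pair, lo = lo, hi = hi)
  m[m[, "hi"] > m[, "lo"], , drop = FALSE]
}

#' Generate the target-conformal S0 segment
#'
#' Per leaf pair the aperture is the outer hull of the target's projected
#' interval(s).
#'
#' @param bev a `bev_projection`.
#' @param target target structure name.
#' @return one-row segment tibble (mu unset).
#' @export
generate_s0 <- function(bev, target) {
  prs <- sort(unique(bev$pair[bev$structure == target]))
  if (length(prs) == 0) stop("empty target projection: ", target)
  hull <- t(vapply(prs, function(p) bev_hull(bev, target, p), numeric(2)))
  segment_row(attr(bev, "gantry_deg"), "S0", target, "both",
              leaf_matrix(prs, hull[, 1], hull[, 2]))
}

#' Generate the OAR-sparing S1 segment(s)
#'
#' The OAR's projected interval, grown by `block_margin_mm`, is removed from
#' the target opening of every leaf pair. If the block is interior on any
#' pair, a left and a right one-sided segment are emitted; a pair the OAR
#' does not shadow keeps its full S0 opening, carried by the side with the
#' larger remaining opening (left on ties).
#'
#' @param bev a `bev_projection`.
#' @param target,oar structure names.
#' @param block_margin_mm extra margin around the OAR shadow (mm).
#' @return segment tibble with one or two rows (mu unset).
#' @export
generate_s1 <- function(bev, target, oar, block_margin_mm = 0) {
  prs <- sort(unique(bev$pair[bev$structure == target]))
  if (length(prs) == 0) stop("empty target projection: ", target)
  ang <- attr(bev, "gantry_deg")
  pieces <- purrr::map(prs, function(p) {
    t_iv <- bev_hull(bev, target, p)
    o_iv <- bev_hull(bev, oar, p)
    if (is.null(o_iv))
      return(list(left = NULL, right = NULL, split = FALSE,
                  full = t_iv, pair = p))
    o_iv <- o_iv + c(-1, 1) * block_margin_mm
    left <- c(t_iv[1], min(t_iv[2], o_iv[1]))
    right <- c(max(t_iv[1], o_iv[2]), t_iv[2])
    list(left = if (left[2] > left[1]) left,
         right = if (right[2] > right[1]) right,
         split = TRUE, full = NULL, pair = p)
  })
  any_split <- any(vapply(pieces, function(x) x$split, logical(1)))
  if (!any_split) {
    lv <- leaf_matrix(prs,
                      vapply(pieces, function(x) x$full[1], numeric(1)),
                      vapply(pieces, function(x) x$full[2], numeric(1)))
    return(segment_row(ang, "S1", target, "both", lv))
  }
  side_rows <- function(side) {
    rows <- purrr::map(pieces, function(x) {
      iv <- if (!x$split) {
        # unshadowed pair: the full S0 opening rides with the left segment
        if (side == "left") x$full else NULL
      } else x[[side]]
      if (is.null(iv)) return(NULL)
      cbind(pair = x$pair, lo = iv[1], hi = iv[2])
    })
    do.call(rbind, rows)
  }
  lv_l <- side_rows("left"); lv_r <- side_rows("right")
  out <- NULL
  if (!is.null(lv_l) && nrow(lv_l) > 0)
    out <- dplyr::bind_rows(out, segment_row(ang, "S1", target, "left", lv_l))
  if (!is.null(lv_r) && nrow(lv_r) > 0)
    out <- dplyr::bind_rows(out, segment_row(ang, "S1", target, "right", lv_r))
  out
}

#' Generate the compensating S2 strip segments
#'
#' Per leaf pair, a strip of width `w = beta * R_PTV` is placed inside the
#' target opening against each edge of the OAR block, with
#' `beta = beta*(gamma, rho_oar) / omega`. Pairs without an OAR shadow get
#' no strip. Geometries outside the table domain are clamped to its
#' boundary with a warning.
#'
#' @param bev a `bev_projection`.
#' @param geo per-pair normalized geometry, as from [pairwise_geometry()].
#' @param table a `beta_star_table`.
#' @param target,oar structure names.
#' @param omega relative strip weight used at generation time.
#' @param block_margin_mm must match the S1 block margin.
#' @return segment tibble with zero, one or two rows (mu unset).
#' @export
generate_s2 <- function(bev, geo, table, target, oar, omega = 1,
                        block_margin_mm = 0) {
  prs <- sort(unique(bev$pair[bev$structure == target]))
  ang <- attr(bev, "gantry_deg")
  n_clamped <- 0L
  strips <- purrr::map(prs, function(p) {
    g <- geo[geo$pair == p, ]
    if (nrow(g) == 0 || g$rho_oar == 0) return(NULL)
    t_iv <- bev_hull(bev, target, p)
    o_iv <- bev_hull(bev, oar, p)
    if (is.null(o_iv)) return(NULL)
    o_iv <- o_iv + c(-1, 1) * block_margin_mm
    bstar <- beta_star_eval(table, g$gamma, g$rho_oar, mode = "generation",
                            quiet = TRUE)
    n_clamped <<- n_clamped + sum(attr(bstar, "clamped"))
    beta <- as.numeric(bstar) / omega
    w <- beta * g$r_ptv
    left <- c(max(t_iv[1], o_iv[1] - w), min(o_iv[1], t_iv[2]))
    right <- c(max(o_iv[2], t_iv[1]), min(t_iv[2], o_iv[2] + w))
    list(pair = p,
         left = if (left[2] > left[1]) left,
         right = if (right[2] > right[1]) right)
  })
  if (n_clamped > 0)
    warning(n_clamped, " leaf pair(s) outside the beta* table domain; ",
            "clamped to its boundary")
  out <- NULL
  for (side in c("left", "right")) {
    lv <- do.call(rbind, purrr::map(strips, function(x) {
      if (is.null(x) || is.null(x[[side]])) return(NULL)
      cbind(pair = x$pair, lo = x[[side]][1], hi = x[[side]][2])
    }))
    if (!is.null(lv) && nrow(lv) > 0)
      out <- dplyr::bind_rows(out, segment_row(ang, "S2", target, side, lv))
  }
  out
}

#' Build a full two-step plan for a structure set
#'
#' For every beam angle and every target, the S0, S1 and S2 segments are
#' generated with initial MU weights from `config` (S2 gets omega times the
#' S1 weight). MUs are meant to be refined afterwards by
#' [optimize_weights()].
#'
#' @param ss a `structure_set`.
#' @param table a `beta_star_table`.
#' @param config a [run_config()].
#' @param isocenter optional isocenter override (mm), e.g. a relocated one.
#' @return an `rt_plan`.
#' @export
make_twostep_plan <- function(ss, table, config = run_config(),
                              isocenter = NULL) {
  mlc <- mlc_spec(config$mlc$leaf_width_mm, config$mlc$field_half_mm)
  targets <- intersect(names(config$prescriptions), structure_names(ss))
  if (length(targets) == 0) stop("no prescription target present in the structure set")
  oar <- config$oar
  ss_gen <- ss
  if (!is.null(isocenter)) attr(ss_gen, "isocenter") <- as.numeric(isocenter)
  segs <- purrr::map_dfr(config$beams, function(ang) {
    bev <- project_to_bev(ss_gen, ang, mlc)
    purrr::map_dfr(targets, function(tg) {
      geo <- pairwise_geometry(ss_gen, ang, mlc, target = tg, oar = oar)
      w1 <- config$weights$s1 * config$weights$target[[tg]]
      s0 <- generate_s0(bev, tg)
      s0$mu <- config$weights$s0 * config$weights$target[[tg]]
      s1 <- generate_s1(bev, tg, oar, config$block_margin_mm)
      s1$mu <- w1
      s2 <- generate_s2(bev, geo, table, tg, oar, omega = config$omega,
                        block_margin_mm = config$block_margin_mm)
      if (!is.null(s2) && nrow(s2) > 0) s2$mu <- config$omega * w1
      dplyr::bind_rows(s0, s1, s2)
    })
  })
  rt_plan(segs, beams = config$beams, prescription = config$prescriptions,
          fractions = config$fractions, mlc = mlc,
          isocenter = if (is.null(isocenter)) isocenter(ss) else as.numeric(isocenter))
}
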