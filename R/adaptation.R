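# MU-preserving plan adaptation. On top of the clinical baseline —
# isocenter relocation to the geometry of the day — three steps adapt a
# two-step plan without changing a single monitor unit:
#   1. fresh two-step generation on the geometry of the day at the
#      relocated isocenter, MUs transferred segment-to-segment from the
#      planning geometry by structural key;
#   2. rescaling of every compensation-strip (S2) width by the ratio of
#      the frozen-weight beta* values of the two geometries,
#      beta_CT2 = beta_CT1 * beta*_adapt(gamma2, rho2) / beta*_adapt(gamma1, rho1);
#   3. replay of the recorded fine-tuning leaf shifts, mapped through the
#      change of the target's BEV vertical extent.
# Steps 2 and 3 touch only geometry, and step 1 copies MUs exactly, so the
# adapted total MU equals the planned total by construction.

#' Plan a native two-step treatment on a geometry
#'
#' Runs the full planning chain — two-step generation, MU weight
#' optimization, greedy leaf fine-tuning with shift recording — and
#' bundles everything the adaptation needs.
#'
#' @param ss the planning `structure_set`.
#' @param table a `beta_star_table`.
#' @param config a [run_config()].
#' @return a `native_plan` list: pre (pre-fine-tune plan with optimized
#'   MUs), plan (leaf-fine-tuned), record (leaf shifts), ss, table, config,
#'   calibration.
#' @export
plan_native <- function(ss, table, config = run_config()) {
  objectives <- config$objectives
  pre0 <- make_twostep_plan(ss, table, config)
  pre <- optimize_weights(pre0, ss, objectives,
                          iterations = config$optimizer$iterations,
                          resolution = config$dose_resolution)
  ft <- finetune_leaves(pre, ss, objectives,
                        step_mm = config$optimizer$step_mm,
                        iterations = config$optimizer$leaf_sweeps,
                        resolution = config$dose_resolution,
                        calibration = attr(pre, "calibration"))
  structure(list(pre = pre, plan = ft$plan, record = ft$record, ss = ss,
                 table = table, config = config,
                 calibration = attr(pre, "calibration")),
            class = "native_plan")
}

#' @export
print.native_plan <- function(x, ...) {
  cat("<native_plan>\n  fine-tuned: "); print(x$plan)
  cat(sprintf("  calibration %.4g Gy/MU\n", x$calibration))
  invisible(x)
}

#' Isocenter relocation between two geometries
#'
#' Rigid shift maximizing the summed overlap volume of the target
#' structures, the clinical couch-correction baseline: centroid alignment
#' followed by exhaustive refinement on a 1 mm in-plane grid within
#' +-10 mm (z probed at whole slices — contours only exist at the slice
#' pitch). Ties break towards the smallest shift norm, then
#' lexicographically.
#'
#' @param ct1,ct2 structure sets.
#' @param targets structures whose overlap is maximized.
#' @param search_mm half-width of the exhaustive search window (mm).
#' @return numeric length-3 shift (mm): translate CT1 (and its plan's
#'   isocenter) by this to match CT2.
#' @export
relocate_isocenter <- function(ct1, ct2, targets = c("PTV", "Boost"),
                               search_mm = 10) {
  targets <- intersect(targets, intersect(structure_names(ct1),
                                          structure_names(ct2)))
  if (length(targets) == 0) stop("no common target structure to align")
  st <- slice_thickness(ct1)
  cent <- function(ss) {
    rows <- ss[ss$structure %in% targets, ]
    a <- vapply(rows$poly, function(p) abs(polygon_area(p)), numeric(1))
    cx <- vapply(rows$poly, function(p) mean(p[, 1]), numeric(1))
    cy <- vapply(rows$poly, function(p) mean(p[, 2]), numeric(1))
    c(sum(a * cx), sum(a * cy), sum(a * rows$z)) / sum(a)
  }
  s0 <- cent(ct2) - cent(ct1)
  s0 <- c(round(s0[1:2]), round(s0[3] / st) * st)

  # 1 mm overlap masks over the union bounding box of the targets
  res <- 1
  bb <- apply(do.call(rbind, c(ct1$poly[ct1$structure %in% targets],
                               ct2$poly[ct2$structure %in% targets])), 2, range)
  xs <- seq(floor(bb[1, 1] - search_mm - 2), ceiling(bb[2, 1] + search_mm + 2), by = res)
  ys <- seq(floor(bb[1, 2] - search_mm - 2), ceiling(bb[2, 2] + search_mm + 2), by = res)
  zs <- sort(unique(c(ct1$z, ct2$z)))
  zpad <- ceiling(search_mm / st) + 1
  zs <- sort(unique(c(zs, min(zs) - st * seq_len(zpad), max(zs) + st * seq_len(zpad))))
  grid <- list(x = xs, y = ys, z = zs)
  m_of <- function(ss) Reduce(`|`, lapply(targets, function(tg)
    structure_mask(ss, tg, grid)))
  m2 <- m_of(ct2)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  overlap_of <- function(m1s, dx, dy, dz) {
    xi1 <- max(1, 1 + dx):min(nx, nx + dx)
    yj1 <- max(1, 1 + dy):min(ny, ny + dy)
    zk1 <- max(1, 1 + dz):min(nz, nz + dz)
    sum(m1s[xi1 - dx, yj1 - dy, zk1 - dz] & m2[xi1, yj1, zk1])
  }
  dzs <- seq(-round(search_mm / st), round(search_mm / st))
  cand <- expand.grid(dx = -search_mm:search_mm, dy = -search_mm:search_mm,
                      dz = dzs)
  # shift CT1 by s0 once, then probe residual offsets on the grid
  ct1s <- translate_structure_set(ct1, s0)
  m1s <- m_of(ct1s)
  ov <- vapply(seq_len(nrow(cand)), function(i)
    overlap_of(m1s, cand$dx[i], cand$dy[i], cand$dz[i]), numeric(1))
  shift_mm <- cbind(s0[1] + cand$dx * res, s0[2] + cand$dy * res,
                    s0[3] + cand$dz * st)
  best <- which(ov == max(ov))
  if (length(best) > 1) {
    nrm <- rowSums(shift_mm[best, , drop = FALSE]^2)
    best <- best[nrm == min(nrm)]
    if (length(best) > 1) {
      o <- do.call(order, as.data.frame(shift_mm[best, , drop = FALSE]))
      best <- best[o[1]]
    }
  }
  as.numeric(shift_mm[best, ])
}

# structural key used for MU transfer between geometries
segment_keys <- function(plan) {
  paste(plan$angle_deg, plan$step_type, plan$target, plan$side, sep = "|")
}

#' Regenerate a two-step plan on the geometry of the day and transfer MUs
#'
#' Fresh S0/S1/S2 generation on `ct2` at the relocated isocenter; every
#' segment's MU is copied from the planning-geometry segment with the same
#' structural key (gantry angle, step type, target, sidedness). A count
#' mismatch between the two geometries' segment sets is an error — no
#' silent MU redistribution.
#'
#' @param native a `native_plan` (planning geometry).
#' @param ct2 geometry-of-the-day structure set.
#' @param shift relocation shift from [relocate_isocenter()].
#' @return the regenerated `rt_plan` with transferred MUs, isocenter at
#'   the relocated position.
#' @export
regenerate_with_mu_transfer <- function(native, ct2, shift = c(0, 0, 0)) {
  iso2 <- isocenter(native$ss) + as.numeric(shift)
  fresh <- make_twostep_plan(ct2, native$table, native$config, isocenter = iso2)
  k1 <- segment_keys(native$plan)
  k2 <- segment_keys(fresh)
  if (!setequal(k1, k2) || anyDuplicated(k1) || anyDuplicated(k2)) {
    missing <- setdiff(k1, k2); extra <- setdiff(k2, k1)
    stop("segment sets of the two geometries do not match:\n",
         if (length(missing)) paste("  only in CT1:", paste(missing, collapse = "; "), "\n"),
         if (length(extra)) paste("  only in CT2:", paste(extra, collapse = "; ")))
  }
  segs <- tibble::as_tibble(fresh)
  segs$mu <- native$plan$mu[match(k2, k1)]
  update_plan(fresh, segs)
}

#' Rescale compensation-strip widths to a changed geometry
#'
#' Every S2 strip width is multiplied by the ratio of the frozen-weight
#' (adapt-mode) beta* values of the new and old geometry of its leaf pair
#' and re-clipped against the new target opening; MUs are untouched. With
#' identical geometries the ratio is 1 and the plan is returned unchanged.
#'
#' @param plan plan whose S2 widths correspond to `geo1` (per-pair strip
#'   widths in mm).
#' @param geo1,geo2 per-(target, pair) normalized geometry tibbles with
#'   columns target, pair, rho_oar, gamma, r_ptv (see
#'   [adaptation_geometry()]).
#' @param table a `beta_star_table`.
#' @param clip_bev optional named list of `bev_projection`s per angle for
#'   re-clipping against the new target opening.
#' @return the plan with rescaled S2 widths.
#' @export
adapt_s2_widths <- function(plan, geo1, geo2, table, clip_bev = NULL) {
  segs <- tibble::as_tibble(plan)
  n_clamped <- 0L
  for (i in which(segs$step_type == "S2")) {
    lv <- segs$leaves[[i]]
    side <- segs$side[i]; tg <- segs$target[i]
    for (k in seq_len(nrow(lv))) {
      pr <- lv[k, "pair"]
      g1 <- geo1[geo1$target == tg & geo1$pair == pr, ]
      g2 <- geo2[geo2$target == tg & geo2$pair == pr, ]
      if (nrow(g1) == 0 || nrow(g2) == 0 || g1$rho_oar == 0 || g2$rho_oar == 0) next
      b1 <- beta_star_eval(table, g1$gamma, g1$rho_oar, mode = "adapt",
                           quiet = TRUE)
      b2 <- beta_star_eval(table, g2$gamma, g2$rho_oar, mode = "adapt",
                           quiet = TRUE)
      n_clamped <- n_clamped + sum(attr(b1, "clamped")) + sum(attr(b2, "clamped"))
      ratio <- b2 / b1
      w_new <- (lv[k, "hi"] - lv[k, "lo"]) * ratio
      if (side == "left") lv[k, "lo"] <- lv[k, "hi"] - w_new
      else lv[k, "hi"] <- lv[k, "lo"] + w_new
      if (!is.null(clip_bev)) {
        bev <- clip_bev[[as.character(segs$angle_deg[i])]]
        hull <- bev_hull(bev, tg, pr)
        if (!is.null(hull)) {
          lv[k, "lo"] <- max(lv[k, "lo"], hull[1])
          lv[k, "hi"] <- min(lv[k, "hi"], hull[2])
        }
      }
    }
    segs$leaves[[i]] <- lv[lv[, "hi"] > lv[, "lo"], , drop = FALSE]
  }
  if (n_clamped > 0)
    warning(n_clamped, " leaf-pair geometry value(s) outside the beta* ",
            "table domain; clamped to its boundary")
  update_plan(plan, segs)
}

#' Replay recorded fine-tuning shifts onto a changed geometry
#'
#' Each planning-geometry leaf pair is mapped to the geometry-of-the-day
#' pair at the same fractional position within the target's BEV vertical
#' extent (nearest-pair rounding), and the recorded (left, right) edge
#' shifts are added to the new pre-shift positions. Pairs without a
#' counterpart (the target extent grew) get zero shift. Apertures are
#' re-validated: degenerate intervals are dropped.
#'
#' @param plan the geometry-of-the-day plan (pre-shift apertures).
#' @param record the planning geometry's `leaf_shift_record`.
#' @param ct2_extents named list per target: leaf-pair index range of the
#'   target's BEV extent on the geometry of the day.
#' @return the shifted `rt_plan`.
#' @export
imitate_finetuning <- function(plan, record, ct2_extents) {
  ct1_extents <- attr(record, "target_extents")
  segs <- tibble::as_tibble(plan)
  segs$leaves <- lapply(seq_len(nrow(segs)), function(i) {
    lv <- segs$leaves[[i]]
    if (is.null(lv) || nrow(lv) == 0) return(lv)
    tg <- segs$target[i]
    e1 <- ct1_extents[[tg]]; e2 <- ct2_extents[[tg]]
    for (k in seq_len(nrow(lv))) {
      p1 <- map_pair(lv[k, "pair"], e2, e1)
      ri <- which(record$segment_id == segs$segment_id[i] & record$pair == p1)
      if (length(ri) == 1) {
        lv[k, "lo"] <- lv[k, "lo"] + record$d_lo[ri]
        lv[k, "hi"] <- lv[k, "hi"] + record$d_hi[ri]
      }
    }
    lv[lv[, "hi"] > lv[, "lo"], , drop = FALSE]
  })
  update_plan(plan, segs)
}

# map pair index from extent `from` to extent `to` at equal fractional
# position, nearest-pair rounding
map_pair <- function(pair, from, to) {
  if (from[2] == from[1]) return(to[1] + (pair - from[1]))
  f <- (pair - from[1]) / (from[2] - from[1])
  as.integer(round(to[1] + f * (to[2] - to[1])))
}

#' Per-pair normalized geometry of all targets (adaptation input)
#'
#' Geometry is measured at a reference gantry angle; for coplanar parallel
#' projection the per-pair target half-width, OAR half-width and gap vary
#' only mildly with angle, and the width adaptation uses one geometry per
#' CT layer.
#'
#' @param ss a `structure_set`.
#' @param config a [run_config()].
#' @param isocenter optional isocenter override (mm).
#' @param gantry_deg reference angle (degrees).
#' @export
adaptation_geometry <- function(ss, config, isocenter = NULL, gantry_deg = 0) {
  mlc <- mlc_spec(config$mlc$leaf_width_mm, config$mlc$field_half_mm)
  targets <- intersect(names(config$prescriptions), structure_names(ss))
  ss_g <- ss
  if (!is.null(isocenter)) attr(ss_g, "isocenter") <- as.numeric(isocenter)
  purrr::map_dfr(targets, function(tg) {
    g <- pairwise_geometry(ss_g, gantry_deg, mlc, target = tg, oar = config$oar)
    g$target <- tg
    g
  })
}

#' Three-step MU-preserving adaptation of a native plan
#'
#' Runs the full protocol: isocenter relocation (the clinical baseline,
#' also returned as the relocated-only comparison plan), two-step
#' regeneration with MU transfer, compensation-strip width rescaling, and
#' fine-tuning imitation. Total MU is preserved exactly through every
#' step. When the estimated native MU requirement of the new geometry
#' differs from the planned MU by more than 10%, the geometry change is
#' beyond the small-change regime the method assumes and a prominent
#' warning is emitted (coverage or sparing will degrade); the adaptation
#' is still carried out.
#'
#' @param native a `native_plan` from [plan_native()].
#' @param ct2 geometry-of-the-day structure set.
#' @return an `adaptation_result`: relocated / step1 / step2 / adapted
#'   plans, the shift, per-geometry tables, an MU ledger, and the shared
#'   calibration.
#' @export
adapt_plan <- function(native, ct2) {
  config <- native$config
  shift <- relocate_isocenter(native$ss, ct2,
                              targets = intersect(names(config$prescriptions),
                                                  structure_names(ct2)))
  relocated <- relocate_plan(native$plan, shift, native$ss)
  step1 <- regenerate_with_mu_transfer(native, ct2, shift)

  iso2 <- isocenter(native$ss) + shift
  geo1 <- adaptation_geometry(native$ss, config)
  geo2 <- adaptation_geometry(ct2, config, isocenter = iso2)

  # carry the planning-geometry S2 widths (per mapped pair) into the fresh
  # segments, then rescale by the adapt-mode beta* ratio and re-clip
  bevs <- lapply(stats::setNames(nm = as.character(unique(step1$angle_deg))),
                 function(a) {
                   ssg <- ct2; attr(ssg, "isocenter") <- iso2
                   project_to_bev(ssg, as.numeric(a), attr(step1, "mlc"))
                 })
  e1 <- attr(native$record, "target_extents")
  e2 <- lapply(stats::setNames(nm = names(e1)), function(tg) {
    zs <- structure_zs(ct2, tg)
    range(pair_of_z(zs, iso2[3], attr(step1, "mlc")$leaf_width_mm))
  })
  carried <- carry_ct1_widths(step1, native$pre, e1, e2)
  step2 <- adapt_s2_widths(carried, geo1, geo2, native$table, clip_bev = bevs)
  adapted <- imitate_finetuning(step2, native$record, e2)

  mu_ledger <- tibble::tibble(
    plan = c("native_ct1", "relocated", "step1", "step2", "adapted"),
    total_mu = c(total_mu(native$plan), total_mu(relocated), total_mu(step1),
                 total_mu(step2), total_mu(adapted)))

  # large-change guard: native-equivalent MU estimate for CT2
  d1 <- compute_dose(step1, ct2, resolution = config$dose_resolution,
                     calibration = native$calibration)
  presc <- config$prescriptions
  tg <- intersect(names(presc), structure_names(ct2))
  tg <- tg[which.max(presc[tg])]
  mtg <- structure_mask(ct2, tg, d1)
  mu_equiv <- total_mu(native$plan) * presc[[tg]] / mean(d1$dose[mtg])
  rel_diff <- abs(mu_equiv - total_mu(native$plan)) / total_mu(native$plan)
  if (rel_diff > 0.10)
    warning(sprintf(paste0(
      "geometry change beyond the small-change regime: native-equivalent MU ",
      "differs by %.0f%% (>10%%) from the planned MU; MU-preserving ",
      "adaptation will compromise coverage or sparing"), 100 * rel_diff))

  structure(list(shift = shift, relocated = relocated, step1 = step1,
                 step2 = step2, adapted = adapted, geo1 = geo1, geo2 = geo2,
                 mu_ledger = mu_ledger, mu_equiv = unname(mu_equiv),
                 calibration = native$calibration, ct2 = ct2,
                 native = native),
            class = "adaptation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# replace the fresh CT2 S2 widths by the planning geometry's pre-fine-tune
# widths at the extent-mapped pair (the Eq.-1 anchor beta_CT1)
carry_ct1_widths <- function(step1, pre_ct1, e1, e2) {
  k1 <- segment_keys(pre_ct1)
  segs <- tibble::as_tibble(step1)
  k2 <- segment_keys(step1)
  for (i in which(segs$step_type == "S2")) {
    j <- match(k2[i], k1)
    if (is.na(j)) next
    lv1 <- pre_ct1$leaves[[j]]
    lv <- segs$leaves[[i]]
    tg <- segs$target[i]
    for (k in seq_len(nrow(lv))) {
      p1 <- map_pair(lv[k, "pair"], e2[[tg]], e1[[tg]])
      k1row <- which(lv1[, "pair"] == p1)
      if (length(k1row) != 1) next
      w1 <- lv1[k1row, "hi"] - lv1[k1row, "lo"]
      if (segs$side[i] == "left") lv[k, "lo"] <- lv[k, "hi"] - w1
      else lv[k, "hi"] <- lv[k, "lo"] + w1
    }
    segs$leaves[[i]] <- lv
  }
  update_plan(step1, segs)
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf("<adaptation_result> shift (%g, %g, %g) mm\n",
              x$shift[1], x$shift[2], x$shift[3]))
  print(as.data.frame(x$mu_ledger), row.names = FALSE)
  cat(sprintf("native-equivalent MU for the new geometry: %.1f\n", x$mu_equiv))
  invisible(x)
}

#' @method tidy adaptation_result
#' @export
tidy.adaptation_result <- function(x, ...) x$mu_ledger

#' @method glance adaptation_result
#' @export
glance.adaptation_result <- function(x, ...) {
  tibble::tibble(shift_x = x$shift[1], shift_y = x$shift[2],
                 shift_z = x$shift[3],
                 total_mu = total_mu(x$adapted),
                 mu_preserved = total_mu(x$adapted) == total_mu(x$native$plan),
                 mu_equiv_ct2 = x$mu_equiv)
}
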