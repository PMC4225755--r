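# Inverse fine-tuning stage. A composite objective value (COV) — the
# weighted sum of volume-normalized quadratic DVH-point penalties — is
# minimized first over segment MU weights (projected gradient descent with
# a monotone line search) and then over individual leaf positions (greedy
# single-leaf moves accepted only when the COV decreases). The leaf stage
# records every accepted shift per segment and leaf pair; the adaptation
# module replays this record onto the geometry of the day. Weight
# optimization never touches leaves and leaf fine-tuning never touches
# MUs, mirroring the separation the MU-preserving adaptation relies on.

#' DVH-point objective specification
#'
#' @param structure structure name (may be a difference expression such as
#'   `"PTV-Boost"`).
#' @param kind `"min_dose"`, `"max_dose"` (point objectives) or
#'   `"max_dvh"` (at most `volume_fraction` of the structure above
#'   `dose_Gy`).
#' @param dose_Gy objective dose (Gy, > 0).
#' @param weight objective weight (> 0).
#' @param volume_fraction volume fraction for `max_dvh` objectives.
#' @return one-row objective tibble; `rbind`/`bind_rows` to combine.
#' @export
objective <- function(structure, kind, dose_Gy, weight = 1,
                      volume_fraction = NA_real_) {
  stopifnot(kind %in% c("min_dose", "max_dose", "max_dvh"),
            dose_Gy > 0, weight > 0)
  if (kind == "max_dvh") stopifnot(volume_fraction > 0, volume_fraction < 1)
  tibble::tibble(structure = structure, kind = kind, dose_Gy = dose_Gy,
                 weight = weight, volume_fraction = volume_fraction)
}

#' Default objective template for the simultaneous-integrated-boost
#' prostate protocol
#'
#' Mirrors the clinical template counts: paired min/max objectives around
#' the PTV prescription plateau (PTV minus Boost), three for the Boost,
#' four shaping the rectum DVH, and a low-weight healthy-tissue ceiling;
#' weights span 0.1 to 100.
#'
#' @param presc named prescription vector (Gy).
#' @export
default_objectives <- function(presc = c(PTV = 60.1, Boost = 74)) {
  dplyr::bind_rows(
    objective("PTV-Boost", "min_dose", presc[["PTV"]] * 0.98, 100),
    objective("PTV-Boost", "min_dose", presc[["PTV"]] * 0.93, 50),
    objective("PTV-Boost", "max_dose", presc[["PTV"]] * 1.03, 30),
    objective("PTV-Boost", "max_dose", presc[["PTV"]] * 1.08, 10),
    objective("Boost", "min_dose", presc[["Boost"]] * 0.98, 80),
    objective("Boost", "max_dose", presc[["Boost"]] * 1.03, 40),
    objective("Boost", "max_dose", presc[["Boost"]] * 1.08, 10),
    objective("OAR", "max_dose", presc[["Boost"]] * 1.00, 5),
    objective("OAR", "max_dvh", presc[["Boost"]] * 0.95, 2, volume_fraction = 0.10),
    objective("OAR", "max_dvh", presc[["Boost"]] * 0.80, 1, volume_fraction = 0.30),
    objective("OAR", "max_dvh", presc[["Boost"]] * 0.50, 0.5, volume_fraction = 0.60),
    objective("body", "max_dose", presc[["Boost"]] * 1.10, 0.1)
  )
}

#' Single-target objective template (phantom geometries)
#' @param presc prescription dose of the ring target (Gy).
#' @export
phantom_objectives <- function(presc = 74) {
  dplyr::bind_rows(
    objective("PTV", "min_dose", presc * 0.97, 100),
    objective("PTV", "min_dose", presc * 0.93, 50),
    objective("PTV", "max_dose", presc * 1.03, 30),
    objective("PTV", "max_dose", presc * 1.08, 10),
    objective("OAR", "max_dose", presc * 0.70, 5),
    objective("OAR", "max_dvh", presc * 0.50, 2, volume_fraction = 0.5),
    objective("body", "max_dose", presc * 1.10, 0.1)
  )
}

# per-objective penalty from a voxel dose vector
objective_penalty <- function(d, kind, dose_Gy, volume_fraction) {
  n <- length(d)
  if (kind == "min_dose") {
    sum(pmax(0, dose_Gy - d)^2) / n
  } else if (kind == "max_dose") {
    sum(pmax(0, d - dose_Gy)^2) / n
  } else {
    # DVH objective (Wu-Mohan form): if more than the allowed fraction
    # exceeds dose_Gy, penalize the excess voxels between dose_Gy and the
    # dose currently at the allowed volume fraction
    over <- d > dose_Gy
    frac <- mean(over)
    if (frac <= volume_fraction) return(0)
    d_v <- stats::quantile(d, probs = 1 - volume_fraction, type = 7, names = FALSE)
    active <- d > dose_Gy & d <= d_v
    sum((d[active] - dose_Gy)^2) / n
  }
}

#' Composite objective value of a dose distribution
#'
#' `COV = sum_k weight_k / N_k * sum_i penalty_ik^2` with one-sided
#' quadratic penalties at the DVH points of `objectives`.
#'
#' @param dose a `dose_grid`.
#' @param ss the structure set.
#' @param objectives objective tibble (see [objective()]).
#' @return scalar COV (Gy^2) with a per-objective breakdown in the
#'   `"by_objective"` attribute.
#' @export
cov_score <- function(dose, ss, objectives) {
  missing <- setdiff(unique(unlist(lapply(objectives$structure, parse_structure_expr))),
                     structure_names(ss))
  if (length(missing) > 0)
    stop("objective names a structure absent from the set: ",
         paste(missing, collapse = ", "))
  vals <- vapply(seq_len(nrow(objectives)), function(k) {
    m <- structure_mask(ss, parse_structure_expr(objectives$structure[k]), dose)
    d <- dose$dose[m]
    objectives$weight[k] *
      objective_penalty(d, objectives$kind[k], objectives$dose_Gy[k],
                        objectives$volume_fraction[k])
  }, numeric(1))
  structure(sum(vals),
            by_objective = tibble::tibble(objectives, penalty = vals))
}

# --- internal machinery shared by the two fine-tuners -----------------------
# Doses of all objective voxels are an affine function of the MU vector:
# d = calibration * A mu, with A the segment-exposure indicator matrix over
# the union of objective-structure voxels. The context caches A, the voxel
# index sets per objective and the calibration.
finetune_context <- function(plan, ss, objectives, resolution, calibration) {
  grid <- dose_sampling_grid(ss, resolution)
  iso <- plan_isocenter(plan, ss)
  w <- attr(plan, "mlc")$leaf_width_mm
  masks <- lapply(stats::setNames(nm = unique(objectives$structure)), function(s)
    structure_mask(ss, parse_structure_expr(s), grid))
  union_mask <- Reduce(`|`, masks)
  vox_idx <- which(union_mask)
  nz <- length(grid$z)
  nxy <- length(grid$x) * length(grid$y)
  sl_of_vox <- (vox_idx - 1L) %/% nxy + 1L
  xy_of_vox <- (vox_idx - 1L) %% nxy + 1L
  xy <- expand.grid(x = grid$x, y = grid$y)
  pair_of_slice <- pair_of_z(grid$z, iso[3], w)
  p_cache <- lapply(stats::setNames(nm = as.character(unique(plan$angle_deg))),
                    function(a) bev_axis_p(xy$x, xy$y, as.numeric(a), iso))
  seg_exposure <- function(lv, ang) {
    p <- p_cache[[as.character(ang)]][xy_of_vox]
    expo <- logical(length(vox_idx))
    if (is.null(lv) || nrow(lv) == 0) return(expo)
    for (k in seq_len(nrow(lv))) {
      expo <- expo | (pair_of_slice[sl_of_vox] == lv[k, "pair"] &
                        p > lv[k, "lo"] & p < lv[k, "hi"])
    }
    expo
  }
  A <- vapply(seq_len(nrow(plan)), function(i)
    seg_exposure(plan$leaves[[i]], plan$angle_deg[i]),
    logical(length(vox_idx)))
  obj_vox <- lapply(seq_len(nrow(objectives)), function(k)
    which(masks[[objectives$structure[k]]][vox_idx]))
  if (is.null(calibration)) {
    presc <- attr(plan, "prescription")
    tg <- intersect(names(presc), structure_names(ss))
    tg <- tg[which.max(presc[tg])]
    mtg <- structure_mask(ss, tg, grid)
    raw <- compute_dose(plan, ss, resolution, calibration = 1)
    calibration <- unname(presc[tg] / mean(raw$dose[mtg]))
  }
  list(A = A * 1, obj_vox = obj_vox, calibration = calibration,
       objectives = objectives, grid = grid, seg_exposure = seg_exposure)
}

context_cov <- function(ctx, d) {
  sum(vapply(seq_len(nrow(ctx$objectives)), function(k) {
    o <- ctx$objectives[k, ]
    o$weight * objective_penalty(d[ctx$obj_vox[[k]]], o$kind, o$dose_Gy,
                                 o$volume_fraction)
  }, numeric(1)))
}

# gradient of COV wrt the voxel dose vector (subgradient for DVH objectives)
context_grad_d <- function(ctx, d) {
  g <- numeric(length(d))
  for (k in seq_len(nrow(ctx$objectives))) {
    o <- ctx$objectives[k, ]
    idx <- ctx$obj_vox[[k]]
    dk <- d[idx]
    n <- length(dk)
    if (o$kind == "min_dose") {
      def <- pmax(0, o$dose_Gy - dk)
      g[idx] <- g[idx] - 2 * o$weight * def / n
    } else if (o$kind == "max_dose") {
      exc <- pmax(0, dk - o$dose_Gy)
      g[idx] <- g[idx] + 2 * o$weight * exc / n
    } else {
      over <- dk > o$dose_Gy
      if (mean(over) > o$volume_fraction) {
        d_v <- stats::quantile(dk, probs = 1 - o$volume_fraction, type = 7,
                               names = FALSE)
        act <- over & dk <= d_v
        g[idx[act]] <- g[idx[act]] + 2 * o$weight * (dk[act] - o$dose_Gy) / n
      }
    }
  }
  g
}

#' Optimize segment MU weights against a composite objective
#'
#' Projected gradient descent on the non-negative MU vector with a
#' backtracking line search, so the COV is non-increasing over the
#' iterations; leaf positions are never touched. The calibration (Gy per
#' MU) is frozen at the input plan's value, so the optimization trades
#' segments off rather than rescaling the plan.
#'
#' @param plan an `rt_plan`.
#' @param ss the structure set.
#' @param objectives objective tibble.
#' @param iterations optimization steps (default 25).
#' @param resolution dose sampling resolution for the objective voxels (mm).
#' @param calibration optional fixed Gy/MU; default from the input plan.
#' @return the plan with optimized MUs; attributes `cov_trace` (COV per
#'   iteration) and `calibration`.
#' @export
optimize_weights <- function(plan, ss, objectives, iterations = 25,
                             resolution = 2, calibration = NULL) {
  stopifnot(nrow(plan) >= 1)
  ctx <- finetune_context(plan, ss, objectives, resolution, calibration)
  mu <- plan$mu
  cal <- ctx$calibration
  dose_of <- function(mu) cal * as.vector(ctx$A %*% mu)
  d <- dose_of(mu)
  cov <- context_cov(ctx, d)
  trace <- cov
  step <- NULL
  for (it in seq_len(iterations)) {
    g_mu <- cal * as.vector(crossprod(ctx$A, context_grad_d(ctx, d)))
    if (all(g_mu == 0)) break
    if (is.null(step)) step <- 0.1 * max(mu) / max(abs(g_mu))
    improved <- FALSE
    for (tries in 1:12) {
      mu_new <- pmax(0, mu - step * g_mu)
      d_new <- dose_of(mu_new)
      cov_new <- context_cov(ctx, d_new)
      if (cov_new < cov - 1e-12) {
        mu <- mu_new; d <- d_new; cov <- cov_new
        step <- step * 1.5
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    trace <- c(trace, cov)
    if (!improved) break
  }
  segs <- tibble::as_tibble(plan)
  segs$mu <- mu
  out <- update_plan(plan, segs)
  attr(out, "cov_trace") <- trace
  attr(out, "calibration") <- cal
  out
}

#' Greedy leaf-position fine-tuning with shift recording
#'
#' Visits every segment and leaf pair and tries moving each leaf (interval
#' edge) by `step_mm` in both directions, accepting a move only when the
#' COV decreases. MUs are never changed. All accepted shifts are
#' accumulated in a `leaf_shift_record`: per segment and leaf pair the net
#' (left, right) edge displacement, together with the target's BEV
#' vertical extent (leaf-pair index range) at recording time, which the
#' adaptation replays onto a changed geometry.
#'
#' @param plan an `rt_plan`.
#' @param ss the structure set.
#' @param objectives objective tibble.
#' @param step_mm leaf step per move (mm, > 0).
#' @param iterations sweeps over all leaves.
#' @param resolution dose sampling resolution (mm).
#' @param calibration optional fixed Gy/MU; default from the input plan.
#' @return list with `plan` (fine-tuned) and `record` (a
#'   `leaf_shift_record` tibble: segment_id, pair, d_lo, d_hi).
#' @export
finetune_leaves <- function(plan, ss, objectives, step_mm = 2, iterations = 2,
                            resolution = 2, calibration = NULL) {
  stopifnot(step_mm > 0)
  leaves <- plan$leaves
  extents <- target_extents(plan, ss)
  rec0 <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    lv <- leaves[[i]]
    if (is.null(lv) || nrow(lv) == 0) return(NULL)
    tibble::tibble(segment_id = plan$segment_id[i], pair = lv[, "pair"],
                   d_lo = 0, d_hi = 0)
  })
  if (iterations == 0) {
    return(list(plan = plan,
                record = new_shift_record(rec0, extents)))
  }
  ctx <- finetune_context(plan, ss, objectives, resolution, calibration)
  cal <- ctx$calibration
  expo <- ctx$A
  mu <- plan$mu
  d <- cal * as.vector(expo %*% mu)
  cov <- context_cov(ctx, d)
  fhalf <- attr(plan, "mlc")$field_half_mm
  rec <- rec0
  for (sweep in seq_len(iterations)) {
    any_move <- FALSE
    for (i in seq_len(nrow(plan))) {
      lv <- leaves[[i]]
      if (is.null(lv) || nrow(lv) == 0 || mu[i] == 0) next
      for (k in seq_len(nrow(lv))) {
        for (edge in c("lo", "hi")) {
          for (dir in c(-step_mm, step_mm)) {
            cand <- lv
            cand[k, edge] <- cand[k, edge] + dir
            if (cand[k, "hi"] <= cand[k, "lo"]) next
            if (abs(cand[k, edge]) > fhalf) next
            new_col <- ctx$seg_exposure(cand, plan$angle_deg[i])
            d_new <- d + cal * mu[i] * (new_col - expo[, i])
            cov_new <- context_cov(ctx, d_new)
            if (cov_new < cov - 1e-12) {
              lv <- cand; leaves[[i]] <- cand
              expo[, i] <- new_col
              d <- d_new; cov <- cov_new
              ri <- which(rec$segment_id == plan$segment_id[i] &
                            rec$pair == lv[k, "pair"])
              col <- if (edge == "lo") "d_lo" else "d_hi"
              rec[ri, col] <- rec[ri, col] + dir
              any_move <- TRUE
            }
          }
        }
      }
    }
    if (!any_move) break
  }
  segs <- tibble::as_tibble(plan)
  segs$leaves <- leaves
  list(plan = update_plan(plan, segs),
       record = new_shift_record(rec, extents))
}

new_shift_record <- function(rec, extents) {
  tibble::new_tibble(rec, target_extents = extents, class = "leaf_shift_record")
}

# leaf-pair index range of each prescription target's BEV projection
target_extents <- function(plan, ss) {
  mlc <- attr(plan, "mlc")
  iso <- plan_isocenter(plan, ss)
  targets <- intersect(names(attr(plan, "prescription")), structure_names(ss))
  out <- lapply(stats::setNames(nm = targets), function(tg) {
    zs <- structure_zs(ss, tg)
    range(pair_of_z(zs, iso[3], mlc$leaf_width_mm))
  })
  out
}

#' Replay a leaf-shift record onto a plan (same geometry)
#'
#' Adds the recorded per-pair edge displacements to the plan's apertures;
#' with the record produced from this plan's pre-fine-tune segments this
#' reproduces the fine-tuned plan exactly.
#'
#' @param plan an `rt_plan`.
#' @param record a `leaf_shift_record`.
#' @export
apply_shift_record <- function(plan, record) {
  segs <- tibble::as_tibble(plan)
  segs$leaves <- lapply(seq_len(nrow(segs)), function(i) {
    lv <- segs$leaves[[i]]
    if (is.null(lv) || nrow(lv) == 0) return(lv)
    for (k in seq_len(nrow(lv))) {
      ri <- which(record$segment_id == segs$segment_id[i] &
                    record$pair == lv[k, "pair"])
      if (length(ri) == 1) {
        lv[k, "lo"] <- lv[k, "lo"] + record$d_lo[ri]
        lv[k, "hi"] <- lv[k, "hi"] + record$d_hi[ri]
      }
    }
    lv[lv[, "hi"] > lv[, "lo"], , drop = FALSE]
  })
  update_plan(plan, segs)
}
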