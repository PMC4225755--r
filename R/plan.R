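# Treatment plans. A plan is a tibble of MLC segments: one row per segment
# with its gantry angle, two-step type (S0 conformal / S1 OAR-sparing / S2
# edge-compensating), target label, sidedness relative to the OAR block, MU
# weight, and the open leaf intervals as a matrix with columns pair, lo, hi
# (mm on the BEV axis). Beam set, prescription, MLC spec and isocenter
# travel as attributes.

#' Construct a plan
#'
#' @param segments tibble with columns `angle_deg`, `step_type`, `target`,
#'   `side` ("both", "left" or "right"), `mu`, `leaves` (list of matrices
#'   with columns pair, lo, hi; closed pairs are simply absent).
#' @param beams numeric vector of allowed gantry angles (degrees).
#' @param prescription named vector of prescription doses (Gy), e.g.
#'   `c(PTV = 60.1, Boost = 74)`.
#' @param fractions number of fractions the prescription is given in.
#' @param mlc an [mlc_spec()].
#' @param isocenter numeric length-3 (mm); `NULL` means the structure set's.
#' @export
rt_plan <- function(segments, beams, prescription, fractions = 33,
                    mlc = mlc_spec(), isocenter = NULL) {
  segments <- tibble::as_tibble(segments)
  need <- c("angle_deg", "step_type", "target", "side", "mu", "leaves")
  stopifnot(all(need %in% names(segments)))
  if (any(segments$mu < 0)) stop("negative MU")
  for (lv in segments$leaves) {
    if (is.null(lv) || nrow(lv) == 0) next
    if (any(lv[, "hi"] < lv[, "lo"])) stop("leaf interval with hi < lo")
  }
  if (!"segment_id" %in% names(segments))
    segments$segment_id <- seq_len(nrow(segments))
  tibble::new_tibble(segments, beams = beams, prescription = prescription,
                     fractions = fractions, mlc = mlc, isocenter = isocenter,
                     class = "rt_plan")
}

#' Total monitor units of a plan
#' @param plan an `rt_plan`.
#' @export
total_mu <- function(plan) sum(plan$mu)

# rebuild a plan keeping attributes, with modified segment tibble
update_plan <- function(plan, segments) {
  rt_plan(segments, attr(plan, "beams"), attr(plan, "prescription"),
          attr(plan, "fractions"), attr(plan, "mlc"), attr(plan, "isocenter"))
}

#' Shift a plan's isocenter (couch relocation)
#' @param plan an `rt_plan`.
#' @param shift numeric length-3 (mm).
#' @param ss structure set supplying the original isocenter when the plan
#'   carries none.
#' @export
relocate_plan <- function(plan, shift, ss) {
  iso <- plan_isocenter(plan, ss)
  out <- update_plan(plan, tibble::as_tibble(plan))
  attr(out, "isocenter") <- iso + as.numeric(shift)
  out
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf("<rt_plan> %d segments, %d beams, total MU %.1f\n",
              nrow(x), length(attr(x, "beams")), total_mu(x)))
  tb <- table(x$step_type)
  cat("  ", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Write a plan to JSON
#'
#' Format: `{meta: {...}, beams: [...], segments: [{angle_deg, type, target,
#' side, mu, leaves: [[pair, lo, hi], ...]}]}`. Byte-stable under
#' write-read-write round trips.
#'
#' @param plan an `rt_plan`.
#' @param path output file.
#' @export
write_plan <- function(plan, path) {
  segs <- lapply(seq_len(nrow(plan)), function(i) list(
    id = plan$segment_id[i],
    angle_deg = plan$angle_deg[i],
    type = plan$step_type[i],
    target = plan$target[i],
    side = plan$side[i],
    mu = plan$mu[i],
    leaves = unname(plan$leaves[[i]])
  ))
  obj <- list(
    meta = list(prescription_Gy = as.list(attr(plan, "prescription")),
                fractions = attr(plan, "fractions"),
                leaf_width_mm = attr(plan, "mlc")$leaf_width_mm,
                field_half_mm = attr(plan, "mlc")$field_half_mm,
                isocenter_mm = attr(plan, "isocenter")),
    beams = attr(plan, "beams"),
    segments = segs
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a plan written by [write_plan()]
#' @param path JSON file.
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- purrr::map_dfr(obj$segments, function(s) tibble::tibble(
    segment_id = s$id, angle_deg = s$angle_deg, step_type = s$type,
    target = s$target, side = s$side, mu = s$mu,
    leaves = list({
      m <- do.call(rbind, lapply(s$leaves, unlist))
      if (is.null(m)) m <- matrix(numeric(0), 0, 3)
      colnames(m) <- c("pair", "lo", "hi")
      m
    })
  ))
  rt_plan(segs, beams = unlist(obj$beams),
          prescription = unlist(obj$meta$prescription_Gy),
          fractions = obj$meta$fractions,
          mlc = mlc_spec(obj$meta$leaf_width_mm, obj$meta$field_half_mm),
          isocenter = if (is.null(obj$meta$isocenter_mm)) NULL else
            unlist(obj$meta$isocenter_mm))
}
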