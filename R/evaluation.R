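# Plan evaluation. Achieved DVH statistics are compared against required
# dose ranges; every violation contributes its distance to the nearest
# range limit (in Gy), and the net quality score S_D is the sum of those
# violations — a plan meeting all requirements scores 0. Rectum load is
# reported as the absolute volumes inside the 50%, 80% and 95% isodoses of
# the reference dose.

#' Required dose ranges for plan scoring
#'
#' The default set covers the simultaneous-integrated-boost protocol:
#' Boost D_mean 76.2 Gy +- 1% (\[75.4, 77.0\]), Boost D_99% > 70 Gy, Boost
#' D_95% 74 Gy +- 2% (\[72.5, 75.5\]), Boost D_1% < 80 Gy, PTV-minus-Boost
#' D_99% > 56 Gy and D_95% 60.1 Gy +- 2% (\[58.9, 61.3\]). One-sided
#' requirements leave the other limit `NA`.
#'
#' @return tibble with columns structure, metric, lo, up (Gy).
#' @export
default_requirements <- function() {
  tibble::tribble(
    ~structure,  ~metric,  ~lo,  ~up,
    "Boost",     "D_mean", 75.4, 77.0,
    "Boost",     "D_99%",  70,   NA,
    "Boost",     "D_95%",  72.5, 75.5,
    "Boost",     "D_1%",   NA,   80,
    "PTV-Boost", "D_99%",  56,   NA,
    "PTV-Boost", "D_95%",  58.9, 61.3
  )
}

#' S_D quality score: summed violations of required dose ranges
#'
#' Per requirement j with achieved value A_j and range \[R_lo, R_up\]:
#' penalty `R_lo - A_j` below the range, `A_j - R_up` above it, else 0;
#' the net S_D is the sum. Requirements with no achieved value are
#' dropped (e.g. a metric not reported for a plan).
#'
#' @param achieved tibble with columns structure, metric, value (Gy).
#' @param requirements tibble as [default_requirements()].
#' @return a `plan_score` tibble (one row per scored requirement with its
#'   achieved value and penalty); net score in the `s_d` attribute.
#' @export
s_d_score <- function(achieved, requirements = default_requirements()) {
  sc <- dplyr::inner_join(requirements, achieved,
                          by = c("structure", "metric"))
  if (nrow(sc) == 0) stop("no achieved value matches any requirement")
  if (!is.numeric(sc$value)) stop("achieved values must be numeric (Gy)")
  sc$penalty <- pmax(0, sc$lo - sc$value, na.rm = TRUE) +
    pmax(0, sc$value - sc$up, na.rm = TRUE)
  # pmax(..., na.rm) treats a missing limit as no constraint, but returns NA
  # when *both* terms are NA — impossible here since lo/up never both NA
  tibble::new_tibble(sc, s_d = sum(sc$penalty), class = "plan_score")
}

#' Net S_D of a plan score
#' @param score a `plan_score`.
#' @export
net_s_d <- function(score) attr(score, "s_d")

#' @export
print.plan_score <- function(x, ...) {
  cat(sprintf("<plan_score> net S_D = %.1f Gy\n", attr(x, "s_d")))
  df <- as.data.frame(tibble::as_tibble(x))
  print(df, digits = 3, row.names = FALSE)
  rv <- attr(x, "rectum_v")
  if (!is.null(rv))
    cat(sprintf("rectum V_95/80/50%%: %.1f / %.1f / %.1f cm^3\n",
                rv[["V_95%"]], rv[["V_80%"]], rv[["V_50%"]]))
  invisible(x)
}

#' @method tidy plan_score
#' @export
tidy.plan_score <- function(x, ...) tibble::as_tibble(x)

#' @method glance plan_score
#' @export
glance.plan_score <- function(x, ...) {
  out <- tibble::tibble(s_d = attr(x, "s_d"), n_requirements = nrow(x),
                        n_violated = sum(x$penalty > 0))
  rv <- attr(x, "rectum_v")
  if (!is.null(rv)) out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(rv)))
  ctv <- attr(x, "ctv_d99")
  if (!is.null(ctv)) out$ctv_d99 <- ctv
  out
}

#' Evaluate a dose distribution against the protocol requirements
#'
#' Computes the achieved DVH statistics (Boost D_mean/D_99%/D_95%/D_1%,
#' PTV-minus-Boost D_99%/D_95%, CTV D_99% when present), scores them with
#' [s_d_score()], and reports the absolute rectum volumes inside the 50%,
#' 80% and 95% isodoses of `reference_dose`.
#'
#' @param dose a `dose_grid`.
#' @param ss the structure set.
#' @param requirements required ranges (default [default_requirements()]).
#' @param reference_dose isodose reference (Gy); the default 76.2 Gy makes
#'   V_95% the volume above 72.4 Gy.
#' @param oar OAR structure name for the isodose volumes.
#' @return a `plan_score` with attributes `s_d`, `rectum_v`, `ctv_d99`.
#' @export
evaluate_plan <- function(dose, ss, requirements = default_requirements(),
                          reference_dose = 76.2, oar = "OAR") {
  wanted <- unique(requirements$structure)
  present <- vapply(wanted, function(s)
    all(parse_structure_expr(s) %in% structure_names(ss)), logical(1))
  if (!any(present)) stop("no scored structure present in the structure set")
  requirements <- requirements[present[requirements$structure], ]
  dvh <- compute_dvh(dose, ss, unique(c(wanted[present],
                                        intersect(c(oar, "CTV"), structure_names(ss)))))
  achieved <- purrr::map_dfr(unique(requirements$structure), function(s) {
    mets <- dvh_metrics(dvh, s, d_pct = c(99, 95, 1))
    tibble::tibble(structure = s, metric = mets$metric, value = mets$value)
  })
  score <- s_d_score(achieved, requirements)
  if (oar %in% structure_names(ss)) {
    rv <- dvh_metrics(dvh, oar, d_pct = 99, v_pct = c(95, 80, 50),
                      reference_dose = reference_dose)
    attr(score, "rectum_v") <- stats::setNames(
      rv$value[match(c("V_95%", "V_80%", "V_50%"), rv$metric)],
      c("V_95%", "V_80%", "V_50%"))
  }
  if ("CTV" %in% structure_names(ss)) {
    attr(score, "ctv_d99") <-
      dvh_metrics(dvh, "CTV", d_pct = 99)$value[2]
  }
  score
}
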