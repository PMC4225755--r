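# One-tailed Wilcoxon signed-rank test for paired plan scores, with the
# exact null distribution. Zero differences are dropped, tied absolute
# differences receive midranks, and the exact p-value enumerates the sign
# assignments via the generating-function (dynamic-programming) recursion,
# which is feasible for any cohort size; a Gaussian approximation with
# tie-corrected variance is reported alongside, since published p-values
# for small cohorts commonly come from that approximation.

#' One-tailed Wilcoxon signed-rank test
#'
#' Tests the alternative `a < b` on paired values: differences `d = a - b`,
#' zeros dropped, midranks for ties, `W+` the rank sum of positive
#' differences. Small `W+` favours the alternative; the exact p-value is
#' `P(W+ <= w_obs)` under random signs.
#'
#' @param a,b paired numeric vectors.
#' @return tibble: n (pairs used), w_plus, p_exact, p_normal,
#'   all_zero flag.
#' @export
wilcoxon_signed_rank_1tail <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    return(tibble::tibble(n = 0L, w_plus = 0, p_exact = 1, p_normal = 1,
                          all_zero = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  m <- length(d)
  # exact: distribution of W+ over the 2^m sign assignments by convolution
  # on twice the ranks (midranks are multiples of 1/2)
  s <- as.integer(round(2 * r))
  total <- sum(s)
  f <- numeric(total + 1)   # f[w + 1] = #assignments with 2*W+ = w
  f[1] <- 1
  for (si in s) {
    g <- numeric(total + 1)
    g[(si + 1):(total + 1)] <- f[1:(total + 1 - si)]
    f <- f + g
  }
  w2 <- as.integer(round(2 * w_plus))
  p_exact <- sum(f[1:(w2 + 1)]) / 2^m
  mu <- m * (m + 1) / 4
  sigma <- sqrt(sum(r^2) / 4)
  p_normal <- stats::pnorm((w_plus - mu) / sigma)
  tibble::tibble(n = m, w_plus = w_plus, p_exact = p_exact,
                 p_normal = p_normal, all_zero = FALSE)
}

#' Pairwise cohort comparison of plan groups
#'
#' Runs the three one-tailed comparisons on the quality score S_D and the
#' rectum V_95%: adapted against relocated (alternative: adapted smaller),
#' native against adapted, and native against relocated.
#'
#' @param scores tibble with columns case, group (one of "relocated",
#'   "native", "adapted"), s_d, v95; every case must appear in every group.
#' @param alpha significance level for the flag column.
#' @return tibble: comparison, metric, n, w_plus, p_exact, p_normal,
#'   significant (p_normal < alpha).
#' @export
compare_cohort <- function(scores, alpha = 0.05) {
  stopifnot(all(c("case", "group", "s_d", "v95") %in% names(scores)))
  groups <- c("relocated", "native", "adapted")
  stopifnot(all(scores$group %in% groups))
  wide <- tidyr::pivot_wider(scores, id_cols = "case", names_from = "group",
                             values_from = c("s_d", "v95"))
  if (anyNA(wide)) stop("every case must appear in every group")
  comps <- list(
    c("adapted", "relocated"),
    c("native", "adapted"),
    c("native", "relocated")
  )
  purrr::map_dfr(comps, function(cp) {
    purrr::map_dfr(c(s_d = "s_d", v95 = "v95"), function(metric) {
      a <- wide[[paste0(metric, "_", cp[1])]]
      b <- wide[[paste0(metric, "_", cp[2])]]
      w <- wilcoxon_signed_rank_1tail(a, b)
      tibble::tibble(comparison = paste(cp[1], "against", cp[2]),
                     metric = metric, n = w$n, w_plus = w$w_plus,
                     p_exact = w$p_exact, p_normal = w$p_normal,
                     significant = w$p_normal < alpha)
    })
  })
}
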