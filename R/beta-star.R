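# Optimal compensation strips for the concentric blocked-rotation model.
# For a central block of normalized radius rho_oar and a target annulus
# rho in [rho_oar + gamma, 1], the composite radial dose is
# D(rho) = D_S1(rho) + omega * D_S2(rho; beta). The pair (omega_opt,
# beta_opt) minimizes the homogeneity objective
#   f^2 = sigma_D^2 + (Dbar - D0)^2 = <(D - D0)^2>,
# the area-weighted (2 pi rho drho) mean square deviation from the
# prescribed level D0, taken here as the mean of an unblocked rotation
# (D0 = 1). The product beta* = omega_opt * beta_opt characterizes the
# optimum and depends only weakly on the gap gamma; sampled over a
# (gamma, rho_oar) grid and fitted with a fourth-order polynomial in
# rho_oar it provides the lookup used at segment generation and at
# MU-preserving width adaptation (where omega is frozen, so beta* reduces
# to beta_opt at omega = 1).

# area-weighted integration nodes over the target annulus
annulus_nodes <- function(rho_oar, gamma, n = 400) {
  lo <- rho_oar + gamma
  stopifnot(lo < 1)
  rho <- seq(lo, 1, length.out = n)
  w <- rho / sum(rho)
  list(rho = rho, w = w)
}

# f^2 as a function of (omega, beta); quadratic in omega, so the moments
# a + 2 b omega + c omega^2 are exposed for profile minimization
f2_moments <- function(beta, rho_oar, gamma, nodes) {
  s1 <- radial_dose_closed_form(nodes$rho, rho_oar, component = "S1")
  s2 <- radial_dose_closed_form(nodes$rho, rho_oar, beta, component = "S2")
  e <- s1 - 1
  list(a = sum(nodes$w * e^2), b = sum(nodes$w * e * s2),
       c = sum(nodes$w * s2^2))
}

f2_value <- function(omega, beta, rho_oar, gamma, nodes) {
  m <- f2_moments(beta, rho_oar, gamma, nodes)
  m$a + 2 * m$b * omega + m$c * omega^2
}

#' Optimal compensation strip weight and width
#'
#' Minimizes the target-homogeneity objective f^2 over the strip weight
#' omega and normalized width beta (joint mode), or over beta alone at a
#' frozen omega (the MU-preserving adaptation setting).
#'
#' The exposure-fraction model has no penumbra, so an unconstrained joint
#' search degenerates into the narrow-strip valley (beta -> 0,
#' omega -> infinity with the product omega * beta nearly constant), which
#' no MLC can deliver. The joint search therefore runs over the deliverable
#' box `omega in omega_range` and `beta in [0.005, min(0.3, 1 - rho_oar)]`:
#' a coarse beta scan with the profile-optimal (box-clamped) omega at each
#' width — f^2 is exactly quadratic in omega — followed by a bounded
#' quasi-Newton polish.
#'
#' @param rho_oar normalized OAR radius, 0 < rho_oar < 1.
#' @param gamma normalized OAR-target gap, 0 <= gamma <= 1 - rho_oar.
#' @param fixed_omega `NULL` for the joint search, or the frozen omega.
#' @param omega_range joint-search bounds on the strip weight.
#' @param n integration nodes over the target annulus.
#' @return list: omega_opt, beta_opt, beta_star (= omega_opt * beta_opt),
#'   f2_min, f2_s1 (the no-strip value), converged.
#' @export
optimize_beta_omega <- function(rho_oar, gamma, fixed_omega = NULL,
                                omega_range = c(0.2, 3), n = 400) {
  stopifnot(rho_oar > 0, rho_oar < 1, gamma >= 0, rho_oar + gamma < 1)
  nodes <- annulus_nodes(rho_oar, gamma, n)
  f2_s1 <- f2_value(0, 1e-3, rho_oar, gamma, nodes)
  beta_lim <- c(0.005, min(0.3, 1 - rho_oar))
  if (is.null(fixed_omega)) {
    prof <- function(beta) {
      m <- f2_moments(beta, rho_oar, gamma, nodes)
      om <- min(max(-m$b / m$c, omega_range[1]), omega_range[2])
      c(m$a + 2 * m$b * om + m$c * om^2, om)
    }
    bs <- seq(beta_lim[1], beta_lim[2], length.out = 120)
    scan <- vapply(bs, prof, numeric(2))
    i0 <- which.min(scan[1, ])
    # golden-section refinement of the profile around the best scan node
    # (exact in omega: f^2 is quadratic there), then a bounded polish
    lo <- bs[max(1, i0 - 1)]; hi <- bs[min(length(bs), i0 + 1)]
    ref <- stats::optimize(function(b) prof(b)[1], c(lo, hi), tol = 1e-8)
    cand <- list(c(scan[1, i0], scan[2, i0], bs[i0]),
                 c(ref$objective, prof(ref$minimum)[2], ref$minimum))
    pol <- stats::optim(c(cand[[2]][2], cand[[2]][3]),
                        function(p) f2_value(p[1], p[2], rho_oar, gamma, nodes),
                        method = "L-BFGS-B",
                        lower = c(omega_range[1], beta_lim[1]),
                        upper = c(omega_range[2], beta_lim[2]))
    cand <- c(cand, list(c(pol$value, pol$par[1], pol$par[2])))
    best <- cand[[which.min(vapply(cand, `[`, numeric(1), 1))]]
    f2 <- best[1]; omega_opt <- best[2]; beta_opt <- best[3]
    conv <- pol$convergence == 0
  } else {
    ob <- stats::optimize(function(b) f2_value(fixed_omega, b, rho_oar, gamma, nodes),
                          c(1e-5, 1 - rho_oar), tol = 1e-7)
    omega_opt <- fixed_omega; beta_opt <- ob$minimum; f2 <- ob$objective
    conv <- TRUE
  }
  list(omega_opt = omega_opt, beta_opt = beta_opt,
       beta_star = omega_opt * beta_opt, f2_min = f2, f2_s1 = f2_s1,
       converged = conv)
}

#' Build the beta*(gamma, rho_oar) lookup table
#'
#' Samples the optimum over a (gamma, rho_oar) grid in both modes
#' (generation: joint omega-beta optimum; adapt: beta optimum at omega = 1)
#' and fits, per gamma node and mode, a fourth-order polynomial in rho_oar
#' through the origin (beta*(gamma, 0) = 0: no block, nothing to
#' compensate). Evaluation interpolates linearly across gamma.
#'
#' @param rho_grid grid of normalized OAR radii.
#' @param gamma_grid grid of normalized gaps.
#' @param n integration nodes per optimization.
#' @return a `beta_star_table`.
#' @export
build_beta_star_table <- function(rho_grid = seq(0.05, 0.6, by = 0.05),
                                  gamma_grid = c(0, 0.1, 0.2, 0.3),
                                  n = 400) {
  grid <- purrr::map_dfr(gamma_grid, function(g) purrr::map_dfr(rho_grid, function(r) {
    if (r + g >= 0.95) return(NULL)
    gen <- optimize_beta_omega(r, g, n = n)
    ad <- optimize_beta_omega(r, g, fixed_omega = 1, n = n)
    tibble::tibble(gamma = g, rho_oar = r,
                   omega_opt = gen$omega_opt, beta_opt = gen$beta_opt,
                   beta_star_gen = gen$beta_star, beta_star_adapt = ad$beta_star,
                   f2_min = gen$f2_min, f2_s1 = gen$f2_s1)
  }))
  fits <- purrr::map_dfr(unique(grid$gamma), function(g) {
    sub <- grid[grid$gamma == g, ]
    purrr::map_dfr(c("generation", "adapt"), function(mode) {
      y <- if (mode == "generation") sub$beta_star_gen else sub$beta_star_adapt
      X <- stats::poly(sub$rho_oar, degree = 4, raw = TRUE)
      # no intercept (beta*(gamma, 0) = 0); weights 1/y^2 keep the
      # *relative* residual small across the dynamic range
      fit <- stats::lm.wfit(X, y, w = 1 / y^2)
      pred <- X %*% fit$coefficients
      tibble::tibble(gamma = g, mode = mode,
                     coef = list(unname(fit$coefficients)),
                     max_rel_residual = max(abs(pred - y) / pmax(y, 1e-9)))
    })
  })
  worst <- max(fits$max_rel_residual)
  if (worst > 0.05)
    warning(sprintf("beta* polynomial fit residual %.1f%% exceeds 5%%",
                    100 * worst))
  structure(list(grid = grid, fits = fits,
                 rho_range = range(grid$rho_oar),
                 gamma_range = range(grid$gamma),
                 settings = list(n_nodes = n, d0 = 1, model = "exposure-fraction")),
            class = "beta_star_table")
}

#' Evaluate beta* from a table
#'
#' Fourth-order polynomial in rho_oar at the bracketing gamma nodes, linear
#' interpolation across gamma. Arguments outside the table domain are
#' clamped to its boundary with a warning.
#'
#' @param table a `beta_star_table`.
#' @param gamma,rho_oar normalized geometry (vectorized over rho_oar).
#' @param mode `"generation"` (joint optimum) or `"adapt"` (frozen omega).
#' @param quiet suppress the clamping warning (callers looping over leaf
#'   pairs summarize it once instead); the `"clamped"` attribute reports
#'   which entries were clamped either way.
#' @return beta* values.
#' @export
beta_star_eval <- function(table, gamma, rho_oar,
                           mode = c("generation", "adapt"), quiet = FALSE) {
  mode <- match.arg(mode)
  if (length(gamma) == 1 && length(rho_oar) > 1) gamma <- rep(gamma, length(rho_oar))
  gamma[is.na(gamma)] <- table$gamma_range[1]
  out_of <- rho_oar < table$rho_range[1] - 1e-9 |
    rho_oar > table$rho_range[2] + 1e-9 |
    gamma < table$gamma_range[1] - 1e-9 | gamma > table$gamma_range[2] + 1e-9
  if (any(out_of) && !quiet)
    warning("geometry outside beta* table domain; clamped to boundary")
  rho <- pmin(pmax(rho_oar, table$rho_range[1]), table$rho_range[2])
  gam <- pmin(pmax(gamma, table$gamma_range[1]), table$gamma_range[2])
  fits <- table$fits[table$fits$mode == mode, ]
  gnodes <- sort(unique(fits$gamma))
  eval_at <- function(g, r) {
    cf <- fits$coef[[which(fits$gamma == g)]]
    sum(cf * r^(1:4))
  }
  out <- vapply(seq_along(rho), function(i) {
    g <- gam[i]; r <- rho[i]
    i_hi <- findInterval(g, gnodes, rightmost.closed = TRUE) + 1L
    i_hi <- min(max(i_hi, 2L), length(gnodes))
    g_lo <- gnodes[i_hi - 1L]; g_hi <- gnodes[i_hi]
    t <- if (g_hi > g_lo) (g - g_lo) / (g_hi - g_lo) else 0
    (1 - t) * eval_at(g_lo, r) + t * eval_at(g_hi, r)
  }, numeric(1))
  attr(out, "clamped") <- out_of
  out
}

#' @export
print.beta_star_table <- function(x, ...) {
  cat(sprintf("<beta_star_table> %d grid points, rho_oar in [%g, %g], gamma in [%g, %g]\n",
              nrow(x$grid), x$rho_range[1], x$rho_range[2],
              x$gamma_range[1], x$gamma_range[2]))
  cat(sprintf("  max relative fit residual: %.2f%%\n",
              100 * max(x$fits$max_rel_residual)))
  invisible(x)
}

#' @method tidy beta_star_table
#' @export
tidy.beta_star_table <- function(x, ...) x$grid

#' @method glance beta_star_table
#' @export
glance.beta_star_table <- function(x, ...) {
  tibble::tibble(n_grid = nrow(x$grid),
                 rho_min = x$rho_range[1], rho_max = x$rho_range[2],
                 gamma_min = x$gamma_range[1], gamma_max = x$gamma_range[2],
                 max_rel_residual = max(x$fits$max_rel_residual))
}

#' Plot beta* against rho_oar per gamma
#' @param object a `beta_star_table`.
#' @param ... unused.
#' @method autoplot beta_star_table
#' @export
autoplot.beta_star_table <- function(object, ...) {
  g <- tidyr::pivot_longer(object$grid, c("beta_star_gen", "beta_star_adapt"),
                           names_to = "mode", values_to = "beta_star")
  ggplot2::ggplot(g, ggplot2::aes(.data$rho_oar, .data$beta_star,
                                  colour = factor(.data$gamma))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = expression(rho[OAR]), y = expression(beta * "*"),
                  colour = expression(gamma)) +
    ggplot2::theme_minimal()
}

#' Serialize a beta* table to JSON
#' @param table a `beta_star_table`.
#' @param path output file.
#' @export
write_beta_star_table <- function(table, path) {
  obj <- list(grid = table$grid,
              fits = lapply(seq_len(nrow(table$fits)), function(i) list(
                gamma = table$fits$gamma[i], mode = table$fits$mode[i],
                coef = table$fits$coef[[i]],
                max_rel_residual = table$fits$max_rel_residual[i])),
              rho_range = table$rho_range, gamma_range = table$gamma_range,
              settings = table$settings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a beta* table written by [write_beta_star_table()]
#' @param path JSON file.
#' @export
read_beta_star_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fits <- purrr::map_dfr(obj$fits, function(f) tibble::tibble(
    gamma = f$gamma, mode = f$mode, coef = list(unlist(f$coef)),
    max_rel_residual = f$max_rel_residual))
  grid <- tibble::as_tibble(lapply(obj$grid, unlist))
  structure(list(grid = grid, fits = fits,
                 rho_range = unlist(obj$rho_range),
                 gamma_range = unlist(obj$gamma_range),
                 settings = obj$settings),
            class = "beta_star_table")
}
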