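# Run configuration: prescriptions, margins, beam layout, MLC, optimizer
# settings, beta*-table grid, requirement set and seed, validated on
# construction and loadable from YAML.

#' Run configuration
#'
#' Defaults follow the simultaneous-integrated-boost prostate protocol:
#' 60.1 Gy to the PTV and 74 Gy to the Boost in 33 fractions, CTV-to-PTV
#' margin 10 mm limited to 7 mm posteriorly, CTV-to-Boost margin 5 mm with
#' no rectum overlap, a 4 mm-leaf MLC, 36 equispaced coplanar beams, 25
#' weight-optimization steps, and V_95% referenced to 76.2 Gy.
#'
#' @param prescriptions named prescription vector (Gy).
#' @param fractions fraction count.
#' @param margins list: ptv_mm, ptv_posterior_mm, boost_mm.
#' @param mlc list: leaf_width_mm, field_half_mm.
#' @param beams gantry angles (degrees).
#' @param omega generation-time weight of the compensation strips relative
#'   to the sparing segments.
#' @param block_margin_mm extra opening margin around the OAR shadow (mm).
#' @param weights initial MU weights: s0, s1 and a per-target factor.
#' @param optimizer list: iterations (weight steps), step_mm (leaf step),
#'   leaf_sweeps (fine-tuning sweeps).
#' @param table_grid list: rho (grid of normalized OAR radii), gamma.
#' @param requirements required dose ranges for scoring.
#' @param objectives fine-tuning objective tibble; `NULL` picks
#'   [default_objectives()] or [phantom_objectives()] by target names.
#' @param reference_dose isodose reference for V_p% (Gy).
#' @param dose_resolution dose sampling step (mm).
#' @param oar OAR structure name.
#' @param seed RNG seed for everything stochastic downstream.
#' @return a validated `run_config` list.
#' @export
run_config <- function(prescriptions = c(PTV = 60.1, Boost = 74),
                       fractions = 33,
                       margins = list(ptv_mm = 10, ptv_posterior_mm = 7,
                                      boost_mm = 5),
                       mlc = list(leaf_width_mm = 4, field_half_mm = 200),
                       beams = seq(0, 350, by = 10),
                       omega = 1,
                       block_margin_mm = 0,
                       weights = list(s0 = 1, s1 = 1, target = NULL),
                       optimizer = list(iterations = 25, step_mm = 2,
                                        leaf_sweeps = 2),
                       table_grid = list(rho = seq(0.05, 0.6, by = 0.05),
                                         gamma = c(0, 0.1, 0.2, 0.3)),
                       requirements = default_requirements(),
                       objectives = NULL,
                       reference_dose = 76.2,
                       dose_resolution = 2,
                       oar = "OAR",
                       seed = 1L) {
  cfg <- list(prescriptions = prescriptions, fractions = fractions,
              margins = margins, mlc = mlc, beams = beams, omega = omega,
              block_margin_mm = block_margin_mm, weights = weights,
              optimizer = optimizer, table_grid = table_grid,
              requirements = requirements, objectives = objectives,
              reference_dose = reference_dose,
              dose_resolution = dose_resolution, oar = oar, seed = seed)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- c("prescriptions", "fractions", "margins", "mlc", "beams", "omega",
             "block_margin_mm", "weights", "optimizer", "table_grid",
             "requirements", "objectives", "reference_dose",
             "dose_resolution", "oar", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stopifnot(length(cfg$prescriptions) >= 1, all(cfg$prescriptions > 0),
            !is.null(names(cfg$prescriptions)),
            cfg$fractions >= 1,
            all(unlist(cfg$margins) >= 0),
            cfg$mlc$leaf_width_mm > 0,
            length(cfg$beams) >= 1,
            cfg$omega > 0, cfg$block_margin_mm >= 0,
            cfg$optimizer$iterations >= 0, cfg$optimizer$step_mm > 0,
            cfg$reference_dose > 0, cfg$dose_resolution > 0)
  if (any(duplicated(cfg$beams %% 360))) stop("duplicated beam angles")
  if (is.null(cfg$weights$target))
    cfg$weights$target <- as.list(stats::setNames(
      rep(1, length(cfg$prescriptions)), names(cfg$prescriptions)))
  if (is.null(cfg$objectives)) {
    cfg$objectives <- if (all(c("PTV", "Boost") %in% names(cfg$prescriptions)))
      default_objectives(cfg$prescriptions) else
        phantom_objectives(max(cfg$prescriptions))
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#' Requirements and objectives may be given as records with the same
#' columns as their tibble forms.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$prescriptions)) y$prescriptions <- unlist(y$prescriptions)
  if (!is.null(y$beams)) y$beams <- as.numeric(unlist(y$beams))
  if (!is.null(y$requirements))
    y$requirements <- purrr::map_dfr(y$requirements, function(r)
      tibble::tibble(structure = r$structure, metric = r$metric,
                     lo = r$lo %||% NA_real_, up = r$up %||% NA_real_))
  if (!is.null(y$objectives))
    y$objectives <- purrr::map_dfr(y$objectives, function(o)
      objective(o$structure, o$kind, o$dose_Gy, o$weight %||% 1,
                o$volume_fraction %||% NA_real_))
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}
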