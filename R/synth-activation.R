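#' Configuration for the critical-pressure generator
#'
#' Describes a stepped aspiration protocol on cells whose latent activation
#' threshold follows a logistic (Boltzmann) law around the line
#' `p50(F) = intercept_a0 + slope_beta * F`.  During the protocol the
#' aspiration pressure is raised in discrete increments, so the observed
#' critical pressure is the first protocol step at or above the latent
#' threshold; cells that never respond below `p_max` are censored.
#'
#' @param forces indentation forces (nN), all > 0.
#' @param n_per_force number of cells per force (scalar or one per force).
#' @param intercept_a0 half-activation pressure at F = 0 (mbar).
#' @param slope_beta d p50 / dF (mbar/nN), typically negative.
#' @param width_b Boltzmann width b (mbar), > 0.
#' @param pressure_step protocol pressure increment (mbar), default 25.
#' @param p_max censoring pressure (mbar), default 400.
#' @param treatment treatment label stored with each record.
#' @param seed RNG seed.
#' @return an object of class `activation_gen_config`.
#' @export
activation_gen_config <- function(forces, n_per_force, intercept_a0,
                                  slope_beta, width_b,
                                  pressure_step = 25, p_max = 400,
                                  treatment = "Ctrl", seed = NULL) {
  if (!is.numeric(forces) || length(forces) < 1L || any(forces <= 0))
    stop("'forces' must be positive", call. = FALSE)
  n_per_force <- as.integer(rep_len(n_per_force, length(forces)))
  if (any(n_per_force < 1L)) stop("'n_per_force' must be >= 1", call. = FALSE)
  stopifnot_scalar(intercept_a0, "intercept_a0")
  stopifnot_scalar(slope_beta, "slope_beta")
  stopifnot_scalar(width_b, "width_b", positive = TRUE)
  stopifnot_scalar(pressure_step, "pressure_step", positive = TRUE)
  stopifnot_scalar(p_max, "p_max", positive = TRUE)
  if (intercept_a0 + slope_beta * max(forces) <= 0)
    stop("mean activation pressure is non-positive at the largest force",
         call. = FALSE)
  structure(list(forces = forces, n_per_force = n_per_force,
                 intercept_a0 = intercept_a0, slope_beta = slope_beta,
                 width_b = width_b, pressure_step = pressure_step,
                 p_max = p_max, treatment = treatment, seed = seed),
            class = "activation_gen_config")
}

#' Generate per-cell critical aspiration pressures
#'
#' For each force F, draws latent thresholds
#' `p_raw = a0 + beta*F + b*log(u/(1-u))`, `u ~ U(0,1)`, and snaps them UP to
#' the next multiple of `pressure_step` (the first protocol step reaching the
#' threshold).  Draws above `p_max` are kept but flagged censored.
#'
#' @param cfg an [activation_gen_config()].
#' @return a data.frame of cell records with columns `cell_id`, `treatment`,
#'   `force_nN`, `p_crit_mbar`, `censored`, `seed`.
#' @export
generate_critical_pressures <- function(cfg) {
  stopifnot(inherits(cfg, "activation_gen_config"))
  with_seed(cfg$seed, {
    recs <- lapply(seq_along(cfg$forces), function(i) {
      F <- cfg$forces[i]
      n <- cfg$n_per_force[i]
      u <- stats::runif(n)
      p_raw <- cfg$intercept_a0 + cfg$slope_beta * F +
        cfg$width_b * log(u / (1 - u))
      p_snap <- cfg$pressure_step * ceiling(p_raw / cfg$pressure_step)
      p_snap <- pmax(p_snap, cfg$pressure_step)  # protocol starts at one step
      data.frame(force_nN = F, p_crit_mbar = p_snap,
                 censored = p_raw > cfg$p_max)
    })
    out <- do.call(rbind, recs)
    out$cell_id <- sprintf("cell_%04d", seq_len(nrow(out)))
    out$treatment <- cfg$treatment
    out$seed <- if (is.null(cfg$seed)) NA_integer_ else cfg$seed
    out[, c("cell_id", "treatment", "force_nN", "p_crit_mbar",
            "censored", "seed")]
  })
}
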