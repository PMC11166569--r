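#' Configuration for the force-curve generator
#'
#' Approach segment of an AFM force-spectroscopy curve on a cell: zero force
#' until the contact offset, then Hertzian loading for a spherical tip
#' (`F = (4/3) E/(1-nu^2) sqrt(R) d^(3/2)`) or linear loading for a flat
#' cylindrical punch (`F = 2 E/(1-nu^2) a d`), with Gaussian force noise.
#' Units: E in Pa, lengths in um, forces in nN.
#'
#' @param E_true elastic modulus (Pa), > 0.
#' @param nu Poisson ratio, default 0.5 (incompressible cell).
#' @param tip `"sphere"` or `"punch"`.
#' @param tip_radius_um sphere radius R or punch radius a (um); default 1,
#'   matching a 2-um cylindrical probe.
#' @param contact_offset_um piezo position of first contact (um).
#' @param max_indentation_um maximum indentation depth (um), > 0.
#' @param noise_sd force noise SD (nN).
#' @param n_points samples along the curve.
#' @param approach_speed_um_s approach speed metadata (um/s), default 1.
#' @param seed RNG seed.
#' @return an object of class `hertz_gen_config`.
#' @export
hertz_gen_config <- function(E_true = 1000, nu = 0.5, tip = c("sphere", "punch"),
                             tip_radius_um = 1, contact_offset_um = 1,
                             max_indentation_um = 1, noise_sd = 0,
                             n_points = 200, approach_speed_um_s = 1,
                             seed = NULL) {
  tip <- match.arg(tip)
  stopifnot_scalar(E_true, "E_true", positive = TRUE)
  if (nu < 0 || nu > 0.5) stop("'nu' must lie in [0, 0.5]", call. = FALSE)
  stopifnot_scalar(max_indentation_um, "max_indentation_um", positive = TRUE)
  stopifnot_scalar(tip_radius_um, "tip_radius_um", positive = TRUE)
  structure(list(E_true = E_true, nu = nu, tip = tip,
                 tip_radius_um = tip_radius_um,
                 contact_offset_um = contact_offset_um,
                 max_indentation_um = max_indentation_um,
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 approach_speed_um_s = approach_speed_um_s, seed = seed),
            class = "hertz_gen_config")
}

## Hertz / punch force law, F in nN for E [Pa], lengths [um]
hertz_force <- function(delta_um, E, nu, tip, radius_um) {
  delta_um <- pmax(delta_um, 0)
  if (tip == "sphere") {
    (4 / 3) * E / (1 - nu^2) * sqrt(radius_um) * delta_um^1.5 * PA_UM2_TO_NN
  } else {
    2 * E / (1 - nu^2) * radius_um * delta_um * PA_UM2_TO_NN
  }
}

#' Generate a synthetic force--indentation curve
#'
#' @param cfg a [hertz_gen_config()].
#' @return a `force_curve`: data.frame with `position_um`, `force_nN`, and
#'   attributes `config` (generator truth) carried in `attr(x, "config")`.
#' @export
generate_force_curve <- function(cfg) {
  stopifnot(inherits(cfg, "hertz_gen_config"))
  z <- seq(0, cfg$contact_offset_um + cfg$max_indentation_um,
           length.out = cfg$n_points)
  F <- hertz_force(z - cfg$contact_offset_um, cfg$E_true, cfg$nu,
                   cfg$tip, cfg$tip_radius_um)
  with_seed(cfg$seed, {
    if (cfg$noise_sd > 0) F <- F + stats::rnorm(length(F), sd = cfg$noise_sd)
    out <- data.frame(position_um = z, force_nN = F)
    attr(out, "config") <- cfg
    class(out) <- c("force_curve", class(out))
    out
  })
}
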