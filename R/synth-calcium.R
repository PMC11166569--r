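#' Configuration for the calcium-movie generator
#'
#' Emulates widefield calcium imaging of a single stimulated cell: a
#' radially expanding intensity front (responder), optional red-channel dye
#' entry (membrane rupture), Gaussian pixel noise, 50-ms frames by default.
#'
#' @param frames,ny,nx movie dimensions.
#' @param pixel_size_um pixel size (um).
#' @param frame_interval_s frame interval (s), default 0.05.
#' @param origin stimulation-site pixel, `c(row, col)` 1-based.
#' @param wave_speed_um_s front propagation speed (um/s), >= 0.  Default is
#'   the measured cytosolic calcium wave speed of 22.4 um/s.
#' @param onset_frame first frame of the response.
#' @param baseline_level mean resting intensity.
#' @param response_fold peak/baseline fold change behind the front (>= 1).
#' @param rise_width_um optional Gaussian softening of the front edge (um).
#' @param noise_sd Gaussian noise standard deviation.
#' @param responder does the cell respond at all?
#' @param rupture add a red channel ramping up inside the cell mask after
#'   `onset_frame` (dye entry through a ruptured membrane).
#' @param cell_radius_um radius of the circular cell mask around `origin`
#'   used for rupture dye entry; `Inf` means the whole frame.
#' @param seed RNG seed.
#' @return an object of class `calcium_movie_config`.
#' @export
calcium_movie_config <- function(frames = 120, ny = 60, nx = 60,
                                 pixel_size_um = 1, frame_interval_s = 0.05,
                                 origin = c(ceiling(ny / 2), ceiling(nx / 2)),
                                 wave_speed_um_s = 22.4, onset_frame = 20,
                                 baseline_level = 100, response_fold = 4,
                                 rise_width_um = 0, noise_sd = 0,
                                 responder = TRUE, rupture = FALSE,
                                 cell_radius_um = Inf, seed = NULL) {
  stopifnot_scalar(wave_speed_um_s, "wave_speed_um_s", nonneg = TRUE)
  stopifnot_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (response_fold < 1) stop("'response_fold' must be >= 1", call. = FALSE)
  if (origin[1L] < 1 || origin[1L] > ny || origin[2L] < 1 || origin[2L] > nx)
    stop("'origin' lies outside the frame", call. = FALSE)
  structure(list(frames = as.integer(frames), ny = as.integer(ny),
                 nx = as.integer(nx), pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, origin = origin,
                 wave_speed_um_s = wave_speed_um_s,
                 onset_frame = as.integer(onset_frame),
                 baseline_level = baseline_level,
                 response_fold = response_fold,
                 rise_width_um = rise_width_um, noise_sd = noise_sd,
                 responder = isTRUE(responder), rupture = isTRUE(rupture),
                 cell_radius_um = cell_radius_um, seed = seed),
            class = "calcium_movie_config")
}

#' Generate a synthetic calcium movie
#'
#' @param cfg a [calcium_movie_config()].
#' @return a `calcium_movie`: list with `green` (and `red` if rupture)
#'   arrays of dim `frames x ny x nx`, plus `pixel_size_um`,
#'   `frame_interval_s`, `origin` and the generating `config`.
#' @export
generate_calcium_movie <- function(cfg) {
  stopifnot(inherits(cfg, "calcium_movie_config"))
  d_um <- pixel_distances(cfg$ny, cfg$nx, cfg$origin) * cfg$pixel_size_um
  cellmask <- d_um <= cfg$cell_radius_um
  with_seed(cfg$seed, {
    green <- array(cfg$baseline_level, c(cfg$frames, cfg$ny, cfg$nx))
    if (cfg$responder && cfg$response_fold > 1) {
      for (k in seq_len(cfg$frames)) {
        if (k < cfg$onset_frame) next
        r <- cfg$wave_speed_um_s * (k - cfg$onset_frame) * cfg$frame_interval_s
        act <- if (cfg$rise_width_um > 0) {
          stats::pnorm(r - d_um, sd = cfg$rise_width_um)
        } else {
          (d_um <= r) * 1
        }
        green[k, , ] <- cfg$baseline_level *
          (1 + (cfg$response_fold - 1) * act)
      }
    }
    if (cfg$noise_sd > 0)
      green <- green + stats::rnorm(length(green), sd = cfg$noise_sd)
    out <- list(green = green, pixel_size_um = cfg$pixel_size_um,
                frame_interval_s = cfg$frame_interval_s,
                origin = cfg$origin, config = cfg)
    if (cfg$rupture) {
      red <- array(0, c(cfg$frames, cfg$ny, cfg$nx))
      for (k in seq_len(cfg$frames)) {
        if (k < cfg$onset_frame) next
        lvl <- cfg$baseline_level *
          min(1, (k - cfg$onset_frame + 1) / 10)  # dye fills over ~10 frames
        red[k, , ][cellmask] <- lvl
      }
      if (cfg$noise_sd > 0)
        red <- red + stats::rnorm(length(red), sd = cfg$noise_sd)
      out$red <- red
    }
    class(out) <- "calcium_movie"
    out
  })
}
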