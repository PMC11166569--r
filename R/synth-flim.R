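#' Configuration for the FLIM scene generator
#'
#' Emulates lifetime imaging of a tension-probe-loaded membrane while a
#' hollow cylindrical pipette (2-um aperture) indents or aspirates the cell:
#' the probe lifetime rises by `tau_site_delta` per stimulus step inside an
#' annulus marking the pipette rim.
#'
#' @param ny,nx image dimensions (pixels).
#' @param pixel_size_um pixel size (um).
#' @param tau_base resting long-component lifetime (ns).
#' @param tau_site_delta lifetime increase per stimulus step at the site (ns).
#' @param site_center annulus center `c(row, col)`, 1-based.
#' @param site_radius_um annulus radius (um), default 1 (the pipette rim).
#' @param site_width_um annulus width (um).
#' @param photons_per_pixel expected signal photons per pixel (>= 1);
#'   default 1000, the minimum for a statistically valid per-pixel fit.
#' @param tau_short,frac_long,irf_fwhm,window,n_bins decay model passed to
#'   the per-pixel TCSPC generator.
#' @param n_steps number of stimulus steps to render (one image per step,
#'   step 0 = unstimulated reference).
#' @param seed RNG seed.
#' @return an object of class `flim_scene_config`.
#' @export
flim_scene_config <- function(ny = 24, nx = 24, pixel_size_um = 0.1,
                              tau_base = 5.0, tau_site_delta = 0.1,
                              site_center = c(ceiling(ny / 2), ceiling(nx / 2)),
                              site_radius_um = 1, site_width_um = 0.3,
                              photons_per_pixel = 1000, tau_short = 2.0,
                              frac_long = 0.7, irf_fwhm = 0.2, window = 25,
                              n_bins = 128, n_steps = 1, seed = NULL) {
  stopifnot_scalar(photons_per_pixel, "photons_per_pixel", positive = TRUE)
  stopifnot_scalar(tau_base, "tau_base", positive = TRUE)
  rmax_px <- (site_radius_um + site_width_um / 2) / pixel_size_um
  if (site_center[1L] - rmax_px < 1 || site_center[1L] + rmax_px > ny ||
      site_center[2L] - rmax_px < 1 || site_center[2L] + rmax_px > nx)
    stop("site annulus does not lie inside the frame", call. = FALSE)
  structure(list(ny = as.integer(ny), nx = as.integer(nx),
                 pixel_size_um = pixel_size_um, tau_base = tau_base,
                 tau_site_delta = tau_site_delta, site_center = site_center,
                 site_radius_um = site_radius_um,
                 site_width_um = site_width_um,
                 photons_per_pixel = photons_per_pixel,
                 tau_short = tau_short, frac_long = frac_long,
                 irf_fwhm = irf_fwhm, window = window,
                 n_bins = as.integer(n_bins), n_steps = as.integer(n_steps),
                 seed = seed),
            class = "flim_scene_config")
}

#' Annulus mask for a FLIM scene
#' @param cfg a [flim_scene_config()].
#' @return logical ny x nx matrix, TRUE inside the pipette-rim annulus.
#' @export
flim_site_mask <- function(cfg) {
  d_um <- pixel_distances(cfg$ny, cfg$nx, cfg$site_center) * cfg$pixel_size_um
  abs(d_um - cfg$site_radius_um) <= cfg$site_width_um / 2
}

#' Generate a stack of FLIM scenes with per-pixel photon histograms
#'
#' One scene per stimulus step; step `s` has lifetime
#' `tau_base + s * tau_site_delta` inside the site annulus and `tau_base`
#' elsewhere.  Each pixel carries a full TCSPC histogram (shared IRF).
#'
#' @param cfg a [flim_scene_config()].
#' @return a `flim_scene`: list with `counts` (list over steps of
#'   `ny x nx x n_bins` arrays), `time_ns`, `irf`, `dt_ns`, `tau_truth`
#'   (list of matrices), `site_mask`, `pixel_size_um`, `config`.
#' @export
generate_flim_scene <- function(cfg) {
  stopifnot(inherits(cfg, "flim_scene_config"))
  site <- flim_site_mask(cfg)
  ref <- tcspc_gen_config(tau_long = cfg$tau_base, tau_short = cfg$tau_short,
                          frac_long = cfg$frac_long, irf_fwhm = cfg$irf_fwhm,
                          n_photons = cfg$photons_per_pixel,
                          window = cfg$window, n_bins = cfg$n_bins)
  with_seed(cfg$seed, {
    steps <- 0:cfg$n_steps
    counts <- vector("list", length(steps))
    truth <- vector("list", length(steps))
    for (si in seq_along(steps)) {
      tau_map <- matrix(cfg$tau_base, cfg$ny, cfg$nx)
      tau_map[site] <- cfg$tau_base + steps[si] * cfg$tau_site_delta
      arr <- array(0L, c(cfg$ny, cfg$nx, cfg$n_bins))
      for (tau in unique(as.vector(tau_map))) {
        idx <- which(tau_map == tau)
        c_i <- ref
        c_i$tau_long <- tau
        for (px in idx) {
          h <- generate_tcspc_histogram(c_i)
          arr[((px - 1L) %% cfg$ny) + 1L,
              ((px - 1L) %/% cfg$ny) + 1L, ] <- h$counts
        }
      }
      counts[[si]] <- arr
      truth[[si]] <- tau_map
    }
    h0 <- generate_tcspc_histogram(ref)
    structure(list(counts = counts, time_ns = h0$time_ns, irf = h0$irf,
                   dt_ns = h0$dt_ns, tau_truth = truth, site_mask = site,
                   pixel_size_um = cfg$pixel_size_um, config = cfg),
              class = "flim_scene")
  })
}

#' Generate a synthetic lifetime kymograph
#'
#' Repeated line scans across the stimulation site and the outer membrane.
#' Per-pixel lifetimes are emitted as truth plus photon-limited noise
#' (`sd = tau / sqrt(photons)`), the precision a reconvolution fit reaches
#' at that photon budget; intensities are Poisson photon counts.  This keeps
#' kymographs desk-scale while image-mode scenes carry real histograms.
#'
#' @param n_lines number of line scans (time axis).
#' @param nx pixels per line.
#' @param line_time_s time per assembled line (s); 16 repetitions of a
#'   500-photon line give 20--80 ms in the imaging protocol emulated here.
#' @param tau_base resting lifetime (ns).
#' @param tau_delta lifetime step applied from `contact_line` on (ns).
#' @param delta_rois which ROIs get the step: any of `"site"`, `"membrane"`.
#'   An intact cell shows a step only at the site; a cytoskeleton-free bleb
#'   also at the distant membrane.
#' @param site_px,membrane_px pixel index ranges of the two ROIs.
#' @param contact_line line index of probe contact.
#' @param photons_per_px photons per kymograph pixel (default 500).
#' @param seed RNG seed.
#' @return a `lifetime_kymograph`: list with `tau` and `intensity` matrices
#'   (`n_lines x nx`), `line_time_s`, `rois`, `contact_line`, `config`.
#' @export
generate_flim_kymograph <- function(n_lines = 100, nx = 64,
                                    line_time_s = 0.08, tau_base = 5.0,
                                    tau_delta = 0.3, delta_rois = "site",
                                    site_px = 28:36, membrane_px = 50:58,
                                    contact_line = 50, photons_per_px = 500,
                                    seed = NULL) {
  stopifnot_scalar(photons_per_px, "photons_per_px", positive = TRUE)
  with_seed(seed, {
    tau_true <- matrix(tau_base, n_lines, nx)
    if (tau_delta != 0 && length(delta_rois)) {
      rows <- contact_line:n_lines
      if ("site" %in% delta_rois) tau_true[rows, site_px] <-
          tau_base + tau_delta
      if ("membrane" %in% delta_rois) tau_true[rows, membrane_px] <-
          tau_base + tau_delta
    }
    tau <- tau_true + stats::rnorm(length(tau_true),
                                   sd = tau_base / sqrt(photons_per_px))
    intensity <- matrix(stats::rpois(n_lines * nx, photons_per_px),
                        n_lines, nx)
    structure(list(tau = tau, intensity = intensity,
                   line_time_s = line_time_s,
                   rois = list(site = site_px, membrane = membrane_px),
                   contact_line = contact_line,
                   config = list(tau_base = tau_base, tau_delta = tau_delta,
                                 delta_rois = delta_rois,
                                 photons_per_px = photons_per_px,
                                 seed = seed)),
              class = "lifetime_kymograph")
  })
}

#' Generate paired lifetime/tension calibration conditions
#'
#' Emulates the osmotic-shock calibration in which mean probe lifetimes
#' (FLIM, ~21-23 cells per condition) are paired with mean membrane tensions
#' (tether pulling, ~7-10 cells per condition) across five osmolarities.
#' Condition means lie on `tension = intercept + slope * lifetime` with
#' Gaussian standard errors scaled by the per-condition cell numbers.
#'
#' @param slope true conversion factor ((mN/m)/ns); default 1.325.
#' @param intercept line intercept (mN/m).
#' @param lifetimes_ns true mean lifetimes per condition (ns).
#' @param n_lifetime,n_tension cells per condition for each arm.
#' @param sd_lifetime_cell,sd_tension_cell per-cell SDs (ns, mN/m).
#' @param seed RNG seed.
#' @return data.frame with `lifetime_ns`, `tension_mN_m`, `se_lifetime`,
#'   `se_tension`.
#' @export
generate_calibration_pairs <- function(slope = 1.325, intercept = -6.0,
                                       lifetimes_ns = c(4.9, 5.05, 5.2, 5.35, 5.5),
                                       n_lifetime = c(21, 22, 22, 23, 23),
                                       n_tension = c(7, 7, 8, 8, 10),
                                       sd_lifetime_cell = 0.15,
                                       sd_tension_cell = 0.2,
                                       seed = NULL) {
  k <- length(lifetimes_ns)
  n_lifetime <- rep_len(n_lifetime, k)
  n_tension <- rep_len(n_tension, k)
  with_seed(seed, {
    se_l <- sd_lifetime_cell / sqrt(n_lifetime)
    se_t <- sd_tension_cell / sqrt(n_tension)
    lt <- lifetimes_ns + stats::rnorm(k, sd = se_l)
    tn <- intercept + slope * lifetimes_ns + stats::rnorm(k, sd = se_t)
    data.frame(lifetime_ns = lt, tension_mN_m = tn,
               se_lifetime = se_l, se_tension = se_t)
  })
}
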