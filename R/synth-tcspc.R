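#' Configuration for the TCSPC decay generator
#'
#' A bi-exponential fluorescence decay convolved with a Gaussian instrument
#' response function (IRF), photon-sampled into a histogram.  Matches the
#' minimal statistics needed for reconvolution lifetime fitting: by default
#' 1000 photons, the per-pixel minimum used for lifetime imaging.
#'
#' @param tau_long,tau_short lifetimes in ns, `tau_long > tau_short > 0`.
#' @param frac_long amplitude fraction of the long component in \[0, 1\].
#' @param irf_fwhm Gaussian IRF full width at half maximum (ns).
#' @param n_photons total signal photons (>= 1).
#' @param window histogram range (ns).
#' @param n_bins number of histogram bins.
#' @param background_rate expected uniform background counts per bin.
#' @param t0 IRF peak position (ns).
#' @param seed RNG seed.
#' @return an object of class `tcspc_gen_config`.
#' @export
tcspc_gen_config <- function(tau_long = 5.2, tau_short = 2.0, frac_long = 0.6,
                             irf_fwhm = 0.2, n_photons = 1000, window = 25,
                             n_bins = 256, background_rate = 0, t0 = 1,
                             seed = NULL) {
  stopifnot_scalar(tau_long, "tau_long", positive = TRUE)
  stopifnot_scalar(tau_short, "tau_short", positive = TRUE)
  if (tau_long <= tau_short)
    stop("'tau_long' must exceed 'tau_short'", call. = FALSE)
  if (frac_long < 0 || frac_long > 1)
    stop("'frac_long' must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar(irf_fwhm, "irf_fwhm", nonneg = TRUE)
  if (n_photons < 1) stop("'n_photons' must be >= 1", call. = FALSE)
  stopifnot_scalar(window, "window", positive = TRUE)
  if (window < 3 * tau_long)
    warning("window shorter than 3*tau_long: truncation will bias fits")
  structure(list(tau_long = tau_long, tau_short = tau_short,
                 frac_long = frac_long, irf_fwhm = irf_fwhm,
                 n_photons = as.integer(n_photons), window = window,
                 n_bins = as.integer(n_bins),
                 background_rate = background_rate, t0 = t0, seed = seed),
            class = "tcspc_gen_config")
}

#' Generate a TCSPC photon-count histogram
#'
#' Photon arrival times are drawn as IRF jitter plus an exponential dwell
#' drawn from the long or short component; times outside the window are
#' redrawn so counts sum to `n_photons` before background.  A companion
#' (noise-free, discretized Gaussian) IRF histogram is returned for
#' reconvolution fitting.
#'
#' @param cfg a [tcspc_gen_config()].
#' @return a `tcspc_histogram`: list with `time_ns` (bin centers), `counts`,
#'   `irf` (same grid), `dt_ns` and the generating `config`.
#' @export
generate_tcspc_histogram <- function(cfg) {
  stopifnot(inherits(cfg, "tcspc_gen_config"))
  dt <- cfg$window / cfg$n_bins
  centers <- (seq_len(cfg$n_bins) - 0.5) * dt
  sigma <- cfg$irf_fwhm / (2 * sqrt(2 * log(2)))
  with_seed(cfg$seed, {
    draw <- function(n) {
      tau <- ifelse(stats::runif(n) < cfg$frac_long, cfg$tau_long,
                    cfg$tau_short)
      jit <- if (sigma > 0) stats::rnorm(n, sd = sigma) else 0
      cfg$t0 + jit + stats::rexp(n, rate = 1 / tau)
    }
    t <- draw(cfg$n_photons)
    bad <- which(t < 0 | t >= cfg$window)
    while (length(bad)) {
      t[bad] <- draw(length(bad))
      bad <- bad[t[bad] < 0 | t[bad] >= cfg$window]
    }
    counts <- tabulate(floor(t / dt) + 1L, nbins = cfg$n_bins)
    if (cfg$background_rate > 0)
      counts <- counts + stats::rpois(cfg$n_bins, cfg$background_rate)
    irf <- if (sigma > 0) {
      stats::pnorm(centers + dt / 2, cfg$t0, sigma) -
        stats::pnorm(centers - dt / 2, cfg$t0, sigma)
    } else {
      as.numeric(seq_len(cfg$n_bins) == (floor(cfg$t0 / dt) + 1L))
    }
    structure(list(time_ns = centers, counts = counts, irf = irf,
                   dt_ns = dt, config = cfg),
              class = "tcspc_histogram")
  })
}
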