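#' Calibrate the lifetime-to-tension conversion factor
#'
#' Least-squares line of membrane tension on probe lifetime across paired
#' conditions (e.g. osmotic shocks measured by FLIM and tether pulling).
#' The slope is the conversion factor c in (mN/m)/ns.
#'
#' @param lifetimes_ns mean probe lifetime per condition (ns).
#' @param tensions_mN_m mean membrane tension per condition (mN/m).
#' @return a `tension_calibration`: list with `c` (slope), `se_c`,
#'   `intercept`, `se_intercept`, `r_squared`, `n`.
#' @export
calibrate_tension <- function(lifetimes_ns, tensions_mN_m) {
  if (length(lifetimes_ns) < 3L)
    stop("need at least 3 paired conditions", call. = FALSE)
  fit <- stats::lm(tensions_mN_m ~ lifetimes_ns)
  sfit <- suppressWarnings(summary(fit))
  cf <- sfit$coefficients
  structure(list(c = cf[2L, 1L], se_c = cf[2L, 2L],
                 intercept = cf[1L, 1L], se_intercept = cf[1L, 2L],
                 r_squared = sfit$r.squared,
                 n = length(lifetimes_ns)),
            class = "tension_calibration")
}

#' Convert a lifetime change to a membrane tension change
#'
#' @param delta_tau_ns lifetime change (ns).
#' @param cal a [calibrate_tension()] result, or a conversion factor
#'   in (mN/m)/ns.
#' @return tension change in mN/m.
#' @export
lifetime_to_tension <- function(delta_tau_ns, cal) {
  c <- if (inherits(cal, "tension_calibration")) cal$c else cal
  if (!is.numeric(c) || c <= 0) stop("invalid calibration", call. = FALSE)
  c * delta_tau_ns
}

#' Fit a stimulus-tension coefficient
#'
#' Least-squares slope of mean tension change versus stimulus magnitude
#' (indentation force in nN or aspiration pressure in mbar), yielding the
#' alpha coefficients.
#'
#' @param stimulus stimulus values (>= 3 steps).
#' @param delta_T mean tension change per step (mN/m, or (mN/m) um^2 for
#'   area-integrated series).
#' @return list with `alpha`, `se`, `intercept`, `r_squared`.
#' @export
fit_stimulus_tension <- function(stimulus, delta_T) {
  if (length(stimulus) < 3L) stop("need at least 3 steps", call. = FALSE)
  fit <- stats::lm(delta_T ~ stimulus)
  sfit <- suppressWarnings(summary(fit))
  cf <- sfit$coefficients
  list(alpha = cf[2L, 1L], se = cf[2L, 2L], intercept = cf[1L, 1L],
       r_squared = sfit$r.squared)
}

#' Area-integrated tension change between two lifetime images
#'
#' Pixels whose lifetime increase exceeds `k_sigma` times the per-pixel
#' noise SD are "affected"; the output integrates the converted tension
#' change over their area.  The per-pixel noise SD comes from the fit
#' standard errors when present, else from photon statistics
#' (`tau/sqrt(N)`).
#'
#' @param before,after `lifetime_image` objects with identical geometry.
#' @param cal a `tension_calibration` or conversion factor ((mN/m)/ns).
#' @param k_sigma significance multiple, default 2.
#' @return list with `integral` ((mN/m) um^2), `affected` (logical
#'   matrix), `delta_tau` (matrix), `pixel_area_um2`.
#' @export
integrate_tension_change <- function(before, after, cal, k_sigma = 2) {
  if (!identical(dim(before$tau_long), dim(after$tau_long)))
    stop("images are misaligned", call. = FALSE)
  valid <- before$mask & after$mask
  dtau <- after$tau_long - before$tau_long
  sd1 <- before$se_tau_long
  sd2 <- after$se_tau_long
  fallback1 <- before$tau_long / sqrt(pmax(before$photons, 1))
  fallback2 <- after$tau_long / sqrt(pmax(after$photons, 1))
  sd1[!is.finite(sd1)] <- fallback1[!is.finite(sd1)]
  sd2[!is.finite(sd2)] <- fallback2[!is.finite(sd2)]
  noise <- sqrt(sd1^2 + sd2^2)
  affected <- valid & !is.na(dtau) & dtau > k_sigma * noise
  px_area <- before$pixel_size_um^2
  cfac <- if (inherits(cal, "tension_calibration")) cal$c else cal
  integral <- sum(cfac * dtau[affected]) * px_area
  list(integral = integral, affected = affected, delta_tau = dtau,
       pixel_area_um2 = px_area)
}

#' Analyze a lifetime kymograph
#'
#' Per-line ROI means of lifetime and intensity with SD bands, and a
#' step-change verdict per ROI: did the post-contact mean exceed the
#' pre-contact mean by more than `k` pre-contact SDs of the per-line means?
#'
#' @param kymo a `lifetime_kymograph` (fields `tau`, `intensity`,
#'   `line_time_s`), e.g. from [generate_flim_kymograph()].
#' @param rois named list of pixel-index vectors (e.g. `site`, `membrane`);
#'   defaults to `kymo$rois`.
#' @param contact_time_s time of probe contact (s); defaults to
#'   `kymo$contact_line * line_time_s`.
#' @param k verdict threshold in pre-contact SDs, default 2.
#' @return list with `time_s`, per-ROI data.frames (`tau_mean`, `tau_sd`,
#'   `intensity_mean`, `intensity_sd`) in `series`, and `verdicts`
#'   (named logical).
#' @export
analyze_kymograph <- function(kymo, rois = NULL, contact_time_s = NULL,
                              k = 2) {
  if (is.null(rois)) rois <- kymo$rois
  n_lines <- nrow(kymo$tau)
  time_s <- (seq_len(n_lines) - 1) * kymo$line_time_s
  if (is.null(contact_time_s))
    contact_time_s <- (kymo$contact_line - 1) * kymo$line_time_s
  if (contact_time_s <= time_s[2L] || contact_time_s >= time_s[n_lines - 1L])
    stop("contact_time outside the recorded window", call. = FALSE)
  pre <- time_s < contact_time_s
  series <- lapply(rois, function(px) {
    data.frame(time_s = time_s,
               tau_mean = rowMeans(kymo$tau[, px, drop = FALSE]),
               tau_sd = apply(kymo$tau[, px, drop = FALSE], 1L, stats::sd),
               intensity_mean = rowMeans(kymo$intensity[, px, drop = FALSE]),
               intensity_sd = apply(kymo$intensity[, px, drop = FALSE], 1L,
                                    stats::sd))
  })
  verdicts <- vapply(series, function(s) {
    mu0 <- mean(s$tau_mean[pre]); sd0 <- stats::sd(s$tau_mean[pre])
    mean(s$tau_mean[!pre]) > mu0 + k * max(sd0, .Machine$double.eps)
  }, logical(1L))
  list(time_s = time_s, series = series, verdicts = verdicts,
       contact_time_s = contact_time_s)
}
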