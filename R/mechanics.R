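#' Find the contact point of a force--distance curve
#'
#' The baseline (pre-contact) segment is linearly detrended; the contact
#' point is the first position where the detrended force exceeds the
#' baseline mean plus a threshold.  By default the threshold is `k` times
#' the baseline noise SD.
#'
#' @param curve a `force_curve` data.frame (`position_um`, `force_nN`).
#' @param force_threshold_nN absolute force threshold (nN); if `NULL`
#'   (default) uses `k * baseline SD`.
#' @param k threshold multiple of the baseline noise SD, default 3.
#' @param baseline_fraction fraction of the curve treated as baseline
#'   (must be >= 0.2), default 0.3.
#' @param sustain number of consecutive supra-threshold samples required
#'   (default 3), so single noise spikes do not trigger.
#' @return list with `contact_um`, `contact_index`, `threshold_nN`,
#'   `force_detrended` (vector).
#' @export
find_contact_point <- function(curve, force_threshold_nN = NULL, k = 3,
                               baseline_fraction = 0.3, sustain = 3) {
  if (baseline_fraction < 0.2)
    stop("baseline segment must be at least 20% of the curve", call. = FALSE)
  z <- curve$position_um
  F <- curve$force_nN
  nb <- max(floor(length(z) * baseline_fraction), 5L)
  bl <- stats::lm(F[seq_len(nb)] ~ z[seq_len(nb)])
  Fd <- F - (stats::coef(bl)[1L] + stats::coef(bl)[2L] * z)
  s <- stats::sd(stats::resid(bl))
  thr <- if (is.null(force_threshold_nN)) k * max(s, .Machine$double.eps)
         else force_threshold_nN
  above <- Fd > thr
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= sustain & starts > nb / 2)
  if (!length(hit)) stop("no contact-point crossing found", call. = FALSE)
  i <- starts[hit[1L]]
  list(contact_um = z[i], contact_index = i, threshold_nN = thr,
       force_detrended = Fd)
}

#' Fit the Hertz model to a force--indentation curve
#'
#' Fits `F = (4/3) E/(1-nu^2) sqrt(R) d^(3/2)` (spherical tip) or
#' `F = 2 E/(1-nu^2) a d` (flat cylindrical punch) over the indentation
#' segment beyond the contact point.  Both laws are linear in a transformed
#' indentation variable, so the fit is a no-intercept least-squares
#' regression.
#'
#' @param curve a `force_curve` data.frame.
#' @param contact_um contact position, e.g. from [find_contact_point()].
#' @param geometry `"sphere"` or `"punch"`.
#' @param tip_radius_um sphere radius R or punch radius a (um).
#' @param nu Poisson ratio, default 0.5.
#' @param max_indentation_um optional cap on the indentation depth used.
#' @param refine_contact_um half-width (um) of a window around
#'   `contact_um` over which the contact point is refined by minimizing
#'   the fit residual (threshold-based contact detection is systematically
#'   late by threshold/slope); `0` disables refinement.  Default 0.2.
#' @return a `stiffness_fit`: list with `E_Pa`, `se_E_Pa`, `contact_um`,
#'   `geometry`, `residual_nN`, `n_points`.
#' @export
fit_hertz <- function(curve, contact_um, geometry = c("sphere", "punch"),
                      tip_radius_um = 1, nu = 0.5,
                      max_indentation_um = Inf, refine_contact_um = 0.2) {
  geometry <- match.arg(geometry)
  ## remove the baseline trend/offset using the pre-contact segment so a
  ## constant force offset is absorbed, as in the contact-point step
  Fc <- curve$force_nN
  pre <- curve$position_um < contact_um - 2 * refine_contact_um
  if (sum(pre) >= 5L) {
    bl <- stats::lm(Fc[pre] ~ curve$position_um[pre])
    Fc <- Fc - (stats::coef(bl)[1L] + stats::coef(bl)[2L] * curve$position_um)
  }
  ## RSS includes a pre-contact window where the model is identically 0:
  ## this breaks the contact/modulus degeneracy of the gentle sphere onset
  rss_at <- function(c0) {
    delta <- curve$position_um - c0
    sel <- delta > 0 & delta <= max_indentation_um
    pre0 <- delta <= 0 & delta > -4 * max(refine_contact_um, 0.05)
    if (sum(sel) < 10L) return(Inf)
    x <- if (geometry == "sphere") delta[sel]^1.5 else delta[sel]
    F <- Fc[sel]
    b <- sum(F * x) / sum(x^2)
    (sum((F - b * x)^2) + sum(Fc[pre0]^2)) / (sum(sel) + sum(pre0))
  }
  if (refine_contact_um > 0) {
    ## threshold detection is late on gentle (sphere) onsets; expand the
    ## search window while the optimum pins against its lower edge
    lo <- contact_um - refine_contact_um
    hi <- contact_um + refine_contact_um
    for (i in 1:6) {
      opt <- stats::optimize(rss_at, c(lo, hi))
      if (!is.finite(opt$objective)) break
      if (opt$minimum > lo + 0.05 * (hi - lo)) break
      hi <- lo + 0.1 * (hi - lo)
      lo <- lo - 2 * refine_contact_um
    }
    if (is.finite(opt$objective)) contact_um <- opt$minimum
  }
  delta <- curve$position_um - contact_um
  sel <- delta > 0 & delta <= max_indentation_um
  if (sum(sel) < 10L)
    stop("need >= 10 points beyond the contact point", call. = FALSE)
  d <- delta[sel]
  F <- Fc[sel]
  x <- if (geometry == "sphere") d^1.5 else d
  fit <- stats::lm(F ~ x - 1)
  coefm <- suppressWarnings(summary(fit))$coefficients
  k2E <- if (geometry == "sphere")
    (4 / 3) / (1 - nu^2) * sqrt(tip_radius_um) * PA_UM2_TO_NN
  else
    2 / (1 - nu^2) * tip_radius_um * PA_UM2_TO_NN
  E <- coefm[1L, 1L] / k2E
  if (E <= 0) stop("fitted modulus is non-positive", call. = FALSE)
  structure(list(E_Pa = E, se_E_Pa = coefm[1L, 2L] / k2E,
                 contact_um = contact_um, geometry = geometry,
                 residual_nN = sqrt(mean(stats::resid(fit)^2)),
                 n_points = sum(sel)),
            class = "stiffness_fit")
}

#' Compare stiffness between two treatment groups
#'
#' Welch's two-sample t-test on fitted moduli, the comparison used for
#' treatment-induced stiffness changes (e.g. actin depolymerization).
#'
#' @param E_group1,E_group2 fitted moduli (Pa) per cell.
#' @return the `htest` object from [stats::t.test()].
#' @export
compare_stiffness <- function(E_group1, E_group2) {
  stats::t.test(E_group1, E_group2, var.equal = FALSE)
}
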