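#' Preprocess a calcium movie
#'
#' Generic denoising, per-pixel baseline (5th-percentile value of the
#' denoised trace) subtraction, spatial Gaussian low-pass, and per-movie
#' max-normalization to \[0, 1\] -- in that order.  Denoising must precede
#' the baseline percentile: on noisy data the 5th percentile sits ~1.6
#' noise-SDs below the resting mean, leaving a spurious offset after
#' subtraction otherwise.  A Gaussian (default) or median spatial filter
#' stands in for the learned denoiser used on real recordings.
#'
#' @param movie a `calcium_movie`, or a `frames x ny x nx` array.
#' @param sigma_px Gaussian low-pass SD (pixels), default 1.
#' @param baseline_quantile baseline quantile, default 0.05.
#' @param denoise `"gaussian"` (default), `"median"` (3x3 spatial
#'   median), or `"none"`.
#' @return the input with `green` replaced by the normalized array (or the
#'   bare array when an array was given); attribute `scale` holds the
#'   normalization divisor.
#' @export
preprocess_movie <- function(movie, sigma_px = 1, baseline_quantile = 0.05,
                             denoise = c("gaussian", "median", "none")) {
  denoise <- match.arg(denoise)
  arr <- if (is.list(movie)) movie$green else movie
  if (dim(arr)[1L] < 20L)
    stop("need >= 20 frames for a stable baseline percentile", call. = FALSE)
  nf <- dim(arr)[1L]; ny <- dim(arr)[2L]; nx <- dim(arr)[3L]
  med3 <- function(img) {
    p <- img
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      p[i, j] <- stats::median(img[max(1, i - 1):min(ny, i + 1),
                                   max(1, j - 1):min(nx, j + 1)])
    }
    p
  }
  dn <- array(0, dim(arr))
  for (k in seq_len(nf)) {
    dn[k, , ] <- switch(denoise,
                        gaussian = gaussian_blur(arr[k, , ], sigma_px),
                        median = med3(arr[k, , ]),
                        none = arr[k, , ])
  }
  ## type-1 (inverse-ECDF) quantile: a pixel dark in exactly 5% of frames
  ## gets its dark level as baseline
  base <- apply(dn, c(2L, 3L), stats::quantile, probs = baseline_quantile,
                names = FALSE, type = 1)
  out <- array(0, dim(arr))
  for (k in seq_len(nf)) {
    out[k, , ] <- gaussian_blur(dn[k, , ] - base, sigma_px)
  }
  mx <- max(out)
  if (mx <= 0) {
    warning("constant movie: normalized output is all zeros")
    out[] <- 0
    mx <- 1
  } else out <- out / mx
  attr(out, "scale") <- mx
  if (is.list(movie)) { movie$green <- out; movie } else out
}

#' Detect the onset of a calcium response
#'
#' First frame in which at least `min_area` pixels of the normalized movie
#' exceed the threshold.
#'
#' @param movie_norm preprocessed movie (list or array).
#' @param threshold activation threshold on the normalized scale,
#'   default 0.2.
#' @param min_area minimum number of supra-threshold pixels, default 5.
#' @param clean remove speckle from the per-frame masks with a 3x3
#'   majority filter (default TRUE); isolated noise pixels otherwise
#'   corrupt front-distance percentiles.
#' @return list with `onset_frame` (NA if no crossing) and `masks`
#'   (list of logical matrices per frame).
#' @export
detect_response <- function(movie_norm, threshold = 0.2, min_area = 5,
                            clean = TRUE) {
  arr <- if (is.list(movie_norm)) movie_norm$green else movie_norm
  nf <- dim(arr)[1L]
  masks <- lapply(seq_len(nf), function(k) {
    m <- arr[k, , ] > threshold
    if (clean) m & (neighborhood_sum(m) >= 5L) else m
  })
  area <- vapply(masks, sum, 0L)
  onset <- which(area >= min_area)[1L]
  list(onset_frame = if (is.na(onset)) NA_integer_ else onset, masks = masks)
}

#' Estimate calcium wave-front propagation speed
#'
#' Per frame, the front position is the 95th percentile of the distances
#' (um) of supra-threshold pixels from the stimulation site (robust to
#' speckle); the speed is the least-squares slope of front distance versus
#' time over `n_frames` frames after onset.  Frames where the front has
#' saturated at the field/cell boundary are dropped with a warning.
#'
#' @param movie_norm preprocessed movie (list with `pixel_size_um`,
#'   `frame_interval_s`, `origin`, or a bare array plus those arguments).
#' @param origin stimulation-site pixel `c(row, col)`.
#' @param n_frames frames after onset used for the fit, default 50.
#' @param threshold,min_area passed to [detect_response()].
#' @param front_quantile front statistic, default 0.95.
#' @param pixel_size_um,frame_interval_s required when `movie_norm` is a
#'   bare array.
#' @return a `wave_result`: list with `onset_frame`, `radius_um` (per used
#'   frame), `time_s`, `speed_um_s`, `speed_se`, `n_used`.
#' @export
wavefront_speed <- function(movie_norm, origin = NULL, n_frames = 50,
                            threshold = 0.2, min_area = 5,
                            front_quantile = 0.95,
                            pixel_size_um = NULL, frame_interval_s = NULL) {
  if (is.list(movie_norm)) {
    arr <- movie_norm$green
    if (is.null(origin)) origin <- movie_norm$origin
    pixel_size_um <- movie_norm$pixel_size_um
    frame_interval_s <- movie_norm$frame_interval_s
  } else arr <- movie_norm
  stopifnot(!is.null(origin), !is.null(pixel_size_um),
            !is.null(frame_interval_s))
  det <- detect_response(arr, threshold, min_area)
  if (is.na(det$onset_frame))
    return(structure(list(onset_frame = NA_integer_, radius_um = numeric(0),
                          time_s = numeric(0), speed_um_s = NA_real_,
                          speed_se = NA_real_, n_used = 0L),
                     class = "wave_result"))
  nf <- dim(arr)[1L]; ny <- dim(arr)[2L]; nx <- dim(arr)[3L]
  d_um <- pixel_distances(ny, nx, origin) * pixel_size_um
  frames <- det$onset_frame:min(nf, det$onset_frame + n_frames - 1L)
  radius <- vapply(frames, function(k) {
    act <- det$masks[[k]]
    if (!any(act)) return(0)
    stats::quantile(d_um[act], front_quantile, names = FALSE)
  }, 0)
  ## saturation: the front cannot exceed the shortest origin-to-edge span
  r_max <- min(origin[1L] - 1L, ny - origin[1L],
               origin[2L] - 1L, nx - origin[2L]) * pixel_size_um
  keep <- radius < 0.95 * r_max
  if (!all(keep)) {
    warning("front saturates at the field boundary; fit restricted to ",
            sum(keep), " pre-saturation frames")
    if (any(keep)) {
      keep <- seq_along(frames) <= max(which(keep))  # contiguous prefix
      keep <- keep & radius < 0.95 * r_max
    }
  }
  t_s <- (frames - det$onset_frame) * frame_interval_s
  if (sum(keep) < 3L || stats::var(radius[keep]) == 0) {
    return(structure(list(onset_frame = det$onset_frame,
                          radius_um = radius, time_s = t_s,
                          speed_um_s = 0, speed_se = NA_real_,
                          n_used = sum(keep)),
                     class = "wave_result"))
  }
  fit <- stats::lm(radius[keep] ~ t_s[keep])
  cf <- summary(fit)$coefficients
  structure(list(onset_frame = det$onset_frame, radius_um = radius,
                 time_s = t_s, speed_um_s = max(cf[2L, 1L], 0),
                 speed_se = cf[2L, 2L], n_used = sum(keep)),
            class = "wave_result")
}

#' Classify a cell trace as responder or non-responder
#'
#' @param trace background-corrected ROI intensity over time.
#' @param n_baseline baseline frames (>= 20) for the baseline mean.
#' @param threshold responder fold threshold, default 3.
#' @return list with `fold` (peak / baseline mean) and `responder`.
#' @export
classify_responder <- function(trace, n_baseline = 20, threshold = 3) {
  if (n_baseline < 20L) stop("need >= 20 baseline frames", call. = FALSE)
  if (length(trace) <= n_baseline)
    stop("trace shorter than the baseline window", call. = FALSE)
  base <- mean(trace[seq_len(n_baseline)])
  fold <- max(trace) / base
  list(fold = fold, responder = fold >= threshold)
}

#' Detect membrane rupture via red-dye entry
#'
#' Rupture is declared when the in-mask red-channel mean exceeds its
#' pre-stimulus mean by more than `k` SDs for at least `sustain` frames.
#'
#' @param red `frames x ny x nx` red-channel array.
#' @param cell_mask logical `ny x nx` mask of the stimulated cell.
#' @param n_baseline pre-contact frames used for the baseline.
#' @param k threshold in baseline SDs, default 5.
#' @param sustain required consecutive frames, default 3.
#' @return list with `rupture` (logical) and `entry_frame` (NA if none).
#' @export
detect_dye_entry <- function(red, cell_mask, n_baseline = 10, k = 5,
                             sustain = 3) {
  if (is.null(red)) stop("red channel is absent", call. = FALSE)
  tr <- vapply(seq_len(dim(red)[1L]),
               function(i) mean(red[i, , ][cell_mask]), 0)
  mu <- mean(tr[seq_len(n_baseline)])
  s <- max(stats::sd(tr[seq_len(n_baseline)]), .Machine$double.eps)
  above <- tr > mu + k * s
  run <- rle(above)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= sustain)[1L]
  if (is.na(hit)) return(list(rupture = FALSE, entry_frame = NA_integer_))
  list(rupture = TRUE,
       entry_frame = ends[hit] - run$lengths[hit] + 1L)
}
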