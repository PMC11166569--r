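#' Empirical cumulative frequency of critical pressures
#'
#' Builds the right-continuous empirical CDF of critical aspiration
#' pressures at one indentation force: one point per distinct observed
#' pressure with value k/n.  Censored cells (no response by the protocol
#' maximum) are excluded by default, mirroring the activation-probability
#' reading of the cumulative histogram.
#'
#' @param records data.frame of cell records (columns `force_nN`,
#'   `p_crit_mbar`, `censored`; see [generate_critical_pressures()]).
#' @param force indentation force to select, or `NULL` for all records
#'   (used for total-activation histograms).
#' @param include_censored if TRUE, censored cells enter the denominator
#'   (Kaplan-Meier-style plateau below 1); default FALSE.
#' @param grid optional full protocol pressure grid (mbar).  When given,
#'   the CDF is evaluated at every grid point (zeros below the first
#'   observation, ones above the last), matching the stepped-protocol
#'   cumulative histogram.  Evaluating only at observed pressures biases
#'   the tails at small n (a tail point enters only when an extreme draw
#'   occurred), so the grid form is preferred for fitting.
#' @return a `cumulative_frequency`: list with `pressures` (ascending),
#'   `cumfreq`, `n_cells`, `force`.
#' @export
cumulative_frequency <- function(records, force = NULL,
                                 include_censored = FALSE, grid = NULL) {
  if (!is.null(force)) records <- records[records$force_nN == force, ]
  obs <- records[!records$censored, , drop = FALSE]
  n <- if (include_censored) nrow(records) else nrow(obs)
  if (nrow(obs) == 0L) stop("all records are censored", call. = FALSE)
  if (nrow(obs) < 3L)
    stop("need at least 3 non-censored records", call. = FALSE)
  p <- if (is.null(grid)) sort(unique(obs$p_crit_mbar)) else sort(grid)
  cf <- vapply(p, function(x) sum(obs$p_crit_mbar <= x), 0) / n
  structure(list(pressures = p, cumfreq = cf, n_cells = n,
                 values = obs$p_crit_mbar,
                 force = if (is.null(force)) NA_real_ else force),
            class = "cumulative_frequency")
}

boltzmann <- function(p, a, b) 1 / (1 + exp(-(p - a) / b))

#' Fit a Boltzmann (sigmoid) curve to a cumulative frequency
#'
#' Least-squares fit of `1/(1 + exp(-(p - a)/b))` to the cumulative
#' frequency points; `a` is the half-maximum critical pressure p_C,50.
#' Alongside the sigmoid, an ordinary straight line is fitted to the same
#' points; the two residual sums of squares define the goodness-of-model
#' `GoM = chi2_lin / chi2_sig + 1` and the composite error
#' `error = sigma + a / GoM`, where `sigma` is the standard deviation of
#' `a` from the sigmoid fit.
#'
#' @param cdf a [cumulative_frequency()], or a list with `pressures` and
#'   `cumfreq`.
#' @return a `sigmoid_fit`: list with `a`, `b`, `sigma`, `sigma_b`,
#'   `chi2_sig`, `chi2_lin`, `GoM`, `error`, `n`, `converged`.
#' @export
fit_boltzmann <- function(cdf) {
  p <- cdf$pressures
  y <- cdf$cumfreq
  if (length(p) < 4L)
    stop("need at least 4 cumulative-frequency points", call. = FALSE)
  if (min(y) >= 0.5 || max(y) <= 0.5)
    warning("points do not straddle 0.5; initialization may be poor")
  ## init: interpolated 0.5 crossing; width from logistic quartile spacing
  q <- function(level) {
    i <- which(y >= level)[1L]
    if (is.na(i)) return(p[length(p)])
    if (i == 1L) return(p[1L])
    p[i - 1L] + (p[i] - p[i - 1L]) * (level - y[i - 1L]) / (y[i] - y[i - 1L])
  }
  a0 <- q(0.5)
  b0 <- max((q(0.75) - q(0.25)) / (2 * log(3)), diff(range(p)) / 100)
  ## half-max outside the observed pressure range: invert the logistic at
  ## the nearest point instead of interpolating a nonexistent crossing
  if (y[1L] > 0.5) a0 <- p[1L] - b0 * stats::qlogis(min(y[1L], 0.99))
  if (y[length(y)] < 0.5)
    a0 <- p[length(p)] - b0 * stats::qlogis(max(y[length(y)], 0.01))
  dat <- data.frame(p = p, y = y)
  fit <- tryCatch(
    stats::nls(y ~ 1 / (1 + exp(-(p - a) / b)), data = dat,
               start = list(a = a0, b = b0),
               control = stats::nls.control(maxiter = 500, tol = 1e-9,
                                            scaleOffset = 1,
                                            minFactor = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(th) sum((y - boltzmann(p, th[1L], exp(th[2L])))^2)
    op <- stats::optim(c(a0, log(b0)), obj, method = "BFGS",
                       control = list(maxit = 1000), hessian = TRUE)
    if (op$convergence != 0) {
      op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 5000), hessian = TRUE)
    }
    if (op$convergence != 0)
      stop("sigmoid fit did not converge", call. = FALSE)
    a <- op$par[1L]; b <- exp(op$par[2L])
    chi2_sig <- op$value
    ## Gauss-Newton covariance: s^2 (J'J)^-1 on (a, b), numeric Jacobian
    ea <- max(1e-6, abs(a) * 1e-6); eb <- max(1e-6, abs(b) * 1e-6)
    J <- cbind((boltzmann(p, a + ea, b) - boltzmann(p, a - ea, b)) / (2 * ea),
               (boltzmann(p, a, b + eb) - boltzmann(p, a, b - eb)) / (2 * eb))
    s2 <- chi2_sig / max(length(p) - 2L, 1L)
    V <- tryCatch(s2 * solve(crossprod(J)), error = function(e) matrix(NA, 2, 2))
    sigma <- sqrt(abs(V[1L, 1L])); sigma_b <- sqrt(abs(V[2L, 2L]))
    conv <- TRUE
  } else {
    sfit <- suppressWarnings(summary(fit))
  cf <- sfit$coefficients
    a <- cf["a", "Estimate"]; b <- cf["b", "Estimate"]
    sigma <- cf["a", "Std. Error"]; sigma_b <- cf["b", "Std. Error"]
    chi2_sig <- sum(stats::resid(fit)^2)
    conv <- TRUE
  }
  if (b < 0) { b <- abs(b) }  # sign-symmetric parameterization guard
  lin <- stats::lm(y ~ p)
  chi2_lin <- sum(stats::resid(lin)^2)
  GoM <- if (chi2_sig == 0) Inf else chi2_lin / chi2_sig + 1
  err <- if (is.finite(GoM)) sigma + a / GoM else sigma
  structure(list(a = a, b = b, sigma = sigma, sigma_b = sigma_b,
                 chi2_sig = chi2_sig, chi2_lin = chi2_lin, GoM = GoM,
                 error = err, n = length(p), converged = conv),
            class = "sigmoid_fit")
}

#' Bootstrap standard error of the half-maximum pressure
#'
#' The least-squares covariance of a sigmoid fitted to ECDF points
#' understates the sampling error of p_C,50 because neighboring ECDF
#' values are strongly correlated.  This resamples the underlying cells
#' and refits, giving an honest standard error of `a`.
#'
#' @param cdf a [cumulative_frequency()] built from raw records (carries
#'   the per-cell `values`).
#' @param n_boot bootstrap replicates, default 200.
#' @param grid optional protocol grid for the resampled CDFs (defaults to
#'   the CDF's own pressure axis when it is a grid, else observed values).
#' @param seed RNG seed.
#' @return list with `se_a` and the vector of bootstrap estimates `a_boot`.
#' @export
boltzmann_se_bootstrap <- function(cdf, n_boot = 200, grid = NULL,
                                   seed = NULL) {
  vals <- cdf$values
  if (is.null(vals)) stop("CDF does not carry per-cell values", call. = FALSE)
  with_seed(seed, {
    a_boot <- vapply(seq_len(n_boot), function(i) {
      v <- sample(vals, replace = TRUE)
      cd <- cumulative_frequency(
        data.frame(force_nN = 0, p_crit_mbar = v, censored = FALSE),
        grid = grid)
      tryCatch(suppressWarnings(fit_boltzmann(cd)$a),
               error = function(e) NA_real_)
    }, 0)
    list(se_a = stats::sd(a_boot, na.rm = TRUE), a_boot = a_boot)
  })
}

#' Fit the p_C,50(F) line
#'
#' Ordinary (unweighted) least-squares line through the per-force
#' half-maximum pressures.  Per-force composite errors are carried for
#' display, not used as weights.
#'
#' @param force indentation forces (nN), >= 3 distinct values.
#' @param pc50 half-maximum pressures (mbar), one per force.
#' @param error optional per-force composite errors (display only).
#' @return a `pcf_curve`: list with `intercept`, `slope`, `se_intercept`,
#'   `se_slope`, `r_squared`, and the input `points` data.frame.
#' @export
fit_pc50_vs_force <- function(force, pc50, error = NULL) {
  if (length(force) < 3L) stop("need at least 3 forces", call. = FALSE)
  fit <- stats::lm(pc50 ~ force)
  sfit <- suppressWarnings(summary(fit))
  cf <- sfit$coefficients
  structure(list(intercept = cf[1L, 1L], slope = cf[2L, 1L],
                 se_intercept = cf[1L, 2L], se_slope = cf[2L, 2L],
                 r_squared = sfit$r.squared,
                 points = data.frame(force_nN = force, pc50_mbar = pc50,
                                     error_mbar = if (is.null(error))
                                       NA_real_ else error)),
            class = "pcf_curve")
}

#' Run the full activation pipeline on a record table
#'
#' Per-force cumulative frequency, Boltzmann fit, then the p_C,50(F) line.
#'
#' @param records cell-record data.frame.
#' @param grid optional protocol pressure grid passed to
#'   [cumulative_frequency()]; `"infer"` reconstructs it from the data
#'   (smallest positive gap between observed pressures, up to the largest
#'   observation), which is exact for stepped-protocol records.
#' @return list with `fits` (named list of `sigmoid_fit` per force),
#'   `curve` (`pcf_curve`).
#' @export
activation_pipeline <- function(records, grid = "infer") {
  if (identical(grid, "infer")) {
    p <- sort(unique(records$p_crit_mbar[!records$censored]))
    step <- min(diff(p))
    gridded <- is.finite(step) && step > 0 &&
      max(abs(p / step - round(p / step))) < 1e-6 &&
      max(p) / step <= 1000
    grid <- if (gridded) seq(step, max(p), by = step) else NULL
  }
  forces <- sort(unique(records$force_nN))
  fits <- lapply(forces, function(f)
    fit_boltzmann(cumulative_frequency(records, force = f, grid = grid)))
  names(fits) <- as.character(forces)
  a <- vapply(fits, `[[`, 0, "a")
  err <- vapply(fits, `[[`, 0, "error")
  list(fits = fits, curve = fit_pc50_vs_force(forces, a, err))
}

#' Bootstrap standard errors for the activation pipeline
#'
#' Resamples cells within each force group and reruns the CDF -> sigmoid
#' -> line pipeline, giving sampling-based standard errors of the
#' p_C,50(F) intercept and slope.  The 5-point line-fit covariance can be
#' accidentally tiny when the per-force estimates happen to fall on a
#' line; the bootstrap reflects the estimator's true variability.
#'
#' @param records cell-record data.frame.
#' @param n_boot bootstrap replicates, default 100.
#' @param grid passed to [activation_pipeline()].
#' @param seed RNG seed.
#' @return list with `se_intercept`, `se_slope`.
#' @export
activation_pipeline_bootstrap <- function(records, n_boot = 100,
                                          grid = "infer", seed = NULL) {
  with_seed(seed, {
    est <- replicate(n_boot, {
      idx <- unlist(lapply(split(seq_len(nrow(records)), records$force_nN),
                           function(i) sample(i, replace = TRUE)))
      pl <- tryCatch(
        suppressWarnings(activation_pipeline(records[idx, ], grid = grid)),
        error = function(e) NULL)
      if (is.null(pl)) c(NA_real_, NA_real_)
      else c(pl$curve$intercept, pl$curve$slope)
    })
    list(se_intercept = stats::sd(est[1L, ], na.rm = TRUE),
         se_slope = stats::sd(est[2L, ], na.rm = TRUE))
  })
}

#' Total activation pressure per cell and its half-maximum
#'
#' Converts the indentation force of each (non-censored) cell into an
#' equivalent pressure via the magnitude of the p_C,50(F) slope, sums it
#' with the critical aspiration pressure, and fits the cumulative histogram
#' of the totals with a Boltzmann curve to obtain the population
#' half-maximum total activation pressure.
#'
#' @param records cell-record data.frame.
#' @param slope slope of the p_C,50(F) line (mbar/nN); its absolute value
#'   is used so totals are sums of positive pressures.
#' @return list with `totals` (per-cell, mbar), `fit` (`sigmoid_fit`),
#'   `half_max` (mbar).
#' @export
total_activation_pressure <- function(records, slope) {
  obs <- records[!records$censored, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no non-censored records", call. = FALSE)
  totals <- obs$p_crit_mbar + abs(slope) * obs$force_nN
  if (length(unique(totals)) < 4L) {
    ## degenerate (e.g. noiseless) input: the half-maximum is the median
    return(list(totals = totals, fit = NULL,
                half_max = stats::median(totals)))
  }
  cdf <- cumulative_frequency(data.frame(force_nN = 0, p_crit_mbar = totals,
                                         censored = FALSE))
  fit <- fit_boltzmann(cdf)
  list(totals = totals, fit = fit, half_max = fit$a)
}

#' Stimulus-to-tension conversion coefficients
#'
#' @param alpha_F mean-tension coefficient for indentation ((mN/m)/nN).
#' @param alpha_p mean-tension coefficient for aspiration ((mN/m)/mbar).
#' @param alpha_F_A area-integrated coefficient ((mN/m) um^2 / nN).
#' @param alpha_p_A area-integrated coefficient ((mN/m) um^2 / mbar).
#' @return a `tension_coefficients` list.
#' @export
tension_coefficients <- function(alpha_F = 0.0065, alpha_p = 0.0024,
                                 alpha_F_A = 0.0076, alpha_p_A = 0.0325) {
  v <- c(alpha_F, alpha_p, alpha_F_A, alpha_p_A)
  if (any(v < 0)) stop("coefficients must be >= 0", call. = FALSE)
  structure(list(alpha_F = alpha_F, alpha_p = alpha_p,
                 alpha_F_A = alpha_F_A, alpha_p_A = alpha_p_A),
            class = "tension_coefficients")
}

#' Total membrane tension change from a combined stimulus
#'
#' `dT_tot = alpha_F * F + alpha_p * p` and its area-integrated counterpart
#' `int dT_tot dA = alpha_F_A * F + alpha_p_A * p`.
#'
#' @param F indentation force (nN), >= 0.
#' @param p aspiration pressure (mbar), >= 0.
#' @param coeffs a [tension_coefficients()].
#' @return list with `dT_tot` (mN/m) and `dT_tot_area` ((mN/m) um^2).
#' @export
delta_T_tot <- function(F, p, coeffs = tension_coefficients()) {
  if (any(F < 0) || any(p < 0))
    stop("'F' and 'p' must be non-negative", call. = FALSE)
  list(dT_tot = coeffs$alpha_F * F + coeffs$alpha_p * p,
       dT_tot_area = coeffs$alpha_F_A * F + coeffs$alpha_p_A * p)
}

#' Fraction of responding cells
#'
#' A cell responds when its peak fluorescence fold change over baseline
#' reaches the threshold (default threefold).
#'
#' @param peak_fold_changes numeric vector of per-cell peak F/F0.
#' @param threshold responder threshold, default 3.
#' @return fraction in \[0, 1\].
#' @export
responder_fraction <- function(peak_fold_changes, threshold = 3) {
  if (!length(peak_fold_changes)) stop("empty input", call. = FALSE)
  mean(peak_fold_changes >= threshold)
}
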