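test_that("delta-IRF noiseless single exponential is recovered exactly", {
  ## noiseless histogram of an exponential launched at the IRF bin center
  ## (the binned-IRF convention: an IRF spike in bin j sits at its center)
  n_bins <- 128
  dt <- 25 / n_bins
  t <- (seq_len(n_bins) - 0.5) * dt
  irf <- as.numeric(seq_len(n_bins) == 1L)
  t0 <- t[1L]
  edges <- pmax(seq(0, 25, by = dt) - t0, 0)
  counts <- 1e5 * diff(-exp(-edges / 4))
  h <- list(time_ns = t, counts = counts, irf = irf, dt_ns = dt)
  f <- fit_reconvolution(h, fix_tau_short = 1)
  expect_equal(f$tau_long, 4, tolerance = 5e-3)
  ## and through the photon-sampling generator at high counts
  hg <- generate_tcspc_histogram(tcspc_gen_config(
    tau_long = 4, tau_short = 1, frac_long = 1, irf_fwhm = 0, t0 = 1,
    n_photons = 1e6, window = 30, seed = 17))
  fg <- fit_reconvolution(hg, fix_tau_short = 1)
  expect_equal(fg$tau_long, 4, tolerance = 0.01)
})

test_that("masking below the photon threshold, not an exception", {
  h <- generate_tcspc_histogram(tcspc_gen_config(n_photons = 200, seed = 1))
  f <- fit_reconvolution(h, min_photons = 1000)
  expect_true(f$masked)
  expect_true(is.na(f$tau_long))
  expect_equal(f$n_photons, 200L)
})

test_that("reconvolution fit matches a grid-search MLE oracle", {
  h <- generate_tcspc_histogram(tcspc_gen_config(
    tau_long = 5, tau_short = 2, frac_long = 0.6, irf_fwhm = 0.2,
    n_photons = 1e5, seed = 5))
  f <- fit_reconvolution(h)
  ## independent coarse grid search over (tau_long, tau_short, frac)
  grid <- expand.grid(tl = seq(4.2, 5.8, 0.1), ts = seq(1.2, 2.8, 0.1),
                      fr = seq(0.35, 0.85, 0.05))
  nll <- function(tl, ts, fr) {
    lam <- 1e5 * tensiopipe:::reconv_shape(h$time_ns, h$dt_ns, h$irf,
                                           tl, ts, fr)
    sum(pmax(lam, 1e-12) - h$counts * log(pmax(lam, 1e-12)))
  }
  vals <- mapply(nll, grid$tl, grid$ts, grid$fr)
  best <- grid[which.min(vals), ]
  expect_lt(abs(f$tau_long - best$tl), 0.1 + 1e-9)   # one grid cell
  expect_lt(abs(f$tau_long - 5), 3 * f$se_tau_long)
  expect_lte(f$nll, min(vals) + 1e-6)                # true optimum is better
})

test_that("fit is invariant to exposure rescaling of counts", {
  h <- generate_tcspc_histogram(tcspc_gen_config(
    tau_long = 5, tau_short = 2, frac_long = 0.6, n_photons = 2e4, seed = 6))
  f1 <- fit_reconvolution(h)
  h2 <- h
  h2$counts <- h$counts * 4L
  f2 <- fit_reconvolution(h2)
  expect_equal(f2$tau_long, f1$tau_long, tolerance = 1e-3)
  expect_equal(f2$tau_short, f1$tau_short, tolerance = 2e-3)
})

test_that("tau_long estimates are unbiased at >= 1e4 photons", {
  est <- vapply(1:12, function(s) {
    h <- generate_tcspc_histogram(tcspc_gen_config(
      tau_long = 5, tau_short = 2, frac_long = 0.6, n_photons = 1e4,
      seed = 100 + s))
    fit_reconvolution(h)$tau_long
  }, 0)
  se_mean <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 5), 3.5 * se_mean)
})

test_that("lifetime image: two-stage fit recovers the site contrast", {
  sc <- small_flim_scene(seed = 7, delta = 0.3, photons = 2000)
  img0 <- fit_lifetime_image(sc, step = 1, min_photons = 1000)
  img1 <- fit_lifetime_image(sc, step = 2, min_photons = 1000)
  site <- sc$site_mask
  d_site <- mean(img1$tau_long[site]) - mean(img0$tau_long[site])
  se <- sqrt(stats::var(img1$tau_long[site]) / sum(site) +
             stats::var(img0$tau_long[site]) / sum(site))
  expect_lt(abs(d_site - 0.3), 4 * se)
  ## background unchanged
  d_bg <- mean(img1$tau_long[!site]) - mean(img0$tau_long[!site])
  expect_lt(abs(d_bg), 0.05)
})

test_that("per-pixel tau SD is consistent with the Cramer-Rao bound", {
  sc <- small_flim_scene(seed = 8, delta = 0, photons = 2000)
  img <- fit_lifetime_image(sc, step = 1, min_photons = 1000)
  sd_obs <- stats::sd(img$tau_long[img$mask])
  ## numeric Fisher information for (tau_long, frac) at the truth,
  ## tau_short fixed as in stage 2
  lam_of <- function(tl, fr) 2000 * tensiopipe:::reconv_shape(
    sc$time_ns, sc$dt_ns, sc$irf, tl, sc$config$tau_short, fr)
  l0 <- lam_of(5, 0.7)
  dtl <- (lam_of(5.001, 0.7) - lam_of(4.999, 0.7)) / 0.002
  dfr <- (lam_of(5, 0.701) - lam_of(5, 0.699)) / 0.002
  ok <- l0 > 1e-9          # skip pre-rise zero-rate bins
  I <- matrix(c(sum(dtl[ok]^2 / l0[ok]), sum(dtl[ok] * dfr[ok] / l0[ok]),
                sum(dtl[ok] * dfr[ok] / l0[ok]), sum(dfr[ok]^2 / l0[ok])),
              2, 2)
  crb_sd <- sqrt(solve(I)[1, 1])
  expect_gt(sd_obs, crb_sd / 1.3)   # cannot beat the bound (noise floor)
  expect_lt(sd_obs, 2 * crb_sd)     # efficient within factor 2
})

test_that("dark pixels are masked; an all-dark image errors", {
  sc <- small_flim_scene(seed = 9, delta = 0, photons = 1500)
  ## darken a corner: those pixels must come back masked, not fitted
  sc$counts[[1]][1:4, 1:4, ] <- 0L
  img <- fit_lifetime_image(sc, step = 1, min_photons = 1000)
  expect_true(all(!img$mask[1:4, 1:4]))
  expect_true(all(is.na(img$tau_long[!img$mask])))
  expect_true(all(!is.na(img$tau_long[img$mask])))
  expect_error(fit_lifetime_image(sc, step = 1, min_photons = 1e7),
               "photon threshold")
})

test_that("calibrate_tension: exact line, units, noisy recovery", {
  lt <- c(4.9, 5.05, 5.2, 5.35, 5.5)
  cal <- calibrate_tension(lt, -6 + 1.325 * lt)
  expect_equal(cal$c, 1.325, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-10)
  ## unit relabeling mN/m <-> nN/um is the identity
  cal2 <- calibrate_tension(lt, (-6 + 1.325 * lt) * 1.0)
  expect_equal(cal2$c, cal$c)
  expect_error(calibrate_tension(c(1, 2), c(1, 2)), "3 paired")
  ## noisy: truth within 3 fitted SE
  d <- generate_calibration_pairs(seed = 10)
  caln <- calibrate_tension(d$lifetime_ns, d$tension_mN_m)
  expect_lt(abs(caln$c - 1.325), 3 * caln$se_c)
})

test_that("lifetime_to_tension is linear through the conversion factor", {
  cal <- calibrate_tension(c(4.9, 5.2, 5.5), -6 + 1.325 * c(4.9, 5.2, 5.5))
  expect_equal(lifetime_to_tension(0, cal), 0)
  expect_equal(lifetime_to_tension(0.1, cal), 0.1325, tolerance = 1e-9)
  expect_equal(lifetime_to_tension(0.2, cal), 2 * lifetime_to_tension(0.1, cal))
  expect_error(lifetime_to_tension(0.1, -2), "invalid")
})

test_that("fit_stimulus_tension recovers exact and zero slopes", {
  F <- c(2, 10, 25, 37, 50)
  expect_equal(fit_stimulus_tension(F, 0.0065 * F)$alpha, 0.0065,
               tolerance = 1e-12)
  p <- c(0, 25, 50, 75, 100)
  expect_equal(fit_stimulus_tension(p, 0.0024 * p)$alpha, 0.0024,
               tolerance = 1e-12)
  set.seed(13)
  z <- fit_stimulus_tension(F, stats::rnorm(5, 0, 0.01))
  expect_lt(abs(z$alpha), 3 * z$se)
})

test_that("integrate_tension_change: identity, arithmetic, additivity", {
  mk <- function(tau, se = 0.01, px = 0.1) {
    structure(list(tau_long = tau, se_tau_long = tau * 0 + se,
                   photons = tau * 0 + 2000, mask = !is.na(tau),
                   pixel_size_um = px),
              class = "lifetime_image")
  }
  base <- matrix(5, 10, 10)
  b <- mk(base)
  expect_equal(integrate_tension_change(b, mk(base), 1.325)$integral, 0)
  ## 25 pixels raised by 0.2 ns at 0.01 um^2 pixels and c = 1.325
  aft <- base
  aft[1:5, 1:5] <- 5.2
  res <- integrate_tension_change(b, mk(aft), 1.325, k_sigma = 2)
  expect_equal(res$integral, 25 * 1.325 * 0.2 * 0.01, tolerance = 1e-9)
  expect_equal(sum(res$affected), 25)
  ## additive over disjoint affected regions
  aft2 <- base
  aft2[6:8, 6:8] <- 5.3
  r2 <- integrate_tension_change(b, mk(aft2), 1.325)
  both <- base
  both[1:5, 1:5] <- 5.2
  both[6:8, 6:8] <- 5.3
  r12 <- integrate_tension_change(b, mk(both), 1.325)
  expect_equal(r12$integral, res$integral + r2$integral, tolerance = 1e-9)
  expect_error(integrate_tension_change(b, mk(matrix(5, 9, 9)), 1.325),
               "misaligned")
})

test_that("kymograph analysis: verdicts for flat, bleb and intact scenes", {
  ## constant lifetime: no ROI reports a change
  k0 <- generate_flim_kymograph(tau_delta = 0, seed = 1)
  v0 <- analyze_kymograph(k0)
  expect_false(any(v0$verdicts))
  ## bleb-like: step at BOTH site and distant membrane at contact
  kb <- generate_flim_kymograph(tau_delta = 0.3,
                                delta_rois = c("site", "membrane"), seed = 2)
  vb <- analyze_kymograph(kb)
  expect_true(vb$verdicts[["membrane"]])
  expect_true(vb$verdicts[["site"]])
  ## intact-cell-like: step only at the site; membrane stays quiet
  ki <- generate_flim_kymograph(tau_delta = 0.3, delta_rois = "site",
                                seed = 3)
  vi <- analyze_kymograph(ki)
  expect_true(vi$verdicts[["site"]])
  expect_false(vi$verdicts[["membrane"]])
  expect_error(analyze_kymograph(ki, contact_time_s = 1e6), "contact_time")
})

test_that("pipeline recovers alpha coefficients from generated scenes", {
  ## image-free shortcut: per-step mean lifetime at the site converted by c;
  ## truth alpha_p = 0.0024 at c = 1.325 -> d tau/d p = alpha_p / c
  set.seed(14)
  p <- c(0, 25, 50, 75, 100)
  dtau_dp <- 0.0024 / 1.325
  dtau <- dtau_dp * p + stats::rnorm(5, 0, 2e-3)
  dT <- lifetime_to_tension(dtau, 1.325)
  f <- fit_stimulus_tension(p, dT)
  expect_lt(abs(f$alpha - 0.0024), 3 * f$se)
})
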