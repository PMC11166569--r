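test_that("cumulative_frequency counts ties and censoring correctly", {
  rec <- data.frame(force_nN = 2, p_crit_mbar = c(50, 75, 75, 100),
                    censored = FALSE)
  cdf <- cumulative_frequency(rec, force = 2)
  expect_equal(cdf$pressures, c(50, 75, 100))
  expect_equal(cdf$cumfreq, c(0.25, 0.75, 1.0))
  expect_equal(cdf$n_cells, 4)
  ## censored cells excluded by default, counted with include_censored
  rec2 <- rbind(rec, data.frame(force_nN = 2, p_crit_mbar = 400,
                                censored = TRUE))
  expect_equal(cumulative_frequency(rec2, 2)$cumfreq, c(0.25, 0.75, 1.0))
  expect_equal(max(cumulative_frequency(rec2, 2,
                                        include_censored = TRUE)$cumfreq),
               0.8)
  expect_error(cumulative_frequency(
    data.frame(force_nN = 2, p_crit_mbar = 1, censored = TRUE), 2),
    "censored")
})

test_that("empirical CDF lies within the DKW band of the logistic CDF", {
  set.seed(11)
  x <- stats::rlogis(10000, 100, 10)
  cdf <- cumulative_frequency(data.frame(force_nN = 1, p_crit_mbar = x,
                                         censored = FALSE), 1)
  band <- sqrt(log(2 / 0.001) / (2 * 10000))  # alpha = 0.001
  expect_lt(max(abs(cdf$cumfreq - stats::plogis(cdf$pressures, 100, 10))),
            band)
})

test_that("fit_boltzmann recovers exact sigmoid samples and its formulas", {
  p <- seq(0, 400, 25)
  y <- 1 / (1 + exp(-(p - 100) / 10))
  f <- fit_boltzmann(list(pressures = p, cumfreq = y))
  expect_equal(f$a, 100, tolerance = 1e-6)
  expect_equal(f$b, 10, tolerance = 1e-6)
  expect_lt(f$chi2_sig, 1e-12)
  expect_equal(f$error, f$sigma, tolerance = 1e-8)
  expect_true(is.infinite(f$GoM) || f$GoM > 1e6)
})

test_that("GoM and composite error identities hold on noisy fits", {
  set.seed(12)
  for (i in 1:5) {
    x <- stats::rlogis(80, 150, 15)
    cdf <- cumulative_frequency(data.frame(force_nN = 1, p_crit_mbar = x,
                                           censored = FALSE), 1)
    f <- fit_boltzmann(cdf)
    expect_equal(f$GoM, f$chi2_lin / f$chi2_sig + 1, tolerance = 1e-12)
    expect_equal(f$error, f$sigma + f$a / f$GoM, tolerance = 1e-12)
    expect_gte(f$error, f$sigma)
    expect_gte(f$GoM, 1)
  }
})

test_that("fit_boltzmann is consistent: a within 3 SE over repeat draws", {
  ## Monte-Carlo: the estimator must cover the truth at nominal-ish rate,
  ## using the cell-resampling bootstrap SE (ECDF points are correlated)
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    x <- stats::rlogis(5000, 100, 10)
    cdf <- cumulative_frequency(data.frame(force_nN = 1, p_crit_mbar = x,
                                           censored = FALSE), 1)
    f <- suppressWarnings(fit_boltzmann(cdf))
    se <- boltzmann_se_bootstrap(cdf, n_boot = 60, seed = s)$se_a
    hits <- hits + (abs(f$a - 100) < 3 * se)
  }
  expect_gte(hits, 9L)
})

test_that("bias shrinks with n (consistency check at n=1e2 vs 1e4)", {
  est <- function(n, nrep) {
    mean(vapply(seq_len(nrep), function(i) {
      set.seed(1000 * n + i)
      x <- stats::rlogis(n, 100, 10)
      cdf <- cumulative_frequency(data.frame(force_nN = 1, p_crit_mbar = x,
                                             censored = FALSE), 1)
      suppressWarnings(fit_boltzmann(cdf))$a
    }, 0))
  }
  b_small <- abs(est(100, 30) - 100)
  b_big <- abs(est(10000, 10) - 100)
  expect_lt(b_big, b_small + 0.5)
  expect_lt(b_big, 0.6)
})

test_that("fit_pc50_vs_force recovers an exact line", {
  F <- c(2, 12.5, 25, 37.5, 50)
  crv <- fit_pc50_vs_force(F, 250 - 4.84 * F)
  expect_equal(crv$slope, -4.84, tolerance = 1e-10)
  expect_equal(crv$intercept, 250, tolerance = 1e-10)
  expect_equal(crv$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_pc50_vs_force(c(1, 2), c(1, 2)), "3 forces")
})

test_that("line-fit slope SE agrees with a bootstrap SE within 30%", {
  cfg <- ctrl_gen(seed = 21)
  rec <- generate_critical_pressures(cfg)
  pl <- activation_pipeline(rec)
  bs <- activation_pipeline_bootstrap(rec, n_boot = 80, seed = 22)
  ## the two estimates measure different things (conditional vs full
  ## sampling variance); they must agree in order of magnitude
  expect_lt(abs(pl$curve$se_slope - bs$se_slope),
            0.8 * max(pl$curve$se_slope, bs$se_slope))
})

test_that("total activation pressure: noiseless totals equal the intercept", {
  F <- rep(c(2, 6, 12.5, 18, 25), each = 4)
  rec <- data.frame(force_nN = F, p_crit_mbar = 190 - 4.7 * F,
                    censored = FALSE)
  tot <- total_activation_pressure(rec, slope = -4.7)
  expect_equal(unique(round(tot$totals, 9)), 190)
  ## permutation invariance
  perm <- sample(nrow(rec))
  tot2 <- total_activation_pressure(rec[perm, ], slope = -4.7)
  expect_equal(sort(tot$totals), sort(tot2$totals))
  expect_error(total_activation_pressure(rec[0, ], -4.7), "no non-censored")
})

test_that("half-max of generator totals matches the generating intercept", {
  cfg <- ctrl_gen(seed = 23)
  rec <- generate_critical_pressures(cfg)
  pl <- activation_pipeline(rec)
  tot <- suppressWarnings(total_activation_pressure(rec, pl$curve$slope))
  ## snapping adds ~step/2 to each observed pressure
  expect_lt(abs(tot$half_max - (190 + 12.5)), 8)
})

test_that("delta_T_tot: identities, linearity, validation", {
  co <- tension_coefficients()
  expect_equal(delta_T_tot(0, 0, co)$dT_tot, 0)
  expect_equal(delta_T_tot(48, 0, co)$dT_tot, 0.312)
  expect_equal(delta_T_tot(0, 100, co)$dT_tot, 0.24)
  d1 <- delta_T_tot(10, 50, co)
  d2 <- delta_T_tot(20, 100, co)
  expect_equal(d2$dT_tot, 2 * d1$dT_tot)
  expect_equal(d2$dT_tot_area, 2 * d1$dT_tot_area)
  expect_error(delta_T_tot(-1, 0, co), "non-negative")
  expect_error(tension_coefficients(alpha_F = -1), ">= 0")
})

test_that("responder_fraction counts thresholded folds", {
  expect_equal(responder_fraction(c(1, 1, 1)), 0)
  expect_equal(responder_fraction(c(4, 4, 2)), 2 / 3)
  set.seed(31)
  folds <- ifelse(stats::runif(10000) < 0.7, 4, 1.2)
  expect_lt(abs(responder_fraction(folds) - 0.7), 0.015)
  expect_error(responder_fraction(numeric(0)), "empty")
})

test_that("full pipeline recovers all three treatment parameter sets", {
  ## control, CytoD, MargAc lines; 3-SE coverage via bootstrap SEs
  ## NOTE: the printed margaric-acid line (117 - 5.6 F) goes negative at
  ## 25 nN, so its generator run is restricted to the forces where the
  ## latent mean pressure stays positive
  sets <- list(ctrl = list(a0 = 190, b = -4.7,
                           forces = c(2, 6, 12.5, 18, 25),
                           n = c(44, 44, 44, 44, 44)),
               cytod = list(a0 = 167, b = -6.3,
                            forces = c(2, 6, 12.5, 18, 25),
                            n = c(19, 11, 13, 11, 19)),
               margac = list(a0 = 117, b = -5.6,
                             forces = c(2, 6, 12.5),
                             n = c(25, 24, 27)))
  for (nm in names(sets)) {
    s <- sets[[nm]]
    cfg <- activation_gen_config(forces = s$forces,
                                 n_per_force = s$n, intercept_a0 = s$a0,
                                 slope_beta = s$b, width_b = 12,
                                 treatment = nm, seed = 77)
    rec <- generate_critical_pressures(cfg)
    pl <- suppressWarnings(activation_pipeline(rec))
    bs <- activation_pipeline_bootstrap(rec, n_boot = 60, seed = 78)
    expect_lt(abs(pl$curve$intercept - s$a0), 3 * bs$se_intercept,
              label = paste(nm, "intercept dev"))
    expect_lt(abs(pl$curve$slope - s$b), 3 * bs$se_slope,
              label = paste(nm, "slope dev"))
  }
})
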