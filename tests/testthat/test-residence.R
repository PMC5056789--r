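test_that("bound-track selection applies Dm threshold and length floor", {
  tl <- timing_tl()
  # slow track (tiny steps) over 4 frames, fast track, single-frame track
  slow <- cbind(c(1, 1.01, 1.02, 1.01), c(1, 1, 1.01, 1.02))
  fast <- cbind(c(0, 1, 2), c(0, 1, 2))
  ts <- toy_track_set(list(slow, fast, cbind(5, 5)), tl)
  sel <- select_bound_tracks(ts)
  expect_equal(n_tracks(sel), 1)
  expect_equal(unique(sel$localizations$track_id), "trk1")
  expect_equal(attr(sel, "fraction_passing"), 0.5)
  expect_warning(select_bound_tracks(toy_track_set(list(slow))),
                 "continuous")
})

test_that("dwell times follow the (n-1) x interval convention", {
  tl <- timing_tl()
  ts <- toy_track_set(list(
    matrix(rep(1, 10), ncol = 2),  # 5 frames
    matrix(rep(2, 4), ncol = 2),   # 2 frames
    cbind(3, 3)                    # 1 frame -> dropped
  ), tl)
  dw <- dwell_times(ts)
  expect_equal(sort(dw$dwell), c(0.2, 0.8))
  expect_equal(attr(dw, "n_dropped"), 1)
  dwn <- dwell_times(ts, convention = "n")
  expect_equal(sort(dwn$dwell), c(0.2, 0.4, 1.0))
})

test_that("empirical CCDF is the right-tail count", {
  cc <- empirical_ccdf(c(0.2, 0.2, 0.8))
  expect_equal(cc$tau, c(0.2, 0.8))
  expect_equal(cc$count, c(3, 1))
  expect_true(all(diff(cc$count) <= 0))
  expect_error(empirical_ccdf(numeric(0)), "no dwell")
})

test_that("empirical CCDF matches the exponential tail law", {
  set.seed(3)
  tau_bar <- 2.5
  d <- stats::rexp(1e4, rate = 1 / tau_bar)
  cc <- empirical_ccdf(d)
  idx <- cc$tau < 3 * tau_bar
  expect_lt(max(abs(cc$count[idx] / 1e4 - exp(-cc$tau[idx] / tau_bar))),
            0.02)
})

test_that("photobleach fitting selects the generating model", {
  grid <- seq(0, 60, by = 0.2)
  two <- photobleach_model(fb1 = 0.5, taub1 = 2, fb2 = 0.5, taub2 = 20)
  sim <- simulate_photobleach_curves(two, n_curves = 9, noise_sd = 0.01,
                                     grid = grid, seed = 4)
  fit <- fit_photobleach(sim$time, sim$curves)
  expect_equal(fit$model_choice, "two_exp")
  expect_equal(fit$taub1, 2, tolerance = 0.15)
  expect_equal(fit$taub2, 20, tolerance = 0.15)

  one <- photobleach_model(fb1 = 1, taub1 = 8)
  sim1 <- simulate_photobleach_curves(one, n_curves = 9, noise_sd = 0.01,
                                      grid = grid, seed = 5)
  fit1 <- fit_photobleach(sim1$time, sim1$curves)
  expect_equal(fit1$model_choice, "one_exp")
  expect_equal(fit1$taub1, 8, tolerance = 0.1)

  expect_error(fit_photobleach(grid, matrix(1, length(grid), 3)),
               "degenerate")
})

test_that("CCDF correction divides by B and is identity at B = 1", {
  cc <- empirical_ccdf(c(0.2, 0.4, 0.4, 1.2))
  flat <- photobleach_model(fb1 = 1, taub1 = 1e9)
  expect_equal(correct_ccdf(cc, flat)$count, cc$count, tolerance = 1e-6)

  mdl <- photobleach_model(fb1 = 1, taub1 = 2)
  corr <- correct_ccdf(cc, mdl)
  expect_equal(corr$count, cc$count / exp(-cc$tau / 2))

  neg <- photobleach_model(fb1 = 1, taub1 = 2, y0 = -0.9)
  expect_error(correct_ccdf(cc, neg), "cannot correct")
})

test_that("nested F-test reproduces the closed-form statistic", {
  # ((10-5)/2) / (5/45) = 22.5
  ft <- ftest_nested(10, 3, 5, 5, 50)
  expect_equal(ft$f_statistic, 22.5)
  expect_equal(ft$p_value, stats::pf(22.5, 2, 45, lower.tail = FALSE))
  expect_true(ft$choose_complex)

  same <- ftest_nested(5, 3, 5, 5, 50)
  expect_equal(same$f_statistic, 0)
  expect_false(same$choose_complex)

  perfect <- ftest_nested(5, 3, 0, 5, 50)
  expect_true(perfect$choose_complex)
  expect_equal(perfect$p_value, 0)

  expect_error(ftest_nested(3, 3, 5, 5, 50), "nested")
})

test_that("dwell fit recovers exact noiseless decay parameters", {
  tau <- seq(0.2, 30, by = 0.2)
  y <- 800 * exp(-tau / 0.8) + 180 * exp(-tau / 7)
  cc <- structure(data.frame(tau = tau, count = y),
                  class = c("dwell_ccdf", "data.frame"))
  fit <- fit_dwell_exponentials(cc)
  expect_equal(fit$model_choice, "two_exp")
  expect_equal(fit$tau_tb, 0.8, tolerance = 1e-4)
  expect_equal(fit$tau_sb, 7, tolerance = 1e-4)
  expect_equal(fit$B1, 800, tolerance = 0.01)
  expect_equal(fit$B2, 180, tolerance = 0.01)
  expect_lt(fit$tau_tb, fit$tau_sb)
})

test_that("dwell fits recover generating time constants from samples", {
  # single-exponential dwells: the one-exponential fit recovers tau.
  # (On unbinned cumulative counts the errors are strongly correlated,
  # so the F-test can still flag a cosmetic second component; when it
  # does, that component carries only a sliver of amplitude.)
  set.seed(12)
  one <- empirical_ccdf(round(stats::rexp(2500, 1 / 5) / 0.2) * 0.2 + 0.2)
  f1 <- fit_dwell_exponentials(one)
  expect_equal(unname(f1$one_exp[["tau"]]), 5, tolerance = 0.1)
  if (f1$model_choice == "two_exp") {
    dominant <- max(f1$B1, f1$B2) / (f1$B1 + f1$B2)
    expect_gt(dominant, 0.9)
  }

  mix <- c(stats::rexp(2400, 1 / 0.79), stats::rexp(600, 1 / 7.3))
  two <- empirical_ccdf(floor(mix / 0.2) * 0.2 + 0.2)
  f2 <- fit_dwell_exponentials(two)
  expect_equal(f2$model_choice, "two_exp")
  expect_equal(f2$tau_tb, 0.79, tolerance = 0.15)
  expect_equal(f2$tau_sb, 7.3, tolerance = 0.12 * 7.3)
})

test_that("subfractions split F1 by amplitude ratio and conserve it", {
  fit <- structure(list(B1 = 1, B2 = 1), class = "dwell_fit")
  expect_equal(subfractions(30, fit), c(F1tb = 15, F1sb = 15))
  fit$B1 <- 5; fit$B2 <- 0
  expect_equal(subfractions(30, fit), c(F1tb = 30, F1sb = 0))
  fit$B1 <- 0.37; fit$B2 <- 1.91
  s <- subfractions(29, fit)
  expect_identical(unname(sum(s)), 29)
  fit$B1 <- 0; fit$B2 <- 0
  expect_error(subfractions(29, fit), "degenerate")
})

test_that("survival probability is a normalized non-increasing curve", {
  set.seed(14)
  d <- floor(stats::rexp(5000, 1 / 3) / 0.2) * 0.2 + 0.2
  cc <- empirical_ccdf(d)
  sp <- survival_probability(cc)
  expect_equal(sp$survival[1], 1)
  expect_true(all(diff(sp$survival) <= 0))
  idx <- sp$tau <= 9
  expect_lt(max(abs(sp$survival[idx] -
                      exp(-(sp$tau[idx] - min(sp$tau)) / 3))), 0.03)
})

test_that("bleach correction removes the truncation bias in tau_sb", {
  cfg <- preset("cbx7_dwell_wt")
  cfg_nb <- cfg; cfg_nb$bleach <- NULL

  # no bleaching: unbiased
  ts_nb <- simulate_timelapse_bound(cfg_nb, seed = 2)
  cc_nb <- empirical_ccdf(dwell_times(select_bound_tracks(ts_nb)))
  f_nb <- fit_dwell_exponentials(cc_nb)
  expect_equal(f_nb$tau_sb, 7.3, tolerance = 0.12 * 7.3)

  ts <- simulate_timelapse_bound(cfg, seed = 2)
  cc <- empirical_ccdf(dwell_times(select_bound_tracks(ts)))

  # bleaching, no correction: biased low by construction
  f_raw <- fit_dwell_exponentials(cc)
  expect_lt(f_raw$tau_sb, 0.9 * 7.3)

  # bleaching + correction: bias removed
  b <- bleach_survival(cfg$bleach, cc$tau)
  f_cor <- fit_dwell_exponentials(correct_ccdf(cc, cfg$bleach),
                                  weights = b^2)
  expect_equal(f_cor$tau_sb, 7.3, tolerance = 0.12 * 7.3)
  expect_gt(f_cor$tau_sb, f_raw$tau_sb)
})

test_that("bound selection passes nearly all slow molecules", {
  cfg <- preset("cbx7_dwell_wt")
  ts <- simulate_timelapse_bound(cfg, seed = 9)
  sel <- select_bound_tracks(ts)
  expect_gt(attr(sel, "fraction_passing"), 0.90)
  expect_lte(attr(sel, "fraction_passing"), 1)
})
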