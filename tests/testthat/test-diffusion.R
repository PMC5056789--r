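test_that("Dm and Df1 match hand-computed squared displacements", {
  tc <- timing_cont()
  trk <- single_track_df(cbind(c(0, 0.1, 0.1), c(0, 0, 0.1)))
  # steps: (0.1,0) and (0,0.1) -> r2 = 0.01 each; Dm = 0.01 / (4*0.03)
  expect_equal(compute_dm(trk, tc), 0.01 / 0.12)
  expect_equal(compute_df1(trk, tc), 0.01 / 0.12)

  trk2 <- single_track_df(cbind(c(0, 0.06), c(0, 0)))
  expect_equal(compute_df1(trk2, tc), 0.0036 / 0.12)
  # two-point track: Dm == Df1
  expect_equal(compute_dm(trk2, tc), compute_df1(trk2, tc))

  # Df1 ignores everything after the first step
  trk3 <- single_track_df(cbind(c(0, 0.1, 5), c(0, 0, 5)))
  expect_equal(compute_df1(trk3, tc), 0.01 / 0.12)

  # stationary track
  trk4 <- single_track_df(cbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(compute_dm(trk4, tc), 0)

  expect_error(compute_dm(single_track_df(cbind(1, 1)), tc), "fewer than 2")
})

test_that("Dm equals the mean of per-step first-step estimators", {
  set.seed(7)
  tc <- timing_cont()
  xy <- cbind(cumsum(rnorm(12, 0, 0.1)), cumsum(rnorm(12, 0, 0.1)))
  trk <- single_track_df(xy)
  # oracle: explicit loop over steps
  per_step <- vapply(seq_len(nrow(xy) - 1), function(i) {
    sum((xy[i + 1, ] - xy[i, ])^2) / (4 * tc$lapse_interval)
  }, numeric(1))
  expect_equal(compute_dm(trk, tc), mean(per_step))
})

test_that("Dm is invariant under rigid motions and time reversal", {
  set.seed(8)
  tc <- timing_cont()
  xy <- cbind(cumsum(rnorm(10, 0, 0.2)), cumsum(rnorm(10, 0, 0.2)))
  trk <- single_track_df(xy)
  d0 <- compute_dm(trk, tc)
  # translation
  expect_equal(compute_dm(single_track_df(xy + 3), tc), d0)
  # rotation by 37 degrees
  th <- 37 * pi / 180
  rot <- xy %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(compute_dm(single_track_df(rot), tc), d0)
  # time reversal
  expect_equal(compute_dm(single_track_df(xy[nrow(xy):1, ]), tc), d0)
})

test_that("per-track Dm follows the chi-squared spread over 2L dof", {
  # for L steps at true D, Dm * 2L / D ~ chisq(2L)
  L <- 5
  cfg <- sim_config(populations = data.frame(weight = 1, d = 0.25),
                    timing = timing_cont(), n_tracks = 3000,
                    mean_frames = L + 1, track_length_law = "fixed")
  ts <- simulate_mixture_tracks(cfg, seed = 31)
  est <- diffusion_estimates(ts)
  expect_true(all(est$n_steps == L))
  expect_equal(mean(est$dm), 0.25, tolerance = 0.02)
  ks <- suppressWarnings(stats::ks.test(est$dm * 2 * L / 0.25,
                                        stats::pchisq, df = 2 * L))
  expect_gt(ks$p.value, 0.01)
})

test_that("log-D histogram is density-normalized and clamps zeros", {
  est <- data.frame(dm = rep(0.032, 50), df1 = rep(0.032, 50))
  h <- build_logd_histogram(est, "dm")
  expect_equal(sum(h$density) * attr(h, "bin_width"), 1)
  expect_equal(sum(h$density > 0), 1)
  expect_equal(max(h$density), 1 / attr(h, "bin_width"))

  est2 <- data.frame(dm = c(rep(0.032, 9), 0), df1 = 0)
  h2 <- build_logd_histogram(est2, "dm")
  expect_equal(attr(h2, "n_clamped_zero"), 1)
  expect_equal(h2$count[1], 1)  # zero-displacement in the lowest bin
  expect_equal(sum(h2$count), 10)

  expect_error(build_logd_histogram(data.frame(dm = numeric(0)), "dm"))
})

test_that("log-D histogram reproduces a known log-normal density", {
  set.seed(21)
  mu <- -0.5; sigma <- 0.3
  est <- data.frame(dm = 10^rnorm(1e4, mu, sigma))
  h <- build_logd_histogram(est, "dm", bin_width = 0.2)
  dens_true <- stats::dnorm(h$center, mu, sigma)
  # binomial error per bin on 1e4 draws
  expect_lt(max(abs(h$density - dens_true)), 0.06)
})

test_that("mixture fit recovers an exact noiseless curve", {
  centers <- c(-1.5, -0.3, 0.4); widths <- c(0.5, 0.5, 0.45)
  areas <- c(0.6, 0.25, 0.15)
  grid <- seq(-3.4, 1.4, by = 0.2)
  y <- smtkin:::gaussian_mixture_value(grid, 0, centers, widths, areas)
  h <- structure(data.frame(center = grid, density = y,
                            count = round(y * 1000)),
                 class = c("logd_histogram", "data.frame"))
  attr(h, "bin_width") <- 0.2; attr(h, "range") <- c(-3.5, 1.5)
  fit <- fit_gaussian_mixture(h, 3)
  expect_true(fit$converged)
  expect_equal(fit$components$center, centers, tolerance = 1e-3)
  expect_equal(fit$components$width, widths, tolerance = 1e-3)
  expect_equal(fit$components$area, areas, tolerance = 1e-3)
  expect_equal(sum(fit$fractions), 100)
})

test_that("two-component fit of a single Gaussian leaves one empty", {
  grid <- seq(-3.4, 1.4, by = 0.2)
  y <- smtkin:::gaussian_mixture_value(grid, 0, -0.5, 0.6, 1)
  h <- structure(data.frame(center = grid, density = y,
                            count = round(y * 1000)),
                 class = c("logd_histogram", "data.frame"))
  attr(h, "bin_width") <- 0.2; attr(h, "range") <- c(-3.5, 1.5)
  fit <- fit_gaussian_mixture(h, 2)
  i <- which.max(fit$components$area)
  expect_equal(fit$components$center[i], -0.5, tolerance = 0.05)
  expect_equal(fit$components$width[i], 0.6, tolerance = 0.05)
  expect_lt(min(fit$components$area), 0.01)
})

test_that("fractions are area shares with exact conservation", {
  fake_fit <- structure(list(
    components = data.frame(center = c(-1.5, -0.3, 0.4),
                            width = 0.5, area = c(2, 1, 1),
                            fixed_center = c(TRUE, FALSE, FALSE)),
    area_vcov = diag(3) * 1e-4
  ), class = "diffusion_fit")
  fr <- fractions_from_fit(fake_fit)
  expect_equal(fr$fraction, c(50, 25, 25))
  expect_equal(sum(fr$fraction), 100)
  expect_true(all(fr$fraction_sd > 0))

  fake_fit$components$area <- c(1, 0, 0)
  expect_equal(fractions_from_fit(fake_fit)$fraction, c(100, 0, 0))

  fake_fit$components$area <- c(0, 0, 0)
  expect_error(fractions_from_fit(fake_fit), "degenerate")
})

test_that("fallback fires for data with no bound population", {
  cfg <- preset("nls_wt")
  ts <- simulate_mixture_tracks(cfg, seed = 5)
  h <- build_logd_histogram(diffusion_estimates(ts))
  fit <- fit_with_fallback(h)
  expect_true(fit$fell_back)
  expect_equal(nrow(fit$components), 2)
  expect_equal(fit$n_components_requested, 3L)
  # slower of the two components carries the bulk nuclear population
  expect_equal(fit$fractions[1], 71, tolerance = 3)
})

test_that("pure slow population yields a dominant fixed component", {
  cfg <- sim_config(populations = data.frame(weight = 1, d = 0.032),
                    timing = timing_cont(), n_tracks = 1500,
                    mean_frames = 6)
  ts <- simulate_mixture_tracks(cfg, seed = 6)
  h <- build_logd_histogram(diffusion_estimates(ts))
  fit <- fit_with_fallback(h)
  slow <- which(fit$components$fixed_center)
  if (length(slow) == 0) slow <- 1L   # fallback branch: slowest component
  expect_gt(fit$fractions[slow], 95)
})

test_that("Df1 and Dm analyses agree on the dominant bound population", {
  # A single displacement is exponentially distributed, so per-track Df1
  # smears each population by ~0.56 log10 units - far more than the
  # multi-step Dm. Under pure Brownian simulation the intermediate
  # population is barely identifiable in the Df1 histogram, so only
  # coarse agreement between the two analyses can be expected.
  cfg <- preset("h2a_wt")
  ts <- simulate_mixture_tracks(cfg, seed = 17)
  est <- diffusion_estimates(ts)
  f_dm <- fit_gaussian_mixture(build_logd_histogram(est, "dm"),
                               3, fixed_slow_center = -1.5)
  f_df1 <- fit_gaussian_mixture(build_logd_histogram(est, "df1"),
                                3, fixed_slow_center = -1.5)
  cb_dm <- f_dm$fractions[which(f_dm$components$fixed_center)]
  cb_df1 <- f_df1$fractions[which(f_df1$components$fixed_center)]
  expect_gt(cb_dm, 50)
  expect_gt(cb_df1, 50)
  expect_lt(abs(cb_dm - cb_df1), 15)
})
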