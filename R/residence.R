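#' Select chromatin-bound tracks from a time-lapse experiment
#'
#' Bound molecules are those detected for at least
#' `min_consecutive_frames` consecutive frames whose per-track diffusion
#' coefficient Dm is below `d_threshold` (default 0.10 um^2/s, below
#' which essentially all nucleosome-incorporated histone control
#' molecules fall).
#'
#' @param ts A time-lapse [track_set()] (a continuous-mode set is
#'   accepted with a warning).
#' @param d_threshold Dm threshold in um^2/s (default 0.10).
#' @param min_consecutive_frames Minimum frames per track (default 2).
#' @return Filtered `track_set` with attribute `fraction_passing`, the
#'   fraction of tracks (with >= `min_consecutive_frames` frames) whose
#'   Dm passed the threshold.
#' @export
select_bound_tracks <- function(ts, d_threshold = 0.10,
                                min_consecutive_frames = 2L) {
  stopifnot(inherits(ts, "track_set"), d_threshold > 0,
            min_consecutive_frames >= 2)
  if (ts$timing$mode != "timelapse") {
    warning("select_bound_tracks: track_set is continuous-mode, not time-lapse")
  }
  len <- table(ts$localizations$track_id)
  long_ids <- names(len)[len >= min_consecutive_frames]
  if (length(long_ids) == 0) {
    out <- ts
    out$localizations <- ts$localizations[0, ]
    attr(out, "fraction_passing") <- NA_real_
    return(out)
  }
  sub <- ts
  sub$localizations <- ts$localizations[
    ts$localizations$track_id %in% long_ids, , drop = FALSE]
  est <- diffusion_estimates(sub)
  keep_ids <- est$track_id[est$dm < d_threshold]
  out <- ts
  out$localizations <- ts$localizations[
    ts$localizations$track_id %in% keep_ids, , drop = FALSE]
  rownames(out$localizations) <- NULL
  attr(out, "fraction_passing") <- length(keep_ids) / length(long_ids)
  out
}

#' Apparent dwell times of tracks
#'
#' The apparent residence time of each molecule is read off its track
#' length: with the default convention, dwell = (n_frames - 1) x
#' frame interval, the time between first and last detection of the
#' fluorescent spot. Tracks with a single frame (dwell 0) are dropped
#' and counted in attribute `n_dropped`.
#'
#' @param ts A [track_set()].
#' @param convention `"n_minus_1"` (default) or `"n"` (dwell =
#'   n_frames x interval).
#' @return data.frame with columns `track_id`, `n_frames`, `dwell`
#'   (seconds).
#' @export
dwell_times <- function(ts, convention = c("n_minus_1", "n")) {
  stopifnot(inherits(ts, "track_set"))
  convention <- match.arg(convention)
  len <- table(ts$localizations$track_id)
  dt <- ts$timing$lapse_interval
  n_frames <- as.integer(len)
  dwell <- switch(convention,
                  n_minus_1 = (n_frames - 1L) * dt,
                  n = n_frames * dt)
  out <- data.frame(track_id = names(len), n_frames = n_frames,
                    dwell = dwell)
  dropped <- out$dwell <= 0
  res <- out[!dropped, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(dropped)
  res
}

#' Cumulative frequency distribution of dwell times
#'
#' The right-tail cumulative count: for each observed dwell value tau,
#' the number of molecules whose dwell is >= tau. This decreasing step
#' function is the object the exponential decay models are fitted to.
#'
#' @param dwells A [dwell_times()] data.frame or a numeric vector of
#'   dwell times (seconds).
#' @return data.frame of class `dwell_ccdf` with columns `tau` (sorted
#'   unique dwell values) and `count`; `count[1]` equals the number of
#'   dwells.
#' @export
empirical_ccdf <- function(dwells) {
  d <- if (is.data.frame(dwells)) dwells$dwell else as.numeric(dwells)
  if (length(d) == 0) stop("no dwell times")
  tau <- sort(unique(d))
  # count with dwell >= tau_k = n minus number of dwells strictly below tau_k
  tab <- tabulate(match(d, tau), length(tau))
  cnt <- length(d) - c(0, cumsum(tab))[seq_along(tau)]
  out <- data.frame(tau = tau, count = cnt)
  class(out) <- c("dwell_ccdf", "data.frame")
  out
}

#' Photobleaching decay model
#'
#' Two-component exponential fluorophore bleaching curve
#' `B(tau) = y0 + fb1 exp(-tau/taub1) + fb2 exp(-tau/taub2)`; `1/taub1`
#' and `1/taub2` are the bleaching rates. A one-component model is
#' represented with `fb2 = 0` and `taub2 = NA`. When `y0 = 0` and
#' `fb1 + fb2 = 1` the curve is also the survival function used to draw
#' bleach lifetimes in simulations.
#'
#' @param fb1,fb2 Amplitudes (>= 0).
#' @param taub1,taub2 Time constants in seconds (> 0); `taub2 = NA`
#'   allowed when `fb2 = 0`.
#' @param y0 Offset (default 0).
#' @return Object of class `photobleach_model`.
#' @export
photobleach_model <- function(fb1, taub1, fb2 = 0, taub2 = NA, y0 = 0) {
  stopifnot(fb1 >= 0, fb2 >= 0, taub1 > 0, is.na(taub2) || taub2 > 0)
  if (fb2 > 0 && is.na(taub2)) stop("taub2 required when fb2 > 0")
  structure(list(y0 = y0, fb1 = fb1, taub1 = taub1,
                 fb2 = fb2, taub2 = taub2),
            class = "photobleach_model")
}

#' Evaluate a photobleaching curve
#' @param model A [photobleach_model()].
#' @param tau Times in seconds.
#' @return `B(tau)`.
#' @export
bleach_survival <- function(model, tau) {
  stopifnot(inherits(model, "photobleach_model"))
  b <- model$y0 + model$fb1 * exp(-tau / model$taub1)
  if (model$fb2 > 0) b <- b + model$fb2 * exp(-tau / model$taub2)
  b
}

#' Fit a photobleaching model to ensemble decay curves
#'
#' Averages a set of intensity-vs-time curves (already background
#' corrected and normalized to 1 at tau = 0) and fits one- and
#' two-component exponential decays with offset, choosing between them
#' with the extra-sum-of-squares F-test at `alpha`.
#'
#' @param time Common time grid in seconds.
#' @param curves Matrix (length(time) x n_curves) or numeric vector of a
#'   single curve.
#' @param alpha F-test significance level (default 0.05).
#' @return A [photobleach_model()] with extra fields `model_choice`
#'   (`"one_exp"`/`"two_exp"`), `f_statistic`, `p_value`, `sds`.
#' @export
fit_photobleach <- function(time, curves, alpha = 0.05) {
  curves <- as.matrix(curves)
  stopifnot(length(time) == nrow(curves))
  y <- rowMeans(curves)
  if (stats::sd(y) < 1e-12) stop("degenerate photobleach data: constant curve")
  fits <- fit_exp_decay_pair(time, y, alpha = alpha)
  p <- fits$chosen_par
  if (fits$model_choice == "one_exp") {
    out <- photobleach_model(fb1 = p[["B1"]], taub1 = p[["tau1"]],
                             y0 = p[["y0"]])
  } else {
    # order components fast first (taub1 < taub2)
    if (p[["tau1"]] <= p[["tau2"]]) {
      out <- photobleach_model(fb1 = p[["B1"]], taub1 = p[["tau1"]],
                               fb2 = p[["B2"]], taub2 = p[["tau2"]],
                               y0 = p[["y0"]])
    } else {
      out <- photobleach_model(fb1 = p[["B2"]], taub1 = p[["tau2"]],
                               fb2 = p[["B1"]], taub2 = p[["tau1"]],
                               y0 = p[["y0"]])
    }
  }
  out$model_choice <- fits$model_choice
  out$f_statistic <- fits$f_statistic
  out$p_value <- fits$p_value
  out$sds <- fits$chosen_sd
  out
}

#' Photobleach-correct a dwell-time CCDF
#'
#' Divides the cumulative counts pointwise by `B(tau)`, undoing the
#' truncation of apparent dwell times by fluorophore bleaching.
#'
#' @param ccdf A [empirical_ccdf()] result.
#' @param model A [photobleach_model()].
#' @return Corrected `dwell_ccdf`.
#' @export
correct_ccdf <- function(ccdf, model) {
  stopifnot(inherits(ccdf, "dwell_ccdf"))
  b <- bleach_survival(model, ccdf$tau)
  if (any(b <= 0)) {
    stop("photobleach curve is <= 0 on the dwell grid; cannot correct")
  }
  out <- ccdf
  out$count <- ccdf$count / b
  attr(out, "bleach_corrected") <- TRUE
  out
}

#' Extra-sum-of-squares F-test between nested fits
#'
#' `F = ((ss_simple - ss_complex) / (p_complex - p_simple)) /
#'      (ss_complex / (n_points - p_complex))`, compared against the F
#' distribution with those degrees of freedom. The complex model is
#' chosen when `p_value < alpha`.
#'
#' @param ss_simple,ss_complex Residual sums of squares (simple >=
#'   complex).
#' @param p_simple,p_complex Parameter counts (complex > simple).
#' @param n_points Number of fitted points (> p_complex).
#' @param alpha Significance level (default 0.05).
#' @return list with `f_statistic`, `p_value`, `choose_complex`.
#' @export
ftest_nested <- function(ss_simple, p_simple, ss_complex, p_complex,
                         n_points, alpha = 0.05) {
  stopifnot(ss_complex >= 0, p_complex > p_simple, n_points > p_complex)
  if (ss_simple < ss_complex) {
    stop("ss_simple must be >= ss_complex (models are nested)")
  }
  df1 <- p_complex - p_simple
  df2 <- n_points - p_complex
  if (ss_complex == 0) {
    if (ss_simple == 0) {
      return(list(f_statistic = 0, p_value = 1, choose_complex = FALSE))
    }
    return(list(f_statistic = Inf, p_value = 0, choose_complex = TRUE))
  }
  f <- ((ss_simple - ss_complex) / df1) / (ss_complex / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(f_statistic = f, p_value = p, choose_complex = p < alpha)
}

# Fit y0 + B1 exp(-t/tau1) [+ B2 exp(-t/tau2)] to (t, y) by
# unconstrained Levenberg-Marquardt (the classical least-squares setting
# in which the extra-sum-of-squares F-test has its nominal level; bounded
# amplitudes make the test conservative). The two-exponential fit runs
# from a deterministic set of starts, including negative-amplitude and
# nested (B2 = 0) ones, and keeps the lowest residual sum of squares,
# which guarantees ss2 <= ss1. With fit_offset = FALSE the offset is
# pinned at 0 and not counted as a parameter.
fit_exp_decay_pair <- function(t, y, alpha = 0.05, weights = NULL,
                               fit_offset = TRUE) {
  n <- length(t)
  sw <- if (is.null(weights)) rep(1, n) else sqrt(weights)
  amp0 <- max(y) - min(y)
  if (amp0 <= 0) amp0 <- max(abs(y), 1)
  tbar <- max(sum(t * y) / max(sum(y), 1e-12), min(diff(sort(unique(t)))))
  y00 <- if (fit_offset) max(min(y), 0) else 0

  model1 <- function(p) sw * (y - (p[1] + p[2] * exp(-t / p[3])))
  model2 <- function(p) sw * (y - (p[1] + p[2] * exp(-t / p[3]) +
                                     p[4] * exp(-t / p[5])))
  y0_hi <- if (fit_offset) Inf else 1e-12
  lo1 <- c(0, -Inf, 1e-6); hi1 <- c(y0_hi, Inf, Inf)
  lo2 <- c(0, -Inf, 1e-6, -Inf, 1e-6); hi2 <- c(y0_hi, Inf, Inf, Inf, Inf)
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)

  f1 <- minpack.lm::nls.lm(par = c(y0 = y00 / 2, B1 = amp0, tau1 = tbar),
                           lower = lo1, upper = hi1, fn = model1,
                           control = ctl)
  ss1 <- f1$deviance
  p1 <- stats::setNames(as.numeric(f1$par), names(f1$par))
  b <- unname(p1["B1"]); tt <- unname(p1["tau1"]); yy <- unname(p1["y0"])

  starts2 <- list(
    c(y0 = yy, B1 = b * 0.6, tau1 = tt * 0.4, B2 = b * 0.4, tau2 = tt * 3),
    c(y0 = yy, B1 = b * 1.2, tau1 = tt, B2 = -0.2 * b, tau2 = tt * 0.3),
    c(y0 = yy, B1 = b * 1.2, tau1 = tt, B2 = -0.2 * b, tau2 = tt * 5),
    c(y0 = yy, B1 = b, tau1 = tt, B2 = 0, tau2 = tt * 5)
  )
  f2 <- NULL
  for (st in starts2) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lo2, upper = hi2, fn = model2,
                         control = ctl),
      error = function(e) NULL
    )
    if (!is.null(cand) && (is.null(f2) || cand$deviance < f2$deviance)) {
      f2 <- cand
    }
  }
  if (is.null(f2)) stop("two-exponential fit failed")
  ss2 <- min(f2$deviance, ss1)
  p2 <- stats::setNames(as.numeric(f2$par), names(f2$par))

  n_par <- if (fit_offset) c(3, 5) else c(2, 4)
  ft <- ftest_nested(ss1, n_par[1], ss2, n_par[2], n, alpha = alpha)
  choice <- if (ft$choose_complex) "two_exp" else "one_exp"
  sd1 <- tryCatch(sqrt(pmax(diag(fit_vcov(f1)), 0)), error = function(e) rep(NA_real_, 3))
  sd2 <- tryCatch(sqrt(pmax(diag(fit_vcov(f2)), 0)), error = function(e) rep(NA_real_, 5))
  names(sd1) <- names(f1$par); names(sd2) <- names(f2$par)
  list(one = p1, two = p2, ss1 = ss1, ss2 = ss2,
       sd_one = sd1, sd_two = sd2,
       f_statistic = ft$f_statistic, p_value = ft$p_value,
       model_choice = choice,
       chosen_par = if (choice == "two_exp") p2 else p1,
       chosen_sd = if (choice == "two_exp") sd2 else sd1,
       n_points = n)
}

#' Fit exponential decay models to a dwell-time CCDF
#'
#' Fits `y = y0 + B1 exp(-tau/tau_tb) + B2 exp(-tau/tau_sb)` and its
#' one-component reduction to the (corrected) cumulative frequency
#' distribution, selecting the model by the nested F-test at `alpha`.
#' Components are labelled so that `tau_tb < tau_sb` (transient vs
#' stable chromatin-bound). When the one-exponential model wins, the
#' single component occupies the stable slot (`B1 = 0`,
#' `tau_tb = NA`).
#'
#' @param ccdf A (typically photobleach-corrected) `dwell_ccdf`.
#' @param alpha F-test level (default 0.05).
#' @param fit_offset Fit the offset y0 (default `FALSE`). The
#'   cumulative frequency of finite dwell times decays to zero, and over
#'   a finite observation window a free offset is nearly degenerate with
#'   the slow exponential, biasing `tau_sb`; set `TRUE` only for data
#'   with a genuine unbleachable/immobile plateau.
#' @param weights Optional per-point least-squares weights. Dividing the
#'   CCDF by `B(tau)` inflates the noise of the tail points by `1/B`;
#'   weighting the corrected curve by `B(tau)^2` undoes that
#'   amplification (it is algebraically the unweighted fit of the raw
#'   counts with the bleach-attenuated model) and is what
#'   [run_residence_study()] uses after correction.
#' @return Object of class `dwell_fit`: `y0`, `B1`, `B2`, `tau_tb`,
#'   `tau_sb`, `sds` (named), `model_choice`, `f_statistic`, `p_value`,
#'   `one_exp` (the competing one-exponential parameters, useful when
#'   the F-test on strongly correlated cumulative counts over-selects
#'   the two-component model), `n_points`, `ccdf`.
#' @export
fit_dwell_exponentials <- function(ccdf, alpha = 0.05, weights = NULL,
                                   fit_offset = FALSE) {
  stopifnot(inherits(ccdf, "dwell_ccdf"))
  if (length(unique(ccdf$tau)) < 6) {
    stop("need >= 6 distinct dwell values to fit exponential models")
  }
  if (!is.null(weights)) stopifnot(length(weights) == nrow(ccdf),
                                   all(weights >= 0))
  fits <- fit_exp_decay_pair(ccdf$tau, ccdf$count, alpha = alpha,
                             weights = weights, fit_offset = fit_offset)
  p <- fits$chosen_par
  s <- fits$chosen_sd
  if (fits$model_choice == "two_exp") {
    if (p[["tau1"]] <= p[["tau2"]]) {
      B1 <- p[["B1"]]; B2 <- p[["B2"]]
      tau_tb <- p[["tau1"]]; tau_sb <- p[["tau2"]]
      sds <- c(B1 = s[["B1"]], B2 = s[["B2"]],
               tau_tb = s[["tau1"]], tau_sb = s[["tau2"]])
    } else {
      B1 <- p[["B2"]]; B2 <- p[["B1"]]
      tau_tb <- p[["tau2"]]; tau_sb <- p[["tau1"]]
      sds <- c(B1 = s[["B2"]], B2 = s[["B1"]],
               tau_tb = s[["tau2"]], tau_sb = s[["tau1"]])
    }
  } else {
    B1 <- 0; B2 <- p[["B1"]]
    tau_tb <- NA_real_; tau_sb <- p[["tau1"]]
    sds <- c(B1 = 0, B2 = s[["B1"]], tau_tb = NA, tau_sb = s[["tau1"]])
  }
  structure(
    list(y0 = p[["y0"]], B1 = B1, B2 = B2,
         tau_tb = tau_tb, tau_sb = tau_sb, sds = sds,
         model_choice = fits$model_choice,
         f_statistic = fits$f_statistic, p_value = fits$p_value,
         one_exp = c(y0 = fits$one[["y0"]], B = fits$one[["B1"]],
                     tau = fits$one[["tau1"]]),
         n_points = fits$n_points, ccdf = ccdf),
    class = "dwell_fit"
  )
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit> %s (F = %.3g, p = %.3g)\n",
              x$model_choice, x$f_statistic, x$p_value))
  cat(sprintf("  tau_tb = %.3g s (B1 = %.3g), tau_sb = %.3g s (B2 = %.3g), y0 = %.3g\n",
              x$tau_tb, x$B1, x$tau_sb, x$B2, x$y0))
  invisible(x)
}

#' Transient / stable chromatin-bound subfractions
#'
#' Splits the chromatin-bound fraction F1 (from the diffusion analysis)
#' by the amplitude ratio of the dwell fit:
#' `F1tb = F1 * B1/(B1+B2)`, `F1sb = F1 * B2/(B1+B2)`. The two
#' subfractions sum to F1 exactly by construction.
#'
#' @param f1 Chromatin-bound fraction in percent (0-100).
#' @param fit A `dwell_fit`.
#' @return Named numeric `c(F1tb =, F1sb =)` in percent.
#' @export
subfractions <- function(f1, fit) {
  stopifnot(inherits(fit, "dwell_fit"), f1 >= 0, f1 <= 100)
  btot <- fit$B1 + fit$B2
  if (btot <= 0) stop("degenerate dwell fit: B1 + B2 = 0")
  f1tb <- f1 * fit$B1 / btot
  c(F1tb = f1tb, F1sb = f1 - f1tb)
}

#' Survival probability curve
#'
#' The CCDF rescaled to 1 at the smallest observed dwell, for visual
#' comparison of conditions.
#'
#' @param ccdf A `dwell_ccdf`.
#' @return data.frame with columns `tau` and `survival` (first value 1,
#'   non-increasing).
#' @export
survival_probability <- function(ccdf) {
  stopifnot(inherits(ccdf, "dwell_ccdf"), nrow(ccdf) >= 1)
  data.frame(tau = ccdf$tau, survival = ccdf$count / ccdf$count[1])
}
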