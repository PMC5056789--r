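#' Per-track diffusion coefficient from all steps (Dm)
#'
#' Dm = <r_i^2> / (4 tau): the mean of the squared frame-to-frame
#' displacements of one track divided by 4 tau, where tau is the
#' frame-to-frame interval of the acquisition (0.03 s for continuous
#' 30-ms imaging, integration + dark time for time-lapse). Using a fixed
#' per-step interval avoids biasing the population estimate toward slow
#' molecules that stay in focus longer.
#'
#' @param track data.frame with columns `frame`, `x`, `y` (one track,
#'   consecutive frames, micrometres).
#' @param timing [acquisition_timing()].
#' @return Dm in um^2/s.
#' @export
compute_dm <- function(track, timing) {
  r2 <- squared_steps(track)
  mean(r2) / (4 * timing$lapse_interval)
}

#' Per-track diffusion coefficient from the first step (Df1)
#'
#' Df1 = r_f1^2 / (4 tau) uses only the squared displacement between the
#' first two positions of a track, avoiding the within-track averaging of
#' [compute_dm()] that can blur transitions between binding and free
#' diffusion.
#'
#' @inheritParams compute_dm
#' @return Df1 in um^2/s.
#' @export
compute_df1 <- function(track, timing) {
  r2 <- squared_steps(track)
  r2[1] / (4 * timing$lapse_interval)
}

squared_steps <- function(track) {
  if (nrow(track) < 2) {
    stop("diffusion estimate undefined: track has fewer than 2 localizations")
  }
  if (any(diff(track$frame) != 1L)) {
    stop("track frames are not consecutive")
  }
  diff(track$x)^2 + diff(track$y)^2
}

#' Diffusion estimates for every track in a set
#'
#' Vectorized driver computing both the whole-track estimator Dm and the
#' first-step estimator Df1 for each track with at least one step.
#'
#' @param ts A [track_set()].
#' @return data.frame of class `diffusion_estimates` with columns
#'   `track_id`, `n_steps`, `dm`, `df1`, `log_dm`, `log_df1` (log10;
#'   `-Inf` for zero-displacement tracks, which downstream histogramming
#'   clamps to its lower edge rather than dropping).
#' @export
diffusion_estimates <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  loc <- ts$localizations
  tau4 <- 4 * ts$timing$lapse_interval
  pieces <- split(loc, loc$track_id)
  keep <- vapply(pieces, nrow, integer(1)) >= 2L
  pieces <- pieces[keep]
  if (length(pieces) == 0) {
    stop("no tracks with >= 2 localizations")
  }
  est <- do.call(rbind, lapply(pieces, function(d) {
    r2 <- diff(d$x)^2 + diff(d$y)^2
    data.frame(track_id = d$track_id[1], n_steps = length(r2),
               dm = mean(r2) / tau4, df1 = r2[1] / tau4)
  }))
  rownames(est) <- NULL
  est$log_dm <- log10(est$dm)
  est$log_df1 <- log10(est$df1)
  class(est) <- c("diffusion_estimates", "data.frame")
  est
}

#' Histogram of log10 diffusion coefficients
#'
#' Builds the density-normalized histogram of log10(D) that the
#' population decomposition is fitted to. Zero-displacement tracks
#' (D = 0, log undefined) are clamped into the lowest bin so the bound
#' fraction is not biased down; finite values outside `range` are counted
#' and reported in the attributes, not silently dropped.
#'
#' @param estimates A [diffusion_estimates()] data.frame.
#' @param which `"dm"` or `"df1"` - which estimator to histogram.
#' @param bin_width Bin width in log10 units (default 0.2).
#' @param range Histogram range in log10 um^2/s, default `c(-3.5, 1.5)`.
#' @return data.frame of class `logd_histogram` with columns `center`,
#'   `density`, `count`; attributes `n` (values histogrammed),
#'   `n_clamped_zero`, `n_below`, `n_above`, `bin_width`, `range`,
#'   `which`. The density integrates to 1 over the range.
#' @export
build_logd_histogram <- function(estimates, which = c("dm", "df1"),
                                 bin_width = 0.2, range = c(-3.5, 1.5)) {
  which <- match.arg(which)
  stopifnot(bin_width > 0, length(range) == 2, range[2] > range[1])
  v <- estimates[[which]]
  if (length(v) == 0) stop("no diffusion estimates to histogram")
  logv <- ifelse(v > 0, log10(v), -Inf)
  n_zero <- sum(v == 0)
  breaks <- seq(range[1], range[2], by = bin_width)
  if (abs(breaks[length(breaks)] - range[2]) > 1e-9) {
    breaks <- c(breaks, range[2])
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # clamp zeros into the lowest bin; out-of-range finite values reported
  logv[v == 0] <- centers[1]
  n_below <- sum(logv < range[1])
  n_above <- sum(logv > range[2])
  inside <- logv[logv >= range[1] & logv <= range[2]]
  if (length(inside) == 0) stop("no log10 diffusion values inside range")
  counts <- graphics::hist(inside, breaks = breaks, plot = FALSE)$counts
  hist <- data.frame(center = centers,
                     density = counts / (length(inside) * bin_width),
                     count = counts)
  class(hist) <- c("logd_histogram", "data.frame")
  attr(hist, "n") <- length(inside)
  attr(hist, "n_clamped_zero") <- n_zero
  attr(hist, "n_below") <- n_below
  attr(hist, "n_above") <- n_above
  attr(hist, "bin_width") <- bin_width
  attr(hist, "range") <- range
  attr(hist, "which") <- which
  hist
}

# sum-of-Gaussians-plus-offset in the area/width parametrization:
# each component contributes A / (w * sqrt(pi/2)) * exp(-2 (x - xc)^2 / w^2),
# i.e. a normal with sd = w/2 and total area A.
gaussian_mixture_value <- function(x, y0, centers, widths, areas) {
  y <- rep(y0, length(x))
  for (i in seq_along(centers)) {
    y <- y + areas[i] / (widths[i] * sqrt(pi / 2)) *
      exp(-2 * (x - centers[i])^2 / widths[i]^2)
  }
  y
}

#' Fit a Gaussian mixture to a log10 D histogram
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt) of
#' `y = y0 + sum_i A_i / (w_i sqrt(pi/2)) exp(-2 (x - x_i)^2 / w_i^2)`
#' to the (bin center, density) pairs. `A_i` is the area of component i,
#' `w_i` its width (twice the standard deviation of the equivalent
#' normal), `x_i` its center in log10 um^2/s. Population fractions are
#' `F_i = A_i / sum(A) * 100`. The slowest center may be fixed (the
#' chromatin-bound convention log10 D = -1.5, i.e. 0.032 um^2/s).
#'
#' Initialization is a deterministic multistart: Levenberg-Marquardt is
#' run from (a) count-weighted quantile-spaced centers, (b) a 1D k-means
#' moment start, and (c) a mode-anchored start placing the slowest
#' component at the histogram mode (or at `fixed_slow_center`) and the
#' others at quantiles of the faster tail; the converged solution with
#' the lowest residual sum of squares is kept. No random restarts, so
#' fits are reproducible.
#'
#' @param hist A [build_logd_histogram()] result.
#' @param n_components 2 or 3.
#' @param fixed_slow_center Optional log10 value at which the slowest
#'   center is pinned (conventionally -1.5); `NULL` leaves all centers
#'   free.
#' @param w_bounds Width bounds in log10 units. The default lower bound
#'   is the histogram bin width: a component narrower than one bin is
#'   not resolvable and only chases single-bin noise.
#' @param min_separation Minimum spacing between component centers in
#'   log10 units (default 0.6, three default bins). Populations closer
#'   than the per-track estimator spread cannot be resolved as distinct,
#'   and without the constraint the optimizer can split one skewed peak
#'   across two Gaussians. Internally the centers are parametrized as
#'   the slowest center plus non-negative gaps, which also enforces
#'   their ordering.
#' @return Object of class `diffusion_fit`: `components` data.frame
#'   (center, width, area + SDs + `fixed_center` flag, sorted by center),
#'   `y0`, `fractions`/`fraction_sd` (percent), `converged`, `fell_back`,
#'   `n_components_requested`, `histogram`, and the area covariance used
#'   for error propagation.
#' @export
fit_gaussian_mixture <- function(hist, n_components = 3,
                                 fixed_slow_center = NULL,
                                 w_bounds = c(attr(hist, "bin_width"), 3),
                                 min_separation = 0.6) {
  stopifnot(inherits(hist, "logd_histogram"),
            n_components %in% c(2L, 3L))
  if (!is.null(fixed_slow_center) && n_components != 3) {
    stop("fixed_slow_center requires n_components = 3")
  }
  x <- hist$center
  y <- hist$density
  if (sum(y > 0) < 3) stop("degenerate histogram: too few occupied bins")
  k <- n_components
  fixed <- !is.null(fixed_slow_center)
  span <- max(x) - min(x)

  # parameters: y0, A1..Ak, w1..wk, [x1 if free], g2..gk (center gaps)
  gap_names <- paste0("g", 2:k)
  par_x <- if (fixed) character(0) else "x1"
  lower <- c(-Inf, rep(0, k), rep(w_bounds[1], k),
             if (!fixed) min(x), rep(min_separation, k - 1))
  upper <- c(Inf, rep(Inf, k), rep(w_bounds[2], k),
             if (!fixed) max(x), rep(span, k - 1))

  centers_of <- function(p) {
    x1 <- if (fixed) fixed_slow_center else p[["x1"]]
    x1 + cumsum(c(0, unname(p[gap_names])))
  }
  resid_fun <- function(p) {
    y - gaussian_mixture_value(x, p[["y0"]], centers_of(p),
                               p[paste0("w", 1:k)], p[paste0("A", 1:k)])
  }

  starts <- mixture_starts(hist, k, fixed_slow_center)
  fit <- NULL
  fit_ok <- FALSE
  for (init in starts) {
    ic <- init$centers
    ic[-1] <- pmax(ic[-1], ic[1] + min_separation * (seq_len(k - 1)))
    start <- c(y0 = init$y0,
               stats::setNames(init$areas, paste0("A", 1:k)),
               stats::setNames(init$widths, paste0("w", 1:k)),
               if (!fixed) c(x1 = ic[1]),
               stats::setNames(pmax(diff(ic), min_separation), gap_names))
    cand <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (is.null(cand)) next
    cand_ok <- cand$info %in% 1:4
    better <- is.null(fit) ||
      (cand_ok && !fit_ok) ||
      (cand_ok == fit_ok && cand$deviance < fit$deviance)
    if (better) {
      fit <- cand
      fit_ok <- cand_ok
    }
  }
  if (is.null(fit)) {
    stop("Gaussian mixture fit failed: solver error from every start")
  }
  solver_ok <- fit_ok

  p <- stats::setNames(as.numeric(fit$par), names(fit$par))
  centers <- centers_of(p)
  areas <- p[paste0("A", 1:k)]
  widths <- p[paste0("w", 1:k)]

  vc <- tryCatch(fit_vcov(fit), error = function(e) NULL)
  sds <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, length(p))
  names(sds) <- names(p)
  area_vcov <- if (!is.null(vc)) {
    vc[paste0("A", 1:k), paste0("A", 1:k), drop = FALSE]
  } else {
    matrix(NA_real_, k, k)
  }

  # center j = x1 + sum of gaps up to j: propagate variance through the sum
  center_sd <- vapply(1:k, function(j) {
    terms <- c(if (!fixed) "x1", if (j >= 2) paste0("g", 2:j))
    if (length(terms) == 0) return(0)
    if (is.null(vc)) return(NA_real_)
    sqrt(max(0, sum(vc[terms, terms])))
  }, numeric(1))

  comp <- data.frame(
    center = unname(centers), width = unname(widths), area = unname(areas),
    center_sd = center_sd,
    width_sd = unname(sds[paste0("w", 1:k)]),
    area_sd = unname(sds[paste0("A", 1:k)]),
    fixed_center = c(fixed, rep(FALSE, k - 1))
  )
  # gap parametrization keeps centers sorted already
  rownames(comp) <- NULL

  # a width stuck at its bound flags misfit, except for components whose
  # area has collapsed to zero: those are absent and their width is
  # meaningless (e.g. a 3-component fit of 1-population data)
  sizable <- areas > 1e-6 * max(sum(areas), 1e-12)
  w_at_bound <- any(sizable & (abs(widths - w_bounds[1]) < 1e-6 |
                                 abs(widths - w_bounds[2]) < 1e-6))
  converged <- solver_ok && all(areas >= 0) && !w_at_bound

  res <- structure(
    list(components = comp, y0 = unname(p["y0"]),
         area_vcov = area_vcov,
         n_components_requested = as.integer(n_components),
         fell_back = FALSE,
         converged = converged,
         solver_ok = solver_ok,
         w_at_bound = w_at_bound,
         histogram = hist),
    class = "diffusion_fit"
  )
  fr <- tryCatch(fractions_from_fit(res), error = function(e) NULL)
  if (is.null(fr)) {
    res$fractions <- rep(NA_real_, k)
    res$fraction_sd <- rep(NA_real_, k)
    res$converged <- FALSE
  } else {
    res$fractions <- fr$fraction
    res$fraction_sd <- fr$fraction_sd
  }
  res
}

# parameter covariance of an nls.lm fit: sigma^2 * (J'J)^-1
fit_vcov <- function(fit) {
  dof <- length(fit$fvec) - length(fit$par)
  if (dof <= 0) stop("no residual degrees of freedom")
  s2 <- fit$deviance / dof
  covm <- tryCatch(solve(fit$hessian) * 2 * s2, error = function(e) NULL)
  if (is.null(covm)) {
    jtj <- fit$hessian / 2
    covm <- pinv_sym(jtj) * s2
  }
  dimnames(covm) <- list(names(fit$par), names(fit$par))
  covm
}

# SVD pseudo-inverse to survive singular J'J near parameter bounds
pinv_sym <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# Deterministic multistart candidates: quantile-spaced, k-means moment,
# and mode-anchored (slow component pinned at the histogram mode or the
# fixed center, remaining centers spread over the faster tail).
mixture_starts <- function(hist, k, fixed_slow_center) {
  x <- hist$center
  xs <- rep(x, hist$count)
  total_area <- sum(hist$density) * attr(hist, "bin_width")
  clamp <- function(v) {
    v <- pmin(pmax(v, min(x)), max(x))
    v + cumsum(c(0, diff(v) <= 1e-9)) * 0.1   # keep centers distinct
  }
  starts <- list()

  probs <- (1:k) / (k + 1)
  qc <- as.numeric(stats::quantile(xs, probs, names = FALSE, type = 1))
  if (!is.null(fixed_slow_center)) qc[1] <- fixed_slow_center
  starts$quantile <- list(y0 = 0, centers = clamp(qc),
                          widths = rep(0.5, k),
                          areas = rep(total_area / k, k))

  km <- tryCatch(
    stats::kmeans(xs, centers = matrix(unique(clamp(qc)), ncol = 1)),
    error = function(e) NULL
  )
  if (!is.null(km) && length(km$size) == k) {
    o <- order(km$centers)
    cw <- vapply(o, function(i) stats::sd(xs[km$cluster == i]), numeric(1))
    cw[!is.finite(cw)] <- 0.25
    kc <- as.numeric(km$centers[o])
    if (!is.null(fixed_slow_center)) kc[1] <- fixed_slow_center
    starts$kmeans <- list(y0 = 0, centers = clamp(kc),
                          widths = pmin(pmax(2 * cw, 0.2), 1),
                          areas = total_area * km$size[o] / length(xs))
  }

  anchor <- if (!is.null(fixed_slow_center)) {
    fixed_slow_center
  } else {
    x[which.max(hist$density)]
  }
  upper_tail <- xs[xs > anchor + 0.5]
  if (length(upper_tail) >= k - 1 && k >= 2) {
    qt <- as.numeric(stats::quantile(upper_tail, (1:(k - 1)) / k,
                                     names = FALSE, type = 1))
    p_slow <- mean(xs <= anchor + 0.5)
    starts$anchored <- list(
      y0 = 0, centers = clamp(c(anchor, qt)), widths = rep(0.5, k),
      areas = total_area * c(max(p_slow, 0.05),
                             rep((1 - p_slow) / (k - 1), k - 1))
    )
  }
  starts
}

#' Population fractions from a mixture fit
#'
#' `F_i = A_i / sum(A) * 100` with standard deviations propagated to
#' first order from the fitted area covariance.
#'
#' @param fit A `diffusion_fit` from [fit_gaussian_mixture()].
#' @return data.frame with one row per component (sorted by center):
#'   `center`, `d_um2s` (10^center), `fraction` (percent, summing to
#'   100), `fraction_sd`.
#' @export
fractions_from_fit <- function(fit) {
  stopifnot(inherits(fit, "diffusion_fit"))
  A <- fit$components$area
  if (any(A < 0)) stop("negative component area in fit")
  S <- sum(A)
  if (S <= 0) stop("degenerate fit: total area is zero")
  frac <- A / S * 100
  k <- length(A)
  vc <- fit$area_vcov
  sd <- rep(NA_real_, k)
  if (!anyNA(vc)) {
    for (i in 1:k) {
      g <- -A[i] / S^2                    # dFi/dAj, j != i
      grad <- rep(g, k)
      grad[i] <- (S - A[i]) / S^2         # dFi/dAi
      grad <- grad * 100
      sd[i] <- sqrt(max(0, as.numeric(t(grad) %*% vc %*% grad)))
    }
  }
  data.frame(center = fit$components$center,
             d_um2s = 10^fit$components$center,
             fraction = frac, fraction_sd = sd)
}

#' Three-component fit with automatic two-component fallback
#'
#' Attempts the three-component fit with the slowest center fixed at
#' `fixed_slow_center`. If that fit does not converge - solver failure,
#' a bound-population fraction below `min_slow_fraction` percent, a
#' width stuck at its bound, or a fixed-center amplitude that is not
#' statistically distinguishable from zero (area below `z_area` times
#' its fitted standard deviation) - the histogram is refitted with two
#' free components and `fell_back` is set.
#' This mirrors the treatment of data sets with no resolvable
#' chromatin-bound population (e.g. a nuclear-localization-signal
#' control), for which a pinned third Gaussian only chases the
#' statistical tail of the mobile populations.
#'
#' @inheritParams fit_gaussian_mixture
#' @param fixed_slow_center Fixed slow center, default -1.5.
#' @param min_slow_fraction Degeneracy floor in percent for the
#'   fixed-center component (default 1).
#' @param z_area Significance multiple for the fixed-center amplitude
#'   (default 2, roughly a 95% criterion).
#' @return A `diffusion_fit`; `fell_back` is `TRUE` when the
#'   two-component fit was used.
#' @export
fit_with_fallback <- function(hist, fixed_slow_center = -1.5,
                              min_slow_fraction = 1, z_area = 2) {
  fit3 <- tryCatch(
    fit_gaussian_mixture(hist, 3, fixed_slow_center = fixed_slow_center),
    error = function(e) NULL
  )
  ok <- !is.null(fit3) && fit3$converged
  if (ok) {
    slow_idx <- which(fit3$components$fixed_center)[1]
    if (is.na(slow_idx)) slow_idx <- 1L
    slow_area <- fit3$components$area[slow_idx]
    slow_area_sd <- fit3$components$area_sd[slow_idx]
    ok <- fit3$fractions[slow_idx] >= min_slow_fraction &&
      (is.na(slow_area_sd) || slow_area > z_area * slow_area_sd)
  }
  if (ok) return(fit3)
  fit2 <- fit_gaussian_mixture(hist, 2)
  if (!fit2$converged) stop("neither 3- nor 2-component mixture fit converged")
  fit2$fell_back <- TRUE
  fit2$n_components_requested <- 3L
  fit2
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> %d components%s%s\n",
              nrow(x$components),
              if (x$fell_back) " (fallback from 3)" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  df <- cbind(x$components[, c("center", "width", "area")],
              d_um2s = 10^x$components$center,
              fraction = x$fractions, fraction_sd = x$fraction_sd)
  print(format(df, digits = 3), ...)
  invisible(x)
}
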