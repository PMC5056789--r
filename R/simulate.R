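#' Simulation configuration
#'
#' Collects the generative parameters for synthetic tracking data:
#' diffusive populations, acquisition timing, track-length law
#' (continuous mode), dwell-time mixture and bleaching (time-lapse
#' mode), and the random seed.
#'
#' By default populations are specified by their *apparent* diffusion
#' coefficient (the measured coefficient, which for bound molecules
#' already folds in chromosomal motion and localization uncertainty) and
#' `localization_sd = 0`. Setting `localization_sd > 0` instead treats
#' the population D as the true coefficient and adds independent
#' Gaussian localization noise of that standard deviation per coordinate
#' per frame.
#'
#' @param populations data.frame with columns `weight` (summing to 1)
#'   and `d` (apparent diffusion coefficient, um^2/s).
#' @param timing [acquisition_timing()].
#' @param n_tracks Number of tracks / molecules to generate.
#' @param mean_frames Mean of the geometric track-length law in frames
#'   (continuous mode; default 6). Lengths are
#'   `1 + Geometric(p = 1/mean_frames)` conditioned on >= 2 frames.
#' @param track_length_law `"geometric"` (default) or `"fixed"`
#'   (every track exactly `mean_frames` frames, for calibration tests).
#' @param localization_sd Localization noise sd in um per coordinate
#'   (0 = apparent-D mode, the default).
#' @param dwell_mixture Optional list `list(weights =, taus =)` for
#'   time-lapse simulations: mixture weights (summing to 1) and time
#'   constants (seconds) of the exponential dwell components.
#' @param bleach [photobleach_model()] used to truncate dwells, or
#'   `NULL` for no bleaching.
#' @param seed Default random seed used when the simulation functions
#'   are called without one.
#' @param label Free-text label.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(populations, timing, n_tracks,
                       mean_frames = 6, track_length_law = c("geometric", "fixed"),
                       localization_sd = 0, dwell_mixture = NULL,
                       bleach = NULL, seed = 1L, label = "") {
  track_length_law <- match.arg(track_length_law)
  populations <- as.data.frame(populations)
  stopifnot(all(c("weight", "d") %in% names(populations)),
            all(populations$weight >= 0), all(populations$d >= 0),
            inherits(timing, "acquisition_timing"),
            n_tracks >= 1, mean_frames >= 2, localization_sd >= 0)
  if (abs(sum(populations$weight) - 1) > 1e-8) {
    stop("population weights must sum to 1")
  }
  if (!is.null(dwell_mixture)) {
    stopifnot(is.list(dwell_mixture),
              length(dwell_mixture$weights) == length(dwell_mixture$taus),
              all(dwell_mixture$taus > 0))
    if (abs(sum(dwell_mixture$weights) - 1) > 1e-8) {
      stop("dwell mixture weights must sum to 1")
    }
  }
  if (!is.null(bleach)) stopifnot(inherits(bleach, "photobleach_model"))
  structure(
    list(populations = populations, timing = timing,
         n_tracks = as.integer(n_tracks), mean_frames = mean_frames,
         track_length_law = track_length_law,
         localization_sd = localization_sd,
         dwell_mixture = dwell_mixture, bleach = bleach,
         seed = as.integer(seed), label = label),
    class = "sim_config"
  )
}

# geometric track length in frames, conditioned on >= 2
draw_track_lengths <- function(n, mean_frames, law) {
  if (law == "fixed") return(rep(as.integer(round(mean_frames)), n))
  p <- 1 / mean_frames
  len <- integer(0)
  while (length(len) < n) {
    cand <- 1L + stats::rgeom(2L * n, prob = p)
    len <- c(len, cand[cand >= 2L])
  }
  len[seq_len(n)]
}

#' Simulate continuous-mode tracks from a diffusive mixture
#'
#' Each track draws a population by weight, a length from the
#' track-length law, and performs isotropic 2D Brownian motion: per-axis
#' step variance `2 D dt` with dt the frame interval. In apparent-D mode
#' (`localization_sd = 0`) the population D is used directly; otherwise
#' independent localization noise is added to every coordinate. Start
#' positions are uniform in a 20 um square.
#'
#' @param cfg A continuous-mode [sim_config()].
#' @param seed Random seed (defaults to `cfg$seed`). Identical
#'   config + seed gives an identical `track_set`.
#' @return [track_set()] whose localization table carries a
#'   `population` attribute with each track's generating population
#'   index (ground truth for recovery tests).
#' @export
simulate_mixture_tracks <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$timing$mode != "continuous") {
    stop("simulate_mixture_tracks requires a continuous-mode config")
  }
  set.seed(seed)
  n <- cfg$n_tracks
  dt <- cfg$timing$lapse_interval
  pop <- sample.int(nrow(cfg$populations), n, replace = TRUE,
                    prob = cfg$populations$weight)
  len <- draw_track_lengths(n, cfg$mean_frames, cfg$track_length_law)
  sd_step <- sqrt(2 * cfg$populations$d[pop] * dt)
  loc <- vector("list", n)
  for (i in seq_len(n)) {
    L <- len[i]
    x <- cumsum(c(stats::runif(1, 0, 20), stats::rnorm(L - 1, 0, sd_step[i])))
    y <- cumsum(c(stats::runif(1, 0, 20), stats::rnorm(L - 1, 0, sd_step[i])))
    if (cfg$localization_sd > 0) {
      x <- x + stats::rnorm(L, 0, cfg$localization_sd)
      y <- y + stats::rnorm(L, 0, cfg$localization_sd)
    }
    loc[[i]] <- data.frame(track_id = sprintf("t%05d", i),
                           frame = seq_len(L) - 1L, x = x, y = y)
  }
  loc <- do.call(rbind, loc)
  ts <- track_set(loc, cfg$timing, label = cfg$label)
  attr(ts, "population") <- pop
  ts
}

# draw bleach lifetimes from the exponential-mixture survival implied by
# a photobleach model (offset ignored; amplitudes renormalized)
draw_bleach_lifetimes <- function(model, n) {
  if (is.null(model)) return(rep(Inf, n))
  w <- c(model$fb1, model$fb2)
  taus <- c(model$taub1, model$taub2)
  keep <- w > 0
  w <- w[keep] / sum(w[keep])
  taus <- taus[keep]
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  stats::rexp(n, rate = 1 / taus[comp])
}

#' Simulate time-lapse tracks of chromatin-bound molecules
#'
#' Each molecule draws a true dwell time from the two-exponential
#' mixture and a bleach lifetime from the bleach model (infinite when
#' `bleach = NULL`); the observed dwell is the minimum of the two. The
#' molecule is detected on `floor(observed / interval) + 1` frames and
#' moves with the (apparent) bound-population diffusion coefficient.
#' Molecules seen on a single frame are emitted but fail the downstream
#' bound-track selection.
#'
#' @param cfg A time-lapse [sim_config()] with `dwell_mixture` set; the
#'   first population row supplies the bound-molecule D.
#' @param seed Random seed (defaults to `cfg$seed`).
#' @return [track_set()] with attribute `true_dwell` (the undiscretized,
#'   unbleached dwell times, ground truth).
#' @export
simulate_timelapse_bound <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$timing$mode != "timelapse") {
    stop("simulate_timelapse_bound requires a time-lapse config")
  }
  if (is.null(cfg$dwell_mixture)) {
    stop("config lacks dwell_mixture")
  }
  set.seed(seed)
  n <- cfg$n_tracks
  dt <- cfg$timing$lapse_interval
  dm <- cfg$dwell_mixture
  comp <- sample.int(length(dm$weights), n, replace = TRUE,
                     prob = dm$weights)
  true_dwell <- stats::rexp(n, rate = 1 / dm$taus[comp])
  bleach_life <- draw_bleach_lifetimes(cfg$bleach, n)
  observed <- pmin(true_dwell, bleach_life)
  n_frames <- pmax(1L, as.integer(floor(observed / dt)) + 1L)
  d_bound <- cfg$populations$d[1]
  sd_step <- sqrt(2 * d_bound * dt)
  loc <- vector("list", n)
  for (i in seq_len(n)) {
    L <- n_frames[i]
    x <- cumsum(c(stats::runif(1, 0, 20), stats::rnorm(L - 1, 0, sd_step)))
    y <- cumsum(c(stats::runif(1, 0, 20), stats::rnorm(L - 1, 0, sd_step)))
    loc[[i]] <- data.frame(track_id = sprintf("m%05d", i),
                           frame = seq_len(L) - 1L, x = x, y = y)
  }
  loc <- do.call(rbind, loc)
  ts <- track_set(loc, cfg$timing, label = cfg$label)
  attr(ts, "true_dwell") <- true_dwell
  attr(ts, "dwell_component") <- comp
  ts
}

#' Simulate ensemble photobleaching decay curves
#'
#' Noisy realizations of `B(tau)` on a time grid, mimicking the
#' background-corrected, normalized intensity decay of a densely
#' labelled nucleus under repeated exposure.
#'
#' @param model A [photobleach_model()].
#' @param n_curves Number of curves (default 9).
#' @param noise_sd Gaussian noise sd per sample (default 0.01).
#' @param grid Time grid in seconds.
#' @param seed Random seed.
#' @return list with `time` (the grid) and `curves`
#'   (length(grid) x n_curves matrix).
#' @export
simulate_photobleach_curves <- function(model, n_curves = 9,
                                        noise_sd = 0.01,
                                        grid = seq(0, 60, by = 0.2),
                                        seed = 1L) {
  stopifnot(inherits(model, "photobleach_model"), n_curves >= 1)
  set.seed(seed)
  b <- bleach_survival(model, grid)
  curves <- matrix(rep(b, n_curves), ncol = n_curves) +
    matrix(stats::rnorm(length(grid) * n_curves, 0, noise_sd),
           ncol = n_curves)
  list(time = grid, curves = curves)
}
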