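#' Run the diffusion fractional study
#'
#' End-to-end orchestration of the population decomposition: per-track
#' diffusion estimates, log10 histogram, Gaussian-mixture fit (fixed
#' slow center with fallback, or free), fractions. Accepts either an
#' existing [track_set()] or the name of a simulation [preset()].
#'
#' @param x A `track_set`, a `sim_config`, or a preset name.
#' @param which `"dm"` (default) or `"df1"` - which estimator drives the
#'   histogram.
#' @param n_components Number of mixture components when
#'   `fallback = FALSE` (2 or 3).
#' @param fixed_slow_center Fixed bound-population center in log10
#'   um^2/s (default -1.5); `NULL` for all-free fits.
#' @param fallback Use [fit_with_fallback()] (default `TRUE`).
#' @param bin_width,range Histogram parameters, see
#'   [build_logd_histogram()].
#' @param seed Seed used when `x` names a preset or is a `sim_config`.
#' @return list of class `fraction_report`: `estimates`, `histogram`,
#'   `fit`, `fractions` (data.frame), `diagnostics` (counts in/out of
#'   filters, convergence flags), `manifest`.
#' @export
run_fraction_study <- function(x, which = c("dm", "df1"),
                               n_components = 3,
                               fixed_slow_center = -1.5,
                               fallback = TRUE,
                               bin_width = 0.2, range = c(-3.5, 1.5),
                               seed = NULL) {
  which <- match.arg(which)
  ts <- resolve_trackset(x, seed, simulate_mixture_tracks)
  n_total <- n_tracks(ts)
  est <- diffusion_estimates(ts)
  hist <- build_logd_histogram(est, which = which,
                               bin_width = bin_width, range = range)
  fit <- if (fallback) {
    if (is.null(fixed_slow_center)) {
      stop("fallback fitting requires a fixed_slow_center")
    }
    fit_with_fallback(hist, fixed_slow_center = fixed_slow_center)
  } else {
    fit_gaussian_mixture(hist, n_components,
                         fixed_slow_center = fixed_slow_center)
  }
  structure(
    list(
      estimates = est, histogram = hist, fit = fit,
      fractions = fractions_from_fit(fit),
      diagnostics = list(
        n_tracks = n_total,
        n_analyzed = nrow(est),
        n_zero_displacement = attr(hist, "n_clamped_zero"),
        n_out_of_range = attr(hist, "n_below") + attr(hist, "n_above"),
        converged = fit$converged,
        fell_back = fit$fell_back
      ),
      manifest = run_manifest(seed)
    ),
    class = "fraction_report"
  )
}

#' Run the residence-time study
#'
#' Orchestrates the time-lapse dwell analysis: bound-track selection,
#' dwell times, CCDF, photobleach correction, nested exponential fits
#' with F-test model choice, subfractions and survival curve.
#'
#' @param x A time-lapse `track_set`, a `sim_config`, or a preset name
#'   (e.g. `"cbx7_dwell_wt"`).
#' @param bleach A [photobleach_model()], a list with `time` and
#'   `curves` (fitted via [fit_photobleach()]), or `NULL` to skip the
#'   correction.
#' @param f1 Chromatin-bound fraction in percent from the diffusion
#'   analysis, used to split into transient/stable subfractions
#'   (`NULL` skips subfractions).
#' @param d_threshold,min_consecutive_frames See
#'   [select_bound_tracks()].
#' @param alpha F-test level.
#' @param seed Seed used when `x` is a preset/config.
#' @return list of class `residence_report`: `dwells`, `ccdf` (raw),
#'   `ccdf_corrected`, `fit` (a `dwell_fit`), `subfractions`,
#'   `survival`, `bleach_model`, `diagnostics`, `manifest`.
#' @export
run_residence_study <- function(x, bleach = NULL, f1 = NULL,
                                d_threshold = 0.10,
                                min_consecutive_frames = 2L,
                                alpha = 0.05, seed = NULL) {
  ts <- resolve_trackset(x, seed, simulate_timelapse_bound)
  if (is.null(bleach) && inherits(x, "sim_config")) bleach <- x$bleach
  if (is.null(bleach) && is.character(x)) bleach <- preset(x)$bleach
  bleach_model <- if (is.null(bleach)) {
    NULL
  } else if (inherits(bleach, "photobleach_model")) {
    bleach
  } else if (is.list(bleach) && !is.null(bleach$curves)) {
    fit_photobleach(bleach$time, bleach$curves, alpha = alpha)
  } else {
    stop("bleach must be a photobleach_model, a time/curves list, or NULL")
  }
  n_total <- n_tracks(ts)
  bound <- select_bound_tracks(ts, d_threshold = d_threshold,
                               min_consecutive_frames = min_consecutive_frames)
  dw <- dwell_times(bound)
  ccdf <- empirical_ccdf(dw)
  ccdf_corr <- if (is.null(bleach_model)) ccdf else correct_ccdf(ccdf, bleach_model)
  fit_weights <- if (is.null(bleach_model)) {
    NULL
  } else {
    bleach_survival(bleach_model, ccdf_corr$tau)^2
  }
  fit <- fit_dwell_exponentials(ccdf_corr, alpha = alpha,
                                weights = fit_weights)
  sub <- if (is.null(f1)) NULL else subfractions(f1, fit)
  structure(
    list(
      dwells = dw, ccdf = ccdf, ccdf_corrected = ccdf_corr,
      fit = fit, subfractions = sub,
      survival = survival_probability(ccdf),
      bleach_model = bleach_model,
      diagnostics = list(
        n_tracks = n_total,
        n_bound = n_tracks(bound),
        fraction_passing = attr(bound, "fraction_passing"),
        n_dwells = nrow(dw),
        model_choice = fit$model_choice
      ),
      manifest = run_manifest(seed)
    ),
    class = "residence_report"
  )
}

resolve_trackset <- function(x, seed, simulator) {
  if (inherits(x, "track_set")) {
    x
  } else if (inherits(x, "sim_config")) {
    simulator(x, seed = if (is.null(seed)) x$seed else seed)
  } else if (is.character(x) && length(x) == 1) {
    cfg <- preset(x)
    simulator(cfg, seed = if (is.null(seed)) cfg$seed else seed)
  } else {
    stop("expected a track_set, sim_config, or preset name")
  }
}

run_manifest <- function(seed) {
  list(
    package_version = as.character(utils::packageVersion("smtkin")),
    seed = if (is.null(seed)) NA_integer_ else seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = R.version.string
  )
}

#' Write a human-readable report of study results
#'
#' Serializes fraction and residence reports to JSON and CSV tables and
#' renders summary figures (fraction bar chart; dwell survival curves)
#' into a directory.
#'
#' @param reports A named list of `fraction_report` and/or
#'   `residence_report` objects (names become file stems).
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
make_report <- function(reports, dir) {
  stopifnot(is.list(reports), length(reports) >= 1)
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    names(reports) <- paste0("report", seq_along(reports))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    if (inherits(rep, "fraction_report")) {
      written <- c(written, write_fraction_report(rep, dir, nm))
    } else if (inherits(rep, "residence_report")) {
      written <- c(written, write_residence_report(rep, dir, nm))
    } else {
      stop("unknown report type for '", nm, "'")
    }
  }
  invisible(written)
}

write_fraction_report <- function(rep, dir, nm) {
  json_path <- file.path(dir, paste0(nm, "_fractions.json"))
  csv_path <- file.path(dir, paste0(nm, "_histogram.csv"))
  png_path <- file.path(dir, paste0(nm, "_fractions.png"))
  comp <- rep$fit$components
  payload <- list(
    components = lapply(seq_len(nrow(comp)), function(i) list(
      center = comp$center[i], center_sd = comp$center_sd[i],
      width = comp$width[i], width_sd = comp$width_sd[i],
      area = comp$area[i], area_sd = comp$area_sd[i],
      d_um2s = 10^comp$center[i],
      fraction_pct = rep$fractions$fraction[i],
      fraction_sd_pct = rep$fractions$fraction_sd[i]
    )),
    y0 = rep$fit$y0,
    converged = rep$fit$converged,
    fell_back = rep$fit$fell_back,
    diagnostics = rep$diagnostics,
    manifest = rep$manifest
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(rep$histogram[, c("center", "density")], csv_path,
                   row.names = FALSE)
  df <- rep$fractions
  df$population <- factor(c("CB", "ID", "FD")[seq_len(nrow(df))],
                          levels = c("CB", "ID", "FD"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$population,
                                        y = .data$fraction,
                                        fill = .data$population)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$fraction - .data$fraction_sd,
      ymax = .data$fraction + .data$fraction_sd), width = 0.2) +
    ggplot2::labs(y = "Fraction (%)", x = NULL, title = nm) +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
  ggplot2::ggsave(png_path, p, width = 3.2, height = 3.2, dpi = 150)
  c(json_path, csv_path, png_path)
}

write_residence_report <- function(rep, dir, nm) {
  json_path <- file.path(dir, paste0(nm, "_residence.json"))
  csv_path <- file.path(dir, paste0(nm, "_ccdf.csv"))
  png_path <- file.path(dir, paste0(nm, "_survival.png"))
  fit <- rep$fit
  payload <- list(
    y0 = fit$y0, B1 = fit$B1, B2 = fit$B2,
    tau_tb_s = fit$tau_tb, tau_sb_s = fit$tau_sb,
    sds = as.list(fit$sds),
    model_choice = fit$model_choice,
    f_statistic = fit$f_statistic, p_value = fit$p_value,
    subfractions = if (is.null(rep$subfractions)) NULL else
      as.list(rep$subfractions),
    bleach = if (is.null(rep$bleach_model)) NULL else
      rep$bleach_model[c("y0", "fb1", "taub1", "fb2", "taub2")],
    diagnostics = rep$diagnostics,
    manifest = rep$manifest
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(rep$ccdf_corrected, csv_path, row.names = FALSE)
  p <- ggplot2::ggplot(rep$survival,
                       ggplot2::aes(x = .data$tau, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (s)", y = "Survival probability", title = nm) +
    ggplot2::theme_classic()
  ggplot2::ggsave(png_path, p, width = 3.6, height = 3.2, dpi = 150)
  c(json_path, csv_path, png_path)
}
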