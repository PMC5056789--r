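#' Acquisition timing for a single-molecule tracking movie
#'
#' Describes how frames were acquired: the camera integration (exposure)
#' time and, for time-lapse movies, the dark interval between exposures.
#' The frame-to-frame interval (`lapse_interval`) is the sum of the two and
#' is the time step used in all diffusion and dwell-time calculations.
#'
#' @param integration_time Exposure time per frame in seconds (must be > 0).
#'   Default 0.03 s, the standard 30-ms exposure for fractional studies.
#' @param dark_time Dark time between exposures in seconds (>= 0). A value
#'   of 0 means continuous acquisition; a positive value (e.g. 0.17 s)
#'   means time-lapse acquisition used for residence-time studies.
#'
#' @return An object of class `acquisition_timing` with fields
#'   `integration_time`, `dark_time`, `lapse_interval` and
#'   `mode` (`"continuous"` or `"timelapse"`).
#' @examples
#' acquisition_timing()                 # continuous, 30 ms
#' acquisition_timing(0.03, 0.17)       # time-lapse, 200 ms interval
#' @export
acquisition_timing <- function(integration_time = 0.03, dark_time = 0) {
  stopifnot(is.numeric(integration_time), length(integration_time) == 1L,
            is.finite(integration_time), integration_time > 0,
            is.numeric(dark_time), length(dark_time) == 1L,
            is.finite(dark_time), dark_time >= 0)
  structure(
    list(
      integration_time = integration_time,
      dark_time = dark_time,
      lapse_interval = integration_time + dark_time,
      mode = if (dark_time == 0) "continuous" else "timelapse"
    ),
    class = "acquisition_timing"
  )
}

#' @export
print.acquisition_timing <- function(x, ...) {
  cat(sprintf("<acquisition_timing> %s: integration %g s, dark %g s, interval %g s\n",
              x$mode, x$integration_time, x$dark_time, x$lapse_interval))
  invisible(x)
}
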