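#' Construct a set of single-molecule tracks
#'
#' A `track_set` bundles the localization table of a tracking experiment
#' with its acquisition timing. Localizations are stored long-format, one
#' row per detection, grouped by track and ordered by frame. Coordinates
#' are physical (micrometres), not pixels.
#'
#' @param localizations data.frame with columns `track_id`, `frame`
#'   (integer, strictly increasing within a track, consecutive — gaps are
#'   rejected), `x`, `y` (micrometres, finite).
#' @param timing [acquisition_timing()] object.
#' @param label Free-text label for the data set.
#' @param pixel_size Camera pixel size in object space, micrometres.
#'   Default 0.064 (16 um camera pixel at 250x overall magnification);
#'   recorded as metadata for provenance, coordinates are already in um.
#' @return Object of class `track_set`.
#' @export
track_set <- function(localizations, timing, label = "", pixel_size = 0.064) {
  stopifnot(inherits(timing, "acquisition_timing"),
            is.numeric(pixel_size), pixel_size > 0)
  loc <- as.data.frame(localizations)
  required <- c("track_id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(loc))
  if (length(missing_cols) > 0) {
    stop("localizations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  loc <- loc[required]
  loc$track_id <- as.character(loc$track_id)
  loc$frame <- as.integer(loc$frame)
  if (nrow(loc) > 0) {
    if (any(!is.finite(loc$x)) || any(!is.finite(loc$y))) {
      stop("non-finite coordinates in localizations")
    }
    loc <- loc[order(loc$track_id, loc$frame), , drop = FALSE]
    rownames(loc) <- NULL
    validate_frames(loc)
  }
  structure(
    list(localizations = loc, timing = timing, label = label,
         pixel_size = pixel_size),
    class = "track_set"
  )
}

# frames must be strictly increasing and consecutive within each track
validate_frames <- function(loc) {
  bad <- vapply(split(loc$frame, loc$track_id), function(f) {
    length(f) > 1 && any(diff(f) != 1L)
  }, logical(1))
  if (any(bad)) {
    offender <- names(bad)[bad][1]
    f <- loc$frame[loc$track_id == offender]
    d <- diff(f)
    if (any(d <= 0)) {
      stop(sprintf("track '%s': frame indices not strictly increasing (frames %d, %d)",
                   offender, f[which(d <= 0)[1]], f[which(d <= 0)[1] + 1L]))
    }
    stop(sprintf("track '%s': gap between frames %d and %d (use split_gaps = TRUE in read_tracks to split)",
                 offender, f[which(d > 1)[1]], f[which(d > 1)[1] + 1L]))
  }
  invisible(TRUE)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d localizations (%s, interval %g s)%s\n",
              n_tracks(x), nrow(x$localizations), x$timing$mode,
              x$timing$lapse_interval,
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' Number of tracks in a track_set
#' @param ts A `track_set`.
#' @return Integer count of distinct tracks.
#' @export
n_tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  length(unique(ts$localizations$track_id))
}

#' Read a track table from CSV
#'
#' The format is a plain CSV with header comment lines carrying the
#' acquisition metadata, then the columns `track_id,frame,x_um,y_um`,
#' one row per localization:
#' \preformatted{
#' # integration_time_s=0.03
#' # dark_time_s=0
#' # pixel_size_um=0.064
#' track_id,frame,x_um,y_um
#' 1,0,1.234000,5.678000
#' }
#'
#' @param path Path to the CSV file.
#' @param split_gaps If `TRUE`, a track containing a frame gap is split
#'   into separate tracks at each gap (ids get a `.1`, `.2`, ... suffix)
#'   instead of raising an error. Displacement-based estimators assume
#'   consecutive frames, so gapped tracks are never analyzed whole.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, split_gaps = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- parse_header_meta(hdr)
  for (key in c("integration_time_s", "dark_time_s")) {
    if (is.na(meta[[key]])) {
      stop("missing header line '# ", key, "=...' in ", path)
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0 || body[1] != "track_id,frame,x_um,y_um") {
    stop("missing or malformed column header line 'track_id,frame,x_um,y_um' in ", path)
  }
  if (length(body) == 1) {
    loc <- data.frame(track_id = character(0), frame = integer(0),
                      x = numeric(0), y = numeric(0))
  } else {
    tab <- tryCatch(
      utils::read.csv(text = body, colClasses = c("character", "integer",
                                                  "numeric", "numeric")),
      error = function(e) stop("malformed track table in ", path, ": ",
                               conditionMessage(e))
    )
    bad <- which(is.na(tab$frame) | !is.finite(tab$x_um) | !is.finite(tab$y_um))
    if (length(bad) > 0) {
      stop(sprintf("malformed row for track '%s' (data line %d) in %s",
                   tab$track_id[bad[1]], bad[1], path))
    }
    loc <- data.frame(track_id = tab$track_id, frame = tab$frame,
                      x = tab$x_um, y = tab$y_um)
  }
  # frames must appear in strictly increasing order within each track as
  # written; sorting would silently repair shuffled tracker output
  if (nrow(loc) > 0) {
    for (id in unique(loc$track_id)) {
      f <- loc$frame[loc$track_id == id]
      if (length(f) > 1 && any(diff(f) <= 0)) {
        i <- which(diff(f) <= 0)[1]
        stop(sprintf("track '%s': frame indices not strictly increasing (frames %d, %d) in %s",
                     id, f[i], f[i + 1L], path))
      }
    }
  }
  if (split_gaps && nrow(loc) > 0) loc <- split_at_gaps(loc)
  timing <- acquisition_timing(meta$integration_time_s, meta$dark_time_s)
  pixel_size <- if (is.na(meta$pixel_size_um)) 0.064 else meta$pixel_size_um
  track_set(loc, timing, label = basename(path), pixel_size = pixel_size)
}

parse_header_meta <- function(hdr) {
  get <- function(key) {
    pat <- paste0("^#\\s*", key, "\\s*=\\s*")
    hit <- grep(pat, hdr, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    as.numeric(sub(pat, "", hit[1]))
  }
  list(integration_time_s = get("integration_time_s"),
       dark_time_s = get("dark_time_s"),
       pixel_size_um = get("pixel_size_um"))
}

split_at_gaps <- function(loc) {
  loc <- loc[order(loc$track_id, loc$frame), , drop = FALSE]
  pieces <- lapply(split(loc, loc$track_id), function(d) {
    if (nrow(d) > 1 && any(diff(d$frame) <= 0)) {
      stop(sprintf("track '%s': frame indices not strictly increasing",
                   d$track_id[1]))
    }
    seg <- cumsum(c(0L, diff(d$frame) > 1L))
    if (max(seg) > 0) {
      d$track_id <- paste0(d$track_id, ".", seg + 1L)
    }
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write a track table to CSV
#'
#' Output is byte-stable for a given `track_set`: fixed column order,
#' coordinates formatted with 6 decimal places, metadata in header
#' comment lines. `read_tracks(write_tracks(ts, f))` reproduces `ts` up
#' to that formatting precision.
#'
#' @param ts A [track_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  hdr <- c(
    sprintf("# integration_time_s=%.10g", ts$timing$integration_time),
    sprintf("# dark_time_s=%.10g", ts$timing$dark_time),
    sprintf("# pixel_size_um=%.10g", ts$pixel_size),
    "track_id,frame,x_um,y_um"
  )
  loc <- ts$localizations
  rows <- if (nrow(loc) > 0) {
    sprintf("%s,%d,%.6f,%.6f", loc$track_id, loc$frame, loc$x, loc$y)
  } else {
    character(0)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Drop tracks with too few displacements
#'
#' Keeps tracks that contain at least `min_steps` frame-to-frame
#' displacements (a track of k frames has k - 1 steps). The number of
#' removed tracks is attached as attribute `n_removed` and reported via
#' `message()`.
#'
#' @param ts A [track_set()].
#' @param min_steps Minimum number of steps (>= 1).
#' @return Filtered `track_set`.
#' @export
filter_min_steps <- function(ts, min_steps = 1L) {
  stopifnot(inherits(ts, "track_set"), min_steps >= 1)
  len <- table(ts$localizations$track_id)
  keep_ids <- names(len)[len >= min_steps + 1L]
  n_removed <- length(len) - length(keep_ids)
  out <- ts
  out$localizations <- ts$localizations[
    ts$localizations$track_id %in% keep_ids, , drop = FALSE]
  rownames(out$localizations) <- NULL
  if (n_removed > 0) {
    message(sprintf("filter_min_steps: removed %d of %d tracks (< %d steps)",
                    n_removed, length(len), min_steps))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Track length distribution
#'
#' Counts tracks by their length in frames, the distribution the quality
#' checks on tracking data look at (short tracks dominate when molecules
#' bleach or defocus quickly).
#'
#' @param ts A non-empty [track_set()].
#' @return data.frame with columns `length` (frames) and `count`; the
#'   counts sum to the number of tracks.
#' @export
track_length_histogram <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  if (nrow(ts$localizations) == 0) stop("empty track_set")
  len <- table(table(ts$localizations$track_id))
  data.frame(length = as.integer(names(len)), count = as.integer(len))
}
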