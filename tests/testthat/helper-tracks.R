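# small constructors used across test files

timing_cont <- function() acquisition_timing(0.03, 0)
timing_tl <- function() acquisition_timing(0.03, 0.17)

# track_set from a list of per-track coordinate matrices (um)
toy_track_set <- function(coords, timing = timing_cont()) {
  loc <- do.call(rbind, c(list(
    data.frame(track_id = character(0), frame = integer(0),
               x = numeric(0), y = numeric(0))),
    lapply(seq_along(coords), function(i) {
      m <- coords[[i]]
      data.frame(track_id = paste0("trk", i), frame = seq_len(nrow(m)) - 1L,
                 x = m[, 1], y = m[, 2])
    })))
  track_set(loc, timing)
}

single_track_df <- function(xy) {
  data.frame(frame = seq_len(nrow(xy)) - 1L, x = xy[, 1], y = xy[, 2])
}
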