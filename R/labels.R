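#' Per-frame behavior label tracks
#'
#' A label track is an integer vector with one entry per frame:
#' `0` not grooming, `1` facial grooming, `2` body grooming. Tracks are used
#' both for human annotation (ground truth) and classifier output.
#'
#' @param values integer vector of labels in `{0, 1, 2}`.
#' @param source_id optional character identifier of the source video.
#' @return an integer vector of class `label_track`.
#' @export
label_track <- function(values, source_id = NULL) {
  values <- as.integer(values)
  if (length(values) == 0L) stop("label track must contain at least one frame")
  if (anyNA(values) || any(values < 0L | values > 2L))
    stop("labels must all be 0 (not grooming), 1 (facial) or 2 (body)")
  structure(values, class = "label_track", source_id = source_id)
}

as_label_values <- function(track) {
  v <- as.integer(unclass(track))
  if (length(v) == 0L) stop("label track must contain at least one frame")
  if (anyNA(v) || any(v < 0L | v > 2L)) stop("labels must be in {0, 1, 2}")
  v
}

#' Run-length view of a track: data.frame(cls, start, end), half-open 0-based
#' @noRd
track_runs <- function(values) {
  r <- rle(values)
  end <- cumsum(r$lengths)
  data.frame(cls = r$values, start = end - r$lengths, end = end)
}

runs_to_track <- function(runs) {
  rep.int(runs$cls, runs$end - runs$start)
}

#' Extract grooming bouts from a label track
#'
#' A bout is a maximal run of frames sharing one grooming class (1 or 2).
#' Intervals are half-open `[start, end)` with 0-based frame indices.
#'
#' @param track a [label_track()] or plain integer vector of labels.
#' @return data.frame with columns `cls`, `start`, `end`, `duration`,
#'   ordered by `start`; zero rows when the track contains no grooming.
#' @export
extract_bouts <- function(track) {
  v <- as_label_values(track)
  runs <- track_runs(v)
  b <- runs[runs$cls != 0L, , drop = FALSE]
  rownames(b) <- NULL
  b$duration <- b$end - b$start
  b
}

#' Validate a track against the annotation bout rules
#'
#' Ground-truth annotation requires every grooming bout to last at least
#' `min_bout` frames and every not-grooming gap between two bouts to last at
#' least `min_gap` frames. Violations are reported, never silently repaired.
#'
#' @param track a label track.
#' @param min_bout minimum bout duration in frames (default 5).
#' @param min_gap minimum between-bout gap in frames (default 6).
#' @return data.frame with columns `type` (`"short_bout"` or `"short_gap"`),
#'   `start`, `end`, `duration`; zero rows when the track conforms.
#' @export
validate_annotation <- function(track, min_bout = 5L, min_gap = 6L) {
  v <- as_label_values(track)
  runs <- track_runs(v)
  out <- list()
  groom <- which(runs$cls != 0L)
  short <- groom[runs$end[groom] - runs$start[groom] < min_bout]
  if (length(short))
    out$bout <- data.frame(type = "short_bout", start = runs$start[short],
                           end = runs$end[short])
  # zero-runs strictly between two grooming runs
  if (length(groom) >= 2L) {
    zr <- which(runs$cls == 0L)
    zr <- zr[zr > min(groom) & zr < max(groom)]
    zr <- zr[runs$end[zr] - runs$start[zr] < min_gap]
    if (length(zr))
      out$gap <- data.frame(type = "short_gap", start = runs$start[zr],
                            end = runs$end[zr])
  }
  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(type = character(), start = integer(), end = integer())
  rownames(rep) <- NULL
  rep$duration <- rep$end - rep$start
  rep
}

#' One-hot encode a label track
#'
#' @param track a label track.
#' @return numeric matrix with one row per frame and 3 columns
#'   (not / facial / body); each row sums to 1.
#' @export
to_onehot <- function(track) {
  v <- as_label_values(track)
  m <- matrix(0, length(v), 3L,
              dimnames = list(NULL, c("not", "face", "body")))
  m[cbind(seq_along(v), v + 1L)] <- 1
  m
}

#' Read / write a label CSV
#'
#' The on-disk format is `frame,label` with a header, 0-based contiguous
#' frame indices and one row per frame.
#'
#' @param path file path.
#' @param track a label track (for writing).
#' @return `read_label_csv` returns a [label_track()].
#' @export
read_label_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("frame", "label") %in% names(d)))
    stop("label CSV must have columns 'frame' and 'label': ", path)
  if (!identical(as.integer(d$frame), seq_len(nrow(d)) - 1L))
    stop("frame indices must be 0-based and contiguous in ", path,
         " (first problem near row ",
         which(as.integer(d$frame) != seq_len(nrow(d)) - 1L)[1] + 1L, ")")
  label_track(d$label, source_id = basename(path))
}

#' @rdname read_label_csv
#' @export
write_label_csv <- function(track, path) {
  v <- as_label_values(track)
  utils::write.csv(data.frame(frame = seq_along(v) - 1L, label = v),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
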