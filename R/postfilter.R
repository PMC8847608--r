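#' Rule-based temporal filters for predicted label tracks
#'
#' Raw per-frame predictions contain three implausible patterns that the
#' posterior filters reverse, in order: (i) sporadic mispredictions -- short
#' isolated grooming runs surrounded by not-grooming; (ii) unlikely
#' interruptions -- short not-grooming gaps sandwiched between grooming runs;
#' (iii) unlikely transitions -- short runs of one grooming class adjacent to
#' the other class. Each filter makes a single left-to-right pass; the video
#' boundary counts as a not-grooming neighbor.
#'
#' @param track a label track (integer vector, values in `{0, 1, 2}`).
#' @param max_len,max_gap pattern length thresholds in frames; a run is
#'   reversed when its length is `<=` the threshold.
#' @return a filtered label track of identical length.
#' @name postfilter
NULL

#' @describeIn postfilter relabel to 0 every grooming run of length
#'   `<= max_len` whose neighbors on both sides are not-grooming (or the
#'   video boundary).
#' @export
filter_sporadic <- function(track, max_len = 4L) {
  stopifnot(max_len >= 1L)
  v <- as_label_values(track)
  runs <- track_runs(v)
  n <- nrow(runs)
  for (i in seq_len(n)) {
    if (runs$cls[i] == 0L) next
    if (runs$end[i] - runs$start[i] > max_len) next
    left0 <- i == 1L || runs$cls[i - 1L] == 0L
    right0 <- i == n || runs$cls[i + 1L] == 0L
    if (left0 && right0) runs$cls[i] <- 0L
  }
  rebuild_track(runs, track)
}

#' @describeIn postfilter fill every not-grooming gap of length `<= max_gap`
#'   flanked by grooming on both sides. Disagreeing flanks are resolved by
#'   the longer flanking run (measured in the current, partially merged
#'   state), ties toward the preceding run.
#' @export
filter_interruption <- function(track, max_gap = 6L) {
  stopifnot(max_gap >= 1L)
  v <- as_label_values(track)
  runs <- track_runs(v)
  n <- nrow(runs)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (runs$cls[i] != 0L) next
      if (runs$end[i] - runs$start[i] > max_gap) next
      lc <- runs$cls[i - 1L]
      rc <- runs$cls[i + 1L]
      if (lc == 0L || rc == 0L) next
      if (lc == rc) {
        runs$cls[i] <- lc
      } else {
        # flank lengths in the current state: the left flank may have grown
        # through earlier fills, so measure it back to the last class change
        llen <- current_flank_len(runs, i - 1L)
        rlen <- runs$end[i + 1L] - runs$start[i + 1L]
        runs$cls[i] <- if (rlen > llen) rc else lc
      }
    }
  }
  rebuild_track(runs, track)
}

#' @describeIn postfilter relabel every grooming run of length `<= max_len`
#'   adjacent to the other grooming class (on either side) to that class;
#'   when other-class runs flank both sides, the longer neighbor wins, ties
#'   toward the preceding run. Runs touching the video boundary are exempt
#'   (they may be truncated bouts whose true length is unknown). The sweep
#'   merges as it goes: a relabeled run absorbs same-class neighbors and the
#'   merged run is re-examined, so no reversible pattern survives the pass.
#' @export
filter_transition <- function(track, max_len = 4L) {
  stopifnot(max_len >= 1L)
  v <- as_label_values(track)
  runs <- track_runs(v)
  i <- 1L
  while (i <= nrow(runs)) {
    ci <- runs$cls[i]
    len <- runs$end[i] - runs$start[i]
    if (ci == 0L || i == 1L || i == nrow(runs) || len > max_len) {
      i <- i + 1L
      next
    }
    other <- 3L - ci
    ladj <- runs$cls[i - 1L] == other
    radj <- runs$cls[i + 1L] == other
    if (!ladj && !radj) {
      i <- i + 1L
      next
    }
    runs$cls[i] <- other
    # absorb same-class neighbors into one run, then re-examine it
    if (radj) {
      runs$end[i] <- runs$end[i + 1L]
      runs <- runs[-(i + 1L), , drop = FALSE]
    }
    if (ladj) {
      runs$start[i] <- runs$start[i - 1L]
      runs <- runs[-(i - 1L), , drop = FALSE]
      i <- i - 1L
    }
  }
  rownames(runs) <- NULL
  rebuild_track(runs, track)
}

#' @describeIn postfilter serial application: sporadic, then interruption,
#'   then transition (each a single pass).
#' @export
apply_filters <- function(track, params = filter_params()) {
  out <- filter_sporadic(track, params$sporadic_max)
  out <- filter_interruption(out, params$interruption_max)
  filter_transition(out, params$transition_max)
}

#' Filter thresholds
#'
#' @param sporadic_max,interruption_max,transition_max maximal pattern
#'   lengths (frames) reversed by the three filters.
#' @return a list of validated thresholds.
#' @export
filter_params <- function(sporadic_max = 4L, interruption_max = 6L,
                          transition_max = 4L) {
  p <- list(sporadic_max = as.integer(sporadic_max),
            interruption_max = as.integer(interruption_max),
            transition_max = as.integer(transition_max))
  if (any(vapply(p, function(x) is.na(x) || x < 1L, logical(1))))
    stop("all filter thresholds must be integers >= 1")
  p
}

# length of the maximal constant-class block ending at run j, in the
# partially relabeled run table (earlier runs may share j's class now)
current_flank_len <- function(runs, j) {
  len <- runs$end[j] - runs$start[j]
  k <- j - 1L
  while (k >= 1L && runs$cls[k] == runs$cls[j]) {
    len <- len + runs$end[k] - runs$start[k]
    k <- k - 1L
  }
  len
}

current_flank_cls <- function(runs, j) runs$cls[j]

rebuild_track <- function(runs, template) {
  v <- runs_to_track(runs)
  if (inherits(template, "label_track"))
    label_track(v, source_id = attr(template, "source_id"))
  else as.integer(v)
}
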