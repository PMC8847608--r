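#' Behavior script for the synthetic scene generator
#'
#' A script is an ordered list of (behavior, duration) segments drawn from
#' `still`, `locomote`, `facial_groom`, `body_groom`. Ground-truth scripts
#' must satisfy the annotation contract: every grooming segment lasts at
#' least 5 frames and consecutive grooming segments are separated by at
#' least 6 non-grooming frames.
#'
#' @param behavior character vector of segment behaviors.
#' @param duration integer vector of segment durations (frames).
#' @return data.frame of class `behavior_script`.
#' @export
behavior_script <- function(behavior, duration) {
  known <- c("still", "locomote", "facial_groom", "body_groom")
  if (!all(behavior %in% known))
    stop("unknown behavior; expected one of: ", paste(known, collapse = ", "))
  duration <- as.integer(duration)
  if (length(duration) != length(behavior) || any(duration < 1L))
    stop("durations must be positive integers, one per segment")
  s <- data.frame(behavior = behavior, duration = duration,
                  stringsAsFactors = FALSE)
  groom <- s$behavior %in% c("facial_groom", "body_groom")
  if (any(groom & s$duration < 5L))
    stop("grooming segments must last at least 5 frames")
  lab <- script_labels(s)
  viol <- validate_annotation(label_track(pmax(lab, 0L)))
  if (nrow(viol) > 0L)
    stop("script violates the bout annotation contract (short bout or gap)")
  class(s) <- c("behavior_script", class(s))
  s
}

script_labels <- function(script) {
  code <- c(still = 0L, locomote = 0L, facial_groom = 1L, body_groom = 2L)
  rep.int(code[script$behavior], script$duration)
}

#' Expand a behavior script into its ground-truth label track
#' @param script a [behavior_script()].
#' @return a [label_track()] (facial_groom = 1, body_groom = 2, else 0).
#' @export
script_to_track <- function(script) {
  label_track(script_labels(script))
}

#' Synthetic scene configuration
#'
#' Emulates a bright mouse-like ellipse on a dark square arena viewed from
#' above. Facial grooming is rendered as a fast, small-amplitude oscillation
#' of an appendage blob at the anterior pole; body grooming as a slower,
#' larger-amplitude deformation of the flank (semi-minor axis modulation) --
#' schematic motion models whose only contract is class-separable motion
#' statistics localized to the right body region.
#'
#' @param arena_side arena side in pixels (default 256).
#' @param body_axes ellipse semi-axes (along-heading, across-heading) px.
#' @param locomotion_speed translation speed, px/frame.
#' @param facial_osc `c(amplitude, period)`: appendage oscillation, px and
#'   frames. Amplitude must stay below the body amplitude.
#' @param body_osc `c(amplitude, period)` of the flank deformation.
#' @param pixel_noise_rate fraction of pixels replaced with random intensity
#'   per frame (sensor noise), at most 0.05.
#' @param seed RNG seed used by [render_video()]; `NULL` uses the current
#'   RNG state.
#' @param fps nominal frame rate (metadata), default 60.
#' @return validated configuration list.
#' @export
scene_config <- function(arena_side = 256L, body_axes = c(28, 16),
                         locomotion_speed = 3, facial_osc = c(2, 4),
                         body_osc = c(6, 10), pixel_noise_rate = 0.002,
                         seed = NULL, fps = 60) {
  stopifnot(arena_side >= 64L, length(body_axes) == 2L, all(body_axes > 0),
            locomotion_speed > 0, length(facial_osc) == 2L,
            length(body_osc) == 2L, all(facial_osc > 0), all(body_osc > 0))
  if (facial_osc[1] >= body_osc[1])
    stop("facial oscillation amplitude must be smaller than body amplitude")
  if (pixel_noise_rate < 0 || pixel_noise_rate > 0.05)
    stop("pixel_noise_rate must be in [0, 0.05]")
  list(arena_side = as.integer(arena_side), body_axes = body_axes,
       locomotion_speed = locomotion_speed, facial_osc = facial_osc,
       body_osc = body_osc, pixel_noise_rate = pixel_noise_rate,
       seed = seed, fps = fps,
       mouse_intensity = 200, arena_intensity = 10)
}

#' Render a synthetic top-view video with ground truth
#'
#' @param script a [behavior_script()].
#' @param scene a [scene_config()].
#' @return list: `frames` (a `frame_sequence`) and `truth` (a
#'   [label_track()] over raw frames).
#' @export
render_video <- function(script, scene = scene_config()) {
  if (!inherits(script, "behavior_script"))
    script <- behavior_script(script$behavior, script$duration)
  if (!is.null(scene$seed)) set.seed(scene$seed)
  A <- scene$arena_side
  a <- scene$body_axes[1]; b <- scene$body_axes[2]
  margin <- a + scene$body_osc[1] + 4

  pos <- c(A / 2, A / 2)
  theta <- stats::runif(1, 0, 2 * pi)
  behaviors <- rep.int(script$behavior, script$duration)
  n <- length(behaviors)
  frames <- vector("list", n)
  clipped <- FALSE
  phase <- 0L # frames elapsed inside the current segment
  base <- matrix(scene$arena_intensity, A, A)
  ext <- ceiling(margin) + 4L # half-side of the window holding the mouse

  for (t in seq_len(n)) {
    beh <- behaviors[t]
    phase <- if (t > 1L && behaviors[t - 1L] == beh) phase + 1L else 0L
    if (beh == "locomote") {
      theta <- theta + stats::rnorm(1, 0, 0.15)
      step <- scene$locomotion_speed * c(cos(theta), sin(theta))
      np <- pos + step
      if (any(np < margin) || any(np > A - 1 - margin)) {
        theta <- theta + pi / 2 + stats::runif(1, 0, pi / 2)
        np <- pmin(pmax(np, margin), A - 1 - margin)
        clipped <- TRUE
      }
      pos <- np
    }
    bt <- b
    if (beh == "body_groom")
      bt <- b + scene$body_osc[1] * sin(2 * pi * phase / scene$body_osc[2])
    img <- base
    # evaluate the body mask only inside a window around the mouse
    rows <- max(1L, floor(pos[1]) - ext):min(A, ceiling(pos[1]) + ext)
    cols <- max(1L, floor(pos[2]) - ext):min(A, ceiling(pos[2]) + ext)
    wr <- rows - 1 - pos[1]
    wc <- cols - 1 - pos[2]
    u <- outer(wr * cos(theta), wc * sin(theta), "+")
    v <- outer(-wr * sin(theta), wc * cos(theta), "+")
    win <- img[rows, cols]
    win[(u / a)^2 + (v / bt)^2 <= 1] <- scene$mouse_intensity
    if (beh == "facial_groom") {
      off <- a + 1 + scene$facial_osc[1] *
        sin(2 * pi * phase / scene$facial_osc[2])
      cen <- pos + off * c(cos(theta), sin(theta))
      fr <- outer((rows - 1 - cen[1])^2, (cols - 1 - cen[2])^2, "+")
      win[fr <= 2.5^2] <- scene$mouse_intensity
    }
    img[rows, cols] <- win
    if (scene$pixel_noise_rate > 0) {
      k <- round(scene$pixel_noise_rate * A * A)
      if (k > 0) {
        ij <- sample.int(A * A, k)
        img[ij] <- stats::runif(k, 0, 255)
      }
    }
    frames[[t]] <- img
  }
  if (clipped) warning("mouse reached the arena wall; trajectory clipped")
  truth <- label_track(script_labels(script))
  list(frames = structure(frames, fps = scene$fps, source_id = "synthetic",
                          class = "frame_sequence"),
       truth = truth)
}

#' Random behavior script
#'
#' Draws `n_bouts` grooming segments (class per `class_mix`) interleaved
#' with non-grooming segments (still or locomotion). Grooming durations are
#' uniform on `bout_frames`, inter-bout gaps uniform on `gap_frames`
#' (defaults keep gaps comfortably above the interruption-filter threshold
#' so that filter-recovery is well defined).
#'
#' @param n_bouts number of grooming segments (>= 0).
#' @param class_mix probabilities `c(facial, body)` for each bout's class.
#' @param bout_frames,gap_frames integer ranges to draw durations from.
#' @return a [behavior_script()].
#' @export
random_script <- function(n_bouts, class_mix = c(0.4, 0.6),
                          bout_frames = 40:100, gap_frames = 20:60) {
  stopifnot(n_bouts >= 0, length(class_mix) == 2L, all(class_mix >= 0),
            sum(class_mix) > 0, min(bout_frames) >= 5L, min(gap_frames) >= 7L)
  beh <- character(0); dur <- integer(0)
  pad <- function() {
    d <- sample(gap_frames, 1L)
    k <- sample(c("still", "locomote"), 1L)
    # split long gaps into a still part and a locomotion part sometimes
    if (d >= 20L && stats::runif(1) < 0.5) {
      d1 <- sample(7:(d - 7L), 1L)
      beh <<- c(beh, "still", "locomote")
      dur <<- c(dur, d1, d - d1)
    } else {
      beh <<- c(beh, k)
      dur <<- c(dur, d)
    }
  }
  pad()
  for (i in seq_len(n_bouts)) {
    cls <- sample(c("facial_groom", "body_groom"), 1L,
                  prob = class_mix / sum(class_mix))
    beh <- c(beh, cls)
    dur <- c(dur, sample(bout_frames, 1L))
    pad()
  }
  behavior_script(beh, dur)
}

#' Corrupt a ground-truth track with filter-reversible patterns
#'
#' Injects the three implausible patterns the posterior filters remove:
#' (a) isolated short grooming runs inside not-grooming stretches,
#' (b) short not-grooming gaps inside bouts, and (c) short class flips at
#' bout edges. Injections are kept more than `min_sep` frames apart and are
#' placed so that a serial filter pass restores the exact truth (gap
#' fragments keep >= 5 frames; flip remainders keep >= 5 frames).
#'
#' @param truth a ground-truth label track.
#' @param rates per-frame injection rates `c(sporadic, gap, transition)`.
#' @param min_sep minimal separation between injected patterns (frames).
#' @return a corrupted [label_track()].
#' @export
corrupt_track <- function(truth, rates = c(0.002, 0.002, 0.002),
                          min_sep = 7L) {
  stopifnot(length(rates) == 3L, all(rates >= 0))
  v <- as_label_values(truth)
  n <- length(v)
  out <- v
  placed <- matrix(numeric(0), ncol = 2) # [start, end) of injected patterns

  far_enough <- function(s, e) {
    if (nrow(placed) == 0L) return(TRUE)
    all(s - placed[, 2] >= min_sep | placed[, 1] - e >= min_sep)
  }
  want <- stats::rbinom(3L, n, pmin(rates, 1))

  # (a) sporadic runs inside zero stretches, >= 1 zero kept on each side
  place_sporadic <- function() {
    for (try in 1:400) {
      L <- sample(1:4, 1L)
      s <- sample.int(n - L + 1L, 1L) - 1L # 0-based start
      win <- (s - 1L):(s + L) # pattern plus one guard zero each side
      if (min(win) < 0L || max(win) > n - 1L) next
      if (any(v[win + 1L] != 0L) || any(out[win + 1L] != 0L)) next
      if (!far_enough(s, s + L)) next
      out[(s + 1L):(s + L)] <<- sample(1:2, 1L)
      placed <<- rbind(placed, c(s, s + L))
      return(TRUE)
    }
    FALSE
  }
  # (b) zero gaps strictly inside bouts, fragments >= 5 on both sides
  bouts <- extract_bouts(v)
  place_gap <- function() {
    if (nrow(bouts) == 0L) return(FALSE)
    for (try in 1:400) {
      G <- sample(1:6, 1L)
      bi <- sample.int(nrow(bouts), 1L)
      lo <- bouts$start[bi] + 5L
      hi <- bouts$end[bi] - 5L - G
      if (hi < lo) next
      s <- sample(lo:hi, 1L)
      if (any(out[(s + 1L):(s + G)] != v[(s + 1L):(s + G)])) next
      if (!far_enough(s, s + G)) next
      out[(s + 1L):(s + G)] <<- 0L
      placed <<- rbind(placed, c(s, s + G))
      return(TRUE)
    }
    FALSE
  }
  # (c) class flips at bout edges, remainder keeps >= 5 frames
  place_flip <- function() {
    if (nrow(bouts) == 0L) return(FALSE)
    for (try in 1:400) {
      Fl <- sample(1:4, 1L)
      bi <- sample.int(nrow(bouts), 1L)
      if (bouts$duration[bi] < Fl + 5L) next
      at_start <- stats::runif(1) < 0.5
      s <- if (at_start) bouts$start[bi] else bouts$end[bi] - Fl
      idx <- (s + 1L):(s + Fl)
      if (any(out[idx] != v[idx])) next
      if (!far_enough(s, s + Fl)) next
      out[idx] <<- 3L - bouts$cls[bi]
      placed <<- rbind(placed, c(s, s + Fl))
      return(TRUE)
    }
    FALSE
  }

  # structural capacity per type, independent of separation constraints
  zr <- track_runs(v)
  has_site <- c(any(zr$cls == 0L & zr$end - zr$start >= 3L),
                nrow(bouts) > 0L && any(bouts$duration >= 11L),
                nrow(bouts) > 0L && any(bouts$duration >= 6L))
  fns <- list(place_sporadic, place_gap, place_flip)
  wanted <- 0L
  done <- 0L
  for (k in 1:3) {
    if (!has_site[k]) next # no candidate sites at all: nothing to inject
    wanted <- wanted + want[k]
    for (i in seq_len(want[k])) {
      if (!fns[[k]]()) break # site pool exhausted under the separation rule
      done <- done + 1L
    }
  }
  if (wanted > 0L && done < wanted) {
    if (done < wanted / 2)
      stop("rates too high: only ", done, " of ", wanted,
           " corruptions fit under the ", min_sep, "-frame separation")
    warning("placed ", done, " of ", wanted,
            " requested corruptions (separation constraint)")
  }
  label_track(out, source_id = attr(truth, "source_id"))
}
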