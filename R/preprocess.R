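#' Preprocessing configuration
#'
#' @param crop_side side (pixels) of the square cropped around the mouse
#'   centroid before resizing. Default 256: comfortably larger than the
#'   animal at the reference camera geometry, halved to the network input.
#' @param binarize_threshold intensity cut in `[1, 255]` applied to the
#'   grayscale difference image; default 20 suppresses sensor noise while
#'   keeping motion pixels.
#' @param centroid_threshold intensity cut used to segment the mouse in the
#'   raw frame before centroid extraction.
#' @param foreground_polarity `"bright"` (white mouse on dark arena, the
#'   default) or `"dark"`.
#' @param out_side side of the resized output (network input), default 128.
#' @return validated configuration list.
#' @export
preprocess_config <- function(crop_side = 256L, binarize_threshold = 20,
                              centroid_threshold = 100,
                              foreground_polarity = c("bright", "dark"),
                              out_side = 128L) {
  foreground_polarity <- match.arg(foreground_polarity)
  crop_side <- as.integer(crop_side)
  out_side <- as.integer(out_side)
  if (crop_side < 1L || out_side < 1L) stop("sides must be positive")
  if (binarize_threshold < 1 || binarize_threshold > 255)
    stop("binarize_threshold must be in [1, 255]")
  if (centroid_threshold < 1 || centroid_threshold > 255)
    stop("centroid_threshold must be in [1, 255]")
  list(crop_side = crop_side, binarize_threshold = binarize_threshold,
       centroid_threshold = centroid_threshold,
       foreground_polarity = foreground_polarity, out_side = out_side)
}

#' Extract frames from a video source
#'
#' Accepts a directory of PGM images (lexicographically ordered), a list of
#' frame matrices/arrays, or an `H x W x T` array. Frames are 8-bit
#' grayscale matrices or `H x W x 3` color arrays with values in
#' `[0, 255]`.
#'
#' @param video path to a frame-sequence directory, a list of frames, or a
#'   3-D array of grayscale frames.
#' @param fps frame rate (metadata only), default 60.
#' @return list of frames with attributes `fps` and `source_id`; class
#'   `frame_sequence`.
#' @export
extract_frames <- function(video, fps = 60) {
  if (is.character(video)) {
    if (!dir.exists(video)) stop("not a readable frame directory: ", video)
    files <- sort(list.files(video, pattern = "\\.pgm$", full.names = TRUE))
    if (length(files) == 0L) stop("empty video: no frames found in ", video)
    frames <- lapply(files, read_pgm)
    sid <- basename(video)
  } else if (is.list(video)) {
    if (length(video) == 0L) stop("empty video: zero frames")
    frames <- video
    sid <- attr(video, "source_id") %||% "memory"
  } else if (is.array(video) && length(dim(video)) == 3L) {
    if (dim(video)[3] == 0L) stop("empty video: zero frames")
    frames <- lapply(seq_len(dim(video)[3]), function(t) video[, , t])
    sid <- "memory"
  } else stop("unsupported video source")
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("frames differ in dimensions")
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 255) stop("intensities must be in [0, 255]")
  structure(frames, fps = fps, source_id = sid, class = "frame_sequence")
}

#' Absolute difference of two frames
#'
#' Computed pixel-wise (channel-wise for color frames) before any
#' grayscaling.
#'
#' @param frame_a,frame_b frames of identical dimensions.
#' @return difference image of the same dimensions.
#' @export
abs_diff <- function(frame_a, frame_b) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frame dimensions differ")
  abs(frame_a - frame_b)
}

#' Centroid of the mouse in a raw frame
#'
#' Thresholds the (grayscaled) frame at `centroid_threshold` with the
#' configured foreground polarity, keeps the largest 8-connected component,
#' and returns its mean pixel coordinates.
#'
#' @param frame a raw frame.
#' @param config a [preprocess_config()].
#' @return numeric `(row, col)`, 0-based.
#' @export
mouse_centroid <- function(frame, config = preprocess_config()) {
  g <- to_gray(frame)
  mask <- if (config$foreground_polarity == "bright")
    g >= config$centroid_threshold else g <= config$centroid_threshold
  res <- cpp_largest_cc_centroid(matrix(as.integer(mask), nrow(g), ncol(g)))
  if (res[3] == 0)
    stop(structure(class = c("ethogroom_centroid_error", "error", "condition"),
                   list(message = "no foreground pixel above threshold",
                        call = sys.call())))
  res[1:2]
}

#' Square crop with zero padding
#'
#' The window of `side x side` pixels starts at
#' `round(center) - side %/% 2` in each axis; regions outside the image are
#' zero-filled.
#'
#' @param image matrix or `H x W x C` array.
#' @param center numeric `(row, col)`, 0-based.
#' @param side window side in pixels.
#' @return cropped image of dimensions `side x side (x C)`.
#' @export
crop_square <- function(image, center, side) {
  side <- as.integer(side)
  if (side < 1L) stop("side must be positive")
  if (length(dim(image)) == 3L) {
    out <- vapply(seq_len(dim(image)[3]),
                  function(c) crop_square(image[, , c], center, side),
                  matrix(0, side, side))
    return(out)
  }
  H <- nrow(image); W <- ncol(image)
  r0 <- as.integer(round(center[1])) - side %/% 2L # 0-based window origin
  c0 <- as.integer(round(center[2])) - side %/% 2L
  out <- matrix(0, side, side)
  rs <- max(0L, r0); re <- min(H - 1L, r0 + side - 1L)
  cs <- max(0L, c0); ce <- min(W - 1L, c0 + side - 1L)
  if (rs <= re && cs <= ce)
    out[(rs - r0 + 1L):(re - r0 + 1L), (cs - c0 + 1L):(ce - c0 + 1L)] <-
      image[(rs + 1L):(re + 1L), (cs + 1L):(ce + 1L)]
  out
}

#' Resize to a square: area averaging for integer-factor downscale
#' (anti-aliasing, so isolated noise pixels do not survive thresholding),
#' bilinear interpolation otherwise.
#' @noRd
resize_image <- function(image, out_side) {
  if (length(dim(image)) == 3L) {
    return(vapply(seq_len(dim(image)[3]),
                  function(c) resize_image(image[, , c], out_side),
                  matrix(0, out_side, out_side)))
  }
  H <- nrow(image); W <- ncol(image); S <- out_side
  if (H == S && W == S) return(image)
  if (H == W && H %% S == 0L) {
    f <- H %/% S
    # block mean via two fold-sum steps
    m <- matrix(colSums(matrix(image, f, S * W)), S, W)
    m <- t(matrix(colSums(matrix(t(m), f, S * S)), S, S))
    return(m / f^2)
  }
  src <- function(n, S) pmin(pmax((seq_len(S) - 0.5) * n / S - 0.5, 0), n - 1)
  sr <- src(H, S); sc <- src(W, S)
  r0 <- floor(sr); ar <- sr - r0; r1 <- pmin(r0 + 1, H - 1)
  c0 <- floor(sc); ac <- sc - c0; c1 <- pmin(c0 + 1, W - 1)
  A <- image[r0 + 1, , drop = FALSE] * (1 - ar) +
       image[r1 + 1, , drop = FALSE] * ar
  A[, c0 + 1, drop = FALSE] * rep(1 - ac, each = S) +
    A[, c1 + 1, drop = FALSE] * rep(ac, each = S)
}

to_gray <- function(image) {
  if (length(dim(image)) == 3L)
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  else image
}

binarize <- function(image, threshold) {
  (image >= threshold) + 0
}

#' Preprocess a video into a binary differential stack
#'
#' Pipeline per frame pair: absolute difference, square crop at the centroid
#' of the later raw frame (falling back to the previous frame's centroid
#' when segmentation fails), bilinear resize to `out_side`, grayscale (luma
#' weights 0.299/0.587/0.114), and binarization. Stack frame `t` (0-based)
#' is aligned with raw frame `t + 1`.
#'
#' @param frames a [extract_frames()] result (or anything it accepts).
#' @param config a [preprocess_config()].
#' @return `out_side x out_side x (T-1)` binary array of class `diff_stack`
#'   with attributes `source_id`, `fps`, `config`.
#' @export
preprocess_video <- function(frames, config = preprocess_config()) {
  if (!inherits(frames, "frame_sequence")) frames <- extract_frames(frames)
  n <- length(frames)
  if (n < 2L) stop("need at least 2 frames to form differences")
  S <- config$out_side
  stack <- array(0, c(S, S, n - 1L))
  centroid <- NULL
  for (t in 2:n) {
    cen <- tryCatch(mouse_centroid(frames[[t]], config),
                    ethogroom_centroid_error = function(e) NULL)
    if (is.null(cen)) {
      if (is.null(centroid))
        stop("cannot locate mouse in the first frames of the video")
      cen <- centroid
    }
    centroid <- cen
    d <- abs_diff(frames[[t - 1L]], frames[[t]])
    d <- crop_square(d, cen, config$crop_side)
    d <- resize_image(d, S)
    d <- to_gray(d)
    stack[, , t - 1L] <- binarize(d, config$binarize_threshold)
  }
  structure(stack, class = "diff_stack",
            source_id = attr(frames, "source_id"),
            fps = attr(frames, "fps"), config = config)
}

#' Labels aligned to a differential stack
#'
#' Stack frame `t` (0-based) is the difference of raw frames `t` and
#' `t + 1` and carries raw frame `t + 1`'s label.
#'
#' @param raw_track label track over raw video frames (length T).
#' @return label track of length `T - 1`.
#' @export
stack_labels <- function(raw_track) {
  v <- as_label_values(raw_track)
  if (length(v) < 2L) stop("need at least 2 raw labels")
  label_track(v[-1L], source_id = attr(raw_track, "source_id"))
}

#' Grouped temporal windows over a differential stack
#'
#' The classifier input at time `t` is the sub-stack of `2w + 1` binary
#' frames from `t - w` to `t + w`; its label is the label at `t`. Windows
#' exist only for `t` in `[w, length - 1 - w]` (no padding at the edges).
#' Returned lazily: `grouped_image(g, i)` materializes window `i`.
#'
#' @param stack a `diff_stack` (or `S x S x T` binary array).
#' @param labels label track aligned to the stack (same length).
#' @param w temporal half-window (frames); the reference configuration uses
#'   10, 20, 30 or 40.
#' @return list of class `grouped_set`: `t` (0-based center indices),
#'   `labels` (per-window), `w`, `depth`, plus the stack itself. Zero
#'   windows (with a warning) when the stack is shorter than `2w + 1`.
#' @export
make_grouped <- function(stack, labels, w) {
  w <- as.integer(w)
  if (w < 1L) stop("w must be a positive integer")
  T_ <- dim(stack)[3]
  v <- as_label_values(labels)
  if (length(v) != T_)
    stop("labels (", length(v), ") not aligned to stack (", T_, " frames)")
  if (T_ < 2L * w + 1L) {
    warning("stack shorter than one window (", T_, " < ", 2L * w + 1L,
            "); no grouped images")
    t_valid <- integer(0)
  } else {
    t_valid <- w:(T_ - 1L - w)
  }
  structure(list(stack = stack, t = t_valid, labels = v[t_valid + 1L],
                 w = w, depth = 2L * w + 1L),
            class = "grouped_set")
}

#' @rdname make_grouped
#' @param g a `grouped_set`.
#' @param i window number (1-based position within `g$t`).
#' @return `grouped_image`: a `depth x S x S` binary array (temporal axis
#'   first).
#' @export
grouped_image <- function(g, i) {
  t0 <- g$t[i] # 0-based center
  sub <- g$stack[, , (t0 - g$w + 1L):(t0 + g$w + 1L), drop = FALSE]
  aperm(sub, c(3L, 1L, 2L))
}

#' Persist / load a differential stack with its metadata
#' @param stack a `diff_stack`.
#' @param path file path (RDS container).
#' @export
write_diff_stack <- function(stack, path) {
  saveRDS(list(frames = unclass(stack), source_id = attr(stack, "source_id"),
               fps = attr(stack, "fps"), config = attr(stack, "config")),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_diff_stack
#' @export
read_diff_stack <- function(path) {
  x <- readRDS(path)
  structure(x$frames, class = "diff_stack", source_id = x$source_id,
            fps = x$fps, config = x$config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
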