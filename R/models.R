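#' Classifier configuration
#'
#' Architecture defaults follow the reference configuration: the 3D-CNN
#' uses C3D-lineage widths, 50% dropout and learning rate 3e-5; the CRNN
#' uses three 2D convolution blocks, two LSTM layers, five fully connected
#' layers, 20% dropout and learning rate 1e-4. All widths are configurable;
#' desk-scale tests use `conv_widths = c(8, 16, 32, 32, 64)`,
#' `input_side = 32` and `w = 10`.
#'
#' @param arch `"cnn3d"` or `"crnn"`.
#' @param w temporal half-window of the grouped images (default 40 for the
#'   3D-CNN, 10 for the CRNN).
#' @param conv_widths filter counts per convolution block.
#' @param fc_widths fully-connected layer sizes (last must be 3).
#' @param dropout dropout rate; arch default when `NULL`.
#' @param learning_rate optimizer step size; arch default when `NULL`.
#' @param seed master RNG seed for weight init, sampling and augmentation.
#' @param input_side spatial side of the input frames (default 128).
#' @param lstm_units hidden units per LSTM layer (CRNN only).
#' @return validated configuration list.
#' @export
model_config <- function(arch = c("cnn3d", "crnn"), w = NULL,
                         conv_widths = NULL, fc_widths = NULL,
                         dropout = NULL, learning_rate = NULL, seed = 1L,
                         input_side = 128L, lstm_units = 128L) {
  arch <- match.arg(arch)
  defs <- if (arch == "cnn3d") {
    list(w = 40L, conv_widths = c(64L, 128L, 256L, 256L, 512L),
         fc_widths = c(512L, 256L, 3L), dropout = 0.50,
         learning_rate = 3e-5)
  } else {
    list(w = 10L, conv_widths = c(32L, 64L, 128L),
         fc_widths = c(256L, 128L, 64L, 32L, 3L), dropout = 0.20,
         learning_rate = 1e-4)
  }
  cfg <- list(arch = arch,
              w = as.integer(w %||% defs$w),
              conv_widths = as.integer(conv_widths %||% defs$conv_widths),
              fc_widths = as.integer(fc_widths %||% defs$fc_widths),
              dropout = dropout %||% defs$dropout,
              learning_rate = learning_rate %||% defs$learning_rate,
              seed = as.integer(seed),
              input_side = as.integer(input_side),
              lstm_units = as.integer(lstm_units))
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$w < 1L) stop("w must be a positive integer")
  if (utils::tail(cfg$fc_widths, 1L) != 3L)
    stop("the final fully-connected layer must have 3 units")
  cfg
}

#' Per-epoch class-balanced sampling plan
#'
#' Each epoch draws a fixed number of grouped images per class, with
#' replacement (defaults 1000 not-grooming / 200 facial / 400 body,
#' batch size 8).
#'
#' @param n_not,n_face,n_body samples per class per epoch.
#' @param batch_size minibatch size.
#' @return validated plan list.
#' @export
epoch_plan <- function(n_not = 1000L, n_face = 200L, n_body = 400L,
                       batch_size = 8L) {
  p <- list(n_not = as.integer(n_not), n_face = as.integer(n_face),
            n_body = as.integer(n_body), batch_size = as.integer(batch_size))
  if (any(unlist(p) < 1L)) stop("all plan counts must be positive")
  p
}

#' Draw one epoch's sample indices
#'
#' Samples exactly `n_not + n_face + n_body` pool indices with replacement,
#' with per-class tallies equal to the plan, in shuffled order.
#'
#' @param labels integer vector of pool labels (0/1/2), one per available
#'   grouped image.
#' @param plan an [epoch_plan()].
#' @return integer vector of 1-based indices into the pool.
#' @export
sample_epoch <- function(labels, plan = epoch_plan()) {
  counts <- c(plan$n_not, plan$n_face, plan$n_body)
  idx <- unlist(lapply(0:2, function(k) {
    pool <- which(labels == k)
    if (length(pool) == 0L)
      stop("cannot sample epoch: class ", k, " (",
           c("not grooming", "facial grooming", "body grooming")[k + 1L],
           ") is absent from the training pool")
    pool[sample.int(length(pool), counts[k + 1L], replace = TRUE)]
  }))
  idx[sample.int(length(idx))]
}

#' Random rotation/flip augmentation of a grouped image
#'
#' One rotation by a multiple of 20 degrees plus independent horizontal and
#' vertical flips, applied identically to every frame of the stack.
#' Nearest-neighbor resampling (re-thresholded at 0.5) keeps the stack
#' binary.
#'
#' @param gi `depth x S x S` binary array (temporal axis first).
#' @param k rotation step in `0:17` (angle `k * 20` degrees); random when
#'   `NULL`.
#' @param flip_h,flip_v flips; random when `NULL`.
#' @return augmented array of identical dimensions.
#' @export
augment <- function(gi, k = NULL, flip_h = NULL, flip_v = NULL) {
  d <- dim(gi)
  S <- d[2]
  stopifnot(length(d) == 3L, d[2] == d[3])
  k <- k %||% sample(0:17, 1L) - 0L
  flip_h <- flip_h %||% (stats::runif(1) < 0.5)
  flip_v <- flip_v %||% (stats::runif(1) < 0.5)
  m <- matrix(gi, d[1], S * S)
  if (k %% 18L != 0L) {
    theta <- k * 20 * pi / 180
    ctr <- (S - 1) / 2
    tgt_r <- rep(seq_len(S) - 1 - ctr, times = S)
    tgt_c <- rep(seq_len(S) - 1 - ctr, each = S)
    src_r <- round(cos(theta) * tgt_r + sin(theta) * tgt_c + ctr)
    src_c <- round(-sin(theta) * tgt_r + cos(theta) * tgt_c + ctr)
    ok <- src_r >= 0 & src_r < S & src_c >= 0 & src_c < S
    map <- ifelse(ok, 1 + src_r + S * src_c, NA_integer_)
    m2 <- matrix(0, d[1], S * S)
    m2[, ok] <- m[, map[ok]]
    m <- (m2 >= 0.5) + 0
  }
  out <- array(m, d)
  if (flip_h) out <- out[, , S:1, drop = FALSE]
  if (flip_v) out <- out[, S:1, , drop = FALSE]
  out
}

shape_after_blocks <- function(depth, side, pools) {
  for (p in pools) {
    depth <- depth %/% p[1]
    side <- side %/% p[2]
    if (depth < 1L || side < 1L)
      stop("input too small for the pooling schedule: increase input_side/w")
    }
  c(depth, side)
}

#' Build the 3D convolutional classifier
#'
#' Five convolution blocks (blocks 3-5 carry two convolution layers), each
#' followed by max pooling -- temporal pooling `(1,2,2)` in block 1 and
#' `(2,2,2)` thereafter -- and dropout; then flatten and three fully
#' connected layers with dropout between the first and second. Hidden
#' activations are ReLU; the 3-unit head is softmax.
#'
#' @param config a [model_config()] with `arch = "cnn3d"`.
#' @return untrained model object (list with `layers`, `config`,
#'   `input_shape`, `output_shape`, `n_params`).
#' @export
build_cnn3d <- function(config = model_config("cnn3d")) {
  stopifnot(config$arch == "cnn3d")
  if (length(config$conv_widths) != 5L)
    stop("cnn3d expects 5 convolution block widths")
  if (length(config$fc_widths) != 3L)
    stop("cnn3d expects 3 fully-connected widths")
  set.seed(config$seed)
  depth <- 2L * config$w + 1L
  S <- config$input_side
  pools <- list(c(1L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 2L),
                c(2L, 2L, 2L), c(2L, 2L, 2L))
  fin <- shape_after_blocks(depth, S, pools)
  nconv <- c(1L, 1L, 2L, 2L, 2L)
  layers <- list()
  in_ch <- 1L
  for (bk in 1:5) {
    for (j in seq_len(nconv[bk])) {
      layers <- c(layers, list(layer_conv3d(in_ch, config$conv_widths[bk])),
                  list(layer_relu()))
      in_ch <- config$conv_widths[bk]
    }
    layers <- c(layers, list(layer_pool3d(pools[[bk]])),
                list(layer_dropout(config$dropout)))
  }
  nflat <- fin[1] * fin[2]^2 * in_ch
  layers <- c(layers, list(layer_flatten()),
              list(layer_dense(nflat, config$fc_widths[1])),
              list(layer_relu()),
              list(layer_dropout(config$dropout)),
              list(layer_dense(config$fc_widths[1], config$fc_widths[2])),
              list(layer_relu()),
              list(layer_dense(config$fc_widths[2], 3L, final = TRUE)))
  new_model(layers, config, depth, S)
}

#' Build the convolutional-recurrent classifier
#'
#' Three 2D convolution blocks applied frame-wise across the temporal axis
#' (realized as 3D convolutions with a `(1,3,3)` kernel and `(1,2,2)`
#' pooling), per-frame flattening, two LSTM layers, and five fully
#' connected layers on the final timestep; 20% dropout after each pooling,
#' recurrent and hidden dense layer.
#'
#' @param config a [model_config()] with `arch = "crnn"`.
#' @return untrained model object.
#' @export
build_crnn <- function(config = model_config("crnn")) {
  stopifnot(config$arch == "crnn")
  if (length(config$conv_widths) != 3L)
    stop("crnn expects 3 convolution block widths")
  if (length(config$fc_widths) != 5L)
    stop("crnn expects 5 fully-connected widths")
  set.seed(config$seed)
  depth <- 2L * config$w + 1L
  S <- config$input_side
  pools <- rep(list(c(1L, 2L, 2L)), 3L)
  fin <- shape_after_blocks(depth, S, pools)
  layers <- list()
  in_ch <- 1L
  for (bk in 1:3) {
    layers <- c(layers,
                list(layer_conv3d(in_ch, config$conv_widths[bk],
                                  kdim = c(1L, 3L, 3L))),
                list(layer_relu()),
                list(layer_pool3d(pools[[bk]])),
                list(layer_dropout(config$dropout)))
    in_ch <- config$conv_widths[bk]
  }
  nfeat <- fin[2]^2 * in_ch
  layers <- c(layers, list(layer_time_flatten()),
              list(layer_lstm(nfeat, config$lstm_units)),
              list(layer_dropout(config$dropout)),
              list(layer_lstm(config$lstm_units, config$lstm_units)),
              list(layer_dropout(config$dropout)),
              list(layer_last_step()))
  n_in <- config$lstm_units
  nf <- length(config$fc_widths)
  for (j in seq_len(nf)) {
    final <- j == nf
    layers <- c(layers, list(layer_dense(n_in, config$fc_widths[j],
                                         final = final)))
    if (!final)
      layers <- c(layers, list(layer_relu()),
                  list(layer_dropout(config$dropout)))
    n_in <- config$fc_widths[j]
  }
  new_model(layers, config, depth, S)
}

new_model <- function(layers, config, depth, S) {
  n_params <- sum(vapply(layers, function(l) {
    sum(vapply(intersect(PARAM_NAMES, names(l)),
               function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
  structure(list(layers = layers, config = config,
                 input_shape = c(depth, S, S, 1L),
                 output_shape = 3L,
                 n_params = n_params,
                 loss_history = numeric(0)),
            class = "groom_model")
}

#' @export
print.groom_model <- function(x, ...) {
  cat("<groom_model>", x$config$arch, "\n",
      " input ", paste(x$input_shape, collapse = "x"),
      " -> softmax(3); ", format(x$n_params, big.mark = ","),
      " parameters; ", length(x$loss_history), " epochs trained\n", sep = "")
  invisible(x)
}
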