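#' Pool grouped-image sets from several videos for training
#'
#' @param grouped_sets list of [make_grouped()] results.
#' @return list of class `grouped_pool` with a flat index (`video`, `pos`,
#'   `labels`) over every available grouped image.
#' @export
grouped_pool <- function(grouped_sets) {
  stopifnot(length(grouped_sets) > 0L)
  video <- rep(seq_along(grouped_sets),
               vapply(grouped_sets, function(g) length(g$t), integer(1)))
  pos <- unlist(lapply(grouped_sets, function(g) seq_along(g$t)))
  labels <- unlist(lapply(grouped_sets, function(g) g$labels))
  ws <- unique(vapply(grouped_sets, function(g) g$w, integer(1)))
  if (length(ws) != 1L) stop("all grouped sets must share one half-window w")
  structure(list(sets = grouped_sets, video = video, pos = pos,
                 labels = as.integer(labels), w = ws,
                 depth = 2L * ws + 1L),
            class = "grouped_pool")
}

# Materialize a batch: x (depth, S, S, 1, N) plus one-hot y (3 x N).
fetch_batch <- function(pool, ids, augment_batch = FALSE) {
  g1 <- pool$sets[[1]]
  S <- dim(g1$stack)[1]
  n <- length(ids)
  x <- array(0, c(pool$depth, S, S, 1L, n))
  y <- matrix(0, 3L, n)
  for (j in seq_len(n)) {
    gi <- grouped_image(pool$sets[[pool$video[ids[j]]]], pool$pos[ids[j]])
    if (augment_batch) gi <- augment(gi)
    x[, , , 1L, j] <- gi
    y[pool$labels[ids[j]] + 1L, j] <- 1
  }
  list(x = x, y = y)
}

#' Train a classifier
#'
#' Class-balanced epochs are drawn with replacement from the pool per the
#' plan, rotated/flipped for augmentation, and optimized with AMSGrad on
#' the categorical cross-entropy. The master seed in the model config fans
#' out to sampling, augmentation and dropout; a fixed seed makes the run
#' reproducible on one machine.
#'
#' @param model an untrained model from [build_cnn3d()] or [build_crnn()].
#' @param pool a [grouped_pool()] of training videos.
#' @param plan an [epoch_plan()].
#' @param epochs number of epochs (the reference configuration trains to a
#'   plateau at 3000; desk-scale runs use far fewer).
#' @param augment_data apply rotation/flip augmentation (default TRUE).
#' @param lr_schedule optional function of the epoch number returning a
#'   multiplier applied to the configured learning rate (e.g. a step decay);
#'   `NULL` keeps the rate constant.
#' @param validate_every evaluate `validate_fn(model)` every this many
#'   epochs (0 = never); results are stored in `model$validation`.
#' @param validate_fn optional function of the model returning a named
#'   numeric vector.
#' @param verbose print per-epoch loss.
#' @return the trained model with `loss_history` of length `epochs`.
#' @export
train <- function(model, pool, plan = epoch_plan(), epochs = 10L,
                  augment_data = TRUE, lr_schedule = NULL,
                  validate_every = 0L, validate_fn = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model, "groom_model"), inherits(pool, "grouped_pool"))
  if (length(pool$labels) == 0L) stop("empty training pool")
  set.seed(model$config$seed + 1L)
  state <- amsgrad_init(model)
  lr <- model$config$learning_rate
  step <- 0L
  history <- numeric(epochs)
  validation <- list()
  for (ep in seq_len(epochs)) {
    lr_ep <- if (is.null(lr_schedule)) lr else lr * lr_schedule(ep)
    ids <- sample_epoch(pool$labels, plan)
    nb <- ceiling(length(ids) / plan$batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      lo <- (bi - 1L) * plan$batch_size + 1L
      hi <- min(bi * plan$batch_size, length(ids))
      batch <- fetch_batch(pool, ids[lo:hi], augment_batch = augment_data)
      fwd <- nn_forward(model, batch$x, training = TRUE)
      ls <- softmax_xent(fwd$out, batch$y)
      if (!is.finite(ls$loss))
        stop("non-finite loss at epoch ", ep, ", batch ", bi,
             "; reduce the learning rate")
      grads <- nn_backward(model, fwd$caches, ls$dlogits)
      step <- step + 1L
      r <- amsgrad_step(model, grads, state, lr_ep, step)
      model <- r$model
      state <- r$state
      ep_loss <- ep_loss + ls$loss * (hi - lo + 1L)
    }
    history[ep] <- ep_loss / length(ids)
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, history[ep]))
    if (validate_every > 0L && !is.null(validate_fn) &&
        ep %% validate_every == 0L)
      validation[[as.character(ep)]] <- validate_fn(model)
  }
  model$loss_history <- c(model$loss_history, history)
  model$validation <- validation
  model
}

#' Predict class probabilities for grouped images
#'
#' Dropout is disabled; outputs lie on the probability simplex.
#'
#' @param model a trained model.
#' @param input a `grouped_set`, a `grouped_pool`, a list of
#'   `depth x S x S` arrays, or a single such array.
#' @param batch_size forward-pass batch size.
#' @return numeric matrix `n x 3` with columns `p0`, `p1`, `p2`
#'   (not / facial / body grooming).
#' @export
predict_probs <- function(model, input, batch_size = 64L) {
  fetch <- grouped_fetcher(model, input)
  n <- fetch$n
  out <- matrix(0, n, 3L, dimnames = list(NULL, c("p0", "p1", "p2")))
  S <- model$input_shape[2]
  depth <- model$input_shape[1]
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- array(0, c(depth, S, S, 1L, j - i + 1L))
    for (k in i:j) {
      gi <- fetch$get(k)
      if (!identical(as.integer(dim(gi)), c(depth, S, S)))
        stop("grouped image of shape ", paste(dim(gi), collapse = "x"),
             " does not match model input ",
             paste(c(depth, S, S), collapse = "x"))
      x[, , , 1L, k - i + 1L] <- gi
    }
    logits <- nn_forward(model, x, training = FALSE)$out
    # softmax over the 3 output units: row k is class k-1
    out[i:j, ] <- t(softmax_cols(logits))
    i <- j + 1L
  }
  out
}

grouped_fetcher <- function(model, input) {
  if (inherits(input, "grouped_set")) {
    list(n = length(input$t), get = function(k) grouped_image(input, k))
  } else if (inherits(input, "grouped_pool")) {
    list(n = length(input$labels),
         get = function(k) grouped_image(input$sets[[input$video[k]]],
                                         input$pos[k]))
  } else if (is.list(input)) {
    list(n = length(input), get = function(k) input[[k]])
  } else if (is.array(input) && length(dim(input)) == 3L) {
    list(n = 1L, get = function(k) input)
  } else stop("unsupported prediction input")
}

#' Hard labels from class probabilities
#'
#' Per row, the label is the index of the maximal probability; ties break
#' toward the smallest class index.
#'
#' @param probs `n x 3` probability matrix (columns = classes 0/1/2).
#' @return a [label_track()].
#' @export
argmax_labels <- function(probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 3L) stop("probability matrix must have 3 columns")
  label_track(max.col(probs, ties.method = "first") - 1L)
}

#' Write / read a prediction CSV (`frame,p0,p1,p2,label_raw`)
#' @param probs `n x 3` probability matrix.
#' @param path file path.
#' @export
write_prediction_csv <- function(probs, path) {
  lab <- as.integer(argmax_labels(probs))
  d <- data.frame(frame = seq_len(nrow(probs)) - 1L,
                  p0 = probs[, 1], p1 = probs[, 2], p2 = probs[, 3],
                  label_raw = lab)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prediction_csv
#' @export
read_prediction_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "p0", "p1", "p2", "label_raw")
  if (!all(need %in% names(d)))
    stop("prediction CSV must have columns ", paste(need, collapse = ", "))
  d
}

#' Save / load a model checkpoint (weights plus embedded config)
#' @param model a model object.
#' @param path file path (RDS container).
#' @export
write_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path, compress = "gzip")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  structure(readRDS(path), class = "groom_model")
}
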