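#' Frame-level confusion matrix
#'
#' Rows are the human (ground-truth) label, columns the predicted label,
#' both in the order body, face, not-grooming -- the layout used by the
#' published benchmark matrices bundled with the package.
#'
#' @param truth,pred label tracks of equal length.
#' @return 3x3 integer matrix of class `confusion3` with dimnames
#'   `truth`/`pred` in order `body, face, not`.
#' @export
confusion <- function(truth, pred) {
  t <- as_label_values(truth)
  p <- as_label_values(pred)
  if (length(t) != length(p))
    stop("truth and prediction tracks differ in length (",
         length(t), " vs ", length(p), ")")
  # label 2 (body) -> row 1, 1 (face) -> row 2, 0 (not) -> row 3
  idx <- function(v) 3L - v
  m <- matrix(0L, 3L, 3L,
              dimnames = list(truth = c("body", "face", "not"),
                              pred = c("body", "face", "not")))
  tab <- table(factor(idx(t), levels = 1:3), factor(idx(p), levels = 1:3))
  m[] <- as.integer(tab)
  class(m) <- c("confusion3", class(m))
  m
}

as_confusion3 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L)) || any(m < 0))
    stop("a confusion matrix must be 3x3 with nonnegative counts")
  m
}

cls_index <- function(cls) {
  if (is.character(cls)) {
    i <- match(cls, c("body", "face", "not"))
    if (is.na(i)) stop("unknown class name: ", cls)
    return(i)
  }
  if (!cls %in% 0:2) stop("class must be 0, 1, 2 or a class name")
  3L - as.integer(cls) # numeric label convention
}

undefined_metric <- function(msg) {
  stop(structure(class = c("ethogroom_undefined_metric", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Per-class and overall metrics from a confusion matrix
#'
#' `sensitivity` (recall) and `ppr` (positive predictive rate, precision)
#' are returned as percentages, `accuracy` as a percentage, and `macro_f1`
#' as a fraction: the unweighted mean over all three classes of the harmonic
#' mean of sensitivity and PPR (a per-class F1 is 0 when its denominator
#' is 0).
#'
#' @param m a 3x3 confusion matrix (rows truth, columns prediction, order
#'   body/face/not).
#' @param cls class selector: `"body"`, `"face"`, `"not"`, or the numeric
#'   label 2/1/0.
#' @return a single number.
#' @export
sensitivity <- function(m, cls) {
  m <- as_confusion3(m)
  i <- cls_index(cls)
  rs <- sum(m[i, ])
  if (rs == 0) undefined_metric("sensitivity undefined: class absent from truth")
  100 * m[i, i] / rs
}

#' @rdname sensitivity
#' @export
ppr <- function(m, cls) {
  m <- as_confusion3(m)
  i <- cls_index(cls)
  cs <- sum(m[, i])
  if (cs == 0) undefined_metric("PPR undefined: class never predicted")
  100 * m[i, i] / cs
}

#' @rdname sensitivity
#' @export
accuracy <- function(m) {
  m <- as_confusion3(m)
  tot <- sum(m)
  if (tot == 0) undefined_metric("accuracy undefined: empty confusion matrix")
  100 * sum(diag(m)) / tot
}

#' @rdname sensitivity
#' @export
macro_f1 <- function(m) {
  m <- as_confusion3(m)
  if (any(rowSums(m) == 0))
    undefined_metric("macro F1 undefined: a class is absent from truth")
  f1 <- vapply(1:3, function(i) {
    sens <- m[i, i] / sum(m[i, ])
    cs <- sum(m[, i])
    prec <- if (cs == 0) 0 else m[i, i] / cs
    if (sens + prec == 0) 0 else 2 * sens * prec / (sens + prec)
  }, numeric(1))
  mean(f1)
}

#' Pearson correlation between per-video bout counts
#'
#' @param truth_counts,pred_counts numeric vectors, one entry per video,
#'   of grooming-bout counts (for one class) from human annotation and from
#'   prediction.
#' @return Pearson product-moment correlation coefficient.
#' @export
bout_correlation <- function(truth_counts, pred_counts) {
  if (length(truth_counts) != length(pred_counts))
    stop("count vectors differ in length")
  if (length(truth_counts) < 3L)
    stop("bout correlation needs at least 3 videos")
  if (stats::sd(truth_counts) == 0 || stats::sd(pred_counts) == 0)
    undefined_metric("bout correlation undefined: zero variance in counts")
  stats::cor(truth_counts, pred_counts)
}

#' Count bouts of one grooming class in a track
#' @param track a label track.
#' @param cls grooming class, 1 (facial) or 2 (body).
#' @export
count_bouts <- function(track, cls) {
  b <- extract_bouts(track)
  sum(b$cls == cls)
}

#' Classify discrepant frames into boundary / oversight / false-detection
#'
#' A discrepant frame is one where truth and prediction differ. A truth bout
#' whose frames have no overlap with predicted grooming (of any class)
#' contributes all its frames as `oversight`; a predicted bout with no
#' overlap with true grooming contributes all its frames as
#' `false_detection`; every remaining discrepant frame is a `boundary`
#' error. The three counts partition the discrepant frames exactly.
#'
#' @param truth,pred label tracks of equal length.
#' @return list with integer counts `boundary`, `oversight`,
#'   `false_detection` and `total_discrepant`.
#' @export
classify_errors <- function(truth, pred) {
  t <- as_label_values(truth)
  p <- as_label_values(pred)
  if (length(t) != length(p)) stop("tracks differ in length")
  disc <- t != p
  oversight <- 0L
  falsedet <- 0L
  tb <- extract_bouts(t)
  for (i in seq_len(nrow(tb))) {
    fr <- (tb$start[i] + 1L):tb$end[i]
    if (all(p[fr] == 0L)) oversight <- oversight + length(fr)
  }
  pb <- extract_bouts(p)
  for (i in seq_len(nrow(pb))) {
    fr <- (pb$start[i] + 1L):pb$end[i]
    if (all(t[fr] == 0L)) falsedet <- falsedet + length(fr)
  }
  total <- sum(disc)
  list(boundary = total - oversight - falsedet,
       oversight = oversight,
       false_detection = falsedet,
       total_discrepant = total)
}

#' Published benchmark confusion matrices
#'
#' Five frame-level confusion matrices bundled as plain-text fixtures
#' (CRNN and 3D-CNN on training and validation data, and the post-filtered
#' 3D-CNN on test data). They exercise the metric engine against values
#' printed to one decimal (percentages) and three decimals (macro F1).
#'
#' @return named list of 3x3 matrices (rows truth, cols prediction,
#'   order body/face/not).
#' @export
benchmark_confusions <- function() {
  dir <- system.file("extdata", "benchmarks", package = "ethogroom")
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  out <- lapply(files, function(f) {
    d <- as.matrix(utils::read.csv(f, row.names = 1L))
    dimnames(d) <- list(truth = c("body", "face", "not"),
                        pred = c("body", "face", "not"))
    d
  })
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Full evaluation report for a truth/prediction pair
#'
#' @param truth,pred label tracks of equal length.
#' @return list: `confusion`, per-class `sensitivity` and `ppr` (percent),
#'   `accuracy` (percent), `macro_f1` (fraction), per-class bout counts, and
#'   the error breakdown from [classify_errors()].
#' @export
evaluation_report <- function(truth, pred) {
  m <- confusion(truth, pred)
  per_cls <- function(f) vapply(c("body", "face", "not"), function(cl)
    tryCatch(f(m, cl), ethogroom_undefined_metric = function(e) NA_real_),
    numeric(1))
  list(confusion = m,
       sensitivity = per_cls(sensitivity),
       ppr = per_cls(ppr),
       accuracy = accuracy(m),
       macro_f1 = tryCatch(macro_f1(m),
                           ethogroom_undefined_metric = function(e) NA_real_),
       bouts_truth = c(face = count_bouts(truth, 1L),
                       body = count_bouts(truth, 2L)),
       bouts_pred = c(face = count_bouts(pred, 1L),
                      body = count_bouts(pred, 2L)),
       errors = classify_errors(truth, pred))
}
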