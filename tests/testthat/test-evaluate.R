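test_that("confusion matches the brute-force tally", {
  t1 <- label_track(c(1, 1, 0))
  expect_equal(unname(diag(confusion(t1, t1))), c(0L, 2L, 1L))

  m <- confusion(label_track(1), label_track(2))
  expect_equal(sum(m), 1L)
  expect_equal(m["face", "body"], 1L)

  set.seed(61)
  for (i in 1:10) {
    a <- sample(0:2, 500, replace = TRUE)
    b <- sample(0:2, 500, replace = TRUE)
    m <- confusion(a, b)
    # independent tally: count each (truth, pred) pair by subscript scan
    idx <- c("2" = 1L, "1" = 2L, "0" = 3L) # body, face, not
    o <- matrix(0L, 3, 3)
    for (k in seq_along(a))
      o[idx[as.character(a[k])], idx[as.character(b[k])]] <-
        o[idx[as.character(a[k])], idx[as.character(b[k])]] + 1L
    expect_equal(unname(unclass(m)), o, ignore_attr = TRUE)
  }
  expect_error(confusion(c(0, 1), c(0, 1, 2)), "length")
})

test_that("per-class metrics reproduce the published values", {
  bm <- benchmark_confusions()
  m <- bm$cnn3d_validation
  expect_equal(round(sensitivity(m, "body"), 1), 87.2)
  expect_equal(round(sensitivity(m, "face"), 1), 78.6)
  expect_equal(round(ppr(m, "body"), 1), 90.2)
  expect_equal(round(ppr(m, "face"), 1), 89.2)
  expect_equal(round(accuracy(m), 1), 97.7)
  expect_equal(round(macro_f1(m), 3), 0.904)

  # numeric class selectors follow the 0/1/2 label convention
  expect_equal(sensitivity(m, 2), sensitivity(m, "body"))
  expect_equal(ppr(m, 1), ppr(m, "face"))

  perfect <- diag(c(10L, 20L, 30L))
  expect_equal(sensitivity(perfect, "body"), 100)
  expect_equal(ppr(perfect, "face"), 100)
  expect_equal(accuracy(perfect), 100)
  expect_equal(macro_f1(perfect), 1.0)
})

test_that("metrics signal undefined cases", {
  m <- matrix(c(0L, 0L, 0L, 0L, 5L, 0L, 0L, 0L, 5L), 3, byrow = TRUE)
  expect_error(sensitivity(m, "body"), class = "ethogroom_undefined_metric")
  expect_error(ppr(m, "body"), class = "ethogroom_undefined_metric")
  expect_error(macro_f1(m), class = "ethogroom_undefined_metric")
})

test_that("accuracy and macro F1 are invariant under class permutation", {
  set.seed(71)
  m <- matrix(sample(1:100, 9), 3, 3)
  for (p in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(accuracy(m[p, p]), accuracy(m))
    expect_equal(macro_f1(m[p, p]), macro_f1(m))
  }
})

test_that("bout correlation matches the textbook formula", {
  expect_equal(bout_correlation(c(1, 2, 3, 5), c(1, 2, 3, 5)), 1.0)
  expect_equal(bout_correlation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  set.seed(81)
  for (i in 1:10) {
    a <- rpois(10, 6)
    b <- a + rpois(10, 2)
    if (sd(a) == 0 || sd(b) == 0) next
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(bout_correlation(a, b), num / den, tolerance = 1e-12)
  }
  expect_error(bout_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(bout_correlation(c(2, 2, 2), c(1, 2, 3)),
               class = "ethogroom_undefined_metric")
})

test_that("classify_errors partitions discrepant frames", {
  t1 <- random_truth_track(3)
  r <- classify_errors(t1, t1)
  expect_equal(unlist(r), c(boundary = 0L, oversight = 0L,
                            false_detection = 0L, total_discrepant = 0L))

  # same-class boundary shift: truth [10,20), pred [12,22)
  n <- 40
  truth <- rep(0L, n); truth[11:20] <- 1L
  pred <- rep(0L, n); pred[13:22] <- 1L
  r <- classify_errors(truth, pred)
  expect_equal(r$boundary, 4L)
  expect_equal(r$oversight, 0L)
  expect_equal(r$false_detection, 0L)

  # missed bout entirely -> oversight
  r <- classify_errors(truth, rep(0L, n))
  expect_equal(r$oversight, 10L)
  expect_equal(r$boundary, 0L)

  # hallucinated bout -> false detection
  r <- classify_errors(rep(0L, n), pred)
  expect_equal(r$false_detection, 10L)

  set.seed(91)
  for (i in 1:25) {
    a <- sample(0:2, 150, replace = TRUE, prob = c(0.6, 0.2, 0.2))
    b <- sample(0:2, 150, replace = TRUE, prob = c(0.6, 0.2, 0.2))
    r <- classify_errors(a, b)
    expect_equal(r$boundary + r$oversight + r$false_detection,
                 sum(a != b))
    expect_true(all(unlist(r) >= 0))
  }
})

test_that("evaluation_report aggregates everything", {
  truth <- random_truth_track(4)
  rep <- evaluation_report(truth, truth)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$macro_f1, 1.0)
  expect_equal(rep$bouts_truth, rep$bouts_pred)
  expect_equal(rep$errors$total_discrepant, 0L)
})
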