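small_cfg <- function(seed = 1) {
  model_config("cnn3d", w = 10, conv_widths = c(2L, 2L, 3L, 3L, 4L),
               fc_widths = c(8L, 4L, 3L), input_side = 32, seed = seed)
}

test_that("model_config applies per-architecture defaults", {
  c3 <- model_config("cnn3d")
  expect_equal(c3$w, 40L)
  expect_equal(c3$dropout, 0.50)
  expect_equal(c3$learning_rate, 3e-5)
  expect_equal(c3$conv_widths, c(64L, 128L, 256L, 256L, 512L))
  cr <- model_config("crnn")
  expect_equal(cr$dropout, 0.20)
  expect_equal(cr$learning_rate, 1e-4)
  expect_length(cr$fc_widths, 5L)
  expect_error(model_config("cnn3d", dropout = 1), "dropout")
  expect_error(model_config("cnn3d", learning_rate = 0), "learning_rate")
  expect_error(model_config("cnn3d", fc_widths = c(8, 4, 2)), "3 units")
})

test_that("cnn3d builds with the right geometry", {
  # reference scale: only construction and shape metadata (a full-scale
  # forward pass is GPU-sized work)
  m <- build_cnn3d(model_config("cnn3d", w = 40, input_side = 128))
  expect_equal(m$input_shape, c(81L, 128L, 128L, 1L))
  expect_equal(m$output_shape, 3L)
  # 3 dense layers + 8 conv layers carry parameters
  expect_equal(sum(vapply(m$layers, function(l) l$type == "dense",
                          logical(1))), 3L)

  # desk scale: a real forward pass produces a probability simplex point
  ms <- build_cnn3d(small_cfg())
  expect_equal(ms$input_shape, c(21L, 32L, 32L, 1L))
  x <- array(round(runif(21 * 32 * 32 * 2)), c(21, 32, 32, 1, 2))
  p <- predict_probs(ms, list(x[, , , 1, 1], x[, , , 1, 2]))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_true(all(p >= 0))

  expect_error(build_cnn3d(model_config("cnn3d", w = 10, input_side = 16)),
               "too small")
})

test_that("cnn3d parameter count equals the layer-by-layer sum", {
  cfg <- small_cfg()
  m <- build_cnn3d(cfg)
  cw <- cfg$conv_widths
  # conv params: 27 * in * out + out, block structure (1,1,2,2,2)
  conv <- function(i, o) 27 * i * o + o
  n_conv <- conv(1, cw[1]) + conv(cw[1], cw[2]) +
    conv(cw[2], cw[3]) + conv(cw[3], cw[3]) +
    conv(cw[3], cw[4]) + conv(cw[4], cw[4]) +
    conv(cw[4], cw[5]) + conv(cw[5], cw[5])
  # after pools: depth 21 -> 21,10,5,2,1; side 32 -> 1; flatten = cw[5]
  n_fc <- (cw[5] * 8 + 8) + (8 * 4 + 4) + (4 * 3 + 3)
  expect_equal(m$n_params, n_conv + n_fc)
})

test_that("crnn builds, accepts (2w+1, S, S) input, runs deterministically", {
  cfg <- model_config("crnn", w = 10, conv_widths = c(2L, 3L, 4L),
                      fc_widths = c(8L, 8L, 6L, 4L, 3L), input_side = 32,
                      lstm_units = 6L, seed = 3)
  m <- build_crnn(cfg)
  expect_equal(m$input_shape, c(21L, 32L, 32L, 1L))
  set.seed(9)
  gi <- array(round(runif(21 * 32 * 32)), c(21, 32, 32))
  p1 <- predict_probs(m, gi)
  p2 <- predict_probs(m, gi)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, p2) # eval mode: dropout off, no RNG dependence
})

test_that("sample_epoch returns exact per-class tallies, shuffled", {
  labels <- rep(c(0L, 1L, 2L), c(500, 40, 80))
  plan <- epoch_plan() # 1000 / 200 / 400
  set.seed(121)
  idx <- sample_epoch(labels, plan)
  expect_length(idx, 1600L)
  expect_equal(unname(table(labels[idx])), c(1000L, 200L, 400L),
               ignore_attr = TRUE)

  # plan (1,1,1) on a 3-frame pool: one index of each class
  idx3 <- sample_epoch(c(0L, 1L, 2L), epoch_plan(1, 1, 1, 1))
  expect_setequal(idx3, 1:3)

  # tallies are exact for every seed
  for (s in 1:100) {
    set.seed(s)
    idx <- sample_epoch(labels, epoch_plan(13, 7, 5, 4))
    expect_equal(unname(table(factor(labels[idx], levels = 0:2))),
                 c(13L, 7L, 5L), ignore_attr = TRUE)
  }
  expect_error(sample_epoch(c(0L, 2L), epoch_plan(1, 1, 1, 1)),
               "facial grooming")
})

test_that("augmentation keeps stacks binary and flips are involutions", {
  set.seed(131)
  gi <- array(round(runif(9 * 16 * 16, 0, 0.7)), c(9, 16, 16))
  expect_identical(augment(gi, k = 0, flip_h = FALSE, flip_v = FALSE), gi)
  fh <- augment(gi, k = 0, flip_h = TRUE, flip_v = FALSE)
  expect_identical(augment(fh, k = 0, flip_h = TRUE, flip_v = FALSE), gi)
  fv <- augment(gi, k = 0, flip_h = FALSE, flip_v = TRUE)
  expect_identical(augment(fv, k = 0, flip_h = FALSE, flip_v = TRUE), gi)

  # rotation by 180 degrees equals two 90-degree rotations
  r180 <- augment(gi, k = 9, flip_h = FALSE, flip_v = FALSE)
  r90 <- function(a) {
    out <- array(0, dim(a))
    S <- dim(a)[2]
    for (d in seq_len(dim(a)[1]))
      out[d, , ] <- t(a[d, , ])[, S:1] # one quarter turn
    out
  }
  expect_equal(r180, r90(r90(gi)))

  for (k in 0:17) {
    a <- augment(gi, k = k, flip_h = FALSE, flip_v = FALSE)
    expect_true(all(a %in% c(0, 1)))
    expect_equal(dim(a), dim(gi))
  }
})

test_that("argmax_labels takes the max with ties to the lowest class", {
  expect_equal(as.integer(argmax_labels(rbind(c(0.1, 0.7, 0.2)))), 1L)
  expect_equal(as.integer(argmax_labels(rbind(c(0.4, 0.4, 0.2)))), 0L)
  expect_equal(as.integer(argmax_labels(rbind(c(0.2, 0.4, 0.4)))), 1L)
  set.seed(141)
  p <- matrix(runif(3000), ncol = 3)
  got <- as.integer(argmax_labels(p))
  want <- apply(p, 1, function(r) {
    best <- 0L
    for (k in 1:2) if (r[k + 1] > r[best + 1]) best <- k
    best
  })
  expect_equal(got, want)
})

test_that("prediction is invariant to batch partitioning", {
  m <- build_cnn3d(small_cfg(seed = 7))
  set.seed(151)
  gis <- lapply(1:5, function(i) array(round(runif(21 * 32 * 32)),
                                       c(21, 32, 32)))
  p_all <- predict_probs(m, gis, batch_size = 5)
  p_one <- do.call(rbind, lapply(gis, function(g) predict_probs(m, g)))
  expect_equal(p_all, p_one, tolerance = 1e-5)
  expect_error(predict_probs(m, array(0, c(9, 32, 32))), "does not match")
})

test_that("training runs, records finite loss, and learns a separable set", {
  # two static blob positions -> classes: small corner blob = face, large
  # central blob = body, empty = not grooming
  S <- 32
  labs <- rep(c(0L, 1L, 2L), each = 40)
  stack <- array(0, c(S, S, 120))
  stack[3:6, 3:6, 41:80] <- 1
  stack[14:22, 14:22, 81:120] <- 1
  g <- make_grouped(stack, labs, 10L)
  pool <- grouped_pool(list(g))
  cfg <- model_config("cnn3d", w = 10, conv_widths = c(4L, 8L, 8L, 8L, 16L),
                      fc_widths = c(8L, 4L, 3L), input_side = 32,
                      learning_rate = 5e-3, dropout = 0.1, seed = 11)
  m <- build_cnn3d(cfg)

  m1 <- train(m, pool, epoch_plan(4, 2, 2, 4), epochs = 1,
              augment_data = FALSE)
  expect_length(m1$loss_history, 1L)
  expect_true(is.finite(m1$loss_history))

  m30 <- train(m, pool, epoch_plan(8, 4, 4, 8), epochs = 30,
               augment_data = FALSE)
  expect_length(m30$loss_history, 30L)
  # loss at the end well below the start on this trivially separable set
  expect_lt(mean(tail(m30$loss_history, 3)), mean(head(m30$loss_history, 2)))
  # windows overlapping a class transition mix two classes and are
  # inherently ambiguous; score only windows fully inside one block
  interior <- g$t %in% c(10:29, 51:69, 91:109)
  p <- predict_probs(m30, g)
  acc <- mean(as.integer(argmax_labels(p))[interior] == g$labels[interior])
  expect_gt(acc, 0.9)
})

test_that("layer gradients match finite differences", {
  eg <- asNamespace("ethogroom")
  set.seed(161)
  # conv layers run their GEMMs in single precision: finite differences
  # need a larger step (rounding ~1e-7 of the output scale) and tolerance
  num_vs_analytic <- function(layer, x, tol = 1e-6, eps = 1e-6) {
    fw <- eg$layer_forward(layer, x)
    dy <- array(rnorm(length(fw$y)), dim(fw$y))
    bw <- eg$layer_backward(layer, fw$cache, dy)
    for (p in intersect(c("W", "b", "Wx", "Wh"), names(layer))) {
      gnum <- layer[[p]] * 0
      for (i in seq_along(gnum)) {
        e <- eps
        l1 <- layer; l1[[p]][i] <- l1[[p]][i] + e
        l2 <- layer; l2[[p]][i] <- l2[[p]][i] - e
        gnum[i] <- (sum(eg$layer_forward(l1, x)$y * dy) -
                    sum(eg$layer_forward(l2, x)$y * dy)) / (2 * e)
      }
      expect_equal(max(abs(gnum - bw$grads[[p]])), 0, tolerance = tol)
    }
    idx <- sample(length(x), min(30, length(x)))
    gx <- vapply(idx, function(i) {
      e <- eps
      x1 <- x; x1[i] <- x[i] + e
      x2 <- x; x2[i] <- x[i] - e
      (sum(eg$layer_forward(layer, x1)$y * dy) -
       sum(eg$layer_forward(layer, x2)$y * dy)) / (2 * e)
    }, numeric(1))
    expect_equal(max(abs(gx - bw$dx[idx])), 0, tolerance = tol)
  }
  x5 <- array(rnorm(4 * 5 * 5 * 2 * 2), c(4, 5, 5, 2, 2))
  num_vs_analytic(eg$layer_conv3d(2L, 3L), x5, tol = 5e-3, eps = 1e-3)
  num_vs_analytic(eg$layer_conv3d(2L, 2L, kdim = c(1L, 3L, 3L)), x5,
                  tol = 5e-3, eps = 1e-3)
  num_vs_analytic(eg$layer_pool3d(c(2L, 2L, 2L)), x5)
  num_vs_analytic(eg$layer_lstm(3L, 5L), array(rnorm(3 * 4 * 2), c(3, 4, 2)))
  num_vs_analytic(eg$layer_dense(6L, 4L), matrix(rnorm(12), 6, 2))
})

test_that("checkpoints round-trip with embedded config", {
  m <- build_cnn3d(small_cfg(seed = 5))
  f <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(m, f)
  back <- read_checkpoint(f)
  expect_equal(back$config, m$config)
  gi <- array(round(runif(21 * 32 * 32)), c(21, 32, 32))
  expect_equal(predict_probs(back, gi), predict_probs(m, gi))
})

test_that("conv3d forward equals a double-precision direct convolution", {
  eg <- asNamespace("ethogroom")
  set.seed(171)
  x <- array(rnorm(4 * 5 * 5 * 2 * 2), c(4, 5, 5, 2, 2))
  ly <- eg$layer_conv3d(2L, 3L)
  got <- eg$layer_forward(ly, x)$y
  d <- dim(x)
  D <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]; N <- d[5]
  Co <- ncol(ly$W)
  want <- array(0, c(D, H, Wd, Co, N))
  for (n in 1:N) for (co in 1:Co) {
    r <- 1
    acc <- array(0, c(D, H, Wd))
    for (c in 1:C) for (cw in -1:1) for (ch in -1:1) for (cd in -1:1) {
      w <- ly$W[r, co]; r <- r + 1
      xs <- array(0, c(D, H, Wd))
      dr <- max(1, 1 - cd):min(D, D - cd)
      hr <- max(1, 1 - ch):min(H, H - ch)
      wr <- max(1, 1 - cw):min(Wd, Wd - cw)
      xs[dr, hr, wr] <- x[dr + cd, hr + ch, wr + cw, c, n]
      acc <- acc + w * xs
    }
    want[, , , co, n] <- acc + ly$b[co]
  }
  expect_equal(got, want, tolerance = 1e-5, ignore_attr = TRUE)
})
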