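test_that("extract_frames preserves order, count and metadata", {
  frames <- lapply(1:3, function(i) matrix(i * 10, 8, 8))
  fs <- extract_frames(frames, fps = 60)
  expect_length(fs, 3L)
  expect_equal(fs[[2]][1, 1], 20)

  fs60 <- extract_frames(lapply(1:60, function(i) matrix(0, 4, 4)), fps = 60)
  expect_equal(length(fs60) / attr(fs60, "fps"), 1.0) # 1 second of video

  expect_error(extract_frames(list()), "empty video")
  d <- withr::local_tempdir()
  expect_error(extract_frames(d), "empty video")
  expect_error(extract_frames(file.path(d, "missing")), "not a readable")
})

test_that("PGM round-trip via a frame directory", {
  d <- withr::local_tempdir()
  set.seed(5)
  imgs <- lapply(1:4, function(i) matrix(sample(0:255, 48, TRUE), 6, 8))
  for (i in 1:4)
    write_pgm(imgs[[i]], file.path(d, sprintf("f%02d.pgm", i)),
              ascii = i %% 2 == 0)
  fs <- extract_frames(d)
  expect_length(fs, 4L)
  for (i in 1:4) expect_equal(fs[[i]], imgs[[i]])
})

test_that("abs_diff is elementwise absolute difference", {
  a <- matrix(10, 4, 4)
  expect_equal(abs_diff(a, a), matrix(0, 4, 4))
  b <- matrix(50, 4, 4)
  expect_true(all(abs_diff(a, b) == 40))
  set.seed(101)
  x <- matrix(sample(0:255, 16), 4)
  y <- matrix(sample(0:255, 16), 4)
  o <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) o[i, j] <- abs(x[i, j] - y[i, j])
  expect_equal(abs_diff(x, y), o)
  expect_error(abs_diff(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("mouse_centroid finds the largest connected component", {
  cfg <- preprocess_config(centroid_threshold = 100)
  img <- matrix(0, 64, 64)
  img[31, 41] <- 200 # 0-based (30, 40)
  expect_equal(mouse_centroid(img, cfg), c(30, 40))

  img <- matrix(0, 64, 64)
  img[21:30, 21:30] <- 200 # corners (20,20)-(29,29)
  expect_equal(mouse_centroid(img, cfg), c(24.5, 24.5))

  # two blobs: the larger (120 px) wins over the smaller (50 px)
  img <- matrix(0, 64, 64)
  img[2:11, 2:6] <- 200      # 50 px at rows 1-10, cols 1-5 (0-based)
  img[41:50, 31:42] <- 200   # 120 px at 0-based rows 40-49, cols 30-41
  expect_equal(mouse_centroid(img, cfg), c(44.5, 35.5))

  expect_error(mouse_centroid(matrix(0, 8, 8), cfg),
               class = "ethogroom_centroid_error")

  # dark-polarity segmentation
  cfgd <- preprocess_config(centroid_threshold = 50,
                            foreground_polarity = "dark")
  img <- matrix(255, 32, 32)
  img[11, 11] <- 0
  expect_equal(mouse_centroid(img, cfgd), c(10, 10))
})

test_that("crop_square windows and zero-pads correctly", {
  set.seed(111)
  img <- matrix(sample(0:255, 100 * 100, TRUE), 100, 100)
  mid <- crop_square(img, c(49, 49), 10)
  expect_equal(mid, img[45:54, 45:54]) # window origin = 49 - 5 (0-based 44)

  tl <- crop_square(img, c(0, 0), 64)
  expect_equal(dim(tl), c(64L, 64L))
  expect_true(all(tl[1:32, 1:32] == 0))        # out of bounds -> zero
  expect_equal(tl[33:64, 33:64], img[1:32, 1:32]) # image corner content

  # brute-force loop oracle on random centers
  for (rep in 1:10) {
    cen <- c(sample(-5:104, 1), sample(-5:104, 1))
    side <- sample(3:20, 1)
    got <- crop_square(img, cen, side)
    o <- matrix(0, side, side)
    r0 <- round(cen[1]) - side %/% 2
    c0 <- round(cen[2]) - side %/% 2
    for (i in seq_len(side)) for (j in seq_len(side)) {
      sr <- r0 + i; sc <- c0 + j # 1-based source
      if (sr >= 1 && sr <= 100 && sc >= 1 && sc <= 100)
        o[i, j] <- img[sr, sc]
    }
    expect_equal(got, o)
  }
})

test_that("binarization is idempotent and thresholds correctly", {
  eg <- asNamespace("ethogroom")
  x <- matrix(runif(64, 0, 255), 8)
  b1 <- eg$binarize(x, 20)
  expect_true(all(b1 %in% c(0, 1)))
  expect_equal(eg$binarize(b1 * 255, 20), b1)
})

test_that("preprocess_video: length, statics, and a moving dot", {
  cfg <- preprocess_config(crop_side = 32, out_side = 16,
                           centroid_threshold = 100)
  base <- matrix(0, 64, 64)
  base[30:34, 30:34] <- 200
  static <- extract_frames(replicate(5, base, simplify = FALSE))
  st <- preprocess_video(static, cfg)
  expect_equal(dim(st)[3], 4L) # T - 1
  expect_true(all(st == 0))

  frames61 <- extract_frames(replicate(61, base, simplify = FALSE))
  expect_equal(dim(preprocess_video(frames61, cfg))[3], 60L)

  # a single moving dot yields exactly two changed pixels per raw diff
  mk <- function(p) { m <- matrix(0, 64, 64); m[p, 40] <- 255; m[5:9, 5:9] <- 200; m }
  fr <- lapply(10:14, mk)
  for (t in 2:5) {
    d <- abs_diff(fr[[t - 1]], fr[[t]])
    expect_equal(sum(d > 0), 2L)
  }
})

test_that("centroid fallback uses the previous frame", {
  cfg <- preprocess_config(crop_side = 16, out_side = 16,
                           centroid_threshold = 100)
  good <- matrix(0, 32, 32); good[11:14, 11:14] <- 200
  blank <- matrix(0, 32, 32)
  st <- preprocess_video(extract_frames(list(good, good, blank)), cfg)
  expect_equal(dim(st)[3], 2L)
  # all-blank start: no centroid anywhere before the first diff
  expect_error(preprocess_video(extract_frames(list(blank, blank)), cfg),
               "first frame")
})

test_that("color frames are diffed channel-wise then grayscaled", {
  cfg <- preprocess_config(crop_side = 8, out_side = 8,
                           centroid_threshold = 100)
  f1 <- array(0, c(16, 16, 3)); f1[8:10, 8:10, ] <- 200
  f2 <- f1
  f2[8, 8, 1] <- 0 # red channel drop of 200 -> luma diff 0.299 * 200 ~ 60
  st <- preprocess_video(extract_frames(list(f1, f2)), cfg)
  expect_equal(sum(st), 1)
})

test_that("grouped windows: counts, depth, labels, laziness", {
  S <- 8
  T_ <- 100
  stack <- array(round(runif(S * S * T_)), c(S, S, T_))
  labs <- rep(0:2, length.out = T_)
  for (w in c(10L, 20L, 30L, 40L)) {
    g <- make_grouped(stack, labs, w)
    expect_length(g$t, T_ - 2L * w)
    expect_equal(g$depth, 2L * w + 1L)
    expect_equal(range(g$t), c(w, T_ - 1L - w))
    gi <- grouped_image(g, 1L)
    expect_equal(dim(gi), c(2L * w + 1L, S, S))
  }
  g <- make_grouped(stack, labs, 10L)
  # label of the window at center t is the stack label at t (0-based)
  expect_equal(g$labels, labs[g$t + 1L])
  # window content is the sub-stack around t, temporal axis first
  gi <- grouped_image(g, 3L)
  t0 <- g$t[3]
  expect_equal(gi[1, , ], stack[, , t0 - 10 + 1])
  expect_equal(gi[21, , ], stack[, , t0 + 10 + 1])
  expect_warning(make_grouped(stack[, , 1:15], labs[1:15], 10L),
                 "no grouped images")
})

test_that("translated scenes give translated centroids, same crop", {
  cfg <- preprocess_config(crop_side = 24, out_side = 24,
                           centroid_threshold = 100)
  img <- matrix(0, 80, 80)
  img[30:40, 30:38] <- 200
  c1 <- mouse_centroid(img, cfg)
  for (d in list(c(5, 0), c(0, 7), c(-3, 4))) {
    sh <- matrix(0, 80, 80)
    sh[30:40 + d[1], 30:38 + d[2]] <- 200
    c2 <- mouse_centroid(sh, cfg)
    expect_equal(c2 - c1, as.numeric(d), tolerance = 0.5)
    expect_equal(crop_square(sh, c2, 24), crop_square(img, c1, 24))
  }
})

test_that("diff stacks persist with metadata", {
  cfg <- tiny_prep_config()
  base <- matrix(0, 70, 70); base[30:40, 30:40] <- 200
  mv <- lapply(0:4, function(i) {
    m <- matrix(0, 70, 70); m[(30:40) + i, 30:40] <- 200; m
  })
  st <- preprocess_video(extract_frames(mv), cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  write_diff_stack(st, f)
  back <- read_diff_stack(f)
  expect_equal(unclass(back)[seq_along(back)], unclass(st)[seq_along(st)])
  expect_equal(attr(back, "config"), cfg)
  expect_equal(attr(back, "fps"), 60)
})
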