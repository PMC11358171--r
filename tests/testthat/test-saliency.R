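cfg16 <- saliency_config()

test_that("channel decomposition behaves on degenerate inputs", {
  gray_patch <- array(0.5, dim = c(16, 16, 3))
  ch <- decompose_channels(gray_patch, NULL, cfg16)
  expect_named(ch, saliency_channels())
  expect_equal(max(abs(ch$orientation)), 0, tolerance = 1e-10)
  expect_equal(max(abs(ch$texture)), 0, tolerance = 1e-10)
  expect_equal(sd(ch$red_green), 0)
  expect_equal(sd(ch$yellow_blue), 0)
  expect_true(all(ch$flow_mag == 0))  # first frame: no motion estimate

  p <- rand_patch(16, seed = 2)
  ch2 <- decompose_channels(p, p, cfg16)
  expect_equal(max(ch2$flow_mag), 0, tolerance = 1e-8)  # static scene
  expect_true(all(vapply(ch2, function(m) all(is.finite(m)), logical(1))))
  expect_error(decompose_channels(p, rand_patch(12, 1), cfg16), "shape")
})

test_that("flow magnitude recovers a one-pixel shift of a blob", {
  side <- 24
  prev <- blob_image(side, 10, 12, sd = 2.5)
  cur <- blob_image(side, 11, 12, sd = 2.5)  # shifted 1 px in x
  # independent oracle: exhaustive integer block matching
  expect_equal(naive_best_shift(prev, cur), c(1, 0))
  mk <- function(m) {
    a <- array(0.5, dim = c(side, side, 3))
    for (ch in 1:3) a[, , ch] <- 0.5 + 0.4 * m
    a
  }
  ch <- decompose_channels(mk(cur), mk(prev), cfg16)
  core <- blob_image(side, 11, 12, sd = 2.5) > 0.4
  expect_equal(mean(ch$flow_mag[core]), 1, tolerance = 0.3)
})

test_that("pyramids have ceiling-halved levels and match the blur oracle", {
  p75 <- matrix(runif(75 * 75), 75, 75)
  pyr <- build_pyramid(p75)
  expect_length(pyr, 4L)
  expect_equal(vapply(pyr, nrow, integer(1)), c(75L, 38L, 19L, 10L))

  cm <- matrix(2.5, 16, 16)
  expect_true(all(vapply(build_pyramid(cm),
                         function(m) all(abs(m - 2.5) < 1e-12),
                         logical(1))))

  # impulse image: each level equals naive blur + decimation
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  pyr2 <- build_pyramid(imp, blur_sigma = 1)
  g <- gaussian_kernel(1)
  ref <- imp
  for (l in 2:4) {
    ref <- naive_conv2d(ref, g)
    ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
    expect_equal(pyr2[[l]], ref, tolerance = 1e-10)
  }
  expect_error(build_pyramid(matrix(0, 6, 6)), "too small")
})

test_that("center-surround activation matches five naive passes", {
  set.seed(5)
  m <- matrix(runif(144), 12, 12)
  got <- center_surround_activate(m, cfg16)
  ref <- naive_activation(m, cfg16)
  expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-8)

  # constant maps die on the first LoG pass
  expect_equal(max(abs(center_surround_activate(matrix(1, 10, 10), cfg16))),
               0, tolerance = 1e-12)

  # a bright blob on dark ground peaks at the blob center
  b <- blob_image(16, 8, 8, sd = 2)
  act <- center_surround_activate(b, cfg16)
  peak <- which(act == max(act), arr.ind = TRUE)[1, ]
  expect_true(all(abs(peak - c(9, 9)) <= 1))
})

test_that("normalization factors follow the decay-blend contract", {
  set.seed(6)
  base <- matrix(runif(100), 10, 10)
  one_stack <- lapply(c(1, 0.5), function(s) base * s)
  stacks <- setNames(rep(list(one_stack), 6), saliency_channels())

  # symmetric channels -> equal factors
  nm <- normalize_stacks(stacks, new_temporal_buffer(), cfg16)
  expect_true(all(abs(nm$factors - nm$factors[1]) < 1e-12))
  expect_false(any(nm$flagged))

  # doubling a channel's maps doubles its raw (first-frame) factor
  stacks2 <- stacks
  stacks2$texture <- lapply(stacks2$texture, function(m) 2 * m)
  nm2 <- normalize_stacks(stacks2, new_temporal_buffer(), cfg16)
  expect_equal(nm2$factors[["texture"]], 2 * nm$factors[["texture"]])
  expect_equal(nm2$factors[["luminance"]], nm$factors[["luminance"]])

  # identical consecutive frames: the blended factor is a fixed point
  buf <- salgaze:::push_buffer(new_temporal_buffer(),
                               matrix(0, 10, 10), nm$factors)
  nm_t2 <- normalize_stacks(stacks, buf, cfg16)
  expect_equal(nm_t2$factors, nm$factors)

  # all-zero channel: flagged, exported as 0, maps untouched
  stacks0 <- stacks
  stacks0$flow_mag <- lapply(stacks0$flow_mag, function(m) m * 0)
  nm0 <- normalize_stacks(stacks0, new_temporal_buffer(), cfg16)
  expect_true(nm0$flagged[["flow_mag"]])
  expect_equal(nm0$factors[["flow_mag"]], 0)
  expect_equal(nm0$stacks$flow_mag[[1]], stacks0$flow_mag[[1]])
})

test_that("fusion sums levels, applies the decaying buffer and squashes to [0, 1]", {
  zero_stack <- setNames(rep(list(list(matrix(0, 8, 8))), 6),
                         saliency_channels())
  fz <- fuse_saliency(zero_stack, new_temporal_buffer(), cfg16)
  mid <- 1 / (1 + exp(cfg16$logistic_k * cfg16$logistic_x0))
  expect_true(all(abs(fz$final_map - mid) < 1e-12))

  set.seed(7)
  rnd <- setNames(lapply(1:6, function(i) {
    lapply(1:4, function(l) matrix(runif(64, -2, 2), 8, 8))
  }), saliency_channels())
  fr <- fuse_saliency(rnd, new_temporal_buffer(), cfg16)
  expect_true(all(fr$final_map >= 0 & fr$final_map <= 1))

  # static input: frame-3 combined map is (1 + 0.5 + 0.25) x frame-1's
  buf <- new_temporal_buffer()
  f1 <- fuse_saliency(rnd, buf, cfg16)
  buf <- salgaze:::push_buffer(buf, f1$current_map, numeric(6))
  f2 <- fuse_saliency(rnd, buf, cfg16)
  buf <- salgaze:::push_buffer(buf, f2$current_map, numeric(6))
  f3 <- fuse_saliency(rnd, buf, cfg16)
  expect_equal(f3$combined_map, 1.75 * f1$combined_map, tolerance = 1e-12)

  # a transient's contribution halves on each subsequent frame
  event <- f1$current_map
  buf_e <- salgaze:::push_buffer(new_temporal_buffer(), event, numeric(6))
  after1 <- fuse_saliency(zero_stack, buf_e, cfg16)$combined_map
  buf_e2 <- salgaze:::push_buffer(buf_e, after1 * 0, numeric(6))
  after2 <- fuse_saliency(zero_stack, buf_e2, cfg16)$combined_map
  expect_equal(after1, 0.5 * event, tolerance = 1e-12)
  expect_equal(after2, 0.25 * event, tolerance = 1e-12)
  buf_e3 <- salgaze:::push_buffer(buf_e2, after2 * 0, numeric(6))
  after3 <- fuse_saliency(zero_stack, buf_e3, cfg16)$combined_map
  expect_equal(max(abs(after3)), 0, tolerance = 1e-12)
})

test_that("saliency index is the regional mean", {
  expect_equal(saliency_index(matrix(0.42, 5, 5)), 0.42)
  half <- matrix(c(rep(0, 8), rep(1, 8)), 4, 4)
  expect_equal(saliency_index(half), 0.5)
  set.seed(10)
  m <- matrix(runif(49), 7, 7)
  region <- matrix(FALSE, 7, 7); region[3:5, 2:4] <- TRUE
  # brute-force oracle: explicit sum over the nine region cells
  acc <- 0
  for (i in 3:5) for (j in 2:4) acc <- acc + m[i, j]
  expect_equal(saliency_index(m, region), acc / 9)
  expect_error(saliency_index(m, matrix(FALSE, 7, 7)), "empty")
})

test_that("sequence processing is deterministic, finite, and zero on invalid frames", {
  set.seed(11)
  pats <- array(runif(10 * 16 * 16 * 3), dim = c(10, 16, 16, 3))
  sq <- make_patch_seq(pats)
  sf <- run_saliency_sequence(sq)
  expect_equal(dim(sf$factors), c(10L, 6L))
  expect_true(all(is.finite(sf$factors)))
  expect_true(all(sf$index >= 0 & sf$index <= 1))
  expect_length(saliency_feature_row(sf), 60L)
  sf2 <- run_saliency_sequence(sq)
  expect_identical(sf$factors, sf2$factors)  # stateless across calls

  allbad <- make_patch_seq(array(0, dim = c(4, 16, 16, 3)),
                           valid = rep(FALSE, 4))
  sfb <- run_saliency_sequence(allbad)
  expect_true(all(sfb$factors == 0))
  expect_true(all(sfb$flagged))
})

test_that("a moving high-contrast blob is more salient than a static uniform patch", {
  side <- 16L
  tt <- 6L
  moving <- array(0.5, dim = c(tt, side, side, 3))
  for (t in seq_len(tt)) {
    b <- blob_image(side, 4 + t, 8, sd = 2, amp = 0.45)
    for (ch in 1:3) moving[t, , , ch] <- 0.5 + b * c(1, -1, 0.5)[ch]
  }
  idx_moving <- mean(run_saliency_sequence(make_patch_seq(moving))$index)
  static <- array(0.5, dim = c(tt, side, side, 3))
  idx_static <- mean(run_saliency_sequence(make_patch_seq(static))$index)
  expect_gt(idx_moving, idx_static)
})
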