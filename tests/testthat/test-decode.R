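test_that("window schemes enumerate cumulative and chunked windows", {
  w <- build_windows(400, 50)
  expect_length(w, 8L)
  expect_true(all(vapply(w, `[[`, numeric(1), "start") == 1L))
  expect_equal(vapply(w, `[[`, numeric(1), "end"), seq(50, 400, 50))

  w2 <- build_windows(40, 5)
  expect_length(w2, 8L)

  expect_equal(build_windows(400, 400), list(c(start = 1L, end = 400L)))

  ch <- build_windows(12, 4, mode = "chunked")
  expect_equal(ch, list(c(start = 1L, end = 4L), c(start = 5L, end = 8L),
                        c(start = 9L, end = 12L)))
  # truncation of a ragged tail
  expect_equal(build_windows(11, 4, "chunked")[[3]], c(start = 9L, end = 11L))
  expect_error(build_windows(10, 0), "positive")
  expect_error(build_windows(10, 11), "exceeds")
})

make_group_data <- function(n_a, n_b, n_frames, dim_pf, sep, seed) {
  set.seed(seed)
  labs <- c(rep("a", n_a), rep("b", n_b))
  mu_a <- rnorm(n_frames * dim_pf)
  mu_b <- mu_a + sep * rnorm(n_frames * dim_pf)
  x <- t(vapply(labs, function(g) {
    (if (g == "a") mu_a else mu_b) + rnorm(n_frames * dim_pf, 0, 0.5)
  }, numeric(n_frames * dim_pf)))
  list(x = unname(x), labels = labs)
}

test_that("leave-one-out decoding iterates once per participant and separates groups", {
  d <- make_group_data(11, 10, 5, 6, sep = 3, seed = 21)
  res <- loo_group_decode(d$x, d$labels, seed = 2)
  expect_s3_class(res, "loo_decode")
  expect_length(res$correct, 21L)  # 21 iterations for 11 + 10
  expect_gt(res$accuracy, 0.9)

  # duplicated features with opposite labels: symmetric and
  # non-separable. Note leave-one-out on label-balanced null data is
  # anti-learning-biased (the held-out twin pulls the fit the wrong
  # way), so the accuracy sits at or below chance rather than at 0.5.
  set.seed(22)
  base <- matrix(rnorm(6 * 30), 6, 30)
  x <- rbind(base, base)
  labs <- c(rep("a", 6), rep("b", 6))
  acc <- loo_group_decode(x, labs, seed = 3)$accuracy
  expect_lte(acc, 0.5)

  expect_error(loo_group_decode(d$x[1:3, ], c("a", "a", "b")),
               "2 participants per group")
  xb <- d$x; xb[1, 1] <- NA
  expect_error(loo_group_decode(xb, d$labels), "non-finite")
})

test_that("max-accuracy summarisation matches brute force and keeps earliest ties", {
  expect_equal(summarize_max_accuracy(c(0.5, 0.7, 0.6))$accuracy, 0.7)
  tie <- summarize_max_accuracy(rep(0.6, 5))
  expect_equal(tie$accuracy, 0.6)
  expect_equal(tie$window, 1L)
  set.seed(23)
  for (i in 1:20) {
    v <- round(runif(8), 2)
    got <- summarize_max_accuracy(v)
    # brute-force oracle over all windows
    best <- -Inf; bw <- 0
    for (j in seq_along(v)) if (v[j] > best) { best <- v[j]; bw <- j }
    expect_equal(got$accuracy, best)
    expect_equal(got$window, bw)
  }
  expect_error(summarize_max_accuracy(numeric(0)), "no window")
})

test_that("per-category chance tests use the Bonferroni-adjusted alpha", {
  acc <- rep(0.5, 12)
  cats <- rep(clip_categories(), each = 3)
  res <- test_vs_chance(acc, cats)
  expect_equal(attr(res, "alpha_adjusted"), 0.0125)
  expect_true(all(res$t == 0))
  expect_true(all(res$degenerate))
  expect_false(any(res$significant))

  # closed-form oracle for the t statistic
  set.seed(24)
  vals <- 0.6 + rnorm(9, 0, 0.01)
  res2 <- test_vs_chance(c(vals, rep(0.5, 2)),
                         c(rep("fight", 9), rep("neutral", 2)),
                         n_tests = 4)
  t_hand <- (mean(vals) - 0.5) / (sd(vals) / sqrt(9))
  expect_equal(res2$t[res2$category == "fight"], t_hand)
  expect_error(test_vs_chance(0.5, "fight"), ">= 2 clips")
})

test_that("channel permutation nulls are deterministic and self-consistent", {
  d <- make_group_data(4, 4, 6, 6, sep = 0.5, seed = 25)
  pn <- permutation_null(d$x, d$labels, n_iter = 5, seed = 9, nfolds = 3)
  expect_length(pn$null, 5L)
  expect_equal(pn$p, mean(pn$null >= pn$observed))
  if (pn$observed < median(pn$null)) expect_gt(pn$p, 0.5)
  pn2 <- permutation_null(d$x, d$labels, n_iter = 5, seed = 9, nfolds = 3)
  expect_identical(pn$null, pn2$null)
  expect_error(permutation_null(d$x, d$labels, n_iter = 0), "n_iter")
})

test_that("channel permutation relabels consistently across frames", {
  row <- as.numeric(1:12)  # 2 frames x 6 channels
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  got <- salgaze:::permute_channels(row, perm, 6L)
  expect_equal(got, c(row[perm], row[6L + perm]))
})

test_that("selection proportions identify the informative channel", {
  # signal only on channel 2, frames 1..8
  set.seed(26)
  n <- 16; nf <- 8
  labs <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * nf * 6, 0, 0.3), n)
  ch2 <- seq(2, nf * 6, by = 6)
  x[labs == "b", ch2] <- x[labs == "b", ch2] + 2
  fit <- loo_group_decode(x, labs, seed = 4)
  props <- selection_proportions(fit)
  expect_named(props, saliency_channels())
  expect_true(all(props >= 0 & props <= 1))
  expect_equal(unname(which.max(props)), 2L)
  expect_gt(props[2], max(props[-2]))

  # all-empty fits give a zero vector
  empty <- structure(list(accuracy = 0.5, correct = logical(2),
                          nonzero = list(integer(0), integer(0)),
                          n_features = 12), class = "loo_decode")
  expect_true(all(selection_proportions(empty) == 0))
})

test_that("fight-vs-rest decoding chunks frames and beats its baseline on signal", {
  set.seed(27)
  n_clips <- 12; nf <- 8; dim_pf <- 4
  labs <- rep(c("fight", "rest"), c(3, 9))
  x <- matrix(rnorm(n_clips * nf * dim_pf, 0, 0.4), n_clips)
  # inject a motion-like signature on fight clips, feature 4 of each frame
  sig_cols <- seq(4, nf * dim_pf, by = dim_pf)
  x[labs == "fight", sig_cols] <- x[labs == "fight", sig_cols] + 3
  res <- decode_fight_vs_rest(x, labs, dim_pf, frames_per_chunk = 2,
                              seed = 5, nfolds = 3)
  expect_length(res$per_frame, nf)
  expect_length(res$per_chunk_max, 4L)  # 8 frames / 2 per chunk
  expect_equal(res$baseline, 0.75)
  expect_gt(res$accuracy, res$baseline)

  # label-independent features hover near chance with balanced weights
  x0 <- matrix(rnorm(n_clips * nf * dim_pf), n_clips)
  res0 <- decode_fight_vs_rest(x0, labs, dim_pf, frames_per_chunk = 4,
                               seed = 6, nfolds = 3)
  expect_true(all(res0$per_frame >= 0 & res0$per_frame <= 1))
  expect_error(decode_fight_vs_rest(x, rep("fight", n_clips), dim_pf, 2),
               "class")
})

test_that("stream combination standardises, concatenates, and is inert when one stream is zero", {
  set.seed(28)
  sal <- rnorm(6 * 5)
  emb <- rnorm(32 * 5)
  comb <- combine_streams(sal, emb, 6L, 32L)
  expect_length(comb, 5L * 38L)
  expect_equal(attr(comb, "dim_per_frame"), 38L)
  # frame blocks interleave: first 6 entries are saliency frame 1
  expect_equal(comb[1:6], (sal[1:6] - mean(sal)) / sd(sal))
  expect_error(combine_streams(rnorm(12), rnorm(9), 6L, 4L), "frame grid")

  # a zero embedding stream leaves decoding equal to saliency-only
  d <- make_group_data(5, 5, 4, 6, sep = 2, seed = 29)
  zrows <- t(apply(d$x, 1, function(r) {
    combine_streams(r, numeric(4 * 8), 6L, 8L)
  }))
  a1 <- loo_group_decode(d$x, d$labels, seed = 7, nfolds = 3)$accuracy
  a2 <- loo_group_decode(zrows, d$labels, seed = 7, nfolds = 3)$accuracy
  expect_equal(a1, a2)
})

test_that("behavior correlations flag degenerate input and recover exact relations", {
  acc <- c(p1 = 0.5, p2 = 0.6, p3 = 0.7, p4 = 0.8, p5 = 0.66)
  beh <- data.frame(participant_id = names(acc),
                    d_prime = 2 * acc - 0.3,  # exact linear function
                    criterion_c = rep(0.1, 5))
  res <- correlate_behavior(acc, beh)
  expect_equal(res$r[res$measure == "d_prime"], 1, tolerance = 1e-12)
  expect_true(res$flagged[res$measure == "criterion_c"])  # zero variance

  # brute-force covariance-ratio oracle on a printed toy table
  acc2 <- c(a = 0.52, b = 0.61, c = 0.55, d = 0.70, e = 0.66)
  dp <- c(1.2, 0.8, 1.5, 2.0, 1.1)
  beh2 <- data.frame(participant_id = names(acc2), d_prime = dp,
                     criterion_c = c(0.2, 0.1, 0.3, 0.25, 0.15))
  res2 <- correlate_behavior(acc2, beh2)
  expect_equal(res2$r[1], naive_pearson(acc2, dp), tolerance = 1e-12)
})
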