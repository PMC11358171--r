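test_that("channel z-normalisation pools across clips and participants", {
  set.seed(31)
  mats <- list(matrix(rnorm(4 * 12, 5, 2), 4), matrix(rnorm(4 * 12, 5, 2), 4))
  zn <- znorm_channels(mats, n_channels = 6L)
  for (ch in 1:6) {
    vals <- unlist(lapply(zn, function(m) m[, seq(ch, 12, 6)]))
    expect_lt(abs(mean(vals)), 1e-10)
    expect_equal(sqrt(mean(vals^2)), 1, tolerance = 1e-10)
  }

  # affine transforms of a channel do not change its z-scores
  mats2 <- lapply(mats, function(m) {
    m[, seq(3, 12, 6)] <- 7 * m[, seq(3, 12, 6)] - 2
    m
  })
  expect_equal(znorm_channels(mats2, 6L), zn, tolerance = 1e-10)

  # two-value toy channel: population-sd convention gives exactly +/- 1
  toy <- matrix(c(0, 2, 2, 0), 2, 2)  # 1 channel, 2 frames
  zt <- znorm_channels(toy, n_channels = 1L)
  expect_true(all(abs(abs(zt) - 1) < 1e-12))

  const <- matrix(rnorm(8), 2)
  const[, c(2, 4)] <- 3
  expect_error(znorm_channels(const, 2L), "ch2")
})

test_that("pairwise ISC averages exactly the within-group pairs", {
  rows <- matrix(rnorm(4 * 50), 4)
  rows[2, ] <- rows[1, ]  # duplicate within group a
  isc <- pairwise_isc(rows[1:2, ], c("a", "a"))
  expect_equal(unname(isc["a"]), 1)

  # 3 participants -> exactly 3 pairs, matching brute-force enumeration
  set.seed(32)
  r3 <- matrix(rnorm(3 * 40), 3)
  got <- pairwise_isc(r3, rep("g", 3))
  oracle <- mean(c(naive_pearson(r3[1, ], r3[2, ]),
                   naive_pearson(r3[1, ], r3[3, ]),
                   naive_pearson(r3[2, ], r3[3, ])))
  expect_equal(unname(got["g"]), oracle, tolerance = 1e-12)
  expect_equal(unname(attr(got, "n_pairs")["g"]), 3L)

  # independent long rows decorrelate
  long <- matrix(rnorm(6 * 4000), 6)
  isc0 <- pairwise_isc(long, rep(c("a", "b"), each = 3))
  expect_true(all(abs(isc0) < 3 / sqrt(4000)))

  # zero-variance rows are excluded with a warning
  rows_z <- rbind(matrix(rnorm(3 * 30), 3), 0)
  expect_warning(pairwise_isc(rows_z, c("a", "a", "a", "a")),
                 "zero-variance")
})

test_that("ISC is symmetric and invariant to participant order", {
  set.seed(33)
  rows <- matrix(rnorm(6 * 60), 6)
  grp <- rep(c("a", "b"), each = 3)
  isc1 <- pairwise_isc(rows, grp)
  perm <- sample(6)
  isc2 <- pairwise_isc(rows[perm, ], grp[perm])
  expect_equal(isc1[sort(names(isc1))], isc2[sort(names(isc2))],
               tolerance = 1e-12)
})

test_that("time-resolved ISC yields one value per 2-s chunk per group", {
  set.seed(34)
  rows <- matrix(rnorm(6 * 400 * 6), 6)  # 400 frames x 6 channels
  grp <- rep(c("a", "b"), each = 3)
  tr <- time_resolved_isc(rows, grp, n_channels = 6L,
                          frames_per_chunk = 50L)
  expect_equal(nrow(tr), 8L)  # 16-s clip, 2-s chunks
  expect_equal(attr(tr, "alpha_adjusted"), 0.05 / 8)
  expect_true(all(c("isc_a", "isc_b") %in% names(tr)))
  expect_true(all(abs(tr$isc_a) <= 1))

  ident <- matrix(rep(rnorm(120), each = 4), 4)
  trid <- time_resolved_isc(ident, rep(c("a", "b"), each = 2),
                            n_channels = 1L, frames_per_chunk = 30L)
  expect_true(all(abs(trid$isc_a - 1) < 1e-12))
  expect_error(time_resolved_isc(rows, grp, 6L, frames_per_chunk = 1L),
               "at least 2")
})

test_that("chunk means only approximately recombine to full-clip ISC", {
  set.seed(35)
  rows <- matrix(rnorm(4 * 100), 4)
  rows <- rows + rep(sin(seq_len(100) / 6), each = 4)  # shared structure
  grp <- rep("a", 4)
  full <- unname(pairwise_isc(rows, grp)["a"])
  tr <- time_resolved_isc(rows, grp, n_channels = 1L,
                          frames_per_chunk = 25L)
  recombined <- mean(tr$isc_a)
  expect_false(isTRUE(all.equal(full, recombined, tolerance = 1e-6)))
  expect_lt(abs(full - recombined), 0.5)  # bounded discrepancy, reported
})

test_that("intergroup correlations separate own- from other-group structure", {
  # all participants identical: own = other = 1
  rows <- matrix(rep(rnorm(30), each = 6), 6)
  grp <- rep(c("a", "b"), each = 3)
  ig <- intergroup_correlation(rows, grp)
  expect_true(all(abs(ig$own_r - 1) < 1e-12))
  expect_true(all(abs(ig$other_r - 1) < 1e-12))

  # orthogonal group templates plus small noise: own >> other
  set.seed(36)
  t1 <- rep(c(1, 0), 25); t2 <- rep(c(0, 1), 25)
  rows2 <- rbind(
    t(replicate(4, t1 + rnorm(50, 0, 0.1))),
    t(replicate(4, t2 + rnorm(50, 0, 0.1)))
  )
  grp2 <- rep(c("a", "b"), each = 4)
  ig2 <- intergroup_correlation(rows2, grp2)
  expect_true(all(ig2$own_r > ig2$other_r + 0.5))

  # leave-self-out oracle: recompute one row by hand
  own_oracle <- naive_pearson(rows2[1, ], colMeans(rows2[2:4, ]))
  expect_equal(ig2$own_r[1], own_oracle, tolerance = 1e-12)
  with_self <- intergroup_correlation(rows2, grp2, leave_self_out = FALSE)
  expect_false(isTRUE(all.equal(ig2$own_r[1], with_self$own_r[1])))
  expect_error(intergroup_correlation(rows2[c(1, 5), ], c("a", "b")),
               ">= 2")
})
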