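# Independent brute-force oracles and small fixture builders shared by
# the unit and acceptance tests. Oracles are deliberately naive: direct
# loops over definitions, no shared code with the implementation paths
# they check.

# Dense 2-D cross-correlation by quadruple loop.
naive_conv2d <- function(x, k, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  nr <- nrow(x); nc <- ncol(x); kr <- nrow(k); kc <- ncol(k)
  cr <- kr %/% 2; cc <- kc %/% 2
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    s <- 0
    for (u in 1:kr) for (v in 1:kc) {
      xi <- i + u - 1 - cr
      xj <- j + v - 1 - cc
      if (pad == "replicate") {
        xi <- min(max(xi, 1), nr)
        xj <- min(max(xj, 1), nc)
      } else if (xi < 1 || xi > nr || xj < 1 || xj > nc) {
        next
      }
      s <- s + x[xi, xj] * k[u, v]
    }
    out[i, j] <- s
  }
  out
}

# One naive center-surround pass (LoG -> rectify -> blur), `passes` times.
naive_activation <- function(m, config, passes = config$activation_passes) {
  lk <- log_kernel(config$activation_log_sigma)
  gk <- gaussian_kernel(config$activation_blur_sigma)
  for (i in seq_len(passes)) {
    m <- naive_conv2d(m, lk)
    m[m < 0] <- 0
    m <- naive_conv2d(m, gk)
  }
  m
}

# Exhaustive integer block-matching shift estimate between two frames.
naive_best_shift <- function(prev, cur, max_shift = 3) {
  best <- c(0, 0); best_err <- Inf
  nr <- nrow(prev); nc <- ncol(prev)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    rows <- (1 + max_shift):(nr - max_shift)
    cols <- (1 + max_shift):(nc - max_shift)
    err <- sum((cur[rows, cols] - prev[rows - dy, cols - dx])^2)
    if (err < best_err) { best_err <- err; best <- c(dx, dy) }
  }
  best
}

# Pearson r from first principles.
naive_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Random RGB patch in [0, 1].
rand_patch <- function(side, seed = 1) {
  set.seed(seed)
  array(runif(side * side * 3), dim = c(side, side, 3))
}

# Build a patch_sequence directly (bypasses clip rendering).
make_patch_seq <- function(patches, valid = rep(TRUE, dim(patches)[1]),
                           clip_id = "toy", participant_id = "p1") {
  structure(list(patches = patches, valid = valid, clip_id = clip_id,
                 participant_id = participant_id,
                 window_px = dim(patches)[2]),
            class = "patch_sequence")
}

# Gaussian blob image.
blob_image <- function(side, cx, cy, sd = 2, amp = 1) {
  d <- seq_len(side) - 1
  amp * exp(-outer((d - cy)^2, (d - cx)^2, "+") / (2 * sd^2))
}

# Small world shared by integration-style tests: 1 clip per category,
# 48x48 px, 20 frames, 3 + 3 participants, 16-px patches.
tiny_world <- function(n_per_category = 1L, n_a = 3L, n_b = 3L,
                       strategy_gap = 0.5, cons_a = 0.8, cons_b = 0.65,
                       seed = 11L, frames = 20L) {
  base <- clip_spec(duration_s = frames / 25, fps = 25, width = 48L,
                    height = 48L, n_agents = 2L, n_distractors = 1L,
                    distractor_salience = 0.8)
  clips <- generate_stimulus_set(n_per_category, base, seed = seed)
  cohort <- cohort_spec(n_a, n_b, strategy_gap = strategy_gap,
                        within_group_consistency_a = cons_a,
                        within_group_consistency_b = cons_b,
                        seed = seed + 1L)
  traces <- generate_cohort_gaze(clips, cohort)
  list(clips = clips, cohort = cohort, traces = traces)
}

# Cache for expensive fixtures, shared across test files in one run.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}
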