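#' @importFrom stats rnorm runif quantile sd cor t.test cor.test qnorm pnorm
#'   coef predict
NULL

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Action categories of the synthetic stimulus set
#' @export
clip_categories <- function() c("fight", "confrontation", "playful", "neutral")

#' Specification of one synthetic surveillance-style clip
#'
#' Defaults mirror the stimulus format the analyses assume: 16-s clips at
#' 25 fps (400 frames) of 576 x 480 px, with a handful of moving "agents"
#' and static or flashing "distractor" elements.
#'
#' @param clip_id character id.
#' @param category one of [clip_categories()]; determines the agents' joint
#'   motion profile (fight/confrontation converge on an interaction locus,
#'   playful orbits it, neutral wanders independently).
#' @param duration_s clip duration in seconds.
#' @param fps frames per second; `duration_s * fps` must be an integer.
#' @param width,height frame size in pixels.
#' @param n_agents number of moving agents.
#' @param n_distractors number of high-contrast distractor elements.
#' @param agent_motion_scale typical agent speed in px/frame.
#' @param distractor_salience contrast of distractors, in \[0, 1\].
#' @return object of class `clip_spec`.
#' @export
clip_spec <- function(clip_id = "clip01", category = "neutral",
                      duration_s = 16, fps = 25,
                      width = 576L, height = 480L,
                      n_agents = 3L, n_distractors = 2L,
                      agent_motion_scale = 1.5,
                      distractor_salience = 0.5) {
  category <- match.arg(category, clip_categories())
  if (width <= 0 || height <= 0 || fps <= 0 || duration_s <= 0) {
    stop("clip dimensions, fps and duration must be positive")
  }
  n_frames <- duration_s * fps
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("duration_s * fps must be an integer frame count")
  }
  if (n_agents < 0 || n_distractors < 0) {
    stop("agent and distractor counts must be non-negative")
  }
  if (distractor_salience < 0 || distractor_salience > 1) {
    stop("distractor_salience must lie in [0, 1]")
  }
  structure(list(
    clip_id = clip_id, category = category,
    duration_s = duration_s, fps = fps,
    width = as.integer(width), height = as.integer(height),
    n_frames = as.integer(round(n_frames)),
    n_agents = as.integer(n_agents),
    n_distractors = as.integer(n_distractors),
    agent_motion_scale = agent_motion_scale,
    distractor_salience = distractor_salience
  ), class = "clip_spec")
}

# Smooth AR(1) jitter with marginal sd `sigma`.
ar1_noise <- function(n, sigma, rho = 0.8) {
  if (sigma <= 0 || n == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sigma)
  innov_sd <- sigma * sqrt(1 - rho^2)
  for (t in seq_len(n)[-1]) e[t] <- rho * e[t - 1] + rnorm(1, 0, innov_sd)
  e
}

# Category-dependent agent tracks (T x 2 matrices, 0-based pixel coords).
make_agent_tracks <- function(spec) {
  tt <- spec$n_frames
  w <- spec$width
  h <- spec$height
  locus <- c(runif(1, 0.3, 0.7) * w, runif(1, 0.3, 0.7) * h)
  tracks <- vector("list", spec$n_agents)
  for (a in seq_len(spec$n_agents)) {
    ang <- runif(1, 0, 2 * pi)
    r0 <- runif(1, 0.25, 0.45) * min(w, h)
    start <- locus + r0 * c(cos(ang), sin(ang))
    jx <- ar1_noise(tt, 1.5)
    jy <- ar1_noise(tt, 1.5)
    u <- seq(0, 1, length.out = tt)
    if (spec$category == "fight") {
      # converge on the locus with increasing speed (quadratic approach)
      prog <- u^2
      px <- start[1] + (locus[1] - start[1]) * prog
      py <- start[2] + (locus[2] - start[2]) * prog
    } else if (spec$category == "confrontation") {
      # approach, then hold a stand-off distance from the locus
      standoff <- 18
      prog <- pmin(1, 1 - exp(-3 * u)) * (1 - standoff / r0)
      px <- start[1] + (locus[1] - start[1]) * prog
      py <- start[2] + (locus[2] - start[2]) * prog
    } else if (spec$category == "playful") {
      # orbit the locus with oscillating radius
      omega <- 2 * pi * runif(1, 0.8, 1.5)
      rr <- r0 * (0.6 + 0.25 * sin(2 * pi * u * 2 + ang))
      px <- locus[1] + rr * cos(ang + omega * u)
      py <- locus[2] + rr * sin(ang + omega * u)
    } else {
      # neutral: independent slow smooth walk
      vel <- spec$agent_motion_scale * 0.5
      px <- start[1] + cumsum(ar1_noise(tt, vel, rho = 0.95))
      py <- start[2] + cumsum(ar1_noise(tt, vel, rho = 0.95))
    }
    px <- pmin(pmax(px + jx, 0), w - 1)
    py <- pmin(pmax(py + jy, 0), h - 1)
    tracks[[a]] <- cbind(x = px, y = py)
  }
  list(tracks = tracks, locus = locus)
}

#' Generate one synthetic clip
#'
#' Agents are rendered as isotropic Gaussian blobs whose joint motion
#' depends on the action category; distractors are static or periodically
#' flashing colored blobs. The frames themselves are rendered lazily, one
#' at a time, via [clip_frame()] (a full default clip would occupy several
#' GB if materialised); the ground-truth `agent_tracks` are stored exactly.
#'
#' @param spec a [clip_spec()].
#' @param seed integer seed; the clip is bit-reproducible given
#'   `(spec, seed)`.
#' @return object of class `video_clip` with elements `spec`, `agent_tracks`
#'   (list of T x 2 matrices, 0-based x/y), `distractors`, `locus`.
#' @export
generate_clip <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "clip_spec"))
  with_seed(seed, {
    ag <- make_agent_tracks(spec)
    agent_colors <- lapply(seq_len(spec$n_agents), function(a) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      dir * runif(1, 0.25, 0.45)
    })
    nd <- spec$n_distractors
    distractors <- if (nd > 0) {
      data.frame(
        x = runif(nd, 0.1, 0.9) * spec$width,
        y = runif(nd, 0.1, 0.9) * spec$height,
        r = runif(nd, 0, 0.5) * spec$distractor_salience,
        g = runif(nd, -0.25, 0.25) * spec$distractor_salience,
        b = runif(nd, -0.5, 0) * spec$distractor_salience,
        periodic = seq_len(nd) %% 2 == 0,
        period = pmax(4, round(runif(nd, 0.5, 2) * spec$fps)),
        phase = runif(nd, 0, 2 * pi)
      )
    } else {
      data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                 g = numeric(0), b = numeric(0), periodic = logical(0),
                 period = numeric(0), phase = numeric(0))
    }
    structure(list(
      spec = spec, seed = seed,
      agent_tracks = ag$tracks, agent_colors = agent_colors,
      locus = ag$locus, distractors = distractors
    ), class = "video_clip")
  })
}

#' @export
print.video_clip <- function(x, ...) {
  cat(sprintf("<video_clip %s: %s, %d frames %dx%d, %d agents, %d distractors>\n",
              x$spec$clip_id, x$spec$category, x$spec$n_frames,
              x$spec$width, x$spec$height, x$spec$n_agents,
              x$spec$n_distractors))
  invisible(x)
}

#' Number of frames in a clip
#' @param clip a `video_clip`.
#' @export
n_frames <- function(clip) clip$spec$n_frames

# Add a Gaussian blob into a frame (H x W x 3), locally within +/- 4 sd.
add_blob <- function(frame, cx, cy, sd_px, rgb_amp, scale = 1) {
  h <- dim(frame)[1]
  w <- dim(frame)[2]
  r <- ceiling(4 * sd_px)
  # 0-based coords -> 1-based indices
  i0 <- max(1L, floor(cy) - r + 1L)
  i1 <- min(h, floor(cy) + r + 1L)
  j0 <- max(1L, floor(cx) - r + 1L)
  j1 <- min(w, floor(cx) + r + 1L)
  if (i0 > i1 || j0 > j1) return(frame)
  yi <- seq(i0, i1) - 1
  xj <- seq(j0, j1) - 1
  g <- exp(-outer((yi - cy)^2, (xj - cx)^2, "+") / (2 * sd_px^2)) * scale
  for (ch in 1:3) {
    frame[i0:i1, j0:j1, ch] <- frame[i0:i1, j0:j1, ch] + g * rgb_amp[ch]
  }
  frame
}

#' Render one frame of a synthetic clip
#'
#' @param clip a `video_clip`.
#' @param t frame index, 1-based.
#' @param agent_sd,distractor_sd blob sds in pixels.
#' @return H x W x 3 array of RGB intensities clipped to \[0, 1\].
#' @export
clip_frame <- function(clip, t, agent_sd = 4, distractor_sd = 3) {
  stopifnot(inherits(clip, "video_clip"))
  spec <- clip$spec
  if (t < 1 || t > spec$n_frames) stop("frame index out of range")
  frame <- array(0.5, dim = c(spec$height, spec$width, 3L))
  for (a in seq_along(clip$agent_tracks)) {
    p <- clip$agent_tracks[[a]][t, ]
    frame <- add_blob(frame, p[1], p[2], agent_sd, clip$agent_colors[[a]])
  }
  d <- clip$distractors
  for (k in seq_len(nrow(d))) {
    scale <- if (d$periodic[k]) {
      0.5 + 0.5 * sin(2 * pi * t / d$period[k] + d$phase[k])
    } else 1
    frame <- add_blob(frame, d$x[k], d$y[k], distractor_sd,
                      c(d$r[k], d$g[k], d$b[k]), scale)
  }
  frame[frame < 0] <- 0
  frame[frame > 1] <- 1
  frame
}

#' Materialise all frames of a clip as a T x H x W x 3 array
#'
#' Only sensible for small clips; a full-size default clip is several GB.
#' @param x a `video_clip`.
#' @param ... unused.
#' @export
as.array.video_clip <- function(x, ...) {
  spec <- x$spec
  out <- array(0, dim = c(spec$n_frames, spec$height, spec$width, 3L))
  for (t in seq_len(spec$n_frames)) out[t, , , ] <- clip_frame(x, t)
  out
}

#' Generate a balanced stimulus set across the four action categories
#'
#' @param n_per_category clips per category (default 9, i.e. 36 clips).
#' @param base_spec template [clip_spec()]; id and category are overridden.
#' @param seed integer seed.
#' @return list of `video_clip`, categories interleaved in blocks.
#' @export
generate_stimulus_set <- function(n_per_category = 9L,
                                  base_spec = clip_spec(),
                                  seed = 1L) {
  if (n_per_category < 1) stop("n_per_category must be >= 1")
  cats <- clip_categories()
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max,
                            4L * n_per_category)
    clips <- vector("list", 4L * n_per_category)
    k <- 0L
    for (cat in cats) {
      for (i in seq_len(n_per_category)) {
        k <- k + 1L
        sp <- base_spec
        sp$clip_id <- sprintf("%s%02d", cat, i)
        sp$category <- cat
        clips[[k]] <- generate_clip(sp, seed = sub_seeds[k])
      }
    }
    clips
  })
}

#' Specification of a two-group observer cohort
#'
#' Group "a" plays the role of the experienced (operator-like) group,
#' group "b" the novice-like group. `strategy_gap` controls how often
#' group-b gaze is captured by distractors instead of following the
#' group-shared agent-tracking policy; 0 makes the two groups draws from
#' the identical generative policy (given equal consistencies).
#'
#' @param n_group_a,n_group_b group sizes (defaults 11 and 10).
#' @param strategy_gap non-negative; distractor-capture probability per
#'   1-s gaze segment in group b is `min(1, 0.6 * strategy_gap)`.
#' @param within_group_consistency_a,within_group_consistency_b in
#'   \[0, 1\]; participant-specific gaze bias and wander scale with
#'   `1 - consistency`.
#' @param missing_rate i.i.d. per-frame probability of a missing gaze
#'   sample (default 0.011).
#' @param gaze_noise_px baseline per-frame gaze noise sd in pixels.
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_group_a = 11L, n_group_b = 10L,
                        strategy_gap = 0.5,
                        within_group_consistency_a = 0.8,
                        within_group_consistency_b = 0.65,
                        missing_rate = 0.011,
                        gaze_noise_px = 8,
                        seed = 1L) {
  if (n_group_a + n_group_b < 2) stop("need at least two participants")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (strategy_gap < 0) stop("strategy_gap must be non-negative")
  for (c_ in c(within_group_consistency_a, within_group_consistency_b)) {
    if (c_ < 0 || c_ > 1) stop("consistencies must lie in [0, 1]")
  }
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    strategy_gap = strategy_gap,
    within_group_consistency_a = within_group_consistency_a,
    within_group_consistency_b = within_group_consistency_b,
    missing_rate = missing_rate, gaze_noise_px = gaze_noise_px,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Index of the agent whose track ends nearest the interaction locus.
target_agent <- function(clip) {
  if (length(clip$agent_tracks) == 0) return(NA_integer_)
  tt <- clip$spec$n_frames
  late <- max(1L, tt - clip$spec$fps + 1L):tt
  d <- vapply(clip$agent_tracks, function(tr) {
    mean(sqrt((tr[late, 1] - clip$locus[1])^2 +
                (tr[late, 2] - clip$locus[2])^2))
  }, numeric(1))
  which.min(d)
}

#' Generate gaze traces for a two-group cohort over a clip list
#'
#' Group-a participants track the agent that ends up nearest the clip's
#' interaction locus, with a persistent participant-specific spatial bias
#' and smooth AR(1) wander, both scaled by `1 - consistency`. Group-b
#' participants follow the same policy, but each 0.5-s dwell segment (a
#' typical fixation-dwell timescale) is captured by a random distractor
#' with probability `min(1, 0.6 * strategy_gap)`. Frames are marked
#' invalid i.i.d. at `missing_rate`.
#'
#' @param clips nonempty list of `video_clip`.
#' @param cohort a [cohort_spec()].
#' @return list of `gaze_trace` objects (participant_id, group, clip_id,
#'   x, y, valid), participants varying fastest.
#' @export
generate_cohort_gaze <- function(clips, cohort) {
  if (length(clips) == 0) stop("clip list must be nonempty")
  stopifnot(inherits(cohort, "cohort_spec"))
  groups <- c(rep("a", cohort$n_group_a), rep("b", cohort$n_group_b))
  ids <- sprintf("%s%02d", ifelse(groups == "a", "op", "nov"),
                 c(seq_len(cohort$n_group_a), seq_len(cohort$n_group_b)))
  p_capture <- min(1, 0.6 * cohort$strategy_gap)
  with_seed(cohort$seed, {
    cons <- ifelse(groups == "a", cohort$within_group_consistency_a,
                   cohort$within_group_consistency_b)
    bias_unit <- cbind(rnorm(length(ids), 0, 1), rnorm(length(ids), 0, 1))
    out <- vector("list", length(clips) * length(ids))
    k <- 0L
    for (ci in seq_along(clips)) {
      clip <- clips[[ci]]
      # consistency-driven dispersion is constant in visual angle, i.e.
      # proportional to the frame: 50 px bias / 30 px wander at the
      # reference 576-px width
      fscale <- clip$spec$width / 576
      bias <- bias_unit * (50 * fscale * (1 - cons))
      tt <- clip$spec$n_frames
      tgt <- target_agent(clip)
      base_xy <- if (is.na(tgt)) {
        cbind(rep(clip$spec$width / 2, tt), rep(clip$spec$height / 2, tt))
      } else {
        clip$agent_tracks[[tgt]]
      }
      seg_len <- max(1L, as.integer(round(clip$spec$fps / 2)))  # 0.5-s dwell
      seg <- rep(seq_len(ceiling(tt / seg_len)), each = seg_len)[seq_len(tt)]
      nseg <- max(seg)
      for (pi in seq_along(ids)) {
        noise_sd <- cohort$gaze_noise_px + 30 * fscale * (1 - cons[pi])
        x <- base_xy[, 1] + bias[pi, 1] + ar1_noise(tt, noise_sd)
        y <- base_xy[, 2] + bias[pi, 2] + ar1_noise(tt, noise_sd)
        if (groups[pi] == "b" && p_capture > 0) {
          captured <- runif(nseg) < p_capture
          for (s in which(captured)) {
            idx <- which(seg == s)
            cap_xy <- if (nrow(clip$distractors) > 0) {
              d <- clip$distractors[sample.int(nrow(clip$distractors), 1), ]
              matrix(c(d$x, d$y), length(idx), 2, byrow = TRUE)
            } else if (length(clip$agent_tracks) > 1) {
              alt <- sample(setdiff(seq_along(clip$agent_tracks), tgt), 1)
              clip$agent_tracks[[alt]][idx, , drop = FALSE]
            } else {
              NULL
            }
            if (!is.null(cap_xy)) {
              x[idx] <- cap_xy[, 1] + bias[pi, 1] +
                rnorm(length(idx), 0, noise_sd / 2)
              y[idx] <- cap_xy[, 2] + bias[pi, 2] +
                rnorm(length(idx), 0, noise_sd / 2)
            }
          }
        }
        valid <- runif(tt) >= cohort$missing_rate
        k <- k + 1L
        out[[k]] <- structure(list(
          participant_id = ids[pi], group = groups[pi],
          clip_id = clip$spec$clip_id,
          x = pmin(pmax(x, 0), clip$spec$width - 1),
          y = pmin(pmax(y, 0), clip$spec$height - 1),
          valid = valid
        ), class = "gaze_trace")
      }
    }
    out
  })
}

# Accept either a list of video_clip or a data.frame(clip_id, category).
clip_meta <- function(clips) {
  if (is.data.frame(clips)) {
    stopifnot(all(c("clip_id", "category") %in% names(clips)))
    clips[c("clip_id", "category")]
  } else {
    data.frame(
      clip_id = vapply(clips, function(cl) cl$spec$clip_id, character(1)),
      category = vapply(clips, function(cl) cl$spec$category, character(1))
    )
  }
}

#' Generate violence-likelihood ratings from a signal-detection model
#'
#' Each participant x clip decision variable is drawn from an
#' equal-variance Gaussian model (fight clips carry the signal, with mean
#' equal to the group's sensitivity) and binned onto the 1-6 scale by five
#' equal-width cuts spaced 0.5 z-units apart and centered on `criterion`,
#' so that the binary "violent" judgement (rating >= 4) has its cut exactly
#' at `criterion`.
#'
#' @param cohort a [cohort_spec()].
#' @param clips list of `video_clip` or data.frame with `clip_id`,
#'   `category`.
#' @param sensitivity_a,sensitivity_b group d-prime in z-units (>= 0).
#' @param criterion absolute decision cut in z-units.
#' @param seed integer seed.
#' @return data.frame (participant_id, group, clip_id, category, rating).
#' @export
generate_ratings <- function(cohort, clips, sensitivity_a = 1.5,
                             sensitivity_b = 1.0, criterion = 0.75,
                             seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (sensitivity_a < 0 || sensitivity_b < 0) {
    stop("sensitivities must be non-negative")
  }
  meta <- clip_meta(clips)
  groups <- c(rep("a", cohort$n_group_a), rep("b", cohort$n_group_b))
  ids <- sprintf("%s%02d", ifelse(groups == "a", "op", "nov"),
                 c(seq_len(cohort$n_group_a), seq_len(cohort$n_group_b)))
  cuts <- criterion + c(-1, -0.5, 0, 0.5, 1)
  with_seed(seed, {
    rows <- expand.grid(clip = seq_len(nrow(meta)), p = seq_along(ids))
    sens <- ifelse(groups[rows$p] == "a", sensitivity_a, sensitivity_b)
    mu <- ifelse(meta$category[rows$clip] == "fight", sens, 0)
    d <- rnorm(nrow(rows), mu, 1)
    data.frame(
      participant_id = ids[rows$p],
      group = groups[rows$p],
      clip_id = meta$clip_id[rows$clip],
      category = meta$category[rows$clip],
      rating = 1L + findInterval(d, cuts)
    )
  })
}
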