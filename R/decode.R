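# Elastic-net group decoding over cumulative temporal windows, with
# max-accuracy summarisation, one-sample tests against chance,
# channel-shuffling permutation nulls and feature-selection proportions.

#' Build temporal feature windows
#'
#' Cumulative windows are anchored at frame 1 and grow in `step`-frame
#' increments (1..step, 1..2*step, ...), modelling accumulating evidence;
#' chunked windows are the disjoint `step`-frame blocks used for the
#' 2-s / 4-s analyses. The final window is truncated at `n_frames`.
#'
#' @param n_frames total frames on the feature grid.
#' @param step window increment in frames.
#' @param mode `"cumulative"` or `"chunked"`.
#' @return list of windows, each `c(start, end)` (1-based, inclusive);
#'   `ceiling(n_frames / step)` of them.
#' @export
build_windows <- function(n_frames, step, mode = c("cumulative", "chunked")) {
  mode <- match.arg(mode)
  step <- as.integer(step)
  n_frames <- as.integer(n_frames)
  if (is.na(step) || step < 1L) stop("step must be a positive integer")
  if (step > n_frames) stop("step exceeds the number of frames")
  ends <- seq.int(step, n_frames, by = step)
  if (ends[length(ends)] < n_frames) ends <- c(ends, n_frames)
  lapply(seq_along(ends), function(i) {
    start <- if (mode == "cumulative") 1L else (i - 1L) * step + 1L
    c(start = start, end = ends[i])
  })
}

# Feature-matrix columns covered by a window, for frame-major rows with
# `dim_per_frame` features per frame.
window_cols <- function(window, dim_per_frame) {
  frames <- window[1]:window[2]
  as.vector(vapply(frames, function(f) {
    ((f - 1L) * dim_per_frame + 1L):(f * dim_per_frame)
  }, integer(dim_per_frame)))
}

# Stratified fold assignment for inner cross-validation.
stratified_foldid <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

# Fit an elastic-net-penalised binomial GLM with the regularisation
# strength chosen by inner cross-validation on the training data only.
# When the training classes are too small to cross-validate (every fold
# split would starve glmnet of a class) the fit falls back to a fixed
# mid-path lambda — deterministic and documented in the methods
# vignette. Returns a predict function and the nonzero coefficients.
fit_enet <- function(x, y, mixing_alpha, nfolds, weights = NULL) {
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L) stop("single-class training fold")
  yb <- as.integer(as.character(y) == classes[2])
  if (!all(is.finite(x))) stop("non-finite features")
  if (is.null(weights)) weights <- rep(1, length(yb))
  sds <- apply(x, 2, stats::var)
  if (all(sds == 0)) {
    # degenerate all-constant features: intercept-only majority model
    p1 <- stats::weighted.mean(yb, weights)
    return(list(predict_prob = function(newx) rep(p1, nrow(newx)),
                nonzero = integer(0), positive = classes[2],
                negative = classes[1]))
  }
  # glmnet warns on every fit below 8 observations per class; that is
  # the normal operating regime here (leave-one-out over ~20 people)
  quiet_small_n <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("fewer than 8|dangerous ground", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  path <- quiet_small_n(
    glmnet::glmnet(x, yb, family = "binomial",
                   alpha = mixing_alpha, weights = weights,
                   nlambda = 30, standardize = TRUE))
  lam <- NULL
  min_class <- min(table(yb))
  if (min_class >= 4L && length(path$lambda) >= 2L) {
    nfolds <- max(3L, min(nfolds, min_class))
    foldid <- stratified_foldid(yb, nfolds)
    cvfit <- tryCatch(
      quiet_small_n(
        glmnet::cv.glmnet(x, yb, family = "binomial",
                          alpha = mixing_alpha, foldid = foldid,
                          weights = weights, lambda = path$lambda,
                          standardize = TRUE, grouped = FALSE)),
      error = function(e) NULL)
    if (!is.null(cvfit)) lam <- cvfit$lambda.min
  }
  if (is.null(lam)) {
    # fixed fallback: two thirds of the way down the lambda path
    lam <- path$lambda[max(1L, ceiling(2 / 3 * length(path$lambda)))]
  }
  beta <- coef(path, s = lam)
  nz <- which(as.vector(beta[-1]) != 0)
  list(
    predict_prob = function(newx) {
      as.vector(predict(path, newx = newx, s = lam, type = "response"))
    },
    nonzero = nz, positive = classes[2], negative = classes[1]
  )
}

#' Leave-one-participant-out group decoding of one feature window
#'
#' For each participant in turn, an elastic-net-penalised binomial GLM is
#' fitted to the remaining participants (regularisation strength chosen
#' by inner cross-validation on the training fold) and the held-out
#' participant's group is predicted at probability threshold 0.5, ties
#' going to the alphabetically first (negative) class. The iteration
#' count equals the participant count (21 for an 11 + 10 cohort).
#' Training folds use balanced class weights: without them the held-out
#' participant's class is always the training minority, so an
#' intercept-dominated fit predicts every participant wrong (leave-one-out
#' anti-learning) instead of sitting at chance.
#'
#' @param x participants x features matrix (one clip, one window).
#' @param labels group label per participant (two classes).
#' @param mixing_alpha elastic-net mixing weight in (0, 1\]; 1 = lasso.
#' @param seed integer seed controlling the inner-CV fold assignment.
#' @param nfolds inner cross-validation folds.
#' @return object of class `loo_decode`: `accuracy`, `correct` (logical
#'   per iteration), `nonzero` (list of nonzero-coefficient indices per
#'   iteration), `n_features`.
#' @export
loo_group_decode <- function(x, labels, mixing_alpha = 1, seed = 1L,
                             nfolds = 5L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (!all(is.finite(x))) stop("non-finite features")
  if (min(table(labels)) < 2L) stop("need at least 2 participants per group")
  n <- nrow(x)
  correct <- logical(n)
  nonzero <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      ytr <- labels[-i]
      wtr <- as.vector((length(ytr) / (2 * table(ytr)))[ytr])
      fit <- fit_enet(x[-i, , drop = FALSE], ytr, mixing_alpha,
                      nfolds, weights = wtr)
      prob <- fit$predict_prob(x[i, , drop = FALSE])
      pred <- if (prob > 0.5) fit$positive else fit$negative
      correct[i] <- pred == labels[i]
      nonzero[[i]] <- fit$nonzero
    }
  })
  structure(list(
    accuracy = mean(correct), correct = correct, nonzero = nonzero,
    n_features = ncol(x)
  ), class = "loo_decode")
}

#' Decode one clip across a set of temporal windows
#'
#' @param x participants x (frames * dim_per_frame) feature matrix.
#' @param labels group label per participant.
#' @param windows list from [build_windows()].
#' @param dim_per_frame features per frame (6 for the saliency stream).
#' @param ... passed to [loo_group_decode()].
#' @return list with `per_window` accuracies, `max` (the per-clip
#'   decoding accuracy), `max_window`, and `fits` (the `loo_decode`
#'   objects).
#' @export
decode_clip_windows <- function(x, labels, windows, dim_per_frame, ...) {
  fits <- lapply(windows, function(w) {
    loo_group_decode(x[, window_cols(w, dim_per_frame), drop = FALSE],
                     labels, ...)
  })
  acc <- vapply(fits, `[[`, numeric(1), "accuracy")
  mx <- summarize_max_accuracy(acc)
  list(per_window = acc, max = mx$accuracy, max_window = mx$window,
       fits = fits)
}

#' Summarise per-window accuracies by their maximum
#'
#' The most informative signal can emerge in different windows for
#' different clips, so each clip is scored by its best window; ties keep
#' the earliest window.
#'
#' @param per_window numeric vector of window accuracies.
#' @return list with `accuracy` and the 1-based `window` index attaining
#'   it.
#' @export
summarize_max_accuracy <- function(per_window) {
  if (length(per_window) == 0) stop("no window accuracies")
  w <- which.max(per_window)  # earliest maximum
  list(accuracy = per_window[w], window = w)
}

#' One-sample t-tests of per-clip accuracies against chance
#'
#' One test per action category at a Bonferroni-adjusted alpha
#' (0.05 / n_tests; 0.0125 for the four categories).
#'
#' @param per_clip_max per-clip maximum accuracies.
#' @param categories category per clip.
#' @param chance chance level (default 0.5).
#' @param alpha family-wise alpha before adjustment.
#' @param n_tests number of tests corrected for (default: number of
#'   categories present).
#' @return data.frame with per-category mean, sd, t, df, p, `significant`
#'   at the adjusted alpha and a `degenerate` flag for zero-variance
#'   cells; the adjusted alpha is attached as attribute
#'   `alpha_adjusted`.
#' @export
test_vs_chance <- function(per_clip_max, categories, chance = 0.5,
                           alpha = 0.05, n_tests = NULL) {
  categories <- as.character(categories)
  stopifnot(length(per_clip_max) == length(categories))
  cats <- unique(categories)
  if (is.null(n_tests)) n_tests <- length(cats)
  alpha_adj <- alpha / n_tests
  rows <- lapply(cats, function(cat) {
    xs <- per_clip_max[categories == cat]
    if (length(xs) < 2L) stop("need >= 2 clips per category")
    if (sd(xs) == 0) {
      data.frame(category = cat, n = length(xs), mean = mean(xs),
                 sd = 0, t = if (mean(xs) == chance) 0 else NaN,
                 df = length(xs) - 1L, p = NA_real_,
                 significant = FALSE, degenerate = TRUE)
    } else {
      tt <- t.test(xs, mu = chance)
      data.frame(category = cat, n = length(xs), mean = mean(xs),
                 sd = sd(xs), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 significant = tt$p.value < alpha_adj &
                   mean(xs) > chance,
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_adjusted") <- alpha_adj
  out
}

# Permute the channel identities of one frame-major feature row,
# consistently across frames.
permute_channels <- function(row, perm, n_channels) {
  n_frames <- length(row) / n_channels
  row[rep((seq_len(n_frames) - 1L) * n_channels, each = n_channels) +
        rep(perm, n_frames)]
}

#' Channel-shuffling permutation null for saliency-stream decoding
#'
#' Per iteration, each participant's six saliency channels are relabelled
#' by a random permutation (applied consistently across frames) and the
#' full window-decoding pipeline is re-run; the p-value is the fraction
#' of null accuracies at or above the observed one.
#'
#' @param x participants x (frames * n_channels) saliency feature matrix.
#' @param labels group label per participant.
#' @param windows list from [build_windows()]; default one full-length
#'   window.
#' @param n_channels features per frame (6).
#' @param n_iter permutation iterations (default 100).
#' @param seed integer seed.
#' @param ... passed to [loo_group_decode()].
#' @return list with `observed`, `null` (length `n_iter`) and `p`.
#' @export
permutation_null <- function(x, labels, windows = NULL, n_channels = 6L,
                             n_iter = 100L, seed = 1L, ...) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  x <- as.matrix(x)
  if (is.null(windows)) {
    windows <- list(c(start = 1L, end = ncol(x) %/% n_channels))
  }
  observed <- decode_clip_windows(x, labels, windows, n_channels, ...)$max
  with_seed(seed, {
    null <- vapply(seq_len(n_iter), function(it) {
      xp <- t(apply(x, 1, function(row) {
        permute_channels(row, sample.int(n_channels), n_channels)
      }))
      decode_clip_windows(xp, labels, windows, n_channels, ...)$max
    }, numeric(1))
    list(observed = observed, null = null, p = mean(null >= observed))
  })
}

#' Proportion of fits selecting each saliency channel
#'
#' Over all leave-one-out iterations (and clips, if several decoding
#' results are supplied), the fraction of fitted models with at least one
#' nonzero coefficient on each channel's frame columns. Proportions need
#' not sum to 1.
#'
#' @param fits a `loo_decode` object or list of them.
#' @param n_channels features per frame (6).
#' @return named proportion vector over [saliency_channels()].
#' @export
selection_proportions <- function(fits, n_channels = 6L) {
  if (inherits(fits, "loo_decode")) fits <- list(fits)
  counts <- numeric(n_channels)
  total <- 0L
  for (f in fits) {
    stopifnot(inherits(f, "loo_decode"))
    for (nz in f$nonzero) {
      total <- total + 1L
      ch <- unique((nz - 1L) %% n_channels + 1L)
      counts[ch] <- counts[ch] + 1L
    }
  }
  props <- if (total > 0) counts / total else counts
  names(props) <- if (n_channels == 6L) saliency_channels() else
    paste0("ch", seq_len(n_channels))
  props
}

#' Per-participant decoding of fight versus non-fight clips
#'
#' For one participant, a frame-by-frame elastic-net classifier separates
#' fight clips from the rest with leave-one-clip-out cross-validation and
#' balanced class weights (9 fight vs 27 non-fight clips would otherwise
#' dominate the loss); the maximum accuracy within each time chunk
#' (default 4 s) is averaged into the participant's score.
#'
#' @param x clips x (frames * dim_per_frame) feature matrix for one
#'   participant.
#' @param labels logical or two-level label per clip (`TRUE` / "fight" =
#'   signal class).
#' @param dim_per_frame features per frame.
#' @param frames_per_chunk frames per time chunk on this feature grid
#'   (100 for 4-s chunks at 25 fps; 10 on the 2.5-fps embedding grid).
#' @param mixing_alpha,seed,nfolds as in [loo_group_decode()].
#' @return list with `per_frame` accuracies, `per_chunk_max`, `accuracy`
#'   (mean of chunk maxima) and `baseline` (majority-class prior).
#' @export
decode_fight_vs_rest <- function(x, labels, dim_per_frame,
                                 frames_per_chunk, mixing_alpha = 1,
                                 seed = 1L, nfolds = 5L) {
  x <- as.matrix(x)
  is_fight <- if (is.logical(labels)) labels else
    as.character(labels) %in% c("fight", "TRUE")
  if (length(unique(is_fight)) < 2L) stop("both classes required")
  if (min(table(is_fight)) < 2L) stop("need >= 2 clips per class")
  y <- ifelse(is_fight, "fight", "rest")
  n <- nrow(x)
  wts <- n / (2 * table(y)[y])
  n_frames <- ncol(x) %/% dim_per_frame
  per_frame <- numeric(n_frames)
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      cols <- ((f - 1L) * dim_per_frame + 1L):(f * dim_per_frame)
      correct <- logical(n)
      for (i in seq_len(n)) {
        fit <- fit_enet(x[-i, cols, drop = FALSE], y[-i], mixing_alpha,
                        nfolds, weights = as.vector(wts[-i]))
        prob <- fit$predict_prob(x[i, cols, drop = FALSE])
        pred <- if (prob > 0.5) fit$positive else fit$negative
        correct[i] <- pred == y[i]
      }
      per_frame[f] <- mean(correct)
    }
  })
  chunk_id <- rep(seq_len(ceiling(n_frames / frames_per_chunk)),
                  each = frames_per_chunk)[seq_len(n_frames)]
  per_chunk_max <- as.vector(tapply(per_frame, chunk_id, max))
  list(per_frame = per_frame, per_chunk_max = per_chunk_max,
       accuracy = mean(per_chunk_max),
       baseline = max(table(y)) / n)
}

#' Concatenate saliency and embedding feature rows frame by frame
#'
#' Both rows must live on the same frame grid (subsample the saliency
#' stream to the embedding frames first). Each stream is standardised
#' (centered, unit sd; constant streams are only centered) before
#' concatenation so neither dominates by scale.
#'
#' @param saliency_row frame-major saliency features.
#' @param embedding_row frame-major embedding features.
#' @param sal_dim,emb_dim features per frame of each stream; `emb_dim`
#'   defaults to the row's `dim_per_frame` attribute.
#' @return combined frame-major row with `dim_per_frame` and `n_frames`
#'   attributes.
#' @export
combine_streams <- function(saliency_row, embedding_row, sal_dim = 6L,
                            emb_dim = attr(embedding_row, "dim_per_frame")) {
  if (is.null(emb_dim)) stop("emb_dim not supplied and not an attribute")
  nf_s <- length(saliency_row) / sal_dim
  nf_e <- length(embedding_row) / emb_dim
  if (nf_s != round(nf_s) || nf_e != round(nf_e) || nf_s != nf_e) {
    stop("streams are not on a common frame grid")
  }
  nf <- as.integer(nf_s)
  zstd <- function(v) {
    v <- v - mean(v)
    s <- sd(v)
    if (is.finite(s) && s > 0) v / s else v
  }
  s <- matrix(zstd(saliency_row), sal_dim, nf)
  e <- matrix(zstd(embedding_row), emb_dim, nf)
  out <- as.vector(rbind(s, e))
  attr(out, "dim_per_frame") <- sal_dim + emb_dim
  attr(out, "n_frames") <- nf
  out
}

#' Correlate per-participant decoding accuracies with behavioral scores
#'
#' Pearson correlations (with two-sided p-values) between each
#' signal-detection measure and the supplied accuracies; zero-variance
#' inputs yield a flagged undefined r.
#'
#' @param accuracies named numeric vector, one accuracy per participant.
#' @param behavior data.frame with `participant_id` and the measure
#'   columns (default `d_prime` and `criterion_c`, as produced by
#'   [dprime_criterion()]).
#' @param measures columns of `behavior` to correlate against.
#' @return data.frame (measure, r, p, n, flagged).
#' @export
correlate_behavior <- function(accuracies, behavior,
                               measures = c("d_prime", "criterion_c")) {
  stopifnot(!is.null(names(accuracies)),
            "participant_id" %in% names(behavior))
  ids <- intersect(names(accuracies), behavior$participant_id)
  if (length(ids) < 3L) stop("need at least 3 matched participants")
  acc <- accuracies[ids]
  rows <- lapply(measures, function(m) {
    v <- behavior[[m]][match(ids, behavior$participant_id)]
    if (sd(acc) == 0 || sd(v) == 0) {
      data.frame(measure = m, r = NA_real_, p = NA_real_,
                 n = length(ids), flagged = TRUE)
    } else {
      ct <- cor.test(acc, v)
      data.frame(measure = m, r = unname(ct$estimate), p = ct$p.value,
                 n = length(ids), flagged = FALSE)
    }
  })
  do.call(rbind, rows)
}
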