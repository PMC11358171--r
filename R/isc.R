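# Inter-subject correlation of time-concatenated feature streams, within
# and between groups, full-clip and time-resolved.

#' Z-score feature channels across all clips and participants
#'
#' Pools every value of a channel over the clip x participant x frame
#' axes and standardises it (population-sd convention, divide by N), so
#' all channels share a common scale before correlation.
#'
#' @param x matrix of frame-major feature rows (rows = participant x clip
#'   combinations, columns = frames * n_channels), or a list of such
#'   matrices (one per clip) which is standardised jointly.
#' @param n_channels features per frame (6 for the saliency stream).
#' @return same structure with each channel standardised; errors naming
#'   the channel if one is constant.
#' @export
znorm_channels <- function(x, n_channels = 6L) {
  was_list <- is.list(x)
  mats <- if (was_list) x else list(x)
  ch_names <- if (n_channels == 6L) saliency_channels() else
    paste0("ch", seq_len(n_channels))
  stats_per_channel <- lapply(seq_len(n_channels), function(ch) {
    vals <- unlist(lapply(mats, function(m) {
      m[, seq.int(ch, ncol(m), by = n_channels), drop = FALSE]
    }))
    mu <- mean(vals)
    sg <- sqrt(mean((vals - mu)^2))  # population sd
    if (sg == 0) stop("constant feature channel: ", ch_names[ch])
    c(mu, sg)
  })
  out <- lapply(mats, function(m) {
    for (ch in seq_len(n_channels)) {
      idx <- seq.int(ch, ncol(m), by = n_channels)
      st <- stats_per_channel[[ch]]
      m[, idx] <- (m[, idx] - st[1]) / st[2]
    }
    m
  })
  if (was_list) out else out[[1]]
}

#' Within-group mean pairwise inter-subject correlation for one clip
#'
#' Pearson correlation of the time-concatenated feature vectors for every
#' within-group pair of participants; the group value is the mean over
#' its n(n-1)/2 pairs. Zero-variance rows are excluded pairwise with a
#' warning.
#'
#' @param rows participants x features matrix (one clip).
#' @param groups group label per participant.
#' @return named numeric vector of per-group mean r, with attribute
#'   `n_pairs`.
#' @export
pairwise_isc <- function(rows, groups) {
  rows <- as.matrix(rows)
  groups <- as.character(groups)
  stopifnot(nrow(rows) == length(groups))
  sds <- apply(rows, 1, sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " zero-variance participant row(s)")
  }
  out <- numeric(0)
  np <- integer(0)
  for (g in unique(groups)) {
    idx <- which(groups == g & sds > 0)
    if (length(idx) < 2L) stop("need >= 2 usable participants in group ", g)
    cm <- cor(t(rows[idx, , drop = FALSE]))
    rs <- cm[lower.tri(cm)]
    out[g] <- mean(rs)
    np[g] <- length(rs)
  }
  attr(out, "n_pairs") <- np
  out
}

#' Time-resolved within-group ISC
#'
#' Applies [pairwise_isc()] to disjoint time chunks (default 2 s: eight
#' chunks of a 16-s clip) and compares groups per chunk with a
#' two-sample t-test on Fisher-z-transformed pairwise correlations at a
#' Bonferroni-adjusted alpha (0.05 / chunks = 0.00625 for eight).
#'
#' @param rows participants x (frames * n_channels) matrix for one clip.
#' @param groups group label per participant.
#' @param n_channels features per frame.
#' @param frames_per_chunk chunk length in frames (50 at 25 fps for 2-s
#'   chunks); a trailing remainder shorter than 2 frames is an error.
#' @param alpha family-wise alpha.
#' @return data.frame (chunk, per-group mean r columns, p,
#'   significant); adjusted alpha attached as `alpha_adjusted`.
#' @export
time_resolved_isc <- function(rows, groups, n_channels = 6L,
                              frames_per_chunk = 50L, alpha = 0.05) {
  rows <- as.matrix(rows)
  n_frames <- ncol(rows) %/% n_channels
  if (frames_per_chunk < 2L) stop("chunks must span at least 2 frames")
  n_chunks <- ceiling(n_frames / frames_per_chunk)
  rem <- n_frames - (n_chunks - 1L) * frames_per_chunk
  if (rem < 2L) stop("trailing chunk shorter than 2 frames")
  gl <- sort(unique(as.character(groups)))
  alpha_adj <- alpha / n_chunks
  res <- lapply(seq_len(n_chunks), function(k) {
    f0 <- (k - 1L) * frames_per_chunk + 1L
    f1 <- min(k * frames_per_chunk, n_frames)
    cols <- ((f0 - 1L) * n_channels + 1L):(f1 * n_channels)
    sub <- rows[, cols, drop = FALSE]
    isc <- pairwise_isc(sub, groups)
    # group comparison on Fisher-z pairwise correlations
    zs <- lapply(gl, function(g) {
      idx <- which(as.character(groups) == g & apply(sub, 1, sd) > 0)
      cm <- cor(t(sub[idx, , drop = FALSE]))
      atanh(pmin(pmax(cm[lower.tri(cm)], -0.999999), 0.999999))
    })
    p <- tryCatch(t.test(zs[[1]], zs[[2]])$p.value, error = function(e) NA)
    row <- data.frame(chunk = k, p = p,
                      significant = !is.na(p) && p < alpha_adj)
    for (g in gl) row[[paste0("isc_", g)]] <- unname(isc[g])
    row
  })
  out <- do.call(rbind, res)
  attr(out, "alpha_adjusted") <- alpha_adj
  out
}

#' Per-participant correlation with own-group and other-group mean
#' features
#'
#' For one clip, each participant's feature row is correlated with the
#' mean feature row of their own group (leaving themselves out by
#' default, to avoid self-correlation inflation) and with the mean of
#' the other group.
#'
#' @param rows participants x features matrix (one clip).
#' @param groups group label per participant (exactly two groups).
#' @param leave_self_out exclude the participant from their own-group
#'   mean (default `TRUE`; requires group sizes >= 2).
#' @return data.frame (participant, group, own_r, other_r).
#' @export
intergroup_correlation <- function(rows, groups, leave_self_out = TRUE) {
  rows <- as.matrix(rows)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  stopifnot(length(gl) == 2L)
  if (leave_self_out && min(table(groups)) < 2L) {
    stop("leave-self-out own-group mean requires group sizes >= 2")
  }
  gmean <- lapply(gl, function(g) {
    colMeans(rows[groups == g, , drop = FALSE])
  })
  names(gmean) <- gl
  res <- lapply(seq_len(nrow(rows)), function(i) {
    g <- groups[i]
    other <- setdiff(gl, g)
    own_mean <- if (leave_self_out) {
      colMeans(rows[setdiff(which(groups == g), i), , drop = FALSE])
    } else {
      gmean[[g]]
    }
    data.frame(participant = i, group = g,
               own_r = cor(rows[i, ], own_mean),
               other_r = cor(rows[i, ], gmean[[other]]))
  })
  do.call(rbind, res)
}
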