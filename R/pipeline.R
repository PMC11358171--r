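# Glue: run patch extraction + feature extraction over a cohort, and
# plain-text I/O for gaze traces and ratings.

#' Per-clip feature matrices for a cohort
#'
#' Runs gaze-centered patch extraction and the chosen feature stream for
#' every participant on every clip, returning one participants x
#' (frames * dim) matrix per clip — the input format of the decoding and
#' ISC analyses.
#'
#' @param clips list of `video_clip`.
#' @param traces list of `gaze_trace` covering every participant x clip
#'   pair (as from [generate_cohort_gaze()]).
#' @param stream `"saliency"` (6 features/frame, full frame rate) or
#'   `"embedding"` (backend features on the frame-downsampled grid).
#' @param window_px patch side in pixels.
#' @param config [saliency_config()] for the saliency stream.
#' @param backend [embedding_backend()] for the embedding stream.
#' @param embed_factor temporal downsampling factor before embedding
#'   (default 10).
#' @return list with one element per clip: `features` (matrix),
#'   `participants`, `groups`, `clip_id`, `category`, `dim_per_frame`,
#'   `n_frames`.
#' @export
cohort_feature_matrices <- function(clips, traces,
                                    stream = c("saliency", "embedding"),
                                    window_px = 75L,
                                    config = saliency_config(),
                                    backend = embedding_backend(),
                                    embed_factor = 10L) {
  stream <- match.arg(stream)
  by_clip <- split(traces, vapply(traces, `[[`, character(1), "clip_id"))
  lapply(clips, function(clip) {
    cid <- clip$spec$clip_id
    tr <- by_clip[[cid]]
    if (is.null(tr)) stop("no traces for clip ", cid)
    rows <- lapply(tr, function(trace) {
      seq <- extract_patch_sequence(clip, trace, window_px)
      if (stream == "saliency") {
        saliency_feature_row(run_saliency_sequence(seq, config))
      } else {
        embed_sequence(downsample_frames(seq, embed_factor), backend)
      }
    })
    feats <- do.call(rbind, rows)
    dim_pf <- if (stream == "saliency") 6L else backend$output_dim
    list(
      features = feats,
      participants = vapply(tr, `[[`, character(1), "participant_id"),
      groups = vapply(tr, `[[`, character(1), "group"),
      clip_id = cid, category = clip$spec$category,
      dim_per_frame = dim_pf,
      n_frames = ncol(feats) %/% dim_pf
    )
  })
}

#' Group decoding across a whole clip set
#'
#' Applies cumulative-window leave-one-out decoding to every clip's
#' feature matrix, summarises each clip by its maximum-window accuracy
#' and tests each action category against chance.
#'
#' @param feature_mats output of [cohort_feature_matrices()].
#' @param step window step in frames on the stream's frame grid (50 for
#'   saliency at 25 fps, 5 on the 10x-downsampled embedding grid).
#' @param mixing_alpha,seed,nfolds passed to [loo_group_decode()].
#' @param mode window mode, see [build_windows()].
#' @return list with `per_clip` (data.frame clip_id, category, max
#'   accuracy, max window), `window_accuracies` (clips x windows),
#'   `tests` (from [test_vs_chance()]), `fits` (per clip).
#' @export
decode_group_membership <- function(feature_mats, step, mixing_alpha = 1,
                                    seed = 1L, nfolds = 5L,
                                    mode = "cumulative") {
  stopifnot(length(feature_mats) > 0)
  res <- lapply(seq_along(feature_mats), function(i) {
    fm <- feature_mats[[i]]
    windows <- build_windows(fm$n_frames, step, mode)
    decode_clip_windows(fm$features, fm$groups, windows,
                        fm$dim_per_frame, mixing_alpha = mixing_alpha,
                        seed = seed + i - 1L, nfolds = nfolds)
  })
  per_clip <- data.frame(
    clip_id = vapply(feature_mats, `[[`, character(1), "clip_id"),
    category = vapply(feature_mats, `[[`, character(1), "category"),
    accuracy = vapply(res, `[[`, numeric(1), "max"),
    window = vapply(res, `[[`, numeric(1), "max_window")
  )
  tests <- if (length(unique(per_clip$category)) > 1 &&
               min(table(per_clip$category)) >= 2) {
    test_vs_chance(per_clip$accuracy, per_clip$category)
  }
  list(
    per_clip = per_clip,
    window_accuracies = do.call(rbind, lapply(res, `[[`, "per_window")),
    tests = tests,
    fits = lapply(res, `[[`, "fits")
  )
}

#' Within-group ISC across a whole clip set
#'
#' Z-normalises channels jointly across clips and participants, then
#' computes per-clip within-group mean pairwise correlations.
#'
#' @param feature_mats output of [cohort_feature_matrices()].
#' @param znorm standardise channels first (default `TRUE`).
#' @return data.frame with one row per clip x group.
#' @export
cohort_isc <- function(feature_mats, znorm = TRUE) {
  mats <- lapply(feature_mats, `[[`, "features")
  if (znorm) {
    mats <- znorm_channels(mats, feature_mats[[1]]$dim_per_frame)
  }
  rows <- lapply(seq_along(mats), function(i) {
    fm <- feature_mats[[i]]
    isc <- pairwise_isc(mats[[i]], fm$groups)
    data.frame(clip_id = fm$clip_id, category = fm$category,
               group = names(isc), isc = as.numeric(isc))
  })
  do.call(rbind, rows)
}

#' Write / read gaze traces as CSV
#'
#' Columns: participant_id, group, clip_id, frame (0-based), x, y
#' (0-based pixels), valid (0/1).
#'
#' @param traces list of `gaze_trace`.
#' @param path file path.
#' @export
write_gaze_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(participant_id = tr$participant_id, group = tr$group,
               clip_id = tr$clip_id, frame = seq_along(tr$x) - 1L,
               x = tr$x, y = tr$y, valid = as.integer(tr$valid))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[c("participant_id", "clip_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$participant_id == keys$participant_id[i] &
      df$clip_id == keys$clip_id[i]
    sub <- df[sel, ][order(df$frame[sel]), ]
    structure(list(
      participant_id = keys$participant_id[i], group = sub$group[1],
      clip_id = keys$clip_id[i], x = sub$x, y = sub$y,
      valid = sub$valid == 1
    ), class = "gaze_trace")
  })
}

#' Write a stimulus-set manifest as JSON
#'
#' Records every clip's spec and seed so a stimulus set can be
#' regenerated exactly.
#'
#' @param clips list of `video_clip`.
#' @param path file path.
#' @param cohort optional [cohort_spec()] to record alongside.
#' @export
write_manifest <- function(clips, path, cohort = NULL) {
  manifest <- list(
    clips = lapply(clips, function(cl) {
      c(unclass(cl$spec), list(seed = cl$seed))
    }),
    cohort = if (!is.null(cohort)) unclass(cohort)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
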