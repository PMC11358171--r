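#' Extract a gaze-centered patch sequence from a clip
#'
#' For every valid frame, crops a `window_px` x `window_px` region of the
#' frame centered on the rounded gaze position; frames with missing gaze
#' yield all-zero patches (zeros are what the downstream models consume
#' for missing data). Gaze coordinates are 0-based with x = column,
#' y = row and origin at the top-left; the crop spans rows
#' `round(y) - floor(w/2) .. + w - 1`, so for odd `w` the patch is
#' symmetric about the fixation and for even `w` the fixation maps to
#' index `w/2` (half-open crop).
#'
#' @param clip a `video_clip` (frames rendered lazily) or a
#'   T x H x W x 3 array.
#' @param trace a `gaze_trace` whose length matches the clip frame count.
#' @param window_px patch side in pixels (default 75; 38 and 150 are the
#'   usual robustness alternatives).
#' @param boundary `"zero"` pads out-of-frame crop regions with zeros
#'   (default); `"clamp"` clamps the crop window inside the frame.
#' @return object of class `patch_sequence`: list with `patches`
#'   (T x w x w x 3 array), `valid`, `clip_id`, `participant_id`,
#'   `window_px`.
#' @export
extract_patch_sequence <- function(clip, trace, window_px = 75L,
                                   boundary = c("zero", "clamp")) {
  boundary <- match.arg(boundary)
  is_array <- is.array(clip)
  if (is_array) {
    stopifnot(length(dim(clip)) == 4L)
    tt <- dim(clip)[1]
    h <- dim(clip)[2]
    w <- dim(clip)[3]
  } else {
    stopifnot(inherits(clip, "video_clip"))
    tt <- clip$spec$n_frames
    h <- clip$spec$height
    w <- clip$spec$width
    if (!is.null(trace$clip_id) && trace$clip_id != clip$spec$clip_id) {
      stop("trace/clip id mismatch: ", trace$clip_id, " vs ",
           clip$spec$clip_id)
    }
  }
  window_px <- as.integer(window_px)
  if (window_px < 1) stop("window_px must be positive")
  if (window_px > h || window_px > w) {
    stop("window_px larger than the frame")
  }
  if (length(trace$x) != tt) {
    stop("trace length does not match clip frame count")
  }
  half <- window_px %/% 2L
  patches <- array(0, dim = c(tt, window_px, window_px, 3L))
  for (t in seq_len(tt)) {
    if (!trace$valid[t]) next
    frame <- if (is_array) clip[t, , , , drop = TRUE] else clip_frame(clip, t)
    cx <- round(trace$x[t])  # 0-based column
    cy <- round(trace$y[t])  # 0-based row
    r0 <- cy - half          # 0-based first row of crop
    c0 <- cx - half
    if (boundary == "clamp") {
      r0 <- min(max(r0, 0L), h - window_px)
      c0 <- min(max(c0, 0L), w - window_px)
    }
    rows <- (r0 + 1L):(r0 + window_px)
    cols <- (c0 + 1L):(c0 + window_px)
    rok <- rows >= 1L & rows <= h
    cok <- cols >= 1L & cols <= w
    if (any(rok) && any(cok)) {
      patches[t, which(rok), which(cok), ] <-
        frame[rows[rok], cols[cok], , drop = FALSE]
    }
  }
  structure(list(
    patches = patches, valid = trace$valid,
    clip_id = if (is_array) trace$clip_id else clip$spec$clip_id,
    participant_id = trace$participant_id,
    window_px = window_px
  ), class = "patch_sequence")
}

#' Temporally downsample a patch sequence
#'
#' Keeps frames at 0-based indices `0, factor, 2 * factor, ...` (i.e. one
#' frame out of every `factor`), subsampling the validity mask identically.
#' The default factor of 10 turns a 400-frame sequence into the 40 frames
#' used for semantic embedding.
#'
#' @param seq a `patch_sequence`.
#' @param factor positive integer sampling period.
#' @return a `patch_sequence` with `ceiling(T / factor)` frames.
#' @export
downsample_frames <- function(seq, factor = 10L) {
  stopifnot(inherits(seq, "patch_sequence"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  keep <- seq.int(1L, dim(seq$patches)[1], by = factor)
  out <- seq
  out$patches <- seq$patches[keep, , , , drop = FALSE]
  out$valid <- seq$valid[keep]
  out
}

#' @export
print.patch_sequence <- function(x, ...) {
  cat(sprintf("<patch_sequence %s/%s: %d frames of %dx%d, %d invalid>\n",
              x$participant_id, x$clip_id, dim(x$patches)[1], x$window_px,
              x$window_px, sum(!x$valid)))
  invisible(x)
}
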