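# Semantic patch embeddings through a pluggable backend. The default
# backend is a deterministic seeded random projection (downsampled pixels
# through a fixed Gaussian linear map plus ReLU), a stand-in for the
# penultimate fully connected layer of a pretrained object-recognition
# CNN; a real CNN backend would need downloaded weights and is therefore
# not bundled.

#' Create an embedding backend
#'
#' @param name `"stub"` (deterministic seeded random projection; always
#'   available) or `"cnn"` (penultimate-layer features of a pretrained
#'   object-recognition network; not bundled — requesting it raises a
#'   capability error naming the stub alternative).
#' @param output_dim embedding length (default 4096, the size of a
#'   classic FC7 layer).
#' @param input_grid the patch is block-averaged to
#'   `input_grid x input_grid x 3` before projection.
#' @param seed seed of the fixed projection matrix.
#' @return object of class `embedding_backend`.
#' @export
embedding_backend <- function(name = c("stub", "cnn"), output_dim = 4096L,
                              input_grid = 8L, seed = 2024L) {
  name <- match.arg(name)
  if (name == "cnn") {
    stop("the pretrained CNN backend requires downloaded network ",
         "weights and is not bundled; use embedding_backend(\"stub\") ",
         "for a deterministic drop-in", call. = FALSE)
  }
  output_dim <- as.integer(output_dim)
  input_grid <- as.integer(input_grid)
  stopifnot(output_dim >= 1L, input_grid >= 1L)
  in_dim <- 3L * input_grid^2
  w <- with_seed(seed, matrix(rnorm(output_dim * in_dim, 0,
                                    1 / sqrt(in_dim)),
                              output_dim, in_dim))
  structure(list(
    name = "stub", output_dim = output_dim, input_grid = input_grid,
    seed = seed, weights = w, deterministic = TRUE
  ), class = "embedding_backend")
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend %s: dim %d, grid %d, %s>\n", x$name,
              x$output_dim, x$input_grid,
              if (x$deterministic) "deterministic" else "stochastic"))
  invisible(x)
}

# Block-average an H x W matrix down to g x g (bilinear resize).
downsample_plane <- function(m, g) {
  if (nrow(m) == g && ncol(m) == g) return(m)
  resize_bilinear(m, g, g)
}

#' Embed a single patch
#'
#' The stub backend resizes the patch to its input grid, flattens it and
#' applies its fixed linear projection followed by half-wave
#' rectification (mirroring a post-ReLU fully connected layer); a zero
#' patch maps to the zero vector.
#'
#' @param patch w x w x 3 array in \[0, 1\].
#' @param backend an [embedding_backend()].
#' @return numeric vector of length `backend$output_dim`.
#' @export
embed_patch <- function(patch, backend = embedding_backend()) {
  stopifnot(inherits(backend, "embedding_backend"),
            length(dim(patch)) == 3L, dim(patch)[3] == 3L)
  g <- backend$input_grid
  v <- c(downsample_plane(patch[, , 1], g),
         downsample_plane(patch[, , 2], g),
         downsample_plane(patch[, , 3], g))
  out <- as.vector(backend$weights %*% v)
  out[out < 0] <- 0
  out
}

#' Embed a (frame-downsampled) patch sequence into one feature row
#'
#' Per-frame embedding vectors are concatenated in frame order; invalid
#' frames contribute zero blocks. Feed sequences through
#' [downsample_frames()] first (factor 10: 400 raw frames -> 40
#' embedding frames).
#'
#' @param seq a `patch_sequence`.
#' @param backend an [embedding_backend()].
#' @return numeric vector of length `T * output_dim`, with attributes
#'   `dim_per_frame` and `n_frames`.
#' @export
embed_sequence <- function(seq, backend = embedding_backend()) {
  stopifnot(inherits(seq, "patch_sequence"))
  tt <- dim(seq$patches)[1]
  d <- backend$output_dim
  out <- numeric(tt * d)
  for (t in seq_len(tt)) {
    if (!seq$valid[t]) next
    patch <- seq$patches[t, , , , drop = TRUE]
    dim(patch) <- dim(seq$patches)[2:4]
    out[((t - 1L) * d + 1L):(t * d)] <- embed_patch(patch, backend)
  }
  attr(out, "dim_per_frame") <- d
  attr(out, "n_frames") <- tt
  out
}
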