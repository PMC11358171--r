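# Six-channel spatiotemporal saliency model: DKL-style cone-opponent
# luminance/color channels, Gabor orientation energy, multi-scale LoG
# texture energy and optical-flow magnitude; Gaussian pyramids with
# iterative center-surround activation; per-channel normalization factors
# and final maps carried through a 3-frame temporal buffer with 0.5 decay.

# RGB (treated as linear) -> LMS cone responses: sRGB/D65 primaries into
# Hunt-Pointer-Estevez cone fundamentals.
rgb_to_lms_matrix <- function() {
  m_xyz <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), 3, 3, byrow = TRUE)
  m_hpe <- matrix(c(
    0.38971, 0.68898, -0.07868,
    -0.22981, 1.18340, 0.04641,
    0.00000, 0.00000, 1.00000
  ), 3, 3, byrow = TRUE)
  m_hpe %*% m_xyz
}

#' Configuration of the saliency model
#'
#' All filter-bank and temporal parameters in one place. Spatial scales
#' are expressed as fractions of the patch side so the same configuration
#' applies to 38-, 75- or 150-px windows.
#'
#' @param gabor_orientations orientations of the Gabor bank, radians.
#' @param gabor_wavelength_frac carrier wavelengths as fractions of the
#'   patch side.
#' @param texture_sigma_frac LoG scales as fractions of the patch side.
#' @param pyramid_levels number of pyramid levels (scales 1, 1/2, ...).
#' @param pyramid_blur_sigma Gaussian blur sd applied before each
#'   downsampling.
#' @param activation_passes iterations of the center-surround operator.
#' @param activation_log_sigma,activation_blur_sigma LoG and blur sds of
#'   one center-surround pass.
#' @param salient_quantile maps values at or above this quantile count as
#'   the "salient region" when computing normalization factors.
#' @param factor_epsilon raw normalization factors at or below this value
#'   mark the channel as (numerically) empty: without the floor, the
#'   division by the factor would amplify float-level residue of constant
#'   maps into order-1 saliency.
#' @param decay_weights weights of (current, previous, one-before) frames
#'   in the temporal buffer.
#' @param logistic_k,logistic_x0 slope and midpoint of the logistic
#'   contrast squashing of the final map. Defaults are calibrated so the
#'   map distribution spans roughly \[0.05, 0.95\] on the synthetic
#'   stimulus fixtures.
#' @param flow_window side of the box neighbourhood of the local
#'   least-squares (orientation-tensor) flow estimator.
#' @param flow_reg diagonal regulariser of the flow normal equations.
#' @param flow_max_frac flow magnitudes are clamped at this fraction of
#'   the patch side per frame (guards against near-singular local
#'   systems).
#' @return list of class `saliency_config`.
#' @export
saliency_config <- function(gabor_orientations = c(0, 45, 90, 135) * pi / 180,
                            gabor_wavelength_frac = c(1 / 4, 1 / 8),
                            texture_sigma_frac = c(1 / 16, 1 / 8, 1 / 4),
                            pyramid_levels = 4L,
                            pyramid_blur_sigma = 1,
                            activation_passes = 5L,
                            activation_log_sigma = 1.2,
                            activation_blur_sigma = 1,
                            salient_quantile = 0.9,
                            factor_epsilon = 1e-10,
                            decay_weights = c(1, 0.5, 0.25),
                            logistic_k = 154,
                            logistic_x0 = 0.0192,
                            flow_window = 5L,
                            flow_reg = 1e-4,
                            flow_max_frac = 0.5) {
  structure(list(
    lms = rgb_to_lms_matrix(),
    gray_weights = c(0.2126, 0.7152, 0.0722),
    gabor_orientations = gabor_orientations,
    gabor_wavelength_frac = gabor_wavelength_frac,
    texture_sigma_frac = texture_sigma_frac,
    pyramid_levels = as.integer(pyramid_levels),
    pyramid_blur_sigma = pyramid_blur_sigma,
    activation_passes = as.integer(activation_passes),
    activation_log_sigma = activation_log_sigma,
    activation_blur_sigma = activation_blur_sigma,
    salient_quantile = salient_quantile,
    factor_epsilon = factor_epsilon,
    decay_weights = decay_weights,
    logistic_k = logistic_k,
    logistic_x0 = logistic_x0,
    flow_window = as.integer(flow_window),
    flow_reg = flow_reg,
    flow_max_frac = flow_max_frac
  ), class = "saliency_config")
}

#' Names and order of the six saliency channels
#' @export
saliency_channels <- function() {
  c("luminance", "red_green", "yellow_blue", "orientation", "texture",
    "flow_mag")
}

# Precompute every kernel the model needs for a given patch side, so the
# per-frame loop does not rebuild them.
make_kernel_bank <- function(config, side) {
  gabor <- list()
  for (frac in config$gabor_wavelength_frac) {
    wl <- max(2, side * frac)
    for (th in config$gabor_orientations) {
      gabor[[length(gabor) + 1L]] <- gabor_kernel(th, wl)
    }
  }
  texture <- lapply(config$texture_sigma_frac, function(frac) {
    log_kernel(max(0.5, side * frac))
  })
  list(
    gabor = gabor, texture = texture,
    act_log = log_kernel(config$activation_log_sigma),
    act_gauss = gaussian_kernel(config$activation_blur_sigma),
    pyr_gauss = gaussian_kernel(config$pyramid_blur_sigma)
  )
}

# Grayscale (luma) of an H x W x 3 patch.
to_gray <- function(patch, w = c(0.2126, 0.7152, 0.0722)) {
  patch[, , 1] * w[1] + patch[, , 2] * w[2] + patch[, , 3] * w[3]
}

# Optical-flow magnitude between two grayscale frames via the local
# least-squares orientation-tensor (Lucas-Kanade-style) estimator.
# Magnitudes are clamped at `max_mag` px/frame: where the local gradient
# system is near-singular (aperture problem) the unregularised solution
# can explode to nonphysical speeds.
flow_magnitude <- function(prev_gray, gray, window = 5L, reg = 1e-4,
                           max_mag = Inf) {
  stopifnot(all(dim(prev_gray) == dim(gray)))
  dxk <- matrix(c(-0.5, 0, 0.5), 1, 3)
  dyk <- matrix(c(-0.5, 0, 0.5), 3, 1)
  avg <- (prev_gray + gray) / 2
  ix <- filter2d(avg, dxk)
  iy <- filter2d(avg, dyk)
  it <- gray - prev_gray
  box <- matrix(1, window, window)
  sxx <- filter2d(ix * ix, box) + reg
  syy <- filter2d(iy * iy, box) + reg
  sxy <- filter2d(ix * iy, box)
  sxt <- filter2d(ix * it, box)
  syt <- filter2d(iy * it, box)
  det <- sxx * syy - sxy * sxy
  vx <- (-syy * sxt + sxy * syt) / det
  vy <- (sxy * sxt - sxx * syt) / det
  pmin(sqrt(vx^2 + vy^2), max_mag)
}

#' Decompose a patch into the six saliency feature channels
#'
#' Luminance is the sum of long and medium cone responses, red-green is
#' long minus medium, yellow-blue is (long + medium) minus short, after a
#' fixed linear RGB-to-LMS transform. Orientation is the max quadrature
#' energy of a Gabor bank on the grayscale patch, texture the max absolute
#' response of a LoG bank with scales proportional to the patch side, and
#' flow the optical-flow magnitude against the previous patch (zero on the
#' first frame).
#'
#' @param patch w x w x 3 RGB array in \[0, 1\].
#' @param prev_patch previous frame's patch, same shape, or `NULL`.
#' @param config a [saliency_config()].
#' @param bank precomputed kernel bank (internal use; built from `config`
#'   when `NULL`).
#' @return named list of six w x w matrices, in [saliency_channels()]
#'   order.
#' @export
decompose_channels <- function(patch, prev_patch = NULL,
                               config = saliency_config(), bank = NULL) {
  stopifnot(length(dim(patch)) == 3L, dim(patch)[3] == 3L)
  if (!is.null(prev_patch) && !all(dim(prev_patch) == dim(patch))) {
    stop("previous patch shape does not match current patch")
  }
  nr <- dim(patch)[1]
  nc <- dim(patch)[2]
  side <- min(nr, nc)
  if (is.null(bank)) bank <- make_kernel_bank(config, side)
  m <- config$lms
  rgbm <- matrix(patch, ncol = 3L)
  lms <- rgbm %*% t(m)
  lum <- matrix(lms[, 1] + lms[, 2], nr, nc)
  rg <- matrix(lms[, 1] - lms[, 2], nr, nc)
  yb <- matrix(lms[, 1] + lms[, 2] - lms[, 3], nr, nc)
  gray <- to_gray(patch, config$gray_weights)

  ori <- matrix(0, nr, nc)
  for (gk in bank$gabor) {
    e <- filter2d(gray, gk$even)
    o <- filter2d(gray, gk$odd)
    ori <- pmax(ori, sqrt(e^2 + o^2))
  }

  tex <- matrix(0, nr, nc)
  for (tk in bank$texture) {
    tex <- pmax(tex, abs(filter2d(gray, tk)))
  }

  flow <- if (is.null(prev_patch)) {
    matrix(0, nr, nc)
  } else {
    flow_magnitude(to_gray(prev_patch, config$gray_weights), gray,
                   config$flow_window, config$flow_reg,
                   max_mag = config$flow_max_frac * side)
  }
  list(luminance = lum, red_green = rg, yellow_blue = yb,
       orientation = ori, texture = tex, flow_mag = flow)
}

#' Build a Gaussian pyramid of a feature map
#'
#' Level sizes follow ceiling-halving: a 75-px side gives 75, 38, 19, 10.
#'
#' @param map numeric matrix, at least 8 x 8 for the default 4 levels.
#' @param levels number of levels.
#' @param blur_sigma Gaussian blur sd applied before each downsampling.
#' @param kernel optional precomputed blur kernel (overrides
#'   `blur_sigma`).
#' @return list of `levels` matrices at scales 1, 1/2, 1/4, ...
#' @export
build_pyramid <- function(map, levels = 4L, blur_sigma = 1, kernel = NULL) {
  stopifnot(is.matrix(map))
  if (min(dim(map)) < 2^(levels - 1L)) {
    stop("map too small for ", levels, " pyramid levels")
  }
  out <- vector("list", levels)
  out[[1]] <- map
  g <- if (is.null(kernel)) gaussian_kernel(blur_sigma) else kernel
  for (l in seq_len(levels - 1L)) {
    out[[l + 1L]] <- decimate2(filter2d(out[[l]], g))
  }
  out
}

#' Iterative center-surround activation of a pyramid stack
#'
#' Each map undergoes `passes` iterations of LoG convolution,
#' half-wave rectification and Gaussian blur, enhancing regions that
#' stand out from their surround.
#'
#' @param stack list of pyramid-level matrices (one channel), or a single
#'   matrix.
#' @param config a [saliency_config()].
#' @param bank precomputed kernel bank (internal use).
#' @return same structure with activated maps.
#' @export
center_surround_activate <- function(stack, config = saliency_config(),
                                     bank = NULL) {
  single <- is.matrix(stack)
  if (single) stack <- list(stack)
  lk <- if (is.null(bank)) log_kernel(config$activation_log_sigma) else
    bank$act_log
  gk <- if (is.null(bank)) gaussian_kernel(config$activation_blur_sigma) else
    bank$act_gauss
  out <- lapply(stack, function(m) {
    for (i in seq_len(config$activation_passes)) {
      m <- filter2d(m, lk)
      m[m < 0] <- 0
      m <- filter2d(m, gk)
    }
    m
  })
  if (single) out[[1]] else out
}

#' Create an empty temporal buffer
#'
#' The buffer holds the per-frame saliency maps and the blended
#' normalization factors of up to the two preceding frames; entries are
#' most-recent first.
#' @export
new_temporal_buffer <- function() {
  structure(list(maps = list(), factors = list()), class = "temporal_buffer")
}

# Weighted blend of the current value with up to two buffered values,
# using decay weights (1, 0.5, 0.25) normalised over available entries.
decay_blend <- function(current, past, weights) {
  n_past <- min(length(past), length(weights) - 1L)
  acc <- current * weights[1]
  wsum <- weights[1]
  for (i in seq_len(n_past)) {
    acc <- acc + past[[i]] * weights[i + 1L]
    wsum <- wsum + weights[i + 1L]
  }
  list(mean = acc / wsum, sum = acc)
}

#' Normalize activated pyramid stacks and export per-channel factors
#'
#' Per channel, the raw factor is the sum of map values at or above the
#' configured salience quantile, pooled over pyramid levels. The raw
#' factor is blended with the factors of the previous two frames by the
#' 0.5-decay weighted mean (so a static input is a fixed point), every
#' map of the channel is divided by the blended factor, and the six
#' blended factors are the frame's exported features. All-zero channels
#' are flagged: their exported factor is 0 and their scaling divisor 1
#' (a no-op), so blank missing-data frames export all-zero features.
#'
#' @param stacks named list (six channels) of pyramid-level lists.
#' @param buffer a [new_temporal_buffer()] or the buffer returned by the
#'   previous frame's processing.
#' @param config a [saliency_config()].
#' @return list with `stacks` (normalized), `factors` (named 6-vector),
#'   `flagged` (logical 6-vector).
#' @export
normalize_stacks <- function(stacks, buffer = new_temporal_buffer(),
                             config = saliency_config()) {
  chans <- names(stacks)
  q <- config$salient_quantile
  raw <- vapply(stacks, function(st) {
    sum(vapply(st, function(m) {
      v <- sort.int(m, method = "quick")  # type-7 quantile, inlined
      h <- (length(v) - 1) * q
      lo <- floor(h)
      thr <- v[lo + 1] * (1 - (h - lo)) + v[min(lo + 2, length(v))] * (h - lo)
      sum(m[m >= thr])
    }, numeric(1)))
  }, numeric(1))
  flagged <- !is.finite(raw) | raw <= config$factor_epsilon
  factors <- numeric(length(raw))
  names(factors) <- chans
  past <- buffer$factors
  for (i in seq_along(raw)) {
    if (flagged[i]) {
      factors[i] <- 0
    } else {
      past_i <- lapply(past, function(f) f[i])
      factors[i] <- decay_blend(raw[i], past_i, config$decay_weights)$mean
    }
  }
  divisor <- ifelse(flagged | factors == 0, 1, factors)
  scaled <- stacks
  for (i in seq_along(scaled)) {
    scaled[[i]] <- lapply(scaled[[i]], function(m) m / divisor[i])
  }
  list(stacks = scaled, factors = factors, flagged = flagged)
}

#' Fuse normalized stacks into the frame's final saliency map
#'
#' Each channel's pyramid levels are upsampled to the base scale, summed
#' and divided by the stack size; the six intermediate maps are summed
#' into the current frame's map; the buffered maps of the previous two
#' frames are added with weights 0.5 and 0.25 (a transient event's
#' contribution therefore halves on each subsequent frame and vanishes
#' after two); and a logistic activation squashes the result to \[0, 1\].
#'
#' @param stacks normalized stacks from [normalize_stacks()].
#' @param buffer temporal buffer.
#' @param config a [saliency_config()].
#' @return list with `final_map` (in \[0, 1\]), `combined_map`
#'   (pre-logistic), `current_map` (this frame only, what enters the
#'   buffer).
#' @export
fuse_saliency <- function(stacks, buffer = new_temporal_buffer(),
                          config = saliency_config()) {
  base_dim <- dim(stacks[[1]][[1]])
  current <- matrix(0, base_dim[1], base_dim[2])
  for (st in stacks) {
    ch <- matrix(0, base_dim[1], base_dim[2])
    for (m in st) ch <- ch + resize_bilinear(m, base_dim[1], base_dim[2])
    current <- current + ch / length(st)
  }
  combined <- decay_blend(current, buffer$maps, config$decay_weights)$sum
  final <- 1 / (1 + exp(-config$logistic_k * (combined - config$logistic_x0)))
  list(final_map = final, combined_map = combined, current_map = current)
}

# Push one frame's current map and blended factors into the buffer.
push_buffer <- function(buffer, current_map, factors) {
  buffer$maps <- c(list(current_map), buffer$maps)[seq_len(
    min(2L, length(buffer$maps) + 1L))]
  buffer$factors <- c(list(factors), buffer$factors)[seq_len(
    min(2L, length(buffer$factors) + 1L))]
  buffer
}

#' Mean saliency within a gaze-centered region
#'
#' @param final_map saliency map in \[0, 1\].
#' @param region optional logical mask or integer index into the map;
#'   default is the full map (the model already runs on gaze-centered
#'   patches).
#' @return scalar mean saliency.
#' @export
saliency_index <- function(final_map, region = NULL) {
  if (is.null(region)) return(mean(final_map))
  vals <- final_map[region]
  if (length(vals) == 0) stop("empty saliency-index region")
  mean(vals)
}

#' Run the saliency model over a patch sequence
#'
#' Stateful pass over the frames of one participant x clip patch
#' sequence, with the temporal buffer initialised empty. Invalid frames
#' are processed as the zero patches they carry. The per-frame exported
#' features are the six blended normalization factors; concatenated over
#' a 400-frame clip they form the 2,400-element saliency vector used for
#' decoding and ISC.
#'
#' @param seq a `patch_sequence`.
#' @param config a [saliency_config()].
#' @param keep_maps if `TRUE`, retain every frame's final map (memory!).
#' @return object of class `saliency_features`: `factors` (T x 6 matrix),
#'   `index` (length-T saliency index), `flagged` (T x 6), and optionally
#'   `final_maps`.
#' @export
run_saliency_sequence <- function(seq, config = saliency_config(),
                                  keep_maps = FALSE) {
  stopifnot(inherits(seq, "patch_sequence"))
  tt <- dim(seq$patches)[1]
  if (tt == 0) stop("empty patch sequence")
  chans <- saliency_channels()
  factors <- matrix(0, tt, 6L, dimnames = list(NULL, chans))
  flagged <- matrix(FALSE, tt, 6L, dimnames = list(NULL, chans))
  index <- numeric(tt)
  maps <- if (keep_maps) vector("list", tt)
  buffer <- new_temporal_buffer()
  prev_patch <- NULL
  bank <- make_kernel_bank(config, min(dim(seq$patches)[2:3]))
  for (t in seq_len(tt)) {
    patch <- seq$patches[t, , , , drop = TRUE]
    dim(patch) <- dim(seq$patches)[2:4]
    ch <- decompose_channels(patch, prev_patch, config, bank)
    stacks <- lapply(ch, build_pyramid, levels = config$pyramid_levels,
                     kernel = bank$pyr_gauss)
    stacks <- lapply(stacks, center_surround_activate, config = config,
                     bank = bank)
    nm <- normalize_stacks(stacks, buffer, config)
    fs <- fuse_saliency(nm$stacks, buffer, config)
    buffer <- push_buffer(buffer, fs$current_map, nm$factors)
    factors[t, ] <- nm$factors
    flagged[t, ] <- nm$flagged
    index[t] <- saliency_index(fs$final_map)
    if (keep_maps) maps[[t]] <- fs$final_map
    prev_patch <- patch
  }
  structure(list(
    factors = factors, index = index, flagged = flagged,
    final_maps = maps, clip_id = seq$clip_id,
    participant_id = seq$participant_id
  ), class = "saliency_features")
}

#' Concatenate per-frame saliency features into one row vector
#'
#' Frame-major order: the six channel factors of frame 1, then frame 2,
#' and so on — 400 frames give a 2,400-element vector.
#'
#' @param feats a `saliency_features` object (or T x 6 matrix).
#' @export
saliency_feature_row <- function(feats) {
  m <- if (inherits(feats, "saliency_features")) feats$factors else feats
  as.vector(t(m))
}
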