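# Signal-detection scoring of violence-likelihood ratings.

#' Score rating outcomes per participant
#'
#' Fight clips rated 4 or more count as hits (misses otherwise);
#' non-fight clips rated 3 or less count as correct rejections (false
#' alarms otherwise). With the default 36-clip set the denominators are
#' 9 signal and 27 noise trials per participant.
#'
#' @param table data.frame with `participant_id`, `category` and
#'   `rating` (integers 1-6), one row per participant x clip, as
#'   produced by [generate_ratings()].
#' @return data.frame (participant_id, hits, misses, fas, crs).
#' @export
score_outcomes <- function(table) {
  stopifnot(all(c("participant_id", "category", "rating") %in%
                  names(table)))
  if (any(!table$rating %in% 1:6)) {
    stop("ratings must be integers between 1 and 6")
  }
  is_fight <- table$category == "fight"
  violent <- table$rating >= 4
  ids <- unique(table$participant_id)
  res <- lapply(ids, function(id) {
    sel <- table$participant_id == id
    data.frame(
      participant_id = id,
      hits = sum(sel & is_fight & violent),
      misses = sum(sel & is_fight & !violent),
      fas = sum(sel & !is_fight & violent),
      crs = sum(sel & !is_fight & !violent)
    )
  })
  do.call(rbind, res)
}

#' Sensitivity d' and criterion C from outcome counts
#'
#' Equal-variance Gaussian model: `d' = qnorm(H) - qnorm(F)` and
#' `C = -(qnorm(H) + qnorm(F)) / 2`. Extreme rates are handled with the
#' log-linear correction (0.5 added to every cell, 1 to every
#' denominator), which keeps both rates strictly inside (0, 1).
#'
#' @param counts data.frame from [score_outcomes()], or the four count
#'   vectors.
#' @param hits,misses,fas,crs alternative direct count inputs.
#' @return data.frame (participant_id if available, hit_rate, fa_rate,
#'   d_prime, criterion_c).
#' @export
dprime_criterion <- function(counts = NULL, hits = NULL, misses = NULL,
                             fas = NULL, crs = NULL) {
  if (!is.null(counts)) {
    hits <- counts$hits
    misses <- counts$misses
    fas <- counts$fas
    crs <- counts$crs
    ids <- counts$participant_id
  } else {
    ids <- NULL
  }
  if (any(c(hits, misses, fas, crs) < 0)) stop("counts must be non-negative")
  n_sig <- hits + misses
  n_noise <- fas + crs
  if (any(n_sig == 0) || any(n_noise == 0)) {
    stop("each participant needs signal and noise trials")
  }
  h <- (hits + 0.5) / (n_sig + 1)
  f <- (fas + 0.5) / (n_noise + 1)
  zh <- qnorm(h)
  zf <- qnorm(f)
  out <- data.frame(hit_rate = h, fa_rate = f, d_prime = zh - zf,
                    criterion_c = -(zh + zf) / 2)
  if (!is.null(ids)) out <- cbind(participant_id = ids, out)
  out
}
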