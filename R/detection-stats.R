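# Detection-overlap and coverage arithmetic for comparing acquisition
# methods and replicates.

#' Sample-overlap statistics of a detection matrix
#'
#' The overlap percent is 100 times the number of analytes detected in all
#' samples divided by the maximum per-sample count (the only simple
#' denominator consistent with the usual reporting of "sample overlap"
#' alongside per-sample detection ranges); the all/mean variant is
#' available via `denominator`.
#'
#' @param matrix Logical matrix or data frame, analytes x samples
#'   (`TRUE` = detected). At least two samples.
#' @param denominator `"max"` (default) or `"mean"` of per-sample counts.
#' @return List: `per_sample` (named counts), `n_all` (detected in every
#'   sample), `percent` (unrounded), `percent_rounded` (nearest integer,
#'   the reporting value), `min`, `max`.
#' @examples
#' m <- cbind(s1 = c(TRUE, TRUE, FALSE), s2 = c(TRUE, TRUE, TRUE))
#' overlap_percent(m)
#' @export
overlap_percent <- function(matrix, denominator = c("max", "mean")) {
  denominator <- match.arg(denominator)
  m <- as.matrix(matrix)
  if (length(m) == 0) stop("empty detection matrix")
  if (ncol(m) < 2) stop("overlap requires at least two samples")
  storage.mode(m) <- "logical"
  per_sample <- colSums(m)
  n_all <- sum(rowSums(m) == ncol(m))
  denom <- switch(denominator, max = max(per_sample), mean = mean(per_sample))
  if (denom == 0) stop("no detections in any sample")
  pct <- 100 * n_all / denom
  list(per_sample = per_sample, n_all = n_all,
       percent = pct, percent_rounded = round(pct),
       min = min(per_sample), max = max(per_sample))
}

#' Percent increase of a count over a reference
#'
#' @param reference_count Positive baseline count.
#' @param new_count New count.
#' @return List: `percent` (unrounded `100 * (new - ref) / ref`) and
#'   `percent_rounded`.
#' @examples
#' percent_increase(72, 172)
#' @export
percent_increase <- function(reference_count, new_count) {
  if (reference_count <= 0) stop("reference count must be positive")
  pct <- 100 * (new_count - reference_count) / reference_count
  list(percent = pct, percent_rounded = round(pct))
}

#' Coverage of a target list relative to a universe
#'
#' @param targeted_count Number of analytes covered (0..universe).
#' @param universe_count Size of the reference universe (> 0).
#' @return List: `percent` and `percent_rounded`.
#' @examples
#' coverage_percent(300, 427)
#' @export
coverage_percent <- function(targeted_count, universe_count) {
  if (universe_count <= 0) stop("universe count must be positive")
  if (targeted_count < 0 || targeted_count > universe_count) {
    stop("targeted count must lie in [0, universe]")
  }
  pct <- 100 * targeted_count / universe_count
  list(percent = pct, percent_rounded = round(pct))
}
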