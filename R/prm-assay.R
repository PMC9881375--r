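# PRM assay construction from a spectral library and retention-time
# scheduling of targets into injections under concurrency caps.

#' Build PRM assay targets from a spectral library
#'
#' For each peptide, selects its most intense precursor charge state (total
#' fragment intensity; ties broken by lower charge) and that charge's
#' `top_k` most intense fragment ions (ties broken by fragment label, so
#' selection is deterministic).
#'
#' @param library Tibble with one row per library fragment: `peptide`,
#'   `charge`, `fragment`, `intensity`, `ref_rt` (minutes; constant within
#'   a peptide ion). Optional columns `modifications` and `is_standard` are
#'   carried along.
#' @param top_k Fragments to retain per target (default 6).
#' @return Tibble of assay targets, one row per retained fragment:
#'   `peptide`, `charge`, `fragment`, `intensity`, `rank`, `ref_rt`.
#'   Attribute `rejected` lists peptides without any fragment.
#' @export
build_assay <- function(library, top_k = 6L) {
  stopifnot(nrow(library) > 0, top_k >= 1)
  bad <- library$intensity < 0 | library$charge < 1
  if (any(bad)) stop("negative intensities or charges < 1 in library")
  empty <- dplyr::anti_join(
    dplyr::distinct(library, .data$peptide),
    dplyr::distinct(library[!is.na(library$fragment), ], .data$peptide),
    by = "peptide")
  lib <- library[!is.na(library$fragment), ]
  chosen <- lib |>
    dplyr::group_by(.data$peptide, .data$charge) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$charge,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  targets <- lib |>
    dplyr::inner_join(chosen[, c("peptide", "charge")],
                      by = c("peptide", "charge")) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::arrange(dplyr::desc(.data$intensity), .data$fragment,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= top_k) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$peptide, .data$rank)
  attr(targets, "rejected") <- empty$peptide
  targets
}

# Targets as one row per peptide ion with an RT window.
.target_windows <- function(targets, rt_window) {
  stopifnot(rt_window > 0)
  tw <- dplyr::distinct(targets, .data$peptide, .data$ref_rt)
  tw$lo <- tw$ref_rt - rt_window / 2
  tw$hi <- tw$ref_rt + rt_window / 2
  tw
}

#' Maximum number of simultaneously monitored targets
#'
#' Computes, over all retention times, the maximum number of targets whose
#' scheduling windows `[ref_rt - w/2, ref_rt + w/2]` cover that RT, by a
#' sweep over window endpoints (the maximum of a piecewise-constant profile
#' is attained at a window start).
#'
#' @param targets Tibble with `peptide` and `ref_rt` (one window per
#'   distinct peptide), e.g. from [build_assay()].
#' @param rt_window Full window width (minutes).
#' @return List `max_concurrent`, `at_rt` (an RT attaining the maximum),
#'   and `n_targets`.
#' @export
concurrency_profile <- function(targets, rt_window) {
  tw <- .target_windows(targets, rt_window)
  counts <- vapply(seq_len(nrow(tw)), function(i) {
    sum(tw$lo <= tw$lo[i] & tw$hi >= tw$lo[i])
  }, integer(1))
  i <- which.max(counts)
  list(max_concurrent = counts[i], at_rt = tw$lo[i], n_targets = nrow(tw))
}

#' Schedule PRM targets into injections under a concurrency cap
#'
#' Greedy first-fit: targets are taken in order of ascending window center
#' and placed into the first injection where adding them keeps the maximum
#' number of simultaneous targets at or below `max_concurrent`; a new
#' injection is opened when none fits. The result always satisfies the cap.
#'
#' @inheritParams concurrency_profile
#' @param max_concurrent Cap on simultaneous targets at any RT.
#' @return List with `assignment` (tibble: `peptide`, `ref_rt`,
#'   `injection`), `n_injections`, and `profile` (tibble: `injection`,
#'   `max_concurrent`).
#' @export
schedule_injections <- function(targets, rt_window, max_concurrent) {
  stopifnot(max_concurrent >= 1)
  tw <- .target_windows(targets, rt_window)
  tw <- tw[order(tw$ref_rt, tw$peptide), ]
  inj_lo <- list(); inj_hi <- list()
  assignment <- integer(nrow(tw))
  for (i in seq_len(nrow(tw))) {
    placed <- FALSE
    for (j in seq_along(inj_lo)) {
      lo <- c(inj_lo[[j]], tw$lo[i]); hi <- c(inj_hi[[j]], tw$hi[i])
      # the cap held before this insertion, so a violation can only occur
      # at RTs covered by the new window: check those window starts only
      cand <- lo[lo >= tw$lo[i] & lo <= tw$hi[i]]
      peak <- max(vapply(cand, function(s) {
        sum(lo <= s & hi >= s)
      }, integer(1)))
      if (peak <= max_concurrent) {
        inj_lo[[j]] <- lo; inj_hi[[j]] <- hi
        assignment[i] <- j; placed <- TRUE
        break
      }
    }
    if (!placed) {
      inj_lo[[length(inj_lo) + 1L]] <- tw$lo[i]
      inj_hi[[length(inj_hi) + 1L]] <- tw$hi[i]
      assignment[i] <- length(inj_lo)
    }
  }
  profile <- tibble(
    injection = seq_along(inj_lo),
    max_concurrent = vapply(seq_along(inj_lo), function(j) {
      lo <- inj_lo[[j]]; hi <- inj_hi[[j]]
      max(vapply(seq_along(lo), function(k) {
        sum(lo <= lo[k] & hi >= lo[k])
      }, integer(1)))
    }, integer(1)))
  list(assignment = tibble(peptide = tw$peptide, ref_rt = tw$ref_rt,
                           injection = assignment),
       n_injections = length(inj_lo),
       profile = profile)
}

#' Injections required without retention-time scheduling
#'
#' When every target is monitored for the whole run, the number of
#' simultaneous targets equals the number of targets per injection, so
#' `ceiling(n_targets / max_concurrent)` injections are needed. This is a
#' deliberately simple model of an unscheduled workflow (real instrument
#' cycle-time constraints can add more).
#'
#' @param n_targets,max_concurrent Positive integers.
#' @return Integer injection count.
#' @examples
#' unscheduled_injections(510, 50)
#' @export
unscheduled_injections <- function(n_targets, max_concurrent) {
  stopifnot(n_targets >= 1, max_concurrent >= 1)
  as.integer(ceiling(n_targets / max_concurrent))
}

#' Calibrate library retention times to an observed run
#'
#' Least-squares linear mapping from library (indexed) RT to observed run
#' RT, fitted on standard peptides and applied to all targets.
#'
#' @param library Tibble with `peptide`, `ref_rt`, and logical
#'   `is_standard`.
#' @param observed Tibble with `peptide` and `run_rt` for (at least) the
#'   standards.
#' @return List with `intercept`, `slope`, and `calibrated` (the library
#'   tibble with a `run_rt` column of mapped RTs).
#' @export
calibrate_rt <- function(library, observed) {
  std <- dplyr::inner_join(
    dplyr::distinct(library[library$is_standard, ], .data$peptide,
                    .data$ref_rt),
    observed, by = "peptide")
  if (nrow(std) < 2) stop("need at least two standard peptides to calibrate")
  fit <- stats::lm(run_rt ~ ref_rt, data = std)
  co <- stats::coef(fit)
  library$run_rt <- co[[1]] + co[[2]] * library$ref_rt
  list(intercept = co[[1]], slope = co[[2]], calibrated = library)
}
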