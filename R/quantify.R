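# Transition-level PRM reports to a peptide quant matrix, with the
# filtering / normalization / imputation rules of the differential
# analysis: >=5 transitions kept per peptide, fragment areas summed over
# charge states and oxidation variants, median MS1 normalization,
# all-or-nothing detection filtering with on/off classes, zero-to-minimum
# imputation, and log10 Student's t tests.

#' Remove flagged interfering transitions, keeping at least five
#'
#' User-flagged interfering transitions are removed only while at least
#' `min_transitions` distinct transitions (charge x variant x fragment
#' combinations) remain for the peptide; removals that would cross the
#' floor are refused and reported. Peptides entering with fewer than
#' `min_transitions` transitions trigger a warning and are retained as-is.
#'
#' @param report Transition tibble with columns `peptide`, `charge`,
#'   `variant`, `fragment` (plus any others, e.g. `run`, `area`).
#' @param flagged Tibble of transitions to drop, with columns `peptide`,
#'   `charge`, `variant`, `fragment`. `NULL` means no removals.
#' @param min_transitions Minimum transitions to keep per peptide.
#' @return Filtered report; attribute `refused` holds the flagged rows
#'   whose removal was refused.
#' @export
retain_transitions <- function(report, flagged = NULL, min_transitions = 5L) {
  key <- c("peptide", "charge", "variant", "fragment")
  trans <- dplyr::distinct(report[, key])
  n_per <- table(trans$peptide)
  low <- names(n_per)[n_per < min_transitions]
  if (length(low)) {
    warning("peptides with fewer than ", min_transitions,
            " transitions retained as-is: ", paste(low, collapse = ", "))
  }
  if (is.null(flagged) || nrow(flagged) == 0) {
    attr(report, "refused") <- flagged[0, ]
    return(report)
  }
  stopifnot(all(key %in% names(flagged)))
  drop <- list(); refused <- list()
  remaining <- as.list(n_per)
  for (i in seq_len(nrow(flagged))) {
    f <- flagged[i, key]
    p <- f$peptide
    exists <- nrow(dplyr::inner_join(trans, f, by = key)) > 0
    if (exists && remaining[[p]] - 1L >= min_transitions) {
      drop[[length(drop) + 1L]] <- f
      remaining[[p]] <- remaining[[p]] - 1L
    } else {
      refused[[length(refused) + 1L]] <- f
    }
  }
  out <- report
  if (length(drop)) {
    out <- dplyr::anti_join(report, dplyr::bind_rows(drop), by = key)
  }
  attr(out, "refused") <- if (length(refused)) dplyr::bind_rows(refused)
                          else flagged[0, ]
  out
}

#' Aggregate transition areas to one value per peptide and run
#'
#' Sums fragment peak areas over fragments, precursor charge states, and
#' oxidation variants, per run. A peptide-run cell is flagged detected when
#' any of its transitions is; a cell with no rows gets area 0 and
#' `detected = FALSE`.
#'
#' @param report Transition tibble with `run`, `condition`, `replicate`,
#'   `peptide`, `area`, `detected`.
#' @return Long quant tibble: `peptide`, `run`, `condition`, `replicate`,
#'   `area`, `detected` — complete over peptide x run.
#' @export
aggregate_peptide_areas <- function(report) {
  stopifnot(all(report$area >= 0))
  runs <- dplyr::distinct(report, .data$run, .data$condition, .data$replicate)
  agg <- report |>
    dplyr::group_by(.data$peptide, .data$run) |>
    dplyr::summarise(area = sum(.data$area), detected = any(.data$detected),
                     .groups = "drop")
  full <- tidyr::expand_grid(peptide = unique(report$peptide), run = runs$run)
  full |>
    dplyr::left_join(agg, by = c("peptide", "run")) |>
    dplyr::left_join(runs, by = "run") |>
    dplyr::mutate(area = dplyr::coalesce(.data$area, 0),
                  detected = dplyr::coalesce(.data$detected, FALSE)) |>
    dplyr::select("peptide", "run", "condition", "replicate", "area",
                  "detected")
}

#' Median MS1 normalization of a quant matrix
#'
#' Divides each run's areas by that run's MS1-feature median relative to
#' the grand median of run medians, so post-normalization MS1 medians are
#' equal across runs. When no MS1 feature table is available the per-run
#' median of the peptide areas themselves is used instead, with a warning.
#'
#' @param quant Long quant tibble from [aggregate_peptide_areas()].
#' @param ms1 Tibble of MS1 features (`run`, `area`), one row per feature
#'   per run; every run in `quant` must be present with at least one
#'   feature.
#' @return Normalized quant tibble; attribute `norm_factors` holds the
#'   per-run division factors.
#' @export
median_normalize <- function(quant, ms1 = NULL) {
  runs <- unique(quant$run)
  if (is.null(ms1)) {
    warning("no MS1 feature table supplied; ",
            "normalizing on per-run medians of peptide areas")
    ms1 <- quant[, c("run", "area")]
  }
  if (!all(runs %in% ms1$run)) {
    stop("runs without MS1 features: ",
         paste(setdiff(runs, ms1$run), collapse = ", "))
  }
  med <- vapply(runs, function(r) median(ms1$area[ms1$run == r]), double(1))
  if (any(med <= 0)) stop("non-positive MS1 feature median")
  factors <- med / median(med)
  out <- quant
  out$area <- out$area / unname(factors[match(out$run, runs)])
  attr(out, "norm_factors") <- tibble(run = runs, factor = unname(factors))
  out
}

#' Classify peptides by detection pattern and impute zeros
#'
#' Applies the all-or-nothing retention rule of a two-condition PRM
#' analysis: peptides detected in all replicates of both conditions are
#' `"quantifiable"`; peptides detected in all replicates of exactly one
#' condition and none of the other are `"on_off"` (their undetected cells
#' keep their background areas); any partial detection pattern is
#' `"dropped"`. Remaining zero areas among retained peptides are replaced
#' by the minimum positive value of the entire retained dataset.
#'
#' @param quant Long quant tibble (normalized).
#' @return List with `quant` (retained peptides, zeros imputed), `classes`
#'   (tibble: `peptide`, `class`, `detected_1`, `detected_2`), and
#'   `imputation_floor` (the dataset minimum used, `NA` if no zeros).
#' @export
apply_detection_policy <- function(quant) {
  conds <- unique(quant$condition)
  if (length(conds) != 2) stop("detection policy requires exactly 2 conditions")
  pat <- quant |>
    dplyr::group_by(.data$peptide, .data$condition) |>
    dplyr::summarise(n_det = sum(.data$detected), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(all_det = .data$n_det == .data$n,
                  none_det = .data$n_det == 0L)
  classes <- pat |>
    tidyr::pivot_wider(id_cols = "peptide", names_from = "condition",
                       values_from = c("all_det", "none_det", "n_det")) |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data[[paste0("all_det_", conds[1])]] &
          .data[[paste0("all_det_", conds[2])]] ~ "quantifiable",
        .data[[paste0("all_det_", conds[1])]] &
          .data[[paste0("none_det_", conds[2])]] ~ "on_off",
        .data[[paste0("none_det_", conds[1])]] &
          .data[[paste0("all_det_", conds[2])]] ~ "on_off",
        TRUE ~ "dropped")) |>
    dplyr::transmute(.data$peptide, .data$class,
                     detected_1 = .data[[paste0("n_det_", conds[1])]],
                     detected_2 = .data[[paste0("n_det_", conds[2])]])
  keep <- classes$peptide[classes$class != "dropped"]
  out <- quant[quant$peptide %in% keep, ]
  floor_val <- NA_real_
  if (any(out$area == 0)) {
    pos <- out$area[out$area > 0]
    if (!length(pos)) stop("all retained areas are zero; nothing to impute from")
    floor_val <- min(pos)
    out$area[out$area == 0] <- floor_val
  }
  list(quant = out, classes = classes, imputation_floor = floor_val)
}

#' Two-condition differential test on log10 areas
#'
#' Per peptide: log10-transforms the (normalized, imputed) areas and runs a
#' two-sided Student's t test between the two conditions (equal-variance by
#' default; Welch behind `var_equal = FALSE`). The fold change is
#' `10^(mean2 - mean1)` on the linear scale. Peptides with zero pooled
#' variance are reported as degenerate with `NA` statistics.
#'
#' @param quant Long quant tibble (e.g. `$quant` of
#'   [apply_detection_policy()]).
#' @param classes Optional class tibble to join onto the result.
#' @param conditions Length-2 character vector fixing the condition order
#'   (fold change is condition 2 over condition 1); defaults to the order
#'   of first appearance in `quant`.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return Tibble: `peptide`, `mean_log10_1`, `mean_log10_2`,
#'   `fold_change`, `t`, `df`, `p`, `p_bh` (Benjamini-Hochberg, reported
#'   alongside but not used for headline counts), `degenerate`, and
#'   `class` when supplied.
#' @export
differential_test <- function(quant, classes = NULL, conditions = NULL,
                              var_equal = TRUE) {
  conds <- conditions %||% unique(quant$condition)
  stopifnot(length(conds) == 2, all(quant$condition %in% conds),
            all(quant$area > 0))
  res <- quant |>
    dplyr::mutate(log_area = log10(.data$area)) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::group_modify(function(d, key) {
      x1 <- d$log_area[d$condition == conds[1]]
      x2 <- d$log_area[d$condition == conds[2]]
      if (length(x1) < 2 || length(x2) < 2) {
        stop("need >=2 replicates per condition for peptide ", key$peptide)
      }
      m1 <- mean(x1); m2 <- mean(x2)
      pooled_var <- (sum((x1 - m1)^2) + sum((x2 - m2)^2)) /
        (length(x1) + length(x2) - 2)
      if (pooled_var == 0) {
        return(tibble(mean_log10_1 = m1, mean_log10_2 = m2,
                      fold_change = 10^(m2 - m1), t = NA_real_,
                      df = NA_real_, p = NA_real_, degenerate = TRUE))
      }
      tt <- stats::t.test(x2, x1, var.equal = var_equal)
      tibble(mean_log10_1 = m1, mean_log10_2 = m2,
             fold_change = 10^(m2 - m1),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, degenerate = FALSE)
    }) |>
    dplyr::ungroup()
  res$p_bh <- p.adjust(res$p, method = "BH")
  if (!is.null(classes)) {
    res <- dplyr::left_join(res, classes[, c("peptide", "class")],
                            by = "peptide")
  }
  res
}

#' Coefficient of variation across replicates
#'
#' Per-peptide CV% (`100 * sd / mean` on linear-scale areas) across the
#' replicates present in `quant`, summarized as the median CV with the
#' standard error of the mean of the per-peptide CVs.
#'
#' @param quant Long quant tibble; typically restricted to technical
#'   replicates of one condition before calling.
#' @return List with `per_peptide` (tibble: `peptide`, `cv_percent`),
#'   `median_cv`, `sem`, and `excluded` (peptides with zero mean).
#' @export
compute_cv <- function(quant) {
  per <- quant |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(mean_area = mean(.data$area), sd_area = sd(.data$area),
                     n = dplyr::n(), .groups = "drop")
  if (any(per$n < 2)) stop("CV requires >=2 replicates per peptide")
  excluded <- per$peptide[per$mean_area == 0]
  per <- per[per$mean_area > 0, ]
  per$cv_percent <- 100 * per$sd_area / per$mean_area
  list(per_peptide = per[, c("peptide", "cv_percent")],
       median_cv = median(per$cv_percent),
       sem = sd(per$cv_percent) / sqrt(nrow(per)),
       excluded = excluded)
}
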