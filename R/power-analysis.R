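# Simulation-based power analysis over effect-size x sample-size grids,
# using the same log10-scale Student's t test as the differential module.

#' Power-analysis configuration
#'
#' @param effect_sizes Fold changes to simulate.
#' @param sample_sizes Replicates per condition to simulate.
#' @param n_sims Simulations per grid cell.
#' @param alpha Significance level of the per-simulation t test.
#' @param seed Integer seed; each grid cell uses its own deterministic
#'   substream, so grids are reproducible cell-by-cell.
#' @return Validated list of class `power_config`.
#' @export
power_config <- function(effect_sizes = c(1.1, 1.2, 1.5, 2, 4),
                         sample_sizes = c(4L, 6L, 8L, 10L, 15L, 20L),
                         n_sims = 500L, alpha = 0.05, seed = 1L) {
  stopifnot(all(effect_sizes > 0), all(sample_sizes >= 2),
            n_sims >= 1, alpha > 0, alpha < 1)
  structure(list(effect_sizes = effect_sizes,
                 sample_sizes = as.integer(sample_sizes),
                 n_sims = as.integer(n_sims), alpha = alpha,
                 seed = as.integer(seed)),
            class = "power_config")
}

# Deterministic per-cell seed below 2^31.
.cell_seed <- function(seed, i_pep, i_fc, i_n) {
  (as.numeric(seed) * 48271 + i_pep * 100003 + i_fc * 1009 + i_n * 31) %%
    2147483647
}

# Vectorized pooled two-sample t on columns of two n x S matrices.
.pooled_t_p <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(x1^2) - n1 * m1^2
  ss2 <- colSums(x2^2) - n2 * m2^2
  df <- n1 + n2 - 2
  sp <- sqrt((ss1 + ss2) / df)
  t <- (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
  2 * pt(-abs(t), df)
}

#' Simulate statistical power over an effect-size x sample-size grid
#'
#' For each peptide and each (fold change, sample size) cell, draws `n`
#' log10 abundances per condition from normal distributions — condition 1
#' at the peptide's estimated mean and sd, condition 2 shifted by
#' `log10(fold change)` and using the second condition's sd — applies a
#' two-sided pooled-variance t test, and records the percentage of
#' simulations significant at `alpha`.
#'
#' @param peptide_stats Tibble with columns `peptide`, `mean_log10`,
#'   `sd_log10_1` and (optionally) `sd_log10_2` (defaults to
#'   `sd_log10_1`): per-peptide log10 mean and per-condition sds estimated
#'   from data.
#' @param config A [power_config()].
#' @return Long tibble of class `power_grid`: `peptide`, `fold_change`,
#'   `n`, `power_percent` (in \[0, 100\]); one row per grid cell per
#'   peptide.
#' @export
simulate_power <- function(peptide_stats, config = power_config()) {
  stopifnot(inherits(config, "power_config"),
            all(c("peptide", "mean_log10", "sd_log10_1") %in%
                  names(peptide_stats)),
            all(peptide_stats$sd_log10_1 >= 0))
  if (!"sd_log10_2" %in% names(peptide_stats)) {
    peptide_stats$sd_log10_2 <- peptide_stats$sd_log10_1
  }
  grid <- tidyr::expand_grid(
    i_pep = seq_len(nrow(peptide_stats)),
    i_fc = seq_along(config$effect_sizes),
    i_n = seq_along(config$sample_sizes))
  power <- vapply(seq_len(nrow(grid)), function(g) {
    i <- grid$i_pep[g]; fc <- config$effect_sizes[grid$i_fc[g]]
    n <- config$sample_sizes[grid$i_n[g]]
    mu <- peptide_stats$mean_log10[i]
    s1 <- peptide_stats$sd_log10_1[i]; s2 <- peptide_stats$sd_log10_2[i]
    local_seed(.cell_seed(config$seed, i, grid$i_fc[g], grid$i_n[g]), {
      x1 <- matrix(rnorm(n * config$n_sims, mu, s1), nrow = n)
      x2 <- matrix(rnorm(n * config$n_sims, mu + log10(fc), s2), nrow = n)
      if (s1 == 0 && s2 == 0) {
        # degenerate separation limit: significant iff means differ
        return(if (fc != 1) 100 else 0)
      }
      p <- .pooled_t_p(x1, x2)
      100 * mean(p < config$alpha)
    })
  }, double(1))
  structure(
    tibble(peptide = peptide_stats$peptide[grid$i_pep],
           fold_change = config$effect_sizes[grid$i_fc],
           n = config$sample_sizes[grid$i_n],
           power_percent = power),
    class = c("power_grid", "tbl_df", "tbl", "data.frame"))
}

#' Fraction of peptides reaching a power threshold per grid cell
#'
#' @param grid A `power_grid` from [simulate_power()].
#' @param threshold Power threshold in percent (default 95).
#' @return Tibble: `fold_change`, `n`, `fraction_reaching` (of peptides
#'   with `power_percent >= threshold`), `n_peptides`.
#' @export
power_grid_summary <- function(grid, threshold = 95) {
  grid |>
    dplyr::group_by(.data$fold_change, .data$n) |>
    dplyr::summarise(
      fraction_reaching = mean(.data$power_percent >= threshold),
      n_peptides = dplyr::n(), .groups = "drop")
}
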