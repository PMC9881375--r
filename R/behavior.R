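# Nictation and locomotion statistics: bout metrics, inter-experimental
# normalization, Dunnett many-to-one comparisons, and track speeds.

#' Nictation metrics of one bout track
#'
#' From a timeline of nictation bouts within an observation window,
#' computes the three standard nictation indices: nictation ratio
#' `T_nict / T_total`, initiation index `N_nict / (T_total - T_nict)`
#' (nictation starts per second of non-nictating time), and average bout
#' duration `T_nict / N_nict`. A bout truncated by the window counts as one
#' initiation and contributes its observed duration.
#'
#' @param start,end Numeric vectors of bout start/end times (s), ordered,
#'   non-overlapping, within `[0, t_total]`.
#' @param t_total Observation window length (s), > 0.
#' @return List: `t_nict`, `n_nict`, `nictation_ratio`,
#'   `initiation_index` (NA when the animal nictates the whole window),
#'   `average_duration` (NA when there are no bouts).
#' @examples
#' nictation_metrics(c(10, 40), c(25, 55), t_total = 90)
#' @export
nictation_metrics <- function(start, end, t_total) {
  stopifnot(t_total > 0, length(start) == length(end))
  if (length(start)) {
    if (any(end <= start)) stop("bouts must have positive duration")
    if (any(start < 0) || any(end > t_total)) {
      stop("bouts must lie within the observation window")
    }
    o <- order(start)
    start <- start[o]; end <- end[o]
    if (any(start[-1] < end[-length(end)])) stop("overlapping bouts")
  }
  t_nict <- sum(end - start)
  n_nict <- length(start)
  list(
    t_nict = t_nict, n_nict = n_nict,
    nictation_ratio = t_nict / t_total,
    initiation_index = if (t_nict < t_total) n_nict / (t_total - t_nict)
                       else NA_real_,
    average_duration = if (n_nict > 0) t_nict / n_nict else NA_real_)
}

#' Nictation metrics for a set of bout tracks
#'
#' Tidy wrapper over [nictation_metrics()] for the track/bout tables
#' produced by [generate_bout_tracks()] or read from bout logs.
#'
#' @param tracks Tibble: `individual`, `group`, `batch`, `t_total`.
#' @param bouts Tibble of nictation intervals: `individual`, `start`,
#'   `end`. Individuals absent from `bouts` have zero bouts.
#' @return Tibble with one row per individual: the track columns plus
#'   `t_nict`, `n_nict`, `nictation_ratio`, `initiation_index`,
#'   `average_duration`.
#' @export
summarize_bout_tracks <- function(tracks, bouts) {
  rows <- lapply(seq_len(nrow(tracks)), function(i) {
    b <- bouts[bouts$individual == tracks$individual[i], ]
    m <- nictation_metrics(b$start, b$end, tracks$t_total[i])
    tibble(t_nict = m$t_nict, n_nict = m$n_nict,
           nictation_ratio = m$nictation_ratio,
           initiation_index = m$initiation_index,
           average_duration = m$average_duration)
  })
  dplyr::bind_cols(tracks, dplyr::bind_rows(rows))
}

#' Median inter-experimental normalization
#'
#' Rescales each batch (experiment) so that the batch's control-group
#' median coincides with the grand control median across batches. The
#' default operation is multiplicative, appropriate for ratio-scale
#' statistics like the nictation ratio (values may optionally be clipped
#' to `[0, 1]`); an additive shift is available via `method`.
#'
#' @param data Tibble with one row per individual.
#' @param value Name of the value column (string).
#' @param control Control group label; every batch must contain it.
#' @param method `"multiplicative"` (default) or `"additive"`.
#' @param clip Clip normalized values to `[0, 1]`? Default `TRUE` for the
#'   multiplicative method on ratios; set `FALSE` for unbounded
#'   statistics.
#' @param group,batch Names of the group and batch columns.
#' @return `data` with an added `<value>_normalized` column; attribute
#'   `batch_factors` records the per-batch adjustment.
#' @export
normalize_batches <- function(data, value = "nictation_ratio",
                              control = "N2",
                              method = c("multiplicative", "additive"),
                              clip = TRUE, group = "group", batch = "batch") {
  method <- match.arg(method)
  v <- data[[value]]; g <- data[[group]]; b <- data[[batch]]
  batches <- unique(b)
  ctrl_med <- vapply(batches, function(bb) {
    x <- v[b == bb & g == control]
    if (!length(x)) stop("batch ", bb, " has no control (", control, ") animals")
    median(x)
  }, double(1))
  grand <- median(ctrl_med)
  adj <- if (method == "multiplicative") {
    if (any(ctrl_med <= 0)) stop("multiplicative normalization needs positive control medians")
    grand / ctrl_med
  } else {
    grand - ctrl_med
  }
  out <- if (method == "multiplicative") v * unname(adj[match(b, batches)])
         else v + unname(adj[match(b, batches)])
  if (clip && method == "multiplicative") out <- pmin(pmax(out, 0), 1)
  data[[paste0(value, "_normalized")]] <- out
  attr(data, "batch_factors") <- tibble(batch = batches,
                                        control_median = unname(ctrl_med),
                                        adjustment = unname(adj))
  data
}

#' Dunnett many-to-one comparison against a control
#'
#' Fits a one-way linear model (group means, pooled residual variance) and
#' computes two-sided Dunnett-adjusted p values for every treatment group
#' against the control, using the multivariate-t distribution of the
#' contrast statistics with correlation `rho_ij = lambda_i * lambda_j`,
#' `lambda_i = sqrt(n_i / (n_i + n_0))`. With a single treatment group the
#' adjusted p value equals the two-sided pooled t test p value exactly.
#'
#' @param values Numeric response vector (one observation per individual).
#' @param groups Group labels, same length as `values`.
#' @param control Control group label.
#' @param seed Seed for the multivariate-t quadrature, so adjusted p
#'   values are reproducible.
#' @return Tibble with one row per group (control first): `group`, `n`,
#'   `lsmean` (group mean), `sem` (pooled-sd standard error of the mean),
#'   `t` (contrast statistic vs control; NA for the control row), `p_adj`
#'   (Dunnett-adjusted; 1 for the control row by convention).
#' @export
dunnett_compare <- function(values, groups, control, seed = 1L) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group not present: ", control)
  lv <- c(control, setdiff(unique(groups), control))
  n <- vapply(lv, function(g) sum(groups == g), integer(1))
  if (any(n < 2)) stop("every group needs at least 2 observations")
  means <- vapply(lv, function(g) mean(values[groups == g]), double(1))
  sse <- sum(vapply(lv, function(g) {
    x <- values[groups == g]; sum((x - mean(x))^2)
  }, double(1)))
  df <- length(values) - length(lv)
  if (df < 1 || sse == 0) stop("no residual variance to estimate")
  s <- sqrt(sse / df)
  k <- length(lv) - 1L
  tstat <- (means[-1] - means[1]) / (s * sqrt(1 / n[-1] + 1 / n[1]))
  lambda <- sqrt(n[-1] / (n[-1] + n[1]))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  p_adj <- vapply(seq_len(k), function(i) {
    q <- abs(tstat[i])
    if (k == 1) {
      2 * pt(-q, df)
    } else {
      local_seed(seed, {
        1 - mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                          df = df, corr = corr)[1]
      })
    }
  }, double(1))
  tibble(group = lv, n = unname(n), lsmean = unname(means),
         sem = s / sqrt(unname(n)),
         t = c(NA_real_, unname(tstat)),
         p_adj = c(1, pmin(pmax(p_adj, 0), 1)))
}

#' Mean crawling speed per track
#'
#' Tracks shorter than `min_seconds` are excluded (reported, not
#' returned). Speed is the mean frame-to-frame displacement over time
#' step, scaled from pixels/s to micrometers/s.
#'
#' @param tracks Tibble of centroid samples: `track`, `t` (s, strictly
#'   increasing within a track), `x`, `y` (pixels); optional `group`.
#' @param pixel_to_micrometer Scale factor (um per pixel).
#' @param min_seconds Minimum track duration for inclusion (default 30).
#' @return Tibble with one row per retained track: `track` (and `group`),
#'   `duration_s`, `speed_um_s`; attribute `excluded` lists tracks below
#'   the duration threshold.
#' @export
track_speed <- function(tracks, pixel_to_micrometer = 1, min_seconds = 30) {
  stopifnot(pixel_to_micrometer > 0)
  ids <- unique(tracks$track)
  rows <- list(); excluded <- character(0)
  for (id in ids) {
    d <- tracks[tracks$track == id, ]
    if (nrow(d) < 2) stop("track ", id, " has fewer than 2 samples")
    if (any(diff(d$t) <= 0)) stop("non-monotone timestamps in track ", id)
    dur <- d$t[nrow(d)] - d$t[1]
    if (dur < min_seconds) {
      excluded <- c(excluded, id)
      next
    }
    disp <- sqrt(diff(d$x)^2 + diff(d$y)^2)
    speed <- mean(disp / diff(d$t)) * pixel_to_micrometer
    rows[[id]] <- tibble(track = id,
                         group = if ("group" %in% names(d)) d$group[1] else NA,
                         duration_s = dur, speed_um_s = speed)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(track = character(), group = character(),
           duration_s = double(), speed_um_s = double())
  attr(out, "excluded") <- excluded
  out
}
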