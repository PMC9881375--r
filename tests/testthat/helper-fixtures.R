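# Shared fixtures, built in code.

# Brute-force dibasic-site oracle: scan for the 4 motifs, then merge
# overlapping matches into maximal basic runs. Independent of the rle-based
# implementation.
oracle_cleavage_sites <- function(sequence, signal_end = 0) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  motif_start <- c()
  for (i in seq_len(max(n - 1, 0))) {
    if (i <= signal_end) next
    pair <- paste0(aa[i], aa[i + 1])
    if (pair %in% c("KK", "KR", "RK", "RR")) motif_start <- c(motif_start, i)
  }
  if (!length(motif_start)) {
    return(data.frame(start = integer(), end = integer()))
  }
  # merge overlapping/adjacent basic pairs into runs
  regions <- list(c(motif_start[1], motif_start[1] + 1L))
  for (s in motif_start[-1]) {
    last <- regions[[length(regions)]]
    if (s <= last[2]) {
      regions[[length(regions)]] <- c(last[1], s + 1L)
    } else {
      regions[[length(regions) + 1L]] <- c(s, s + 1L)
    }
  }
  data.frame(start = vapply(regions, `[`, integer(1), 1),
             end = vapply(regions, `[`, integer(1), 2))
}

random_protein <- function(n, alphabet = c(LETTERS[LETTERS %in%
  c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")])) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small transition report built by hand for aggregation tests.
toy_report <- function() {
  tibble::tibble(
    run = rep(c("r1", "r2"), each = 5),
    condition = rep(c("c1", "c2"), each = 5),
    replicate = 1L,
    peptide = "PEP",
    charge = 2L, variant = "none",
    fragment = rep(sprintf("y%d", 1:5), 2),
    area = c(10, 20, 30, 15, 25, 1, 2, 3, 4, 5),
    detected = TRUE)
}

# Minimal concurrency oracle: evaluate the window-count profile on a fine
# RT grid.
oracle_max_concurrency <- function(centers, width, grid_n = 4001) {
  lo <- centers - width / 2; hi <- centers + width / 2
  grid <- seq(min(lo), max(hi), length.out = grid_n)
  grid <- sort(unique(c(grid, lo, hi)))
  max(vapply(grid, function(g) sum(lo <= g & hi >= g), integer(1)))
}

# Exhaustive scheduling oracle: minimum number of injections such that each
# injection's peak concurrency is <= cap, by enumerating assignments of
# targets to k injections for increasing k.
oracle_min_injections <- function(centers, width, cap) {
  n <- length(centers)
  lo <- centers - width / 2; hi <- centers + width / 2
  peak_ok <- function(idx) {
    if (!length(idx)) return(TRUE)
    max(vapply(idx, function(k) sum(lo[idx] <= lo[k] & hi[idx] >= lo[k]),
               integer(1))) <= cap
  }
  for (k in 1:n) {
    assignment <- rep(1L, n)
    repeat {
      groups <- split(seq_len(n), assignment)
      if (all(vapply(groups, peak_ok, logical(1)))) return(k)
      # next assignment in base-k counting
      i <- 1L
      while (i <= n) {
        if (assignment[i] < k) {
          assignment[i] <- assignment[i] + 1L
          assignment[seq_len(i - 1L)] <- 1L
          break
        }
        i <- i + 1L
      }
      if (i > n) break
    }
  }
  n
}
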