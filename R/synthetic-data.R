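# Seeded generators for every input the pipeline consumes: toy proteomes
# with embedded precursor structure, transition-level PRM reports with
# log-normal abundances / dropout / per-run scale factors, and alternating
# crawl/nictation bout tracks.

#' Simulation configuration
#'
#' Central parameter object for the synthetic-data generators. Defaults
#' mirror the study conditions the package's analyses assume: four
#' replicates per condition, a technical CV of 21.63%, 90-second behavioral
#' observations, candidate fold changes \{1.1, 1.2, 1.5, 2, 4\}, and a
#' 50-minute chromatographic gradient.
#'
#' @param seed Integer seed; identical seed + config give bit-identical
#'   outputs.
#' @param n_precursors Number of true neuropeptide precursors.
#' @param n_decoys Number of decoy proteins (half lack a signal peptide,
#'   half lack dibasic sites).
#' @param n_peptides_per_precursor Length-2 integer range (inclusive).
#' @param peptide_length Length-2 range of mature-peptide core lengths.
#' @param signal_peptide_length Length-2 range of signal-peptide lengths.
#' @param frac_amidated Fraction of mature peptides carrying a C-terminal
#'   amidation donor glycine.
#' @param frac_pyroglu Fraction starting with a pyroglutamate donor (Q/E).
#' @param gradient_minutes Chromatographic gradient length; reference RTs
#'   are uniform over it.
#' @param n_replicates_per_condition Replicates in each of the two
#'   conditions.
#' @param base_log10_abundance Length-2 vector `c(mean, sd)` of true
#'   peptide log10 abundances in condition 1.
#' @param technical_cv_percent Technical coefficient of variation (%) of
#'   replicate areas on the linear scale.
#' @param fold_changes Positive ratios assigned to peptides (condition 2 /
#'   condition 1), recycled over peptides.
#' @param dropout_threshold Linear-scale abundance below which a peptide is
#'   undetected in a replicate and only background signal is recorded.
#' @param bout_rate_nict,bout_rate_crawl Exponential bout rates (1/s);
#'   means 1/rate. Defaults give a stationary nictation ratio of
#'   5/(5+8.5) ~ 0.37.
#' @param observation_seconds Behavioral observation window (s).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_precursors = 20L,
                       n_decoys = 10L,
                       n_peptides_per_precursor = c(2L, 5L),
                       peptide_length = c(5L, 15L),
                       signal_peptide_length = c(16L, 24L),
                       frac_amidated = 0.5,
                       frac_pyroglu = 0.2,
                       gradient_minutes = 50,
                       n_replicates_per_condition = 4L,
                       base_log10_abundance = c(mean = 5, sd = 0.5),
                       technical_cv_percent = 21.63,
                       fold_changes = c(1.1, 1.2, 1.5, 2, 4),
                       dropout_threshold = 1e3,
                       bout_rate_nict = 1 / 5,
                       bout_rate_crawl = 1 / 8.5,
                       observation_seconds = 90) {
  cfg <- list(
    seed = as.integer(seed), n_precursors = as.integer(n_precursors),
    n_decoys = as.integer(n_decoys),
    n_peptides_per_precursor = as.integer(n_peptides_per_precursor),
    peptide_length = as.integer(peptide_length),
    signal_peptide_length = as.integer(signal_peptide_length),
    frac_amidated = frac_amidated, frac_pyroglu = frac_pyroglu,
    gradient_minutes = gradient_minutes,
    n_replicates_per_condition = as.integer(n_replicates_per_condition),
    base_log10_abundance = base_log10_abundance,
    technical_cv_percent = technical_cv_percent,
    fold_changes = fold_changes, dropout_threshold = dropout_threshold,
    bout_rate_nict = bout_rate_nict, bout_rate_crawl = bout_rate_crawl,
    observation_seconds = observation_seconds)
  stopifnot(
    cfg$n_precursors >= 1, cfg$n_decoys >= 0,
    all(cfg$n_peptides_per_precursor >= 1),
    all(cfg$peptide_length >= 2), all(cfg$signal_peptide_length >= 8),
    cfg$n_replicates_per_condition >= 1,
    cfg$technical_cv_percent >= 0, all(cfg$fold_changes > 0),
    cfg$dropout_threshold >= 0,
    cfg$bout_rate_nict > 0, cfg$bout_rate_crawl > 0,
    cfg$observation_seconds > 0,
    cfg$frac_amidated >= 0, cfg$frac_amidated <= 1,
    cfg$frac_pyroglu >= 0, cfg$frac_pyroglu <= 1)
  structure(cfg, class = "sim_config")
}

# Log10-scale sd equivalent to a linear-scale CV (log-normal identity).
cv_to_sigma10 <- function(cv_percent) {
  sqrt(log1p((cv_percent / 100)^2)) / log(10)
}

# Residue pools. Mature cores exclude K/R so cleavage inference is exact;
# first/last residues additionally avoid unintended PTM donors.
.aa_all <- names(.residue_mass)
.aa_core <- setdiff(.aa_all, c("K", "R"))
.aa_core_first <- setdiff(.aa_core, c("Q", "E"))
.aa_core_last <- setdiff(.aa_core, "G")
.aa_hydrophobic <- c("A", "L", "I", "V", "F", "M", "W", "S", "T", "C")

.rand_range <- function(range, n = 1) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

.make_mature_core <- function(len, pyroglu) {
  first <- if (pyroglu) sample(c("Q", "E"), 1) else sample(.aa_core_first, 1)
  last <- sample(.aa_core_last, 1)
  mid <- if (len > 2) sample(.aa_core, len - 2, replace = TRUE) else character(0)
  paste0(first, paste(mid, collapse = ""), last)
}

#' Generate a synthetic proteome with known precursor structure
#'
#' Each synthetic precursor is a signal peptide (hydrophobic-biased
#' residues) followed by mature-peptide segments alternating with dibasic
#' cleavage regions (KK/KR/RK/RR). A configurable fraction of mature
#' peptides carries a C-terminal amidation-donor glycine or an N-terminal
#' pyroglutamate donor (Q/E). Decoy proteins lacking a signal peptide
#' and/or dibasic sites are interleaved. The emitted ground truth is the
#' exact mature-peptide complement, so precursor discovery can be
#' round-trip tested.
#'
#' @param config A [sim_config()].
#' @return List with `proteome` (`AAStringSet`), `signals` (tibble of true
#'   signal-peptide calls: `protein_id`, `has_signal`,
#'   `cleavage_position`), `ground_truth` (tibble: `protein_id`,
#'   `peptide`, `start`, `end`, `n_flank`, `c_flank`, `amidated`,
#'   `pyroglu`), and `config`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    sites <- c("KK", "KR", "RK", "RR")
    truth <- list(); seqs <- character(0); signals <- list()
    for (i in seq_len(config$n_precursors)) {
      pid <- sprintf("NPP%03d", i)
      sp_len <- .rand_range(config$signal_peptide_length)
      signal <- paste0("M", paste(sample(.aa_hydrophobic, sp_len - 1,
                                         replace = TRUE), collapse = ""))
      n_pep <- .rand_range(config$n_peptides_per_precursor)
      lead_site <- runif(1) < 0.5 # dibasic region directly after the signal?
      body <- character(0); pep_rows <- list()
      pos <- sp_len
      for (j in seq_len(n_pep)) {
        if (j > 1 || lead_site) {
          site <- sample(sites, 1)
          body <- c(body, site); pos <- pos + 2L
        }
        amid <- runif(1) < config$frac_amidated
        pg <- runif(1) < config$frac_pyroglu
        core <- .make_mature_core(.rand_range(config$peptide_length), pg)
        seg <- if (amid) paste0(core, "G") else core
        body <- c(body, seg)
        pep_rows[[j]] <- tibble(
          protein_id = pid, peptide = core,
          start = pos + 1L, end = pos + nchar(seg),
          n_flank = if (j == 1 && !lead_site) "signal_boundary" else "dibasic",
          c_flank = if (j == n_pep) "chain_end" else "dibasic",
          amidated = amid,
          pyroglu = .flag_pyroglu(substr(core, 1, 1)))
        pos <- pos + nchar(seg)
      }
      seqs[pid] <- paste0(signal, paste(body, collapse = ""))
      signals[[pid]] <- tibble(protein_id = pid, has_signal = TRUE,
                               cleavage_position = sp_len)
      truth[[pid]] <- dplyr::bind_rows(pep_rows)
    }
    for (i in seq_len(config$n_decoys)) {
      pid <- sprintf("DEC%03d", i)
      if (i %% 2 == 1) {
        # decoy without signal peptide (may contain dibasic sites)
        seqs[pid] <- paste(sample(.aa_all, 120, replace = TRUE), collapse = "")
        signals[[pid]] <- tibble(protein_id = pid, has_signal = FALSE,
                                 cleavage_position = NA_integer_)
      } else {
        # decoy with signal peptide but no dibasic sites downstream
        sp_len <- .rand_range(config$signal_peptide_length)
        seqs[pid] <- paste0(
          "M", paste(sample(.aa_hydrophobic, sp_len - 1, replace = TRUE),
                     collapse = ""),
          paste(sample(.aa_core, 100, replace = TRUE), collapse = ""))
        signals[[pid]] <- tibble(protein_id = pid, has_signal = TRUE,
                                 cleavage_position = sp_len)
      }
    }
    list(proteome = Biostrings::AAStringSet(seqs),
         signals = dplyr::bind_rows(signals),
         ground_truth = dplyr::bind_rows(truth),
         config = config)
  })
}

#' Write a proteome to FASTA
#'
#' @param proteome `AAStringSet` or named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  if (!inherits(proteome, "AAStringSet")) {
    proteome <- Biostrings::AAStringSet(proteome)
  }
  Biostrings::writeXStringSet(proteome, path)
  invisible(path)
}

#' Generate a transition-level PRM report with known effects
#'
#' Emulates the quantitative observable of a scheduled PRM experiment: for
#' every mature peptide and replicate, fragment peak areas are drawn from a
#' log-normal abundance model (log10-normal with sd matching the configured
#' technical CV); condition 2 abundances are shifted by the peptide's
#' assigned log10 fold change; a per-run global scale factor (to be undone
#' by median normalization) multiplies all areas; peptides whose sampled
#' abundance falls below the dropout threshold in a replicate are flagged
#' undetected and carry background-level areas near the dataset floor. A
#' fraction of peptides appears with a second charge state and, when the
#' sequence contains methionine, an oxidized variant. An MS1 feature table
#' carrying the same per-run scale factors is emitted for normalization.
#'
#' @param config A [sim_config()].
#' @param ground_truth Peptide table from [generate_proteome()], or any
#'   tibble with a `peptide` column; peptides must be unique.
#' @param conditions Length-2 character vector of condition labels.
#' @param n_fragments Fragments per peptide ion.
#' @return List with `report` (tibble: `run`, `condition`, `replicate`,
#'   `peptide`, `charge`, `variant`, `fragment`, `area`, `detected`,
#'   `ref_rt`), `ms1` (tibble: `run`, `feature`, `area`), `truth` (tibble:
#'   `peptide`, `mean_log10_1`, `mean_log10_2`, `fold_change`, `ref_rt`),
#'   and `run_scale` (tibble of injected per-run scale factors).
#' @export
generate_transition_report <- function(config, ground_truth,
                                       conditions = c("L3", "dauer"),
                                       n_fragments = 6L) {
  stopifnot(inherits(config, "sim_config"), length(conditions) == 2)
  peptides <- unique(ground_truth$peptide)
  n_pep <- length(peptides)
  n_rep <- config$n_replicates_per_condition
  sigma10 <- cv_to_sigma10(config$technical_cv_percent)
  local_seed(config$seed + 1L, {
    base <- config$base_log10_abundance
    m1 <- rnorm(n_pep, base[[1]], base[[2]])
    fc <- rep_len(config$fold_changes, n_pep)
    m2 <- m1 + log10(fc)
    ref_rt <- runif(n_pep, 0, config$gradient_minutes)
    has_charge3 <- runif(n_pep) < 0.3
    has_metox <- grepl("M", peptides, fixed = TRUE) & runif(n_pep) < 0.5
    frag_w <- lapply(seq_len(n_pep), function(i) {
      w <- sort(runif(n_fragments), decreasing = TRUE); w / sum(w)
    })
    runs <- tidyr::expand_grid(condition = conditions,
                               replicate = seq_len(n_rep))
    runs$run <- sprintf("run_%s_%d", runs$condition, runs$replicate)
    runs$scale <- 10^rnorm(nrow(runs), 0, 0.1)

    n_runs <- nrow(runs)
    rows <- vector("list", n_pep)
    for (i in seq_len(n_pep)) {
      # ion variants share the peptide's sampled abundance in a replicate
      variants <- tibble(charge = 2L, variant = "none", share = 1)
      if (has_charge3[i]) {
        variants <- tibble(charge = c(2L, 3L), variant = "none",
                           share = c(0.7, 0.3))
      }
      if (has_metox[i]) {
        variants <- dplyr::bind_rows(
          dplyr::mutate(variants, share = .data$share * 0.8),
          tibble(charge = 2L, variant = "metox", share = 0.2))
      }
      mu <- ifelse(runs$condition == conditions[1], m1[i], m2[i])
      x <- mu + rnorm(n_runs) * sigma10
      abundance <- 10^x
      detected <- abundance >= config$dropout_threshold
      # undetected replicates carry background integration near the floor
      bg <- config$dropout_threshold * runif(n_runs, 0.005, 0.02)
      abundance[!detected] <- bg[!detected]
      nv <- nrow(variants)
      per_run <- nv * n_fragments
      # fragment-by-variant weights, fragment index moving fastest
      vw <- as.vector(outer(frag_w[[i]], variants$share))
      rows[[i]] <- tibble(
        run = rep(runs$run, each = per_run),
        condition = rep(runs$condition, each = per_run),
        replicate = rep(runs$replicate, each = per_run),
        peptide = peptides[i],
        charge = rep(rep(variants$charge, each = n_fragments),
                     times = n_runs),
        variant = rep(rep(variants$variant, each = n_fragments),
                      times = n_runs),
        fragment = rep(sprintf("y%d", seq_len(n_fragments)),
                       times = nv * n_runs),
        area = rep(abundance * runs$scale, each = per_run) *
          rep(vw, times = n_runs),
        detected = rep(detected, each = per_run),
        ref_rt = ref_rt[i])
    }
    # MS1 features: fixed base areas scaled per run, so the per-run median
    # carries exactly the injected scale factor.
    feat_base <- 10^rnorm(50, 4, 0.6)
    ms1 <- tidyr::expand_grid(run = runs$run, feature = seq_along(feat_base))
    ms1$area <- feat_base[ms1$feature] * runs$scale[match(ms1$run, runs$run)]
    list(report = dplyr::bind_rows(rows),
         ms1 = ms1,
         truth = tibble(peptide = peptides, mean_log10_1 = m1,
                        mean_log10_2 = m2, fold_change = fc, ref_rt = ref_rt),
         run_scale = tibble(run = runs$run, scale = runs$scale))
  })
}

#' Generate alternating crawl/nictation bout tracks
#'
#' Two-state alternating renewal process: bout durations are exponential
#' with means `1/bout_rate_nict` and `1/bout_rate_crawl`, truncated at the
#' observation window. Each track starts in its stationary state (the
#' initial state is nictation with probability `mu_n / (mu_n + mu_c)`);
#' with memoryless durations this makes the expected nictation ratio equal
#' to the stationary ratio at any window length.
#'
#' @param config A [sim_config()].
#' @param n_individuals Number of tracks.
#' @param group,batch Labels attached to every track.
#' @return List with `tracks` (tibble: `individual`, `group`, `batch`,
#'   `t_total`), `bouts` (tibble of nictation intervals: `individual`,
#'   `start`, `end`), and `truth` (list with the true mean bout durations).
#' @export
generate_bout_tracks <- function(config, n_individuals = 30L,
                                 group = "N2", batch = "batch1") {
  stopifnot(inherits(config, "sim_config"), n_individuals >= 1)
  mu_n <- 1 / config$bout_rate_nict
  mu_c <- 1 / config$bout_rate_crawl
  t_obs <- config$observation_seconds
  p_nict <- mu_n / (mu_n + mu_c)
  local_seed(config$seed + 2L, {
    bouts <- list()
    for (i in seq_len(n_individuals)) {
      id <- sprintf("%s_%s_%03d", group, batch, i)
      t <- 0; nict <- runif(1) < p_nict
      starts <- c(); ends <- c()
      while (t < t_obs) {
        d <- rexp(1, if (nict) config$bout_rate_nict else config$bout_rate_crawl)
        if (nict) {
          starts <- c(starts, t); ends <- c(ends, min(t + d, t_obs))
        }
        t <- t + d
        nict <- !nict
      }
      if (length(starts)) {
        bouts[[id]] <- tibble(individual = id, start = starts, end = ends)
      }
    }
    ids <- sprintf("%s_%s_%03d", group, batch, seq_len(n_individuals))
    list(tracks = tibble(individual = ids, group = group, batch = batch,
                         t_total = t_obs),
         bouts = if (length(bouts)) dplyr::bind_rows(bouts) else
           tibble(individual = character(), start = double(), end = double()),
         truth = list(mean_nict_s = mu_n, mean_crawl_s = mu_c,
                      stationary_ratio = p_nict))
  })
}
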