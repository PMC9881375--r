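# Rule-based neuropeptide precursor discovery: signal peptide + dibasic
# cleavage sites, mature-peptide derivation with PTM inference, peptide
# mapping, and neuropeptide-complement (Venn) accounting.

# Monoisotopic residue masses (Da), standard 20-letter alphabet.
.residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.water_mass <- 18.010565

#' Recognized post-translational modification mass shifts
#'
#' Mass deltas (Da) used throughout the package, following the reporting
#' convention of peptidomics search engines: C-terminal amidation is counted
#' relative to the free acid of the mature sequence (the glycine donor is
#' already removed), pyroglutamate relative to the unmodified N-terminal
#' residue.
#'
#' @return Named numeric vector of mass shifts in Da:
#'   `amidation` (-0.98), `pyroglu_from_Q` (-17.03), `pyroglu_from_E`
#'   (-18.01), `met_oxidation` (+15.99), `cys_half_bridge` (-1.01).
#' @export
ptm_mass_shifts <- function() {
  c(amidation = -0.98, pyroglu_from_Q = -17.03, pyroglu_from_E = -18.01,
    met_oxidation = +15.99, cys_half_bridge = -1.01)
}

#' Monoisotopic peptide mass with optional terminal modifications
#'
#' @param sequence Amino-acid string (uppercase one-letter codes). `X` is not
#'   allowed here since its mass is undefined.
#' @param amidated Apply the C-terminal amidation shift (-0.98 Da)?
#' @param pyroglu One of `"none"`, `"fromQ"`, `"fromE"`.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("APLDF")
#' peptide_mass("APLDF", amidated = TRUE)
#' @export
peptide_mass <- function(sequence, amidated = FALSE,
                         pyroglu = c("none", "fromQ", "fromE")) {
  pyroglu <- match.arg(pyroglu)
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) == 0) stop("empty peptide sequence")
  if (!all(aa %in% names(.residue_mass))) {
    stop("sequence contains residues with undefined mass: ",
         paste(setdiff(aa, names(.residue_mass)), collapse = ", "))
  }
  shifts <- ptm_mass_shifts()
  m <- sum(.residue_mass[aa]) + .water_mass
  if (amidated) m <- m + shifts[["amidation"]]
  m + switch(pyroglu,
             none = 0,
             fromQ = shifts[["pyroglu_from_Q"]],
             fromE = shifts[["pyroglu_from_E"]])
}

#' Locate dibasic cleavage regions downstream of the signal peptide
#'
#' Scans a precursor for dibasic motifs (KK, KR, RK, RR) downstream of the
#' signal-peptide boundary. Overlapping motifs are merged: a maximal run of
#' two or more consecutive basic residues (K/R) is reported as a single
#' cleavage region, so e.g. `KRR` yields one region of width 3. A run that
#' begins at the first residue after the boundary is counted with its full
#' downstream extent. Single basic residues are not cleavage sites.
#'
#' @param sequence Precursor amino-acid string.
#' @param signal_end 1-based index of the last signal-peptide residue; use 0
#'   for a protein treated as having no signal peptide.
#' @return Tibble with one row per cleavage region: `start`, `end` (1-based
#'   inclusive coordinates on the precursor) and `motif` (the basic run).
#' @examples
#' find_cleavage_sites("MAFILSAKRSLD", signal_end = 7)
#' @export
find_cleavage_sites <- function(sequence, signal_end = 0) {
  n <- nchar(sequence)
  signal_end <- as.integer(signal_end)
  if (n == 0) stop("empty protein sequence")
  if (signal_end < 0 || signal_end >= n) {
    stop("signal boundary (", signal_end, ") inconsistent with protein length (",
         n, ")")
  }
  aa <- strsplit(sequence, "")[[1]]
  basic <- aa %in% c("K", "R")
  basic[seq_len(signal_end)] <- FALSE # never look inside the signal peptide
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  tibble(
    start = starts[keep],
    end = ends[keep],
    motif = vapply(which(keep), function(i) {
      substr(sequence, starts[i], ends[i])
    }, character(1))
  )
}

.empty_peptides <- function() {
  tibble(precursor_id = character(), sequence = character(),
         start = integer(), end = integer(), n_flank = character(),
         c_flank = character(), amidated = logical(), pyroglu = character(),
         mass_shift_da = double())
}

.flag_pyroglu <- function(first_residue) {
  switch(first_residue, Q = "fromQ", E = "fromE", "none")
}

#' Derive mature peptides from a precursor
#'
#' Cuts the precursor at its dibasic cleavage regions and the signal-peptide
#' boundary. Candidate mature peptides are the non-empty segments between
#' consecutive cleavage regions, the segment between the signal boundary and
#' the first region, and (optionally) the segment after the last region. A
#' trailing glycine is consumed as the amidation donor (`amidated = TRUE`,
#' -0.98 Da); a leading glutamine/glutamate is flagged as an optional
#' pyroglutamate variant (-17.03 / -18.01 Da).
#'
#' @inheritParams find_cleavage_sites
#' @param sites Cleavage regions as returned by [find_cleavage_sites()];
#'   computed if `NULL`.
#' @param include_cterm Accept the segment between the last cleavage region
#'   and the chain C-terminus as a candidate peptide? Default `TRUE`; the
#'   detected neuropeptides of real proteomes require it.
#' @param id Precursor identifier carried into the output.
#' @return Tibble of mature peptides: `precursor_id`, `sequence` (mature,
#'   amidation-donor glycine removed), `start`, `end` (1-based inclusive
#'   segment coordinates on the precursor, including any donor glycine),
#'   `n_flank` (`signal_boundary`, `dibasic`, or `chain_start`), `c_flank`
#'   (`dibasic` or `chain_end`), `amidated`, `pyroglu`, `mass_shift_da`.
#' @examples
#' cleave_precursor("MALWTRLLPLKRAPLDFGKRSMDE", signal_end = 10)
#' @export
cleave_precursor <- function(sequence, signal_end = 0, sites = NULL,
                             include_cterm = TRUE, id = NA_character_) {
  if (is.null(sites)) sites <- find_cleavage_sites(sequence, signal_end)
  n <- nchar(sequence)
  seg_start <- c(signal_end + 1L, sites$end + 1L)
  seg_end <- c(sites$start - 1L, n)
  k <- length(seg_start)
  shifts <- ptm_mass_shifts()
  out <- vector("list", k)
  for (i in seq_len(k)) {
    s <- seg_start[i]; e <- seg_end[i]
    if (e < s) next # empty segment (adjacent regions)
    c_flank <- if (i == k) "chain_end" else "dibasic"
    if (c_flank == "chain_end" && !include_cterm && nrow(sites) > 0) next
    seg <- substr(sequence, s, e)
    amidated <- endsWith(seg, "G") && nchar(seg) > 1L
    core <- if (amidated) substr(seg, 1, nchar(seg) - 1L) else seg
    if (nchar(core) == 0 || core == "G") next
    pg <- .flag_pyroglu(substr(core, 1, 1))
    n_flank <- if (i > 1) "dibasic" else if (signal_end > 0) "signal_boundary" else "chain_start"
    out[[i]] <- tibble(
      precursor_id = id, sequence = core, start = s, end = e,
      n_flank = n_flank, c_flank = c_flank,
      amidated = amidated, pyroglu = pg,
      mass_shift_da = amidated * shifts[["amidation"]] +
        switch(pg, fromQ = shifts[["pyroglu_from_Q"]],
               fromE = shifts[["pyroglu_from_E"]], 0)
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) .empty_peptides() else res
}

#' Annotate a protein as a candidate neuropeptide precursor
#'
#' A protein is a candidate precursor when (1) it carries a signal peptide
#' and (2) it yields at least one properly flanked mature peptide: when a
#' detected-peptide list is supplied, at least one detected peptide must
#' match a predicted mature peptide exactly; otherwise at least one dibasic
#' cleavage site must exist downstream of the signal boundary.
#'
#' @inheritParams cleave_precursor
#' @param has_signal Does the protein carry a predicted signal peptide?
#' @param detected_peptides Optional character vector of detected (mature)
#'   peptide sequences.
#' @return List with `id`, `is_candidate`, `evidence` (list: `has_signal`,
#'   `n_cleavage_sites`, `n_detected_flanked`), and `mature_peptides`
#'   (tibble as from [cleave_precursor()]; empty when there is no signal).
#' @export
annotate_precursor <- function(sequence, has_signal, signal_end = 0,
                               detected_peptides = NULL,
                               include_cterm = TRUE, id = NA_character_) {
  if (!has_signal) {
    return(list(id = id, is_candidate = FALSE,
                evidence = list(has_signal = FALSE, n_cleavage_sites = 0L,
                                n_detected_flanked = 0L),
                mature_peptides = .empty_peptides()))
  }
  sites <- find_cleavage_sites(sequence, signal_end)
  peps <- cleave_precursor(sequence, signal_end, sites,
                           include_cterm = include_cterm, id = id)
  n_det <- if (is.null(detected_peptides)) 0L else
    sum(detected_peptides %in% peps$sequence)
  is_candidate <- if (is.null(detected_peptides)) nrow(sites) >= 1L
                  else n_det >= 1L
  list(id = id, is_candidate = is_candidate,
       evidence = list(has_signal = TRUE, n_cleavage_sites = nrow(sites),
                       n_detected_flanked = as.integer(n_det)),
       mature_peptides = peps)
}

# as.character() strips names from plain character vectors; keep them.
.proteome_seqs <- function(proteome) {
  nm <- names(proteome)
  seqs <- as.character(proteome)
  names(seqs) <- nm
  seqs
}

#' Annotate every protein of a proteome
#'
#' @param proteome Named character vector or `Biostrings::AAStringSet` of
#'   protein sequences.
#' @param signals Tibble of signal-peptide predictions with columns
#'   `protein_id`, `has_signal`, `cleavage_position` (1-based index of the
#'   last signal residue; ignored when `has_signal` is `FALSE`).
#' @inheritParams annotate_precursor
#' @return List with `annotations` (tibble: `protein_id`, `is_candidate`,
#'   `has_signal`, `n_cleavage_sites`, `n_detected_flanked`, `n_peptides`)
#'   and `mature_peptides` (tibble over all candidate precursors).
#' @export
annotate_proteome <- function(proteome, signals, detected_peptides = NULL,
                              include_cterm = TRUE) {
  seqs <- .proteome_seqs(proteome)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("proteome must have unique names")
  }
  rows <- lapply(names(seqs), function(pid) {
    sig <- signals[signals$protein_id == pid, ]
    if (nrow(sig) != 1) stop("missing or duplicated signal prediction for ", pid)
    ann <- annotate_precursor(
      seqs[[pid]], has_signal = sig$has_signal,
      signal_end = if (sig$has_signal) sig$cleavage_position else 0,
      detected_peptides = detected_peptides,
      include_cterm = include_cterm, id = pid)
    list(
      row = tibble(protein_id = pid, is_candidate = ann$is_candidate,
                   has_signal = ann$evidence$has_signal,
                   n_cleavage_sites = ann$evidence$n_cleavage_sites,
                   n_detected_flanked = ann$evidence$n_detected_flanked,
                   n_peptides = nrow(ann$mature_peptides)),
      peps = if (ann$is_candidate) ann$mature_peptides else NULL
    )
  })
  list(annotations = dplyr::bind_rows(lapply(rows, `[[`, "row")),
       mature_peptides = dplyr::bind_rows(lapply(rows, `[[`, "peps")))
}

#' Strip modification annotations from peptide strings
#'
#' Removes bracketed modification annotations (e.g. `"M(+15.99)"`) and any
#' non-letter characters, and upper-cases the result.
#'
#' @param peptides Character vector.
#' @return Bare uppercase sequences.
#' @export
strip_modifications <- function(peptides) {
  toupper(gsub("[^A-Za-z]", "", gsub("\\([^)]*\\)|\\[[^]]*\\]", "", peptides)))
}

#' Map detected peptides back to precursor proteins
#'
#' Exact substring matching of (modification-stripped) peptide sequences
#' against a proteome. Peptides matching several proteins are flagged
#' ambiguous and contribute one row per distinct matching protein.
#'
#' @param peptides Character vector of detected peptide sequences, possibly
#'   carrying modification annotations.
#' @param proteome Named character vector or `AAStringSet`.
#' @return List with `mapping` (tibble: `peptide`, `protein_id`,
#'   `ambiguous`), `unmatched` (character vector), and `n_precursors`
#'   (number of distinct proteins hit).
#' @export
map_peptides_to_precursors <- function(peptides, proteome) {
  if (any(!nzchar(peptides))) stop("empty peptide sequences are not allowed")
  seqs <- .proteome_seqs(proteome)
  if (is.null(names(seqs))) stop("proteome must be named")
  bare <- strip_modifications(peptides)
  hits <- lapply(bare, function(p) names(seqs)[grepl(p, seqs, fixed = TRUE)])
  n_hits <- lengths(hits)
  mapping <- tibble(
    peptide = rep(peptides, n_hits),
    protein_id = unlist(hits, use.names = FALSE) %||% character(0),
    ambiguous = rep(n_hits > 1L, n_hits)
  )
  list(mapping = mapping,
       unmatched = peptides[n_hits == 0L],
       n_precursors = dplyr::n_distinct(mapping$protein_id))
}

#' Three-set complement accounting of a neuropeptide gene census
#'
#' Partitions the union of three gene-id sets — MS-detected, in-silico
#' predicted, and cross-species homolog — into the seven exclusive Venn
#' regions plus the union, the accounting used to report the expansion of a
#' species' neuropeptide complement.
#'
#' @param detected,predicted,homolog Character vectors of gene ids sharing
#'   one id space (orthology resolution is upstream of this function).
#' @return List with `regions` (named integer vector over the 7 exclusive
#'   regions), `set_sizes`, and `union` (total complement size).
#' @export
classify_complement <- function(detected, predicted, homolog) {
  d <- unique(detected); p <- unique(predicted); h <- unique(homolog)
  u <- union(union(d, p), h)
  in_d <- u %in% d; in_p <- u %in% p; in_h <- u %in% h
  regions <- c(
    all_three          = sum(in_d & in_p & in_h),
    detected_predicted = sum(in_d & in_p & !in_h),
    detected_homolog   = sum(in_d & !in_p & in_h),
    predicted_homolog  = sum(!in_d & in_p & in_h),
    detected_only      = sum(in_d & !in_p & !in_h),
    predicted_only     = sum(!in_d & in_p & !in_h),
    homolog_only       = sum(!in_d & !in_p & in_h)
  )
  list(regions = regions,
       set_sizes = c(detected = length(d), predicted = length(p),
                     homolog = length(h)),
       union = length(u))
}

# Kyte-Doolittle hydropathy, used only by the naive signal heuristic below.
.kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Naive hydrophobic-window signal-peptide heuristic
#'
#' A deliberately simple stand-in for a real signal-peptide predictor,
#' intended for synthetic proteomes only: scores the most hydrophobic
#' `window`-residue stretch within the first `n_search` residues
#' (Kyte-Doolittle mean) and calls a signal peptide when it exceeds
#' `threshold`. This is not SignalP and must not be used on real proteomes;
#' real signal-peptide calls are an input to the discovery functions.
#'
#' @param sequence Protein sequence.
#' @param window Sliding-window width (residues).
#' @param n_search How far from the N-terminus to search.
#' @param threshold Mean-hydropathy call threshold.
#' @return List `has_signal`, `cleavage_position` (end of the best window,
#'   `NA` if no call), `score`.
#' @export
naive_signal_heuristic <- function(sequence, window = 8L, n_search = 30L,
                                   threshold = 1.5) {
  aa <- strsplit(substr(sequence, 1, n_search), "")[[1]]
  vals <- unname(.kd[aa]); vals[is.na(vals)] <- 0
  if (length(vals) < window) {
    return(list(has_signal = FALSE, cleavage_position = NA_integer_,
                score = -Inf))
  }
  sums <- stats::filter(vals, rep(1, window), sides = 1)
  sums <- sums[!is.na(sums)]
  best <- which.max(sums)
  score <- max(sums) / window
  list(has_signal = score > threshold,
       cleavage_position = if (score > threshold)
         as.integer(best + window - 1L) else NA_integer_,
       score = score)
}
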