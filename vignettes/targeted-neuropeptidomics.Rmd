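---
title: "Methods: targeted neuropeptidomics and nictation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted neuropeptidomics and nictation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemapep)
```

## Scope

Neuropeptides are cleaved out of larger precursor proteins and further
matured by post-translational modification, so neither RNA-Seq nor
protein-level proteomics measures them directly. `nemapep` implements the
computational side of a comparative neuropeptidomics workflow for
nematodes: rule-based precursor discovery from a proteome, construction
and retention-time (RT) scheduling of parallel reaction monitoring (PRM)
assays, label-free differential quantification of mature neuropeptides
between two conditions (the motivating contrast is *C. elegans* dauer
versus L3 juveniles), a simulation-based power analysis, and the
behavioral statistics used to test candidate neuropeptide genes for a
role in nictation. A synthetic-data module generates all inputs with the
statistical structure the analysis assumes, so the whole pipeline is
testable without instrument data.

## Precursor discovery

A protein is treated as a candidate neuropeptide precursor when it
carries a signal peptide and yields at least one properly flanked mature
peptide. Cleavage is modeled with explicit dibasic rules: any maximal run
of two or more consecutive basic residues (K/R) downstream of the
signal-peptide boundary is one cleavage region (`KRR` is a single region,
not two overlapping motifs). Mature peptides are the non-empty segments
between consecutive regions, between the signal boundary and the first
region, and — by default — between the last region and the chain
C-terminus. The C-terminal segment is accepted because detected peptides
in real data sets require it; `include_cterm = FALSE` disables this.
Monobasic and tetrabasic cleavage models are deliberately out of scope:
the discovery criterion is the dibasic rule, and adding weaker site
classes would change the candidate set's meaning.

PTM inference is structural: a trailing glycine is consumed as the
amidation donor (−0.98 Da relative to the free acid of the mature
sequence), and a leading Gln/Glu is flagged as an optional pyroglutamate
variant (−17.03 / −18.01 Da). The half-cystine shift (−1.01 Da) and Met
oxidation (+15.99 Da) are recognized mass shifts (`ptm_mass_shifts()`)
but are not inferred from sequence. Coordinates are 1-based inclusive
throughout, and the segment coordinates of a peptide include its donor
glycine, so concatenating signal peptide, cleavage regions, and segments
reconstructs the precursor exactly — a property the test suite asserts.

Signal-peptide calls are an *input* (in practice they come from a
dedicated predictor). `naive_signal_heuristic()` is a deliberately simple
hydrophobic-window score intended only for synthetic proteomes; it is not
a replacement for a real predictor and is documented as such.

Peptide-to-precursor mapping is exact substring matching after stripping
modification annotations; ambiguous peptides count once per distinct
precursor. The three-set complement accounting
(`classify_complement()`) partitions MS-detected, in-silico-predicted,
and cross-species-homolog gene sets into the seven exclusive Venn
regions; orthology resolution between species id spaces is upstream of
this package (a user-supplied mapping).

## PRM assay design and scheduling

`build_assay()` follows standard targeted-proteomics practice: per
peptide, the precursor charge state with the highest total library
fragment intensity is selected (ties to the lower charge), then the six
most intense fragments (ties broken by fragment label so the choice is
deterministic and stable across runs).

Scheduling windows are full-width and centered on the reference RT; the
package defaults mirror common practice of 5 min windows for technical
replicates and 10 min when biological variability widens RT spread.
Instrument software solves the injection-assignment problem opaquely;
here `schedule_injections()` uses greedy first-fit by ascending window
center under a hard concurrency cap, which is reproducible and auditable.
The test suite compares it against an exhaustive-partition oracle on
small instances: greedy is never below the optimum and stayed within one
injection of it in every tested instance. The unscheduled baseline is
modeled as `ceiling(n_targets / cap)` — every target monitored for the
whole run. Real unscheduled workflows can need more injections than this
ceiling (cycle-time constraints are not modeled), so the model is a
documented approximation, not a reproduction of any published injection
count.

## Quantification rules

The differential pipeline applies, in order:

1. **Transition retention** — user-flagged interfering transitions are
   removed only while at least five transitions remain per peptide;
   removals that would cross the floor are refused and reported.
2. **Aggregation** — fragment areas are summed over fragments, charge
   states, and Met-oxidized variants, per run.
3. **Median MS1 normalization** — each run is divided by its MS1-feature
   median relative to the grand median of run medians. When no MS1
   feature table is available, the per-run median of the peptide areas is
   used with a warning.
4. **Detection policy** — a peptide is retained as `quantifiable` when
   detected in all replicates of both conditions, as `on_off` when
   detected in all replicates of exactly one condition and none of the
   other (the undetected side keeps its integrated background signal);
   any partial pattern is dropped. Remaining zeros are then replaced by
   the minimum positive value of the entire retained dataset.
5. **Testing** — areas are log10-transformed and compared with a
   two-sided Student's t test. Equal variances are assumed by default
   (the classical "Student's" reading); Welch is available via
   `var_equal = FALSE`. The fold change is `10^(mean2 − mean1)`.

Normalization precedes imputation so the imputation floor is on the
normalized scale; imputation precedes the log transform so zeros never
reach `log10`. No multiple-testing correction is applied to the headline
statistics — the volcano-style presentation reports raw p values — but a
Benjamini–Hochberg column (`p_bh`) is emitted alongside.

This ordering makes the pipeline scale-invariant: multiplying one run's
raw areas (and its MS1 features) by any positive constant leaves every
t statistic, p value, and fold change unchanged, which the tests verify
to 1e-9.

CVs are computed per peptide as `100·sd/mean` on linear-scale areas and
summarized as the median across peptides with the standard error of the
mean of the per-peptide CVs. Note that with few replicates the sample sd
underestimates the population sd (by the usual `c4` factor, about 8% at
n = 4), so a four-replicate median CV sits slightly below the generating
CV; the generator-level CV tests therefore use many replicates.

## Power analysis

`simulate_power()` re-implements the simulation design of the
differential experiment: per peptide and per (fold change, sample size)
cell, `n` log10 abundances per condition are drawn from normal
distributions and tested with the same pooled-variance t test, recording
the percentage of `n_sims` simulations with `p < alpha`. The default
grid is fold changes {1.1, 1.2, 1.5, 2, 4} × sample sizes
{4, 6, 8, 10, 15, 20} (30 cells) at 500 simulations per cell.

Two design choices were genuinely open. First, the effect is applied as
a one-sided shift (condition 2 mean = condition 1 mean + log10(fc));
splitting the shift symmetrically is equivalent for the test. Second,
when the two conditions have different estimated sds, each condition
keeps its own sd rather than pooling. Simulation uses per-cell seed
substreams, so any single cell can be reproduced without simulating the
rest of the grid. The suite checks one cell against the closed-form
noncentral-t power (`stats::power.t.test`) and checks monotonicity in
`n` and fold change after averaging over peptides.

## Detection statistics

"Sample overlap" is reported as 100 × (analytes detected in all samples)
/ (maximum per-sample count). The denominator is not standardized in the
field; all/max is the only simple choice consistent with the usual joint
reporting of overlap percentages and per-sample detection ranges, and it
is adopted here (all/mean is available behind `denominator = "mean"`).
Reported values are rounded to the nearest integer; the unrounded value
is always retained.

## Behavioral statistics

Nictation is quantified per individual over a fixed observation window
(default 90 s) by three indices: nictation ratio `T_nict/T_total`,
initiation index `N_nict/(T_total − T_nict)` (starts per second of
non-nictating time), and average duration `T_nict/N_nict`. These satisfy
the identity `initiation_index × average_duration = ratio/(1 − ratio)`,
which the tests assert on random tracks. Bouts truncated by the window
count as one initiation and contribute their observed duration; the
initiation index is undefined for an animal that nictates the entire
window, and the average duration for one that never nictates.

Median inter-experimental normalization rescales each batch so its
control-group median coincides with the grand (median-of-medians)
control median. The operation is multiplicative — natural for a ratio
statistic, with optional clipping to [0, 1] — with an additive variant
behind a flag, since the operation is not standardized. With three or
more batches the grand median is robust, so rescaling a single
non-median batch leaves the normalized values unchanged.

Group comparisons use a one-way linear model with Dunnett's many-to-one
adjustment: contrast statistics against the control are referred to the
equicorrelated multivariate t distribution
(`rho_ij = lambda_i·lambda_j`, `lambda_i = sqrt(n_i/(n_i + n_0))`),
evaluated with `mvtnorm::pmvt` under a fixed quadrature seed so p values
are reproducible. With a single treatment group the adjusted p value
reduces analytically to the two-sided pooled t test. The implementation
is cross-checked in the tests against both a seeded Monte-Carlo estimate
of the max-|t| null distribution and `multcomp::glht`. Statistical
analysis is performed on individual animals within batches; pooled
plots are presentation only.

Track speeds are the mean frame-to-frame displacement over time step,
scaled from pixels/s to µm/s; tracks shorter than 30 s are excluded, the
standard minimum for stable speed estimates.

## The synthetic-data generators

The generators emulate exactly the structure the analysis assumes, and
their defaults are the package's fixed study conditions:

* **Proteomes** — signal peptide (hydrophobic-biased, 16–24 residues)
  followed by 2–5 mature segments alternating with dibasic regions;
  half the peptides carry an amidation donor, a fifth a pyroglutamate
  donor; decoys lack the signal peptide or the dibasic sites. Mature
  cores avoid K/R (and unintended terminal donors) so the emitted ground
  truth is the exact cleavage-rule output, making the discovery
  round-trip a zero-false-negative, zero-false-positive test.
* **Transition reports** — peptide abundances are normal on the log10
  scale (matching the scale on which the tests operate); the technical
  CV (default 21.63%) is converted to a log10 sd via the log-normal
  identity `sigma = sqrt(log(1 + cv²))/ln 10`; fold changes enter as
  additive log10 shifts in condition 2; four replicates per condition;
  a log-normal per-run scale factor is injected and carried identically
  by an emitted MS1 feature table, so median normalization removes it
  exactly; abundances below the dropout threshold are flagged undetected
  and replaced by background areas near the dataset floor, reproducing
  the dauer-only on/off pattern when a peptide's two condition means
  straddle the threshold; reference RTs are uniform over a 50 min
  gradient.
* **Bout tracks** — alternating crawl/nictation bouts with exponential
  durations (defaults: mean 5 s nictation, 8.5 s crawl, for a
  stationary nictation ratio of ≈ 0.37, a typical wildtype dauer
  figure). Each track starts in its stationary state; because
  exponential durations are memoryless this makes the expected
  nictation ratio equal to `mu_n/(mu_n + mu_c)` at any window length,
  which the parameter-recovery tests exploit.

What the generators do **not** emulate: raw spectra, chromatographic
peak shapes, isotope envelopes, interference between transitions,
RT drift, inter-culture (biological) variance structure beyond a single
CV parameter, and non-exponential bout-duration distributions. Passing
tests therefore demonstrate the correctness of the rules and estimators,
not the field performance of the assay on real samples.

## Problem sizes and numerical choices

The test suite and the reproduction script use deliberately moderate
sizes chosen to make Monte-Carlo intervals tight while keeping runs
quick: 2000 peptides for the null type-I check, 500 simulations per
power cell, 500–600 individuals for behavioral parameter recovery, 1000
random sequences for the cleavage-site oracle, and exhaustive scheduling
oracles up to 10 targets. Ties are broken deterministically everywhere
(lower charge, lexicographic fragment labels, stable orderings), all
generators take explicit seeds and restore the caller's RNG state, and
degenerate inputs (zero pooled variance, all-window nictation, empty
bout lists, runs without MS1 features) are flagged or rejected rather
than silently propagated.

## Known limitations

* Discovery implements dibasic cleavage only; precursors processed
  exclusively at monobasic sites are invisible by design.
* The unscheduled-injection model ignores cycle-time constraints.
* Greedy scheduling is not guaranteed optimal (it was within one
  injection of the exhaustive optimum on all tested instances).
* The detection-overlap denominator is a documented convention, not a
  community standard.
* Background-signal levels for undetected peptides are a synthetic
  stand-in for re-integrated chromatographic noise.
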