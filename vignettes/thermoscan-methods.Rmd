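---
title: "Scanning transcripts for ordered and temperature-sensitive RNA structure"
author: "thermoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning transcripts for ordered and temperature-sensitive RNA structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscan)
```

## The problem

Functional RNA secondary structures leave two statistical footprints in a
transcript. First, *sequence-ordered stability*: a structure maintained by
selection is more stable than the base composition alone predicts, so its
minimum free energy (MFE) sits in the low tail of the MFE distribution of
shuffled sequences with identical composition. Second, *conformational
response to temperature*: a structure that melts (or forms) across a
physiological temperature ramp changes the shape of its Boltzmann ensemble,
which is measurable as a change in ensemble diversity.

`thermoscan` implements both screens as one pipeline:

1. **Window scan.** A fixed-width window (default 120 nt) slides along the
   transcript in steps (default 1 nt). Each window is folded at a set
   temperature; the per-window metrics are the MFE and its structure, the
   ensemble diversity (ED) and the centroid structure.
2. **Thermodynamic z-score.** For *full* runs, each window's sequence is
   shuffled mononucleotide-wise (default 100 times) and refolded. The
   z-score is `(MFE_native - mean(MFE_shuffled)) / sd(MFE_shuffled)` with
   the sample (n − 1) standard deviation; negative values indicate more
   ordered stability than composition explains. An empirical p-value (the
   fraction of shuffles at or below the native MFE, ties counted) is
   reported alongside.
3. **Consensus structure.** MFE base pairs recur across overlapping
   windows. Every pair is mapped to transcript coordinates and annotated
   with the z-scores of the windows it appeared in. Each position then
   nominates, among all pairs it participated in, the one with the lowest
   mean z; a pair enters the consensus only when *both* endpoints nominate
   it (mutual best). Ties break by higher recurrence count, then smaller
   span, then smaller 5′ coordinate — a fully deterministic rule. The
   consensus is filtered at z thresholds (none, −1, −2 by default) and
   contiguous structured regions become *motifs*, trimmed of unpaired
   flanks for downstream covariation hand-off.
4. **Temperature-differential screen (ΔED).** Scan-only runs (no
   shuffling) at a moderate and an elevated temperature — 28 °C and 42 °C
   by default — are aligned window-by-window and differenced:
   `ΔED = ED(high) − ED(low)`. Positive ΔED means the window samples a
   larger ensemble when heated (a melting, thermometer-like element);
   negative ΔED means the ensemble concentrates. Per-gene means feed
   cohort statistics (mean, sample SD, median and type-7 interpolated
   quartiles), per-gene standard scores, and a one-sample t-test of a gene
   family against a reference mean.

## Ensemble diversity

ED is defined as the expected base-pair distance between two independent
draws from the Boltzmann ensemble. With pair probabilities
$p_{ij}$ this is

$$\mathrm{ED} = \sum_{i<j} 2\, p_{ij} (1 - p_{ij}),$$

the form used by the reference engine and verified against a brute-force
average of symmetric-difference distances over enumerated ensembles. The
production engine (`RNAfold`) reports its own ensemble diversity, which is
used as-is when scanning with that engine; the centroid is the set of
pairs with $p_{ij} > \tfrac12$.

Boltzmann weights use $RT = 0.0019872\ \mathrm{kcal\,mol^{-1}K^{-1}}
\times (T_{\mathrm{C}} + 273.15)$ — the standard thermodynamic convention.

## Folding engines

Folding is pluggable behind a two-method engine interface.

**ViennaRNA adapter** (`vienna_engine()`). Production scans call
`RNAfold` in batches through a single process invocation per window set
and parse the MFE, centroid and ensemble diversity from its output (pair
probabilities come from the dot plot when a single [fold()] is asked for
them). The adapter records the program version in every output header.
The engine's option set (dangling ends, lonely pairs) is left at the
program defaults and recorded; no attempt is made to guess settings used
by any particular external study.

**Reference engine** (`toy_engine()`). A deliberately simple additive
model: each GC/CG pair contributes −3 kcal/mol, AU/UA −2, GU/UG −1;
hairpin loops need ≥ 3 unpaired nucleotides; `N` and IUPAC ambiguity
codes never pair. Its virtues are exactness and speed: MFE by
Nussinov-style dynamic programming with a deterministic traceback
(unpaired-first, then smallest partner), pair probabilities by
McCaskill-style inside/outside recursions, and — for sequences up to the
enumeration guard (18 nt) — *exhaustive enumeration* of all nested
structures, which serves as an independent oracle. The test suite asserts
that the dynamic-programming ensemble equals the enumerated ensemble to
1e−9 across random sequences.

An optional *stacking bonus* (`toy_energy_params(stack = ...)`, default
0) adds a fixed energy for every pair whose immediate interior neighbour
is also paired. The plain additive model scores scattered pairings and
contiguous helices of equal composition identically, so a planted helix
is not reliably the unique MFE; a negative stacking term (−1 kcal/mol in
the validation studies) restores the helix cooperativity of
nearest-neighbor models while keeping the model exactly enumerable. The
inside/outside recursions track the stacking factor through a paired-
state partition function, and per-nucleotide rescaling by
$\sigma = e^{\mathrm{MFE}/(RT\,n)}$ keeps partition sums inside double
range for long GC-rich windows; the scaling cancels exactly in
$p_{ij}$.

## Reproducibility and numerical choices

* Per-window shuffle streams are seeded from `(master seed, window
  start)` via a multiplicative hash, so scans are independent of
  evaluation order and reruns are byte-identical apart from a timestamp
  comment. Per-gene seeds derive from the master seed and a hash of the
  gene identifier.
* A degenerate null (`sd = 0`, e.g. homopolymer windows) yields z = 0
  with a `degenerate` flag rather than NaN; sequences shorter than the
  window are folded once as a flagged `short` window rather than dropped,
  so short transcripts do not silently vanish from cohort statistics.
  ΔED aggregation excludes flagged windows and reports how many were
  excluded.
* Internal coordinates are 0-based half-open; every file format (TSV,
  wig, bp, CT, GFF3) is written 1-based inclusive per genome-browser
  convention. Minus-strand genes map transcript position $t$ to genomic
  coordinate $g_{\mathrm{start}} + L - 1 - t$; the mapping is bijective
  and property-tested as an involution.
* Consensus pairs from different windows may cross; crossings are kept in
  the evidence table and the browser arc track (they are real competing
  evidence) and resolved only at dot-bracket/CT/motif export, dropping
  the pair with the smaller |mean z| and logging the count.
* Window metrics are anchored at the window *start* in wig output, which
  keeps window arithmetic exactly invertible.
* Motif grouping merges threshold-surviving pairs whose spans overlap or
  sit closer than `min_gap` (default 10 nt). Motif counts are inherently
  grouping-dependent; `min_gap` is an explicit, recorded parameter.
* Cohort quartiles use linear interpolation (`quantile` type 7), recorded
  in the output; the t-test reference mean is supplied by the caller
  (typically the cohort mean), keeping the statistic reusable for any
  family.

## The synthetic cohort generator

Real transcriptome data cannot ship with a package, so every stage is
exercised on synthetic cohorts built by `make_cohort()`:

* **Backgrounds** are i.i.d. sequences with controllable GC fraction
  (P(G) = P(C) = gc/2).
* **Ordered-stability signal**: `plant_hairpin(..., composition = "GC")`
  overwrites a perfect GC inverted repeat — a deep-energy, low-z element
  the scanner and consensus must recover.
* **Thermometer signal**: thermometer genes carry a regular array of
  marginally stable AU hairpins (stem 7 bp, loop 4 nt, spaced 20 nt).
  A single marginal hairpin raises ΔED only in the few windows containing
  it and is diluted in the per-gene mean; an array both multiplies the
  affected windows and creates alternative pairing registers for the
  melted arms, producing the strong positive per-gene ΔED that the
  ranking studies require. Element strength was chosen once, on the
  design principle that rank separation — not effect magnitude — is what
  the validation asserts.
* **Gene models**: each gene gets a toy isoform layout (5′UTR exon,
  intron, coding exon with 3′UTR), giving every cohort a 5′UTR–intron
  junction; the first thermometer gene's element is anchored there. A
  manifest TSV records every planted element for recovery scoring.

What the generator does *not* emulate: real dinucleotide composition and
codon structure, splice-isoform diversity, long-range base pairing beyond
the window, and nearest-neighbor loop energetics in the toy model.
Passing the synthetic studies therefore demonstrates that the pipeline's
statistics behave as designed under their own assumptions — calibrated
nulls, recoverable planted signal, nominal test size — not that any
particular biological transcript harbors a thermometer.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` run five studies, sized for a
single CPU (each seeded, each recomputed from scratch):

1. *Oracle agreement*: 30 random sequences ≤ 14 nt; dynamic-programming
   ED/pair probabilities/centroid vs exhaustive enumeration at 1e−9.
2. *Null calibration*: ≥ 200 windows of 40 nt over random sequence, 50
   shuffles each; mean window z within ±0.3 and < 2 % of |z| > 3.
3. *Planted-stem recovery*: 20 fixtures with a 10-bp GC hairpin in a
   200-nt background; ≥ 90 % of planted pairs recovered in the ≤ −1
   consensus (stacking-enabled reference model).
4. *Type-I error*: a 200-gene null cohort scanned at 28/42 °C; 500
   10-gene family draws t-tested against the cohort mean at α = 0.05
   must reject at 5 % ± 2 %.
5. *Headline direction*: 50 random 500-nt transcripts scanned with
   `RNAfold` at 28 °C and 42 °C (120-nt windows, step 10); the mean
   per-gene ΔED must be positive — heating broadens ensembles on
   average. The script also reports the median and quartiles of the
   per-gene means.

## Known limitations

* The consensus rule is a deterministic reconstruction of the
  "recurring low-z pairs" idea; it is not a byte-for-byte reimplementation
  of any external tool's output.
* The ΔED screen compares two fixed temperatures; intermediate melting
  curves are out of scope.
* No multiple-testing correction is applied across genes or families, by
  design — the screen is a ranking device, and its outputs feed targeted
  follow-up rather than hypothesis registration.
* Pseudoknots are never predicted; crossing evidence is preserved in
  track output but resolved to nested structure in file formats that
  require it.
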