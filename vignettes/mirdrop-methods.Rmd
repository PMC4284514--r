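---
title: "mirdrop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirdrop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdrop)
```

`mirdrop` analyses pooled lentiviral miRNA precursor screens: a cell pool
is infected with a library of miRNA precursors, selected under a drug or
vehicle for weeks, and the genome-integrated precursors surviving in each
arm are quantified on two-channel microarrays in biological duplicate.
This vignette documents the models, the parameter choices and their
rationale, and what the package's validation does and does not establish.

## The screen deconvolution model

### Normalization

`normalize_signals(method = "median_scale")` rescales every channel (an
array × condition combination) so all channels share the same median
intensity: channel signals are multiplied by (global median of channel
medians) / (channel median). This removes any per-channel linear gain —
dye incorporation and scanner differences between the two fluorophores —
and is the only property the downstream classification relies on: the hit
classes are invariant to multiplying any channel by a positive constant
(a property-based test asserts this). Proprietary scanner-software
normalization pipelines do more (background subtraction, spatial
correction); those steps are out of scope here and assumed to have
happened upstream or to be unnecessary for simulated data.

### Replicate summarization and the CV filter

For each miRNA and condition, `summarize_replicates()` computes the mean
and sample standard deviation (denominator *n* − 1) over replicate arrays
and the coefficient of variation CV = 100 × SD/mean. With duplicate
arrays, *n* − 1 = 1; the printed "mean ± SD" convention of screen hit
tables does not state the denominator, and the sample SD is the standard
choice. A zero mean leaves the CV undefined (`NA`), which is treated as a
filter failure.

`classify_hits()` passes a miRNA through the reproducibility filter only
when CV < `cv_max` (default 60) in **both** conditions and both condition
means exceed `signal_floor` (default 0). The both-conditions rule is the
conservative reading of a filter computed "in the duplicated treated and
control experiments": a miRNA whose readout is irreproducible in either
arm cannot support a ratio between them.

### Fold-change classification

The drug:vehicle ratio is the ratio of condition means (one ratio per
miRNA, matching a single printed ratio per table row), not the mean of
per-array ratios. Classes are assigned with strict inequalities:
ratio < `dropout_max` (default 0.2) → `dropout`; ratio > `retained_min`
(default 5) → `retained`; otherwise `neutral`; CV-filter failures →
`filtered`. Every miRNA receives exactly one class. `hit_tables()` orders
dropouts by ascending and retained miRNAs by descending ratio and renders
ratios to two decimals rounding half away from zero; this reproduces the
published tables bundled with the package except for one retained row
(miR-891b, recomputed 5.83 vs printed 5.82) where the printed means are
themselves rounded — `reproduce_tables()` flags the row rather than
hiding it.

## The screen simulator

The simulator exists so the pipeline can be validated by parameter
recovery without access to raw screen data. It models:

* **Infection.** Integrations per cell are Poisson(MOI), so the infected
  fraction is `1 − exp(−MOI)` (`infection_fraction()`). The default
  configuration derives MOI ≈ 0.357 from the 30% target infection
  fraction at which screens select their pools; multiple integration is
  excluded by construction — each infected cell carries one construct —
  matching the purpose of selecting ~30% pools.
* **Selection.** Clones grow exponentially: the relative abundance of
  miRNA *i* after *t* days is proportional to
  `a0_i · exp((g + s_i) · t)`, with `g` the shared baseline growth rate
  (default 0.35/day, a ~2-day doubling; it cancels on renormalization)
  and `s_i` the condition-specific selection coefficient in 1/day. This
  is the simplest kinetics with a closed-form oracle, and the tests
  compare the implementation against that closed form at machine
  precision. A selection difference Δs over 28 days multiplies the
  treated:control ratio by `exp(28·Δs)`: the 0.2-fold dropout threshold
  corresponds to Δs ≈ −0.057/day and the 5-fold retained threshold to
  Δs ≈ +0.057/day.
* **Readout.** Signals are `signal_scale × abundance × exp(σ·z)` with
  `z` standard normal, independent per array, channel and miRNA —
  log-normal multiplicative noise, chosen because array intensities are
  positive and duplicate scatter is linear on the intensity scale. The
  default `noise_sigma = 0.2` gives duplicate CVs around 30%, i.e. most
  probes pass the CV < 60 filter, consistent with roughly half of all
  probes (many near the detection floor) passing in real screens whose
  additional variance sources are listed below.
* **Sampling.** `sampling = "multinomial"` resamples the end-of-culture
  abundances as counts over `n_mirnas × initial_cells_per_mirna` cells,
  emulating clonal drift and harvest sampling; `"deterministic"` (the
  default) bypasses it. A `shared_pool` flag controls whether replicate
  cultures descend from one infected pool (default, the usual design) or
  are infected independently (in which case multinomial draws are taken
  per replicate).

A single `rng_seed` governs all stochastic draws; identical
configurations reproduce identical screens byte-for-byte.

### The recovery experiment

The package's end-to-end validation plants 5 dropout miRNAs at
Δs = −0.30/day and 6 retained miRNAs at Δs drawn uniformly in
[0.08, 0.12]/day in a 445-member library, simulates 28-day selection with
2 arrays per arm at `noise_sigma = 0.2`, and requires the classifier to
recover at least 90% of planted hits with at most 2% of neutral miRNAs
mislabeled, averaged over 20 seeds. The planted effect sizes were chosen
a priori: −0.30/day drives a carried clone to ~2×10⁻⁴-fold (deep, typical
of a toxic-when-lost modifier under drug), and +0.08–0.12/day yields
9–29-fold retention, the "clearly enriched" regime; both sit well past the
classification thresholds so the experiment tests the pipeline, not the
luck of borderline draws. The experiment uses deterministic sampling: at
these effect sizes a multinomial harvest of ~4.5×10⁵ cells yields zero
remaining cells for strong dropouts, and a zero-count miRNA is correctly
*filtered* (undefined CV), not classified — complete extinction is a
censoring phenomenon, not a measurable fold change. The test suite runs
the full experiment in a few seconds.

### What the simulator does not model

PCR primer and amplification bias, dye-swap designs, array background and
spatial artifacts, cell-cycle or density-dependent growth, drug
pharmacokinetics, and fitness interactions between co-cultured clones.
Passing recovery therefore shows the deconvolution logic is correct under
the stated generative assumptions; it does not certify performance on
real arrays whose noise is structured.

## Target consensus and seed-site scanning

`consensus()` counts, for each gene symbol in the union of prediction
lists, how many predictors contain it, and returns genes with support ≥ k
(the screen's follow-up used 4 predictors and k = 3). Symbols are matched
by exact case-insensitive equality after whitespace stripping; alias and
ortholog mapping are out of scope. `consensus(sets, 1)` is the union and
`consensus(sets, n)` the intersection — both identities are tested.
`venn_counts()` returns all exclusive region counts for 2–4 sets; the
counts sum to the union size.

`seed_sites()` enumerates canonical seed-match sites on the provided
(sense) strand, using the standard nomenclature: with `rc()` the reverse
complement and miRNA positions numbered 5′→3′, a 6mer matches
`rc(miRNA 2–7)`, a 7mer-m8 matches `rc(miRNA 2–8)`, and the A1 variants
add a target `A` at the position opposite miRNA nucleotide 1 (an unpaired
anchor recognized by the silencing complex, required to be `A` regardless
of the miRNA's first base). Each locus is reported once as its most
specific type. Because the A1 adduct is not a Watson–Crick seed pair,
every record also carries `seed_match` and `seed_match_length` — the
exact seed-complementary substring (7 nt when position 8 pairs, else
6 nt). On the bundled wild-type reporter insert for the CLTC 3′-UTR the
scanner finds one site: an 8mer-A1 whose exact seed match is the 7-nt
heptamer `TGAGCGT` — the "7-mer exact seed match" a prediction database
reports for this locus sits inside that site, and the distinction matters
only for nomenclature, not for the match itself. The scanner is verified
against a sliding-window brute-force oracle on random and site-implanted
sequences. Conservation, context scores and 3′-supplementary pairing are
out of scope.

## Validation statistics

* **2^−ΔΔCt** (`relative_expression()`): per replicate,
  ΔCt = Ct(target) − Ct(reference); ΔΔCt subtracts the calibrator group's
  mean ΔCt; RQ = 2^−ΔΔCt with amplification efficiency exactly 2. The
  group point estimate is the geometric mean `2^−mean(ΔΔCt)` — this makes
  the calibrator group exactly 1 by construction, which an arithmetic
  mean of replicate RQs would not (Jensen's inequality) — and the SE is
  the sample SE of the per-replicate RQs. Results are invariant to adding
  a constant to all Ct values.
* **Dual luciferase** (`dual_luciferase()`): per well, Renilla/firefly;
  relative activity divides by the mean normalized value of the reference
  miRNA arm for the same construct (or a fixed reference construct such
  as an empty-vector mock, if named). Triplicate mean ± SE.
* **Viability folds** (`viability_fold()`): mean absorbance of each
  group × timepoint over the baseline mean — the control group at the
  matching timepoint by default, since growth comparisons are made
  against the control transfection at each day — with SE propagated from
  the numerator replicates.
* **Wilcoxon signed rank** (`wilcoxon_signed_rank()`): zero differences
  dropped (Wilcoxon's original policy), midranks for ties. Exact mode
  computes the null distribution of the positive-rank sum by dynamic
  programming over doubled ranks (so midranks become integer steps),
  equivalent to enumerating all 2^n sign assignments, supported to
  n = 20. The default two-sided p is `P(|W − E[W]| ≥ |w − E[W]|)` under
  the enumerated null; a doubled-tail convention is available and matches
  `stats::wilcox.test`. The approximate mode uses the normal
  approximation with tie and continuity correction, and agrees with the
  exact mode within 0.02 for n ≥ 15 tie-free pairs.

All summaries report n, the estimate and its SE — never a bare mean. The
underlying per-sample measurements of the motivating study (raw Ct,
luminescence, immunoreactivity scores) are unpublished, so its specific
p-values and bar heights cannot be recomputed; the package covers these
procedures by identity and oracle-equivalence tests plus direction
checks, and that is the strongest claim the tests make.

## Numerical and degenerate-input policies

* Printed-style ratios round half away from zero at two decimals.
* Zero-mean rows are `filtered`, never infinite ratios.
* Abundance renormalization subtracts the maximum log-abundance before
  exponentiating, so long cultures cannot overflow.
* Classification thresholds are strict inequalities; a ratio exactly at
  0.2 or 5 is neutral.
* `load_fixtures()` verifies md5 checksums of the bundled files and fails
  loudly on drift. The bundled mature miR-574-3p sequence is sourced from
  miRBase (MIMAT0003239) and is the only bundled constant not taken from
  the published tables and methods.

## Problem sizes used in the test suite

The suite simulates screens of 12–445 miRNAs; the recovery experiment
runs the full 445-miRNA, 2-arrays-per-arm configuration over 20 seeds
(about two seconds total); oracle comparisons use 200 random
(miRNA, target) pairs and exhaustive sign enumeration to n = 12. These
sizes were chosen to exercise the full published library size while
keeping the default test run fast.
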