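---
title: "Scoring protein-protein interactions from co-elution profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein-protein interactions from co-elution profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coelute)
library(dplyr)
```

## The problem

Members of a stable protein complex travel together. When a crude cell
extract is fractionated through orthogonal chromatographic separations --
hydrophobic interaction (HIC) followed by size exclusion (SEC) -- the
subunits of an endogenous complex elute in the same fractions of both
dimensions, without any affinity tagging. If the relative abundance of every
protein in every fraction is quantified (here via isobaric iTRAQ labeling of
pooled fractions, a "multiplex" of up to eight fractions measured in one MS
run), similarity of elution profiles becomes evidence of physical
interaction.

The evidence is weak on its own: fractions contain dozens of proteins, so
unrelated proteins frequently co-elute by chance, and data-dependent
acquisition loses many detections. `coelute` implements the analysis layer
of this design: profile normalization, per-pair scoring, supervised
classification with cross-validation honest about the correlation structure
of pairs, FDR control against curated gold standards, and the audit
statistics used to judge whole interactomes.

## Data model

Everything is tabular. An `elution_dataset` bundles four tibbles: a long
abundance table (protein x multiplex x fraction), the multiplex design
(which fractions belong to which multiplex and dimension; adjacent
multiplexes of one column share a "joint" fraction so profiles can be
stitched), per-protein per-multiplex unique-peptide counts, and protein
annotations (operon, functional role, exclusion flag). A protein counts as
*detected* in a multiplex if it has at least one abundance record there;
upstream search-engine confidence filtering is assumed already applied.
Fraction identifiers are opaque strings ordered by their declaration in the
design table, which avoids any 0/1-based indexing ambiguity.

Two preprocessing steps precede all scoring:

* **Exclusion filtering.** Ribosomal proteins and the most abundant
  chaperonins co-elute promiscuously and are removed (`filter_exclusions()`).
  The default list is a ribosomal-annotation regex plus four named
  chaperonins; other organisms supply their own.
* **Apex normalization.** Within each (protein, multiplex) profile the
  highest fraction is set to 1 and the rest rescaled
  (`normalize_apex()`). Ties at the maximum all become 1 -- nothing
  downstream needs a unique apex. All-zero profiles cannot be normalized and
  are dropped with a warning. Pre-normalization ("raw") intensities are
  retained because the correlation eligibility screen below is defined on
  them.

## The eight features

Only *co-occurring* pairs -- both proteins detected in at least one common
multiplex -- can be scored; this is the candidate universe. For each
candidate pair `assemble_features()` computes:

1. **`cc_sec`** -- the maximal Pearson correlation (CC) of the two
   normalized profiles over multiplexes of the SEC dimension. A multiplex
   only counts if at least one of the two proteins has raw intensity >= 0.01
   in at least 3 of its fractions (otherwise the vectors are too sparse for
   a meaningful correlation); undetected fractions contribute 0; constant
   profiles are skipped (Pearson undefined). Pairs never co-detected in an
   eligible SEC multiplex take the sentinel -1, the worst value on the
   correlation scale.
2. **`cc_hic`** -- the same over the HIC dimension.
3. **`dice`** -- co-migration frequency: multiplexes together divided by the
   sum of each protein's individual multiplex observances, range [0, 0.5].
   This is half the classic Dice coefficient; the as-stated form is kept
   because a monotone classifier is indifferent to the constant, and
   `classic = TRUE` is available. Promiscuous "frequent fliers" detected
   in very many multiplexes score near 0 here even when they correlate with
   something by chance. Joint fractions do not double-count: the multiplex,
   not the fraction, is the unit of observation.
4. **`peptide_ratio`** -- for each shared multiplex, each protein's
   unique-peptide count there divided by its maximum count anywhere; the
   pair takes the smaller of the two ratios, maximized over shared
   multiplexes. Complex members should be near peak abundance where they
   co-elute with their partners.
5. **`min_proteins`** -- over multiplexes where the pair co-elutes with CC
   >= 0.85, the protein count of the emptiest such multiplex. Tight
   co-elution in a sparse region of fraction space is far less likely to be
   fortuitous than in a crowded one. Pairs never reaching the cutoff take
   the sentinel (largest multiplex protein count) + 1, the worst possible
   density; the count is taken on the exclusion-filtered dataset.
6. -- 8. **`string_neighborhood`, `string_cooccurrence`, `string_fusion`** --
   genome-context scores in [0, 1] (gene neighborhood conservation, gene
   co-occurrence across genomes, gene fusion), ingested from a STRING-style
   table and defaulting to 0 for absent pairs. They are inputs, never
   recomputed from genomes.

The "MS-only" model uses features 1-5; the "MS+STRING" model all eight.

## Classification and FDR control

`fit_logistic()` trains a logistic regression on gold-standard positive and
negative pairs restricted to the candidate universe. Features are z-scaled
on the training data (sentinels participate as ordinary numbers after
scaling) and a light fixed ridge penalty (`lambda = 0.01`, fitted with
glmnet along a short decreasing path for solver stability) keeps
coefficients finite on separable data. The fit is deterministic.

Pairs are not independent observations: pairs sharing a protein -- above all
pairs from one operon-encoded complex -- are strongly correlated, and naive
cross-validation would leak. `cv_score_pairs()` therefore uses
**one-operon-out** folds: for each operon, every candidate pair touching any
of its proteins is held out and the classifier is trained on gold pairs
touching none of them. Proteins without operon annotation form singleton
operons. Two implementation choices the procedure's definition leaves open:
folds whose operon contains no gold protein share the full-gold model (their
training sets are literally identical, so this is a pure optimization), and
a pair spanning two operons is validated in both folds and receives the mean
of its two held-out scores.

The FDR at a threshold is estimated from gold counts alone:
`#negatives >= t / (#positives >= t + #negatives >= t)`. This matches the
arithmetic used for published reanalyses, and it is only calibrated against
the candidate universe when gold positives and negatives are sampled at
comparable rates from their sub-populations; no prior reweighting is applied
(a documented limitation). `threshold_for_fdr()` picks the lowest threshold
whose running estimate meets the target (default 20%), inclusive of ties, so
the prediction set is maximal subject to the estimate. Thresholds above the
first gold pair are not estimable. `select_high_confidence()` exposes the
further high-confidence cut as an explicit score parameter with a quality
report for the kept and discarded portions, rather than hard-coding any
manual curation rule.

## Interactome audit statistics

* `ppi_fold_enrichment()` -- fraction of a pair set (both members detected)
  co-occurring with CC >= 0.85 in *both* dimensions, normalized by the same
  fraction over all detected-protein pairs. The full detected-pair universe
  is its own reference, so it scores exactly 1 by construction. The
  normalization removes detection-rate differences between sets.
* `estimate_fnr()` -- `1 - recovered/eligible`, in percent.
* `overlap_report()` -- union/intersection accounting of two interactomes
  plus conditional overlaps restricted to pairs detectable by the other
  assay; one minus the conditional overlap of assay A in assay B estimates
  assay B's false-negative rate, a consistency check the package verifies on
  synthetic twin assays.
* `heldout_fdr()` / `fdr_from_counts()` -- FDR re-estimation on gold pairs
  held out of training.
* `overlap_enrichment_bound()` -- if a set's novel pairs overlap an
  independent reference k-fold less than its trusted gold pairs do, the
  novel pairs are at most 100/k percent accurate even granting the gold
  pairs perfection.
* `quality_metrics()` -- same-operon percentage, functional-role sharing
  enrichment over a marginal-frequency null, and percent overlap with
  reference interactomes.

Percentages are reported at full precision; rounding is left to display.

## The synthetic experiment generator

`simulate_experiment()` produces complete experiments with known ground
truth, which is how the package demonstrates that the whole chain works.
Default geometry mirrors the two-dimensional design: HIC columns of 12
fractions tiled into 8- and 5-fraction multiplexes sharing a joint fraction,
and SEC columns of 19 fractions (run from evenly spaced HIC fractions) tiled
8/8/5 with joints, matching an 8-plex labeling scheme.

Elution peaks are Gaussian over fraction index -- the conventional
chromatographic approximation; the design gives profiles, not a peak model.
Complex members share apices in both dimensions with jitter (SD 0.25
fractions), abundances are log-normal with multiplicative measurement noise
(CV 25%), fractions below a detection floor are unobserved, and each
(protein, multiplex) detection is additionally lost with probability 0.10,
emulating data-dependent acquisition -- the loss process that motivates the
-1 sentinel. Five percent of monomers are frequent fliers: broad, two-apex
profiles present on every column, exercising the Dice feature's purpose.
Unique-peptide counts are `1 + Poisson(7 x relative abundance)`. Complexes
are encoded in one operon with probability 0.7; genome-context scores are
drawn high for co-operonic pairs, moderate for other co-complex pairs, and
near zero (with a 2% noise floor) elsewhere.

Gold standards are sampled from the candidate universe at one common rate
(35% of co-occurring true pairs as positives, the same fraction of
co-occurring non-interacting pairs as negatives). The common rate is what
makes the gold-count FDR estimator unbiased for the prediction set's true
FDR, so the end-to-end benchmark is a genuine calibration check rather than
a self-fulfilling one. Negatives are drawn from all non-co-complex
co-occurring pairs, including monomer pairs, for the same reason.

What the generator does *not* emulate: spectra and ion statistics, reporter
chemistry, shared-peptide ambiguity between homologous proteins,
column-to-column retention drift, and non-Gaussian (tailing) peaks. Passing
tests therefore show that the analysis machinery is correct and calibrated
under a faithful statistical cartoon of the assay, not that any particular
real dataset meets these assumptions.

## Benchmark problem sizes and numerical choices

The principal benchmark simulates 500 proteins in 60 complexes at the
moderate-noise defaults, runs the MS+STRING classifier under one-operon-out
cross-validation, thresholds at a 20% target FDR, and compares the empirical
FDR against planted truth with a binomial 95% confidence interval; this is
repeated over five seeds. A 200-protein / 25-complex configuration drives
the fold-enrichment and distribution-contrast checks, and property tests of
the feature layer compare against brute-force oracles on one hundred small
randomized datasets. All randomness flows from explicit integer seeds; the
generator restores the caller's RNG state.

Degenerate inputs have defined behavior throughout: all-zero profiles are
dropped with a warning, constant profiles yield no CC, pairs without an
eligible multiplex take sentinels, an unreachable FDR target returns an
empty prediction set with a warning, and a zero reference fraction makes
fold enrichment not-estimable rather than infinite.

## Known limitations

* The gold-count FDR estimator ignores the relative sizes of the positive
  and negative candidate populations; with gold sets sampled at very
  different rates it is biased, exactly the failure mode the held-out
  re-estimation statistics are designed to expose.
* The interolog mapping that lets cross-species pair sets be audited is an
  ingested translation table; no homology inference is performed.
* The ">= 0.01 raw intensity" eligibility scale is instrument-dependent;
  the threshold is a parameter, not a law.
* Complex membership is scored pairwise only; no attempt is made to
  partition predicted pairs into complexes.
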