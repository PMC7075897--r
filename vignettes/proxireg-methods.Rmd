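---
title: "Methods: from labelled pulldowns to chromatin contact pile-ups"
author: "proxireg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from labelled pulldowns to chromatin contact pile-ups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxireg)
```

proxireg implements the computational backbone of a common experimental
programme in regulatory genomics: identify the molecular neighbourhood of a
chromatin-bound bait by proximity-dependent biotin labelling, then
characterise where the recovered partners sit relative to the bait's genomic
targets, in both the linear genome (ChIP-seq pile-ups) and the folded genome
(Hi-C aggregate analyses). The motivating system is the *Drosophila*
ecdysone receptor: the EcR/Usp heterodimer fused to BioID2 or APEX2,
streptavidin pulldowns scored by LC-MS/MS spectral counts, and the insulator
cofactor CP190 examined at hormone-responsive enhancers and promoters. The
package itself is agnostic to the organism; it consumes count tables,
binned coverage, interval sets and binned contact matrices.

## Candidate selection from spectral counts

A pulldown experiment is summarised as a table of peptide counts per protein
in six conditions: two baits x two treatments (sham and hormone) plus the
unfused labelling enzyme in both treatments as the negative control. A
protein is a candidate partner when

1. its best bait-condition count reaches a technique-dependent peptide
   threshold (`min_peptides`; 10 for BioID2's long labelling window, 20 for
   the more promiscuous APEX2), compared as `>=`;
2. its enrichment over the maximal negative control,
   $\max_c \; n_c / (\max(n_{ctrl}) + \epsilon)$ over bait conditions $c$,
   reaches `min_enrichment` (2.5); and
3. it carries a prior nuclear annotation (supplied as a plain accession
   list; without one, `require_nuclear` must be `FALSE`).

Two boundary choices deserve explanation because the raw criteria leave them
open.

**Zero controls.** Most genuine partners are entirely absent from the
enzyme-only control, making the raw ratio undefined. `control_enrichment()`
therefore takes a `pseudocount` $\epsilon \ge 0$ applied to the denominator
only. With $\epsilon = 0$ a zero-control protein with any bait signal gets
the `Inf` sentinel and passes every finite threshold — the behaviour that
reproduces the bundled reference tables, which include many zero-control
rows. The default for exploratory use is $\epsilon = 1$, which shrinks
ratios for weakly covered proteins; note that it is deliberately *not* the
setting under which the bundled tables reproduce, because their strongest
shared candidate sits at $27/(10+1) = 2.45$ while its raw ratio is
$27/10 = 2.7$.

**Threshold comparisons.** Both thresholds are compared inclusively
(`>=`). The bundled APEX2 table fixes this reading: two of its rows sit
exactly at an enrichment of 2.5 and two more at exactly 20 peptides, so a
strict comparison would exclude proteins the reference selection kept.
`strict_enrichment = TRUE` restores the strict reading when wanted. The
related open choice — whether each bait condition should be compared to the
control of its own treatment arm rather than to the maximum over both — is
exposed as `per_condition_control`; the default uses the maximum, the more
conservative reading of "maximal negative control".

Quantitative treatment response uses `top3_fold_change()`: the mean peak
area of the three most intense peptides per protein (all areas when fewer
than three), ratioed between treatments with an optional `pseudo_area`
offset. Proteins move less than two-fold in either direction are flagged
unchanged; the two-fold default reflects the resolution one can expect from
label-free top-3 quantification on single runs. Aggregating by mean rather
than sum is immaterial whenever both conditions have at least three
peptides, since the factor of three cancels in the ratio.

## Coverage normalisation and pile-up profiles

Read coverage is consumed already binned (bedGraph at a fixed bin size);
read alignment, fragment extension and peak calling are upstream of this
package. `rpgc_normalize()` rescales raw per-bin counts to 1x genomic
content — dividing by
$\textrm{reads} \times \textrm{fragment length} / \textrm{genome size}$ —
so tracks from libraries of different depth are comparable;
`enrichment_over_input()` then forms the per-bin pseudocounted ratio of
ChIP to input. The ratio (not log-ratio) is used because the downstream
summaries are medians and means of binding levels displayed on a linear
scale; the pseudocount (default 1, i.e. one expected read at 1x coverage)
bounds ratios where input coverage drops.

`site_pileup()` anchors a window of `flank` bp (default 2000, a scale that
spans typical transcription-factor footprints plus nucleosome-scale
context at 50 bp bins) on each site — the summit when the site list carries
one (narrowPeak column 10), otherwise the interval midpoint — and
summarises columns by the median (robust to a few high-signal sites) or
the mean. Heatmap rows are ordered by descending row mean with stable ties
so output is reproducible. Sites whose window would leave the chromosome
are dropped and counted rather than padded, avoiding edge artefacts.

`metagene_profile()` concatenates each gene's exonic bins 5'→3' (introns
ignored), rescales the concatenation to `body_bins` columns (default 100)
by linear interpolation, and appends unscaled flanks outside the TSS and
TES. Minus-strand genes are reversed before rescaling, so "upstream" is
always promoter-side; rescaling a reversed body equals reversing the
rescaled body because the interpolation grid is symmetric.

## Hi-C aggregate analyses

Both aggregate statistics consume symmetric binned cis contact matrices
(5 kb bins by convention here), read from triplet text. Matrix balancing is
out of scope: matrices are used as given and a `balanced` flag records
what was supplied — on synthetic matrices, where the decay law is planted
directly, the distinction is moot.

**Average loop.** `make_loop_pairs()` enumerates all cross-set cis anchor
pairs (midpoint-collapsed, de-duplicated per bin pair) with separations
under 1 Mb. `average_loop()` extracts the $(2\,\textrm{pad}/\textrm{bin}+1)$
square window centred on each pair pixel (pad ±100 kb), averages windows
over pairs, and divides element-wise by the analogous average over randomly
shifted control pairs — 10 replicates per pair, each shifting both anchors
by one shared uniform offset so the separation, and hence the expected
distance-decay signal, is preserved exactly while the window stays inside
the chromosome. Averaging submatrices first and dividing once (rather than
averaging per-pair ratios) keeps the estimator stable when individual
control windows are sparse. The **loop strength** is the mean of the
central 3x3 pixels of the normalised pile-up: 1 means no enrichment over
local background, the planted factor is recovered when loops are real.
Near-diagonal pixels are not masked by default; the analyses here operate
at separations far from the diagonal, and masking is a deliberate
non-feature until a use case requires it.

**Rescaled local domain.** For each feature (TSS or enhancer) the nearest
peak farther than 25 kb defines an on-diagonal region between the two
midpoints. The region plus one region-length of pad on each side — so the
region occupies the central third of the window, and domain corners fall
at fixed relative positions regardless of region size — is extracted and
resampled to 99x99 pixels: area-preserving block means when shrinking,
bilinear interpolation when enlarging, and the identity when the window is
already 99 bins. Normalisation again uses randomly placed same-length
on-diagonal windows. No loop strength is reported for domains; the
quantity of interest is the shape of the normalised map.

Every stochastic step draws from an explicitly seeded private RNG stream
(restored afterwards), so identical configurations give bit-identical
results.

## What the synthetic data emulates — and what it does not

The generators produce data with exactly the statistical structure the
analyses assume, with truth labels, so every stage is testable offline.

* `simulate_count_table()`: spectral counts are Poisson; background
  proteins draw mean `background_mean` (default 1) everywhere, partners
  draw `background_mean * bait_factor` (default 20) in bait conditions
  only. The defaults mirror the bundled tables' regime — controls of 0–3
  against bait counts around 20. Under them the filter's per-partner
  recovery probability is analytically ~0.999: the partner bait maximum
  (four draws at mean 20) exceeds 10 with near certainty, and the control
  maximum (two draws at mean 1) rarely exceeds 3, which still needs only
  a bait count of 10 at the default pseudocount. Real spectral counts are
  over-dispersed and share peptides between homologous proteins; passing
  these tests shows the selection logic is correct, not that real
  pulldowns are this clean.
* `simulate_chip_tracks()`: input is flat Poisson background (50 reads per
  bin, large enough that the +1 ratio pseudocount biases the central
  enrichment by under 2%); ChIP adds Gaussian bumps (sd 150 bp) of
  amplitude `peak_height` x background at planted sites, so the planted
  central ChIP/input factor is `1 + peak_height`. Real coverage has
  mappability gaps, copy-number structure and fragment-length smearing
  none of which are modelled.
* `simulate_contact_matrix()`: expected counts follow a power-law decay
  $(d+1)^{-\alpha}$ with $\alpha = 1$ (typical of fly chromatin at sub-Mb
  separations), times planted loop/domain factors, realised with
  mean-preserving multiplicative log-normal noise (sdlog 0.3) and
  symmetrised. Real matrices add A/B compartment structure, TAD nesting
  and coverage biases; the synthetic matrices test background
  cancellation and planted-structure recovery, not biological inference.

## Problem sizes and tolerances in the test suite

The suite runs at desk scale, chosen so the whole suite completes in well
under a minute: 500-protein tables for recovery (20 planted partners), 200
planted ChIP sites on a 2 Mb chromosome, and 5 Mb / 1000-bin contact
matrices with 200 background pairs or 40 planted loops. At these sizes the
stochastic checks use the tolerances the estimators support: background
loop strength within [0.9, 1.1], planted factor-3 loops above 1.5 (the
3x3 centre averages the planted pixel with its shoulder), decoy pairs
within 0.1 of 1, and ChIP central enrichment within 15% of the planted
factor. Exact assertions (pile-up extraction, rescaling, RPGC, round
trips) are compared bit-for-bit against independent brute-force oracles.

## Known limitations

* Selection operates on spectral counts only; no probabilistic scoring
  (SAINT/CompPASS-style) and no peptide-level FDR control.
* Interval inputs must share the chromosome naming of the tracks and
  matrices; no alias resolution is attempted.
* The contact-matrix container is dense; chromosomes beyond ~50 Mb at 1 kb
  bins would need a sparse backend.
* The shifted-control scheme preserves separation but not local coverage
  structure; on strongly banded real matrices more controls than the
  default 10 may be needed for a stable background.
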