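---
title: "Marker-based cultivar analysis with msapclade: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based cultivar analysis with msapclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapclade)
```

## The problem

Closely related cultivated plants — sports, somatic variants, horticultural
selections — often cannot be told apart by sequence markers alone, and the
conspicuous traits used to classify them (pigmentation, organ size) are
exactly the traits most prone to parallel selection. Two dominant
fingerprinting systems remain the workhorses at this taxonomic depth:

* **AFLP** produces hundreds of anonymous presence/absence bands per
  primer-pair combination, scoring genome-wide sequence variation.
* **MSAP** is the methylation-sensitive variant: every CCGG locus is
  scored twice, once after an EcoRI/HpaII digest and once after
  EcoRI/MspI. The isoschizomers HpaII and MspI cut the same site but are
  blocked by different cytosine-methylation states, so the joint band
  pattern reads out the methylation status of each locus.

`msapclade` implements the full downstream pipeline for such panels:
matrix I/O and filtering, MSAP methylation typing and indices, Nei–Li
distance / neighbor-joining clustering with locus bootstrap, Fitch
parsimony mapping of morphological characters on the resulting tree, and
flow-cytometry ploidy and genome-size estimation. A seeded synthetic-data
generator emulates a 14-sample two-clade reference panel so the whole
pipeline is testable end to end.

## MSAP methylation typing

The joint digest pattern of a locus maps to the four canonical types:
present in both digests → **type I** (non-methylated); only in
EcoRI/MspI → **type II** (fully methylated internal cytosines); only in
EcoRI/HpaII → **type III** (hemimethylated); in neither → **type IV**
(fully methylated on both strands). `classify_site()` is total on
$\{0,1\}^2$; a missing digest state yields `NA` and the site is skipped.

```{r}
classify_site(c(1, 0, 1, 0), c(1, 1, 0, 0))
```

Two conventions in the per-sample profile deserve comment:

* **The panel.** Counts are taken over the union of loci amplified (in
  either digest) in at least one sample, so every sample's four type
  counts sum to the same panel size, and "absent in both digests" is
  scored type IV only where the fragment exists somewhere in the panel.
  A locus absent from every sample is indistinguishable from a locus
  that does not exist — a structural limitation of dominant markers.
* **Methylation-sensitive type I.** A sample's type-I locus enters the
  overall methylation index only if the locus is methylation-polymorphic,
  i.e. non-type-I in at least one other sample. This predicate is
  pluggable (`ms_predicate` argument) because intensity-based variants of
  the rule exist in the literature and cannot be expressed on binary
  matrices.

The indices are

$$\mathrm{MSAP\%} = 100\,\frac{\mathrm{I_{ms}} + \mathrm{II} +
\mathrm{III} + \mathrm{IV}}{\mathrm{panel}},\qquad
\mathrm{full\%} = 100\,\frac{\mathrm{II} + \mathrm{IV}}{\mathrm{panel}}.$$

The fully-methylated index counts types II + IV by default: both classes
have internal cytosines methylated on both strands, and the published
per-cultivar tables this package ships as reference data are consistent
with II + IV, not with a IV-only numerator. The IV-only convention is
retained as `fully_methylated = "IV"`. Reported percentages are rounded
half-up to two decimals (`round_half_up()`), matching conventional table
rendering rather than R's round-half-even.

```{r}
methylation_indices(101, 210, 155, 90, total = 668)
```

## Distances, trees and supports

For dominant markers a shared absence carries no signal, so similarity is
measured on band sharing only: with $a$ bands present in both samples and
$b, c$ private to each, the Nei–Li distance is $D = 1 - 2a/(2a+b+c)$ —
the complement of the Dice coefficient, the standard form for AFLP data.
Loci missing in either sample are excluded pairwise; an all-absent
comparison is defined as distance 0.

`neighbor_joining()` is the standard Saitou–Nei agglomeration and is
exact on additive matrices. Two numerical choices are pinned down because
they affect reproducibility:

* **Ties** in the $Q$ criterion are broken toward the lowest active-pair
  index, making the topology deterministic on degenerate inputs.
* **Negative branch estimates** (which NJ can produce on non-additive
  data) are clamped to zero with the deficit transferred to the sister
  branch, preserving the joined pair's path length; phylograms then carry
  only non-negative lengths.

Bootstrap supports resample loci (columns) with replacement to the
original locus count, rebuild the tree, and report the percentage of
replicates containing each internal bipartition of the full-data tree —
supports annotate the one estimated tree, not a consensus. The replicate
count is a free parameter; the default of 1000 gives a Monte-Carlo
standard error below 1.6 points on any support value, adequate for a
desk-scale analysis (published analyses of this kind cite anywhere from
10,000 to 50,000 replicates). Rooting is by outgroup
(`root_with_outgroup()`); with a single outgroup taxon, ingroup monophyly
is carried by the outgroup's pendant edge and has no separate support
value — supports are meaningful for internal splits such as the clade
partition itself.

```{r}
p <- simulate_marker_panel(panel_config(), seed = 42)
fm <- filter_monomorphic(p$aflp)
bt <- bootstrap_supports(fm, n_reps = 200, seed = 7)
bipartition_support(bt, p$truth$clade_a)
```

## Character mapping

`fitch_steps()` counts the minimum number of unordered state changes a
binary character needs on a fixed tree. Internally the count uses the
multifurcation-safe generalization of the Fitch set rule (keep the states
contained in the maximal number of child sets; add children-minus-max
steps), which reduces to the classic intersection/union rule on binary
trees. Missing states are wildcards and never force a change. When
several optimal internal labelings exist, one is reported
deterministically — the down-pass preference is state 0 — and the result
is flagged `ambiguous`.

Classification against an outgroup-defined ancestral state follows the
usual reading: 0 steps → plesiomorphic; 1 step with the derived state on
one ingroup leaf → autapomorphy; 1 step on two or more leaves (then
necessarily a clade) → synapomorphy; more than 1 step → homoplastic.
"Paraphyletic" patterns (a derived state scattered over a non-monophyletic
set) necessarily take more than one step and are reported under the
homoplastic label; a finer operational distinction is not defined for
binary characters on a fixed tree.

## Flow cytometry

Peak finding deliberately avoids a parametric fit: the histogram is
smoothed with a short moving average (default 5 channels), local maxima
are ranked by height, and modes within 20% of an accepted mode are
suppressed. Each peak is then summarized by the count-weighted mean
channel and CV inside a ±20% window around the mode. For the
well-separated, roughly Gaussian peaks of a plant nuclei prep this is
unbiased to well below channel resolution; it will not deconvolve
overlapping peaks (the simulator warns when centers sit closer than four
combined SDs).

The scale is tied to absolute DNA amounts by the internal standard:
2C = (sample peak / standard peak) × standard 2C. The default standard
value, 9.09 pg, is the literature 2C of *Pisum sativum* 'Ctirad', the
most common internal standard in this size range; it is a configuration
input because instrument-matched calibrations vary. Genome size uses
1 pg = 978 Mbp on the 1C amount, rounded half-up to an integer. Ploidy
scales 2C against a diploid reference (for a uniform panel, its median)
and flags calls farther than `rel_tol` (default 0.1) from an integer as
inconclusive rather than failing: a borderline flag on a panel extreme is
informative, not an error.

## The synthetic panel: what it emulates, and what it does not

The generator's defaults describe a 14-sample ornamental panel split
2 + 12 plus one divergent outgroup: 549 AFLP loci with 53.2%
polymorphic, and 667 MSAP loci structured as 116/84/77 type-I/II/III loci
uniform across the panel, 39/20/21 loci private to the small clade,
51/22/25 private to the large one, and the remaining 212 loci drawn
independently per sample from per-clade type proportions calibrated so
that per-sample type counts land in the published ranges
(200–221 / 181–216 / 144–164 / 84–134 out of ~667). AFLP diagnostic
loci default to 29 + 38, putting the clade-associated share of
polymorphic variation near the reported ~23%. Within-clade polymorphic
loci are independent Bernoulli draws (presence 0.5); the outgroup draws
independent states everywhere it is not fixed (presence 0.35 at variable
AFLP loci, uniform over the four MSAP types).

Two generator details matter for testing:

* Free loci are redrawn if they happen to mimic a planted class (uniform
  type across the ingroup, or a type fixed in one clade and absent from
  the other), so planted shared/private counts are **exact**, not merely
  expected — `clade_fragment_tally()` can be checked against them with
  `expect_identical`.
* MSAP cells are generated type-first and emitted through the inverse of
  `classify_site()`, so typing round-trips by construction.

What the panel does **not** emulate: linkage between loci, fragment-size
homoplasy (co-migrating non-homologous bands), scoring error, gel-to-gel
intensity variation, or any within-clade phylogenetic substructure —
within-clade variation is exchangeable noise. Tests passing on synthetic
panels therefore validate the estimators' arithmetic and their behavior
under the assumed independence structure, not robustness to the artifacts
of real gels. The published per-cultivar summary tables shipped under
`inst/extdata/` provide the complementary check that the index formulas
reproduce real printed values; the raw gel matrices behind them were
never deposited, so tree lengths and support values from the original
study are not reproducible and are covered instead by the additive-matrix
and planted-truth properties above.

For characters, the planted classes are synapomorphies (derived state on
one proper ingroup clade, 1 step), autapomorphies (one leaf, 1 step) and
two-leaf homoplasies (two non-sister leaves, 2 steps); planted step
totals are recovered exactly by `total_steps()`. The histogram simulator
draws `n_events` Gaussian events **per peak** and bins them onto an
integer channel axis (standard peak at channel 300 of 1024 by default);
with CV 3% a peak spans enough channels that binning bias is negligible
and the recovered 2C lands within $3\,\mathrm{CV}/\sqrt{n}$ of truth.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and is a pure function
of (configuration, seed). The shipped tests run the default 549/667-locus
panel, 1000 bootstrap replicates on 15 taxa, brute-force parsimony
oracles up to 8 leaves (2^6 internal labelings), and 10,000-event
histograms — a few seconds in total; these sizes were chosen as the
smallest at which the binomial and Monte-Carlo tolerances quoted above
are comfortably resolvable.

## Known limitations

* Dominant markers cannot distinguish a fully methylated locus (type IV)
  from a deleted or primer-mutated site; type-IV counts are upper bounds.
* The methylation-sensitivity predicate for type I is a panel-relative
  definition; singleton panels score `typeI_ms = 0` by construction.
* NJ supports are attached to the full-data topology; splits absent from
  it are not reported even if frequent among replicates.
* No statistical test is attached to genome-size differences; replicate
  summaries are descriptive (mean ± n−1 SD).
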