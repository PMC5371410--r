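---
title: "Detecting endoribonuclease cleavage sites and measuring transcript decay"
author: "cleaverate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting endoribonuclease cleavage sites and measuring transcript decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleaverate)
```

## The two questions the package answers

RNase III is a double-strand-specific endoribonuclease. Where it cleaves a
transcript in vivo, steady-state coverage in a wild-type (WT) strain is
locally depleted, while a strain deleted for the enzyme (the *rnc* mutant)
retains full coverage. Comparing per-base RNA-seq coverage between the two
strains therefore reveals cleavage sites as spikes in the per-base ratio

$$r(b) = \frac{\text{mutant coverage at } b}{\text{WT coverage at } b},$$

and a rifampin chase — arresting transcription and sampling RNA over a
20-minute time course — turns the subsequent coverage decline into a direct
measurement of each transcript's decay rate. `cleaverate` implements both
analyses over plain coverage tracks (bedGraph or fixed-step wiggle), plus a
seeded synthetic-data generator so that every stage can be validated
end-to-end against known ground truth.

## Cleavage-site detection

**Ratio with pseudocount.** Ratios are computed on *raw* time-zero counts.
Any zero count, in numerator or denominator, is replaced by a pseudocount
of 0.01 reads so the ratio is always defined; a base covered in the mutant
but empty in the WT (the signature of an efficient site) then yields a very
large finite ratio. Both quantities are kept raw because the calling
threshold was calibrated on raw read ratios; depth differences between
libraries at time zero are assumed small compared to the threshold.

**Dual-replicate threshold.** A base is a candidate only if its ratio
reaches the threshold (default 30, inclusive) against *both* WT replicates.
The default is anchored to the weakest ratio observed at a well-established
processing site (near *tufB*), i.e. it is the most permissive value that
still recovers the known-site catalogue.

**Minimum spacing.** Coverage troughs are wide, so thresholding alone
yields runs of candidate bases — shoulders of one peak. Candidates are
ranked by descending `min(ratio_A, ratio_B)` (ties broken toward the
smaller coordinate, for determinism) and accepted greedily if they lie at
least 400 bp (`|p1 - p2| >= min_spacing`) from every accepted site. The
strongest base of each peak therefore represents it. This greedy rule is
deliberately *not* a maximum-cardinality selection: an optimal packing
would sometimes shift representative positions off-peak, or report two
shoulder positions where one site is the right answer. On random candidate
configurations the two selections can genuinely differ, which is expected
behavior, not an approximation error we attempt to close.

**Annotation.** A called position inside one or more gene intervals is
labeled with those gene names (all of them, sorted, when genes overlap);
otherwise it is labeled `intergenic(L-R)` from the nearest flanking genes,
with `.` at replicon ends. Reports carry full-precision ratios plus an
integer view rounded half away from zero (so a ratio of 899.5 displays as
900), matching the convention of published site tables.

## Decay kinetics

**Model.** Abundance after transcription arrest is modeled as
$A(t) = A(0)\,10^{-kt}$. For each decay region (an explicit interval; the
package never guesses a window) and each strain/replicate series, the mean
normalized per-base coverage over the region is the abundance, and ordinary
least squares of $y = \log_{10}(A(t)/A(0))$ against $t$ estimates the slope
$-k$. The intercept is fitted freely by default — the gate below uses the
$R^2$ of a regression *line*, and an intercept forced through zero is
available as an option. Time points with zero abundance are dropped (their
log is undefined); fewer than three usable points marks the fit
indeterminate.

**Gates.** A half-life is reported only when (i) time-zero coverage exceeds
1 read and (ii) $R^2 \ge 0.7$. A perfectly flat series has zero response
variance, making $R^2$ a 0/0; it is treated as failing the gate rather than
as undefined arithmetic. The half-life is

$$t_{1/2} = \frac{-\log_{10}(0.5)}{k} = \frac{\log_{10} 2}{k},$$

defined only for $k > 0$; a flat or growing signal has none. (The textbook
shorthand $t_{1/2} = \log(0.5)/k$ gives a negative time under this model's
sign convention; the package uses the sign-correct form. The logarithm base
is 10 throughout, matching the model.)

**Time labels.** Times are minutes relative to the sample called 0, which
is itself drawn 3.5 min after rifampin addition to allow drug uptake. The
offset is recorded as sample-set metadata and never enters the regression:
decay rates are invariant to a shift of the time origin, and the labels
match how chase experiments are reported.

**Normalization.** Library depth drifts across a chase. Factors are
computed per (strain, replicate) series as $S(t)/S(0)$, where $S$ is the
mean per-base coverage over the union of stable-gene bases (in E. coli:
ssrA, ssrS, rnpB — transcripts that do not decay on this time scale).
The union mean counts bases under overlapping intervals once and is robust
to unequal gene lengths; a mean-of-per-gene-means variant is available as
`method = "gene_mean"` and recorded in the factor table. Tracks are
*divided* by their factor (depth acts multiplicatively), the time-zero
factor is exactly 1, and each series anchors to its own time zero. WT
replicates are fitted separately; the contrast then uses the mean of the
replicate half-lives that passed both gates.

**Contrast classification.** For a region with WT and mutant half-lives
$h_W$ and $h_M$, cleavage *destabilized* the transcript when
$h_M / h_W \ge$ `fold_threshold` (cleavage shortened the WT half-life, the
*pnp*-type pattern), *stabilized* it when $h_W / h_M \ge$ the threshold
(the *pflB*/*ahpC*-type pattern), and otherwise left it unchanged. The
default fold threshold of 1.25 is a package choice: reported contrasts in
this literature are eyeballed differences of roughly "~3 vs ~5 min", and
1.25 separates those while absorbing replicate scatter. Whenever either
half-life is absent (a gate failed), the contrast is `indeterminate` — a
deliberately conservative rule, since very fast decay can empty the WT
signal before the first sample.

## Coordinate and format conventions

All internal coordinates are 1-based inclusive, the convention in which
site positions are reported; conversion happens only at file boundaries
(bedGraph and BED are 0-based half-open, wiggle and GFF3 1-based
inclusive). Tracks are unstranded — the assay this pipeline targets did
not retain strand — so GFF3 strand fields are read but ignored with a
notice. Overlapping bedGraph intervals are a hard error rather than
last-writer-wins: a silent overwrite would corrupt counts. Output bedGraph
is deterministic (sorted, runs of equal value merged, zero runs omitted)
and values are printed as decimal text that round-trips exactly, so
write-then-read is the identity and file checksums are reproducible.

## What the synthetic generator emulates

`synthetic_study_spec()` builds a fixed 200-kb design: 30 transcripts of
2 kb; WT replicates A and B and one mutant replicate sampled at 0, 2.5, 5,
7.5, 10 and 20 min, plus a partial WT replicate C at 0, 2.5 and 7.5 min
(21 tracks); three stable genes; 10 strong planted cleavage sites
(WT coverage divided by 100–1000 over a 150-bp interval at the site —
depletion is modeled as a contiguous trough, not a point spike, mirroring
real coverage profiles) and 5 weak sites (depletion 5, 8, 12, 16, 20) as
sub-threshold negative controls; transcript pairs destabilized by cleavage
(e.g. WT 3 min vs mutant 5 min), stabilized by it (e.g. WT 14 min vs
mutant 6 min), and unchanged; and per-library depth factors drifting over
0.7–1.3 across the chase for normalization to undo. Decay is
half-life-parameterized, $0.5^{t/t_{1/2}}$, which is identical to
$10^{-kt}$ with $k = \log_{10}(2)/t_{1/2}$.

Choices a real dataset forced:

* **Noise.** Per-base counts get multiplicative lognormal noise with
  sd 0.1 on the natural-log scale (the standard lognormal
  parameterization), applied independently per base; a Poisson mode gives
  integer counts. Lognormal is the default because coverage dispersion in
  bulk RNA-seq is super-Poissonian and the chase analysis operates on
  continuous normalized values.
* **Time-zero depths are exactly 1.** Site detection runs on raw t0
  counts, so the synthetic conditions model depth-matched time-zero
  libraries; drift at later time points is what normalization corrects.
  With strongly unequal t0 depths the raw-ratio threshold itself would
  need depth correction, which the published procedure does not apply.
* **Boundary behavior of the negative controls.** A weak site at
  depletion 20 sits at two-thirds of the ratio-30 threshold. Under sd-0.1
  noise an isolated base in its 150-bp trough can cross the threshold in
  both replicates in occasional runs, producing a rare false call. That is
  a real property of a negative control placed near the decision boundary,
  and it is left visible rather than engineered away.

What the generator does **not** emulate — so passing tests bound what they
can claim about real data: read-level artifacts (mapping bias, soft
clipping), strand structure, correlated noise along the genome, rRNA
contamination, overlapping transcription units with different rates, and
partial cleavage (depletion is constant over its interval and over time).

## Problem sizes and numerical choices

Validation runs use the full 200-kb, 21-track design for 20 seeds
(detection precision/recall and contrast accuracy), 400 simulated chases
for half-life recovery (half-lives 2–16 min, the six-point grid), and
noise-free grids for exactness checks; the complete suite runs in a couple
of minutes on one core. Exactness claims are literal: noise-free decay is
recovered to relative error below 1e-9 with $R^2 = 1$, the identity
$t_{1/2} \cdot k = \log_{10} 2$ is bit-exact at the tested decay constants,
and post-normalization stable-gene means agree across time points to
relative deviation below 1e-9 (they are equal by construction; only
floating-point summation order intervenes).

## Known limitations

* Half-life point values for real transcripts depend on the genomic window
  chosen for aggregation; the package requires explicit decay regions and
  makes no attempt to reproduce published per-transcript values without
  the underlying raw data.
* The greedy representative-site rule reports one position per peak; sites
  closer than the spacing cannot be resolved, and multi-site regions
  collapse to their strongest base.
* Ratios on raw counts inherit any time-zero depth imbalance between
  strains; grossly unequal t0 libraries would shift all ratios
  multiplicatively.
* Replicate half-lives are combined by a simple mean over gate-passing
  fits; no weighting by fit precision is attempted.
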