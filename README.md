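# cleaverate

Cleavage-site detection and transcript decay kinetics for bacterial
RNA-seq coverage data.

## What problem this solves

RNase III is a double-strand-specific endoribonuclease whose in-vivo
cleavage sites leave a characteristic fingerprint in RNA-seq data: at a
cleaved position, steady-state coverage in the wild type (WT) collapses,
while a strain deleted for the enzyme (an *rnc* mutant) keeps full
coverage. `cleaverate` is for researchers who have per-base coverage
tracks from such a paired WT/mutant experiment — optionally with a
rifampin-chase time course on top — and want to

1. **call cleavage sites** from the per-base ratio
   `r(b) = mutant(b) / WT(b)`, computed on raw time-zero counts with a
   0.01-read pseudocount for empty bases, requiring `r >= 30` in **both**
   WT replicates, and collapsing peak shoulders with a greedy 400-bp
   minimum-spacing rule (each peak is represented by its strongest base);
2. **measure transcript decay** after transcription arrest, by fitting
   `A(t) = A(0) * 10^(-k t)` via least squares on
   `log10(A(t)/A(0))` per region and strain/replicate, reporting a
   half-life `t1/2 = log10(2) / k` only when time-zero coverage exceeds
   1 read and `R^2 >= 0.7`, after stable-gene normalization (the ssrA /
   ssrS / rnpB anchor set); and
3. **classify each region's WT-vs-mutant contrast** as destabilized by
   cleavage (mutant half-life longer — the *pnp*-type pattern),
   stabilized by it (WT longer — the *pflB*/*ahpC*-type pattern), or
   unchanged.

Everything runs from plain text formats (bedGraph / fixed-step wiggle
tracks, BED / GFF3 intervals), and a seeded synthetic generator produces
complete WT/mutant time-course datasets with planted sites and known
half-lives so the whole pipeline is testable without any external data.

## Worked example

Simulate a study-scale dataset (200-kb replicon, 2 full WT replicates +
1 partial + mutant over 0–20 min, 10 strong planted sites, 5 sub-threshold
decoys), detect sites, and fit decay:

```r
library(cleaverate)

d <- simulate_dataset(synthetic_study_spec(), seed = 1)
calls <- detect_cleavage_sites(d$samples, genes = d$genes)
print(calls)
#> <cleavage_calls> 10 sites on chr (threshold 30, spacing 400 bp)
#>    position ratio_rep_a ratio_rep_b min_ratio wt_reads_a wt_reads_b
#> 1     56591    1281.885    1290.275  1281.885   0.213047   0.211662
#> 2     26617     644.144     638.357   638.357   0.191976   0.193716
#> 3     44612     536.348     542.745   536.348   0.133402   0.131830
#> ...
```

All 10 planted strong sites are recovered (each call lies inside one
planted depletion interval; the five weak decoys at depletion 5–20 stay
below the dual-replicate ratio-30 threshold), each annotated with its host
transcript and both replicate ratios plus the raw counts they came from.

A single decay fit is an S3 model object with the usual methods
(`print`, `summary`, `coef`, `predict`, `plot`, `residuals`, `simulate`):

```r
fit <- fit_decay(
  time = c(0, 2.5, 5, 7.5, 10, 20),
  abundance = c(118, 73, 44, 27, 17, 3.9)
)
print(fit)
#> <decay_fit> NA/NA
#>   k = 0.0739997 /min, R^2 = 0.9931, A(0) = 118 (n = 6)
#>   gates: coverage pass, R^2 pass
#>   half-life: 4.068 min
```

The decay constant is in log10 units per minute; the half-life
`log10(2)/k = 4.07 min` is reported because both gates passed. The whole
normalize–fit–contrast stage in one call:

```r
res <- analyze_decay(d$samples, d$stable, d$regions)
head(res$contrasts[res$contrasts$classification != "no_change", ], 3)
#>   region wt_half_life mutant_half_life           classification
#> 1   tx01     3.000148         4.992403 destabilized_by_cleavage
#> 2   tx02     2.001013         3.993666 destabilized_by_cleavage
#> 3   tx03     4.000403         7.988673 destabilized_by_cleavage
```

Planted truth for `tx01` was WT 3 min vs mutant 5 min; the recovered
half-lives are within a fraction of a percent, and the contrast is
classified correctly (fold threshold 1.25).

The same stages run from the shell over manifest + track files:

```sh
Rscript inst/scripts/rnc-pipeline.R all --out run1 --seed 1
```

which writes `sites.tsv` / `sites.bed`, `factors.tsv`, `decay_fits.tsv`,
`contrasts.tsv` and per-stage metadata JSON; reruns with identical inputs
are byte-identical.

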