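---
title: "divscan: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{divscan: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

`divscan` is a windowed genome-scan pipeline for multi-population
all-sites variant data: diversity (π), absolute divergence (d~XY~),
Hudson's F~ST~ and Tajima's D per window; SD-threshold classification of
windows into four evolutionary scenarios; a degenerate-site dN/dS against
an outgroup; and the concordance of F~ST~ and dN/dS outliers. This
vignette records the statistical model behind each stage, the package's
conventions where the field's verbal definitions are ambiguous, and the
reasoning behind the simulator that the test suite uses as ground truth.

## Estimators

### Counting, not averaging

All window statistics are **ratios of sums** of per-site counts, never
means of per-site ratios. For a window *W* and a population with
per-site allele counts c₀, c₁ among n genotyped haplotypes,

$$\pi_W = \frac{\sum_{s \in W} c_0(s)\,c_1(s)}{\sum_{s \in W} \binom{n(s)}{2}},
\qquad
d_{XY,W} = \frac{\sum_{s} c_{A0}c_{B1} + c_{A1}c_{B0}}{\sum_{s} n_A n_B}.$$

Invariant sites contribute zero to the numerators and their full pair
counts to the denominators; that is why they must be present in the VCF
and survive filtering. Per-genotype missingness then only shrinks a
site's contribution rather than biasing the ratio — adding a
fully-missing genotype changes nothing (a property the test suite checks
exactly). Sites with fewer than 2 haplotypes (π, F~ST~) or an empty side
(d~XY~) are skipped; a window whose denominator is zero is **undefined
(`NA`), not zero**, and undefined windows are excluded from all
downstream standardization.

### Hudson's F~ST~

Per site, with ALT frequencies p₁, p₂ and haplotype counts n₁, n₂ ≥ 2:

$$N_s = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad D_s = p_1(1-p_2) + p_2(1-p_1),$$

and the window estimate is ΣN~s~ / ΣD~s~ (the "ratio of averages", which
is much less biased for sparse windows than averaging per-site ratios).
The subtraction terms are the Bhatia-style finite-sample correction;
`fstCorrection = FALSE` gives the uncorrected `(p1 - p2)^2` numerator for
comparison with tools that omit it. Negative window values are
**retained** — truncating at zero would bias the downstream
z-standardization.

### Tajima's D under missingness

The classical variance constants assume one fixed sample size n for the
whole window, so the package uses **complete-case windows**: any site
with a missing genotype in the focal population is excluded, and n stays
the population's full haplotype count. The alternative (per-site n with
re-derived constants) is deliberately out of scope; with the ~3%
per-genotype missingness the pipeline is designed around, complete-case
exclusion costs a modest fraction of sites and keeps the estimator
textbook-exact. `tajimaDFromSummary(n, S, thetaPi)` exposes the bare
formula; the suite pins it to independently computed references
(n = 4 with one singleton ⇒ −0.6124; one balanced site ⇒ +1.6330).

## Filters

`filterConfig()` defaults to per-genotype quality ≥ 20 and depth in
[15, 50], and per-site missingness ≤ 10% with at most two alleles.
Conventions the verbal rules leave open, fixed here:

* **Bounds are inclusive for retention** (depth 15 and 50, quality 20 are
  kept; depth 14/51 and quality 19 are masked), matching the semantics of
  the common VCF filtering tools.
* **The missingness denominator is all samples** in the table (ingroup +
  outgroup), because the filters are meant to reproduce joint filtering
  of one combined VCF; `missingDenominator = "ingroup"` is available.
* The biallelic rule never removes invariant sites.
* Filtering only masks genotypes or drops sites; it is idempotent.

## Windows

Target regions (BED-like, 0-based half-open) are tiled into consecutive
`windowBp` windows anchored at the region start; reported coordinates are
1-based inclusive, so window *w* covers ((w−1)·L, w·L]. The default is
non-overlapping 10 kb tiles; a smaller `step` yields sliding windows (a
site then legitimately feeds several windows). Sites outside every region
fall back to a chromosome-level tiling and are flagged, never silently
dropped. Windows with zero usable sites stay in the output with
`n_sites = 0` and undefined statistics.

## Scenario classification

For each pairwise comparison the three inputs are window F~ST~, window
d~XY~, and **π averaged between the two populations**. Each is
z-standardized over the comparison's defined windows using the
**population (divide-by-N) standard deviation** — the convention had to
be fixed somewhere; with thousands of windows the difference from N−1 is
negligible, and the choice is stated so results are reproducible.

The four rules are evaluated in fixed order, first match wins:

| order | scenario | F~ST~ | d~XY~ | π |
|---|---|---|---|---|
| 1 | divergence with gene flow | z > 2 | z > 3 | z < +3 |
| 2 | allopatric selection | z > 2 | z < +3 | z < −1 |
| 3 | recurrent selection | z > 1 | z < −1 | z < −1 |
| 4 | balancing selection | z < +3 | z > 3 | z > 3 |

Two subtleties:

* **"< k SD" is ambiguous.** The default (`semantics = "two-sided"`)
  reads the d~XY~/π conditions against explicit upper (+3 SD) and lower
  (−1 SD) boundaries: "< 3 SD" means z < +3 (below the upper boundary)
  and "< 1 SD" means z < −1 (below the lower boundary). The
  all-above-the-mean reading (`semantics = "upper"`, every "< k" as
  z < +k) is available behind the flag; both are tested.
* **Precedence matters**: a window with z~FST~ > 2 and both z~dXY~ and
  z~π~ < −1 satisfies the allopatric and recurrent rules simultaneously;
  fixed ordering prevents double counting, and the per-pair summary
  therefore has mutually exclusive categories.

F~ST~ outlier windows use a strict z > 3 cut and are mapped to genic
regions by any interval overlap. The d~XY~~π relationship is an OLS slope
plus Spearman ρ over windows where both are defined; fewer than three
windows, or zero variance, yields `NA` rather than a number.

## Degenerate-site dN/dS

The approximation is taken literally: within each codon (region start +
frame, trailing partial codon dropped) positions 1–2 are non-synonymous
and position 3 synonymous, with no genetic-code lookup. This knowingly
misclassifies some real codons; it is the approximation the scan is
defined with, and it makes the arithmetic exactly checkable
(30 codons, 3 nonsyn + 2 syn fixed ⇒ (3/60)/(2/30) = 0.75).

Per gene × population, a site is *covered* if it survived upstream
filters, at most 50% of the population's genotypes are missing
(inclusive), and at least one outgroup allele was observed. A *fixed
difference* is declared when the allele set observed in the population is
disjoint from the outgroup's ("disjoint" rule; the "strict" variant also
requires both sides monomorphic). Genes need ≥ 1 fixed synonymous and
≥ 1 fixed non-synonymous site; the gate removes genes where the ratio
would be 0/0 or divide by zero, at the cost of a mild upward selection
bias that the neutral calibration quantifies. Outliers are ratios
strictly above mean + 3 SD within a population; the divergent-selection
set is the intersection of the union of F~ST~-outlier genes (over pairs)
with the union of dN/dS-outlier genes (over populations).

## The simulator

The generator is deliberately a *frequency-based* model with closed-form
expectations, not a coalescent: every calibration the tests assert can be
derived by hand.

* **Ancestral polymorphism.** Each site is polymorphic with probability
  θ·ln(1/ε)/(1−ε)², with frequency density ∝ 1/p on (ε, 1)
  (ε = `freqFloor` = 0.005). This is the stationary neutral frequency
  spectrum, so E[heterozygosity] = θ and a binomial haplotype sample has
  E[ξ~k~] ∝ 1/k — which is what makes the simulator's equilibrium
  Tajima's D sit near zero instead of being an artifact of the frequency
  law chosen.
* **Drift.** Population *i* draws Balding–Nichols Beta(p(1/F−1),
  (1−p)(1/F−1)) frequencies. Drift shrinks within-population diversity to
  θ(1−F) but leaves cross-population expectations untouched, so
  **E[d~XY~] = θ + d~i~ + d~j~ exactly**, where d~i~ is the expected
  per-site substitution load of branch *i*.
* **Divergence** is parameterized **per population branch**
  (`branchDivergence`), with pair divergence d~i~ + d~j~. A per-pair
  matrix cannot in general be consistent for > 2 populations; the branch
  parameterization is, and reduces to the usual 2μT for any pair.
* **Migration** shares a branch's substitutions with the partner
  population with probability `migrationShare`, deflating that pair's net
  divergence; **expansion** adds private singletons at a per-site rate,
  producing the excess of rare alleles (negative Tajima's D) expected
  after post-bottleneck growth. Both are off by default: the neutral
  equilibrium baseline is what the closed-form checks need, and the
  treatments are opt-in experimental conditions.
* **Per-region diversity heterogeneity** (`thetaShape`): region θ is
  multiplied by a Gamma(shape, shape) variable (mean 1, CV = 1/√shape).
  Targeted-capture regions genuinely differ in diversity; this is also
  what makes the window-level d~XY~~π regression informative (slope near
  1, strongly positive ρ) rather than pure noise.
* **Depth/quality**: negative-binomial depth (mean 30, size 30) and a
  two-point quality distribution exist solely so the filter stage has
  something to act on; no sequencing-error model is implied.

Defaults mirror the targeted-capture study design the package is built
around: five populations of 40/36/32/28/20 samples plus two outgroup
samples, θ = 0.003, branch divergences giving pairwise d~XY~ of
0.0034–0.0041, and 4,184 regions (4,051 genic + 133 non-genic) of ~600
usable bp under 10 kb windows. Tests and the acceptance script use
smaller explicit configurations (their sizes are listed below); the
defaults describe the emulated design, not the test workload.

### Scenario injections

`injectScenario()` edits a window's frequency matrix so the *expected*
statistics land in the target classifier region; the strengths are
derived from Poisson approximations of the per-window SDs
(sd(d~XY~) ≈ √(E[d~XY~]/L), sd(π) ≈ √(θ/L)):

* *allopatric*: remove within-pair polymorphism (π → 0, z~π~ ≈
  −θ/sd(π) « −1), place fixed differences at the neutral mean-d~XY~ rate
  (z~dXY~ ≈ 0 < +3); window F~ST~ becomes ≈ 1 (z » 2).
* *gene flow*: same, but fixed differences at mean + 5·sd(d~XY~) so
  z~dXY~ > 3.
* *recurrent*: thin polymorphism to 25% (π and d~XY~ drop ≈ 1.5–3 SD
  below the mean) and add ⌈0.8·0.25·θL⌉ fixed differences — enough to
  lift the ratio-of-sums F~ST~ about 1.5 SD above the mean without
  crossing the allopatric z > 2 condition.
* *balancing*: add 3θL shared p = 0.5 variants to both populations
  (π and d~XY~ rise ≈ +1.5θ, several SD; F~ST~ is pulled toward 0).

The recurrent target is intentionally the narrowest (its window must
land in 1 < z~FST~ ≤ 2); its recall in the seeded runs is correspondingly
the lowest of the four while still several times the neutral
false-labeling rate, which is the property the acceptance suite asserts.

### Coding injections

`codingInjections` (and the standalone `simulateCodingGene()`) place
exact numbers of population-vs-outgroup fixed differences on synonymous
(codon position 3) and non-synonymous (positions 1–2) sites;
`nFixedTotal` instead places substitutions uniformly over all positions,
the neutral regime whose mean dN/dS is ≈ 1. Note the exact neutral
expectation is slightly above 1 — E[1/n~S~] > 1/E[n~S~] plus the ≥1+≥1
gate — by roughly 3/k for k total substitutions, which is why the
calibration uses k = 60 per gene (bias ≈ 0.05, inside the asserted
[0.9, 1.1] band over 500 genes).

## Problem sizes used by the tests and acceptance script

Chosen to give each assertion comfortable Monte-Carlo margin:

* d~XY~ calibration: 2,000 windows × 1,000 bp, 8+8 diploids
  (relative SE of the mean ≈ 1%, asserted within 5%).
* Null F~ST~: 800 windows; split-half identity: 500 windows, 10 diploids.
* Injection recall: 300 windows × 5,000 bp, 20 injected (5 per
  scenario), 10+10 diploids.
* d~XY~~π relationship: 300 windows × 10,000 bp, `thetaShape = 4`.
* Neutral dN/dS: 500 genes × 100 codons, 60 substitutions each.
* Normal-tail outliers: 10,000 windows (expected strict z > 3 count
  ≈ 13.5).

## What passing tests do and do not show

The simulator has no linkage, recombination, sequencing error, indels,
multi-allelic variation beyond what the reader flags, or realistic
haplotype structure; genotypes are Hardy–Weinberg draws from population
frequencies. Passing tests therefore demonstrate that the estimators,
thresholds and bookkeeping are correct and calibrated under the stated
model — not that the scan's biological interpretation is robust to LD,
reference bias or demographic misspecification in real data. The
degenerate-site dN/dS is an approximation by construction, and the
SD-threshold scenario rules are descriptive cutoffs, not hypothesis
tests; both should be read accordingly on real datasets.
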