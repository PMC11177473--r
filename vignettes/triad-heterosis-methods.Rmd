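---
title: "Methods: triad expression patterns and biomass heterosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triad expression patterns and biomass heterosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadheterosis)
```

## The problem

Heterosis (hybrid vigor) is the superiority of an F1 hybrid over its
parents. For a quantitative trait it is summarized by mid-parent heterosis,

$$\mathrm{MPH}(\%) = \frac{F_1 - MP}{MP} \times 100,$$

where $F_1$ is the hybrid trait value and $MP$ the mean of the two parental
values. At the transcriptome level, comparing an F1 against both parents
(the *triad* contrasts F1 vs parent1, F1 vs parent2, parent1 vs parent2)
lets every differentially expressed gene (DEG) be assigned an expression
mode: *additive* (F1 at the mid-parent level), *expression-level dominant*
(F1 indistinguishable from one parent), or *overdominant/transgressive*
(F1 above or below both parents). The balance between these modes is the
standard transcriptomic readout of which genetic model of heterosis is in
play — in tobacco leaf biomass triads, overdominance dominates, with
up-regulated overdominant photosynthesis genes and down-regulated
overdominant TCA-cycle (respiration) genes.

This package implements that analysis end to end: a seeded synthetic-data
generator with known pattern labels, negative-binomial differential
expression for the three contrasts, the 12-pattern classifier,
hypergeometric term enrichment, trait-level MPH time courses with Duncan
letter groupings, and qPCR concordance.

## Differential expression

The DE stage is intentionally minimal and self-contained.

**Normalization.** Median-of-ratios size factors: for each sample, the
median over genes detected in every sample of the ratio of the gene's count
to its across-sample geometric mean, rescaled to geometric mean one. If no
gene is detected everywhere, total-count factors are used with a warning.

**Dispersion.** A per-gene method-of-moments estimate of the NB dispersion
$\phi$ in $\mathrm{Var} = \mu + \phi\mu^2$, pooling within-genotype moments:
$\hat\phi = \sum_g (s_g^2 - \bar y_g) / \sum_g \bar y_g^2$ over the genotype
groups, floored at $10^{-8}$. Genes whose variance does not exceed their
mean sit on the floor. No mean–dispersion trend or shrinkage is fitted; a
single global dispersion is also what the generator simulates, which keeps
the calibration of the test directly checkable.

**Test.** A Wald statistic on the log scale. With $\bar y_g$ the mean of
normalized counts in group $g$ of size $n_g$ and size factors $s_j$,

$$\widehat{\mathrm{Var}}(\bar y_g) = \frac{1}{n_g^2}\sum_{j \in g}
  \left(\frac{\bar y_g}{s_j} + \hat\phi\,\bar y_g^2\right), \qquad
  z = \frac{\log \bar y_B - \log \bar y_A}
           {\sqrt{\sum_g \widehat{\mathrm{Var}}(\bar y_g)/\bar y_g^2}}.$$

Because the plug-in moment estimates make a normal reference
anticonservative at three replicates, $z$ is referred to a $t$ distribution
with the pooled residual degrees of freedom (samples minus genotype groups
over the whole design; 6 for a 3×3 triad). Under the null at $\phi = 0.05$,
$n = 3$, the empirical type-I rate sits near 0.04; the normal reference
gives ~0.085.

**Screening.** A gene is a DEG when $p < 0.05$ (strict, raw p-value by
default — `use_adjusted = TRUE` switches to the BH-adjusted value) and
$|\log_2 FC| \ge 2$ (inclusive). The displayed fold change uses a
pseudocount of 1 on both group means; the test itself uses the raw means.
Before testing, genes are restricted to those detected (nonzero mean) in
all three genotypes, so the tested universe is the three-genotype
intersection — this is also the enrichment background.

Zero means are floored at half a normalized count in the variance formula
so the statistic stays finite; genes at zero in both groups are reported as
$p = 1$, $\log_2 FC = 0$.

## The 12-pattern classifier

Each DEG (union of the three contrasts' DEG sets by default) is classified
from its significance flags and fold-change signs:

| category | codes | rule |
|---|---|---|
| up-overdominant | P10–P12 | F1 significantly above both parents |
| down-overdominant | P7–P9 | F1 significantly below both parents |
| dominant | P3–P6 | parents differ; F1 indistinguishable from exactly one |
| additive | P1–P2 | parents differ; F1 differs from both and lies strictly between |
| unclassified | — | anything else |

Sub-codes encode the parental configuration: within overdominance, the
parental contrast (parent1 lower / equal / higher gives P10/P11/P12 and
P7/P8/P9); within dominance, which parent is matched and whether it is the
high or low parent (P3/P4/P5/P6); within additivity, which parent is higher
(P1/P2). "Indistinguishable" always means the corresponding contrast is not
significant at the screening thresholds — the classifier reuses the DE
machinery rather than a tolerance on means. The sub-code orientation is
this package's convention (the category groupings are the established
ones); it is pinned down by a parent-swap symmetry property
(P1↔P2, P3↔P4, P5↔P6, P7↔P9, P10↔P12, P8/P11 fixed) and by an exhaustive
equivalence test against a scalar rule-table oracle over every combination
of calls and mean orderings. When calls contradict the observed means
(possible only on degenerate inputs), overdominance takes precedence over
additivity.

Category percentages are reported over classified genes (P1–P12), so the
category shares sum to 100%; the unclassified count is reported separately.

## Synthetic data: what it emulates

`simulate_triad()` draws, per gene, a baseline log2 abundance uniform on
[3, 9], realizes the assigned pattern by placing the three genotype means a
designed `effect_log2fc = 3` apart (dominant hybrids sit exactly on one
parental mean; additive hybrids at the arithmetic mid-parent; overdominant
hybrids at least one effect beyond both parents), and draws replicate
counts NB($\mu$, $\phi = 0.05$) with three replicates per genotype —
matching the triad design the analysis targets. Default pattern proportions
put half the genes in an unchanged background and split the other half
0.13% / 23.18% / 76.69% across additive, dominant and overdominant (the
category balance reported for tobacco biomass triads), with equal sub-code
shares within a category and an equal up/down overdominance split (the
within-category split is not established; it is a config knob). Gene labels
are allocated by largest remainder, so realized label counts match the
proportions exactly up to integer rounding.

One structural consequence worth knowing: an additive gene's mid-parent
expression can never be 4-fold away from the nearer parent (the ratio of
mid-parent to high parent is bounded by 2), so under the $|\log_2 FC| \ge 2$
screen designed additive genes are unrecoverable as additive for any
parental separation — they surface as dominant or unclassified. This is
consistent with the near-zero additive share observed in real triads
screened at the same thresholds, and it costs the recovery tests only the
0.13% additive mass.

The generator does **not** model library-size imbalance by default
(uniform factors; log-normal factors are a config option used in the
normalization tests), nor a mean–dispersion trend, zero inflation, batch
effects, or isoform-level variation. Passing recovery tests therefore
demonstrate correctness of the statistical machinery on its own
assumptions, not robustness to those real-data complications.

`simulate_biomass()` gives the five parents logistic growth curves
(asymptotes 50–75 g dry weight, midpoint 52 days, rate 0.15/day —
plausible field values for the crop), measures at 38, 45, 52, 59 and 66
days after transplanting, and sets each of the six hybrids' means to
$MP \cdot (1 + \mathrm{MPH}/100)$ under a designed schedule: a common mean
path (10, 15, 29.99, 17.09, 22.77%) whose consecutive differences are the
reported trend deltas (+14.99, −12.90, +5.68 points after day 45) plus
constant per-hybrid offsets summing to zero, with Va116×GDH94 at +7.5 so
its day-45 MPH is 22.50%, the largest of the six. Replicates get
multiplicative Gaussian noise with CV 0.05 (the replicate CV is not
reported for the real data; 5% is a typical dry-weight replicate spread).
With zero noise the pipeline inverts the schedule to machine precision;
with noise, the single-experiment MPH estimate has a sampling sd of ~3.5
points (error propagation of three 5%-CV replicates through the ratio), and
a small positive Jensen bias of order $\mathrm{CV}_{MP}^2$ (~0.1 point),
which is why Monte-Carlo averages over seed replicates are used when
checking unbiasedness.

## Duncan letters

Group separation at a timepoint uses Duncan's new multiple range test: a
one-way ANOVA pooled MSE, means sorted descending, and a least significant
range for a stretch of $p$ ordered means
$LSR_p = q'(p, \mathrm{df}, \alpha)\sqrt{MSE/n}$, where $q'$ is the
studentized-range quantile at Duncan's protection level
$1 - (1-\alpha)^{p-1}$. Two means differ when their gap exceeds the LSR for
the stretch they span; compact letters come from maximal non-significant
stretches of the ordered means, so the largest mean always carries "a".
Unbalanced groups use the harmonic mean of the group sizes in place of
$n$. With $p = 2$ the procedure reduces exactly to Fisher's LSD, which is
how it is cross-checked against pooled-variance t-tests. A degenerate
all-equal-replicates input (MSE = 0) assigns distinct letters to distinct
means.

## Enrichment and qPCR

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ (via the stable cumulative distribution), BH adjustment across
tested terms, and `rich_factor = k/K`. Terms are flat gene sets — no GO DAG
propagation; pre-propagate the map if ancestors should count. Significance
is flagged at $p \le 0.05$ inclusive on the raw p-value by default (the
adjusted column is a flag away). The background is the set of genes tested
for DE (the three-genotype intersection), the standard over-representation
choice when the assay universe is known. Terms with zero query overlap are
omitted from the output.

Relative qPCR expression is $2^{-\Delta\Delta C_t}$ with amplification
efficiency fixed at 2 and no multi-reference normalization; replicate Ct
values are averaged before differencing. The calibrator genotype returns
exactly 1 by construction. Concordance with RNA-seq reports the fraction of
genes with matching up/down direction and the Spearman correlation of the
log2 folds over the shared genes (at least three required).

## Numerical choices and tie-breaks

- Key heterosis period: the consecutive-timepoint interval with the largest
  MPH increase; no interval is flagged when the trend never rises, and
  exact ties resolve to the earliest interval.
- Dispersion floor $10^{-8}$; normalized-mean floor of half a count in the
  Wald variance; BH capped at 1.
- Pattern-label allocation by largest remainder; gene order randomized
  within the seeded RNG stream.
- All generators and the pipeline are deterministic functions of their
  integer seed.

## Problem sizes

The shipped checks run at desk scale by design: 5000-gene triads for
pattern recovery, 2000-gene null triads for test calibration, 200 seed
replicates for DE power, 500 for MPH unbiasedness, an exhaustive
hypergeometric sweep over backgrounds up to $N = 60$, and a 729-case
exhaustive classifier enumeration. These sizes keep every property
estimable with comfortable Monte-Carlo margins while completing in minutes.

## Limitations

- The NB test is a two-group Wald test: no covariates, no shrinkage, no
  GLM interactions. It matches the thresholds and semantics of heavier DE
  tools, not their per-gene numbers.
- Flat annotation maps only; enrichment p-values ignore term overlap
  structure.
- Better-parent (high-parent) heterosis is out of scope; only MPH is
  computed.
- The trait ANOVA is one-way per timepoint; no repeated-measures or
  spatial field-design modeling.
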