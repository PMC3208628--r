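---
title: "Methods: transcription factor activity screening and target-cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcription factor activity screening and target-cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A transcription factor (TF) that is active in one cell state but not
another leaves two independent traces: its binding motif is over-represented
in the promoters of the genes it controls, and those genes shift expression
between the states. `tfcohort` integrates the two traces. Given several
two-class expression comparisons (for example pluripotent stem cell lines
against matched fibroblasts, with only a handful of replicates each) and a
library of position weight matrices (PWMs), it asks two questions:

1. **Which matrices show transcription factor activity (TFA)?** — is the
   overlap between "high predicted binding density" genes and "strongly
   differentially expressed" genes larger than chance, robustly across
   comparisons and separately for up- and down-regulation?
2. **Which functional gene groups does a chosen regulator control?** — within
   a pathway or GO group, do differential expression and similarity to the
   regulator's own expression profile rise with predicted binding density,
   and which members form the high-confidence "target cohort"?

Everything runs on plain files (expression TSV, promoter FASTA, TRANSFAC
flat PWMs, GMT groups), and a synthetic-data generator with planted ground
truth exercises the full pipeline without any external download.

## Expression scoring

For each comparison the package computes the SAM moderated difference
statistic per gene, $d = (\bar x_{case} - \bar x_{control}) / (s + s_0)$,
with $s$ the pooled standard error and $s_0$ an exchangeability constant.
The default $s_0$ is the median of the per-gene standard errors — a
deterministic, widely used simplification; the coefficient-of-variation
minimizing quantile search is available via `s0_rule = "tusher"`, and a
fixed numeric $s_0$ is accepted. Scores are scaled per comparison to mean 0
and standard deviation 1.

A note on moments: scaling uses the sample ($n-1$) standard deviation — the
R convention, and the one consistent with the worked example
$d = \{1,2,3\} \mapsto z = \{-1,0,1\}$ — while the covariance similarity
below uses population ($1/n$) moments, matching its own closed-form test
cases. At genome scale the distinction is immaterial; it only matters for
reproducing the package's toy examples exactly.

Three per-gene summaries feed everything downstream:

* the **differential expression score**, the mean of $|z|$ across
  comparisons;
* the **dot-product similarity** with the designated regulator gene,
  $dp_B = \sum_c a_c b_c$ (raw sum over comparisons, no $1/n$);
* the **covariance similarity**,
  $cov_B = \frac{1}{n}\sum_c (a_c-\bar a)(b_c - \bar b)$.

The raw-sum/population-covariance convention reproduces the scale of the
shipped reference cutoffs (dot-product cutoffs of order 2–3 against
covariance cutoffs of order 0.1 over seven unit-variance comparisons).
Group-level versions are unweighted means over members — the only
aggregation that is stable when subsets of different sizes are compared
across propensity thresholds. Probe identifiers ending in `_a_at`, `_s_at`
or `_x_at` (cross-hybridizing designs) are dropped before scoring; the same
gene symbol at different loci stays distinct.

## Promoter scanning and target propensity

Matrices are read from TRANSFAC flat format with a pseudo-count of 1 added
before frequency normalization, so no frequency is zero. Scanning follows
the MATCH scheme: each offset scores
$S = \sum_i I(i)\, f(i, b_i)$ with the information vector
$I(i) = \sum_b f(i,b)\ln(4 f(i,b))$, rescaled between the worst and best
attainable scores to the matrix similarity score (MSS), and analogously over
the 5-position maximum-information core block (CSS). Both strands are
scanned; overlapping hits are all counted (no de-overlap rule is imposed —
the simplest reproducible convention); `N` bases contribute a position's
minimum frequency so masked sequence degrades rather than truncates a
score. Default cutoffs are MSS ≥ 0.75 and CSS ≥ 0.90 — deliberately
permissive, in the spirit of minimum-false-negative profiles, and
configurable per matrix.

The **target propensity** of a gene with $J$ alternative promoters is

$$tp = \frac{1}{J} \sum_{j=1}^{J} \frac{n_j}{\rho\, l_j}, \qquad
  \rho = \frac{\sum_i n_i}{\sum_i l_i},$$

the mean of each promoter's observed site density relative to the global
background density $\rho$ over all promoters. A background-level gene has
$tp \approx 1$, and a separation threshold of 4.9 reads as "4.9× the global
background density". Promoter windows default to $[-500, +100)$ around the
transcription start site (0-based half-open coordinates; minus-strand genes
reverse-complemented), and FASTA headers `gene|promoter` group alternative
promoters by prefix.

## The TFA screen

For one matrix, one comparison and one direction, genes are ranked twice:
by signed scaled SAM score (descending for the up screen, ascending for the
down screen — absolute values are never used for ranking) and by descending
target propensity, ties broken by gene ID in both. For every pair of rank
cutoffs $(r_s, r_t)$ the 2×2 table of top-list membership is scored with the
Yates-corrected chi-square

$$\chi^2 = \frac{N\,(\max(0, |ad-bc| - N/2))^2}{(a+b)(c+d)(a+c)(b+d)},$$

and the screen statistic is the maximum over all admissible tables. A table
is admissible when the expected overlap $r_s r_t / N$ exceeds 10, the
observed overlap exceeds the expected one, and — a constraint this package
adds — **every** cell's expected count reaches `min_cell_expected`
(default 5), the classic chi-square validity rule. The last constraint is
load-bearing: without it the null maximum is dominated by near-degenerate
corner tables whose complement margin holds a handful of genes, the
statistic's null tail turns into a power law, and the $-\log p$ /
chi-square relationship stops being linear (measured $R^2 \approx 0.7$–$0.8$
instead of $> 0.99$). With it, the relationship is linear to $R^2 > 0.99$,
which is exactly what the extrapolation step needs.

Since true targets need not occupy the very top SAM ranks, the scan then
removes the top-$k$ SAM genes ($k = 0, s, 2s, \dots$ up to the base
maximizer's $r_s$; $s$ defaults to a third of that cap, so at most four
depths are evaluated) and re-maximizes on the reduced universe; the final
statistic is the maximum over depths. The identical schedule runs inside the
null, so observed and null values stay exchangeable regardless of how the
aggregation over depths is chosen. Both the refined statistic and the base
maximum are reported.

Significance comes from a permutation null: the propensity ranking is
permuted uniformly relative to the SAM ranking (default 10,000 draws) and
the full statistic recomputed. The null depends only on the universe size
and scan settings, so one null sample per universe size is shared across
matrices, comparisons and directions by default — an exact saving, not an
approximation. Empirical tail probabilities at null points with
$\hat p \in [10/n_{perm}, 0.5]$ (below the noisy extreme tail, above the
non-linear bulk) are fitted by OLS of $-\log_{10}\hat p$ on the statistic.
Where the empirical tail probability is measurable ($\hat p \ge
10/n_{perm}$) it is reported as-is — this keeps permuted inputs uniformly
calibrated; beyond that window the fitted line extrapolates, floored at the
empirical bound so extrapolation never reduces significance inside the
sampled range.

Per matrix the screen reports the mean and median $-\log_{10} p$ per
direction, the number of comparisons with $-\log_{10} p \ge 2$, and a
consistency flag (default: at least 6 comparisons significant). The
per-matrix mean $-\log_{10} p$ in the relevant direction is the
candidate-ranking quantity.

## Target-cohort analysis

For a gene group and a metric (differential expression score, dot-product
or covariance similarity — the similarity metrics enter *signed*, since a
regulator's targets are expected concordant with it), the **score
increment** at propensity threshold $\tau$ is the mean metric over members
with $tp \ge \tau$ minus the whole-group mean (the above-minus-below
baseline is available by configuration; above-minus-all is the default
because it stays stable when the below-set is tiny). The threshold grid
defaults to the group's propensity deciles; the min-P correction below makes
the test valid for any grid.

The null keeps the group's propensity values fixed and assigns members
metric values drawn without replacement from the global pool (B = 1000
sampled groups by default; drawing whole gene rows instead, preserving
inter-metric correlation, is available as `null_mode = "rows"`). All
B + 1 units — the observed group and the samples — are ranked jointly at
each threshold: a unit's interim p-value is the fraction of units
(including itself) whose increment reaches its own. The self-count is
exactly the +1 smoothing term for the observed group, so p-values live in
$[1/(B+1), 1]$ and the construction is symmetric across units. The
**final p-value** compares the observed minimum interim p over thresholds
with every sampled group's own minimum (leave-self-in): a min-P
family-wise adjustment. Symmetry makes the final p of a null group uniform
up to tie-induced conservatism; it is never anti-conservative, and always
at least the minimum interim p. An earlier draft that gave sampled groups
both a self-count and an extra +1 biased null p-values visibly downward —
the joint-rank construction is the correct one.

Across groups, false discovery is controlled with Storey–Tibshirani
q-values: $\hat\pi_0(\lambda)$ is smoothed over
$\lambda \in \{0.05, \dots, 0.95\}$ with a cubic smoothing spline (df = 3)
and evaluated at the largest $\lambda$; the step-down
$q_i = \min_{t \ge p_i} \hat\pi_0 m t / \#\{p \le t\}$ is monotone in $p$ by
construction. The shipped reference analyses used a q cutoff of 0.267.

**Separation threshold and cohort identification.** The per-threshold
average of $-\log_{10}$ interim p across metrics typically rises as the
threshold decreases and then plateaus; the separation threshold $\tau^*$ is
the plateau onset approached from above — the *largest* threshold whose
profile value is within 10% of the maximum. (A specification draft read
this as the smallest such threshold; that contradicts the described
behaviour of significance increasing *as the threshold decreases to* the
reported value before plateauing, so the largest-threshold rule is used.)
A manual override is first-class, because reference analyses chose
separation thresholds by inspection. Envelope cutoffs per metric are the
maxima over below-$\tau^*$ members after excluding Q3 + 1.5 IQR outliers
(absolute values for the similarity metrics), and the cohort is the set of
members with $tp \ge \tau^*$, differential expression above its cutoff, and
either similarity above its cutoff. The published WNT (strict and
exploratory) and FGF cutoff configurations ship via `reference_cutoffs()`.

## The synthetic-data generator

The generator emulates the structure of the motivating study design: 7
two-class comparisons with 3 replicates per class; 5,000 genes; 600-base
promoters (the −500/+100 window), 1–3 alternative promoters per gene drawn
uniformly; 200 planted target genes; background binding sites planted at
0.002 sites/base (Poisson, mean 1.2 per promoter) and 5× that rate for
targets; expression noise SD 1; a case-class up-shift of 3 noise-SD units
for targets, scaled by each gene's planted site density relative to the
mean target density so that propensity and expression strength are coupled
by construction; 100 gene groups of 50 members, 5 of them drawing 40% of
members from the planted targets. Gene 1 is reserved as the regulator: it
is never a target and its case class is up-shifted deterministically, so
the similarity metrics have a signed reference. These defaults are the
study conditions; the acceptance checks run against them unchanged.

Background sequence is i.i.d. uniform ACGT. Planted sites are drawn
per-position from the matrix's frequencies and rejection-sampled to pass
the matrix's own MSS/CSS cutoffs — a planted site is a *detectable* site.
Without the rejection step a quarter or more of distribution draws fail the
core-similarity cutoff and planted-site recovery becomes ill-defined.
Sites are placed non-overlapping at uniform positions on a uniformly drawn
strand, with up to 100 placement retries before the promoter is reported as
over capacity.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: promoter composition bias and dinucleotide
structure (real promoters are GC-rich, so chance MATCH hits are more
frequent and background density estimates shift), probe-level microarray
noise and normalization artifacts, batch effects, correlated expression
between co-regulated non-target genes, and the heavy discreteness of real
propensity scores. On uniform background with the default permissive
cutoffs, chance hits dilute the realized target/non-target propensity
ratio well below the planted site-density ratio; the screen still separates
the planted matrix from decoys sharply because the test is relative, but
absolute propensity values should not be over-interpreted.

All outputs are pure functions of the configuration (a single integer seed
drives stage-specific derived seeds; the permutation kernels use their own
seeded Mersenne Twister independent of R's RNG state), and two runs with
the same configuration are byte-identical.

## Numerical and design choices

* **Grid resolution.** The threshold scan is exact (`grid_step = 1`) up to
  2,000 genes and switches to a rank grid of about 2,000 points for larger
  universes; the statistic is simply defined on the grid, identically for
  observed and null values. Calibration (uniformity of null p-values) holds
  at any grid resolution.
* **Ties.** SAM-score and propensity ties break by gene ID, identically in
  observed and null runs.
* **Zero-margin and inadmissible tables** score 0; a screen in which no
  table is admissible is flagged rather than silently zero.
* **Permutation p floors.** All permutation p-values are bounded below by
  $1/(B+1)$ or the extrapolated value; nothing is reported as exactly zero.
* **Degenerate inputs.** Zero-variance genes with $s_0 = 0$, zero global
  site counts, empty groups, single-comparison covariance (undefined, set
  to `NA` and dropped from the cohort metrics), windows running off contig
  ends (truncated with a warning) and flat significance profiles
  (separation threshold undefined) all produce explicit errors, warnings or
  flags, never silent propagation.
* **Problem sizes in the shipped checks.** The package's own test suite
  validates the kernel against exhaustive enumeration at universes of
  200–300 genes, calibrates TFA p-values at 2,000 genes with 500-draw
  nulls on a coarse (8-rank) grid over 1,000 replicates and cohort p-values
  at B = 200 over 500 replicates with independent pools, fits the 10,000
  draw null at the full 5,000-gene study conditions, and recovers the
  planted regulator among ten decoys with a shared 500-draw null. These
  sizes were chosen to make each property measurable with comfortable
  statistical margins while keeping a full run of the suite in the
  minutes range on a single core.

## Known limitations

* The all-cells expected-count validity rule is required for the linear
  extrapolation; analyses wanting the literal overlap-only constraint set
  can set `min_cell_expected = 0`, accepting that extrapolated significance
  then rests on a fit with visible curvature.
* The extrapolation assumes the log-linear tail continues beyond the
  sampled range; for observed statistics far outside it (planted-regulator
  screens reach $-\log_{10} p$ in the tens) the reported values are
  linear extrapolations, suitable for ranking and thresholding rather than
  as literal tail probabilities.
* TRANSFAC's proprietary minimum-false-negative cutoff profiles are not
  reproduced; the permissive defaults mimic their intent only.
* Column-shuffled decoys vary in hardness: the regulator motif is C/G-rich,
  so a shuffle that happens to permute mostly within the similar C/G/S
  columns remains partially matched to the planted sites and can retain a
  sizable share of the planted signal. The screen's ranking comparison
  (planted matrix versus the best decoy) is unaffected, but individual
  decoys are not all equally "null".
* The min-P cohort test is conservative under heavy ties (small B, many
  thresholds); B = 1000 keeps this mild.
* `fgsea::gmtPathways` drops the GMT description column on read; the
  writer emits it, so a round trip preserves membership but not
  descriptions.
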