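---
title: "Methods: granulocyte maturation signatures of sepsis versus SIRS"
author: "granulosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: granulocyte maturation signatures of sepsis versus SIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulosig)
```

# The model

Blood CD15⁺ cells are a mixture of maturation stages — late promyelocytes
(LPM), myelocytes (MY), metamyelocytes (MM), band cells (BC) and mature
segmented neutrophils (PMN). Granule biogenesis is "targeted by timing":
azurophilic-granule (AG) genes are transcribed at the promyelocyte stage,
specific-granule (SG) genes at the myelocyte/metamyelocyte stages,
gelatinase (GG) genes around metamyelocyte/band, and
ficolin-granule/secretory-vesicle/cell-membrane (FG/SV/CM) genes in the
latest stages. Proliferation and metabolic programs (cell cycle,
mitochondrial, proteasome, ribosome, lysosome) are precursor programs that
decline at the metamyelocyte stage.

The package's central object is therefore a mixture model. For sample $j$
with stage composition $\pi_j$ (a 5-simplex point) and a gene-by-stage
profile matrix $P$, expected bulk expression is

$$\mu_j = P\,\pi_j, \qquad x_{gj} = \mu_{gj}\,e^{\varepsilon_{gj}},
\quad \varepsilon_{gj}\sim N(0,\sigma^2_{\mathrm{tech}}),$$

and the stage-resolved blood counts of the same sample are
$\mathrm{round}(t_j\,\pi_j)$ with $t_j$ the total CD15 count. Coupling the
expression and count layers through one $\pi_j$ turns the study's central
interpretive claim — expression differences reflect precursor expansion,
not neutrophil activation — into a testable property of the generator:
any manipulation that raises LPM/MY mass must raise AG-gene bulk
expression *and* precursor counts together, which the test suite asserts.

# Synthetic-cohort parameters and their calibration

`cohort_config()` defaults encode the study conditions:

* **Group sizes** 11 presurgical / 16 SIRS / 15 sepsis (discovery
  transcriptomes); count analyses use 20 sepsis / 14 SIRS, the
  count-cohort sizes.
* **Compositions** $\pi \sim \mathrm{Dirichlet}(c\,\bar\pi_g)$ with
  $c = 600$ and group means

  | group | LPM | MY | MM | BC | PMN |
  |---|---|---|---|---|---|
  | presurgical | 0.0005 | 0.001 | 0.003 | 0.008 | 0.9875 |
  | SIRS | 0.0015 | 0.003 | 0.008 | 0.015 | 0.9725 |
  | sepsis | 0.0173 | 0.0223 | 0.0355 | 0.1185 | 0.8064 |

  together with total-count log-means (4 500 / 8 000 / 11 700 cells/µL,
  log-SD 0.4). These were derived once, in closed form, from the reported
  sepsis/SIRS count folds: with total-count ratio $R = 1.468$ the expected
  mean-count folds are LPM $16.9\times$, MY $10.9\times$, MM $6.5\times$,
  BC $11.6\times$ and PMN $1.22\times$ — the published pattern of strong
  precursor expansion with a modest, non-significant PMN difference. The
  concentration $c = 600$ makes per-patient precursor fractions spread
  over roughly an order of magnitude, matching the visual scatter of real
  count data. Note that the *estimator* (ratio of group means at
  $n = 20/14$) averages a few points above its expectation because the
  denominator is noisy; the acceptance run reports the Monte-Carlo mean of
  the estimator, which is the quantity a cohort actually yields.
* **Stage profiles**: each labelled gene has a plateau profile — baseline
  $b_g$ (log-normal, meanlog $\log 100$, sdlog 1) off-stage and
  $b_g \times$ peak ratio at its program's stage(s). Default peak ratios
  are AG 40, SG 12, GG 10, FG/SV/CM 8, precursor metabolic programs 25,
  reflecting that azurophilic-granule transcripts are the most sharply
  stage-restricted. With these ratios the expected global AG fold is
  $\approx 1.7$ for sepsis vs presurgical and $\approx 1.05$ for SIRS vs
  presurgical — elevated in sepsis only — while SG rises monotonically
  presurgical → SIRS → sepsis and the late compartments stay within a few
  ten percent of unity. `build_stage_profiles()` uses a fallback peak
  ratio of 10 for unconfigured labels.
* **Technical noise** $\sigma_{\mathrm{tech}} = 0.3$ (natural-log scale),
  a microarray-like multiplicative error.
* **Bead-array layer**: duplicate signal
  $y = \mathrm{gain}\cdot x\,(1 + \mathrm{cv}\,z) + e$, floored at the
  plate background (gain 5, background 150, background noise SD 15,
  duplicate CV 0.1). The floor reproduces the at-or-below-background
  phenomenon that drives the missing-value rule: dim transcripts read out
  *at* background and are treated as missing, not zero.

All draws flow from one seed in a documented order (baselines, then
compositions, noise, totals, bead-array), so identical configurations are
byte-identical.

What the generator does **not** emulate: probe-level artefacts,
batch/array effects, within-stage activation states (low-density
granulocytes, granulocytic MDSCs), inter-gene correlation beyond the
shared composition, and absolute expression units (chosen only for
recoverability). Passing recovery tests therefore demonstrate that the
pipeline is correct under the mixture mechanism, not that real cohorts
will behave this cleanly.

# Statistical procedures

**Differential expression.** One-way fixed-effects ANOVA on log₂
intensities gives the global F p-value. Pairwise contrast p-values use
the ordinary pooled-variance two-group t on the two groups' log₂ values;
this makes the ranking statistic of the enrichment module and the dge
contrast identical by construction (whether the original analysis used
the global ANOVA error term for contrasts is not stated anywhere; the
two-group choice is recorded as this package's design decision).
FDR control is Benjamini–Hochberg applied per contrast across all genes —
the published analysis names the concept ("FDR-q"), not the procedure;
BH is the microarray standard. Fold changes are ratios of arithmetic
group means on the linear scale, reported as $\max(r, 1/r)$ with a
direction sign, matching the "x-fold" usage. Degenerate genes: all
values equal → p = 1 and fold 1; distinct means with zero within-group
variance → variance floor $10^{-8}$ on the log₂ scale.

**DEG universe.** Percentages and the Venn partition are taken over genes
significant in at least one contrast; within a Venn region, up/down
tallies are per contrast, so they need not sum to the region size when a
gene moves in opposite directions in different contrasts.

**Enrichment.** Genes are ranked by the signed contrast t; the
enrichment score is the extreme deviation of the running sum
$S_i = \sum_{\mathrm{hits}\,\le i} w/\!\sum_{\mathrm{hits}} w - i/N$
with weights $w = |t|$ — the weighted hit CDF against the uniform
position CDF. This form starts and ends at 0 for every set and weighting,
lies in $[-1, 1]$, and is 0 by convention for a set covering the whole
universe. The null distribution permutes sample labels between the two
contrast groups (preserving inter-gene correlation); gene permutation is
available for tiny cohorts. NES divides ES by the mean magnitude of
same-sign null ES per set; FDR-q follows the sign-pooled null
convention. The original analysis ran inside a commercial package whose
exact statistic is unpublished; this module is the standard open
equivalent of an NES/FDR-q enrichment and reproduces the reported
patterns qualitatively, which is all the package claims.

**Selection strategies.** Strategy 1 reads "top 100 … each" as two
top-100 lists (one per group's mean expression) joined, ranked by
ascending FDR-adjusted p; exclusions (e.g. a gene dropped for assay
reasons) shrink the top-50 shortlist without promoting the next-ranked
gene. Mean expression is taken on the linear scale. The range rule uses
type-7 (linear-interpolation) quantiles with strict inequalities; a
boundary tie — including one at floating-point resolution — fails the
rule, the conservative reading. Range-rule candidates are drawn from the
joined pool (not all DEGs), per the wording "from this list". Strategy 2
gates on linear fold magnitudes (>2 and <1.1). Strategy 3 intersects the
joined pool with a user-supplied lysosome list.

**Bead-array validation.** Duplicates are averaged *before* the
background comparison; masking uses the raw duplicate mean against a
single per-plate background (the published text defines background
neither numerically nor per-analyte; a per-plate constant is the
simplest faithful reading). Normalization divides by the reference
gene's duplicate mean per sample; a reference at or below background is
an error, not a missing value. Confirmation needs ≥ 4 above-background
patients per group. The Mann–Whitney test is exact (full enumeration of
label assignments) for min(n, m) ≤ 8 and N ≤ 20, and tie-corrected
normal with continuity correction otherwise. Bonferroni multipliers are
the number of *confirmed* genes per strategy list and over all confirmed
selected genes; a gene validates when any adjusted p falls below α —
this is what lets a gene on a short strategy-3 list validate while its
globally adjusted p stays above threshold.

**Counts and PCA.** Count comparisons use the ratio of arithmetic group
means and the same Mann–Whitney test, with no multiplicity correction
across the five populations (matching the published reading). Fisher's
2×2 test is two-sided by the probability-mass rule. PCA centers and
unit-variance-scales features and uses SVD on otherwise untransformed
data; missing bead-array values are set to 0 (nominal background) under
the `zero_fill` policy, a convention used for PCA only — everywhere else
missing stays missing. Constant features are dropped with a warning
(their scale is undefined); covariance PCA (`scale = FALSE`) is available
and is the form under which the explained-variance spectrum is exactly
rotation-invariant.

# Numerical and design notes

* Quantiles: type 7 throughout (the most common default; no convention is
  published for the range rule).
* Zero-variance floors: $10^{-8}$ on the log₂ scale, used only when group
  means differ with zero within-group variance.
* Ties in rankings are broken by gene id, making every selection a
  deterministic function of its inputs.
* Gene identity is by case-sensitive symbol; no alias resolution.
  Multi-probe collapsing is out of scope — each expression row is one
  gene.
* Expression is stored linearly; log₂ happens inside the statistics.
  Fold gates and reported folds are linear ratios.
* The exclusion list is configuration, not code: the analysis that
  motivated it dropped one gene from the strategy-1 shortlist for
  assay-design reasons, and the package models that as a user-supplied
  list.
* Global compartment expression averages per-gene group means with equal
  gene weights (the alternative — pooling all sample values — is not what
  the published figure describes; the per-gene-mean reading is
  implemented).

# Problem sizes used by the tests and acceptance run

Unit and property tests run on reduced universes (hundreds to a few
thousand genes, 5–20 genes per stage program) chosen so that every
planted structure is recoverable; the acceptance run uses the full
20,000-gene default for the signature and enrichment summaries, 10
Monte-Carlo cohorts per quantity, and 200 label permutations for the
enrichment null. The exact-test oracles enumerate all 2×2 tables with
N ≤ 30 and all Mann–Whitney configurations with group sizes ≤ 7.

# Known limitations

* The enrichment NES is comparable across sets within a run, but its
  absolute scale depends on the permutation count and the null
  convention; only patterns (sign, ordering, q-threshold crossings) are
  meaningful.
* With 14–20 samples per group, ratio-of-means fold estimates for rare
  populations (LPM fractions of ~0.1–2%) are right-skewed; single-cohort
  folds can land well away from their expectation, which is why the
  acceptance quantities are Monte-Carlo means.
* The validation false-call guarantee is Bonferroni's: with ~40 confirmed
  genes and α = 0.05, the familywise false-validation probability per
  plate is below 5%, not zero in the limit of many plates.
* Sample-label permutation with very small groups has coarse p-value
  granularity; the gene-permutation null is provided for that regime but
  ignores inter-gene correlation.
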