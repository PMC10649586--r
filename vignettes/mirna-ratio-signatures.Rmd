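---
title: "MicroRNA expression-ratio signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MicroRNA expression-ratio signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRatio)
```

## The problem

Distinguishing borderline from malignant mucinous ovarian tumors is hard:
the tumors are large and heterogeneous, intra-operative pathology frequently
under-calls invasive disease, and the surgical consequences of the call are
drastic (conservative surgery vs radical excision plus chemotherapy).
Tissue microRNAs (miRNAs) are attractive biomarkers for this two-group
problem, but small-cohort miRNA studies are notoriously sensitive to
normalization choices: microarray intensities are quantile-style normalized
as a "black box", while RT-qPCR validation depends on picking endogenous
reference genes that may themselves drift.

`miRatio` implements a workflow built around a simple algebraic observation:
the **ratio of an up-regulated to a down-regulated miRNA cancels any
sample-level normalization factor**. If sample $j$ carries a multiplicative
technical factor $c_j$ (RNA amount, labeling, RT efficiency), then both
measured expressions are scaled by $c_j$ and

$$
r_{ud}(j) \;=\; \frac{c_j\,x_u(j)}{c_j\,x_d(j)} \;=\; \frac{x_u(j)}{x_d(j)},
$$

so the ratio is normalization-free, and the diagnostic signals of the two
miRNAs reinforce each other. Pairs of such ratios ("double ratios"), each
thresholded at its own ROC-derived cutoff, form a tiny two-feature
classifier searched exhaustively.

## Pipeline stages

1. **Candidate selection** (`select_stringent()`, `select_fc_only()`).
   From a two-group log2 expression matrix, the stringent step keeps miRNAs
   with mean expression above `expr_min = 5` log2 in at least one group and a
   linear fold-change factor of at least 2 (i.e. $|\log_2 FC| \ge 1$,
   boundary included). A complementary pass keeps additional up-regulated
   miRNAs on a strict fold-change criterion alone ($|\log_2 FC| > 1$),
   reflecting that over-expressed markers are the scarcer and more useful
   resource (they become ratio numerators). Single-marker quality is
   summarized by `classification_errors()`: the resubstitution error of the
   best single threshold, with the rule "call malignant when the value
   exceeds $t$" (orientation fixed by the marker's direction, thresholds at
   midpoints of consecutive sorted unique values plus $\pm\infty$).

2. **Reference-gene stability** (`stability_values()`,
   `select_normalizers()`, `normalize_expr()`). Stability is scored with a
   grouped NormFinder-style model. After centering each sample over the
   candidate genes ($z_{ij} = x_{ij} - \bar{x}_{\cdot j}$), the model
   estimates, per gene $i$ and group $g$, the intragroup variance
   $v_{ig}$ and the gene-by-group interaction $\hat d_{ig}$ (the double-
   centered group mean). A method-of-moments interaction variance
   $\hat\tau^2$ (truncated at zero) shrinks the deviations,
   $\tilde d_{ig} = \hat d_{ig}\,\hat\tau^2/(\hat\tau^2 + v_{ig}/k_g)$, and
   the stability value is
   $$
   \rho_i = \frac{1}{G}\sum_g \left( |\tilde d_{ig}| +
     \sqrt{\tfrac{v_{ig}}{k_g}\cdot\tfrac{\hat\tau^2}{\hat\tau^2 + v_{ig}/k_g}}
     \right),
   $$
   i.e. the average magnitude of the shrunken group deviation plus its
   standard error — lower is more stable. The literature contains more than
   one reading of the grouped NormFinder estimator; this contract (per-sample
   centering, two-way interaction with shrinkage, truncation of negative
   variance estimates) was fixed so that every quantity is assertable in
   tests, and equivalence with any particular historical implementation is
   not claimed. Normalizers must also pass a mean-expression filter
   ($\ge 5$ log2) and a stability bound ($\rho < 0.25$); the top `k = 3`
   (ties broken by higher expression, then id) define the per-sample
   normalization factor as the arithmetic mean of their log2 values — the
   log-space equivalent of the geometric mean, mirroring how a
   three-normalizer geometric mean is used in qPCR practice.

3. **RT-qPCR quantification** (`aggregate_replicates()`, `delta_cq()`,
   `delta_delta_cq()`, `differential_test()`). Technical triplicates are
   aggregated by mean and SD (no automatic outlier removal; an undetermined
   Cq stays missing — no limit-of-detection substitution is attempted,
   because no censoring model is part of the design). Relative expression is
   $2^{-\Delta Cq}$ with $\Delta Cq = Cq_\text{target} - Cq_\text{ref}$ and
   $Cq_\text{ref}$ the arithmetic mean of the normalizers' Cq values; group
   fold-changes are $2^{-\Delta\Delta Cq}$. Differential testing is the
   pooled-variance two-sample Student's $t$ (two-sided, $\alpha = 0.05$,
   B-minus-M sign convention). Tests run by default on the log2 scale
   ($-\Delta Cq$), where the equal-variance assumption is more credible than
   on the linear $2^{-\Delta Cq}$ scale; linear-scale testing is available.
   Zero-variance degenerate inputs are flagged rather than raised as errors.

4. **Ratio analysis** (`build_ratios()`, `roc_curve()`, `youden_optimal()`,
   `test_ratios()`). All $|up| \times |down|$ ratios are built per sample
   (50 for the default 5 × 10 design), tested (equal-variance $t$ on log2
   ratios, no multiplicity adjustment by default, a BH column on request),
   and scored by ROC with malignant as the positive class. The AUC is the
   trapezoid area, identical to the rank statistic (ties counted ½). The
   operating threshold maximizes the Youden index
   $J = \text{sensitivity} + \text{specificity} - 1$; ties prefer higher
   specificity (fewer borderline tumors over-called), then the lower
   threshold. Orientation is never auto-flipped: ratios are up/down by
   construction, and an observed AUC below 0.5 is reported as-is rather than
   silently inverting the classifier family.

5. **Double-ratio search** (`enumerate_ratio_pairs()`, `pair_error_matrix()`,
   `perfect_pairs()`). All unordered pairs of ratios sharing no miRNA
   (equivalently, involving ≥ 4 distinct miRNAs) are enumerated —
   $\binom{ab}{2} - a\binom{b}{2} - b\binom{a}{2}$ pairs, 900 for the 5 × 10
   design. Each pair classifies a sample by combining the two fixed
   single-ratio Youden thresholds. How two thresholded ratios combine into
   one call is genuinely open; the default **AND** rule (malignant iff both
   ratios exceed their thresholds) is the conservative "malignant quadrant"
   reading, with **OR** and a log-scale **SUM** rule selectable and recorded
   in the output. Thresholds are deliberately *not* re-optimized per pair:
   joint 2-D optimization over 900 pairs on ~23 samples would overfit
   immediately. Error counts are resubstitution errors: thresholds and
   errors come from the same samples, which is the right description of a
   discovery cohort and an optimistic estimate of generalization.

## The synthetic-data generator

`simulate_microarray()` draws
$x_{ij} = \mu_i + \delta_i\,\mathbf{1}[j \in M] + s_j + \varepsilon_{ij}$:
uniform baselines $\mu_i \in [4, 12]$ log2 (typical of RMA-normalized miRNA
arrays, straddling the expression filter at 5), group effects $\delta_i$ for
the planted differential miRNAs, per-sample offsets
$s_j \sim N(0, 0.5^2)$ emulating RNA-amount/labeling variation, and noise
$\varepsilon_{ij} \sim N(0, 0.5^2)$ (SD 0.1 for the planted stable
normalizers). Planted biomarkers and normalizers take baselines in the upper
part of the range: a validated assay target is well-expressed by
construction, and recovery of a marker planted below the detection filter
would be meaningless. Defaults encode the study conditions the package is
tested under: 11 borderline vs 12 malignant samples, 5 up-regulated miRNAs
at $+2$ log2, 10 down-regulated at $-2$ log2, 5 normalizer candidates.

`simulate_qpcr()` maps the *same* latent expression (same $\mu_i$,
$\delta_i$ and crucially the same sample offsets $s_j$, all derived
deterministically from the seed) through $Cq = 30 - \log_2 x$ — slope −1,
i.e. perfect PCR efficiency, matching the $2^{-\Delta Cq}$ model — and adds
replicate noise (SD 0.2 cycles, triplicates). Sharing $s_j$ across the two
views is what lets the package demonstrate, against one ground truth, both
that geometric-mean normalization removes sample offsets and that ratios
cancel them without any normalizer at all.

What the generator does **not** emulate: probe-level microarray effects and
RMA itself, PCR efficiencies different from 2, censored ("undetermined") Cq
values near the detection limit, batch-by-group confounding, and the heavy
non-Gaussian tails of FFPE-derived measurements. Passing recovery tests on
this generator therefore shows the machinery is correct and well-calibrated
under its stated model — not that any particular clinical cohort will yield
perfectly separating double ratios.

## Numerical and design notes

- All expression arithmetic is in log space; linear values are produced only
  at the boundaries ($2^{-\Delta Cq}$, ratio values). Normalization is exact
  subtraction, symmetric with Cq arithmetic.
- Threshold grids use midpoints between consecutive sorted unique values
  plus $\pm\infty$; a value exactly on a threshold is called borderline
  (strict `>` for the malignant call). This makes every reported operating
  point reproducible from the data alone.
- Degenerate inputs: constant values give $\min(n_B, n_M)$ single-marker
  errors, AUC 0.5, and $J^* = 0$ at the infinite threshold (specificity
  tie-break prefers calling everything borderline).
- Negative method-of-moments variance estimates truncate to zero, which also
  forces zero shrinkage weight and $\rho = 0$ for exactly constant genes.
- The group-mean expression rule for up-regulated candidates
  (B-mean > 5 **or** M-mean > 20, both in log2) is implemented exactly as
  configured defaults even though a 20 log2 intensity is above any plausible
  RMA range — the value is configurable and the disjunction is the weakest
  filter consistent with its description; with the default it effectively
  reduces to the borderline-group branch.
- The expression filter of the stringent step applies to the group *mean* in
  at least one group (OR over groups): the weakest reading consistent with a
  mean-intensity-vs-fold-change volcano plot, and configurable.
- Test problem sizes: oracle equivalences run on 1000 random small instances
  ($n \le 12$); recovery checks use 100 simulated cohorts of 11 + 12 samples
  with 500 miRNAs each — sizes chosen to mirror the study design while
  keeping the full suite fast.

## Limitations

Resubstitution error on ~23 samples is an optimistic, high-variance measure;
the package reports it because it is the quantity the workflow defines, not
because it estimates out-of-sample accuracy. No confidence intervals on AUC
and no cross-validated pair selection are provided. The double-ratio search
is exhaustive over pairs only; higher-order combinations are out of scope.
The minimal GEO reader parses only the series-matrix table block, not full
SOFT metadata.
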