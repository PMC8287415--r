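---
title: "Identifying dysregulated pathways from gene-pair co-expression shifts"
author: "dyspathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying dysregulated pathways from gene-pair co-expression shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most pathway enrichment methods summarise genes one at a time (differential
expression or variability) and treat a pathway as a bag of genes.  They are
blind to *differential co-expression* (dysregulation): two genes whose
correlation changes between conditions, e.g. a regulatory edge that is
active in tumours but silent in normal tissue, even when neither gene's
mean changes.  `dyspathway` tests pathways as **sets of regulated gene
pairs** and asks whether a pathway's pairs gained or lost co-expression in
cases relative to controls.

## The model

### Per-pair score (DysGPS)

For each gene, expression is mean-centred and scaled **separately within
each phenotype group** (case/control).  We use the unbiased $(n-1)$ sample
standard deviation throughout; see *Numerical conventions*.  For a gene
pair $(X_i, X_j)$ and sample $k$, the CILP
(correlation-by-individual-level-product) statistic is the product of the
two standardized values,

$$y_{ij,k} = \tilde x_{ik}\, \tilde x_{jk}.$$

Its group mean is algebraically tied to the within-group Pearson
correlation: $\bar y_{\text{group}} = \frac{n-1}{n} r_{\text{group}}$
(exactly, under $(n-1)$ scaling — the package tests this identity).  Each
sample therefore contributes one observation of co-expression, and the
dysregulated gene-pair score is the Welch two-sample $t$ statistic

$$\mathrm{DysGPS}_{ij} =
  \frac{\bar y^{\,\text{case}} - \bar y^{\,\text{control}}}
       {\sqrt{s_1^2/n_1 + s_2^2/n_2}},$$

with unbiased group variances $s_\ell^2$.  The sign convention is **case
minus control**: positive scores mean the pair is more co-expressed in
cases.  DysGPS is used purely as a ranking score — no degrees of freedom or
parametric p-value are ever computed from it.

### Per-pathway score (DysPS)

All $N$ pairs of a *combined background* (below) are ranked by DysGPS in
descending order.  For a pathway $P$ with pairs at ranks
$r_1 < \dots < r_m$, a weighted Kolmogorov–Smirnov running sum walks the
list, stepping up by $|\mathrm{DysGPS}|^p / N_R$ at hits
($N_R = \sum_{g\in P} |\mathrm{DysGPS}_g|^p$) and down by $1/(N - m)$ at
misses.  DysPS is the extremum of largest magnitude of
$S_{hit} - S_{miss}$.  With $p = 0$ this is the classic two-sample KS
statistic on ranks; the default $p = 1$ weights pathway pairs by their
dysregulation strength.  $|\mathrm{DysPS}| \le 1$ for $p \in \{0, 1\}$.

### Significance

Case/control labels are randomly permuted (group sizes preserved); each
shuffle re-standardizes, re-scores every background pair, re-ranks, and
re-scores **every** pathway — one shared shuffle serves all pathways, which
is what makes large permutation counts affordable.  The nominal p-value
compares the observed DysPS against the same-signed portion of its own
pathway's null,

$$p = \frac{1 + \#\{ \text{null same-sign, at least as extreme} \}}
           {1 + \#\{ \text{null same-sign} \}},$$

so $p \in (0, 1]$ and is never exactly zero.  Benjamini–Hochberg FDR is
applied across all tested pathways of a run as one family, and a pathway is
called a **gain** of correlation if FDR < α and DysPS > 0, a **loss** if
FDR < α and DysPS < 0 (default α = 0.05).

### The combined background

Ranking pathway pairs only against other pathway pairs biases the null:
curated regulatory pairs are systematically more co-expressed than random
gene pairs.  The background therefore combines (i) the **observed** set —
the union of all pairs appearing in the pathway collection — and (ii) a
**random** set of unordered gene pairs sampled uniformly without
replacement from the gene universe, by default in roughly 1:1 proportion.
Pairs present in both are kept once (provenance `both`).  Pairs are stored
canonically (symbols in ascending byte order), compared case-sensitively,
without locale folding.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_perm` | 10000 (`run`), 1000 (simulation study) | label permutations; ≥1000 needed for usable p-values, ≥10000 for stable FDRs over many pathways |
| `p_exp` | 1 | DysPS weight exponent; 0 gives the unweighted KS statistic |
| `min_size`, `max_size` | 5, 5000 | usable-pair window for testing a pathway (pairs present in the restricted background) |
| `alpha` | 0.05 | FDR threshold for the gain/loss call |
| `seed` | — | master seed; permutations and random backgrounds derive sub-seeds from it |

## Numerical conventions and edge cases

* **Standard deviation.**  The standardization formula can be read with
  either the population or the unbiased estimator; the Welch test is
  explicitly unbiased.  We use $(n-1)$ in both places, keeping one
  convention, with the measurable consequence
  $\bar y = \frac{n-1}{n} r$ that the tests assert.
* **Welch denominator.**  $s_\Delta = \sqrt{s_1^2/n_1 + s_2^2/n_2}$, the
  standard Welch standard error.
* **Ranking ties.**  Exact DysGPS ties are broken by canonical pair name
  (`gene_a`, then `gene_b`, byte order) so rankings are reproducible across
  platforms.  An exact $|S_{max}| = |S_{min}|$ tie returns $S_{max}$.
* **Zero variance.**  Pairs whose genes are unmeasured or constant within
  a group are removed once, before scoring (`restrict_to_expression()`),
  so the ranked-list length $N$ is identical across permutations.
* **Tiny samples.**  When $\binom{n}{n_1} \le$ `n_perm`, all distinct label
  assignments are enumerated instead of sampled (with a warning).  Note a
  hard limit of the statistic itself: with exactly 2 samples per group the
  group-wise z-scores are forced to $\pm 1/\sqrt 2$, the CILP products are
  constant within each group and the Welch denominator is zero — DysGPS
  requires at least 3 samples per group in practice, and the package warns
  below that.
* **Missing data.**  Rejected at ingest by default; optional row-mean
  imputation must be requested explicitly, because silent imputation would
  change scores.
* **Degenerate nulls.**  If no null value shares the observed sign, the
  p-value is reported as 1 with a warning.

## The synthetic benchmark

The simulation module generates the study conditions used for validation.
Each background pair is an independent bivariate normal with unit variances
and condition-specific correlation ($r_1$ in cases, $r_2$ in controls;
Cholesky construction, which is exactly the classic multivariate-normal
sampler for this 2×2 case).  The default composition of 100,000 pairs:

* 95,000 non-dysregulated (NDG): $r_1 = r_2 \sim U[-1, 1]$;
* 2,500 gain-of-correlation (GCDG), 500 per shift
  $\delta \in \{0.4, \dots, 0.8\}$: $r_1 \sim U[\delta - 1, 1]$,
  $r_2 = r_1 - \delta$;
* 2,500 loss-of-correlation (LCDG), mirrored.

100 case and 100 control samples are drawn per pair.  1,000 pathways are
built — 200 at each size in $\{20, 40, 60, 80, 100\}$, 20 of which are
dysregulated (100 total).  A dysregulated pathway takes
$\mathrm{round}(p_{dysgp} \cdot \text{size})$ pairs from its assigned pool
and the rest from the NDG pool; pools split the dysregulated pathways
half/half into gain/loss direction and, within direction, half *strong*
(shifts 0.7/0.8) and half *weak* (shifts 0.4/0.5).  The strong/weak split
is a design choice of this package: the totals, sizes and the 100
dysregulated pathways match the published design, but the exact per-pathway
composition of the original benchmark is not public, so the detailed split
here is a declared reconstruction, configurable through `sim_config()`.
Detection is evaluated by ranking pathways by nominal p-value (ties by
$|\mathrm{DysPS}|$) and computing the ROC AUC against the truth flags, both
pooled and per size.  With this reconstruction the pipeline separates
dysregulated from null pathways almost perfectly at full scale (pooled AUC
≈ 0.995–1.0 across $p_{dysgp}$ 0.2–0.6, computed by
`scripts/acceptance.R`), with AUC increasing in $p_{dysgp}$ and in pathway
size.

**What the generator does not emulate:** marginal distributions are exactly
normal (no heavy tails, no count noise), pairs are independent and share no
genes (real backgrounds reuse genes across many pairs, correlating their
scores), pathways overlap only through pair reuse, and there are no batch
effects or covariates.  Passing the benchmark therefore demonstrates the
statistical machinery under the stated model, not robustness to everything
real expression data can do.

**Problem sizes in the test-suite.**  The package's own tests run the same
study scaled down (10,000 pairs, 200 pathways, 500 permutations, 3 seeds) —
a size chosen so the whole suite runs in minutes while leaving the
qualitative claims (high AUC, ordering across $p_{dysgp}$, near-perfect
detection at sizes ≥ 80) testable; means/medians over the 3 seeds absorb
the ceiling effects that single scaled runs show.  The full-size benchmark
is reproduced by `scripts/acceptance.R`.

## Design choices made where the design was open

* **Per-pathway null.**  Each pathway is compared to its own permutation
  null; no cross-pathway size normalisation (no NES analogue) is applied.
* **P-value pseudocount.**  The $(1+b)/(1+m)$ form guarantees $p > 0$ at
  any permutation count.
* **ROC ranking statistic.**  The nominal p-value is the method's decision
  variable, so it drives the ROC; $|\mathrm{DysPS}|$ breaks its ties
  (p-values are discrete at resolution ~$1/n_{perm}$).
* **Pair-file format.**  No standard exists for pathway *edge* sets as
  enrichment inputs, so the package defines `pair_gmt` (GMT lines whose
  member tokens are `GENEA|GENEB`) and also reads SIF edge lists.
* **Random-pair sampling.**  Unordered pairs are sampled uniformly without
  replacement directly (index-decoding into the upper triangle), which is
  distributionally identical to sampling ordered pairs and keeping the
  ascending half, without wasted draws.
* **Seeds.**  A master seed deterministically derives per-stage sub-seeds
  (generator, pathway sampler, permutation engine), so stages are
  independently reproducible.

## Limitations

* DysGPS needs ≥ 3 samples per group to be meaningful (see above) and, like
  all correlation-shift statistics, many more for power.
* The case/control assignment fixes the sign of every score; swapping the
  phenotype mapping negates all DysGPS and DysPS values (an invariant the
  tests verify) and swaps gain/loss calls.
* Covariate adjustment inside the per-sample product is not implemented.
* The permutation null assumes exchangeability of samples across groups
  under the null; strong batch structure violates this.
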