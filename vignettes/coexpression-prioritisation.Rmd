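---
title: "Co-expression candidate-gene prioritisation: models and methods"
author: "coexRank maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression candidate-gene prioritisation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexRank)
```

# The statistical model

## Guilt by association

`coexRank` assumes that genes causing the same disease tend to participate
in a small number of convergent regulatory networks, so that a true
candidate will be co-expressed with already-confirmed disease genes. The
method therefore *requires* a seed list of known disease genes; it cannot
discover disease genes de novo, and it will underperform when the known
genes are not themselves co-expressed (a dispersed, non-convergent
disease architecture).

## Donor-weighted correlation

Brain expression resources typically collect several samples per donor
(different regions, repeated arrays). Treating those as independent
observations overstates the effective sample size and biases correlation
estimates toward whatever is shared within donors. Every correlation in
this package is therefore a weighted Pearson correlation with per-sample
weight $w_i = 1/n_{d(i)}$, the inverse of the number of samples donor
$d(i)$ contributes:

$$ r_w = \frac{\sum_i w_i (x_i - \bar x_w)(y_i - \bar y_w)}
  {\sqrt{\sum_i w_i (x_i - \bar x_w)^2 \sum_i w_i (y_i - \bar y_w)^2}}. $$

Each donor carries unit total weight; the weights sum to the number of
donors. The statistic is invariant to positive affine transforms of
either variable and to rescaling of the weights, and reduces exactly to
the unweighted Pearson correlation when every donor contributes one
sample — properties the test suite checks against independent oracles
(direct formula evaluation and `cov.wt`).

## The permutation threshold

An absolute-correlation cutoff cannot be fixed a priori: its null
distribution depends on sample size, donor structure and residual
artefacts, all of which differ across datasets. The cutoff is therefore
calibrated per dataset:

1. draw a random gene set the size of the candidate set from the eligible
   pool; record each drawn gene's maximum $|r_w|$ with any disease gene;
   repeat $B = 1000$ times and pool all maxima;
2. take the empirical $(1-p)$ quantile of the pooled maxima, where $p$ is
   the user's tolerated proportion of random genes prioritised
   (default 0.2);
3. prioritise candidates whose maximum $|r_w|$ with any disease gene is
   *strictly* greater than the cutoff.

Three design points deserve explanation, as the procedure admits
variants:

* **The eligible pool excludes candidates as well as disease genes.**
  If candidates carried real signal and were sampled into the null, the
  threshold would inflate and the procedure would lose power exactly when
  it matters.
* **Maxima are pooled across repeats** rather than thresholded per
  repeat, and the quantile is the inverse-ECDF (type-1, lower) empirical
  quantile. This is the simplest rule that satisfies the calibration
  contract — *on average* a fraction $p$ of random genes passes — which
  the acceptance suite verifies directly (mean prioritised fraction of
  random candidates within ±0.03 of 0.2 over 50 pure-noise replicates of
  1000 genes × 120 samples).
* **Strictness at the cutoff** means a threshold equal to the null
  maximum (at $p = 0$) prioritises nothing.

Because a gene's maximum $|r_w|$ against the disease set does not depend
on which repeat draws it, the implementation computes the per-gene maxima
once and lets the $B$ repeats resample indices only; this is
mathematically identical to the literal loop and makes $B = 1000$ cheap.

## Consensus across datasets

The three steps run in each dataset separately; merging raw intensities
across platforms is unsound, so evidence is combined at the decision
level. A candidate's *consensus count* is the number of datasets that
prioritise it; candidates absent from a dataset are *untestable* there
and are reported with the count of testable datasets rather than
penalised. Ranking is by consensus count, then by the sum of
above-cutoff $|r_w|$ aggregated over the prioritising datasets (the
per-dataset sums are well defined; aggregation by summation is this
package's choice), then alphabetically, with exact ties flagged. The
consensus sets are nested in $k$, so requiring $k \ge 2$ (the default)
strictly trades sensitivity for specificity; the benchmarking harness
quantifies that trade-off.

# Cleaning strategies

Neither strategy needs batch metadata, which real resources frequently
lack.

**Background + quantile.** Inputs are summarised log-scale matrices, so
probe-level background models are unavailable; background correction is
a per-sample positivity shift (subtract the sample's 2% quantile only
when that quantile is negative, floor at $10^{-8}$), followed by
`limma`-style quantile normalisation with tie averaging. The
only-when-negative rule makes the composite operation idempotent.

**RUV with negative controls.** Unwanted factors are estimated as the
top-$k$ right singular vectors of the row-centred negative-control
submatrix (housekeeping genes by default, always purged of disease
genes, candidates and user exclusions). Every gene is then adjusted by
removing its projection onto those factors shrunk by $1/(1+\lambda)$: a
ridge-regularised removal, with $\lambda = 0$ removing the factors
completely (control rows end exactly orthogonal to them) and
$\lambda \to \infty$ leaving the centred data untouched. The ridge
guards against removing biology correlated with the unwanted factors.
Defaults: $k = 10$ factors; $\lambda$ chosen per dataset from the grid
$\{0, 0.1, 0.5, 1, 5, 10, 50\}$ so that the cleaned control-gene mean
$|r|$ best matches the independence expectation
$\sqrt{2/(\pi(n-1))}$. Both the factor estimator and the selection rule
are this package's own concrete choices for a regularised RUV and are
fully overridable (`ruvConfig`).

# Developmental periods

Samples are binned into 15 developmental periods, embryonic (4
post-conception weeks, PCW) through late adulthood (60+ years). Prenatal
ages are expressed in PCW, postnatal ages in months or years; the two
scales are never converted into each other — the unit selects the
prenatal (1–7) or postnatal (8–15) block. All intervals are half-open
$[\mathrm{lower}, \mathrm{upper})$, which makes the mapping total and
non-overlapping on a dense age grid (property-tested). The late-fetal
period is taken as 24–38 PCW, reading its upper bound as term birth; the
printed source of the table garbles that bound, and 38 PCW is the value
that tiles the prenatal axis without gaps. PCW ages below 4 are
rejected as pre-embryonic.

Period subsetting precedes every other computation in the pipeline, and
donor weights are always recomputed on the subset.

# Network views

Partial correlations are computed from the inverse of the correlation
matrix after linear shrinkage toward the identity
($C^* = (1-s)C + sI$, default $s = 0.1$); gene panels routinely exceed
the sample count, so the raw matrix can be singular. With $s = 0$ on a
well-conditioned matrix the values agree with the textbook first-order
partial-correlation formula, and on a Gaussian chain $X \to Y \to Z$ the
$X$–$Z$ partial vanishes while the marginal does not (both are tested
against closed forms). Cross-dataset "combined" matrices are weighted
averages of per-dataset correlation matrices over shared genes, weighted
by donor counts — combination happens at the correlation level because
merging intensities across platforms is not meaningful.

# The benchmarking harness

Leave-one-out cross-validation: each known gene in turn becomes the
"defector", removed from the disease set and hidden among 99 random
decoys drawn from genes not in the known set (drawn once per trial so
the trial is coherent across datasets; "not known to be associated"
means not in the supplied set — no external database is consulted). At
each consensus level $k$, defectors supported by $\ge k$ datasets are
true positives and supported decoys are false positives, giving
sensitivity, specificity, precision and negative predictive value as
functions of $k$; undefined ratios (zero denominators) are reported as
`NA`, and across-set averages are unweighted.

# The synthetic-data generator

The generator emulates exactly the structures the method exploits, with
Gaussian components throughout (the simplest model exhibiting every
structure of interest):

* **modules**: latent factors with per-gene loadings $\lambda$,
  optionally active only in chosen periods; with equal loadings and no
  other shared variance the implied intra-module correlation is
  $\lambda^2/(\lambda^2 + \sigma_d^2 + \sigma^2)$;
* **donors**: mixed donor sizes (1–4 samples by default); all samples of
  a donor share its age (hence period) and a per-donor, per-gene random
  effect with variance $\sigma_d^2 = 0.1\sigma^2$ by default — samples
  within a donor correlate across genes, while gene–gene correlations
  are untouched because the effect is independent across genes;
* **unwanted factors**: per-gene loadings drawn once and shared across
  datasets (technical artefacts such as probe or sequence effects hit
  the same genes on every platform), with fresh factor scores per
  dataset. This sharing is what makes unwanted variation costly at the
  consensus stage — the same decoys are inflated in every dataset — and
  is the regime in which RUV's specificity advantage is measured;
* **housekeeping controls**: a trailing fraction of genes (10% by
  default) barred from modules but exposed to unwanted variation and
  noise, i.e. valid negative controls by construction.

Ground truth (module membership, loadings, unwanted loadings, and the
implied correlation matrix over module genes) accompanies every draw,
and generation is byte-identical under a fixed seed.

What the generator does *not* emulate: platform-specific intensity
distributions, probe-level noise, annotation discrepancies between
platforms, and non-Gaussian expression heterogeneity. Passing tests on
synthetic data therefore demonstrate the statistical machinery —
calibration, weighting, consensus, cleaning — not robustness to every
artefact of real arrays.

# Numerical choices and degenerate inputs

* Correlations require ≥ 3 samples (hard floor; a warning below 10);
  zero-variance genes get correlation 0 plus a degeneracy flag rather
  than being dropped, keeping matrix shapes stable for ranking.
* Quantile-normalisation ties within a column receive the mean of the
  tied ranks' normalised values.
* Duplicate gene symbols collapse to the highest-variance row
  (most-informative-probe rule); symbols are matched case-insensitively
  after whitespace stripping; rows with missing values are dropped with
  a warning.
* Candidates absent from a dataset are untestable there, not failures;
  datasets failing preconditions are skipped with a warning and leave
  the consensus denominators.
* A single user-visible seed drives everything; per-dataset and
  per-trial streams are derived from it by fixed offsets, so any run is
  reproducible from its manifest.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to make the statistical contracts measurable on a single CPU in a
few minutes: calibration on 50 replicates of 1000 genes × 120 samples
with $B = 1000$; module recovery and the RUV-versus-quantile comparison
over 20 seeds of three datasets (1000 and 600 genes, 100 and 80
samples); oracle agreement on 1000 random vector pairs; closed-form
checks at $n = 2000$. These sizes are the package's definition of its
reference experiments and are stated here so they can be scaled up
deliberately rather than accidentally.

# Known limitations

* Guilt by association fails by design for non-convergent gene sets; a
  defector whose pathway is not co-expressed cannot be re-discovered.
* No p-values or FDR are attached to prioritised candidates; the
  proportion threshold controls an *average* random-gene rate, which is
  an overestimate of false positives when random genes are not truly
  independent of the disease genes.
* The RUV variant here is a deliberately simple regularised projection;
  when unwanted and biological variation are strongly correlated, some
  signal loss is unavoidable and the ridge only mitigates it.
* Brain-region stratification and probe-to-gene annotation are out of
  scope; inputs are assumed to be gene-level matrices.
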