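---
title: "Propagating technical replicate variance in omics differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating technical replicate variance in omics differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repvar)
```

## Why keep the technical variance?

Mass-spectrometry proteomics and metabolomics experiments commonly acquire
several technical replicates per biological sample — typically three — to
buffer instrument noise. Standard practice collapses them to a mean (or
median, or trimmed mean) and carries only that point estimate forward, so the
information about *how uncertain* each sample's measurement was is discarded.
Yet the replicate spread often differs strongly between samples: one
biological sample may be measured cleanly, another on a bad run. Treating both
as equally reliable degrades both differential-abundance ranking and
exploratory projections.

`repvar` keeps the discarded variance. Each biological sample contributes a
pair: the summarized log intensity $y_{ij}$ and its technical variance
$\nu_{ij}$ (condition $i$, sample $j$). Three downstream methods consume
these pairs:

* the **PPLR** (probability of positive log ratio) differential-abundance
  score, built on a hierarchical Gaussian measurement-error model;
* a heteroscedastic-noise **probabilistic PCA** whose EM estimation
  down-weights noisy samples;
* a conventional **empirical-Bayes moderated t** comparator on the
  mean-summarized data, so the variance-aware ranking can always be compared
  against the field-standard analysis of the same contrast.

## The measurement-error model and the PPLR score

Per molecule, the summarized signal of biological sample $j$ under condition
$i$ is modeled as

$$y_{ij} \sim N(\mu_i,\; \lambda + \nu_{ij}),$$

with $\mu_i$ the condition mean, $\lambda$ the biological between-sample
variance shared across conditions, and $\nu_{ij}$ the known technical
variance of that sample's point estimate. With a flat prior on each $\mu_i$,
integrating the means out gives a closed-form marginal likelihood in
$\lambda$ alone; for weights $w_{ij} = 1/(\lambda + \nu_{ij})$ the posterior
of $\mu_i$ is Gaussian with

$$m_i = \frac{\sum_j w_{ij} y_{ij}}{\sum_j w_{ij}}, \qquad
  v_i = \frac{1}{\sum_j w_{ij}}.$$

`fit_molecule_model()` maximizes this profile marginal likelihood over
$\lambda$. The surface can be *bimodal* at realistic sample sizes (a boundary
mode near $\lambda = 0$ competing with an interior mode), so the
implementation first brackets the global mode with a 64-point scan on
$\log(\lambda + \epsilon)$ and then refines by Brent search inside the
bracket; a small floor $\epsilon = 10^{-12}$ guards divisions when both
$\lambda$ and $\nu$ vanish. The default search interval is
$[0,\, 10 \times \max_i \operatorname{var}(y_{i\cdot})]$.

The differential score between conditions $a$ and $b$ is

$$\mathrm{PPLR} = \Phi\!\left(\frac{m_a - m_b}{\sqrt{v_a + v_b}}\right),$$

the posterior probability that condition $a$'s mean exceeds $b$'s. Ranking
uses $\max(\mathrm{PPLR}, 1-\mathrm{PPLR}) - 0.5 \in [0, 0.5]$ so both
directions of regulation rank high. The score is computed through
$\Phi(|z|)$ so that the two orientations of a contrast sum to 1 exactly in
floating point. No p-value is attached to the PPLR — it is a posterior
probability, not a tail probability — so FDR control is reported only for the
moderated-t track.

A deliberate scope decision: $\lambda$ is estimated per molecule, with no
sharing of variance hyperparameters across molecules. The original PPLR
literature stabilizes small-sample fits by exactly such sharing; without it,
fits with 3–4 biological samples per group lean harder on the observed
$\nu_{ij}$, which is worth remembering when interpreting rankings from
minimal designs.

## Summarization and the $\nu$ fallback

`summarize_technical()` supports mean, median, and trimmed mean (default trim
0.1 per tail) as location estimates. In all cases $\nu_{ij} = s^2/n$, the
variance *of the point estimate*, taken from the untrimmed unbiased sample
variance — simple and mildly conservative for the robust locations. The
whisker-plot display intentionally shows the raw replicate SD (not
$s/\sqrt{n}$), because the plot depicts replicate spread, not the standard
error.

Samples with one technical replicate carry no variance information. Their
$\nu$ is imputed as the median of the molecule's observed $\nu$ values, else
the global median, else — when the entire dataset has single technical
replicates — zero, with a warning. The last case makes the model collapse to
$y_{ij} \sim N(\mu_i, \lambda)$, the correct no-information limit: all noise
is absorbed into the biological variance term.

## Noise-aware PCA

The PCA track models the summarized data as a linear-Gaussian factor model
with sample-specific diagonal noise:

$$x_n = W z_n + c + \varepsilon_n, \qquad
  z_n \sim N(0, I_k), \qquad
  \varepsilon_n \sim N(0, \sigma^2 I + \mathrm{diag}(\nu_n)),$$

where $\nu_n$ is sample $n$'s vector of technical variances. The E-step
computes each sample's score posterior under its own noise covariance; the
M-step solves a weighted least-squares problem per molecule row of $W$
(rows decouple because the noise is diagonal, weights
$1/(\sigma^2 + \nu_{gn})$). Because $\sigma^2$ sits inside those weights, no
closed-form $\sigma^2$ update exists; the implementation instead maximizes
the expected complete-data log-likelihood over $\sigma^2$ by a bounded 1-D
search. Both half-steps increase the EM surrogate, so this is a generalized
EM and the marginal log-likelihood is non-decreasing — the fitter asserts
this per iteration and the test suite re-checks it on every fitted instance.
The center $c$ is fixed at the per-molecule mean rather than re-estimated;
with a flat noise field the two coincide, and fixing it keeps the M-step
exact.

With $\nu \equiv 0$ the model is standard probabilistic PCA, and the fitted
subspace coincides with the top-$k$ SVD subspace (verified to principal
angles below $10^{-4}$ rad); with $\nu$ constant it equals plain PPCA with an
inflated residual. Under genuinely heteroscedastic noise the model
down-weights the noisy samples, and on simulations with a few high-noise
samples it recovers the true subspace substantially better than plain SVD
(median principal angle roughly half that of plain PCA in the bundled
simulations, 200 molecules × 12 samples with 3 samples at 20× noise).
Components are reported ordered by explained variance with the sign of each
fixed so its largest-magnitude loading is positive; defaults are $k = 3$,
tolerance $10^{-8}$ on the relative log-likelihood change, at most 1000
iterations.

## The moderated-t comparator

The comparator track is the classical empirical-Bayes moderated t on
mean-summarized values (always mean-summarized, regardless of the
summarization chosen for the PPLR track, so the comparison is the standard
analysis a practitioner would run). Per molecule the pooled two-sample
variance $s_g^2$ with $d_g = n_a + n_b - 2$ degrees of freedom is shrunk
toward a prior:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and $\tilde t_g = (\bar y_a - \bar y_b)/(\tilde s_g \sqrt{1/n_a + 1/n_b})$
is referred to a t distribution on $d_0 + d_g$ degrees of freedom. The prior
$(d_0, s_0^2)$ is estimated by moment matching on $\log s_g^2$ with
digamma/trigamma corrections, inverting the trigamma equation by Newton
iteration; when the observed spread of log variances does not exceed its
sampling expectation the prior degenerates to $d_0 = \infty$ (full
shrinkage). This construction is cross-checked in the test suite against the
independent `limma` implementation of the same estimator, and the tiny
worked example ($s^2 = 0.5$, $d_g = 2$, $d_0 = 2$, $s_0^2 = 1$ giving
$\tilde s^2 = 0.75$, $\tilde t = -3.4641$) is asserted to six decimals.
Benjamini–Hochberg adjustment is applied to the moderated p-values.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` draws baseline condition means from $N(8, 1)$ — a
typical log2 intensity scale — between-sample variances $\lambda$ and
technical variances $\nu$ from log-normals parameterized by their natural
mean and spread (defaults: mean 0.3, spread 0.15 for both, a moderate-noise
regime for replicated MS experiments), per-sample signals from
$N(\mu_i, \lambda)$, and a `frac_de` subset (default 10%) whose
second-condition mean is shifted by $\pm\delta$.

One convention matters for interpreting every benchmark built on this
generator: technical replicate runs are drawn with variance
$\nu \cdot n_{tech}$, so that the variance of their mean is exactly $\nu$
for any replicate count. This keeps the generative truth aligned with the
summarizer's definition of $\nu$ and makes parameter-recovery tests exact in
expectation. The flip side is that the *precision of the summarized data
does not improve with* $n_{tech}$ by construction — additional replicates
improve only the estimate of $\nu$, not the point estimates themselves. On
such data, ranking accuracy is nearly flat in the replicate count, and with
very few replicates the 2-df variance estimates are noisy enough that
treating them as known can cost a little accuracy relative to the
no-information limit. Real experiments, where replicate averaging does
improve precision, can be emulated by scaling `nu_dist` down as $1/n_{tech}$
manually. The generator also draws no missing values and no batch structure;
conclusions from these simulations transfer to real data only to the extent
that log-scale Gaussianity and independent technical noise hold.

`benchmark_ranking()` computes the ROC AUC of any score column against the
ground-truth differential flags via the Mann–Whitney formulation with
averaged ties.

## Normalization choices

Median scaling shifts each run additively so all runs share the median of the
original per-run medians — symmetric across runs and idempotent. The
variance-stabilizing option applies a generalized log,
$g(x) = \log_2\big((x + \sqrt{x^2 + c^2})/2\big)$, to linear-scale
intensities, with a single global constant $c$; `c = "auto"` picks $c$ from
a fixed grid of quantiles of the positive intensities by minimizing the
absolute Spearman correlation between per-molecule mean and SD. This is a
deliberately simple transform: it meets the goal of removing the mean–variance
dependence without the per-run affine calibration of full VSN, which would
drag in an entire robust-ML machinery that is not this package's subject.

## Clustering and report

The heat map of the top-ranked molecules (default 25) uses average-linkage
(UPGMA) clustering implemented directly, with a deterministic tie-break on
cluster indices so that re-runs are byte-identical; euclidean distance on
row-standardized values is the default, correlation distance an option. The
test suite verifies the merge sequence against a brute-force re-scan oracle
and the heights against `stats::hclust`. Rows with zero variance are flagged
and displayed as zeros rather than NaN. The report directory contains the
ranking TSV, PCA score TSVs, whisker-plot and heat-map PNGs, and a static
`index.html`.

## Problem sizes and determinism

The bundled tests and the acceptance script run entirely on synthetic data
generated in code: Monte-Carlo checks use $10^6$ posterior draws, parameter
recovery uses 2 × 50 samples, ranking benchmarks use 150 molecules × 20
seeds per replicate-count setting, PCA comparisons 200 molecules × 12
samples × 50 seeds, and the end-to-end determinism check 2000 molecules in a
2-condition, 4-biological-sample, 3-technical-replicate design — sizes at
which every result above reproduces in a few minutes on a single core. All
randomness flows from explicit integer seeds; two runs of the pipeline with
the same seed produce byte-identical tables.

## Worked example

```{r example, eval = FALSE}
sim <- generate_dataset(p = 500, n_bio = 4, n_tech = 3,
                        frac_de = 0.1, delta = 1, seed = 42)
dir <- tempfile(); write_synthetic(sim, dir)

cfg <- run_config(file.path(dir, "matrix.tsv"), file.path(dir, "design.tsv"),
                  out_dir = file.path(dir, "report"), seed = 42)
res <- run_pipeline(cfg)
head(res$ranking)
benchmark_ranking(sim$truth, res$ranking)
```

## Known limitations

* Pairwise contrasts only; multi-group designs are analyzed one pair at a
  time.
* No missing-data EM in the PCA track: molecules with incomplete summaries
  are dropped from the projection (with a warning), though they remain in the
  differential ranking.
* $\lambda$ is per molecule with no cross-molecule shrinkage; rankings from
  designs with fewer than three biological samples per group should be read
  with care.
* The generalized-log transform uses one global $c$, not per-run affine
  calibration.
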