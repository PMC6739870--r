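---
title: "A multiplicative model of taxonomic bias in MGS measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiplicative model of taxonomic bias in MGS measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgsbias)
```

## The model

Marker-gene and shotgun metagenomic sequencing (MGS) measure *relative*
taxon abundances, and every step of the workflow — cell lysis and DNA
extraction, PCR amplification, sequencing, bioinformatic classification —
recovers some taxa more efficiently than others. `mgsbias` models this bias
as a composition-independent multiplication: if `A` is the vector of actual
relative abundances in a sample and `B` the protocol's vector of relative
efficiencies, the observed relative abundances are

    O ~ A * B            (element-wise; "~" = equal up to a positive factor)

with per-step efficiencies composing by element-wise multiplication,
`B = B1 * B2 * ... * BL`.  Only ratios carry meaning, so `B` has K − 1 free
parameters for K taxa; we report it standardized to geometric mean 1
("relative to the average taxon", `gstandardize()`).

Three consequences drive everything in the package:

* **Ratios are consistently wrong.** The fold-error in the ratio of taxa i
  and j is `B_i/B_j` in every sample, so fold-*changes* in taxon ratios
  between samples are invariant to bias (`ratio_foldchange()`).
* **Proportions are inconsistently wrong.** The fold-error in taxon i's
  proportion is `B_i` divided by the sample mean efficiency
  `sum_j Pr(A)_j B_j` (`sample_mean_efficiency()`), which depends on the
  whole composition — the same taxon can be over-estimated in one sample and
  under-estimated in another, and proportion-based statistics (evenness,
  diversity, proportion fold-changes) can reverse sign under bias.
* **Bias divides out.** Given an estimate of `B`, calibration is
  compositional division, `A_hat ~ O / B_hat`, followed by closure
  (`calibrate()`).  Two protocols measuring the same sample differ by their
  *differential bias* `B(P)/B(R)`, which is estimable without knowing the
  truth and calibrates measurements onto a reference protocol
  (`estimate_differential_bias()`, `calibrate_to_reference()`).

## Estimation

For control samples `s` with known composition, we model
`O(s) ~ A(s) * B * eps(s)` where the noise `eps(s)` is a random composition
centered (in the geometric / Aitchison sense) on the identity.  The estimate
minimizes the summed squared Aitchison norm of the residual compositions
`O(s) / (A(s) * B)`, each norm restricted to the taxa present in sample `s`.
In clr (centered log-ratio) coordinates this is a linear least-squares
problem in the log-efficiencies with a per-sample centering projection.  We
solve it exactly by (rank-deficient) normal equations with the Moore-Penrose
pseudo-inverse, fixing the undetermined overall factor by the sum-to-zero
(geometric mean 1) convention.  This formulation:

* reduces to the element-wise geometric mean of `O(s)/A(s)` whenever every
  control contains every covered taxon — the closed-form complete-design
  estimator;
* combines controls with only *partial* taxon overlap, identifiable exactly
  when the taxon co-occurrence graph is connected
  (`check_identifiability()` reports the components; disconnected designs
  are an error, since only within-component ratios are estimable);
* is equivariant: rescaling any sample or perturbing all observations by a
  fixed composition shifts the estimate the way the model says it must.

**Zero handling.**  "Undefined" (`NA`) means a taxon is not part of the
sample's design; 0 means designed-in but not detected.  Reads assigned to
out-of-design taxa (cross-contamination) are dropped with a warning;
designed-in zeros receive a pseudocount (default 0.5, on the observed-count
scale) so logs exist.  Samples with fewer than two defined taxa carry no
ratio information and are dropped with a warning.

**Uncertainty.**  `bootstrap_bias()` re-solves the weighted problem under
random per-sample weights — Dirichlet with unit concentration (default), or
multinomial with `n_trials` draws, which mimics the precision of `n_trials`
control samples and is how precision-versus-number-of-controls curves are
made.  Per-taxon geometric standard errors are
`exp(sd of log replicate efficiencies)` with each replicate standardized to
geometric mean 1; they are 1 exactly when the fit is exact.  Multinomial
draws can zero out enough samples to disconnect the overlap graph; such
replicates are redrawn with a warning up to a retry cap.  This retry policy
is a package choice and is documented rather than derived.

## Step decomposition and copy-number bias

When the same workflow is entered at different points (cell mixtures, DNA
mixtures, PCR-product mixtures) the entry-point biases are cumulative over
nested step sets, so each step's bias is the compositional quotient of
adjacent entry points (`decompose_steps()`), and the final entry point's
bias is the last step itself.  We compute the PCR step as
`B(DNA)/B(PCR product)` — the form consistent with the cumulative chain
`B(DNA) = B(PCR) * B(seq)` — since the quotient orientation is easy to get
backwards; `compose_steps()` verifies a decomposition by reassembly.

16S copy-number (CN) predicted bias (`cn_bias()`) depends on the entry
point: copies per genome for cell mixtures, copies per bp (CN / genome
size) for DNA mixtures, and the identity for PCR-product mixtures.
`cn_correct()` divides it out.  How much of an estimated bias CN explains is
measured by a slope-free fraction of variance on the log efficiency scale,

    VE = 1 − ||target / predictor||² / ||target||²   (Aitchison norms),

which uses the prediction as-is, with no fitted coefficient — appropriate
because the CN hypothesis predicts the efficiencies themselves, not merely a
direction.  An OLS-on-clr R² is available via `method = "ols"` for
comparison.  `permutation_pvalue()` permutes the predictor's taxon
assignment, exhaustively for up to 8 taxa (8! = 40,320 evaluations run in
seconds), and counts the identity permutation in the one-sided p-value, so
p is deterministic and bounded below by 1/K!.

## Summary statistics

`max_pairwise_bias()` is the geometric range `max(B)/min(B)` — the worst
fold-error in any taxon ratio.  `avg_pairwise_bias()` averages
`|log(B_i/B_j)|` over pairs before exponentiating.  The matching noise
statistic `avg_pairwise_noise()` applies the same mean-absolute form to the
fitted residual compositions, pooled over samples; the published tables this
mirrors do not state their noise formula explicitly, so the mean-absolute
convention (chosen to mirror the bias statistic) is the default and an RMS
variant sits behind `method = "rms"`.

## The simulator and what it does (not) show

`simulate_experiment()` draws `O(s) ~ A(s) * B * eps(s)` with `eps(s)` a
centered log-normal (clr-normal) composition — the natural noise model given
that the residual geometry is Aitchison — optionally followed by multinomial
read sampling at a fixed depth.  Two design generators mirror the two
classic control designs:

* `make_even_subset_design()`: even mixtures over taxon subsets (the
  mock-community design with 2-7 taxa per sample);
* `make_spikein_design()`: a fixed known mock subcomposition (default
  log-uniform over 2.5 orders of magnitude) mixed into variable, unknown
  backgrounds at a random spike fraction (default 5-50% of the sample) —
  only the mock taxa's actual values are disclosed to the estimator, so
  estimation uses the spike-in subcomposition alone.  Background abundances
  default to log-normal with sd 2 log units, the order-of-magnitude
  variation typical of natural communities.

Defaults were fixed once from the designs being emulated, before any test
outcomes, and the validation suite uses them as stated study conditions:
clr noise sd 0.3 with 20 complete 7-taxon controls for parameter recovery,
sd 0.2 with a 20-fold efficiency range and 30 even-subset samples for the
calibration mean-squared-error experiment, 500 samples for
law-of-large-numbers checks, 1000 bootstrap replicates.  These sizes keep the
whole suite under a minute while leaving Monte-Carlo margins comfortably
wide.

The simulator reproduces exactly the structure the model assumes:
multiplicative, composition-independent bias and exchangeable log-scale
noise.  Passing tests therefore validate the *estimators*, not the model's
adequacy for any particular real workflow.  Real data can violate the
assumptions in ways the simulator does not emulate: PCR saturation and other
abundance-dependent efficiencies, bias that differs between sample matrices
(e.g. lab-grown control cells vs preserved specimens), contamination and
index switching, and aggregation — a genus or phylum whose member species
differ in efficiency is *not* biased multiplicatively even when each species
is, so estimates apply only at the taxonomic resolution of the input tables.

## Numerical choices and degenerate inputs

* Compositional equality (`comp_equal()`) compares closed proportions with
  absolute tolerance 1e-9; efficiencies are stored gstandardized.
* The two equivalent Aitchison-norm formulas (pairwise log-ratio and clr
  forms) agree to ~1e-10 relative in tests; the clr form is implemented.
* Alignment is by taxon label when names are present (mismatch is an error);
  a bare vector against a named one of equal length aligns positionally.
* All-zero or empty compositions, division by zero entries, missing
  efficiencies for present taxa, non-nested or taxon-mismatched step
  designs, and fewer than 3 shared taxa for variance-explained are errors.
* Every stochastic function takes an explicit `seed`; the command-line
  interface refuses stochastic subcommands without `--seed`.

## Worked example

The package's running example is a hypothetical three-taxon community
measured with bias `(1, 18, 6)`:

```{r}
obs <- predict_observed(even_comp(3), c(1, 18, 6))
obs                      # (4%, 72%, 24%) from an even mixture
fit <- estimate_bias(obs, even_comp(3))
coef(fit) / coef(fit)[1] # recovers (1, 18, 6)
calibrate(obs, coef(fit))
```

A second sample with actual composition `(0.75, 0.05, 0.20)` shows why
proportions mislead: taxon 3's actual proportion is lower than in the even
sample, but its observed proportion is higher, while the taxon 2 : taxon 1
ratio changes by the same factor 1/15 in actual and observed data:

```{r}
s2 <- c(0.75, 0.05, 0.20)
predict_observed(s2, c(1, 18, 6))
ratio_foldchange(predict_observed(s2, c(1, 18, 6)), obs, 2, 1)
```

## Limitations

Estimation is possible only for taxa present in controls, so targets are
calibrated as a subcomposition over covered taxa; no efficiencies are
imputed for uncovered taxa (phylogenetic prediction of efficiencies is out
of scope).  The estimator is a point-estimation procedure with bootstrap
uncertainty, not a full count-level statistical model — it does not
propagate read-depth uncertainty into calibrated proportions.  Saturation
and other abundance-dependent efficiencies are outside the model.
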