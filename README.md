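# mgsbias

Taxonomic bias in marker-gene and shotgun metagenomic sequencing (MGS):
estimation from control samples, calibration, decomposition, and simulation.

## The problem

Every MGS protocol measures some taxa more efficiently than others — lysis,
DNA extraction, PCR, sequencing, and classification each favor particular
cell walls, genome sizes, primer matches, or reference entries.  The result
is that measured relative abundances are systematically wrong, in a way that
differs between protocols, so measurements are neither accurate nor
comparable across studies.  `mgsbias` is for microbiome researchers who run
mock-community or spike-in controls and want to quantify and remove this
bias, and for method developers comparing protocols.

## The model

Bias is modeled as a composition-independent multiplication.  For actual
relative abundances **A** and protocol bias **B** (the vector of relative
efficiencies, one per taxon, defined only up to a constant factor):

    O ~ A · B                          (element-wise product)
    B = B⁽¹⁾ · B⁽²⁾ · … · B⁽ᴸ⁾          (bias multiplies across steps)
    Â ~ O / B̂                          (calibration)
    O⁽ᴾ⁾ / O⁽ᴿ⁾ ~ B⁽ᴾ⁾ / B⁽ᴿ⁾            (differential bias between protocols)

Given controls `s` of known composition, the estimate **B̂** minimizes
`Σ_s ‖O(s)/(A(s)·B)‖²` in the Aitchison norm, restricted per sample to the
taxa it contains; with complete controls this is the element-wise geometric
mean of `O(s)/A(s)`.  Uncertainty comes from a Dirichlet- or
multinomial-weighted bootstrap (geometric standard errors).

## Worked example

A hypothetical even mixture of three taxa measured with bias `(1, 18, 6)`:

```r
library(mgsbias)

obs <- predict_observed(even_comp(3), c(1, 18, 6))
obs
#> taxon1 taxon2 taxon3
#>   0.04   0.72   0.24

fit <- estimate_bias(obs, even_comp(3))
coef(fit) / coef(fit)[1]     # efficiencies relative to taxon 1
#> taxon1 taxon2 taxon3
#>      1     18      6

calibrate(obs, fit)          # remove the bias again
#> taxon1    taxon2    taxon3
#> 0.3333333 0.3333333 0.3333333

max_pairwise_bias(fit)       # worst fold-error in any taxon ratio
#> [1] 18
```

The even mixture is measured as 4% / 72% / 24%: taxon 2 is 18× easier to
measure than taxon 1 and ends up at 72% instead of 33%.  Estimating bias
from that one control recovers the efficiencies exactly, and calibration
(compositional division by the estimate, then re-closure) returns the even
composition.

Multi-sample tables (samples × taxa, `NA` for taxa absent from a sample's
design) work the same way; `bootstrap_bias()` adds geometric standard
errors, `summary()` prints the efficiency table with the pairwise bias and
noise statistics, and `estimate_differential_bias()` /
`calibrate_to_reference()` do the same against a reference protocol instead
of the truth.  `decompose_steps()` splits total bias into per-step biases
from cell / DNA / PCR-product entry-point experiments, and `cn_bias()` /
`cn_correct()` handle 16S copy-number prediction and correction.
`make_even_subset_design()`, `make_spikein_design()` and
`simulate_experiment()` generate synthetic control experiments with known
bias for validation.  A thin CLI over these functions is installed at
`inst/cli/mgsbias.R` (subcommands `estimate`, `calibrate`, `decompose`,
`cn-correct`, `summarize`, `simulate`).

Printed reference tables for a seven-taxon vaginal mock-community experiment
(cell/DNA/PCR-product mixtures, with genome sizes and 16S copy numbers) and
a ten-taxon fecal spike-in experiment across three extraction protocols ship
in `inst/extdata/` and are used throughout the tests and examples.

See the vignette (`vignettes/bias-model.Rmd`) for the model's assumptions,
the estimator, zero handling, and what the simulator does and does not
validate.

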