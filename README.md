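# bcpseg

Bayesian changepoint segmentation of binned copy-number profiles from
low-pass (liquid biopsy) whole-genome sequencing.

## The problem

Copy-number alterations (CNAs) — somatic gains and losses of large
genomic regions — can be read from cheap low-pass sequencing: read
counts per fixed-width genomic bin approximate relative copy number. In
cell-free DNA from blood, however, tumor-derived fragments are only a
small fraction *P* (the purity, often < 10%) of the total, so a tumor
segment with copy number *C* appears at the diluted level
*P·C + (1 − P)·2*. Steps between segments shrink toward zero while
sequencing noise does not, and standard segmentation tools lose
sensitivity exactly where liquid-biopsy monitoring needs it most.

`bcpseg` is built for that regime. It treats segmentation as Bayesian
changepoint detection under the Barry–Hartigan product-partition model:
bins within a segment are Gaussian with a shared mean, segment means are
shrunk toward the genome-wide mean with a strength that adapts to
segment length, and the only two hyperparameters are the prior bounds
`p0` (per-boundary changepoint probability, uniform on `[0, p0]`) and
`w0` (noise-to-signal ratio `σ²/(σ² + σ₀²)`, uniform on `[0, w0]`). A
Gibbs sampler yields per-bin posterior changepoint probabilities

        p*_i = (1/M) Σ_m 1{ U_i^(m) = 1 },

which are then filtered at a noise floor `ε`, peak-called, turned into
segments valued at their medians, and cleaned by merging adjacent
segments whose medians differ by less than `η` noise standard
deviations. The result is a segmented floating-point copy-number
profile (plus posterior mean and 95% credible band) ready for
downstream absolute-copy-number or tumor-fraction estimation.

An exact enumeration oracle (`exact_posterior()`) validates the sampler
on small inputs, a synthetic-profile generator reproduces the
purity-dilution / multiplicative-noise evaluation design, and metric
functions implement tolerance-window precision/recall/F1 and normalized
mutual information between segmentations.

## Worked example

```r
library(bcpseg)

# a 1000-bin profile: tumor purity 30%, realistic noise
sim <- simulate_cn_profile(purity = 0.3, noise_level = 1, seed = 11)
fit <- bcpseg(sim$observed, seed = 42)
fit
#> Bayesian changepoint segmentation
#>   1000 bins, 14 segments (13 changepoints)
#>   noise scale (MAD): 0.1049
#>   p0 = 0.01, w0 = 0.2, sweeps = 500 + 2000, epsilon = 0.05, eta = 0.5

m <- match_changepoints(sim$changepoints, fit$changepoints)
changepoint_metrics(m)
#> $precision
#> [1] 0.8461538
#>
#> $recall
#> [1] 1
#>
#> $f1
#> [1] 0.9166667
```

The print method summarizes the fit: the sampler ran 500 burn-in plus
2000 retained sweeps with the default priors, and the robust noise-scale
estimate of the residuals is ≈ 0.10 (the generator's truth at this
setting). All eleven true state changes are recovered within the ±2-bin
matching window (recall 1), while two of the thirteen calls are
spurious boundaries a few bins from a real one (precision 0.85, F1
0.92) — the characteristic failure mode at moderate purity is
over-segmentation next to genuine changepoints, not missed segments.
`summary(fit)` lists the segment table, `plot(fit)` draws the
three-panel diagnostic (data with posterior mean and credible band,
probability track with the `ε` line, reconstructed profile), and
`fitted()`/`residuals()`/`coef()` behave as for any fitted model.

Genomic input goes through `read_bins()` (bedGraph or headered TSV, NA
bins masked, chromosomes segmented independently) and results back out
through `write_segments()` (SEG table plus a probability bedGraph).

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "bcpseg.R", package = "bcpseg"))') \
    segment --input bins.tsv --output-prefix sample1 --seed 7
```

with further subcommands `simulate`, `benchmark` and `plot`.

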