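# kincrac

Quantitative analysis of **kinetic CRAC** (time-resolved UV cross-linking /
CLIP) experiments, in which protein–RNA interactions are sampled at minute
resolution after a stress shift, alongside a control shift, with biological
replicates. The package is for analysts of such time courses who need to go
from aligned reads and per-timepoint FPKM tables to:

- a per-transcript **Gaussian-process Bayes-factor test** for differential
  binding dynamics between a control and a treated series,
- **escape-index** screening for transcriptionally attenuated genes,
- binding-site (**peak**) calling with permutation FDRs and detection of
  non-encoded **oligo(A) tails**,
- temporal-profile **filtering and K-means clustering**, TSS-aligned
  matrices and length-normalized **meta-profiles**,
- plus the read-level plumbing (barcode demultiplexing, UMI duplicate
  collapsing, multimapper placement, strand-aware pileups, FPKM) and a
  seeded **synthetic-data generator** that makes every stage testable
  offline.

Everything is tidyverse-shaped: long tibbles in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` / `plot_*()` for figures.

## The statistical core

For each transcript, let `f_j(t)` be the latent binding response in
condition `j` (control or treated) relative to `t = 0`, modeled with a
zero-mean Gaussian-process prior under a squared-exponential covariance

    cov(f_j(s), f_j(t)) = a² · exp(−(s − t)² / (2λ²)),

with observations `y_j(t) = f_j(t) + ε`, `ε ~ N(0, σ²)`. The latent
function marginalizes exactly, giving the evidence
`p(y(0), …, y(T) | a, λ, σ)` in closed form. The test compares

- **H0** — one shared latent explains control and treated series, vs.
- **H1** — each condition has its own latent,

via the Bayes factor, flagging transcripts with `BF ≥ 10`. Hyperparameters
are set per transcript by empirical-Bayes rules (`a²` = 50% of the variance
of all of the transcript's values, `λ` = 1 min globally, `σ²` = variance of
the control-condition values) and shared by both hypotheses. See
`vignettes/kincrac-methods.Rmd` for the full account, including
normalization, escape indices, peak/oligo(A) calling and the simulators.

## Worked example

Simulate a small two-condition time course with condition-specific
dynamics, normalize it, and test every transcript:

```r
library(kincrac)

sim <- simulate_timecourse(sim_spec(n_transcripts = 6, hypothesis = "H1",
                                    seed = 42))
ntc <- relative_to_baseline(sim$timecourse)
res <- test_all(ntc)
res
#> # A tibble: 6 × 8
#>   gene_id   logml_h0 logml_h1 log_bf       bf flagged alpha_sq noise_sq
#>   <chr>        <dbl>    <dbl>  <dbl>    <dbl> <lgl>      <dbl>    <dbl>
#> 1 gene_0001    -59.2   -14.8    44.4 1.93e 19 TRUE      0.0851  0.0268
#> 2 gene_0002    -50.7   -31.4    19.3 2.42e  8 TRUE      0.151   0.0684
#> 3 gene_0003   -142.    -14.6   127.  1.77e 55 TRUE      0.132   0.0194
#> 4 gene_0004    -44.8    -8.90   35.9 3.95e 15 TRUE      0.0752  0.0317
#> 5 gene_0005    -84.4   -15.5    68.8 7.73e 29 TRUE      0.168   0.0486
#> 6 gene_0006   -479.    -20.2   458.  1.21e199 TRUE      0.189   0.00898
```

`logml_h0`/`logml_h1` are the log evidences (nats) of the shared-dynamics
and condition-specific models; `log_bf = logml_h1 − logml_h0`; all six
simulated transcripts carry a two-fold treated-specific shift, and all six
exceed the `BF ≥ 10` bar (`flagged`). The fitted empirical-Bayes signal and
noise variances are reported per transcript.

Peak calling on a pileup, with a seeded permutation FDR:

```r
cov <- numeric(2000); cov[501:570] <- 9
call_peaks(new_pileup(cov), read_lengths = rep(40, 60), seed = 1)
#> # A tibble: 1 × 9
#>   gene_id chrom strand start   end width max_height total_reads   fdr
#>   <chr>   <chr> <chr>  <dbl> <dbl> <int>      <dbl>       <dbl> <dbl>
#> 1 <NA>    <NA>  +        500   570    70          9         630  0.16
```

One maximal interval satisfies the ≥ 5-read / ≥ 20-nt constraints; under
100 uniform re-placements of the same 60 reads, spurious peaks arise in 16%
of permutations, which is the reported empirical FDR.

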