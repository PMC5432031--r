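---
title: "Models and methods behind kincrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kincrac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kincrac)
library(dplyr)
```

kincrac analyzes kinetic UV cross-linking (kinetic CRAC / time-resolved
CLIP) experiments: an RNA-binding protein is cross-linked to its RNA
targets at minute resolution after a shift to stress medium, alongside a
control shift back into the original medium, with two biological
replicates per condition. The package takes the experiment from read-level
processing through per-transcript FPKM time courses to the statistical
question at its core: *for which transcripts does binding follow different
dynamics in the treated series than in the control series?* This vignette
explains the models, the tunable parameters, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## The time-course model and its normalization

All quantitative analyses operate on a long table of FPKM values indexed by
(transcript, condition, replicate, timepoint) sharing one timepoint grid,
by default $\{0, 1, 2, 4, 8, 14, 20\}$ minutes with $t = 0$ sampled before
the shift. Transcripts not detected in every sample are removed first
(`filter_detected_all_timepoints()`): a zero FPKM is indistinguishable from
a dropout and would otherwise propagate non-finite ratios.

Normalization is two-step:

1. `scale_timepoints()` multiplies every (condition, replicate, timepoint)
   column by a constant so all column sums are equal (default target: the
   mean of the observed sums; the target is configurable because only the
   *equality* of the sums matters). This removes sequencing-depth
   differences between libraries while preserving within-column transcript
   ratios exactly.
2. `relative_to_baseline()` divides each replicate series by its own value
   at $t = 0$, so every surviving series starts at 1 a.u. and later values
   are relative binding. Each replicate is normalized to its own baseline,
   not a replicate average, so replicate-specific baseline noise is not
   shared across series. Transcripts with any non-finite normalized value
   are dropped and reported, never imputed.

A caveat worth stating explicitly: total-sum scaling assumes that the bulk
of the signal is stable across samples. If essentially *every* transcript
shifts in one condition — as in an all-alternative synthetic data set — the
column-sum equalization absorbs the common shift and can erase the very
signal of interest. That is a property of sum normalization, not of this
implementation; the calibration and power simulations below therefore apply
only the baseline step, since simulated series share a common scale by
construction.

The differential-dynamics test models the **log2** of the
baseline-normalized ratio with a zero-mean prior (the $t=0$ points are then
exactly 0, and fold-changes are symmetric around 0); the linear scale with
constant mean 1 is available via `test_all(scale = "linear")`.

## The Gaussian-process Bayes-factor test

Let $f_j(t)$ be the latent binding response of one transcript in condition
$j \in \{\text{control}, \text{treated}\}$, relative to $t = 0$. The
response, averaged over the cell population, is assumed smooth in time,
encoded by a zero-mean Gaussian-process prior with squared-exponential
covariance

$$\mathrm{cov}\!\left(f_j(s), f_j(t)\right) =
  a^2 \exp\!\left[-\frac{(s - t)^2}{2\lambda^2}\right],$$

and observations $y_j(t) = f_j(t) + \varepsilon$ with iid Gaussian noise of
standard deviation $\sigma$. Because everything is Gaussian, the latent
function marginalizes exactly: stacking the observations of one latent into
$\mathbf{y}$ with covariance $C = K + \sigma^2 I$ (replicates at the same
time share the latent value, $K_{ij} = a^2$, but carry independent noise),
the evidence $p(\mathbf y \mid a, \lambda, \sigma)$ is a multivariate
normal density, computed via Cholesky factorization.

Two hypotheses are compared per transcript:

* **H0** — one shared latent $f(t)$ explains all series (control and
  treated stacked into a single evidence computation);
* **H1** — each condition has its own latent; the evidence is the product
  of the two per-condition evidences.

The Bayes factor $\mathrm{BF} = p(\mathbf y \mid H_1)/p(\mathbf y \mid
H_0)$ is the decision statistic, with $\mathrm{BF} \ge 10$ (log BF
$\ge \ln 10$) treated as strong evidence for condition-specific dynamics,
following the Kass–Raftery convention. The test runs independently per
transcript; because marginalization already accounts for sampling
variability, no multiple-testing correction is applied.

### Empirical-Bayes hyperparameters

Full marginalization over $(a, \lambda, \sigma)$ would cost the exactness
of the evidence, so hyperparameters are fixed per transcript by data-driven
rules, identical under both hypotheses (so neither hypothesis can over-fit
through its hyperparameters):

| parameter | rule | unit |
|---|---|---|
| $a^2$ | 50% of the population variance of all of the transcript's values (both conditions, all replicates) | a.u.² |
| $\lambda$ | globally 1 min | minutes |
| $\sigma^2$ | population variance of the transcript's control-condition values, floored at $10^{-6}$ | a.u.² |

The $\sigma^2$ rule leans on the design: the control shift is a null
experiment (same medium back), so its variability estimates noise plus any
shift-induced response common to both arms. The rule is deliberately
conservative — under H1 it charges some control-latent variability to
noise — and it breaks the control/treated symmetry of the likelihood; with
explicitly supplied hyperparameters the log BF is exactly invariant under
swapping condition labels (this is tested).

Design choices recorded here because the literature leaves them open: the
$t = 0$ observations are included in the likelihood (they are informative
about $\sigma$ through the replicate structure; exclusion is available via
`include_t0 = FALSE`); replicate series are *stacked* into one likelihood
sharing a latent per condition rather than averaged (averaging would
discard the replicate-noise information the $\sigma^2$ floor relies on);
variances use divisor $n$ (population variance).

### Numerics

The Cholesky factorization adds an escalating diagonal jitter
($10^{-9} \to 10^{-5}$, multiplying by 100 per step) when $C$ is not
numerically positive definite — with $\lambda = 1$ min and minute-spaced
grids $C$ is well conditioned and jitter is almost never engaged. Failure
beyond the maximum jitter is a hard error naming the transcript, never a
silent fallback. All bookkeeping is in natural log; the threshold is
$\ln 10$.

## Synthetic data: what it emulates, and what it does not

`simulate_timecourse()` draws data exactly from the generative structure
the test assumes, on the experimental grid: latent log2 responses from a
zero-mean squared-exponential GP on $\{0,1,2,4,8,14,20\}$ min, 2 replicates
per condition, observations with iid Gaussian noise on the log2 scale, and
FPKM mimicry by exponentiating around a transcript-specific baseline
abundance drawn log-normal across transcripts ($\log_2$ baseline
$\sim N(5, 2)$). Under H0 one latent is shared by both conditions; under H1
the conditions get independent latents and the treated one is offset by the
effect size at every $t > 0$ (a baseline-anchored step: a constant offset
at all times would vanish under baseline normalization).

Defaults, chosen once as plausible for this kind of experiment: latent
amplitude $a^2 = 0.04$ (sd 0.2 log2 units — modest dynamics), generator
lengthscale 2 min (smooth minute-scale responses; intentionally different
from the test's fixed $\lambda = 1$ min so simulations exercise mild
misspecification), noise $\sigma = 0.1$ log2 units (roughly 7% FPKM
replicate noise), H1 effect size 1.0 log2 units (a two-fold
condition-specific change, an order of magnitude above $\sigma$). At these
settings, 500-transcript simulations give a false-flag rate of 1–3% under
H0 and recovery of 96–99% under H1 (recomputed by `scripts/acceptance.R`
and the test suite; exact values depend on the seed).

What the generator does **not** emulate: realistic sequence content or
error models, transcript-length and GC biases, correlated noise across
transcripts, the mixture of differential and non-differential transcripts
of a real experiment, or count-level (Poisson/negative-binomial)
measurement noise at low abundance. Passing tests on this generator
therefore demonstrate correctness of the inference machinery under its own
assumptions and robustness to a mildly misspecified lengthscale — not
end-to-end validity on any particular real library.

`simulate_gene_reads()` builds toy read sets for the read-level modules:
reads Poisson-placed around specified peaks plus uniform background, PCR
duplicates sharing (UMI, sequence), multimappers with decoy alignments, and
planted oligo(A) tails. The accompanying synthetic reference contig is
generated free of A-runs ($\ge 3$) so that planted runs are the only
genomically encoded decoys; truth labels record encodedness against the
*final* genome, since a decoy run planted for one read can land downstream
of another read's end.

## Read-level conventions

Coordinates are 0-based half-open internally; BED is read/written as
0-based half-open and GTF/GFF is converted from 1-based closed on ingest.
A gene's `tss` is the first transcribed base and `end3` one past the last
in the direction of transcription, so `length_nt = |end3 - tss|` on both
strands. Barcode demultiplexing is exact-match by default with an optional
Hamming-1 mode (ambiguous matches go to the unassigned bin); barcode
layouts are configurable strings (`N` = random base, letters = sample code)
because real in-read barcodes interleave the two. Duplicate collapsing
defaults to the pre-alignment `(UMI, sequence)` key, matching the pipeline
order in which collapsing precedes alignment; `(UMI, position)` mode is
available post-alignment. Multimapping reads are distributed uniformly at
random over their candidate locations under an explicit seed. Pileups are
strand-specific: CRAC reads are sense to the bound RNA, so a region only
accumulates reads on its own strand.

## Escape index

For attenuation screening, each gene is split at its 5′ anchor (the TSS;
the anchor is configurable since annotations differ in whether the 5′UTR
start or the start codon is recorded) into a promoter-proximal region
(PPR, −100 to +250 nt, 351 nt in total) and a body (+251 nt to the 3′
end; genes shorter than 252 nt are skipped). With library-normalized
densities (coverage per nt per million mapped reads),

$$\mathrm{EI} = \frac{\mathrm{ppr}(t)/\mathrm{body}(t)}
                     {\mathrm{ppr}(0)/\mathrm{body}(0)},$$

so per-sample library scaling cancels within each ratio. A transcription
change is reported alongside as the whole-gene density ratio between the
samples. Candidate attenuated genes are those with EI $\ge 2$, a
transcription increase $\ge 1.5$, and coverage $\ge 10$ FPKM (all
boundary-inclusive), optionally requiring a binding-site peak overlapping
the PPR and a replicate experiment reaching the EI threshold. Genes whose
body density is zero are reported unresolved rather than silently dropped.

## Peaks, oligo(A) tails, profiles

**Peak calling** reports maximal contiguous intervals with coverage
$\ge$ 5 reads spanning $\ge$ 20 nt (height semantics by default;
`count_mode = "total"` switches the 5-read rule to interval mass). The
false discovery rate is an in-package permutation scheme: the gene's reads
are re-placed uniformly over the locus `n_perm` times (default 100,
seeded), peaks are re-called, and FDR = mean null peak count / observed
count, clipped to $[0, 1]$. This needs the read lengths behind the pileup;
without them the FDR is `NA` rather than a guess.

**Oligo(A) tails** are called from 3′ soft-clipped bases, strand-oriented:
a clip that is a run of $\ge$ 3 A's (configurable; published analyses say
only "short") counts only if the reference immediately downstream of the
alignment on the transcribed strand is *not* an A-run of the same length —
genomically encoded runs are template, not degradation marks.

**Profile clustering** first filters transcripts to those with a maximum
fold-change $\ge 1.5$ (max of the replicate-averaged ratio and its inverse,
so down-regulation counts symmetrically) and mean pairwise replicate
Pearson correlation $\ge 0.7$, then clusters the replicate-averaged log2
profiles with Lloyd's K-means under k-means++ seeding and a fixed seed.
K-means replaces the external model-based clustering tool used in the
original analyses; the cluster count (4 in the published figures) is a
parameter, not an algorithmic claim. Filtering uses replicate-averaged
profiles (the per-replicate alternative would double-count the correlation
rule's information).

**Meta-profiles** divide each transcript into 1000 equal-width bins and
apportion coverage mass with fractional-overlap weighting, which conserves
mass exactly for lengths not divisible by the bin count (nearest-bin
assignment would not); per-transcript fractions sum to 1 and the summed
profile totals the number of contributing transcripts. TSS-aligned
matrices distinguish missing cells (`NA`, outside available coverage) from
true zero coverage.

## Problem sizes and limitations

The shipped simulations use 500 transcripts for calibration/power, 200
random instances for evidence exactness, $10^6$ draws for the Monte-Carlo
consistency check, and a few hundred reads per toy gene — sizes at which
every check runs in seconds to a couple of minutes on one core while
keeping Monte-Carlo error well below the decision margins.

Known limitations: hyperparameters are fixed by the empirical-Bayes rules,
not optimized by evidence maximization; the noise model is Gaussian on the
log2 scale, which under-serves very low counts; the permutation FDR is a
documented stand-in for the original external peak tool's unspecified null;
and the escape-index region boundaries for composite loci (e.g.
retrotransposon families) are not reconstructed — the generic two-region
ratio is the exposed primitive.
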