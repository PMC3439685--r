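---
title: "Detecting and masking binding-affinity-different probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and masking binding-affinity-different probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(badprobes)
```

## The problem

Multi-probe expression arrays (Affymetrix 3'IVT and exon/gene designs)
measure one transcript with a probe set of J short probes.  Downstream
analysis assumes every probe binds its target equally well in all samples, so
that intensity differences reflect abundance differences.  When the two
compared groups differ in the probe's target sequence (SNPs or indels between
strains or species), in expressed isoforms, or in cross-hybridizing
transcripts, that assumption fails: the probe's *binding affinity* differs
between groups, and its signal confounds affinity with abundance.  We call
such probes BAD (binding-affinity-different) probes.  They create spurious
differential-expression (DE) calls, hide real ones by dragging probe-set
summaries in the wrong direction, and disrupt normalization.  Between
groups with ~1% nucleotide divergence, a fifth or more of 25-mer probes can
be affected.  Conversely, between genetically distinct groups, detected BAD
probes are usable genetic markers (single feature polymorphisms).

## Signal model and detection statistic

The intensity of probe $j$ on array $i$ is modelled as

$$O_{ij} = \nu_j + \Phi_i\,\theta_j + \varepsilon_{ij},$$

where $\nu_j$ is the probe's baseline response to nonspecific hybridization,
$\Phi_i$ the abundance of the target transcript in sample $i$, and
$\theta_j$ the probe's binding affinity.  Two probes of one probe set share
$\Phi_i$, so their intensities satisfy an affine relation

$$O_{i2} = \left(\nu_2 - \nu_1\frac{\theta_2}{\theta_1}\right)
          + \frac{\theta_2}{\theta_1}\,O_{i1} + \varepsilon,$$

whose slope is the affinity ratio and whose intercept
$\beta = \nu_2 - \nu_1\theta_2/\theta_1$ does not involve $\Phi$.  If a
probe's affinity (or baseline) is group-specific, the within-group relation
remains linear but the slope differs between groups, while the intercept can
still be estimated from both groups pooled.

Detection of a probe pair therefore proceeds as:

1. estimate $\beta$ by ordinary least squares over *all* samples pooled;
2. form per-sample ratios $r_i = (O_{i2} - \beta)/O_{i1}$, which estimate
   the slope $\theta_2/\theta_1$ sample by sample, and compare the two
   groups' ratios with a two-sided Welch t-test;
3. do this for every ordered pair of distinct probes in the set, in both
   directions, giving a $J \times J$ p-value matrix with an undefined
   diagonal;
4. iteratively eliminate probes: each surviving probe's score is the
   geometric mean of all surviving matrix entries in its row and column; the
   smallest-scoring probe is recorded (score = that geometric mean, rank =
   elimination step) and struck from the matrix;
5. when two probes remain, both receive the geometric mean of the two
   p-values connecting them.

The per-probe score (the *mP-value*) is small when the probe's relation to
its set-mates differs consistently between groups.  One genuinely BAD probe
contaminates all pairs it participates in; eliminating it first and scoring
the rest on the reduced matrix keeps a single bad probe from dragging down
its innocent set-mates.

## What a score means, and choosing a cutoff

Scores are *not* calibrated p-values: the $2(J_{\text{live}}-1)$ values
averaged at each step are dependent (they share probes and samples), and the
minimum over live probes is selective.  Scores are comparable within one
data set only — they shift with sample size and probe-set size — so cutoffs
are data-set specific.  The package deliberately does not automate the
choice: `plot()` on a mask shows the score histogram/ECDF (a cluster of very
low scores separated from the bulk suggests a cutoff between them), and when
BAD status is known externally for a subset of probes, `overlap_masks()`
tabulates sensitivity and false-positive rate per cutoff with Wilson 95%
intervals, `score_distribution_test()` checks the two classes are separable
at all, and `mask_auc()` summarises the ranking.  A stringent (high) cutoff
suits expression comparisons; a relaxed (low) cutoff suits marker discovery,
where false positives are costlier.

A note on error naming: throughout the evaluation module, **type 1 error is
the false-negative rate and type 2 error the false-positive rate** of BAD
detection against the reference — the convention of the probe-masking
literature, the reverse of the usual hypothesis-testing usage.

## Tunable parameters

* `presence_fraction` (default 0.90): detection only makes sense for
  expressed probe sets; with external P/M/A detection calls, a set is kept
  when called Present in at least this fraction of samples *in each group*.
  Without calls, a linear-scale mean-intensity threshold plays the same role.
* `cutoff` (in $[0,1]$, strict `<`): quality-score threshold for removal;
  `cutoff = 0` removes nothing.
* `min_probes` (default 1): a probe set that falls below this size after
  masking is dropped entirely; survivors form redefined probe sets.
* `alpha` (default 0.01): DE significance level on Benjamini–Hochberg
  adjusted Welch t-test p-values.
* At least five samples per group are recommended for useful power (the
  package warns below five and refuses below two).

## Numerical choices and degenerate inputs

* All computations are on the **linear** intensity scale; the affine
  pair relation above does not survive log transformation.  Readers convert
  declared log2 input on load.
* P-values are clamped to $[10^{-300}, 1]$ and geometric means computed in
  log space, so an underflowing t-test cannot collapse a whole probe set's
  scores to zero.
* Elimination ties break toward the smallest within-set probe index; the
  final two probes share one score, with the last two ranks assigned by
  index order.  This makes scoring fully deterministic.
* A constant predictor probe makes the pair's intercept undefined; that
  entry contributes p = 1 (with a warning) rather than aborting the set.
* If both groups' ratio vectors have exactly zero variance, p is 1 when the
  means agree to within $10^{-12}$ relative and $10^{-300}$ otherwise.  The
  same rule is applied at a $10^{-8}$ relative scale when both spreads are at
  rounding level for the OLS/ratio computation chain — noise-free data
  produces ratio vectors whose variance is floating-point error, not zero,
  and $10^{-8}$ is still orders of magnitude below any real array noise.
* Missing intensities are rejected, not imputed; the method defines no
  missing-data handling.  A probe may belong to several probe sets; each
  (probe set, probe) occurrence is scored independently.

## Open design choices

* The flavour of t-test is unspecified in the method's description; Welch
  (unequal variances) is used as the conservative default, for the pairwise
  ratio tests and for DE alike.
* The intercept estimator is ordinary least squares, the natural estimator
  of the pooled affine relation; no robust alternative is attempted.
* The geometric mean at each elimination step includes the probe's row
  *and* column entries — the probe as predictor and as response — reading
  "all p-values involving the probe" literally.
* Scores for probe sets of different sizes are not rescaled.
* Probe-set summarization for the DE step is the mean of log2 intensities —
  a deliberately transparent stand-in for heavier summarizers, swappable at
  the expression-table interface.  Confidence intervals on detection rates
  use the Wilson score method at 95%.

## The synthetic-data generator

`simulate_batch()` draws $\nu_j$, $\theta_j$ log-normally (medians 50 and 1)
and $\Phi$ per probe set and sample (median 500, i.e. specific signal about
ten-fold over background), applies group-B affinity scaling
(`affinity_ratio`) to the designated BAD probes and group-B abundance
scaling (`de_log2fc`) to true-DE sets, and adds multiplicative Gaussian
noise (`noise_cv`, default 10%).  The distribution families and defaults are
the package's own choices — the signal model constrains the mean structure,
not the laws — and every parameter is exposed and recorded in the returned
truth tables.  The canonical validation conditions used by the test suite
and the acceptance script are 50 probe sets of J = 11 probes, 10 samples per
group, 10% noise, and one BAD probe per set at affinity ratios 1 (null),
1.2, 1.5 and 2.

The generator emulates the features the detector relies on — shared
per-sample abundance within a probe set, probe-specific affinities and
baselines, signal-proportional noise — and *not* other features of real
arrays: probe-sequence-dependent affinity structure, optical background,
saturation, spatial artifacts, or correlated noise across probes.  Passing
tests therefore demonstrate correctness of the machinery under the model's
own assumptions, and say nothing quantitative about any particular real
data set.

Two engineered batches (`simulate_flip_batch()`) reproduce the
reciprocal-signal phenomenon where a single BAD probe flips a probe set's DE
status: one probe's group-B affinity is scaled by $2^{\mp J\,d}$ so that its
opposite-direction intensity shift exactly cancels (direction `"gain"`:
true fold change $d$ hidden until the probe is masked) or single-handedly
creates (direction `"loss"`) the set-level mean shift.  The engineering has
to balance two opposing requirements: the fold change must be large against
the between-sample abundance spread for the set-level Welch test to resolve
it, while that same spread supplies the leverage the pooled-intercept
regression needs.  The defaults (J = 8, $d$ = 1, abundance log-sd 0.3, 15
samples per group, 5% noise) satisfy both; target baselines are drawn low
(median 2) so the log2-scale cancellation is nearly exact.  Every generated
flip batch is verified at generation time and generation aborts if the flip
does not hold.

## Validation design

The test suite validates each layer against an independent oracle:
elimination scoring against a literal re-computation of every geometric mean
after every removal; intercepts against the closed-form OLS solution; Welch
p-values against the textbook statistic and Welch–Satterthwaite degrees of
freedom; BH adjustment against the step-up procedure written out; Wilson
intervals against the score-test inversion; counting-based rates against
double loops.  Null calibration of the single-pair test is checked by KS
uniformity on 1000 *independent* pair tests (one direction of one pair from
each of 1000 two-probe null sets): pooling a probe set's full pairwise
matrix would be invalid for this purpose, since its $J(J-1)$ entries share
probes and are strongly dependent — empirically the pooled version's KS
p-value is severely over-dispersed even though the mean p-value is exactly
0.5.  The matched random-removal null re-runs summarization and DE 200
times with removals stratified per probe set; problem sizes throughout
(50-set batches, 200 iterations) were chosen to exercise every code path at
comfortable statistical margins.

## Worked example

```{r example, eval = FALSE}
library(badprobes)

sim <- simulate_batch(sim_config(n_probe_sets = 50, probes_per_set = 11,
                                 bad_fraction = 1/11, affinity_ratio = 2,
                                 noise_cv = 0.1, seed = 42))
mask <- detect_bad(sim$intensities, sim$map, sim$groups)
print(mask)
plot(mask)                       # score histogram/ECDF, cutoff by eye

masked <- apply_mask(sim$intensities, sim$map, mask = mask,
                     cutoff = 1e-3, min_probes = 1)
print(masked)

expr <- summarize_expression(masked$intensities, masked$map)
de <- differential_expression(expr, sim$groups, alpha = 0.01)
head(de)

ref <- subset(sim$truth$probes, is_bad)[c("probe_set_id", "probe_id")]
overlap_masks(mask, ref, cutoffs = 10^seq(-6, -1))
mask_auc(mask, ref)
```

## Known limitations

* Exactly two groups; no multi-group generalisation.
* The pooled intercept needs intensity spread across samples: when target
  abundance barely varies, the regression has no leverage, intercept
  estimates degrade and power drops.  Very large affinity ratios can
  likewise bias the pooled intercept (one line fitted through two
  different-slope clouds) and paradoxically soften the evidence relative to
  moderate ratios.
* Scores are rankings, not calibrated error rates; no multiple-testing
  correction across probes is attempted, matching the raw-cutoff usage the
  method was designed for.
* Presence calls are consumed, never computed; normalization and heavier
  summarization (RMA/GCRMA and relatives) are out of scope — which also
  means their outlier down-weighting, known not to remove BAD-probe bias, is
  not silently re-introduced.
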