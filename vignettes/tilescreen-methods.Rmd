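---
title: "Methods: tiling-screen design, bias correction and function-based ranking"
author: "tilescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling-screen design, bias correction and function-based ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilescreen)
```

# Scope

`tilescreen` covers the computational chain of a pooled CRISPR tiling
screen aimed at function-based drug discovery: deciding how many cells
and virions a library needs, gating the sorted cytometry read-out,
turning guide counts into dropout (fitness) and function (sorting)
scores on protein residues, removing guide-dependent efficiency bias
with an out-of-fold regression model, extracting the functional sequence
interval, ranking compounds against that sequence through a pluggable
interaction scorer, and predicting brain penetration with a stacked
classifier-then-regressor model. Every stage has a seeded synthetic-data
generator so the whole chain is testable offline.

# Library coverage and transduction design

A pooled library is acquired by repeated transduction draws whose
per-guide probabilities follow the plasmid-pool abundances, which in
real pools span several orders of magnitude. Collecting every k-guide
combination is a weighted coupon-collector problem. Writing $a_s$ for
the summed abundance, $a_n$ for the abundance product of the $n$-th
k-combination, and indexing the $n = \binom{g}{k}$ combinations by
ascending probability, the expected number of draws is bounded by

$$E[C] \;\le\; \sum_{i=1}^{n} \frac{(a_s)^k}{i\,a_n}.$$

Under Poisson transduction the fraction of cells with exactly $k$
integrations at $v$ effective virions on $c$ cells is the Poisson pmf at
mean $v/c$; it is maximized at $v = kc$. Combining the two gives the
cell requirement

$$c = r\,k!\,(e/k)^k \sum_i \frac{(a_s)^k}{i\,a_n},$$

with $r$ single-cell replicates per combination. The titer read-out
inverts the zero class of the binomial infection model,
$v = \ln f_0 / \ln(1 - 1/c_i)$, and the volume of stock to add is
$A = c\,k\,L\,\ln(1 - 1/c_i)/\ln f_0$; $A$ inherits the unit of $L$
unchanged.

Numerical choices. The combination sum is accumulated in log space
(abundances span orders of magnitude, and $(a_s)^k/a_n$ overflows
doubles quickly). Exact enumeration is used while
$\binom{g}{k} \le 5\times10^6$ — $k = 1$, the common case, is always
exact. Above the cap the sum is estimated stratified: the largest
20,000 weights are found exactly by a best-first search over k-subset
log-abundance sums (a heap-based k-smallest-subset-sum enumeration, no
full enumeration needed), and the remaining stratum — where the $1/i$
factor is nearly flat, so sampling error comes almost entirely from the
weight variance — is estimated by Monte-Carlo with a standard error from
independent batches; the result is flagged approximate.

Two readings left open by the source material are resolved as follows.
The volume formula is written for general $k$ but described as the
"one guide per cell" upper limit; the implementation exposes general
$k$ and documents that $k = 1$ is the intended screening use. The
ascending-probability ordering of the bound is stated for single
coupons; the same ordering is applied after substituting combinations
(the rarest combination receives the full weight), which keeps the
expression an upper bound.

What the bound does and does not promise: it dominates the *expected*
draw count. Individual collection times have a heavy right tail
(empirically, coefficient of variation around 0.5–0.7 for skewed pools,
with the bound roughly 1.2 times the mean), so a substantial minority of
individual simulated collections exceed the bound while batch means sit
below it; the tests assert the mean form.

# Synthetic screens

The generator works at cell level, per replicate (stream `seed +
replicate`): guides per cell are Poisson(MOI, default 0.3, the standard
screening multiplicity); each integrated guide edits its locus with the
guide's efficiency (Beta-distributed with mean 0.7, plus a noisy
observable "guide-dependent score" correlated with it, mimicking
sequence-based efficiency predictions); an edited locus adds the
residue's dropout effect to the cell's log2 survival weight between
day 6 and day 14 (multiplicative fitness, matching the log2 fold-change
read-out) and its function effect to the logit of the cell's activation
probability (baseline 0.5, so the null is symmetric and probabilities
stay bounded); cells are sorted once by a Bernoulli draw; and each
sample's reads are multinomial at the requested depth over cell-weighted
guide frequencies. Non-targeting controls carry no landscape position
and behave as nulls regardless of efficiency. Library abundances are
log-normal; $\sigma = 2.8$ reproduces the four-to-five orders of
magnitude seen in real plasmid pools, while study-condition fixtures use
$\sigma = 1.5$, a well-constructed but still skewed pool.

The analytic expectations of this model (`expectedFunctionScore`,
`expectedDropoutScore`) serve as the recovery oracles: a guide of
efficiency $q$ on a residue with effect $e$ yields a mixture of edited
and unedited cells, so the expected function score is
$\log_2\mathrm{odds}(w) - \log_2\mathrm{odds}(p_0)$ with
$w = q\,\sigma(\mathrm{logit}(p_0) + e) + (1-q)p_0$, and the expected
dropout score is $\log_2(q\,2^e + 1 - q)$.

What the generator does *not* emulate: sequence-level reads, indel
spectra, PCR amplification bias, copy-number effects, guide dropout
during packaging, or correlated multi-locus genotypes beyond additive
effects in multi-guide cells. Passing recovery tests therefore
demonstrates that the analysis chain inverts this generative model, not
that it removes every artefact of a wet screen.

# Scoring and residue mapping

Dropout is $\log_2((c_{14}+\alpha)/(c_6+\alpha))$ and function
$\log_2((c_{act}+\alpha)/(c_{unact}+\alpha))$, computed per biological
replicate and averaged into a mean score per unique sgRNA. The
pseudocount defaults to $\alpha = 1$ (the source states the fold change
but no pseudocount). Counts-per-million normalisation is on by default —
fold changes across samples of different depth are otherwise biased —
and can be switched off for exact-reproduction attempts; with
normalisation on, $\alpha$ applies on the CPM scale so depth cancels.

Cas9 cuts bluntly ~3 bp 5′ of the NGG PAM, between protospacer
positions 17 and 18. The cut is treated as a genomic boundary and
projected strand-aware onto the CDS: a codon-boundary cut returns the
two flanking residues; a within-codon cut returns the containing residue
and the neighbour sharing the nearer codon edge. Each guide therefore
maps to two adjacent residues and contributes its mean score to both;
a residue's raw score is the mean over contributions. Guides cutting
outside the CDS are flagged unmapped and excluded from aggregation.
Protein positions are 1-based inclusive throughout the user interface.

Group statistics use the tie-corrected Kruskal-Wallis test followed by
Dunn's pairwise z-tests with Bonferroni correction. Because a median
"read-count ratio reduction" can be read as the median of per-guide
ratios or as the back-transformed median log2 score, both percent-change
readings are reported (`percent_change_ratio` and
`percent_change_medianlog`), the ratio scale being the default.

# Guide-dependent bias correction

A gradient-boosted regressor (eta 0.1, depth 4, 150–200 rounds, single
thread for bit-reproducibility) predicts the raw residue score from the
guide-dependent score plus residue-context features (position in the
pipeline's default table; conservation, disorder, SASA, 3D coordinates
and one-hot amino-acid identity when richer annotation tables are
supplied). Validation is 8-fold out-of-fold: rows are shuffled into
folds by seed, each fold is predicted by a model blind to it, and the
OOF residuals back both the benchmark metrics (RMSE, Pearson, Spearman,
each with a seeded 10,000-resample percentile bootstrap) and the
prediction interval (corrected score ± the level-quantile of absolute
OOF residuals — a global residual-quantile interval, not a per-point
variance model).

The correction itself replaces every declared guide-dependent feature
column by its global median over the training rows and re-predicts with
the final all-data model; an ensemble-mean alternative over the fold
models is available (`use_ensemble`), since the source does not state
which was used. Guide-dependent columns are declared by name, never
inferred — the validity of the correction hinges on this set, so
guessing it silently would be worse than failing loudly. Median
replacement is idempotent, and two residues identical in all non-guide
features receive identical corrected scores by construction.

Missing features are median-imputed with a 0/1 missingness indicator
column per imputed feature; an all-missing column is dropped with a
warning.

# Functional-sequence extraction

The functional sequence is the full width at half maximum of the
negative corrected function score relative to the median baseline:
baseline = profile median, trough = global minimum, half level =
baseline − (baseline − trough)/2, and the interval is the maximal
contiguous run of positions at or below the half level that contains
the trough. Uncovered positions inside the covered range are linearly
interpolated before thresholding so tiling gaps do not split one
physical region; boundaries stay on residue positions (no sub-residue
interpolation) because the output is a residue interval. Other
sub-half-level runs are reported as secondary, and tied troughs break
deterministically to the lower index with a flag — the source does not
state its tie handling, so the choice is surfaced rather than hidden.
A flat profile (trough at baseline) is a no-signal error.

# FACS gating at a target FDR

Gating replaces manual boundary drawing with a gradient-boosted binary
classifier over the event channels (e.g. ASC area vs ASC height),
trained on labelled reference conditions with a 25% held-out
calibration split. For a requested false-discovery rate, each class's
posterior cutoff is the smallest threshold at or above 0.5 whose
estimated FDR on the calibration split — the fraction of
opposite-condition events among calibration events above the threshold —
does not exceed the target; ties at the cutoff are included. Events
clearing neither cutoff are "unspecific". At FDR = 1 the cutoffs sit at
0.5 and nothing is unspecific. The FDR is per class (whether the
source's level is per class or global is unstated; per class is the
implemented and flagged reading). Channels can optionally be
arcsinh-transformed with a configurable cofactor; the default applies
no transform since none is described.

# Compound ranking against the functional sequence

Compound–protein scoring is a pluggable contract:
`function(smiles, sequence) -> logit score`. The bundled
`kmerStubScorer` — hashed 3-gram tokens of the SMILES string against
hashed protein 3-mers — is a deterministic stand-in used only for tests
and demonstrations; it contains no chemistry, and a neural
sequence-based interaction model attaches through the same contract.
Ranking is by descending reference-sequence score with ties broken
lexicographically and flagged; percentile is 100·rank/N, matching
"top X%" phrasing. The single-residue deletion scan re-scores every
compound against each deletion variant across the interval as a
stability band; the headline ranking uses the reference-sequence score
(how the deletion scores would otherwise aggregate is unstated).
Context comparison ranks the same library against the functional region,
the parent with that region excised, and the full protein.

# Stacked brain-penetration model

Stage 1 is a binary penetrance classifier trained with seeded 8-fold
out-of-fold predictions (fold count mirrors the screen model; the
source does not state it) and then refit on all classification rows.
Its probability on the regression compounds — which are disjoint from
the classification set once `deduplicateCompounds` has removed shared
compound keys, so the full-data refit leaks nothing — is appended to the
descriptors, and stage 2 regresses logBB on descriptors + probability.
The logBB prediction itself is the ranking score for ROC evaluation,
with a compound-level bootstrap (mean AUC and percentile CI).

Stage 2 is a boosted linear model plus a tree boost on its residuals.
This is a deliberate design choice: descriptor→logBB relations are
close to linear, and pure tree ensembles approximate smooth linear
functions poorly in ten and more dimensions, while an AutoML system —
whose role this deterministic model stands in for — would include linear
members. The linear stage captures that component exactly; the tree
stage picks up the remainder. Compound keys are compared as exact
strings unless a canonicaliser function (e.g. a canonical-SMILES
backend) is supplied.

# Problem sizes and runtime envelope

The study-condition suites run at: 1,000 targeting guides + 100
controls over 300 residues, 50,000 cells, MOI 0.3, depth 5×10⁵, three
replicates, 20 seeds for bias-correction recovery; 500 weighted
coupon-collector collections at g = 50; 20 seeded two-population
Gaussian mixtures of 3,000 events for gating; n = 1,000 training
compounds with 10 descriptors and noise at 10% of signal SD for the
stacked model. These sizes were chosen as the smallest at which the
recovery properties are comfortably identified; everything completes in
well under a minute per component on a single core.

# Known limitations

* The corrected landscape is on the observed score scale at median
  efficiency, an attenuated transform of the latent per-residue effect;
  comparisons to ground truth use the generative model's analytic
  expectation at that efficiency.
* The FDR calibration is label-based and assumes the calibration split
  is exchangeable with the events being gated; covariate shift between
  reference and sample is not modelled.
* The coupon-collector Monte-Carlo path reports a standard error but no
  bias bound for the sampled stratum; exact enumeration covers all
  k = 1 designs and any design with at most five million combinations.
* The deletion-scan stub scorer shares only its interface with real
  interaction models; rank stability under the stub says nothing about
  chemical plausibility.
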