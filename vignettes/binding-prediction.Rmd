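---
title: "Predicting cell type-specific TF binding from accessibility and motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell type-specific TF binding from accessibility and motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcast)
```

## The problem

Transcription factors (TFs) bind short, degenerate sequence motifs, but
only a small fraction of motif matches in a genome is actually bound in a
given cell type.  The strongest cell type-specific signal available
without doing the ChIP-seq experiment itself is chromatin accessibility
(DNase-seq or ATAC-seq): bound sites are overwhelmingly in open
chromatin.  peakcast predicts, for a TF with ChIP-seq training data in at
least one cell type, where that TF binds in another cell type, from that
cell type's accessibility track plus motif scans of the (shared) genome.

The prediction unit follows the ENCODE-DREAM convention: 200-bp windows
every 50 bp, labelled from ChIP-seq peaks as B ("bound", overlapping a
conservative IDR-thresholded peak by at least 100 bp), A ("ambiguous",
touching a relaxed peak by at least 1 bp) or U ("unbound").  Ambiguous
windows are excluded from training and evaluation throughout.

## Model

The genome is tiled into non-overlapping 50-bp bins and every signal is
reduced to per-bin features: summary statistics (min, max, mean, median)
of the accessibility fold enrichment, means over broader windows
("long-range"), accessibility-peak overlap and distance features,
cross-cell-type variation of the signal, per-bin PWM scores (the maximum
log-probability of a site in the bin and the log of the average site
probability, both from strand-combined sliding-window scans), and simple
sequence statistics (G/C content, CpG frequency, homopolymer runs).

A candidate binding region is an odd number $W$ of adjacent bins centred
on a potential peak-summit bin $i$; $W$ is derived from the TF's typical
peak width (median across cell types of the per-cell-type median peak
width, divided by 50 bp, rounded and forced odd upwards).  The
two-class model treats the concatenated features $x = (x_1, \dots, x_D)$
of those bins as independent within each class $c \in \{B, U\}$:

$$f_c(x) = \prod_d f_{c,d}(x_d),$$

with Gaussian densities for numeric features, Bernoulli distributions
for 0/1 indicator features, and optionally a homogeneous Markov model of
order 3 for the raw window sequence.  All components are written in
their natural parameterization ($\eta_1 = \mu/\sigma^2$,
$\eta_2 = -1/(2\sigma^2)$ for a Gaussian), so the classifier's log-odds

$$\log \frac{P(B \mid x)}{P(U \mid x)} =
  \beta_B - \beta_U + \sum_d \big(\log f_{B,d}(x_d) - \log f_{U,d}(x_d)\big)$$

is linear in the per-feature sufficient statistics $(x_d, x_d^2)$.

### Discriminative training

Parameters are estimated by the weighted discriminative maximum
conditional likelihood (MCL) principle: maximise
$\sum_n w_n \log P(c_n \mid x_n)$ rather than the joint likelihood.
Because the conditional likelihood depends only on the *between-class
contrasts* of the natural parameters (shifting both classes equally
changes nothing), the implementation optimises directly in the contrast
parameterization — an intercept plus one coefficient per sufficient
statistic — where the penalised objective is strictly concave.  A
Gaussian prior with standard deviation `prior_scale` (default 1) is
placed on the contrasts; the shift-invariant direction is unpenalised.
In this form the optimum coincides exactly with an L2-regularised
logistic regression on $(x_d, x_d^2)$, which the test suite exploits as
an independent oracle (an independently written Newton/IRLS optimiser
must reproduce the fitted posteriors to $10^{-4}$).

After optimisation the per-class component parameters are reconstructed
around a moment-matched fit of the unbound class: class-U Gaussians take
the weighted class-U mean and variance, class-B parameters add the
fitted contrasts, and all normaliser differences are absorbed into the
class log-priors, so `posterior()` computed from the per-class densities
reproduces the optimised discriminant exactly.  The constraint
$\eta_2 < 0$ is enforced in this reconstruction (shifting both classes'
$\eta_2$ when needed — the posterior is unaffected).

Numerical choices: features are standardised internally (weighted mean
and population SD, stored in the model) so the quasi-Newton optimiser
(BFGS, relative tolerance $10^{-14}$, at most 500 iterations, followed by
exact-Hessian Newton polishing to gradient norm $10^{-6}$) sees
well-conditioned coordinates; class-U variances are floored at
$\max(10^{-6}, 10^{-4}\hat\sigma_d^2)$ to keep the reconstruction
numerically benign for near-degenerate features.  Optimisation failure
raises an error with the gradient norm and iteration counts.  The
optional order-3 Markov sequence component is estimated from weighted
per-class 4-mer frequencies (pseudo-count 0.5, the first three positions
scored uniformly) and enters the discriminative fit as a fixed
log-likelihood-ratio offset: the normalisation constraints of the
conditional probability tables make a fully discriminative Markov
contrast inequivalent to unconstrained logistic regression on 4-mer
counts, so the generative estimate is used and documented here rather
than hidden behind an approximation.

### Training data

Positives are all conservative-peak summit bins (weight 1; the relaxed
peaks substitute when a TF has no conservative calls).  Negatives come
from three chromosome-stratified schemas:

1. **Uniform** — per chromosome, 10 times as many centre bins as there
   are positives, uniform over bins not covered by a relaxed peak.
2. **Accessibility-matched** — negatives whose per-bin DNase median
   resembles the positives' are over-sampled (they are the hard cases)
   and down-weighted by the importance weight
   $(N_g/N_\text{neg})/(n_g/n_\text{total})$ over ten equal-population
   strata of the eligible bins' medians, so the weighted sample still
   represents the eligible-negative population.  The number of draws (10
   per positive, per chromosome) mirrors the uniform schema's magnitude;
   the stratum count and statistic are this package's concrete choice
   for an under-specified step.  Draws aimed at an empty stratum are
   redistributed to the nearest non-empty strata with a warning.
3. **Cross-cell-type** — four times as many regions as positives, drawn
   from bins inside another training cell type's conservative peaks that
   do not touch the current cell type's relaxed peaks; their uniform
   weights sum to the rate of such regions among all putative negatives
   times the schema-1/2 weight on that chromosome (the anchor resolves
   an ambiguity in how that rate is to be normalised).  Skipped when
   only one cell type is available.

No sampled negative centre bin ever intersects a relaxed peak — a hard
invariant asserted in the tests.

### Iterative hard-negative training

Five rounds: train, score all labelled windows on the selection
chromosomes with the average of all classifiers so far, find the
$\lceil 0.01\, n_B \rceil$-th smallest score among B windows, add every U
window scoring *strictly* above it as a new weight-1 negative, retrain.
A selected 200-bp window contributes one training region centred at the
bin with the highest averaged posterior among the window's own four bins
(leftmost on ties) — this keeps the relaxed-peak invariant — and a
window enters the negative set at most once.  The interpolation-free
order-statistic percentile and the strict inequality are deliberate,
deterministic choices.  Positives never change; the negative set grows
monotonically; the result is five classifiers per training cell type.

### Prediction and peak calling

Each classifier yields per-bin summit posteriors $P_i$ (edge bins whose
window does not fit get $P_i = 0$).  The probability that the 200-bp
window starting at bin $i$ overlaps a predicted peak by at least 100 bp
is the complement of the product of complements over the contributing
centre set,

$$S_i = 1 - \prod_{\ell \in C_i} (1 - P_\ell), \qquad
  C_i = \{\ell : |[\ell - h, \ell + h] \cap [i, i+3]| \ge 2 \text{ bins}\},$$

with $h = (W-1)/2$; for $W = 5$ this is exactly $\ell \in
\{i-1, \dots, i+4\}$.  The $S$ tracks of all $5K$ classifiers ($K$
training cell types) are averaged per window.  Peak calls join maximal
runs of windows with $S > t$ ($t = 0.6$ relaxed, $0.8$ conservative),
record the maximum probability $p$, trim bordering windows with
$S < 0.8\,p$ from the outside in (never removing the maximal window;
trimming only shrinks run ends, it never splits a run), and emit
narrowPeak records with the summit at the centre of the maximal window
(leftmost on ties), score $-100\log_{10}(1-p)$ (with $p$ capped at
$1 - 10^{-8}$ and the score clamped to 0–1000) and signal value $p$.
Conservative calls provably nest inside relaxed calls: a window with
$S > 0.8$ can never be trimmed at threshold $0.8\,p \le 0.8$.

### Evaluation

AUC-PR is computed with the continuous (non-linear) interpolation
between operating points — along a segment the true- and false-positive
counts grow linearly, so precision follows a hyperbolic arc whose
integral has a closed form; tied scores form one operating point.  This
matches the challenge evaluator's semantics and differs from step-wise
average precision; a fine-grid numeric integration oracle pins the
definition to $10^{-6}$ in the tests.  AUC-ROC uses midrank
(Mann–Whitney) ties, cross-checked against pROC.  Recall at 10%/50% FDR
is the best recall over thresholds with precision at least 0.9/0.5.
Peak agreement uses the bp-level Jaccard coefficient of merged
intervals.

## The synthetic data generator

`simulate_dataset()` builds the package's study conditions: 3
chromosomes of 200 kb, 2 cell types, 80 bound sites per cell type of
which half are shared, 160 decoy regions, a planted 12-bp motif
(consensus probability 0.85 per position), accessibility bumps of mean
fold-enrichment 8 (log-normal site-to-site variation, 10% deliberately
weak sites) over low gamma background noise, smoothed with a 150-bp
moving average like the challenge tracks; conservative ChIP peaks are
summit ±150 bp, relaxed ±200 bp, so conservative peaks nest inside
relaxed ones as in the real data.  Crucially it contains both kinds of
hard negatives: decoys are open in every cell type but carry no motif,
and sites specific to the other cell type carry the motif but stay
closed.  The generator does *not* emulate read-level noise, fragment
size effects, copy-number or mappability artefacts, footprint structure
within peaks, or realistic genome composition — so green tests show the
pipeline's logic and statistics are right, not that real-data
performance numbers transfer.

Scale choices keep the whole pipeline under a minute per run on one
CPU: the test suite runs the full iterative procedure on ten seeds of
the default configuration (~600 kb × 2 cell types each) and the
acceptance script runs one complete end-to-end analysis; both complete
in a few minutes.

## Design decisions on open points

* Natural log everywhere in motif scoring; strands are combined by a
  per-position maximum before aggregation (the alternative — separate
  per-strand features — doubles the feature count for little gain on
  palindromic-ish motifs).
* PWM pseudo-probability flooring mixes each position with the uniform
  distribution ($p' = (1-4f)p + f$, $f = 10^{-4}$), which keeps rows
  normalised and every entry at least $f$; `N` bases contribute the
  position's minimum probability.
* Peak widths are converted to bins after taking medians, and rounded
  up to odd.
* Distance features are capped at 10 kb: unbounded distances are poorly
  modelled by Gaussian components.
* Trailing partial bins are dropped so bin↔coordinate arithmetic stays
  exact.
* The iterative-selection chromosomes default to all training
  chromosomes; restricting them (as one would on a full genome for
  runtime) is a configuration option, not a behavioural default, at toy
  scale.

## Limitations

Only PWM motif models are implemented behind the motif interface;
dependency-aware motif models and de novo discovery are out of scope.
Accessibility input is bedGraph (plain text); bigWig is not read.
Quantile normalisation across cell types is deliberately skipped, so
tracks from different sources should be comparably processed upstream.
The classifier's independence assumption across features is knowingly
wrong (adjacent bins are strongly correlated) — discriminative training
compensates in the decision function, but the per-class densities should
not be interpreted generatively.
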