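---
title: "From expert annotations to automatic IC classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expert annotations to automatic IC classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ICAnnotate)
```

## The problem

Independent component analysis (ICA) decomposes multichannel EEG into
source components, each described by a topomap (one mixing weight per
scalp channel) and a source time series. Cleaning an EEG recording means
deciding, per component, whether it carries brain activity (possibly a
specific rhythm such as occipital alpha or sensorimotor mu) or an
artifact: eye movements, muscle, heartbeat, noisy channels. Experts
disagree substantially on these decisions — one annotator may list every
activity faintly present in a mixed component while another only marks
clear, single-pattern components — so a supervised classifier needs a
principled way to turn several conflicting annotations into one training
target per component and class. `ICAnnotate` implements that pipeline:
label aggregation, agreement quantification, feature extraction,
classifier validation and selection, plus a synthetic data generator that
makes every stage testable without any real EEG recording.

## Label aggregation

An *annotation* is one expert's label set for one component, drawn from a
fixed vocabulary (`annotationVocabulary()`). Before any aggregation the
class set is consolidated (`mergeClasses()`): horizontal and vertical eye
movements merge into a single Eyes class, line-noise labels are dropped
(an annotation left empty becomes Uncertain, so the component keeps a row
and agreement denominators stay consistent), and any annotation carrying
Alpha or Mu is ensured to carry Brain too, since those rhythms *are*
brain activity.

Votes are then aggregated per class with one of two strategies:

* **Majority vote.** The weighted probability of class $k$ for component
  $c$ is the mean of the binary votes of the experts who annotated $c$.
* **Probabilistic vote.** Each expert has a single vote, split equally
  over the $m$ classes they listed ($1/m$ each), and these contributions
  are averaged. An expert who lists Eyes, Muscle and Heart therefore
  contributes $1/3$ to each; their vote is conserved
  ($\sum_k$ contributions $= 1$).

The boolean target is 1 when the weighted probability *strictly* exceeds
the class threshold. The default threshold is 0.33 for both strategies,
chosen so that a component with three or fewer labels still counts as a
simple pattern of interest. Two boundary conventions needed fixing, since
"0.33" and "one third" are interchangeable in prose but not in floating
point:
probabilities are rounded to 12 decimal places before comparison, and the
default threshold is stored as exactly 0.33 — hence a one-of-three vote
($0.333\ldots$) passes, while the same vote against an exact-$1/3$
threshold does not. Experts who did not annotate a component are excluded
from its denominator rather than counted as all-negative: only cast votes
are averaged.

The default per-class plan (`defaultAggregationPlan()`) uses the
probabilistic vote for the well-represented classes (Brain, Eyes, Muscle,
Channel noise) and the majority vote for the sparse ones (Alpha, Mu,
Heart), mirroring the aggregation used for the reference annotation
corpus this pipeline was built around. Other and Uncertain are carried
through the vote matrix — so that a splitter's vote is diluted correctly —
but are annotation-quality flags, not classification targets, and carry
no strategy.

## Agreement between experts

Per class, agreement between two experts is Cohen's $\kappa$ on the
components both annotated; with three or more experts Fleiss' $\kappa$ is
used on the components annotated by all of them (subsampling ragged
panels is deliberately left to the caller). The degenerate case $p_e = 1$
(both raters constant with identical marginals) returns 1 when agreement
is perfect and 0 otherwise, with a warning. The inter-expert correlation
(IEC) is the mean over jointly annotated components of the Pearson
correlation between the two experts' binary label vectors; components
where either vector is constant have undefined correlation and are
skipped but counted (`nSkipped`). Agreement is always computed after
class merging, on the class set the classifiers will actually see.

## Features

`extractFeatures()` produces eleven named features per component.
Topographic features are computed on weights normalised to unit sum of
absolute values, with sign preserved; all features are invariant to
component scale, and all but the signed eye-difference convention are
invariant to a global sign flip (both properties are enforced by tests).

* **kurtosis** — Pearson (non-excess) fourth standardised moment with
  population moments, computed per epoch and averaged; an excess variant
  is available via a flag. Gaussian signals give $\approx 3$, a pure
  sinusoid exactly $1.5$, blink-like sparse events much more.
* **max_epoch_variance** — max/mean ratio of per-epoch variances after
  discarding the largest $\lceil 0.01\,n\rceil$ variances; the trimmed
  values are removed from both numerator and denominator.
* **SAD / SVD** — mean and variance of absolute weights over a frontal
  electrode set minus the same over a posterior set.
* **SED** — by default $|\overline{w}_\text{left}| -
  |\overline{w}_\text{right}|$ over the periocular sets (the literal
  reading of the defining sentence); the alternative
  $|\overline{w}_\text{left} - \overline{w}_\text{right}|$, which is the
  one sensitive to the antisymmetric topography of horizontal saccades,
  is available as `sedConvention = "diff_of_means"`. No published set
  list exists for these regions, so the defaults (frontal
  Fp1/Fpz/Fp2/F3/Fz/F4/F7/F8, posterior P3/Pz/P4/O1/Oz/O2/P7/P8, left eye
  Fp1/F7, right eye Fp2/F8) are this package's choice and are
  user-overridable.
* **MIF** — integrated PSD over 20–100 Hz divided by the integrated PSD
  over (0, Nyquist]; $\approx 0.64$ for white noise at 250 Hz, near 1 for
  muscle.
* **pattern_corr_blink / pattern_corr_saccade** — maximum over epochs of
  the absolute Pearson correlation with a z-scored template (centred
  Gaussian hump with $\sigma = 10\%$ of the epoch; logistic step at
  mid-epoch), signed by the correlation at the maximising epoch. The
  original template waveforms were hand-picked and never published, so
  parametric stand-ins are used.
* **MT / AT** — sum of normalised absolute weights inside the mu
  (fronto-central) or alpha (centro-parieto-occipital) electrode set
  minus the sum outside it. C3/Cz/C4 belong to both sets. On a uniform
  31-channel topomap each evaluates to $(12 - 19)/31 = -7/31$.
* **AMALB** — ratio of summed spectral amplitude ($\sqrt{\text{PSD}}$)
  inside 6–12 Hz to the summed amplitude at all other estimated
  frequencies. The band reaches down to 6 Hz because the alpha peak sits
  lower in children. The defining formula excludes exactly $[6, 12]$ from
  the denominator, so the 12–13 Hz bins are *included* there even though
  a prose reading ("0–6; 13–125") would skip them; the formula wins.

Spectral estimates use a Welch average: Hann-windowed one-second
segments, 50% overlap, per-segment mean removal, pooled across epochs,
one-sided density scaling. One-second segments give a 1 Hz grid, enough
to resolve the 6–12 Hz band. No installed R package provides this
estimator, so it is implemented here and checked against Parseval's
identity (integrated PSD $\approx$ variance within 5% on stationary
noise). Epoch conventions degrade gracefully: a continuous recording is
treated as a single epoch, in which case the per-epoch features still
work and `max_epoch_variance` alone is reported missing (and the
component flagged).

Channel names are normalised to modern 10-10 labels (legacy T3/T4/T5/T6
map to T7/T8/P7/P8) so montages written in either convention match the
electrode sets. Set members missing from a montage are dropped with a
warning; a set left empty is an error.

## Classification and validation

Three fixed-hyperparameter model families are compared per class
(one-vs-rest): L2-penalised logistic regression with inverse
regularisation $C = 1$ (via `glmnet`, $\lambda = 1/(Cn)$, matching that
objective), a linear SVM with cost 1 (via `e1071`), and gradient-boosted
trees with 30 estimators of maximum depth 4 (via `xgboost`). No
hyperparameter search is performed anywhere.

`repeatedSplitValidate()` runs 50 stratified 70/30 train/test splits.
Stratification is a deliberate addition: with an 8% positive class,
unstratified splits regularly produce degenerate test sets. Features are
standardised with training-set statistics for the linear families; trees
take raw features. Continuous scores are probabilities for logistic
regression and the trees and the signed margin for the SVM (no
probability calibration); per split the pipeline records ROC-AUC (rank
estimator), PR-AUC (average precision) and F1 at the default decision
point — probability 0.5, equivalently margin 0 (margins are mapped
through the logistic wherever a probability-scale threshold is applied,
which keeps threshold semantics uniform and monotone across families).
ROC and PR curves are interpolated onto fixed 101-point grids and
aggregated as pointwise means with 2.5/97.5-percentile bands over the
repeats.

`selectModel()` picks one family per class: by mean ROC-AUC when the
class is relatively balanced, by mean PR-AUC when unbalanced. "Relatively
balanced" was never given a number in the source description, so the
cutoff is a documented default (positive fraction 0.25); ties break by
the other metric, then by the fixed family order (logistic regression,
trees, SVM). Final models (`fitFinal()`) are refit on all data and export
to self-describing JSON — family, hyperparameters, feature schema,
standardisation parameters, and coefficients or tree dump — so an
imported model reproduces predictions exactly, across machines, with no
binary state.

## The synthetic generator

`generateDataset()` emulates the study conditions end to end: a
31-channel 10-10 montage, 250 Hz sampling, 100 one-second epochs per
component, 200 components per class by default. Topographies are
parametric Gaussian patterns over standard 2-D cap coordinates — not
forward-modelled dipoles, which none of the features require — and each
class has a signal recipe anchored to its electrophysiology: occipital
8–12 Hz amplitude-modulated oscillation over 1/f noise (alpha); central
arch wave, 9–11 Hz fundamental plus a 2f harmonic (mu); broad dipole
with 1/f noise and mild 4–8 Hz content (brain); frontal-polar sparse
positive humps at 0.2–0.5 events/s (blinks); antisymmetric periocular
topography with smoothed gaze steps (horizontal eye movements);
edge-channel >20 Hz broadband bursts (muscle); low-spatial-contrast
topography with periodic QRS-like spikes at 1.0–1.5 Hz (heart); and a
single dominant channel (at least 80% of absolute weight mass) carrying
white noise (channel noise).

Two realism choices matter for interpreting results. First, per-component
amplitudes are drawn from wide ranges reaching down to near the
background level, and topomaps receive spatial leakage noise: a generator
with fixed amplitudes makes every class perfectly separable (ROC-AUC
exactly 1.0), which no real IC dataset shows. Second, a configurable
fraction of components can be convex mixtures of two class recipes with
both ground-truth labels — the mixed-nature components that motivate the
probabilistic vote in the first place. What the generator does *not*
emulate: volume conduction and realistic forward models, non-stationary
artifacts coupled across components, line noise, or annotator drift over
time. Passing tests on this corpus therefore demonstrate that the
pipeline's machinery is correct and that the features separate idealised
class phenomenology; they do not certify performance on any real
recording.

`generateAnnotations()` adds simulated experts in the two styles observed
in practice: *purists* report only the dominant activity (missing it with
rate $1 - \text{sensitivity}$, falling back to Uncertain) and *splitters*
report everything present plus spurious labels at a false-label rate.
Purist/splitter panels on mixed components reproduce the qualitative
strategy contrast: the probabilistic vote assigns fewer positive targets
than the majority vote.

## Numerical choices and degenerate inputs

* Thresholding: strict `>` after rounding probabilities to 12 decimals
  (see above).
* Zero-variance epochs are skipped by kurtosis (all-constant input is an
  error); constant epochs are skipped by the template correlations.
* A validation split whose test set is single-class is redrawn with an
  incremented sub-seed; classes with fewer than 2 positives or negatives
  are skipped with a warning.
* All randomness is driven by explicit integer seeds; generation,
  validation and the CLI are reproducible bit-for-bit given the seed.
* Interchange formats are plain delimited text (weights written at 15
  significant digits, signals likewise), so save/load is the identity
  within write precision and files stay diffable.

## Problem sizes used by the test suite

The packaged tests exercise the full pipeline at sizes chosen to make
the statistical checks sharp while keeping a complete run comfortable on
a single CPU: the vote-strategy oracle enumerates all two-expert,
two-class tables up to two components and checks three thousand further
random tables against a hand-rule oracle; the kappa oracle enumerates
every 2×2 rater table up to $n = 6$ and a 100-seed Fleiss null at 500
items; feature separations use 20 generator seeds with five components
per class; and the end-to-end recovery check uses the full 200-per-class
corpus (1400 components) with all 50 splits. These are the package's own
choices of problem size, stated here so results are interpretable.

## Known limitations

* The SED default convention is the literal reading of its one-sentence
  definition and is blind to antisymmetric saccade dipoles; switch to
  `diff_of_means` when that matters.
* Fleiss' kappa requires a complete rater panel per component; ragged
  panels must be subsampled by the caller.
* The per-class benchmark figures published for the real two-expert
  children's corpus (per-class kappas, per-class AUC tables) depend on
  that private annotated dataset and cannot be reproduced from this
  package alone; the synthetic corpus reproduces the qualitative
  pattern (strong Brain/Eyes/Muscle recovery, imbalance penalty on
  PR-AUC) but not those numbers.
* Boosted trees on very small training sets can split on uninformative
  features; the validation defaults (hundreds of components) avoid that
  regime.
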