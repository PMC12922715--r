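---
title: "Error consistency for speeded object recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error consistency for speeded object recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errcon)
```

## The problem

When two observers — two people, two image-classification models, or one of
each — classify the same natural images, their accuracies alone say little
about whether they process the images similarly.  Error consistency asks a
finer question: do they make their mistakes *on the same images*?  `errcon`
implements the full analysis for speeded n-alternative forced-choice
identification experiments: the agreement statistic and its stability
diagnostics, the stimulus corruption operators, superclass aggregation of
model outputs, psychometric fitting over presentation time, and a seeded
synthetic-data generator so that every stage can be exercised and tested
without any external data.

## The agreement model

Each observer's responses are reduced to a binary correctness sequence on
the shared items.  For a pair of observers the four joint outcomes form a
2x2 table \((n_{11}, n_{10}, n_{01}, n_{00})\).  Error consistency is
Cohen's kappa,

\[
\kappa = \frac{p_o - p_e}{1 - p_e},
\]

where \(p_o = (n_{11} + n_{00})/n\) is the observed agreement and the
expected agreement treats the observers as *independent binomial
responders* at their marginal accuracies \(p_1, p_2\):
\(p_e = p_1 p_2 + (1-p_1)(1-p_2)\).  \(\kappa = 1\) iff the sequences are
identical, 0 under chance agreement, and it is undefined when \(p_e = 1\)
(both observers all-correct or both all-wrong); `cohens_kappa()` signals a
classed error in that case rather than silently returning 0, and the
pairwise and bootstrap wrappers convert it to an explicit `NA`.

### Stability near ceiling

Because the denominator \(1 - p_e\) shrinks as accuracies approach 0 or 1,
a single changed response is amplified by \(1/(1-p_e)\) — a factor of 20
at \(p_e = 0.95\).  Two diagnostics quantify this:

* `kappa_max()`: with both marginals held fixed, observed agreement is
  maximised at \(p_o^{\max} = 1 - |p_1 - p_2|\), so
  \(\kappa_{\max} = (p_o^{\max} - p_e)/(1-p_e)\).  The closed form is not
  taken on trust: the test suite checks it against brute-force
  breadth-first enumeration of accuracy-preserving flip sets for every 2x2
  table with \(n \le 20\).
* `flips_to_kappa_max()`: the number of trials that would have to be
  flipped in one observer — always one correct together with one incorrect
  trial, so that the observer's accuracy is maintained — to reach
  \(\kappa_{\max}\).  Each such pair moves the table by
  \((+1,-1,-1,+1)\), so the distance is \(2\min(n_{10}, n_{01})\) flipped
  trials.  We count *trials* (two per pair) and expose the pair count as an
  attribute; `stability_flag()` marks a condition unstable when fewer than
  10 flipped trials would suffice.  The threshold of 10 is deliberately
  conservative; it is a default argument, not a constant.

```{r}
ag <- agreement(contingency_counts(96, 1, 1, 1))
ag
```

A near-ceiling pair like this one moves from \(\kappa \approx 0.49\) to
\(\approx 0.66\) when a single both-wrong trial is appended, while a
balanced pair at the same disagreement count barely moves — which is why
unstable cells must be flagged rather than averaged blindly.

### Bootstrap intervals

`bootstrap_kappa()` reports central percentile intervals (68% by default,
i.e. roughly one standard error) from paired resampling of trials: the
same item index is drawn for both observers, preserving the joint
structure.  Since kappa depends on trials only through their cell in the
2x2 table, the paired resample is realised as a multinomial draw of the
cell counts, which is distributionally identical and orders of magnitude
faster.  Resamples that land at \(p_e = 1\) carry no kappa; they are
dropped and the effective resample count is reported.  Coverage is checked
empirically in the test suite: across 500 simulated pairs with known
kappa, the 68% interval covers the truth at the nominal rate within
binomial tolerance.

## Corruption operators

The stimulus manipulations that induce classification errors are
deterministic-under-seed operators on `height x width x 3` arrays in
\([0,1]\):

* `add_uniform_noise()`: one uniform draw per pixel from
  \([-w, w]\) (default \(w = 0.5\)) added to all three channels, then
  clipped to \([0,1]\).  The phrase "added to all three channels" is read
  as a single achromatic noise field; `per_channel = TRUE` gives
  independent chromatic noise instead, since the text alone cannot decide
  between the two.
* `lowpass_filter()`: separable Gaussian convolution
  (\(\sigma = 5\) px default), truncated at \(4\sigma\) and renormalised
  (mass lost below \(10^{-4}\)), with the border padded by the constant
  experimental background gray 0.454, then clipped.
* `to_grayscale()`: fixed luma weights \((0.299, 0.587, 0.114)\); no
  standard weights are mandated by the experiment, so the common video
  luma convention is used.
* `pink_noise_mask()`: the backward mask; seeded Gaussian white noise
  shaped in the frequency domain by a \(1/f\) amplitude envelope (DC
  zeroed), inverse-transformed and min-max rescaled.  Its radially
  averaged log-log amplitude slope is \(-1.0\) within \(\pm 0.15\) at
  512 px.

Every operator preserves shape and range; noise at \(w = 0\) and blur at
\(\sigma \to 0^+\) converge to the identity.  Quantisation happens only in
the PNG I/O wrappers, never inside an operator.

## Superclass aggregation

Models that emit fine-grained class probabilities (e.g. 1,000 ImageNet
classes) are scored on the 8 basic-level superclasses (airplane, bear,
bicycle, bird, boat, car, dog, elephant) by *averaging* the probabilities
of each superclass's constituent fine classes
(`aggregate_probabilities()`).  The mean — not the sum — is the correct
aggregation under a shifted class prior at test time, so scores are not
renormalised before the argmax (renormalised scores are returned for
reporting).  Ties break by the fixed canonical label order, or
reproducibly at random.  `softmax_scores()` covers embedding-similarity
models that first need similarities turned into probabilities.  A small
editable two-column mapping file ships with the package
(`inst/extdata/toy_fine_to_super.tsv`); a full 1000-class map is a
user-supplied drop-in with the same format.

## Psychometric fitting

Performance as a function of presentation time is modelled on the log-time
axis (durations are strictly positive and psychophysics convention fits
duration-like variables on a log abscissa):

\[
\psi(x) = \gamma + (1 - \gamma - \lambda)\,
  \bigl[1 - e^{-e^{(\log x - m)/s}}\bigr],
\]

the reverse-Gumbel (log-Weibull) CDF oriented to increase with time.  The
guess rate \(\gamma\) is fixed by design (1/8 for the 8-way task, 1/2
after `collapse_to_animal_task()` merges the four animal and four
non-animal classes); the lapse rate \(\lambda\) is bounded to
\([0, 0.1]\) and given a Beta(1.5, 20) prior, making the fit a MAP
estimate: lapses should be rare but near-ceiling points must not force the
asymptote.  Optimisation is L-BFGS-B from five fixed deterministic starts;
all-ceiling or all-floor data raise a classed degenerate-fit error with
diagnostics.  `threshold_at()` inverts \(\psi\) at 60%, 75% or 90%
correct.  The fit is validated by parameter recovery on simulated
6-point curves (location recovered within three bootstrap standard
errors), not by matching any external toolbox output bit for bit.

## The synthetic-data generator

The generator exists so that every pipeline stage has realistic, fully
seeded inputs.

`simulate_binary_pair()` inverts the kappa formula: given marginals and a
target kappa, the implied both-correct cell is
\(p_{11} = (p_o + p_1 + p_2 - 1)/2\) with
\(p_o = \kappa(1-p_e) + p_e\), and trials are drawn i.i.d. from the
resulting 2x2 joint.  Targets outside the Frechet-derived
`feasible_kappa_range()` raise an error naming the valid interval.

`simulate_trial_table()` emulates the experiment's structure: sessions,
rounds, one block per presentation time (longest first), corruption sets
in fixed order, 48/96 images per set so that the default design yields
exactly \(2 \cdot 2\,(2\cdot3\cdot48 + 4\cdot3\cdot96) = 5{,}760\) trials
per observer, with 88 images allocated per class and time (44 at the two
extreme times), 22 (11) of them shared across corruptions.  The response
model is the key scientific ingredient: each image carries a latent
difficulty drawn once and *shared across human-like observers* — stimulus
heterogeneity is precisely what makes above-chance error consistency
possible — which shifts each observer's psychometric location.  "Model"
observers can load on an independent second difficulty axis; the loading
knob spans the gap between human–human consistency and human–model
chance-level consistency.  Wrong responses are uniform over the other 7
classes, a small fraction of trials miss the 800-ms response window
(`NO_RESPONSE`, scored incorrect by default, excludable by option — real
data do not dictate the choice, so both paths exist and are logged), and
reaction times follow a shifted lognormal that speeds up with presentation
time except for a fast guessing bump at the single-frame condition.  The
RT model is a qualitative stand-in whose only job is to make the median
split testable.

Because responses are conditionally independent given the difficulties,
the generator's implied pairwise kappa is computable exactly:
`analytic_condition_kappa()` integrates \(\psi_a \psi_b\) over the
difficulty distribution by Gauss–Hermite quadrature (41 nodes, two axes
when a model observer is involved) and maps through the kappa formula.
This closed analytic route is the oracle for the end-to-end tests: the
pipeline estimate must recover it within three bootstrap standard errors,
and human–model pairs must sit at chance.

### Default parameters

All generator defaults were fixed once, before any end-to-end runs, at
values a psychophysicist would call realistic for this task, and are not
tuned:

| parameter | default | meaning |
|---|---|---|
| `difficulty_sd` | 0.8 | SD of the latent per-image location shift (log-time units); yields pairwise human kappas in the 0.15–0.4 range at mid accuracies |
| `location` | 3.15–3.45 | log-ms psychometric locations (24–31 ms), matching rapid-recognition performance |
| `scale` | 0.55–0.65 | log-time psychometric scale |
| `lapse` | 0.02 | lapse rate |
| `corruption_shift` | 0 / 0.35 / 0.55 / 0.15 | location shift for none / noise / lowpass / grayscale; lowpass is hardest, as observed empirically |
| `p_no_response` | 0.01 | missed 800-ms deadlines |
| RT model | shift 150 ms, median 400 ms, sdlog 0.25 | shifted lognormal, faster at longer times |

All randomness flows from one root seed through a single RNG stream with a
fixed draw order (image allocation and difficulties first, then each
observer's trials in observer order), so tables are bit-reproducible.

## Numerical choices and degenerate inputs

* \(p_e = 1\) signals `errcon_undefined_kappa`; aggregation steps skip
  such pairs as `NA` and report them, never as 0.
* Kappa arithmetic is done from integer counts, so printed-precision
  checks (e.g. 0.96 vs 0.9604) are exact.
* The median split computes the median *within*
  (observer, time, corruption) cells — a global split would confound the
  RT cut with condition-level RT differences — and ties at the median go
  to the faster half.
* Strict item alignment is the default for pairwise consistency; the
  intersection of item sets is taken only under an explicit
  `align = "intersect"` flag (practice trials consume different images per
  observer, so intersection is the natural mode for generated studies with
  few rounds).
* Gaussian-blur padding uses the experimental background gray so that a
  uniform-background image is an exact fixed point of the filter.

## Problem sizes used in the tests

The checks run at deliberately desk-sized configurations chosen for
statistical power rather than scale: binary-pair calibration at
\(n = 10^5\) trials over a 3x3x3 (accuracy, accuracy, kappa) grid;
the end-to-end study with five observers, two times, two corruptions and
320 items per cell; bootstrap coverage over 500 replicates of 400-trial
pairs; oracle enumeration over all 10,625 contingency tables with
\(n \le 20\).

## What passing tests do and do not show

The generator reproduces the *structure* of a speeded identification
experiment — heterogeneous difficulty shared across observers, accuracy
rising with presentation time, corruption-dependent difficulty, a
median-splittable RT distribution — but not the content of real images,
real observers' lapses of attention, sequential dependencies, or learning
across sessions.  Passing the end-to-end recovery tests therefore shows
that the estimators are correct and calibrated under the stated model; it
does not by itself validate conclusions about any particular empirical
dataset.  Known limitations: kappa is deliberately not orthogonalised
against accuracy (two observers of very different accuracy genuinely are
less similar); no agreement coefficients beyond Cohen's kappa are offered;
and the MAP psychometric fit is a documented approximation rather than a
re-implementation of any specific toolbox's posterior machinery.
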