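---
title: "EEG channel selection with binary cuckoo search: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG channel selection with binary cuckoo search: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuckooEEG)
```

## The problem

EEG-based biometric identification asks: given multichannel scalp recordings,
which person produced them? Full montages (64 electrodes in the
motor/imagery setting this package emulates) are uncomfortable and slow to
fit, and many channels are redundant or noisy. Channel selection seeks a
small subset of electrodes that identifies people as well as — often better
than — the full montage.

`cuckooEEG` treats this as a wrapper feature-selection problem over channel
subsets. A candidate subset (a binary mask over channels) is scored by the
identification accuracy of a k-nearest-neighbour classifier under stratified
10-fold cross-validation, combined with a channel-reduction reward in a
weighted-sum multiobjective fitness. The subset space is searched with a
binary cuckoo search metaheuristic.

## The fitness

Each recording is represented by autoregressive (AR) coefficients per
channel, laid out in contiguous channel blocks so that masking a channel
removes its whole block. For a mask selecting $L$ of $d$ channels with
cross-validated accuracy $a \in [0,1]$:

$$\mathrm{Fit} = W_1\, a + W_2\left(1 - \frac{L}{d}\right),
\qquad W_1 + W_2 = 1,\; W_k > 0,$$

with defaults $W_1 = 0.8$, $W_2 = 0.2$. The reduction term is normalized so
the fitness always lies in $[0,1]$, equals $0.8a$ when every channel is
kept, and gains exactly $W_2/d$ per channel dropped at fixed accuracy. The
convention matters: rewarding the raw *count* of selected electrodes inside
a maximized objective would contradict the goal of a minimal montage, so the
reduction fraction $1 - L/d$ is used as the second objective.

Accuracy enters the fitness as the multiclass fraction correct, pooled over
the cross-validation folds. One-vs-rest confusion counts (true/false
acceptance, true/false rejection) are also pooled — each row is tested in
exactly one fold, so pooled counts equal the sum of per-fold counts — and
macro-averaged precision, recall, F-score and per-class accuracy are
reported alongside. Averaging macro metrics *within* folds was rejected:
with ~1 test recording per subject per fold, per-fold class denominators
are constantly zero.

Cross-validation folds are stratified by subject and fixed by a dedicated
fold seed, so every mask in a run is scored on identical folds and the
fitness is a deterministic function of the mask. Reports are memoized by
bit pattern because the metaheuristic revisits masks and cross-validation
dominates the cost. With `k = 1` (the default, conventional in biometric
identification) the evaluator uses a vectorized nearest-neighbour path —
one squared-distance matrix per mask; `class::knn` serves the general
`k > 1` case, and the two paths are tested for agreement.

## The optimizer

Binary cuckoo search maintains $N$ nests (default 30), each holding a
continuous position vector $x \in \mathbb{R}^d$, its binarized channel mask
and the mask's fitness report. Per iteration:

1. **Global walk.** Each position proposes
   $x' = x + \alpha \cdot \ell \odot (x - x_{best})$, with $\ell$ a vector
   of Lévy-distributed steps (Mantegna construction, exponent
   $\beta = 1.5$); the best nest itself takes a pure $\alpha\,\ell$
   perturbation. The proposal is binarized and scored, then compared
   against a *randomly chosen* other nest, which it replaces if strictly
   fitter.
2. **Local (abandonment) walk.** Every coordinate of every nest is, with
   probability $p_a = 0.25$, displaced along the difference of two other
   randomly chosen nests, scaled by a fresh uniform step; proposals replace
   their own nest greedily.
3. **Elitism.** The best-ever solution is tracked separately, so the
   convergence trace is non-decreasing by construction.

Binarization uses the sigmoid transfer function: bit $i$ is set when a
fresh uniform draw falls below $\sigma(x_i) = 1/(1+e^{-x_i})$. All-zero
masks are repaired by switching on one uniformly chosen bit, since an empty
channel set cannot be scored. The opposite comparison direction (bit set
when the draw *exceeds* the sigmoid), which appears in parts of the binary
metaheuristic literature, is available behind
`cs_config(transfer_direction = "printed")`; it inverts the meaning of
large positions and is not the default.

### Parameter defaults and the step scale

| parameter | default | meaning |
|---|---|---|
| `n_nests` | 30 | population size |
| `max_iter` | 100 | iteration budget |
| `p_a` | 0.25 | abandonment probability (per coordinate) |
| `beta` | 1.5 | Lévy tail exponent |
| `alpha` | 1 | step-size scale |
| `w1`, `w2` | 0.8, 0.2 | fitness weights |
| `k_neighbors` | 1 | KNN neighbourhood |
| `n_folds` | 10 | cross-validation folds |

Positions are initialized uniformly on $[-1, 1]$: the sigmoid discriminates
on the order-1 scale, so initial bit probabilities sit near $1/2$ and the
position *range* needs no upper bound tied to the channel count. The step
scale deserves a note: continuous cuckoo search is often quoted with
$\alpha \approx 0.01$ of the problem scale, but with positions of order 1
that choice makes the global walk numerically inert — positions never leave
the sigmoid's indifferent zone, masks are re-randomized at every
binarization, and the search degrades towards random sampling. We measured
this directly on planted 32-channel tables: mean best fitness 0.432 at
$\alpha = 0.01$ (barely above a matched random search at 0.406) versus
0.511 at $\alpha = 1$, which also converges with fewer unique evaluations
because committed positions re-propose identical masks. The default is
therefore $\alpha = 1$.

## The feature pipeline

Phase order: zero-phase band-pass (Butterworth order 4, default
0.5–50 Hz) plus a narrow band-stop notch (default 60 Hz, 2 Hz wide — the
emulated montage is US-recorded), optional wavelet denoising, then AR
coefficient extraction per channel, orders 5, 10 or 20 being the
conventional presets. Filtering is forward–backward with odd-reflection end
padding and mean removal, so there is no group delay and a constant input
maps to zero exactly.

AR coefficients are estimated by Burg's method (`stats::ar.burg`), the
standard choice for short EEG segments; Yule–Walker is available via
`method = "yule-walker"`. Denoising decomposes with a periodized orthogonal
Daubechies wavelet (`haar`, `db2`, `db4`; default `db4`, level 4) and
soft-thresholds detail coefficients at the universal threshold
$\hat\sigma\sqrt{2\log n}$, with $\hat\sigma$ the MAD of the finest details.
The transform is implemented in the package (periodized filter bank with
exact reconstruction, verified to $10^{-8}$ in the tests) and denoising is
off by default: it is a preprocessing option, not part of the contribution.

"Mean value of each electrode" is ambiguous between per-recording features
and per-subject means; both are provided
(`aggregate = "per_recording"` / `"mean_per_subject"`), with per-recording
rows as the default because 10-fold cross-validation needs multiple rows
per subject. Channels are 1-based in every user-facing output.

## The synthetic plant

Real 109-subject motor/imagery data cannot ship with the package, so
validation uses a *planted-channel* generator emulating its shape: many
subjects, a few recordings each, 64-or-fewer channels, and a known
informative subset $S^*$ carrying all subject identity.

Two surfaces are generated:

* **Signals** (`generate_signals`): channels in $S^*$ follow
  subject-specific stable AR processes — each subject draws reflection
  coefficients squashed through `tanh`, so `effect_size = 0` collapses
  everyone to the same white process — jittered per recording by Gaussian
  noise on the coefficients and re-stabilized by shrinking any pole back
  inside the unit circle. Channels outside $S^*$ share one AR process
  across subjects. Identity therefore lives exactly where the feature
  pipeline looks: in AR coefficients, not amplitude.
* **Feature tables** (`generate_feature_table`): the fast surface that
  bypasses signal synthesis. Informative columns get subject-specific
  Gaussian means, noise columns are pure noise.

`effect_size` is defined as the **total** multivariate separation budget:
per-column subject means have standard deviation
$\mathrm{effect\_size}/\sqrt{|S^*|\,p}$. This is deliberate. If the scale
applied per column, a single informative channel would saturate
identification, the channel-penalized fitness optimum would be a one-channel
mask, and "did the selector recover $S^*$?" would be unanswerable by
design. Under the distributed budget, accuracy grows steadily with each
informative channel selected and noise channels actively dilute the
distance metric, so recovering most of $S^*$ — and little else — is what
maximizes the fitness.

What the plant does *not* emulate: real EEG artifacts (blinks, line-noise
bursts, electrode pops), volume-conduction correlation between neighbouring
electrodes, non-stationarity across sessions, and realistic inter-subject
variability structure (no statistical characterization of it exists to
copy). Passing the planted-recovery studies therefore demonstrates that the
optimizer and objective do their job on data whose answer is known — not
that any particular accuracy will be reached on real recordings.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` recompute these studies from
scratch; sizes are chosen for a single desktop CPU:

* **Oracle agreement** — 7 channels ($|S^*| = 3$, AR order 2, 10 subjects
  × 12 recordings), search (15 nests, 100 iterations) vs exhaustive
  enumeration of all 127 masks, 20 seeds. The search should match the
  optimum fitness to $10^{-9}$ in ≥ 90% of seeds.
* **Planted recovery** — 32 channels, $|S^*| = 8$, effect size 3, 16
  subjects × 12 recordings, default optimizer, 10 seeds. Success: Jaccard
  index with $S^*$ ≥ 0.5 and accuracy within 0.05 of the all-channels
  mask; ≥ 80% of seeds.
* **Matched-budget superiority** — 16 channels, $|S^*| = 4$, search vs
  random masks at the identical number of unique fitness evaluations,
  20 paired seeds; the search should win ≥ 90%.
* **Chance-level control** — effect size 0, 10 subjects: mean
  cross-validated accuracy must sit within three Monte-Carlo standard
  errors of $1/10$. (It sits very slightly below $1/n$ by construction:
  under stratified folds a test row's own class is one training row short.)
* **Distributional checks** — empirical bit rates of the transfer function
  against $\sigma(s)$ at $s \in \{-2, 0, 1, 2\}$; Lévy tail mass beyond
  $|10|$ at least ten times the Gaussian counterpart; Burg recovery of
  known AR(2)/AR(5) coefficients within ±0.05 at $n = 20000$; Wilcoxon
  signed-rank closed forms (25 same-signed pairs give the maximal
  $|Z| = 4.3724$).

## Numerical conventions and edge cases

* Empty masks are impossible by repair; `weighted_fitness` refuses
  `n_selected = 0` as a contract violation.
* Exhaustive enumeration breaks fitness ties towards fewer channels, then
  towards the lexicographically smallest bit string.
* The Wilcoxon comparison drops zero differences, uses average ranks for
  tied magnitudes, and the *untied* normal-approximation variance without
  continuity correction — the convention under which all-same-signed
  $n = 25$ pairs give $|Z| = 4.3724$. Fewer than 5 pairs is an error.
* Rank summation uses dense ranking (ties share the better rank, the next
  method gets the following integer), ascending for channel count and
  descending for all other measures.
* Unstable AR polynomials arising from per-recording jitter are projected
  back to stability by shrinking poles to radius 0.95; generation fails
  loudly after bounded retries rather than emitting divergent signals.
* Accuracies are fractions internally; the `EEG_ACC` column of serialized
  reports is a percentage.

## Limitations

The weighted-sum scalarization explores only the convex part of the
accuracy/channel-count trade-off; a Pareto-front variant is out of scope by
design. The seven comparison metaheuristics from the surrounding literature
are likewise not reimplemented — `run_batch()` accepts any optimizer with
the `(features, obj_config, config)` signature, and a matched-budget random
search is provided as the honest baseline. Real-data preprocessing (EDF
parsing, artifact rejection) is a user-side step: the package consumes
delimited signal tables or ready feature tables.
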