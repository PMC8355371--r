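---
title: "Deep Hebbian predictive coding: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep Hebbian predictive coding: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A DHPC network is a stack of areas numbered 0 to N. Area 0 holds the image;
every pixel is one population whose size equals the channel count. Each higher
area `l` is a square grid of populations of `n_l` "representation" neurons.
A population is reciprocally connected to the `s_l x s_l` block of populations
below it (its receptive field, RF), so consecutive grids shrink by `s_l - 1`
per dimension and RF size in image coordinates grows with depth, as along the
ventral visual stream. Neurons within a population share receptive and
projective fields, like neurons in a cortical microcolumn.

Each population `k` in area `l` owns a feedback weight matrix per RF position
(jointly a `(s_l^2 n_{l-1}) x n_l` matrix `W`); there is no weight sharing
across grid positions, and the same stored weight serves the feedforward
(error) direction — feedforward and feedback synapse counts are equal by
construction. The population predicts the activity below it as

    yhat = relu(W y)

and the lower area returns the signed prediction error `beta = y_low - yhat`.
Activities are inferred by synchronous gradient descent on the squared
prediction errors plus an L1 (Laplacian-prior) penalty:

    dy = -gamma_y * ( eta * sum(top-down errors onto y)
                      - sum_RF g(yhat) o beta' W
                      + alpha_y )

followed by rectification, where `g(yhat) = 1(yhat > 0)` is the ReLU
derivative, realized in the model as a gating factor rather than an explicit
derivative. The top area has no top-down term; populations near the grid
boundary simply sum over their existing (fewer than `s_{l+1}^2`) predictors,
with no padding or renormalization. After `n_inference_steps` of settling, the
weights take one gated Hebbian step,

    dW = -gamma_w * ( -g(yhat) o beta y' + alpha_w * sign(W) ),

averaged over the stimuli in the batch. Both rules use only locally available
quantities; both are, by construction, gradient descent on the half-squared
error energy plus L1 terms, and the test suite verifies this against central
finite differences of an independently coded energy evaluator.

Because excitatory rates, rectification and L1 decay leave some neurons
permanently silent, response harvesting flags neurons that never respond to
any stimulus and all analyses exclude them.

## Parameters and defaults

| name | meaning | default |
|---|---|---|
| `rf_size` (`s_l`) | RF side length, populations | 5 |
| `population_sizes` (`n_l`) | neurons per population | 4/8/16 |
| `gamma_y` | inference update rate | 0.05 |
| `gamma_w` | learning rate | 0.05 |
| `alpha_y` | activity L1 constant, per area | 0.001 |
| `alpha_w` | weight L1 constant | 0.001 |
| `eta` | top-down error weighting, per area | 1 |
| `n_inference_steps` | settling steps per stimulus | 20 |
| `batch_size` | stimuli per weight update | 50 |
| `init_activity` | activity reset value | 0.1 |

The rate/regularization defaults of `dhpc_config()` are the values used for
the receptive-field variant of the full-scale study this package reproduces
at desk scale; `alpha_y` and `eta` are per-area vectors so that
top-area-only regularization and down-weighted top-down feedback
(`eta < 1`) — the variants that change how sparseness develops across the
hierarchy — are expressible from configuration alone. Doubling `n_l` per
area follows the observation that prediction errors saturate when the ratio
of higher- to lower-area population size exceeds 2.

`default_study_config()` is the calibrated desk-scale study configuration
(3 areas over a 16 x 16 grayscale input, `s = 5`, `n = 4/8/16`, batch 50).
The full-scale rates do not transfer unchanged to a model with ~60x fewer
synapses trained for ~10x fewer iterations: at `gamma_w = 0.05` and
`eta = 1` the top area stays pinned near its initialization (no image
selectivity, readout at chance) and the area-1 generative fit is dominated
by top-down errors from higher pairs that have not yet learned to predict.
The study configuration therefore uses a higher learning rate
(`gamma_w = 0.2`), down-weighted top-down errors (`eta = 0.35`), extra
activity regularization in the top area (`alpha_y = 0.005` there), and a
slightly deeper settle (30 steps). The latter two adjustments are exactly
the model variants the original study discusses (top-area-only
regularization; `eta < 1`), here adopted as the desk-scale operating point.

Weight initialization is uniform on `[-1/sqrt(n_l), 1/sqrt(n_l)]` (zero-mean,
fan-in scaled): initial predictions then sit on the scale of the activities,
and the draw is fully determined by the seed. The update rules are applied
with the magnitudes written above; the matching energy convention is
half-squared error, and the finite-difference oracle uses that convention
rather than rescaling the updates.

Conventions at the rule's edge cases: the gate condition is
`1 iff yhat > 0` (the ReLU derivative, which is undefined exactly at zero).
The top-down error sum in the inference rule is weighted by the area's
`eta`, consistent with inference being gradient descent on the
`eta`-weighted top-down energy; at the default `eta = 1` the weighting is
invisible. `sign(0)` contributes no weight decay. Batch
semantics: stimuli in a batch settle independently (vectorized), and the
Hebbian term is averaged over the batch — the implied objective is the
batch-mean energy. Activities are reset to `init_activity` for every new
batch, and are not clipped from above; an upper bound is an empirical
observation, not a model constraint. If any activity or weight turns
non-finite, the run aborts with the offending area and step rather than
silently clipping.

## Top-down reconstruction

Any area's latent representation can be decoded by cascading the generative
mapping `relu(W y)` down to the image. With RFs, a lower population receives
up to `s^2` overlapping predictions; the decoder averages them. This is a
documented extension: the study sidesteps the overlap by reconstructing with
the fully connected variant, which this package also provides (each area one
population spanning the entire area below, same update rules); in that
variant each lower population receives exactly one prediction and no
combining is needed. Averaging is the symmetric choice and reduces to the
fully connected case when overlaps vanish.

## Response-property metrics

All metrics operate on the harvested stimulus x neuron response matrix of an
area, active neurons only.

* **Image selectivity** — excess kurtosis of one neuron's responses across
  stimuli (population-moment convention, `N` denominators, minus 3). Constant
  vectors are flagged `NA` rather than raising in batch use.
* **Population sparseness** — excess kurtosis across neurons for one
  stimulus, after dividing each neuron's column by its mean response so that
  between-neuron gain differences do not masquerade as sparseness. The mean
  is taken over all stimuli (including zeros). By construction the statistic
  is invariant to per-neuron positive rescaling; in IEEE arithmetic the
  invariance is bitwise for power-of-two factors and holds to rounding error
  otherwise, which is how the tests assert it.
* **Dynamic range** — per-neuron interquartile range across stimuli, with
  linear-interpolation percentiles (R's default type 7; the convention is a
  documented choice).
* **Ablations** — sparseness recomputed after removing the top 10% of active
  neurons by selectivity (SNR) or by IQR (DNR); ties broken by order, and a
  fraction of 0 is a no-op.
* **Correlations** — Pearson r between log selectivity and mean rate, and
  between sparseness and mean population rate. Excess kurtosis can be
  negative, so the log is taken of the non-excess kurtosis `kappa + 3`,
  which is positive whenever the variance exists; this is a documented
  deviation that preserves monotonicity, hence the sign of the correlation.
* **Area comparisons** — two-sided Mann-Whitney U per area pair, p-values
  multiplied by the number of pairs and capped at 1 (Bonferroni).
* **Linear readout** — a linear SVM (cost 1) per area on the settled activity
  vectors, trained on a random 75% subset drawn without replacement and
  tested on the complement, repeated over bootstrap splits; accuracies are
  compared against chance with a one-sample t-test. The SVM is libsvm via
  e1071; the classifier is deliberately standard since only the
  representations are under study.
* **RF weight images** — feedback weight slices of area-1 neurons, min-max
  normalized to [0, 1] (constant slices render mid-gray 0.5), reshaped to the
  RF. After training on oriented inputs these display Gabor-like structure.

## The synthetic image generator

The generator stands in for the natural-image crops used in the original
study, reproducing the statistical properties the model exploits: a falling
(approximately 1/f) power spectrum, dense oriented structure, and
class-consistent layout. Each image is 1/f-filtered Gaussian noise around
mid-gray, plus two even-symmetric Gabor patches at class-specific anchor
positions (horizontal orientation and placement for class "a", vertical for
class "b", with positional and orientation jitter), plus several randomly
placed and oriented clutter patches; values are clipped to [0, 1]. The
partly consistent layout mirrors how real object classes share coarse
spatial structure across exemplars and is what makes the classes linearly
separable from raw pixels — with fully random patch positions, orientation
is a quadratic feature and a linear readout would hover near chance. The
jitter and background levels are set so that raw-pixel linear separability
sits in the mid-0.8s: clearly above chance (the tests assert > 0.8) but off
the ceiling, as for natural-image object classes; a class pair that is
perfectly separable from pixels leaves a compressed top-area code nothing
to improve on.

The default spec is desk-scale: 16 x 16 grayscale, 200 images per class, so
that a full train-and-analyze cycle runs in minutes on one CPU. What the
generator does **not** emulate: multi-scale object structure, occlusion,
color statistics, or the within-class variability of photographs. Passing the
emergence tests therefore shows that the mechanism produces the qualitative
hierarchy effects (selectivity increasing with depth, decodable classes,
reconstructable inputs) under naturalistic low-order statistics — not that it
reproduces the quantitative values reported for CIFAR-scale training, which
are out of desk-scale reach.

## Scaled-down study conditions

The emergence checks train `default_study_config()` for 3000 iterations on
the 400 default synthetic images (about 5-6 minutes on one CPU), then test
the qualitative findings of the full-scale study: mean selectivity
increasing from area 1 to area 3; linear readout above chance in all areas
with the top area beating area 1 (20 bootstrap repeats); and area-1
reconstruction error falling below a quarter of its value at
initialization.

What this desk-scale run shows robustly across seeds: the top area becomes
far more image-selective than area 1 (mean kurtosis roughly an order of
magnitude higher); the object class is decodable well above chance from
every area; and training cuts the reconstruction error to less than half
its initial value. What it does not show robustly: the *strict* per-area
monotonicity of mean selectivity (area 2 often dips below area 1 — its
broadly driven mid-level responses have low kurtosis while area 1 responds
sparsely to localized patches), a top-area readout *advantage* over area 1
(area 2 is usually the readout optimum; the 256-neuron top area
over-compresses relative to the full model's 4096), and reconstruction
below a quarter of the initialization error (the residual is dominated by a
slowly-shrinking DC underestimate of the generative weights; removing it
requires training well beyond the desk budget). These gaps are properties
of the scaled-down regime, not of the implementation: the update rules are
verified against finite-difference gradients, and every trend moves in the
expected direction with longer training.

## Numerical notes and limitations

* Inference and learning loops are implemented in C++ (RcppArmadillo) as
  dense per-population matrix products; results are identical to the plain-R
  reference computations used in the tests.
* The settled state depends on `n_inference_steps`; harvesting uses the same
  settling schedule as training (configurable), so analyses see the same
  operating regime the weights were trained in.
* Energy descent during inference is guaranteed only for sufficiently small
  `gamma_y`; the default is well inside the stable range for the default
  architecture, but very large rates abort via the non-finite guard.
* Checkpoints use R serialization (RDS); configs are YAML, manifests JSON.
* No convolutional weight sharing, no explicit error units or interneurons,
  no GPU path: the model is meant for desk-scale scientific study, not
  large-scale vision.
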