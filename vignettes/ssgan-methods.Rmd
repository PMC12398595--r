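---
title: "Semi-supervised GANs for melanoma features: model, training and tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised GANs for melanoma features: model, training and tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(melanogan)
```

## The model

`melanogan` trains a binary melanoma / non-melanoma classifier from a
partially labeled pool of feature vectors using a semi-supervised GAN.
The discriminator $D$ emits probabilities over three classes —
melanoma, non-melanoma, and *fake* — so every kind of sample teaches it
something:

* labeled real samples drive the supervised cross-entropy
  $L_{D,\mathrm{sup}} = -\mathbb{E}\,\log p_m(\hat y = y \mid x)$;
* real samples must not land in the fake class and generated ones must:
  $L_{D,\mathrm{usup}} = -\mathbb{E}_{x \sim p_d}\log(1 - p_{\mathrm{fake}}(x))
  - \mathbb{E}_{x \sim G}\log p_{\mathrm{fake}}(x)$;
* the generator tries to escape the fake class:
  $L_{G,\mathrm{usup}} = -\mathbb{E}_{x \sim G}\log(1 - p_{\mathrm{fake}}(x))$.

Four mechanisms extend this baseline, each individually switchable from
configuration (this is how the "without X" ablations are produced —
there are no code forks):

1. **Reconstruction loss** (generator): with $D_F$ the discriminator
   minus its final layer, $L_r = \mathbb{E}_x \lVert G(D_F(x)) - x
   \rVert_2$ and $L_G = L_{G,\mathrm{usup}} + \lambda_r L_r$. Because
   the generator must be able to reproduce *every* real sample from its
   encoded features, it cannot collapse onto a few modes.
2. **Self-attention** (both networks): one scaled dot-product head,
   $\mathrm{softmax}(QK^\top/\sqrt{d_k})\,V$ with learned $W_Q, W_K,
   W_V \in \mathbb{R}^{d \times d_k}$, applied to the minibatch treated
   as $n$ tokens of dimension $d$. We set $d_k = d$ and wrap the head in
   a residual connection ($\mathrm{out} = X + \mathrm{attn}(X)$), so
   zeroing the three weight matrices turns the block into an exact
   identity — the attention ablation is exact, and the "feature
   dimension unchanged" property holds by construction.
3. **Consistency regularization** (discriminator):
   $L_{\mathrm{cons}} = \mathbb{E}\lVert p_m(\cdot\mid x) -
   p_m(\cdot\mid \tilde x)\rVert^2$ where $\tilde x$ is an augmented
   copy of $x$.
4. **Confidence-based pseudo-labeling** (discriminator): unlabeled rows
   whose largest *real-class* probability reaches $\tau$ contribute
   cross-entropy on that predicted label. Restricting the argmax to the
   two real classes is a deliberate reading: a "fake" pseudo-label for a
   real image is meaningless, and an unrestricted argmax would let the
   adversarial term recruit confident-fake rows into supervised
   training.

The total discriminator objective is
$L_D = L_{D,\mathrm{sup}} + L_{D,\mathrm{usup}} +
\lambda_c L_{\mathrm{cons}} + \lambda_p L_{\mathrm{pseudo}}$.

After training the generator is discarded; classification is the argmax
over the two real classes, and the ROC score renormalizes the fake class
away: $s(x) = p_{\mathrm{mel}}/(p_{\mathrm{mel}} + p_{\mathrm{non}})$.

## Architecture choices that were genuinely open

* **Where attention acts.** The source description places the
  generator's attention on the input noise and the discriminator's on
  the incoming feature vector, so both networks apply the residual
  attention block to their raw input before the MLP.
* **$D_F$ versus the noise width.** $G(D_F(x))$ requires the encoder
  output to match the generator input. Nothing fixes the penultimate
  width to the noise size, so the discriminator ends in a linear
  projection to exactly `noise_size` units; this is the single
  architectural addition, and it doubles as the feature map used by the
  classification head.
* **Hidden widths.** Only layer *counts* are tuned; all hidden layers
  share one `hidden_width` knob (default 64 at desk scale) to keep the
  free structure minimal.
* **Masking rule.** During the discriminator step, an unlabeled real row
  enters the first term of $L_{D,\mathrm{usup}}$ only while the current
  model classifies it as fake. The indicator is recomputed from the
  current minibatch predictions each step and treated as a constant
  under differentiation (a stop-gradient), like the pseudo-label
  selection.
* **Optimizer and schedule.** Adam with separate generator/discriminator
  learning rates; one discriminator step then one generator step per
  minibatch; fixed epochs, no early stopping. The training source is
  silent on all three; these are the conventional choices.
* **Reconstruction pairs** are the same real minibatch used in the
  discriminator step, encoded with dropout off (the encoder is a frozen
  feature extractor from the generator's point of view).

All gradients are hand-derived (reverse mode through the attention
block, the MLP stacks and the three loss heads) and verified against
central finite differences in the test suite to ~1e-6.

## Numerical choices

* Probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$ before logs; the
  adversarial losses are undefined at 0/1.
* The reconstruction gradient divides by $\max(\lVert\cdot\rVert_2,
  10^{-12})$ to stay defined at exact reconstruction.
* Softmax is computed with max-subtraction; inputs of any magnitude are
  safe.
* Dropout is inverted (scaling by $1/(1-p)$ at train time), so
  evaluation forwards are deterministic, pure functions.
* Training aborts with the offending term named if any loss goes
  non-finite.

## The synthetic world

Real use consumes image embeddings from a pretrained extractor (the
plug-in point is any function producing an $n \times d$ matrix; no
weights ship with the package). Desk-scale development and testing use
`ring_mixture_spec()`: 8 isotropic Gaussian modes (sd 0.5) on a ring of
radius 4 in the first two of $d = 16$ dimensions, classes interleaved
around the ring, 30% of the mass on the melanoma class, observation
noise sd 0.1, 70/15/15 stratified splits, and 30% of training rows
labeled. This reproduces the statistical features the method assumes —
two imbalanced classes, strong multi-modality within each class (lesion
subtypes), a labeled/unlabeled split, additive noise — and is rich
enough to exhibit real mode collapse in an unregularized generator.

What it does not emulate: the anisotropic, heavy-tailed geometry of real
VGG embeddings, label noise, domain shift between acquisition devices,
or any image-space structure. A green test on this world establishes
that the mechanisms work as specified, not that the headline accuracies
on dermoscopy benchmarks are reproduced; those require the real images
and GPU-scale budgets and are out of scope here.

The augmentation behind consistency regularization is additive Gaussian
noise in feature space (`aug_sigma`, default 0.1): flips and rotations
have no meaning for feature vectors, and noise is one of the listed
admissible transformations. The augmentation scale used in the original
experiments is not reported, so it is an explicit configuration knob.
Likewise τ (default 0.9) is the conventional high-confidence threshold;
the source does not state its value.

## Class imbalance

Imbalance is handled by data-level oversampling: labeled minority rows
are duplicated (sampling with replacement) until the labeled classes
balance, before training. The losses themselves are unweighted — class
weighting and focal variants belong to the baselines this method is
compared against, not to the method.

## Random-key tuning with the mutual-learning bee colony

The tuner encodes each configuration as a genome in $[0,1]^D$:
continuous and integer parameters use one gene mapped affinely onto
their range (integers round half-up; the published best values are
integers but no rounding rule is stated), and a categorical parameter
with $K$ options uses $K$ genes decoded by argmax. The argmax rule is
adopted because the two prose descriptions of categorical decoding
contradict each other (one sorts descending, the worked figure sorts
ascending and would always select the first option as written); argmax
is the standard random-key selection variant, is invariant under any
strictly increasing transform of the sub-vector, and makes decoding
total — every point of the unit box is a valid configuration, which is
what lets a box-constrained metaheuristic search freely.

The colony alternates employed, onlooker and scout phases with greedy
replacement and a trial counter per food source (`limit` failures →
uniform re-initialization). Following the conventional ABC update, a
proposal modifies one randomly chosen coordinate. The mutual-learning
rule replaces the classic blind perturbation with a fitness-guided move:
the candidate starts from the worse of the (current, neighbor) pair and
moves toward the better one by $\varphi \sim U(0, F)$. An all-dimension
version of the same rule was evaluated first and rejected: moving every
coordinate into the segment spanned by the pair contracts the colony
prematurely (on the 10-dimensional sphere the median best objective
stalls near 0.7, versus ~$10^{-8}$ for the single-coordinate rule). $F$ defaults to 1;
larger values reduce update variability but can destabilize the
exploration/exploitation balance.

Because the onlooker roulette wheel needs positive weights while the
fitness being maximized may be negative, probabilities use the classic
transform $\mathrm{fit} = 1 + f$ for $f \ge 0$ and $1/(1 - f)$
otherwise — monotone in $f$, so selection pressure is preserved.

The model-tuning fitness is the validation F-measure of a short-budget
`train_ssgan()` run with a fixed per-evaluation seed; the scalar being
optimized is not named in the source, and F-measure is the headline
metric it reports. Configurations that diverge score 0 rather than
aborting the search.

## Distribution metrics

No formulas are given in the source for the four generator-quality
metrics, so standard estimators are used, with their knobs logged:

* **MMD** — square root of the unbiased RBF-kernel two-sample
  statistic, median-heuristic bandwidth on the pooled squared
  distances. The unbiased statistic can be marginally negative at
  finite $n$; it is clamped at 0 before the root.
* **KLD** — $k$-nearest-neighbour estimator of
  $\mathrm{KL}(\mathrm{real}\,\|\,\mathrm{fake})$ ($k = 5$), clamped
  at 0.
* **WD** — sliced Wasserstein-1: 64 random unit projections, exact 1-D
  transport per slice via the CDF-difference integral.
* **Mode score** — the synthetic world doubles as the oracle: the
  posterior over modes is the Gaussian responsibility under the known
  `mixture_spec`, and the score is
  $\exp(\mathbb{E}_{x \sim G} \mathrm{KL}(p(y|x) \| \bar p_{\mathrm{real}})
  - \mathrm{KL}(\bar p_{\mathrm{fake}} \| \bar p_{\mathrm{real}}))$,
  normalized by the number of modes so it lies in $(0, 1]$ — 1 for a
  generator matching real mode coverage with sharp assignments, near
  $1/K$ for collapse onto one of $K$ modes. The normalization is this
  package's choice (the unnormalized score is bounded by the mode
  count); only relative comparisons are meaningful across packages.

## Tolerances, budgets, known limitations

* Desk-scale property checks (mode-collapse mitigation, the
  semi-supervised gain) train at a reduced budget of 20 epochs,
  5 seeds, $n = 4000$; medians over seeds are compared. Single-seed GAN
  runs are noisy — occasionally a full-model seed underperforms its
  supervised twin — which is why the claims are median claims.
* One known blind spot of the ring world: with mode sd 0.5 and radius 4
  the classes are nearly separable, so classification metrics saturate
  near 0.99 and differences between ablation variants are small; the
  generator-side metrics (mode score, MMD) are the sensitive
  instruments at this scale.
* Checkpoints serialize weights as JSON at 17 significant digits, which
  round-trips IEEE doubles exactly; training is bit-reproducible given
  the config seed (one seed fans out to per-stage streams via a fixed
  integer scheme, kept below $2^{31}$).
* The printed FNR definition in the source ("FNR = 1 − FNR") is a
  self-referential typo; the package implements FNR = 1 − TPR, which is
  consistent with every TPR/FNR pair in the reported tables.
* The epoch search range starts at 64, but the training API accepts any
  positive count: the desk-scale tests and the tuner's short-budget
  evaluations legitimately train for far fewer; strict range checking
  is available separately (`check_table2()`) and is applied by the
  pipeline, and the tuner's decode guarantees in-range values by
  construction.
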