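---
title: "Angular-margin supervised contrastive learning: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angular-margin supervised contrastive learning: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amcontrast)
```

## The model

A double-viewed batch takes N labelled source images, applies two
independent stochastic augmentations to each, and stacks the 2N views as
`[first views; second views]`, so the sibling of view *i* is *i + N* (an
involution, enforced everywhere). The network is Enc → {Proj, Class}: a
convolutional encoder produces a representation *r*, normalized to the unit
hypersphere; a 2-layer perceptron projection head maps *r* to a unit-norm
*z* consumed only by the contrastive loss; a linear classifier on *r*
produces class scores and is the entire inference path (the tests assert
that scrambling the projection head cannot change predictions).

Three contrastive losses share one code path. The self-supervised form
treats only the sibling view as positive. SupCon widens the positive set
P(i) to every view with the anchor's label, dividing by |P(i)|. The
angular-margin form converts inner products to angles,
θ = arccos(z_i · z_a), and adds a margin before re-entering the cosine:
m_u for the anchor's augmented positive (the set U(i), always exactly one
view, because the framework generates exactly two views per source), m_v
for same-label positives V(i), nothing for negatives. Since cosine falls
with angle, a margined positive must close a larger gap to score the same
similarity, and m_u > m_v orders the two kinds of positives by intended
closeness. All three losses report the **mean over the 2N anchors** rather
than the sum, so values are comparable across batch sizes; the brute-force
oracles and every documented spot value use the same convention.

The training objective adds cross-entropy on the class scores of **both**
views (2N terms — both views pass through the classifier) to λ times the
contrastive loss, and takes one Adam step per batch. Model selection is the
epoch with the best validation accuracy, ties to the earlier epoch;
validation choice (accuracy rather than AUC or loss) is a package decision.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| m_u | 0.2 | radians | margin of the augmented positive |
| m_v | 0.1 | radians | margin of same-label positives |
| τ | 0.05 | — | softmax temperature; smaller sharpens weighting |
| λ | 1 | — | weight of the contrastive term in the combined loss |
| batch N | 64 | images | doubled to 2N views |
| lr | 2e-4 | — | Adam step size (full-scale default) |
| epochs | 20 | — | full-scale protocol |
| image size | 64 | px | configurable; 224 at full scale |

Margins are additive angles, so they only make sense while θ + m ≤ π;
the implementation clamps the sum at π (see below) and the margin-grid
ablation harness keeps m_u between 1× and 3× m_v, where larger multiples
degrade the loss for exactly this reason.

## Numerical choices

* Inner products are clamped to [−1 + ε, 1 − ε] with ε = 1e-7 before
  `acos`, keeping the angle derivative finite; log-sum-exp with max
  subtraction stabilizes every denominator. A consequence worth knowing:
  the derivative of the penalized similarity, sin(θ+m)/(τ sin θ), grows
  like 1/θ as a positive pair approaches coincidence — margins actively
  sharpen gradients near perfect alignment, and at the clamp boundary the
  gradient is defined as 0 (the clamped branch is constant). These are
  measure-zero boundaries; finite-difference checks validate the gradient
  everywhere else.
* θ + m is clamped at π before the cosine, so the penalized similarity
  stays monotone in θ; without the clamp, cos would wrap around and reward
  pushing a positive past the antipode.
* The identical-batch spot value: an all-identical 2N = 4 batch with one
  label gives log 3 ≈ 1.0986 for the plain losses, and with
  (m_u, m_v, τ) = (0.2, 0.1, 0.05) the closed form
  (1/3)[log(1 + 2e^Δ) + 2 log(2 + e^{−Δ})], Δ = (cos 0.1 − cos 0.2)/τ,
  ≈ 1.1082 for the margin loss — the acos clamp perturbs this case by
  O(1e-3), which the tests allow for.
* Uniformity is the log of the mean kernel over **all M² ordered pairs,
  self-pairs included**: the definition is an expectation over i.i.d.
  draws, and including self-pairs keeps the double-loop oracle and the
  vectorized path trivially identical.
* Cross-entropy consumes probabilities; the binary branch evaluates
  −log p or −log(1−p) directly so certainty (p ∈ {0, 1}) is exact rather
  than NaN.
* Degenerate metric denominators (a class never predicted, or absent from
  the truth) contribute 0 to macro precision/recall with a warning, and
  absent classes are skipped by macro one-vs-rest AUC — stable behaviour
  on the tiny label sets that short runs produce. Multiclass metrics use
  **macro** (unweighted) averaging and one-vs-rest rank-based AUC with
  midranks; rank statistics make AUC exactly invariant under monotone
  score transforms.

## The stratified splitter

Each class of size n is split 70/15/15 deterministically: the held-out
count is round-half-even(0.3 n), validation is round-half-even of half the
holdout, test is the remainder, and a seeded within-class shuffle decides
membership. This rule reproduces, cell for cell, the published per-grade
partition of the five-grade reference dataset with class sizes
(1805, 370, 999, 193, 295) — e.g. n = 370 → (259, 56, 55) and
n = 295 → (207, 44, 44) — which is the acceptance check. For the second
reference dataset in the literature two rows are off by one under *any*
single deterministic rounding rule, so counts there should be compared
within ±1; the splitter stays deterministic rather than emulating what was
likely a shuffled allocation. Splitting is done once per dataset and
reused across tasks; binary stratification pools grades 1–4.

## Augmentation

Supported operators: random-resized-crop (area scale, default (0.8, 1.0)),
horizontal and vertical flips (p = 0.5), random grayscale (p = 0.2),
colour jitter (brightness/contrast/saturation, strength 0.4) and rotation
(±30°). Crop scale and flip probabilities follow the full-scale training
protocol; the grayscale/jitter/rotation parameters are package defaults
that exist for the augmentation-pair ablation harness, which trains one
short run per unordered operator pair (single operator on the diagonal)
and reports a symmetric AUC matrix. Every view's augmentation is driven by
a seed derived from the batch seed, so batches are bit-reproducible.

## The synthetic generator, and what passing tests mean

`generate_fundus_like()` draws an orange, radially shaded disc on a dark
background and scatters lesion marks inside it — bright exudate-like spots
and dark hemorrhage-like blobs of 2–4 px radius — with the count drawn
uniformly from a per-grade range: (0,0), (1,3), (4,7), (8,11), (12,16)
for grades 0–4. The ranges are non-decreasing by construction and grade 0
is lesion-free, so class-conditional structure exists and grows
monotonically with severity; mild Gaussian pixel noise (σ = 0.02) is
added. The generator emulates exactly one property of real fundus data —
lesion load increasing with DR grade — and none of the others: no vessel
trees, no optic disc or macula, no camera vignetting, no inter-patient
variability, no label noise. Tests passing on this fixture therefore
demonstrate that the losses, gradients, training loop and metrics behave
as specified on a learnable class-conditional imaging task; they say
nothing about clinical performance on real photographs, and the published
full-scale accuracies are explicitly not reproduction targets here.

## Desk-scale study conditions

The encoder for CPU-scale work is a small CNN: 3×3 stride-2 convolution
blocks with channels (8, 16, 32, 64), each followed by batch normalization
and a rectifier, then global average pooling (D_E = 64), a projection head
with hidden width 128 and D_P = 128, and the linear classifier. Batch
normalization (running statistics for inference, so evaluation is
deterministic) and centring of the [0,1] pixel input are what make a
from-scratch CNN trainable in a few hundred steps; without them the
combined objective at τ = 0.05 can drive a weak encoder into a collapsed,
zero-gradient configuration. The full-scale option in the literature — a
residual backbone with D_E = 2048 and a 2048-hidden projection — is
expressible through `model_spec()` but is not exercised by the tests.

The behavioural experiment mirrored by the tests and the acceptance script
uses 200 synthetic images (40 per grade, 64×64), batch N = 32, Adam at
2e-3, 300 steps, alignment and uniformity logged every 10 steps, three
fixed seeds. Under these conditions the mean batch alignment over the
logged tail is lower with margins (0.2, 0.1) than with SupCon (margins
zero) in at least two of three seeds — the package's analogue of the
full-scale observation that margins pull positives closer — and training
accuracy exceeds 80% in a majority of seeds, confirming the fixture is
learnable, not that the margin improves accuracy at this scale. These
problem sizes were chosen as the smallest at which the effect is stable;
per-step losses, per-epoch validation reports and the logged
alignment/uniformity trail are all retained in the fitted object
(`plot()` draws them).

## Design decisions taken where the design was open

* **Single-stage joint training** of encoder, projection and classifier on
  L_ce + λ L_a−m, rather than the two-stage contrastive-then-linear
  protocol of the original SupCon work: the combined objective trains both
  heads together by construction.
* **Anchor reduction is the mean over all 2N views**; the sum would merely
  rescale λ's meaning with batch size.
* **The classifier reads r, not z**, and both augmented views contribute
  cross-entropy terms.
* **U(i) is exactly the sibling view**: multi-view (>2) batches are
  rejected by the pairing validator rather than silently accepted.
* **Margin-grid degeneracy**: at multiplier 1.0 (m_u = m_v) the loss is
  SupCon-*like* — every positive is margined equally — but not numerically
  equal to SupCon; only m_u = m_v = 0 reduces to SupCon exactly, and the
  harness tests check both facts.
* **Encoder pretraining is off**: nothing in the framework requires
  pretrained weights, and determinism from a seed is worth more here.
* L2 normalization to the unit hypersphere is used throughout; a
  scale-to-[0,1] reading of "normalization" is incompatible with the
  arccos of cosine similarity and is not implemented.

## Known limitations

* Pure-R training is CPU-bound: roughly 0.15 s per 64-view step at 64×64;
  full-scale runs (224×224, batch 64, 20 epochs) are out of reach and out
  of scope.
* The margin gradient near θ = 0 is intrinsically steep (the 1/sin θ
  factor); very small batches or aggressive learning rates can still
  destabilize training even with batch normalization.
* Macro averaging and one-vs-rest AUC are fixed conventions; weighted
  averaging is not offered.
* JPEG input requires EBImage; PNG is read natively.
* Uniformity on small batches is dominated by the M self-pairs, biasing
  it towards 0; comparisons should hold M fixed.
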