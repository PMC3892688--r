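---
title: "Methods: automated developmental-stage annotation of embryo expression images"
author: "stagefly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated developmental-stage annotation of embryo expression images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagefly)
```

## The problem

In-situ hybridization images of *Drosophila melanogaster* embryos capture
where a gene is expressed, but comparing expression patterns is only
meaningful between embryos at a similar developmental time. Embryogenesis
is conventionally divided into morphological stages 1–17; large image
collections, however, are annotated only with coarse stage *ranges*.
`stagefly` annotates individual standardized images (grayscale,
128 × 320 pixels, lateral view, anterior left) with:

* a specific **stage** `S` in {3, …, 17} (stages 1–3 are morphologically
  indistinguishable at this imaging resolution — the only difference is
  nuclear count — and are collapsed into the single label 3);
* an early/late **sub-stage** flag (`E`/`L`) for interior stages 4–16;
* a continuous **stage score** `SS` in `[S − 0.5, S + 0.5]` used to order
  embryos within a sub-stage;
* optionally, **thirds** (`a`/`b`/`c`) of each sub-stage cohort by sorted
  stage score.

The package assumes its inputs are already size- and
orientation-standardized; segmentation, alignment and view classification
are out of scope.

## Texture features

Each image is filtered with a bank of log-Gabor filters — Gaussian
transfer functions on a *logarithmic* radial-frequency axis and Gaussian
in orientation:

$$G(r, \theta) \;=\; \exp\!\left(-\frac{(\log (r/f_0))^2}{2\,(\log \sigma_{r}/f_0)^2}\right)\,
\exp\!\left(-\frac{(\theta - \theta_0)^2}{2\sigma_\theta^2}\right)$$

Log-Gabor filters have no DC response and localize texture jointly in
space and frequency, which suits this task: stages differ both in gross
morphology and in fine texture (e.g. germ-band position during
mid-embryogenesis). The bank crosses 4 scales with 6 orientations,
giving 24 filters. The per-pixel modulus of the complex (in-phase +
quadrature) response is the "Gabor image"; the modulus is the standard
phase-invariant texture-energy choice.

Each of the 24 Gabor images is divided into 640 sub-blocks of 8 × 8
pixels and represented by the block means; concatenating the 24
down-sampled images yields a feature vector of dimension
24 × 640 = 15 360. The ordering contract is fixed: feature
`(k−1)·640 + b` is region `b` (row-major) of Gabor image `k`
(scale-major).

Filter-bank defaults — minimum wavelength 3 px, scale multiplier 2.1,
$\sigma_r/f_0 = 0.55$, angular sigma 0.66 of the π/6 orientation spacing —
are the canonical general-purpose log-Gabor settings from the texture
literature. They place the four center wavelengths at roughly 3, 6.3,
13.2 and 27.8 px, covering fine stripes through gross morphology at the
128 × 320 scale. All are exposed as arguments of `log_gabor_bank()`.

## Sparse linear classifiers

With one feature vector $x_i \in \mathbb{R}^{15360}$ per image and far
fewer training images than features, the package uses regularized binary
linear classifiers,

$$\min_{w, b}\; \mathrm{loss}(w, b) + \mathrm{penalty}(w),$$

wrapped one-vs-rest over the 15 stages (prediction = largest decision
value, ties toward the smaller stage). Seven configurations are
available — a hinge-loss linear SVM with ridge penalty, and the
least-square and logistic losses crossed with three sparsity-inducing
penalties:

* **Lasso** ($\ell_1$): selects individual features;
* **group Lasso** ($\ell_1/\ell_2$ over groups): each image region
  contributes one feature per filter, so features partition naturally
  into 640 groups of 24 — the group penalty selects whole *regions*;
* **sparse group Lasso** ($\ell_1 + \ell_1/\ell_2$): selects regions and,
  within kept regions, individual filters.

### Solvers and numerical choices

The smooth-loss problems are solved by accelerated proximal gradient
(FISTA) with backtracking line search and a monotone safeguard (an
iterate that would increase the objective is rejected and momentum
restarted, so the accepted objective sequence is non-increasing). The
initial step is $1/L$ with $L$ the loss-gradient Lipschitz constant
estimated by power iteration on the augmented design. The proximal
operators are closed-form: soft-thresholding ($\ell_1$), block
soft-thresholding (group), and their composition, which is the exact
proximal operator of the sparse-group penalty. In one-vs-rest fits the 15
binary problems share the design matrix, so they are solved as one
matrix-valued FISTA iteration (the steps are separable per class; sharing
the iteration turns 15 matrix–vector products into one matrix–matrix
product). Default convergence: relative objective change below 1e−6 or
1000 iterations; non-convergence flags the model rather than erroring.

The hinge-loss SVM is solved exactly by dual coordinate descent with
random sweep order, the standard large-scale linear-SVM algorithm. The
intercept is carried as an augmented constant feature and therefore
shares the ridge penalty — the usual linear-SVM formulation; for the
smooth losses the intercept is unpenalized. Its stopping rule is the
largest projected gradient over a sweep.

Penalty strengths are not cross-validated: each binary problem uses
$\lambda = 0.01\,\lambda_{\max}$, where $\lambda_{\max}$ is the smallest
strength that zeroes the solution (the largest (group) norm of the loss
gradient at $w = 0$ with the intercept at its unregularized optimum).
This keeps pool construction reproducible and puts every member at a
comparable, problem-relative operating point; the sparse-group penalty
sets both strengths equal. Features are z-scored per training split
(training mean/sd applied to validation and later inputs) so penalties
act on comparable scales.

## The classifier pool and voting

A pool crosses the 7 algorithms with 5 training ratios (50–90%) × 30
stratified random train/validation partitions = 1050 members; partitions
are shared across algorithms so algorithm disagreement is measurable on
identical splits. Each member's **confidence** $a^i$ is its multiclass
accuracy on its own validation part. Splits are stratified by stage so
no class disappears from a training part (the generic failure mode is
still handled: such a member is excluded from voting and logged).

For a new image, every member casts one vote for its predicted stage,
weighted by $a^i$, giving the histogram
$H(j) = \sum_i a^i p^i_j$ with $p^i$ the member's one-hot prediction.
Then:

* stage: $S = \arg\max_j H(j)$ (ties toward the smaller stage);
* sub-stage (4 ≤ S ≤ 16): `E` if $H(S{-}1) > H(S{+}1)$, else `L`
  (tie counts as late — a deterministic, documented convention);
* stage score:
  $SS = S + \tfrac{1}{2}\,\frac{H(S{+}1) - H(S{-}1)}{H(S{-}1) + H(S{+}1)}$,
  with $SS = S$ when both neighbours are empty.

The score formula is a declared convention: it is the unique
antisymmetric form linear in the neighbour ratio that stays within half a
stage, equals $S$ for symmetric neighbours, and decreases as the early
neighbour gathers relatively more votes. It is recorded in output
metadata; scores order embryos *within* a sub-stage and are not
calibrated across stages (a score of 7.9 is not necessarily closer to
stage 8 than 6.7 is to 7).

Thirds: within each (stage, sub-stage) cohort, images sorted by stage
score are split into three equal groups `a`/`b`/`c` (remainders to the
earliest groups; stable sort, ties keep input order).

## Evaluation criteria

Three nested accuracies: **sub-stage accuracy** (exact stage + E/L),
**stage accuracy** (stage only), and **plus-minus-sub-stage accuracy**
(within one half-stage on the axis `2·stage + [0 for E, 1 for L]`). Edge
stages carry no sub-stage; they are scored at stage resolution and sit
one half-step from their only neighbouring sub-stage (stage 3 below 4E,
stage 17 above 16L) — edge behaviour under the sub-stage criteria is a
package convention, chosen so the three criteria remain nested. A
reference label lacking an E/L flag on an interior stage sits between its
own two halves, so either sub-stage of the correct stage is accepted by
the ±½ criterion.

## The synthetic-data generator

Real annotated corpora of this kind are external databases; the package
therefore ships a generator whose outputs exercise every pipeline
component with known ground truth. Each image draws a latent
developmental time $t \in [0, 1]$; the generator's 15 stages occupy
equal sub-intervals, with E/L the lower/upper half of each. Appearance
changes monotonically with $t$ through two channels chosen to map onto
the two feature mechanisms:

* a striped texture whose spatial frequency interpolates from 0.04 to
  0.18 cycles/px (wavelengths 25 → 5.5 px, inside the filter bank's
  sensitive band) — exercising the scale channels;
* a dark expression band whose anterior–posterior position interpolates
  from 25% to 75% of the image width — exercising region selection by
  the group penalties.

The texture is mean-centred inside the elliptical embryo mask and
constant along rows, so its optical mass is exactly symmetric about the
image centre; the band is then the only asymmetric component and the
column centroid of inverted intensity is strictly monotone in $t$, which
is what the expression-map monotonicity checks rely on. Pixel noise is
Gaussian (default sd 0.05, a moderate level relative to the 0.5-deep
band) and clipped to `[0, 1]` rather than renormalized, keeping
intensities bounded without rescaling the signal.

What passing on synthetic data does *not* show: real embryo images have
staining variability, partial-pattern expression (many genes express in
restricted domains), focus and illumination artifacts, and
between-embryo morphological variation — none of which the generator
emulates. Synthetic results validate the machinery (features, solvers,
voting, ordering), not field performance on microscope images.

## Expression maps

A stage (or sub-stage, or score-bin) composite is built by inverting
intensities (staining is dark-on-light, so signal becomes high),
averaging pixelwise, and min–max rescaling per map. Min–max rescaling is
a declared choice: it makes composites from groups of very different
sizes contrast-comparable at the cost of absolute intensity
comparability. Series are emitted in developmental order; a well-behaved
corpus shows the composite signal centroid progressing monotonically
along the anterior–posterior axis.

## Problem sizes and defaults used in validation

The shipped validation runs use a training corpus of 15 stages × 40
images and a reduced pool of 7 algorithms × 2 ratios (0.7, 0.8) × 3
partitions = 42 members, evaluated on an independently seeded held-out
set of 10 images per stage. The two ratios sit in the middle of the
50–90% design, where validation accuracy has been observed to saturate;
three partitions per ratio already average over split noise. Pool
training caps the proximal solvers at 200 iterations (tolerance 1e−5)
and the SVM dual solver at projected-gradient 0.01 — pool members are
deliberately many and approximate, and voting does not reward solving
each member past the accuracy of its validation estimate. Exact-solve
settings (tolerance 1e−13, iteration caps in the tens of thousands) are
reserved for the solver-vs-oracle equivalence checks on small instances.

## Known limitations

* Inputs must be pre-standardized; nothing corrects rotation, scale or
  non-lateral views.
* Pool members store dense weight matrices; a full 1050-member pool at
  d = 15 360 is ~2 GB in memory. The reduced pools used here are ~80 MB.
* Vote confidences are validation accuracies, not calibrated
  probabilities; no ensemble pruning is implemented.
* The stage score orders embryos within a sub-stage only; it is not a
  calibrated developmental clock.
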