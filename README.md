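# stagefly

Automated developmental-stage annotation for standardized *Drosophila
melanogaster* embryo gene-expression images.

High-throughput in-situ hybridization collections record where genes are
expressed in the embryo, but most images carry only coarse stage-*range*
labels (e.g. "stages 4–6"), even though expression comparisons are only
biologically meaningful between embryos at similar developmental time.
`stagefly` annotates each standardized image (grayscale, 128 × 320 px,
lateral view) with a specific stage, a finer early/late sub-stage, and a
continuous stage score for ordering embryos along developmental time. It is
aimed at curators and analysts of expression-image databases, and at anyone
who wants the underlying sparse-ensemble machinery (log-Gabor features,
group-sparse linear classifiers, confidence-weighted voting) as reusable R
functions.

## Method in brief

1. **Features.** Each image is filtered with a log-Gabor bank
   (4 scales × 6 orientations; transfer function
   `G(r,θ) = exp(−(log(r/f₀))²/(2(log σᵣ/f₀)²)) · exp(−(θ−θ₀)²/(2σ_θ²))`,
   zero DC response). Each of the 24 Gabor magnitude images is reduced to
   640 means over 8 × 8 blocks; concatenation gives a 24 × 640 = 15 360-dim
   feature vector whose coordinates partition into 640 region groups of 24.
2. **Classifiers.** Binary linear models `min loss(w, b) + penalty(w)` in
   seven flavours: a hinge-loss linear SVM (ridge penalty, dual coordinate
   descent) and least-square/logistic losses with Lasso, group-Lasso or
   sparse-group-Lasso penalties (FISTA with backtracking and exact proximal
   operators), wrapped one-vs-rest over stages 3–17 (stages 1–3 are
   indistinguishable at this imaging resolution and collapse to label 3).
3. **Pool + voting.** The algorithms are crossed with stratified random
   train/validation partitions at several training ratios (7 × 5 × 30 = 1050
   members at full size). Each member votes for one stage, weighted by its
   validation accuracy `aⁱ`, giving a histogram `H(j) = Σᵢ aⁱ pⁱⱼ`. The
   annotation is `S = argmax H`; the neighbour ratio refines it into an E/L
   sub-stage and the stage score
   `SS = S + ½·(H(S+1) − H(S−1))/(H(S−1) + H(S+1)) ∈ [S−½, S+½]`.
4. **Evaluation & maps.** Three nested accuracies (sub-stage, stage,
   ±sub-stage), and stage-wise expression-map composites (inverted,
   averaged, min–max rescaled) for visualizing global expression change
   over developmental time.

A synthetic embryo-image generator (latent developmental time drives both a
texture frequency and the position of a dark expression band) makes the full
pipeline testable end-to-end with known ground truth.

## Worked example

Train a small pool on synthetic images of stages 7–11 and annotate noisier
query images:

```r
library(stagefly)

corpus <- generate_corpus(synthetic_spec(n_per_stage = 12, stages = 7:11,
                                         noise_sd = 0.05, seed = 42))
feats <- featurize_images(corpus$images)
spec <- pool_spec(algorithms = c("lasso_logistic", "sparse_group_ls",
                                 "svm_hinge_l2"),
                  ratios = c(0.6, 0.8), n_partitions = 3, master_seed = 7)
pool <- build_pool(feats$X, corpus$labels$stage, spec, groups = feats$groups)
print(pool)
#> <model_pool: 18 members (0 excluded), 5 classes, 15360 features>
#>   confidence: median 0.900, range [0.700, 1.000]

query <- generate_corpus(synthetic_spec(n_per_stage = 2, stages = 7:11,
                                        noise_sd = 0.12, seed = 43))
ann <- assign_thirds(annotate_images(pool, featurize_images(query$images)$X))
ann[, c("image", "stage", "substage", "stage_score", "top3_stages", "top3_votes")]
#>           image stage substage stage_score top3_stages      top3_votes
#>  synthetic_0001     7        L         7.0      7;11;3    13.02;2.88;0
#>  synthetic_0002    11        L        11.0      11;8;7 10.78;2.56;2.56
#>  ...
#>  synthetic_0006     9        L         9.5     9;11;10 12.38;2.56;0.96
#>  synthetic_0007    10        L        10.5     10;11;3    12.14;3.76;0
```

Each row gives the voted stage, the E/L refinement, the continuous stage
score (`9.5` means the votes for stage 10 pulled this stage-9 embryo to the
late edge of its stage), and the three top-voted stages with their
confidence-weighted vote mass for audit. Scoring against the generator's
ground truth:

```r
evaluate_annotations(ann, data.frame(stage = query$labels$stage,
                                     substage = query$labels$substage))
#> <evaluation_report, n = 10>
#>   sub-stage accuracy (exact stage + E/L): 0.5000
#>   stage accuracy:                         0.8000
#>   plus-minus-sub-stage accuracy:          0.8000
```

On an easy, low-noise corpus most members agree, so histograms concentrate
and many scores sit at stage centres; heavier noise or harder corpora
spread the votes and the scores. `build_gem_series()` then aggregates
annotated images into stage-ordered expression-map composites, and
`write_gem_series()` exports them as PNGs with a manifest.

A thin command-line wrapper with subcommands `simulate`, `featurize`,
`train-pool`, `annotate`, `evaluate` and `gem` is installed at
`system.file("scripts", "stagefly", package = "stagefly")`.

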