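# lemap — local extremum mapping for weakly supervised lesion analysis

`lemap` implements **local extremum mapping (LEM)**: a classification
head for convolutional networks that classifies an image from the
*local extrema* of its score map, and localizes lesions by propagating
those extrema back to pixel level — all under weak supervision
(image-level benign/malignant labels only, no pixel annotations).

The intended users are researchers in medical image analysis who want
a transparent, fully testable reference implementation of
extremum-based weak supervision: every component — the head, the
sparse loss, the training loop, the excitation-style backpropagation —
is plain R, exercised end-to-end on a bundled synthetic lesion
benchmark with pixel ground truth.

## The method

A backbone produces a feature map `M` (C×W×H); a 1×1 projection with
weights `V` yields the **score map**

    S[i,j] = Σ_c M[c,i,j] · V[c]        (no activation; scores are signed)

The sigmoid of `mean(S)` is exactly the classical GAP classifier.
LEM instead flags the local maxima and minima of `S` under
boundary-clipped neighbourhoods (4/6/9 cells, centre included) and
aggregates only those:

    a_m = Σ smax·max(S,0),   a_b = Σ smin·min(S,0)
    y_lem = σ( (a_m + a_b) / n_extrema )

Training minimizes the blend
`J = α(μ·L_spa + L_lem) + (1−α)·L_gap + (λ/2)‖θ‖²`, where the sparse
loss `L_spa` eliminates wrongly signed extrema and confines non-salient
scores to `(−τ, τ)`, and `α` ramps from GAP-dominated (0.1) to
LEM-dominated (1.0). For localization, the extrema selected by the
predicted class are propagated top-down through positive-weight ×
activation fractions, normalized per neuron so each extremum delivers
unit mass to the pixels; the resulting importance map is thresholded
and scored by Dice and recall against the ground-truth mask.

See the methods vignette
(`vignettes/local-extremum-mapping.Rmd`) for the full model, the
parameter table, and the design choices.

## Worked example

```r
library(lemap)

train <- lem_simulate(400, image_size = 64, seed = 11)
test  <- lem_simulate(100, image_size = 64, seed = 12)
print(train)
#> Synthetic lesion dataset: 400 images (200 malignant, 200 benign), 64x64 px, seed 11

fit <- lem(train, lem_benchmark_config(seed = 1))   # ~2 min on one CPU
print(fit)
#> LEM fit: 400 training images (64x64), 30 epochs
#> LEM backbone: 64x64 input, 3 conv blocks (8-16-32 channels), 8x8 score map, 5921 parameters
#> final objective 3.3344 (l_lem 0.3116, l_gap 0.2632, l_spa 30.2107) at alpha=1.00

lem_evaluate(fit, test)
#> LEM evaluation on 100 images
#>   accuracy 0.880, AUC 0.937
#>   mean DSC 0.241, mean recall 0.156

im  <- test$images[[which(lem_labels(test) == 1)[1]]]
loc <- localize(fit, im)
print(loc)
#> LEM localization: y_lem=1.000, 1 extrema propagated (max), mass 1.0000 (conserved)
binarize_and_score(loc$map, im$mask)$dsc
#> [1] 0.44
```

Reading the output: the fitted model classifies held-out synthetic
images at AUC 0.937 from image-level labels alone; for the shown
malignant image one positive score-map maximum is selected and
propagated, its unit importance mass lands on the lesion
(`mass 1.0000 (conserved)`), and the binarized map overlaps the
ground-truth mask with Dice 0.44. `mean DSC` is the unweighted mean
over all 100 test images, both classes included.

The same pipeline is available from a shell:

```sh
Rscript inst/scripts/lem-cli.R generate --n 100 --size 64 --seed 7 --out data/
Rscript inst/scripts/lem-cli.R train    --data data/ --out run/
Rscript inst/scripts/lem-cli.R localize --checkpoint run/checkpoint.rds --data data/ --out loc/
```

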