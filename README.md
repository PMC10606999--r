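# simexplain

Explainable image similarity for biological and general image collections:
a Siamese verification network that scores how similar two images are,
Grad-CAM saliency that shows *why*, and a heatmap-driven crop-refinement
pass that cleans distracting context out of training images.

Typical users are researchers comparing labeled image collections — skin
lesions, flowers, tissue patches, room scenes — who need a similarity
score they can interrogate rather than trust blindly.

## The model

Two weight-sharing convolutional branches embed the images of a pair; the
Euclidean distance between the embeddings passes through a one-neuron
sigmoid head, giving the output *d* ∈ (0, 1). The similarity reported to
the user is

&nbsp;&nbsp;&nbsp;&nbsp;*s* = 1 − *d*,

and a pair is called same-class when *d* < threshold (0.5 by default).
Training minimizes the contrastive loss

&nbsp;&nbsp;&nbsp;&nbsp;L = ½ (1 − y) D<sub>w</sub>² + y · max(0, m − D<sub>w</sub>)²,

with pair label y (0 = same class, 1 = different) and margin m = 2, using
Adam on pairs built two-per-anchor (one same-class mate, one
different-class mate).

Each decision is explained at the last convolutional layer by Grad-CAM:
neuron importance weights α<sub>k</sub> = (1/Z) Σ<sub>ij</sub> ∂y/∂A<sub>ijk</sub>
(the spatially pooled gradients of the target scalar with respect to the
layer's activation maps A<sub>k</sub>), combined as
ReLU(Σ<sub>k</sub> α<sub>k</sub> A<sub>k</sub>). The **factual** heatmap
targets the model output *d*; the **counterfactual** heatmap targets
1 − *d* (equivalently, negated gradients) and highlights the regions that
would push the decision the other way. Both branches of a pair get both
maps. The convolutional forward/backward passes are implemented in the
package itself, so the saliency gradients are exact and are tested against
finite differences.

The crop-refinement pass turns explanations into better data: for each
training image with a confidently similar same-class mate (similarity
strictly above 80%), the factual heatmap is binarized at half its maximum,
the largest 8-connected component's bounding box is taken, and the image
is replaced by that crop.

## Worked example

```r
library(simexplain)

# a 5-class synthetic dataset with known discriminative regions
gen   <- generate_shape_dataset(synthetic_spec(seed = 1))
split <- stratified_split(gen$dataset, test_frac = 0.2, val_frac = 0.1, seed = 1)
fit   <- train_siamese(split, train_config(epochs = 10, seed = 1))

pairs <- build_pairs(split$test, seed = 2)
evaluate_pairs(fit$model, split$test, pairs, threshold = 0.5)
#> pair_metrics on 80 pairs (40 similar / 40 dissimilar), threshold 0.50
#>   accuracy 0.9125  AUC 0.9894  macro precision 0.9255  macro recall 0.9125

# score and explain one pair (two held-out red discs)
a <- split$test$images[[6]]
b <- split$test$images[[7]]
forward_pair(fit$model, a, b)$d
#> [1] 0.1392     # similarity s = 1 - d = 86.1%, called "same" at 0.5
ex <- explain_pair(fit$model, a, b, mode = "factual")
heatmap_to_bbox(ex$a)                  # where the model looked on image a
#> bounding_box [x 34:59) [y 29:55)
```

The accuracy line says 73 of the 80 held-out pairs were called correctly
at the 0.5 cut, and the AUC near 1 says the score ranks almost every
similar pair above every dissimilar one. The bounding box is the region
of concentrated factual saliency — on this synthetic data it should frame
the class-defining shape, which is exactly what `refine_dataset()` crops
to. (Numbers above are from the shown seed; other seeds vary slightly.)

A command-line wrapper covering the same pipeline
(`synth | train | evaluate | explain | refine`) is installed at
`inst/cli/simexplain.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "simexplain.R", package = "simexplain"))')" \
    synth --out run --data-root run/data --seed 1
```

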