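# heartseg

Fully automatic segmentation of the heart in 2-D short-axis cardiac MR
frames: the left-ventricular (LV) blood pool, the LV myocardium and the
right-ventricular (RV) blood pool are labeled in one pass by a residual
encoder-decoder convolutional network. The package is aimed at researchers
working on cardiac cine MR post-processing — in particular free-breathing,
real-time acquisitions, where manual contouring of end-diastolic and
end-systolic frames is the bottleneck of function analysis — and at anyone
who wants a fully inspectable, dependency-light reference implementation
of this class of segmenter: every layer, the back-propagation and the
optimizer are implemented in the package (R + compiled kernels), not
wrapped from a deep-learning framework.

Label convention everywhere: `1` background, `2` RV blood pool, `3` LV
myocardium, `4` LV blood pool.

## The method

The segmenter is a U-Net-style encoder-decoder built from residual blocks
(two 3x3 convolutions and a 1x1 shortcut, each followed by batch
normalization, joined by ReLU(main + shortcut)), with 2x2 max pooling down
a 4-level encoder (widths 24-48-96-192, bottleneck 384 with dropout 0.5),
a 2x2 transposed-convolution decoder with skip concatenations, and a 1x1
SoftMax head to K = 4 classes — 4.57 million trainable parameters, against
31.0 million for the standard 64-filter U-Net baseline that is also
provided (`build_unet_baseline()`).

Training minimizes a generalized Dice loss

    Loss = 1 - 2 (Σ_k w_k Σ_m Y_km T_km + ε) / (Σ_k w_k Σ_m (Y_km² + T_km²) + ε)

whose class weights w_k = 1/Σ_m T_km counter class imbalance, and — the
key refinement — remain finite when a class is absent from the ground
truth (apex slices have no RV; some datasets are partially labeled): an
absent class is weighted by the predicted mass assigned to it,
w_k = 1/(Σ_m Y_km + ε), ε = 1e-8. The classical inverse-square weighting
(`gdl_weights()`), which is infinite in that situation, and pixel-wise
cross-entropy are included as comparison arms. Evaluation is per-class
Dice = 2|Y∩T|/(|Y|+|T|) and IoU = |Y∩T|/|Y∪T| with explicit empty-class
rules.

The schedule follows the published recipe: ADAM, learning rate 1e-3
decayed by 0.98 per epoch and restored every 100 epochs, L2 weight decay
1e-4, minibatch 16 (drop-last), He initialization, per-epoch shuffling,
on-the-fly random augmentation (affine, elastic, Gaussian noise/blur —
never written to disk), and best-model selection on validation mean Dice.

A built-in phantom generator (`generate_phantom()`) synthesizes SSFP-like
short-axis frames — bright blood, gray wall, dark background, bias field,
noise, apex/mid/base slice modes, ED/ES phases, respiratory shifts — so
the entire pipeline trains and evaluates end-to-end on one CPU with no
data download. See the methods vignette
(`vignettes/heartseg-methods.Rmd`) for the model, the loss, all defaults
and the generator's scope.

## Worked example

Train the reduced demonstration network (base width 8, 3 levels, 126,796
parameters) on 128 synthetic mid-ventricular phantoms for 15 epochs —
about six and a half minutes on one CPU — and evaluate the 32 held-out
frames:

```r
library(heartseg)

dir <- tempfile()
man <- generate_dataset(160, phantom_config(), seed = 11, out_dir = dir,
                        splits = c(0.8, 0.2, 0), slice_mode = "mid")
tr  <- load_dataset(man, split = "train")
va  <- load_dataset(man, split = "valid")

net <- build_network(net_spec(base_width = 8, levels = 3), seed = 1)
fit <- train(net, tr, va,
             train_config(epochs = 15, loss = "igd", augment = TRUE,
                          seed = 1),
             verbose = TRUE)
#> ...
#> epoch  14  lr 7.69e-04  train loss 0.3098 dice 0.624  valid loss 0.1945 dice 0.668
#> epoch  15  lr 7.54e-04  train loss 0.2908 dice 0.713  valid loss 0.1756 dice 0.786

evaluate_dataset(fit$net, va)
#> Segmentation metrics (per-class means over included images):
#>   RV          Dice 0.443  IoU 0.286  (n=32, excluded=0)
#>   Myocardium  Dice 0.941  IoU 0.889  (n=32, excluded=0)
#>   LV          Dice 0.942  IoU 0.890  (n=32, excluded=0)
#>   Mean        Dice 0.775  IoU 0.688
```

After 120 optimizer steps the wall and cavity are segmented at Dice 0.94;
the RV — distinguishable from the LV blood pool only by its position, and
therefore always the last structure to appear (see the methods vignette on
the dead-class dynamic of Dice-family losses) — has emerged and reached
0.44, still climbing steeply when the schedule ends. `excluded` counts
frames where a class is absent from both prediction and ground truth
(apex slices), which do not enter the means.

Segment and inspect any image with `predict()` and `write_overlay()` (LV
red, myocardium green, RV blue):

```r
lab <- predict(fit$net, tr$images[[1]])
write_overlay(gray_image(tr$images[[1]] * 255, "8"), lab, "overlay.png")
```

The same pipeline is scriptable from a shell through the bundled
executable (`system.file("cli", "heartseg", package = "heartseg")`) with
subcommands `phantoms`, `preprocess`, `train`, `segment`, `evaluate` and
`summary`.

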