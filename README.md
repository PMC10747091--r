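# retinasign

Contrast self-regulation for images, modeled on mammalian retinal
photoreceptors, feeding a static sign-gesture classification pipeline.

Vision systems that classify hand gestures degrade sharply in poor
lighting: dark scenes pile their histogram into a few intensity levels and
both hand detectors and classifiers lose the structure they need.
`retinasign` addresses this the way the retina does. The outer plexiform
layer (photoreceptors, horizontal and bipolar cells) is modeled as a
frequency-domain low-pass filter

    F_ph(fs, ft) = 1 / (1 + β_ph + 2 α_ph (1 − cos 2π fs) + j 2π τ_ph ft)

whose output is the local-luminance map `L(m,n)`. Each pixel then adapts
by a Michaelis–Menten saturating response,

    C = R (V_max + R0) / (R + R0),    R0 = V0 · L + V_max (1 − V0)

which amplifies dark regions while leaving bright ones near their value
(defaults: `V0 = 0.7`, `V_max = 255`, `β_ph = 0`, `α_ph = 1`, `τ_ph = 1`).
On top of the enhancement sit:

* a 21-point hand-landmark skeleton rasterizer with a pluggable detector
  interface (a deterministic synthetic stub ships with the package);
* a dataset builder producing the three training variants — **V1** raw,
  **V2** enhanced, **V3** enhanced + landmark skeletons on black —
  standardized to 50×50 grayscale;
* a small convolutional network (16·2×2 → 32·3×3 → 64·5×5 convolutions
  with max-pooling to 1×1×64, a 128-unit hidden layer, SoftMax over 29
  classes; 68,045 trainable parameters), with training implemented in
  vectorized R;
* per-class precision/recall/F1/support evaluation reports;
* deterministic synthetic fixture generators (dark-biased scenes,
  separable gesture glyphs, hand landmarks) so everything runs without an
  external dataset;
* a command-line interface
  (`Rscript inst/cli/retinasign.R <subcommand> …`).

Intended users: researchers experimenting with bio-inspired preprocessing
in recognition pipelines, and anyone needing a dependency-light, fully
reproducible testbed for low-light contrast enhancement.

## Worked example

```r
library(retinasign)

# a severely under-exposed synthetic scene: 90% of pixels below 31
scene <- gen_dark_scene(fixture_spec(seed = 3))
enh   <- enhance(scene)   # Table-1 defaults: V0 = 0.7, beta = 0, alpha = 1
c(mean(scene), mean(enh))
#> [1] 24.93744 53.47446
c(shannon_entropy(scene), shannon_entropy(enh))
#> [1] 5.307461 6.647507
```

The enhanced scene's mean intensity more than doubles (24.9 → 53.5) and
its histogram entropy rises by 1.3 bits — dark-packed mass has been spread
across the usable range while already-bright pixels stay put.

```r
net <- build_network()   # 29 classes
layer_parameter_counts(net)
#> conv1 conv2 conv3   fc1   fc2
#>    80  4640 51264  8320  3741
count_parameters(net)
#> [1] 68045

ds <- gen_gesture_dataset(fixture_spec(seed = 7, samples_per_class = 20))
ds$images <- lapply(ds$images, resize_area, size = c(50, 50))
sp  <- split_dataset(ds, 0.2, seed = 7)
net <- train_network(net, sp$train, train_config(epochs = 10, seed = 7))
mean(predict_dataset(net, sp$test) == sp$test$labels)  # held-out accuracy
#> [1] 1
```

The same flow is available from a shell:

```sh
Rscript inst/cli/retinasign.R gen-fixtures --out fx --seed 7 --classes 29 --per-class 20
Rscript inst/cli/retinasign.R build-dataset --src fx --variant V2 --out v2
Rscript inst/cli/retinasign.R train --data fx --variant V2 --out model.ckpt --seed 7
Rscript inst/cli/retinasign.R evaluate --model model.ckpt --data fx --variant V2 --out report.csv
```

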