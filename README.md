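# rfctsr

Low-dose CT super-resolution reconstruction with regression random forests
and coupled dictionary learning.

## The problem

Reducing the radiation dose of a CT scan raises image noise and artifacts,
which can obscure diagnostic detail. `rfctsr` restores a quarter-dose CT
image toward full-dose quality by *learning* the mapping between registered
low-dose (LD) and high-dose (HD) image pairs, instead of relying on generic
interpolation or hand-designed priors. It is aimed at researchers in medical
image restoration who want a self-contained, reproducible, CPU-only
implementation that can be trained and evaluated entirely on synthetic
phantom data.

## The method

Images are processed as overlapping 8&times;8 patches. For a patch with LD
feature vector `x_L` (first- and second-order derivative responses) the
model predicts the HD detail `x_H` (the HD patch minus the LD patch mean):

* **Regression forest.** `T` binary trees route `x_L` by thresholded split
  functions `delta(x, Theta) in {0, 1}` (0 iff `r_Theta(x) < 0`). Candidate
  splits at each node are scored by the weighted child impurity
  `Q = |X_L| E_L + |X_R| E_R` with
  `E(X_L, X_H) = mean(||x_H - m(x_L)||^2 + k ||x_L - mean(x_L)||^2)`,
  a label-space residual plus `k` times the data-space scatter. Each leaf
  stores the closed-form ridge regression
  `W^T = (Psi^T Psi + eta I)^{-1} Psi^T X_H` over basis-expanded features
  `Psi(x) = [1, x]`, and the forest prediction averages the `T` leaf-model
  outputs. Defaults: `T = 10`, maximum depth 15, `eta = 0.01`, `k = 1`.
* **Coupled dictionaries.** An LD dictionary `D_L` and HD dictionary `D_H`
  sharing one sparse code matrix `E` are learned by alternating ISTA sparse
  coding and MOD least-squares updates of the jointly weighted objective
  `(1/D_L)||X_L - D_L E||^2 + (1/D_H)||X_H - D_H E||^2 + lambda ||E||_1`.
  At inference the forest output is cleaned by sparse coding against `D_H`
  (`l1` sparse-consistency reconstruction).
* **Iterative refinement.** The trained mapping is re-applied to its own
  output; each pass ends with the back-projection correction
  `x <- M(x) + beta (y - M(x))` toward the observed input `y`
  (`beta = 0.3`), which anchors the iterates and gives the characteristic
  quality optimum at two passes. Default: 2 iterations.
* **Evaluation.** PSNR `= 10 log10(255^2 / MSE)` and a global SSIM
  `(2 u_x u_y + C1)(2 s_xy + C2) / ((u_x^2 + u_y^2 + C1)(s_x^2 + s_y^2 + C2))`
  with `C1 = C2 = 1`, against a bicubic-interpolation baseline
  (down-up round trip at factor 2 in the same-size restoration framing).

Because clinical paired LD/HD corpora are proprietary, the package ships a
synthetic generator: piecewise-constant ellipse phantoms as HD ground truth,
degraded to quarter dose either by image-domain Gaussian noise with
`sd = base_sigma / sqrt(dose_fraction)` or by projection-domain Poisson
photon statistics with filtered back-projection.

## Worked example

```r
library(rfctsr)

train <- make_training_set(8, phantom_spec(size = 96, seed = 1),
                           dose_model(base_sigma = 5, dose_fraction = 0.25,
                                      seed = 2))
test  <- make_training_set(2, phantom_spec(size = 96, seed = 3),
                           dose_model(base_sigma = 5, dose_fraction = 0.25,
                                      seed = 4))

cfg   <- pipeline_config(patch = patch_config(n_samples_cap = 8000), seed = 7)
model <- train_sr_model(train, cfg)
model
#> <sr_model: 10 trees (depth <= 15), gradient_filters features,
#>  dictionary stage on (B=256), trained on 8 pairs / 8000 patches>

report <- evaluate_run(model, test, n_iterations = 2)
summarize_metrics(report)
#>        label mean_psnr sd_psnr mean_ssim  sd_ssim n
#> 1    bicubic     30.13 1.34090    0.9733 0.005479 2
#> 2       ldct     29.33 0.01152    0.9677 0.015614 2
#> 3 rfsr_iter1     32.40 0.72015    0.9842 0.005570 2
#> 4 rfsr_iter2     32.16 1.10983    0.9833 0.004600 2
```

The rows mirror the usual comparison table: the raw quarter-dose input
(`ldct`, 29.3 dB), the bicubic baseline (30.1 dB), and the forest
reconstruction after one and two refinement passes (32.4 / 32.2 dB). On this
run the method output is 2.0 dB above the bicubic baseline with a strictly
higher SSIM — the qualitative behaviour the method is designed for: markedly
better noise suppression than interpolation at the same resolution.

A command-line front end is installed at `exec/rfctsr`:

```sh
rfctsr make-data --n-pairs 20 --size 128 --seed 1 --out data/
rfctsr train --data data/ --out model.json
rfctsr reconstruct --model model.json --input data/ld_001.png --out sr.png
rfctsr evaluate --model model.json --data data/ --report report.csv
rfctsr sweep --data data/ --axis T --values 1,2,4,10 --report sweep.csv
```

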