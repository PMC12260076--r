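# genaug

End-to-end generative augmentation for semantic segmentation in
ultra-low-data regimes, in pure R.

## The problem

Training a segmentation model from tens of annotated image–mask pairs —
the situation in much of medical imaging — fails because the model
overfits long before it generalizes. `genaug` implements a *mask-first*
generative remedy: a real annotated mask **M** is perturbed by label-safe
augmentation (rotation, flipping, translation, optionally elastic
deformation) into **M̂**, and a conditional generator synthesizes the
matching image **Î(M̂; G, A)**, so every synthetic pair is perfectly
labelled by construction. What distinguishes the method from ordinary
generative augmentation is that the generator's weights **G** *and its
architecture* **A** are optimized end-to-end against the segmenter's
validation performance, through a three-level program:

```
min_A      L_seg(S*(A), D_val)                                   (architecture)
s.t.  S*(A) = argmin_S L_seg(S, D̂(G*(A), D_tr)) + γ L_seg(S, D_tr)   (segmenter)
      G*(A), H* = argmin_G argmax_H L_gan(G, A, H, D_gan)        (adversarial)
```

The nested optima are approximated by differentiable one-step ("virtual")
updates G → G′ and S → S′, and the architecture update descends

```
∇_A L_seg(S', D_val) = (∂G'/∂A) (∂S'/∂G') (∂L_seg/∂S'),
∂G'/∂A = -η_g ∇²_{A,G} L_gan,     ∂S'/∂G' = -η_s ∇²_{G',S}[...]
```

— a product involving cross second derivatives, which the package
computes **exactly** with a small reverse-mode autodiff engine whose
backward passes are themselves differentiable (double backward). The
generator's architecture is a sequence of searchable cells, each mixing
K = 3 strided-convolution (encoder) or transposed-convolution (decoder)
candidates from the pool 4-2-1 / 6-2-2 / 8-2-3 (kernel-stride-padding)
with softmax selection weights `α`; `discretize_architecture()` retains
the strongest operator per cell.

Everything runs on synthetic paired shape data (lesion-like blobs, rings,
vessel-like branching trees) with controllable contrast, texture, noise
and out-of-domain shifts, so the whole pipeline is testable on one CPU
without downloads.

## Worked example

```r
library(genaug)

train <- generate_shape_dataset(shape_dataset_config(n = 8, image_size = 32, seed = 7))
val   <- generate_shape_dataset(shape_dataset_config(n = 4, image_size = 32, seed = 8,
                                                     split = "validation"))
test  <- generate_shape_dataset(shape_dataset_config(n = 10, image_size = 32, seed = 9,
                                                     split = "test"))
train
#> <seg_dataset: 8 train pairs, 32x32, L=2>

fit <- train_genseg(train, val,
                    mlo_config(iterations = 60, warmup = 40, l1_weight = 10, seed = 1))
fit
#> <genaug_fit method='genseg': 60 iterations, best val dice = 0.6018 @ iter 50>

glance(fit)
#> # A tibble: 1 × 6
#>   method iterations metric best_val best_iteration arch_entropy
#>   <chr>       <int> <chr>     <dbl>          <int>        <dbl>
#> 1 genseg         60 dice      0.602             50         1.07

evaluate(best_segmenter(fit), test, "dice")
#> <seg_evaluation: mean dice = 0.6874 over 10 pairs>

fit$arch
#> <arch_weights: 4 cells x K=3>
#>       enc1  enc2  dec1  dec2
#> [1,] 0.300 0.306 0.242 0.313
#> [2,] 0.274 0.477 0.318 0.336
#> [3,] 0.425 0.217 0.439 0.352
```

`train_genseg()` ran 40 adversarial warm-up iterations, then 60 trilevel
iterations, each combining a virtual GAN step, mask augmentation and
synthesis, a virtual segmenter step, the exact unrolled architecture
gradient, and committed optimizer updates. `best_segmenter()` returns the
checkpoint with the highest validation Dice; `evaluate()` scores it
per-pair on held-out data (here mean Dice 0.687 over 10 test pairs after
only a minute of training on 8 annotated pairs). The selection weights
have begun to drift from uniform (1/3); `tidy(fit)` returns the full loss
history and `autoplot(fit)` plots it.

The built-in reference comparison (10/5/30 pairs at 32×32, 3 seeds,
300 iterations — a few minutes per run on one core) trains the end-to-end
model against the *separate* baseline (generator trained then frozen) and
the *vanilla* no-augmentation baseline:

```r
rep <- run_experiment(toy_benchmark_config(seeds = 1:3))
attr(rep, "summary")
#> # A tibble: 3 × 5
#>   method   dataset    mean      sd n_seeds
#>   <chr>    <chr>     <dbl>   <dbl>   <int>
#> 1 genseg   in_domain 0.673 0.00544       3
#> 2 separate in_domain 0.665 0.00651       3
#> 3 vanilla  in_domain 0.646 0.0146        3
```

End-to-end generation beats the identically trained no-augmentation
baseline on every seed, and the separate (non-end-to-end) baseline on the
mean — the qualitative ordering the method predicts.

A thin command-line front end ships at `inst/cli/genaug`
(`simulate`, `train`, `train-separate`, `train-vanilla`, `evaluate`,
`report`), driven by the same YAML run configurations as
`run_experiment()`.

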