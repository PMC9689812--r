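# deabc — metaheuristic contrast stretching for skin-lesion images

Dermoscopy images often reach segmentation pipelines with a lesion barely
darker than the surrounding skin, uneven illumination, and sensor noise.
Global remappings (histogram equalisation, linear stretching) treat every
region alike and either over-stretch noise or wash out the lesion boundary.
`deabc` implements a **per-image, local-statistics, brightness-preserving
contrast transform** whose four parameters are tuned for each image by a
hybrid metaheuristic — **Differential Evolution (DE)** followed by
**Artificial Bee Colony (ABC)** refinement. It is aimed at people building
lesion-segmentation or classification pipelines who want a self-contained,
deterministic preprocessor in R.

## The method

The RGB image is converted to HSI and only the intensity plane
Ξ is transformed (hue and saturation are preserved). Each pixel
`f(i,j)` becomes

```
g(i,j) = delta * M / (sigma(i,j) + beta + eps) * [ f(i,j) - gamma * mu(i,j) ] + mu(i,j)^alpha
```

where `mu` and `sigma` are the mean and population standard deviation of the
`k x k` window around the pixel, `M` is the global mean, and
`(alpha, beta, gamma, delta)` are the decision variables, bounded by
`lb = (0, 0, 0, 0.5)`, `ub = (1.6, 0.5, 0.8, 1.5)`. Low-variance regions get
a high gain (contrast stretch); the `mu^alpha` term re-injects local
brightness so the image does not drift dark or bright.

A candidate parameter vector is scored on the enhanced channel Ξ\* by

```
Ox(Ξ*) = ln(ln(E(Ξ*))) * n_edgels(Ξ*) * H(Ξ*) / (R * S)
```

with `E` the summed Sobel gradient magnitude, `n_edgels` the count of pixels
whose magnitude exceeds a threshold `tau`, and `H` the 256-bin histogram
entropy in bits. The double logarithm keeps raw edge energy from dominating
(which would reward over-stretching).

The score is maximised per image by DE (best/2 mutation, binomial
crossover, greedy selection) and the final DE population then seeds an ABC
colony (employed, onlooker and scout phases with trial counters and a
memorised global best). Everything is deterministic under a fixed seed.

The package also ships segmentation-overlap metrics (Jaccard/IoU and
Dice/F1), an Otsu + largest-component baseline segmenter, and a synthetic
lesion-image generator, so the whole pipeline is testable with no external
dataset.

## Worked example

```r
library(deabc)

# a 64 x 64 synthetic lesion under low-contrast study conditions:
# 8% lesion/skin gap, 20% illumination drift, 3% noise
fx  <- make_lesion_image(low_contrast_lesion_spec(seed = 3))
res <- enhance_image(fx$image, run_config(np = 15, de_iters = 20,
                                          abc_iters = 15, seed = 42))
print(res)
#> DE-ABC enhancement: Ox 7.92742 -> 12.46598
#>   params: alpha 1.6000  beta 0.2745  gamma 0.8000  delta 1.4993

d0 <- overlap_score(otsu_mask(rgb_to_hsi(fx$image)$intensity),    fx$mask)$dice
d1 <- overlap_score(otsu_mask(rgb_to_hsi(res$enhanced)$intensity), fx$mask)$dice
sprintf("Otsu Dice: %.4f (original) -> %.4f (enhanced)", d0, d1)
#> "Otsu Dice: 0.6093 (original) -> 0.6970 (enhanced)"
```

The first two lines say the optimiser raised the edge/entropy quality score
of the intensity channel from 7.93 to 12.47, choosing a strong local gain
(`delta` near its upper bound) with heavy local-mean subtraction
(`gamma = 0.8`). The Dice comparison shows the practical payoff: the same
baseline segmenter recovers the lesion much better from the enhanced image.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/deabc.R enhance lesion.png --seed 4 --np 30
Rscript inst/cli/deabc.R batch images/ --out enhanced/
Rscript inst/cli/deabc.R eval --pred enhanced_masks/ --truth truth_masks/
```

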