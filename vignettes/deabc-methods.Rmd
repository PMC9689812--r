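---
title: "DE-ABC contrast stretching: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DE-ABC contrast stretching: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deabc)
```

## The problem and the model

Lesion segmentation degrades when the lesion/skin intensity gap is small
relative to illumination drift and noise. `deabc` preprocesses each image
individually: it decomposes the RGB image into hue, saturation and
intensity, and remaps only the intensity plane with a local-statistics
transform,

$$g(i,j) = \frac{\delta\,M}{\sigma(i,j) + \beta + \varepsilon}
\bigl[f(i,j) - \gamma\,\mu(i,j)\bigr] + \mu(i,j)^{\alpha},$$

where $\mu$ and $\sigma$ are the mean and population standard deviation of
the $k \times k$ window centred on the pixel and $M$ is the global mean.
The gain is large where local variance is small, so flat low-contrast
regions are stretched hardest; $\gamma$ controls how much of the local mean
is subtracted before amplification (an illumination-flattening effect); the
$\mu^{\alpha}$ addend re-injects a power of the local brightness, which is
what keeps the output from drifting globally dark or bright.

The four decision variables are chosen *per image* by maximising

$$O_x(\Xi^*) = \ln\bigl(\ln E(\Xi^*)\bigr) \cdot
n_{\mathrm{edgels}}(\Xi^*) \cdot H(\Xi^*) / (R S),$$

where $E$ is the summed Sobel gradient magnitude over the enhanced channel,
$n_{\mathrm{edgels}}$ the number of pixels whose magnitude exceeds a
threshold $\tau$, and $H$ the histogram entropy in bits. A good enhancement
creates many, well-distributed edges and a rich intensity histogram; the
double logarithm deliberately flattens the influence of raw edge energy,
which otherwise rewards unbounded over-stretching.

Optimisation is a two-stage hybrid. Differential Evolution explores the
bounded box (best/2 mutation with a fresh scale factor $F \sim U(0,1)$ per
mutant, binomial crossover, greedy replacement); its final population then
seeds an Artificial Bee Colony whose employed/onlooker/scout phases refine
the solutions one coordinate at a time, with trial counters triggering
random restarts of exhausted sources and a global best memorised outside
the colony so no phase can lose it.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| bounds on $(\alpha,\beta,\gamma,\delta)$ | $(0,0,0,0.5)$–$(1.6,0.5,0.8,1.5)$ | the search box for the transform; dimensionless |
| `k` | 7 px | window for $\mu,\sigma$; large enough for texture statistics at the 512-px working size, cheap via integral images |
| `eps` | $10^{-6}$ | guard added to $\sigma + \beta$; $\beta$'s lower bound is 0 and $\sigma = 0$ occurs on flat patches, so the denominator can otherwise vanish |
| `tau` | 0.08 | edgel threshold on the $[0,1]$ magnitude scale ($\approx 20$ grey levels of an 8-bit image): a small fixed fraction of the Sobel dynamic range |
| `bins` | 256 | entropy histogram bins on $[0,1]$, right-closed final bin; entropy is reported in bits ($\log_2$), the double-log term uses natural logs |
| `np`, `de_iters`, `abc_iters` | 30, 50, 50 | population and iteration budget of the hybrid |
| `cr` | 0.9 | DE crossover rate; a `"random"` mode draws it fresh per crossover for users who want the fully stochastic variant |
| `limit` | `np * 4` | ABC trial limit before a scout replaces a source (population times number of decision variables, the usual colony convention) |
| `max_side` | 512 px | images larger than this are bilinearly downsampled before optimisation |

## Numerical and semantic choices

* **Intensity scale.** All arithmetic is on $[0,1]$, converting 8-bit data
  at the I/O boundary. This keeps $\mu^{\alpha} \in [0,1]$ for
  $\alpha \ge 0$, so the brightness term can never inject out-of-range
  energy. $0^0$ follows the limit convention and equals 1.
* **HSI variant.** The geometric (Gonzalez–Woods) model with
  $I = (R+G+B)/3$; achromatic pixels take hue 0. Recombining an enhanced
  intensity with the original hue/saturation can leave the RGB gamut;
  out-of-gamut values are clipped, which is the only place the output's
  chromaticity can deviate from the input's.
* **Window statistics.** Population standard deviation (divide by $k^2$),
  replicate padding at borders — zero padding would inject spurious border
  variance and darken $\mu$ at the frame edge.
* **Sobel and borders.** The gradient is evaluated only on interior pixels;
  the one-pixel border ring is zero. No wraparound.
* **Degenerate guard.** $O_x := 0$ whenever $E \le e$, no edgels exist, or
  $H = 0$, so $\ln(\ln \cdot)$ is never evaluated out of domain; a
  maximiser then simply never prefers degenerate candidates, and constant
  input images short-circuit to an identity result.
* **Selection ties.** Both stages resolve fitness ties in favour of the
  candidate (DE keeps the parent only on a strictly higher score; ABC keeps
  it only on strictly higher fitness). This keeps populations moving on
  plateaus.
* **Fitness direction.** The classical colony fitness map
  $1/(1+f)$ for $f \ge 0$, $1+|f|$ otherwise, minimises a cost $f$; the
  enhancement objective is maximised. The objective enters as $f = -O_x$,
  which reduces to $\mathrm{fitness} = 1 + O_x$ for $O_x \ge 0$: strictly
  increasing in $O_x$, so both stages optimise the same thing while the
  branch structure of the map is kept intact.
* **DE mutation reading.** Mutation uses the best member plus *two*
  scaled difference pairs over four distinct partners (DE/best/2). Crossover
  uses a fixed rate `cr` with a fresh uniform draw per component plus one
  forced donor component (index drawn over the four components); a per-call
  random rate is available as `cr = "random"` but makes the crossover
  intensity uncontrollable, so it is not the default.
* **Scout policy.** At most one renewal per iteration: the single source
  with the largest trial count above the limit (lowest index on ties) is
  replaced by a fresh uniform draw without greedy comparison.
* **Evaluation cache.** Candidates are cached keyed on the parameter vector
  rounded to 6 decimals; repeated candidates (common once a population
  converges) are served from the cache. This is transparent to results.

## The synthetic generator and what tests do (and do not) show

`make_lesion_image()` renders a soft-edged ellipse (logistic boundary,
0.25 px width — the scale of anti-aliasing) darker than a skin-toned
background, plus three nuisance fields: a diagonal illumination plane, a
weak sinusoidal texture, and i.i.d. Gaussian noise. Colour comes from a
constant base hue/saturation through the HSI inverse, so the ground-truth
mask is exact by construction and every image is bit-reproducible from its
seed.

`low_contrast_lesion_spec()` fixes the study conditions used by the
end-to-end experiments: a lesion only 0.08 intensity units darker than the
skin, an illumination drift of 0.20 across the frame (2.5 times the lesion
gap) and noise with standard deviation 0.03, at 64 × 64 px. These are the
conditions under which a global threshold genuinely fails — the Otsu
baseline reaches a mean Dice of only about 0.6 on the originals — and
they are what "low contrast and low brightness" failure looks like to a
histogram segmenter. The improvement experiment (20 seeded fixtures,
optimiser at population 15 with 20 + 15 iterations) checks that Dice after
enhancement is at least Dice before on at least 70% of fixtures and in the
mean; `scripts/acceptance.R` recomputes exactly this.

What the fixtures do **not** emulate: hair and ruler artefacts, specular
highlights, vignetting, colour variegation inside the lesion, and the
texture statistics of real skin. Passing tests therefore demonstrate the
mechanism — contrast stretching that flattens illumination and widens the
lesion/skin separation helps a downstream segmenter — not clinical
performance on dermoscopy archives, which additionally depends on artefact
handling and on the segmentation model used.

The baseline segmenter is deliberately minimal (global Otsu on 256 bins,
darker class, largest connected component): a stronger segmenter would mask
the preprocessor's contribution, which is the quantity under test.

## Experiment sizing

The package's own experiments run at desk scale, chosen so the full suite
re-runs in minutes on one CPU: 16 × 16 fixtures for the grid-dominance
study (where the $5^4 = 625$-point exhaustive grid over the box is
computable as an oracle), 32 × 32 for the instrumented full-budget
feasibility run, and 64 × 64 for the segmentation experiments. For the
grid-dominance study the hybrid runs an exploration-oriented configuration
(population 60, 50 + 30 iterations, `cr = 0.5`): the objective's best basin
sits at a corner of the box in $\alpha$ and $\gamma$, and a lower crossover
rate makes DE moves more axis-aligned, which is the standard setting for
such near-separable landscapes. That run spends several times the grid's
625 evaluations, so the comparison is conservative in the grid's favour.

## Known limitations

* The transform is global in its *parameters* (one vector per image), so a
  single image containing both an over- and an under-exposed region gets a
  compromise enhancement.
* Gamut clipping after recombination can locally desaturate strongly
  chromatic pixels; on the synthetic fixtures this affects a minority of
  pixels but it is unavoidable whenever the enhanced intensity leaves the
  range representable at the original chromaticity.
* The objective rewards edges and entropy wherever they come from; on very
  noisy images it will happily amplify noise. The double-log term tempers
  but does not eliminate this.
* The optimiser is stochastic; different seeds can land in different basins
  of the multimodal objective. All entry points are deterministic given a
  seed, and batch runs derive one seed per image from the run seed.
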