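Package: deabc
Title: Hybrid Differential Evolution-Artificial Bee Colony Contrast
    Enhancement for Dermoscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Brightness-preserving, local-statistics contrast stretching for
    dermoscopy-style skin-lesion images. A four-parameter intensity transform
    (local mean/standard deviation based) is tuned per image by a hybrid
    metaheuristic: Differential Evolution (best/2 mutation, binomial
    crossover, greedy selection) followed by Artificial Bee Colony refinement
    (employed, onlooker and scout phases with trial counters). Candidate
    enhancements are scored by a Sobel edge-count/edge-intensity/entropy
    objective. Includes segmentation-overlap metrics (Jaccard, Dice), an Otsu
    baseline segmenter, and a synthetic lesion-image generator so the whole
    pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
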