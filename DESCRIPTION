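Package: vesselkd
Title: Multi-Teacher Knowledge Distillation for Vessel Segmentation
Version: 0.1.0
Authors@R: person("vesselkd", "maintainers", email = "vesselkd@example.org",
    role = c("aut", "cre"))
Description: Response-based multi-teacher knowledge distillation for binary
    vessel segmentation. Three specialist U-Net teachers (full vasculature,
    thick vessels only, thin vessels only) are distilled into a single
    student network via temperature-softened sigmoid probabilities and
    pixel-wise binary Kullback-Leibler divergence, with an optional penalty
    factor on the hard-label loss. Includes a deterministic synthetic
    vascular phantom generator with width-based thin/thick ground-truth
    decomposition, a segmentation loss zoo (Dice, Tversky, focal and
    composites), exact closed-form parameter and multiply-accumulate
    accounting for the U-Net family, pixel-pooled evaluation metrics, and a
    small CPU training pipeline with ablation sweep support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
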