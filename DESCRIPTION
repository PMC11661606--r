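Package: morphogwas
Title: Univariate Phenotyping Strategies for GWAS of 3D Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for comparing univariate
    phenotyping strategies in genome-wide association studies of dense 3D
    shape data. Generates synthetic genotype panels with block linkage
    disequilibrium and quasi-landmark shape cohorts with a known additive
    genetic architecture; aligns, symmetrizes, covariate-adjusts and
    segments the shapes; derives six families of univariate traits
    (inter-landmark distances, principal component scores, auto-encoder
    latents, and resemblance scores to random, extreme and syndromic
    gestalts); runs per-cohort univariate GWAS with
    inverse-variance-weighted meta-analysis; aggregates scans per trait
    family with min-p combination and permutation-based effective trait
    counts; calls and compares genetic loci; and estimates SNP
    heritability with an LD-score-regression-style estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
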