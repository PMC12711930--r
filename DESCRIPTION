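Package: achdyn
Title: Spatially Resolved Striatal Acetylcholine Dynamics During Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for two-photon imaging of genetically encoded
    acetylcholine sensor fluorescence in the dorsal striatum of mice performing
    a reversal-learning maze task. Provides a seeded synthetic-data generator
    (sensor binding kinetics, outcome-response templates, vignetting, bleaching,
    motion jitter, and acetylcholine-coupled lose-shift behavior), rigid
    normalized cross-correlation registration, grid/quadrat trace extraction
    with delta-F/F and baseline z-scoring, outcome-aligned response
    quantification, PCA plus complete-linkage hierarchical clustering with
    elbow and silhouette diagnostics, rule-based response-type and switch/stay
    classification, anatomical quadrat mapping with axis-gradient regression,
    behavioral-flexibility metrics (win-stay/lose-shift, perseverative and
    regressive errors, trials-to-criterion), and the supporting statistical
    primitives (Student t, chi-square, Pearson r, Cohen's d with confidence
    interval, two-way repeated-measures ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    cluster,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
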