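Package: bshape
Title: Statistical Shape Modelling and B-Score Analysis of Femoral Bone Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying osteoarthritic femoral bone shape change with
    the B-score: rigid generalized Procrustes alignment of corresponded
    triangulated bone surfaces, principal-component shape spaces, definition of
    an osteoarthritis (OA) vector between non-OA and OA population means, and
    standardized orthogonal projection of shapes onto that vector. Includes a
    synthetic cohort generator emulating a bilateral-knee placebo-controlled
    trial (paired index/control knees, longitudinal B-score trajectories,
    ICRS cartilage-defect grades, regional cartilage-thickness changes),
    Bland-Altman smallest-detectable-difference and progressor classification,
    and the paired-knee statistical analysis (paired and Welch t-tests, Pearson
    correlations with Fisher z confidence intervals, quartile stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    vegan
Config/testthat/edition: 3
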