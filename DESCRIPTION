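Package: slrsa
Title: Searchlight Representational Similarity Analysis with Verifiable
    Synthetic BOLD Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A searchlight representational similarity analysis (RSA)
    pipeline for event-related fMRI: trial-wise activation estimates via
    Least-Squares-Single (LSS) general linear models with canonical HRF
    regressors, discrete-cosine high-pass filtering and AR(1)
    prewhitening; representational dissimilarity matrices (RDMs) from
    semantic vector spaces and property-listing feature profiles;
    whole-brain spherical searchlight Spearman comparison of neural and
    model RDMs (with optional partial correlation against nuisance RDMs);
    group-level inference with Shapiro-Wilk normality screening, t maps,
    minimum-statistic conjunctions and cluster-level family-wise error
    control by sign-flip permutation; and overlap reporting against
    localizer activation masks.  A synthetic-data module generates
    designs, semantic spaces, property listings and 4D BOLD volumes with
    a plantable representational geometry, so every pipeline stage can be
    validated against known ground truth without any MRI download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
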