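Package: matvseg
Title: Semi-Automatic FDG-PET Tumour Segmentation and Metabolic Tumour
    Burden Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for semi-automatic delineation of tumour lesions on
    SUV-calibrated FDG-PET volumes. Implements four voxel-threshold
    segmentation methods (fixed SUV 2.5 and 4.0 g/mL, adaptive 41% of
    lesion SUVmax, background-corrected 50% of lesion SUVpeak), their
    majority-vote consensus variants (MV2, MV3), a 3 mL minimum lesion
    volume rule, and replayable operator interactions (click-based
    removal of physiological uptake and addition of missed lesions).
    Quantifies metabolically active tumour volume (MATV), total lesion
    glycolysis (TLG), SUVmax and SUVpeak per lesion and per patient;
    compares segmentations with Jaccard and overlap-fraction metrics,
    Pearson correlation and paired log-scale t tests; and relates MATV
    to overall survival via median-split Kaplan-Meier estimates,
    log-rank tests and ROC analysis. A digital phantom and survival
    cohort generator emulating EARL-like PET acquisition makes every
    component testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    survival,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
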