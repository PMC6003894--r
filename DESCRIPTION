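Package: suvadc
Title: Voxel-Matched PET/MR Analysis of Tumor Glucose Uptake and Water Diffusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of [18F]FDG-PET standardized uptake
    values (SUV) and MR diffusion apparent diffusion coefficients (ADC) in
    solid tumors imaged on simultaneous PET/MR. Provides NIfTI volume I/O with
    explicit grid geometry, resampling of the PET volume onto the ADC voxel
    grid, threshold segmentation of the metabolic tumor volume at a fraction
    of SUVmax, global PET and ADC metrics (SUVmax, SUVmean, MTV, TLG,
    tumor-to-muscle ratios, ADCmin, ADCmean, ADC volume), per-tumor voxel-wise
    SUV-ADC least-squares association, cohort-level correlation and
    Mann-Whitney group comparison, Kaplan-Meier / log-rank / univariate Cox
    biomarker analysis with median dichotomization, and a fully synthetic
    PET/MR tumor phantom cohort generator (correlated Gaussian fields,
    mono-exponential diffusion-weighted signal synthesis and ADC map fitting,
    and outcome simulation) providing ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    survival,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'association.R'
    'cohort-sim.R'
    'cohort.R'
    'dwi.R'
    'metrics.R'
    'phantom.R'
    'pipeline.R'
    'resample.R'
    'segmentation.R'
    'smooth.R'
    'survival.R'
    'suvadc-package.R'
    'volume-io.R'
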