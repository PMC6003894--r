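# suvadc

Voxel-matched analysis of [18F]FDG-PET glucose uptake and MR diffusion in
solid tumors.

## The problem

Simultaneous PET/MR acquisition makes it possible to compare a tumor's
metabolic activity (the standardized uptake value, SUV) and its water
diffusivity (the apparent diffusion coefficient, ADC, in 10^-6 mm²/s) not
just as whole-tumor summaries but voxel by voxel: resample the PET volume
onto the ADC matrix so the voxels correspond one-to-one, collect the matched
(SUV, ADC) pairs inside the tumor volume of interest, and fit a least-squares
line. The per-tumor Pearson correlation r between voxel SUV and ADC is a
candidate imaging biomarker — densely cellular, highly glycolytic tumor
regions restrict diffusion, so aggressive tumors tend to show an inverse
SUV-ADC relationship — and its prognostic value can be probed by median
dichotomization with Kaplan-Meier, log-rank and univariate Cox analysis.

`suvadc` implements this pipeline end to end for researchers working with
paired PET/ADC volumes (NIfTI-1), and ships a fully synthetic phantom-cohort
generator with known ground truth so that every stage — resampling, 40 %-of-
SUVmax threshold segmentation of the metabolic tumor volume (MTV), global
metric extraction, voxel-pair association, group comparison, survival
stratification — is testable against oracles.

## What it computes

Per tumor (with muscle reference region):

| Quantity | Definition |
|---|---|
| SUVmax | maximum SUV in the tumor VOI |
| MTV | volume (mL) of the 26-connected component above 0.4 × SUVmax |
| SUVmean | mean SUV within the MTV |
| TLG | MTV × SUVmean |
| SUV_T/M | SUVmean / mean muscle SUV |
| ADCmin, ADCmean | min / mean tumor ADC (non-positive voxels excluded) |
| ADC_T/M | ADCmean / mean muscle ADC |
| ADCvol | tumor VOI volume (mL) |
| r, slope, intercept, p | per-tumor voxel OLS of ADC on SUV; Pearson r with two-sided t test, t = r·sqrt((n−2)/(1−r²)) |

Across patients: Pearson correlations between global metrics, two-sided
Mann-Whitney U group comparisons (exact null distribution for small tie-free
groups), the correlation of per-tumor r with MTV, and per-metric median
dichotomization with Kaplan-Meier curves, the log-rank test and univariate
Cox proportional hazards (Breslow ties). No multiple-testing correction is
applied; the cohort analyses are exploratory.

## Worked example

```r
library(suvadc)

## one synthetic patient: tumor phantom with a prescribed voxel SUV-ADC
## correlation of -0.35, PET on a 4.17 x 4.17 x 2.03 mm grid, ADC on
## 3.4 x 3.4 x 5 mm, ADC map fitted from synthesized b = 50/500/1000 DWI
ph <- generatePhantom(phantomSpec(rho = -0.35), seed = 42)
analyzePatient(ph$pet, ph$adc, ph$tumorVoi, ph$muscle, id = "P01")
#>    id SUVmax SUVmean SUV_TM  MTV TLG ADCmin ADCmean ADC_TM ADCvol      r slope
#> 1 P01   13.9    8.04   8.86 27.3 219    559     949  0.761     43 -0.319 -19.2
#>   intercept        p   n
#> 1      1075 4.87e-19 744
```

The pipeline resampled the PET volume onto the ADC grid, segmented a 27.3 mL
MTV at 40 % of SUVmax 13.9, and recovered a voxel correlation of −0.319 from
744 matched pairs against the generator's imposed −0.35 (the small shortfall
is the documented resampling/noise attenuation). ADC_T/M of 0.76 means tumor
diffusivity is three-quarters that of the muscle reference.

A whole cohort, analyzed and stratified:

```r
co  <- generateCohort(cohortSpec(seed = 1))   # 17 patients, 9 SCCA / 6 AdenoCA / 2 other
tab <- analyzeCohort(co)
survivalTable(tab, metrics = c("ADCmean", "SUVmax", "MTV", "r"))
#>    metric    hr  ciLow ciHigh waldP logrankP diverged
#> 1 ADCmean 0.760 0.1014   5.69 0.789    0.789    FALSE
#> 2  SUVmax 0.991 0.1393   7.05 0.993    0.993    FALSE
#> 3     MTV 0.760 0.1014   5.69 0.789    0.789    FALSE
#> 4       r 0.271 0.0259   2.83 0.276    0.249    FALSE
```

Hazard ratios are high-vs-low at the cohort median; for the voxel
correlation r, "low" means a more strongly inverse SUV-ADC relationship, so
an HR below 1 for the high group points the same way as the generator's
outcome model (stronger anticorrelation, worse disease-free survival).

## Documentation

The methods vignette (`vignettes/voxelwise-pet-adc.Rmd`) describes the
analysis model, the phantom generator's construction (how a prescribed voxel
correlation is imposed exactly on the noise-free fields), every tunable
default with its rationale, and known limitations.
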