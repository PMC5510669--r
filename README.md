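# mwtriage

Diagnostic-accuracy analysis of multi-antenna microwave scattering
measurements for pre-hospital screening of intracranial hematoma.

## The problem

Intracranial hematomas after head trauma need rapid detection, but the CT
scanners that diagnose them definitively only exist in hospitals. A
head-worn array of eight microwave antennas offers a portable alternative:
it sweeps low-power microwaves over 0.1–1.95 GHz and records, for every
antenna pair, a complex scattering coefficient (S-parameter) whose amplitude
and phase respond to the dielectric contrast between blood and brain tissue.
`mwtriage` implements, as tested reusable R functions, the statistical
pipeline that turns such measurements into a screening decision — for
biostatisticians and medical-device researchers who want to study, stress or
extend this class of diagnostic algorithms.

The clinical raw measurements behind this class of studies are not publicly
deposited, so the package ships a synthetic measurement generator that
emulates their statistical structure (triplicate measurements, inter-subject
head variability, measurement noise, and a hematoma perturbation whose
magnitude scales with lesion volume) plus a transcribed patient
characteristics table for the cohort-summary computations.

## The method

For each subject the three repeated channel-by-frequency complex matrices
are averaged coherently, channels confined to the forehead/occiput antenna
groups are excluded (26 of 36 channels are retained), frequencies are
restricted to a working interval (default 0.75–1.95 GHz), and the remainder
is concatenated into one complex feature vector (default length 650).

Classification is by per-class signal subspaces. Training vectors of class
*k* are stacked as columns of `X_k` and the rank-`r` subspace `U_k` is taken
from the leading left singular vectors of `X_k` (default `r = 1`, the first
subspace dimension). A subject with feature vector `x` receives the decision
value

    d(x) = ||x − U_HC U_HCᴴ x|| / ||x||  −  ||x − U_cSDH U_cSDHᴴ x|| / ||x||

(larger = more hematoma-like; the score is invariant to complex rescaling of
`x`). Accuracy is estimated by leave-one-out cross-validation and summarized
by the ROC curve, its area (AUC, equal to the normalized Mann–Whitney
statistic), and the specificity at 100% sensitivity. Model selection sweeps
all frequency intervals on a 50 MHz grid (minimum width 400 MHz; 465
candidates) crossed with candidate subspace ranks. Robustness and bias are
probed by repeated leave-one-out runs under random removal of two subjects
and under random reassignment of every diagnosis.

## Worked example

```r
library(mwtriage)

cohort <- generate_cohort(synthetic_config(seed = 1))
cohort
#> <mw_cohort: 40 subjects (20 cSDH, 20 HC), 36 channels x 38 frequencies (0.10-1.95 GHz), 3 repetitions>

eval <- loo_cross_validate(cohort)
eval
#> <leave-one-out evaluation: 40 subjects, AUC 0.955, specificity 55% at 100% sensitivity>
head(eval$scores, 3)
#>   subject_id label         score total_volume
#> 1        P01  cSDH  0.0007143364    214.56823
#> 2        P02  cSDH  0.0022541961     64.97944
#> 3        P03  cSDH -0.0013211012    113.65740

robustness_remove_k(cohort, k = 2, n_iterations = 100, seed = 5)
#> <remove_k resampling: 100 iterations, mean AUC 0.95 +/- 0.01>
random_diagnosis_null(cohort, n_iterations = 100, seed = 11)
#> <random_diagnosis resampling: 100 iterations, mean AUC 0.44 +/- 0.13>

cohort_summary(load_patient_table())
#> Patients: 20 (12 male, 8 female)
#> Mean age: 75.6 years (range 54-90)
#> Mean total hematoma volume: 112 mL (6 bilateral)
#> Mean midline shift: 5.8 mm
```

Reading the numbers: the default synthetic cohort is separated almost
perfectly by the rank-1 classifier (AUC 0.955); at the most permissive
threshold that still detects every patient, 55% of controls are correctly
rejected. The AUC barely moves when two random subjects are dropped
(0.95 ± 0.01), while destroying the labels collapses it to chance —
slightly below 0.5, the usual leave-one-out pessimism under the null. The
patient table reproduces the clinical cohort's descriptives: mean age 75.6
years, mean total hematoma volume 112 mL, 12 men and 8 women.

`plot(eval$roc)` draws the ROC curve and `plot(eval)` the decision-value
scatter with patients ordered by hematoma volume.

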