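# mwfmix

Lesion-mask-free statistical reduction of whole-brain white-matter
myelin water fraction (MWF) maps, for neuroimaging researchers studying
demyelinating disease (multiple sclerosis in particular) who want a
subject-level summary of white-matter damage that does not depend on
manually drawn lesion masks.

## The model

MWF is the per-voxel share of MRI signal from myelin water,
`MWF = c_MW / (c_MW + c_CW + c_CSF)`, a surrogate marker of myelin
content. For each subject, the distribution of MWF over all
white-matter (WM) voxels is modelled as a two-component gamma mixture

```
p(MWF) = λ Γ(MWF; α₁, β₁) + (1 − λ) Γ(MWF; α₂, β₂)
```

fitted by expectation maximization (with a quasi-Newton refinement; no
histogram or binning is involved), and compared against a single gamma
with a penalized likelihood ratio test calibrated by parametric
bootstrap. The subject is reduced to three numbers:

* `m1 = (α₁ − 1) β₁` — mode of the low-MWF component (lesion-like and
  "dirty" WM),
* `m2 = (α₂ − 1) β₂` — mode of the high-MWF component
  (normal-appearing WM),
* `λ` — the mixing ratio, the fraction of WM in the low-MWF component.

The spatial meaning of the components is validated by Dice overlap:
`ROI[m1]` (WM voxels below `m1`) against the lesion mask, and
`ROI[m2]` (voxels above `m2`) against the NAWM mask, with Welch
two-sample t-tests at the group level. Group analyses regress cortical
thickness on either the mixture reduction `(m1, m2, λ)` or classical
lesion-mask means, with exhaustive subset search under 10-fold
cross-validation, adjusted R² comparison, and LMG relative-importance
decomposition of R².

A synthetic-data module generates MWF volumes (ellipsoidal WM mask,
spherical lesions with a dirty rim, known ground-truth mixture),
FLAIR-like intensity volumes for the lesion-threshold rule, and cohorts
whose cortical thickness follows a known linear model — so the whole
pipeline is testable without patient data.

## Worked example

```r
library(mwfmix)

# one synthetic subject with known ground truth
spec <- volumeSpec(seed = 11)        # 64x64x32 grid, ~60,000 WM voxels
vol  <- makeMWFVolume(spec)
x    <- wmValues(vol)

fit  <- fitGammaMixture(x)
summarizeFit(fit)
#>         m1         m2     lambda
#> 0.05403122 0.16736048 0.21711721

sel <- penalizedLRT(fitSingleGamma(x), fit, x, nBootstrap = 99, seed = 11)
sel@chosen
#> [1] "mixture"
```

The ground truth here is `m1 = 0.06`, `m2 = 0.17`, `λ = 0.25`
(`referenceMixture()`); the fit recovers the modes to a few thousandths
and the mixing ratio to a few hundredths — the mixing ratio of heavily
overlapping components is intrinsically the hardest parameter. The
selection test prefers the mixture whenever lesions are present.

Interpreting fitted ROIs against the ground-truth masks:

```r
s <- summarizeFit(fit)
r <- roiFromModes(vol, s["m1"], s["m2"])
diceCoefficient(lesionMask(vol), r$roiM1)   # ~0.40
diceCoefficient(nawmMask(vol),  r$roiM2)    # ~0.77
```

Group level, on a synthetic cohort with the published coefficient
values baked in:

```r
cohort <- makeCohort(rrmsCohortSpec(seed = 1))   # 134 subjects
sel <- exhaustiveCVSelect(cohort, c("m1", "m2", "lambda", "age",
                                    "gender", "dd", "dmt"), seed = 1)
sel$best@predictors
#> [1] "m1"     "lambda" "age"    "gender" "dd"
signif(deltaForThicknessChange(sel$best, "lambda"), 2)
#> [1] 0.13
```

The generating predictors (`m1`, `lambda`, `age`) are recovered — with
two spurious covariates along for the ride, as minimum-CV-error subset
selection is prone to do (across seeds the modal selection is exactly
`{m1, lambda, age}`). The delta line reads: a 0.05 mm
cortical-thickness decrease is associated with a ~0.13 increase in λ,
all else equal. `runStudy(studyConfig(...))` chains all
stages (simulate → fit → select → ROIs/Dice → cohort → regressions)
into one reproducible results bundle; a thin command-line front end
with `simulate`, `fit`, `dice`, `cohort` and `study` subcommands is in
`inst/cli/mwfmix.R`.

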