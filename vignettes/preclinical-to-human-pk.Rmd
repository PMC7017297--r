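---
title: "Preclinical-to-human PK translation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preclinical-to-human PK translation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligopk)
```

## The problem

Phosphorothioate-backbone oligonucleotides (including locked-nucleic-acid
antisense drugs such as LNA-i-miR-221, whose preclinical dataset ships with
this package) show a characteristic plasma disposition after an i.v. bolus:
a fast distribution phase over the first hour or two as drug transfers into
tissues, followed by a much slower terminal phase reflecting elimination
from the tissue depot. They are also very highly bound to plasma protein
(typically > 98%), which limits renal filtration. Before a first-in-human
trial, the sponsor must translate animal PK into a predicted human
clearance, exposure, and a safe starting dose. `oligopk` implements that
whole chain: non-compartmental analysis (NCA) of the animal profiles,
ultrafiltration protein-binding arithmetic, interspecies allometric scaling
of total and unbound clearance, and dose translation.

## Non-compartmental analysis

For one subject's profile \(C(t)\) after an i.v. bolus of dose \(D\)
(mg/kg), the package computes:

* **Terminal rate** \(\lambda_z\): the negated slope of \(\ln C\) on \(t\)
  in the terminal phase. The terminal window is not fixed a priori:
  `fit_lambda_z()` searches every contiguous window of at least three
  usable samples that starts after \(T_\max\) and ends at the last usable
  sample, and keeps the window with the best adjusted \(R^2\) (ties go to
  the longer window). This is the best-fit convention of the commercial NCA
  tools this field uses, and on multi-exponential data it reliably discards
  early points still contaminated by the distribution phase.
* **Half-life** \(t_{1/2} = \ln 2 / \lambda_z\). \(\ln 2\) is used at full
  precision; reported values that used 0.693 differ by far less than the
  comparison tolerances.
* **\(C_0\)**: log-linear back-extrapolation through the first two positive
  samples to \(t = 0\). When the first two samples are non-decreasing there
  is no initial decay to extrapolate and the first observation is used,
  with a warning.
* **AUC**: trapezoidal, by default linear-up/log-down (the log trapezoid
  \(\Delta t\,(C_1 - C_2)/\ln(C_1/C_2)\) on strictly decreasing intervals),
  which is exact on mono-exponential segments; a plain linear rule is
  available by flag. \(C_0\) is prepended at \(t=0\) when the design has no
  time-zero sample. The tail \(C_\mathrm{last}/\lambda_z\) extends AUC to
  infinity and its share of the total is reported as the extrapolated
  percentage.
* **Clearance and volume**: \(CL = D/\mathrm{AUC}_{0-\infty}\) (reported in
  mL/min/kg, so a single factor of 60 appears, implemented once in a units
  helper) and \(V_z = CL/\lambda_z\). The identity \(CL \cdot 60 / V_z =
  \lambda_z\) is exact by construction and is used as an internal
  consistency check in the tests.

**BLQ policy.** Samples below the limit of quantification are flagged, not
deleted. Before \(T_\max\) they are dropped; from the first BLQ after
\(T_\max\) onward the profile is truncated. Nothing is imputed (no LLQ/2
convention): imputation would bias the terminal slope low and is not needed
when, as here, downstream use only requires the quantifiable segment.

**Group summaries** are computed per subject and then averaged (mean,
sample SD with \(n-1\), CV%), matching how multi-subject PK tables are
conventionally laid out; dose-normalised quantities are averaged as
per-subject ratios, not ratios of averages. For the bundled rat dataset the
two conventions differ by under half a percent, but the per-subject
convention is the one the reference table satisfies.

## Protein binding by ultrafiltration

The assay measures percent unbound as
\(100 \cdot C_\mathrm{filtrate}/C_\mathrm{reference}\) against a
non-filtered reference. Oligonucleotides adsorb strongly to ultrafiltration
plastics, so a protein-free buffer arm measures the device recovery at each
test concentration; `binding_summary()` divides the apparent unbound
percentage by that concentration-matched recovery. The division convention
is an assumption (the underlying report only states that a correction was
applied): it is the standard recovery correction, it is consistent with the
concentration-specific non-specific binding the assay observed (50% and 35%
loss at 1 and 10 µM after coating), and under it the simulated assay
round-trips the true unbound fraction exactly at zero noise. Corrected
values above 100% are capped with a warning rather than silently accepted.

Species-level reporting averages plasma protein binding over the two test
concentrations (unweighted), and \(f_u = (100 - \mathrm{PPB})/100\).
Display rounding is half-up (98.625 → 98.63), matching reporting
conventions; base R's round-half-even would disagree in exactly these
cases, hence `round_half_up()`.

## Allometric scaling

Four parallel methods predict human clearance, all operating on
weight-normalised clearance \(Y\) (mL/min/kg) versus body weight \(W\):

1. **Direct two-species regression**: \(\log_{10} Y = \log_{10} a + b
   \log_{10} W\) fitted on rat and monkey; human \(Y = a\,W_h^b\). With two
   species the power law interpolates both points exactly.
2. **Tang fixed-exponent rule**: keep the fitted intercept \(a\) but fix
   the exponent at 0.65 *on the absolute-clearance scale*:
   \(CL_\mathrm{abs} = a\,W_h^{0.65}\). The per-kg and absolute scales are
   related by \(CL_\mathrm{abs} = Y \cdot W = a\,W^{b+1}\), so one
   intercept serves both; the package stores \(a\) on the natural scale and
   reports \(\log_{10} a\) alongside, because published coefficient tables
   in this field commonly print the logarithm (an \(a\) of 0.6789 next to a
   human prediction of 76 mL/min is only coherent as \(\log_{10} a\)).
3. **Single-species scaling** from each species:
   \(CL_\mathrm{abs,h} = CL_\mathrm{abs,a}\,(W_h/W_a)^{0.75}\).
4. The **geometric mean** of the parallel predictions is the final
   estimate; because \(\mathrm{AUC/Dose} = 10^6/(60\,CL)\) is a power of
   \(CL\), the geometric-mean AUC/Dose equals the AUC/Dose of the
   geometric-mean clearance exactly, which the tests exploit as a
   cross-check.

The **unbound basis** repeats all four methods on \(CL^u = CL/f_u\) and
multiplies the human prediction by human \(f_u\), so both bases report on
the total scale. When all species share the same \(f_u\) the two pipelines
agree to machine precision — the observation that binding correction
"changes little" for uniformly highly bound compounds is an exact theorem
at equal \(f_u\), and a property test asserts it.

**Which clearance goes in.** The bundled species table carries both the
published per-kg clearances (7.9, 3.0, 129 mL/min/kg for rat, monkey,
mouse) and a working value per species: dose/AUC recomputed from the
published primitives for monkey and mouse, and the per-subject mean for
rat. The working values are what the scaling uses — the published
regression coefficient \(b = -0.362198\) is only reproducible from the
unrounded monkey clearance \(8.75 \times 10^6 / 49{,}300 / 60 = 2.958\)
mL/min/kg, and using the rounded 3.0 shifts the human prediction by over
3%. The monkey AUC is an AUC to 48 h rather than infinity (the fixture
records this); with a 12.8 h terminal half-life the truncated tail is
small. The **mouse is excluded from scaling by default**: its first sample
at 1.5 h post-dose misses the distribution phase entirely, so its AUC is
underestimated and its apparent clearance (129 mL/min/kg) is not credible
for cross-species regression. Re-including it is a one-flag change and the
tests verify doing so visibly degrades the reproduction.

## Dose translation and exposure

* Body-surface-area correction factor \((W_h/W_a)^{1-0.67}\); the human
  equivalent dose is the animal NOAEL divided by it (rat 5 mg/kg/day →
  0.78 mg/kg/day at 70 kg vs 0.25 kg).
* The pharmacodynamically active dose scales the same way (mouse 25 mg/kg
  → 1.82 mg/kg).
* MRSD = HED / safety factor (default 10), with an explicit comparison
  flag against the human PAD: only a PAD *below* the MRSD argues for
  lowering the clinical start dose further.
* Exposure: \(\mathrm{AUC/Dose} = 10^6/(60\,CL)\) in h·ng/mL per (mg/kg);
  candidate doses default to the HED, the human PAD, and the untranslated
  NOAEL (0.78, 1.82, 5.0 mg/kg). "Per dose" means per (mg/kg) throughout —
  the only convention under which the published table rows are internally
  consistent (AUC/Dose × 0.78 reproduces the tabulated AUC at the HED).

## The simulation module

`simulate_profiles()` draws from \(C(t) = \sum_i A_i e^{-\alpha_i t}\)
with multiplicative lognormal error (\(\sigma^2 = \log(1+CV^2)\), the PK
convention — measurement error in concentrations is proportional, and
log-scale errors keep concentrations positive), flags values under the LLQ,
and supports serial and sparse designs. Sparse cohorts are interleaved:
subjects are split round-robin into cohorts and each cohort samples every
\(k\)-th nominal time, the usual rodent sparse layout. `spec_from_nca()`
inverts the closed forms to build a bi-exponential curve whose
\(\lambda_z\), \(C_0\) and AUC match given NCA parameters exactly (the
fast rate must exceed \(C_0/\mathrm{AUC}\) for the terminal coefficient to
be positive — the bundled rat rows need \(\alpha_1 = 3\) h\(^{-1}\), since
two of them have \(C_0/\mathrm{AUC} > 2\)).

Default problem sizes were chosen to keep every property informative at
desk scale: the rich serial design has 14 samples from 5 min to 24 h
(on it, noise-free NCA recovers all bundled rat table cells within 1%,
trapezoid discretisation being the only error source); Monte-Carlo checks
use 200 replicates at 15% CV for \(\lambda_z\) recovery and 500 draws for
the jittered power-law exponent. What the generator does *not* emulate:
absorption phases (i.v. bolus only), inter-subject parameter variability
(noise is residual-only; every subject shares the true curve),
time-dependent or target-mediated clearance, and assay calibration error
structure. Passing tests therefore demonstrate correctness of the
estimators under the stated error model, not robustness to model
misspecification in real animals.

## Numerical choices and degenerate inputs

* Terminal-window ties (equal adjusted \(R^2\) within \(10^{-12}\)) resolve
  to the window with more points; flat log-concentration windows carry no
  decay signal and are skipped, so an all-flat profile raises "no terminal
  decay" rather than returning a zero slope.
* Groups of one report SD 0 with an explicit `sd_defined = FALSE` flag
  rather than NA, so downstream CV% stays computable.
* All validation is fail-fast with named errors ("insufficient terminal
  data", "invalid reference", "degenerate regression", ...), asserted
  verbatim in the tests.
* `reproduce_reference()` compares recomputed to published values with
  group tolerances (binding and NCA identity arithmetic 0.5%, scaling 2%,
  exposure aggregates 3% — sized to the demonstrated input-rounding
  uncertainty) and additionally accepts agreement to within half a unit of
  the last published decimal, because several published values carry only
  two significant figures (a computed 1.93 against a printed 1.9 is
  agreement, not error).

## Known limitations

Allometry on two species is an interpolation with no degrees of freedom:
the fit quality of the power law is untestable, and the spread across the
four methods (about a factor of two in predicted exposure) is the honest
uncertainty statement. Scaling assumes similar disposition mechanisms
across species — defensible here because phosphorothioate
oligonucleotides show sequence-independent, conserved PK and near-identical
plasma protein binding across the tested species, but not a general
guarantee. The monkey clearance rests on a single animal profile truncated
at 48 h, and the mouse exclusion, while well motivated, leaves the
regression with the minimum possible species set.
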