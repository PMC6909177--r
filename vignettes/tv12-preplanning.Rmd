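---
title: "Modeling TV12 for SRS pre-planning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TV12 for SRS pre-planning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srspreplan)
```

## The problem and the model

Radiation necrosis after single-fraction stereotactic radiosurgery (SRS)
correlates strongly with V12, the volume of normal brain receiving at least
12 Gy. During pre-planning the physician fixes the gross tumor volume
(GTV), the margin (hence the planning target volume, PTV), the prescription
dose (PD) and the delivery technique; a realistic V12 forecast at that
moment prevents prescriptions that no plan can satisfy.

`srspreplan` models the *total* volume inside the 12 Gy isodose surface,
TV12, so that V12 = TV12 − GTV whenever the surface stays inside brain
parenchyma. Within one category — one plan type (cone arcs, CAT, or
dynamic conformal arcs, DCAT) at one prescription dose — TV12 versus PTV is
close to a power law for small targets, so stage 1 fits

$$\log_{10}(TV12) = m\,\log_{10}(PTV) + b$$

by ordinary least squares on the log10 scale (volumes normalized by 1 cc).
Stage 2 captures how the category parameters move with dose:
$m = a\,PD^{\,c}$ (slope falls as dose rises: at higher prescriptions the
12 Gy surface sits further down the dose gradient where fall-off geometry,
not aperture size, dominates) and $10^{b} = n\,PD + d$ (the unit-PTV volume
grows linearly with dose). Substituting back gives the closed-form surface

$$TV12 = (n\,PD + d)\; PTV^{\,a\,PD^{\,c}},$$

one parameter set per plan type. The model deliberately carries no
covariates for dosimetrist, target shape or conformity index: an
ellipsoid-surface-area covariate (available as
`ellipsoid_surface_area()`) was explored in the source clinic's data
without qualitative improvement, and leaving CI out keeps the physician's
pre-planning inputs (PTV, PD, plan type) separate from the dosimetrist's
outputs.

### Assumptions

* **Single isocenter, single target.** Beam overlap between isocenters adds
  dose the model never sees; multi-isocenter plans will be underestimated.
* **12 Gy surface inside parenchyma.** Where it exits the skull contents
  the model predicts the unclipped TV12 and therefore *overestimates* V12;
  the clipped variant (cTV12) is case-specific and out of scope.
* **Small targets.** The packaged parameters were fitted for PTV up to
  2.43 cc and prescriptions of 15–24 Gy; this is exactly the region where
  TV12 versus PTV is visibly non-linear. Queries outside the fitted domain
  are answered but flagged (see *Extrapolation policy*).

## Dose rescaling

Changing only the prescription dose scales the absolute dose everywhere by
one factor; the *relative* distribution — coverage, conformity index, the
prescription isodose line (PIDL) and every isodose line — is untouched. So
TV12 at any dose can be read off the plan's isodose-volume curve: with the
prescription line at 80% of maximum, 12 Gy sits at 64, 53.3, 45.7 and 40%
of maximum for prescriptions of 15, 18, 21 and 24 Gy. `expand_cohort()`
uses this to multiply a measured cohort across doses with no dose
recalculation; `rescale_plan()` copies CI, COV and PIDL bit-identically by
construction.

Two percent conventions coexist in practice: curves here are indexed by
percent of *maximum* dose, and the DVH-style percent of *prescription* is
reached through the explicit converters `isodose_percent_for_dose()` and
`isodose_percent_of_pd()` rather than through an ambiguous single percent.
`tv_at_dose()` interpolates linearly between curve nodes by default —
the better estimator — and offers `mode = "bin1pct"`, which first snaps the
queried dose to a 1%-of-prescription grid, emulating planning systems whose
DVH reports in those steps; re-reads under such binning move TV12 by about
0.01 cc, which is clinically negligible but reproducible in this mode.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| goals: min COV (%) / max CI / max V12 (cc) | `goal_set()` | 99 / 1.5 / 3.3 | nominal single-isocenter SRS planning goals; all strict inequalities, boundaries fail |
| `stage2_slope` | `build_model()` | `"nls"` | fit $m = a\,PD^c$ on the $m$ scale; `"loglinear"` keeps the log-space solution for users of that convention (both reproduce the packaged parameters within the rounding of their inputs) |
| curve mode | `tv_at_dose()` | `"interp"` | linear interpolation between nodes; `"bin1pct"` emulates 1%-of-PD DVH granularity |
| `pd_range` | `max_pd_for_goal()` | model PD domain (Gy) | inverse dose query is bracketed root finding, tolerance 1e-6 Gy |
| `local_convention` | `rtog_dose_guideline()` | `FALSE` | if `TRUE`, lesions over 20 mm are marked not treated — a conservative single-fraction cutoff some clinics apply |

## The synthetic-cohort generator

No raw plan cohort ships with the package, so `generate_cohort()` emulates
one: it is first-class, tested code, and the parameter-recovery oracle for
the whole fitting pipeline.

* **Geometry.** PTVs are log-uniform over 0.05–2.43 cc (log-uniform spreads
  points evenly along the fitted log axis; 2.43 cc is the upper end of the
  small-target regime, matching a maximal diameter under 20 mm). GTV is
  `ptv / (1 + f)` with `f` uniform on 0–1.5: margins of 0–2 mm on lesions a
  few mm in radius inflate volume by a factor of roughly 1–2.5, and this
  volumetric stand-in replaces the geometric margin the generator does not
  model.
* **Dosimetry.** TV12 scatters log-normally around the truth surface
  (multiplicative noise matches fitting in log space). The PIDL is fixed at
  80% of maximum — the usual starting point for cone and conformal arc
  plans — with the maximum dose set consistently. CI is drawn as
  `1 + |N(0.30, 0.12)|` and coverage just above 99%, the region where
  clinically approved plans live.
* **Noise structure.** Because dose rescaling preserves the relative
  distribution, a plan expanded across doses keeps *the same* log residual
  at every dose. The default `noise = "per_plan"` therefore draws one
  residual per lesion and plan type, shared across doses — the structure a
  rescaled cohort actually has, and the reason the dose-dependence
  parameters $a, c$ are recoverable at all (independent per-record noise,
  available as `noise = "per_record"`, inflates the stage-2 exponent error
  by an order of magnitude because only four dose levels constrain it).
* **Noise level.** The residual standard deviation is calibrated per plan
  type from the closed-form relation between R², the slope and the PTV
  spread, so that stage-1 fits land in the clinically observed bands:
  σ(CAT) = 0.105 gives R² ≈ 0.91–0.96 (band 0.921–0.947) and
  σ(DCAT) = 0.065 gives R² ≈ 0.96–0.98 (band 0.962–0.974). CAT is noisier
  in practice because cone plans accumulate over years from many
  dosimetrists, while conformal re-plans are more homogeneous.
* **Pairing.** In `paired` mode the DCAT record of each lesion keeps its
  CAT coverage within ±0.5 percentage points (the replanning goal a
  forward-planned DCAT can realistically hit) and improves CI in 90% of
  pairs, since a micro-multileaf aperture almost always conforms better
  than a circular cone.
* **Curves.** `generate_curve()` builds each plan's isodose-volume curve as
  a power decay $V(p) = A\,p^{-k}$ passing exactly through the plan's 12 Gy
  node and its prescription node (PIV = CI · PTV); the two nodes fix $k$,
  and a single-node curve defaults to $k = 2.5$, a steep radiosurgical
  fall-off.

**What passing tests show — and do not.** Recovery of the generating
parameters from synthetic cohorts (median absolute relative error ≈ 1% at
σ = 0.05 over 100 seeds; exact to 1e-6 at σ = 0) validates the *fitting
machinery*, not the model's adequacy for any particular clinic: the
generator draws from the model's own family, with none of the convexity,
dosimetrist or planning-system idiosyncrasies of real data. The packaged
reference parameters remain specific to the clinical service they came
from; the intended use is to refit `build_model()` on local data.

## Numerical choices

* **Stage-2 slope fit.** Levenberg–Marquardt on the $m$ scale, initialized
  at the exact log-log linear solution (so convergence is from a point that
  is already exact whenever the inputs lie on a power law, and the fit
  reduces to the log-linear answer in that case). R² for each stage-2 fit
  is reported on the fitted variable's natural scale ($m$, respectively
  $10^b$); a zero total sum of squares (constant inputs) reports R² as
  `NA` rather than a misleading 1.
* **Degenerate inputs.** Fewer than 3 points, non-positive volumes, or a
  category with all PTVs equal abort stage 1 with a message naming the
  category; `build_model()` lists exactly which (plan type, dose)
  categories are missing or under-filled.
* **Inverse queries.** The PTV inversion is closed-form. The dose inversion
  brackets `uniroot` at tolerance 1e-9 (asserted to 1e-6 Gy); roots landing
  on a bracket edge within 1e-9 are accepted as boundary solutions, and an
  unattainable goal returns an explicit no-solution value carrying the V12
  at both bracket ends rather than throwing.
* **Crossover.** At fixed dose both surfaces are affine in
  $\log_{10}(PTV)$, so the CAT/DCAT crossing is closed-form and unique;
  equal slopes (parallel lines) return `NA`. The high-dose crossings sit
  near — at 24 Gy slightly above — the 2.43 cc edge of the fitted domain,
  and are flagged as extrapolations there.
* **Extrapolation policy.** Out-of-domain queries are answered with a
  machine-readable warning (class `srspreplan_extrapolation`) instead of
  refusing: pre-planning is advisory, but silent extrapolation would hide
  misuse. Negative V12 predictions are likewise returned with a warning
  (class `srspreplan_negative_v12`), never clamped, preserving exact
  invertibility.
* **Guideline brackets.** The RTOG 90-05 table prints integer bracket
  edges (≤20, 21–30, 31–40 mm), leaving non-integer diameters in
  (20, 21) mm unassigned; they are placed in the 18 Gy bracket, the
  conservative reading. Strict printed inequalities are kept for
  RTOG 1270. Diameters beyond the last bracket return `NA` (not eligible).
* **Rounding.** Percents are rounded (to one decimal) only for display;
  all internal computation is full precision.
* **Ellipsoid area.** The Thomsen approximation ($p = 1.6075$, worst-case
  error ≈ 1.06%) on semi-axes rescaled to match the target volume; the test
  suite checks it against exact numerical quadrature of the surface
  integral. Diameters measured through the isocenter are treated as
  principal-axis diameters, as the ellipsoid analogy requires.

## Validation problem sizes

The shipped test suite fits cohorts of 50 plans × 4 doses per plan type;
stochastic parameter recovery runs 100 seeds at σ = 0.05, and the stage-1
R² band check runs 25 seeds at the calibrated per-type noise. These sizes
mirror the scale at which a single clinic can realistically assemble a
fitting cohort.

## Known limitations

* Parameters are clinic-specific: planning templates, collimator hardware
  and dosimetric goals all move $(a, c, n, d)$. Refit locally before
  clinical use.
* No uncertainty intervals on parameters or predictions; the recovery
  simulations bound estimation error under the generator's assumptions
  only.
* No necrosis-probability model: risk-quartile thresholds are a
  user-supplied goal (`goal_set()`), not a packaged dose-response.
* The DVH-granularity emulation covers 1%-of-prescription binning only;
  other planning-system quirks (volume-grid resolution, interpolated
  surface rendering) are not modeled.
* IMRS and VMAT deliveries are outside the fitted plan types, although the
  DCAT surface has been reported by others to transfer usefully to
  single-isocenter VMAT of small targets.
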