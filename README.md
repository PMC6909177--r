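# srspreplan

Knowledge-based pre-planning for single-isocenter, linac-based stereotactic
radiosurgery (SRS) of small intracranial lesions.

In SRS, the volume of normal brain receiving at least 12 Gy (**V12**) is
strongly correlated with the incidence of radiation necrosis, so a V12 goal
is set before treatment planning begins. If the prescribed combination of
target volume, dose and delivery technique cannot meet that goal, planning
time is wasted and treatment is delayed. `srspreplan` answers the
pre-planning question — *what V12 should we expect?* — from a closed-form
model, without constructing a treatment plan. It is aimed at medical
physicists and radiation oncologists who want a locally fitted, low-cost
alternative to heavyweight knowledge-based planning systems.

## The model

Writing **TV12** for the total volume enclosed by the 12 Gy isodose surface
(so V12 = TV12 − GTV when that surface stays inside brain parenchyma), the
package fits, per delivery technique,

```
log10(TV12 / 1 cc) = m · log10(PTV / 1 cc) + b        (per PD category)
m = a · (PD / 1 Gy)^c                                 (slope vs dose)
10^b = n · (PD / 1 Gy) + d                            (intercept vs dose)
```

which assemble into the prediction surface

```
TV12 / 1 cc = (n · PD / 1 Gy + d) · (PTV / 1 cc)^(a · (PD / 1 Gy)^c)
```

with one parameter set `(a, c, n, d)` for circular-cone arc therapy (CAT)
and one for dynamic conformal arc therapy (DCAT). The fit is hierarchical:
stage 1 is an ordinary least-squares line per (plan type, prescription dose)
category on the log10 scale; stage 2 fits the dose dependence of the stage-1
slopes (power law, Levenberg–Marquardt) and intercepts (linear in `10^b`).

Around the model the package provides:

* **Dose rescaling** — changing only the prescription dose leaves the
  relative dose distribution (and hence CI, COV, PIDL) unchanged, so TV12 at
  any dose is read off a plan's isodose-volume curve; a measured cohort is
  expanded across doses with no dose recalculation.
* **Inverse queries** — largest PTV, or largest prescription dose, whose
  predicted V12 still meets a goal (default goals: COV > 99%, CI < 1.5,
  V12 < 3.3 cc).
* **RTOG guideline lookups** — diameter-based prescription doses from the
  RTOG 90-05 and RTOG 1270 brackets.
* **CAT-vs-DCAT comparison** — paired percent changes ΔCI and ΔTV12 with
  per-dose summaries, and the crossover PTV below which DCAT is expected to
  spread more low dose than CAT.
* **A synthetic-cohort generator** — simulates plan cohorts with the
  statistical structure the fit assumes, used throughout the test suite for
  parameter-recovery validation.

## Worked example

```r
library(srspreplan)

m <- reference_model("CAT")           # packaged clinical parameter set

predict_tv12(m, ptv = 1.2, pd = 24)   # 5.189682 cc
predict_v12(m, ptv = 1.2, pd = 24, gtv = 0.8)
#> 4.389682

# the predicted V12 misses the 3.3 cc goal; what would meet it?
max_ptv_for_goal(m, pd = 24, gtv = 0.8, v12_goal = 3.3)
#> 0.8906795                          # shrink the margin to ~0.89 cc, or
max_pd_for_goal(m, ptv = 1.2, gtv = 0.8, v12_goal = 3.3)$pd
#> 19.96437                           # lower the prescription to ~20 Gy

rtog_dose_guideline(14, "RTOG_9005")  # 24 Gy for a 14 mm lesion

# below ~1.85 cc a DCAT plan is expected to spread more 12 Gy dose at 18 Gy
crossover_ptv(reference_model("CAT"), reference_model("DCAT"), pd = 18)
#> 1.845752
```

For a 1.2 cc PTV around a 0.8 cc GTV prescribed 24 Gy with cone arcs, the
model predicts 5.19 cc inside the 12 Gy surface, i.e. V12 ≈ 4.39 cc — well
above the 3.3 cc necrosis-risk goal — and quantifies the two remedies:
a smaller margin (PTV ≤ 0.89 cc) or a lower prescription (≤ 19.96 Gy).

Fitting your own cohort:

```r
models <- build_model(read_cohort("my_cohort.csv"))
write_model(models, "my_model.json")
```

A thin command-line front end with `simulate`, `scale`, `fit`, `predict`,
`advise` and `compare` subcommands is installed at
`system.file("cli", "srsplan.R", package = "srspreplan")`.

## Vignette

`vignettes/tv12-preplanning.Rmd` documents the model and its assumptions,
the calibration of the synthetic-cohort generator, the numerical choices,
and the package's limitations.
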