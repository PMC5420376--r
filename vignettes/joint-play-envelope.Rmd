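---
title: "Methods: the Joint Play Envelope pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Joint Play Envelope pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointplay)
```

## The scientific question

After anterior cruciate ligament (ACL) reconstruction, neither anterior
tibial translation (KT-1000 arthrometry) nor axial lower-limb rotation alone
reliably identifies the patients who end up dissatisfied with their knee.
`jointplay` implements an analysis in which the two laxities are combined
into a single composite factor — the **Joint Play Envelope (JPE)**, total leg
rotation (degrees) multiplied by the KT-1000 manual-maximum anterior
translation (mm), in units of mm·deg — and that composite is evaluated as a
*diagnostic screening test* for lower patient satisfaction, alongside the
standard clinical criteria (KT manual maximum alone, pivot-shift positivity,
total rotation alone).

Satisfaction is measured on a 0–100 visual analog scale (VAS) and
partitioned into three groups: Group 1 (higher satisfaction, VAS ≥ 80),
Group 2 (lower satisfaction, 50 < VAS < 80), and Group 3 (outliers,
VAS < 50, described individually and excluded from two-group statistics).
The strict published inequalities leave VAS = 50 unassigned; `assign_group()`
closes that gap downward into Group 3 by default (a score that low belongs
with the outliers; the choice is configurable and affects no printed group).

Because the original patient data were never deposited, every downstream
stage is exercised on a **synthetic cohort generator** whose defaults encode
the published study conditions. Passing tests therefore demonstrate that the
*procedures* are correct and that the generator reproduces its own design
targets — not that any real cohort behaves this way.

## The limb model

A recording is one cycle of a torque-limited axial-rotation test: the limb
is driven into external rotation (ER) until the torque reaches the protocol
limit $L$ (5.65 Nm), reversed into internal rotation (IR) until $-L$, and
reversed again to close the loop. The generator models the measured torque
as an exponential-stiffening elastic backbone plus frictional hysteresis:

$$
T(\theta) = \underbrace{S_d\,\mathrm{sign}(\delta)\,
  \bigl(e^{\beta_d |\delta|} - 1\bigr)}_{\text{backbone}}
  \;+\; h \cdot \mathrm{dir} \;+\; \varepsilon,
\qquad \delta = \theta - \theta_0,
$$

with direction-specific scale $S_d$ (Nm) and stiffening rate $\beta_d$
(1/deg), hysteresis half-width $h \ge 0$ (Nm), drive direction
$\mathrm{dir} = \pm 1$, and Gaussian torque noise $\varepsilon$ clamped at
three standard deviations. The model was chosen because it matches the
concave morphology of robotic laxity loops *and* every extracted feature has
a closed form, which makes the generator invertible and the whole pipeline
testable against analytic truth:

* maximum rotation per direction: $M_d = \log(1 + (L-h)/S_d)/\beta_d$;
* play at 0 Nm: $\sum_d \log(1 + h/S_d)/\beta_d$ (the loop width where the
  measured torque crosses zero);
* endpoint slope (derivative at the reversal): $\beta_d (S_d + L - h)$.

`params_from_features()` inverts these forms by nested one-dimensional root
finding: given targets for max ER, max IR, play and endpoint slope, it
solves each direction's $(S_d, \beta_d)$ at a trial $h$ and then solves $h$
against the play target. A target is *infeasible* exactly when the requested
endpoint slope does not exceed the secant slope $(L-h)/M_d$ — the curve
cannot stiffen less than a straight line to its own endpoint — or when the
requested play approaches the total rotation; both are rejected with a
diagnostic.

### Feature extraction and its one systematic caveat

`extract_features()` measures reversal angles at the extreme samples,
locates zero-torque crossings per directional branch by linear interpolation
between straddling samples (taking the median of all crossings, which is
exact for noiseless data and robust when noise wiggles around zero), and
fits the **endpoint slope** by least squares over the last 10% of the
rotation range approaching each reversal on its loading branch. The 10%
window is defined on the *rotation* range (not torque), because the window
is drawn at the rotation extreme and rotation windows remain stable where
the curve is steep. Device resolution (0.01°, 0.001 Nm) makes higher-order
interpolation unnecessary.

A windowed least-squares slope on a convex curve is systematically smaller
than the derivative at the endpoint (it averages the slope over the window):
on the worked example limb ($S = 1$, $\beta = 0.05$, $h = 0.25$) the
derivative is 0.32 Nm/deg while the fitted slope is ≈ 0.26 Nm/deg.
`closed_form_features()` therefore returns both: the analytic continuous
least-squares slope over the same window (the oracle for what extraction
estimates) and the derivative (`slope_*_deriv`, the quantity
`params_from_features()` inverts). Tests compare each estimator to its own
closed form; the ~20% attenuation is a property of the estimator, not an
error.

## Generator defaults: the study conditions

Defaults in `study_feature_targets()` and `cohort_spec()`:

| quantity | group 1 (n = 9) | group 2 (n = 6) | group 3 (n = 2) | SD |
|---|---|---|---|---|
| healthy max ER (deg) | 48.7 | 64.5 | 48.7 | 8 |
| healthy total rotation (deg) | 76.9 | 95.8 | 76.9 | — |
| reconstructed total rotation (deg) | 70.4 | 92.2 | 70.9 | — |
| endpoint slope (Nm/deg) | 0.32 | 0.26 | 0.32–0.34 | 0.04 |
| play at 0 Nm (deg) | 9 | 9 | 7–9 | 2 |
| KT manual max, healthy (mm) | 8.0 | 8.0 | 8.0 | 1.5 |
| KT manual max, reconstructed (mm) | 9.5 | 13.0 | 11.0 | 1.5 |

Rotational means are the published group means; max IR is the published
total minus max ER, and the group-2 reconstructed limb carries the published
8.7° ER deficit relative to its healthy side. The published stiffness values
"1.3 vs 1.6" carry no stated units; taken literally as Nm/deg they are ~14×
the secant slope implied by the same Results' torque limit and rotations,
which would degenerate the loop into a flat line with near-vertical ends and
a hysteresis offset below the device's torque resolution. The defaults
therefore preserve the published 1.6 : 1.3 stiffness *ratio* at a magnitude
consistent with the printed torque limit and rotations (0.32 / 0.26 Nm/deg,
SD scaled identically to 0.04); the inversion itself accepts the literal
1.6 Nm/deg target if a user wants it. Play and KT values are not printed per
group; the defaults are clinically plausible magnitudes chosen once, with
the group-2 reconstructed limb carrying the elevated anterior translation
that makes it separable — the signature the JPE exploits. The
manual-maximum KT force is modelled as a nominal 180 N (its magnitude is
examiner-dependent and unstated). VAS is uniform within each group's range;
group 3's limb targets emulate the two described outliers (≈6° less
rotation and ≈3 mm more translation in the reconstructed limb). Sub-maximal
KT values are fractions (0.50/0.60/0.75) of the manual maximum with 4%
noise, sorted and capped to enforce monotonicity in force. Pivot-shift
positivity probabilities (2/3 for group-2 reconstructed limbs, 1/12
elsewhere) are back-derived from the published pivot-shift screening row
under the 6-positive/24-negative split. The generator imposes **no**
correlation between manual-exam grades and curve features beyond these
marginal rates, and no biomechanical coupling between rotation and
translation — it reproduces curve morphology and group structure, nothing
deeper. Real recordings additionally contain multi-cycle drift, soft-tissue
creep and angle-dependent friction that the model deliberately omits.

## Screening statistics

Limbs are labelled for the screening question as: condition-positive = the
reconstructed limbs of Group 2 (6 limbs); condition-negative = all Group 1
limbs plus Group 2 healthy limbs (24 limbs — patients report full
satisfaction with the healthy knee); Group 3 excluded. This split is the one
arithmetically consistent with the published JPE screening row.

`screening_values()` computes the Altman–Bland descriptors (sensitivity,
specificity, PPV, NPV) at full precision and rounded to the nearest integer,
halves away from zero; a zero denominator yields an explicit undefined
(`NA`), never 0. `fisher_exact()` enumerates the full hypergeometric support
with log-factorials; the two-sided p sums all tables (at the observed
margins) whose probability is at most the observed table's, compared with a
relative tolerance of 1e-12 — the probability-mass definition used by
common statistical software; a tail-doubling variant is available behind a
flag. Since the published analysis states no cut-offs, continuous criteria
are dichotomized either at a user-fixed threshold (ties are test-negative)
or by exhaustive search over midpoints of sorted unique values, minimizing
the Fisher p with ties broken toward fewer test-positives. The searched
threshold is an *optimistic* operating point: under permuted labels the
fixed-threshold test holds its nominal size (it is exact), while the search
inflates the type-I rate substantially — the acceptance script measures and
reports both rather than hiding the inflation.

`recover_table()` runs the audit in the opposite direction: given four
rounded percentages it enumerates every integer 2×2 table consistent with
the rounding, pruned by the implied integer intervals. The published JPE row
(83/96/83/96) is uniquely `(tp, fp, fn, tn) = (5, 1, 1, 23)` once the total
is fixed at 30 with 6 positives, and its exact Fisher p (≈ 2.4e-4)
reproduces the printed "< 0.001". The published total-rotation row
(29/92/83/59) admits **no** integer table at any size up to n = 200 — the
audit reports the inconsistency (plausibly a rounding or transcription
artifact upstream); it does not resolve it.

## Comparisons

`compare_feature()` uses the paired t test for reconstructed-vs-healthy
contrasts within subjects and the Welch (unequal-variance) form for
Group 1 vs Group 2 contrasts — group sizes of 9 and 6 are small and unequal,
so the pooled-variance form is not assumed. Curves are compared pointwise
after registration onto a common torque grid (`register_curves()`, linear
interpolation of angle on torque per drive direction; torque is the natural
axis because the protocol is torque-limited). A limb whose branch does not
span the grid is excluded with a warning — with hysteresis half-width $h$,
the ER-ward branch only reaches down to $-L + 2h$, so the default grid spans
±90% of the torque limit. `pointwise_t()` applies the Welch test per grid
point, uncorrected for multiplicity by default (matching exploratory
pointwise practice; Bonferroni is one argument away). Whether a published
curve comparison would use the loading or unloading branch is unknowable
from the text; the drive-direction branch is selectable.

## Pipeline, determinism and numerical choices

`run_pipeline()` executes generate → extract → metrics → screen → compare.
A single master seed spawns one substream per stage, so disabling a late
stage cannot perturb earlier randomness, and every CSV carries the seed and
a hash of the scientific configuration (stage toggles excluded, by design)
in a header comment; reruns under one seed are byte-identical, which the
acceptance checks verify with file digests. Figures are regenerated from the
CSVs, never from in-memory state. A thin command-line wrapper
(`inst/cli/jointplay.R`, subcommands `generate | extract | metrics | screen |
compare | run`) exposes the same functions; configs are JSON with a
mandatory seed.

Numerical details worth knowing:

* sampling step defaults to 0.05° (device resolution 0.01° is the floor);
  reversal angles are exact samples, so extraction recovers them to within
  one step;
* torque noise defaults to 0.001 Nm (the stated device accuracy) and is
  clamped at ±3 SD so a recording never materially exceeds the torque limit;
* ties at a reversal take the first extreme sample; ties at a dichotomization
  threshold are test-negative;
* root finding uses `uniroot` at tolerance 1e-12 with brackets grown/shrunk
  geometrically; the near-linear limit $\beta \to 0$ is handled through
  `expm1`/`log1p` so no series fallback is needed;
* feature-target draws are clamped away from infeasible corners (slope above
  1.1× the secant, play below 60% of total rotation, KT ≥ 2 mm); at the
  default SDs the clamps essentially never bind.

Problem sizes used by the test suite and acceptance script — 100 random
limbs for closed-form recovery, all 10,625 tables with n ≤ 20 for the Fisher
oracle, 400 label permutations for type-I rates, 200 subjects per arm (at a
0.2° step) for effect recovery, 10 seeds for power — were chosen so each
check is decisive at desk scale while the whole suite stays fast.

## Known limitations

* The generator's realism stops at curve morphology and group structure; it
  cannot validate clinical claims, only the pipeline's correctness.
* The published stiffness units and the denominators of two published
  screening rows are unresolved in the source material; the package
  documents and audits these rather than asserting an answer.
* Threshold search is an exploratory device: its screening values are
  optimistic and its type-I inflation (measured under permutation) should be
  kept in mind whenever a searched cut-off is reported.
* No ROC/AUC machinery and no confidence intervals for screening values are
  provided; the analysis reports single operating points, as the original
  design did.

## A worked example

```{r example, eval = FALSE}
library(jointplay)

co <- generate_cohort(study_cohort_spec(seed = 1))
an <- build_analysis_table(co)
screening_report(an)

# audit a published screening row
recover_table(c(83, 96, 83, 96), diseased = 6, n_total = 30)
fisher_exact(contingency_table(5, 1, 1, 23))
```
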