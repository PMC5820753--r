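---
title: "Predicting aqueous racemization risk: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting aqueous racemization risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racemizr)
```

## The chemistry being modelled

A carbon stereogenic center bearing one α-hydrogen can lose its
configuration in aqueous buffer by general-base catalysis: a buffer base
abstracts the proton, the resulting carbanion is planar (or rapidly
pyramidally inverting), and reprotonation occurs on either face. The
observable is loss of enantiomeric excess,

$$ee(t) = ee_0\,e^{-k_{obs}t}, \qquad
   \text{fraction racemized} = 1 - e^{-k_{obs}t},$$

with $k_{obs} = k_{gb}\,[\mathrm{base}]$ under pseudo-first-order
conditions. Two diagnostics support the S$_E$1 picture this package
assumes: hydantoin racemization kinetics, and Hammett series that correlate
better with $\sigma^-$ than with $\sigma$ (positive $\rho$), both
indicating negative charge on the stereocenter in the rate-determining
step. `fit_hammett()` reproduces that comparison for user-supplied series.

Everything in the package flows from one idea: *the rate of
general-base-catalyzed racemization tracks the thermodynamic ease of
deprotonation*. Deprotonation energies come from outside (quantum
chemistry) or from the group-contribution model below; calibrated affine
relationships convert them to rate constants; buffer speciation and
first-order kinetics convert rate constants to half-lives and fractions.

## Structure analysis

`find_stereocenters()` reports every tetrahedral, uncharged, non-aromatic
carbon with exactly one hydrogen (implicit hydrogens are made explicit at
parse time) and three mutually distinguishable heavy branches. Centers are
reported whether or not stereochemistry is drawn: the risk belongs to the
center, not to the depiction. Distinguishability is decided by canonical
branch invariants — iterative Weisfeiler–Lehman color refinement on the
molecular graph with the center deleted, read off in breadth-first shells
from each branch root. This is a constitutional criterion: meso-type parity
is invisible to it, which is acceptable for risk screening (a
pseudo-asymmetric center with an acidic hydrogen is still a liability).

Substituents are classified by an ordered rule table
(`inst/extdata/substituent_rules.json`), each rule an anchored substructure
pattern evaluated at the substituent atom as seen from the center. The
pattern language is a documented SMARTS subset (elements, aromaticity,
H-count, connectivity, charge, ring membership/size, branches, ring
closures); rules needing an exclusion carry a separate `veto_smarts`
(e.g. *alkyl* is an sp³ carbon vetoed when it bears a heteroatom, which is
what sends CF₃ and CH₂OH to `other`). The shipped order is
specificity-first — acyl rules (acidic secondary amide, primary amide,
carboxylic acid, ester) before ketone; imide-type nitrogens before plain
amide nitrogens; five-membered aromatic before phenyl; alkyl last — because
no precedence is published; a fixed, documented order makes classification
reproducible, and the rule file is data, so users can reorder or extend it
to the full sixty-type catalogue. The sixteen shipped labels cover every
structure used in the package's tests and the fourteen recognised center
types A–N (`center_type_table()`).

## Aromatic-anion assessment

Centers whose deprotonation yields a cyclic 4n+2 π system racemize much
faster than the acyclic trend predicts, hence the separate, steeper
calibration line. `assess_aromatic_anion()` implements a Hückel heuristic
on every ring of size ≤ 6 through the center: the deprotonated center
contributes two electrons; a ring atom with an endocyclic multiple bond
contributes one; exocyclic C=O/C=S contribute zero; heteroatom lone pairs
contribute two; an sp³ ring carbon blocks the count. Exocyclic C=C/C=N
double bonds count one electron, deliberately, so that fused aromatic
neighbours give the same answer under either kekulization of the input.

The heuristic is generous: a hydantoin C5 anion counts six π electrons and
is flagged "potentially aromatic". Which of the fourteen center types were
actually fitted on the aromatic-anion line is reference data not shipped
with the package, so the default per-type override table
(`default_aromatic_overrides()`) conservatively routes **all classified
types through the non-aromatic line**; the Hückel result still decides for
unclassified centers, and users holding the published assignment can
supply, e.g., `c(D = TRUE, F = TRUE)`. This default is also what the
physiological screening examples reproduce.

## Group contributions and cross-conjugation

`sum_ddg()` adds the three ΔΔG(R,H,H) values. When ≥ 2 substituents are
flagged delocalizing, the most stabilizing (most negative) keeps full
weight and the others are scaled by the policy factor (default 0.5,
`xconj_policy()`); `mode = "none"` and `factor = 1` both recover the plain
sum, a property the tests exploit. The exact published functional form of
the correction is supplementary-only; scale-all-but-strongest with a single
configurable factor is this package's declared interpretation. Ties between
equally stabilizing delocalizing groups resolve to the lexicographically
smallest type label — arbitrary, but deterministic and permutation-stable.

Delocalizing flags live in the rule file (and in the group table for the
energy-only path): C-linked π-acceptors and aromatic rings are
delocalizing; N- and S-linked substituents (reversed amides, thioethers,
amines) are not, since their attachment atom donates rather than accepts
electron density. The shipped ΔΔG(R,H,H) numbers are **provisional
placeholders** with plausible signs and ordering (`provenance =
"provisional"`): the published per-type values are not reproduced here, and
every quantitative claim the tests make about rate constants goes through
supplied ΣΔΔG values, never through this table.

## Calibration lines and uncertainty

The three shipped lines (`calibration_lines()`) are fixed constants of the
package. `fit_line()` refits user data by OLS with optional class-mean
aggregation (each center type collapses to its mean energy and mean
log k~gb~ before fitting, so populous classes cannot dominate), honoring
per-point exclusion flags as data attributes — no compound is ever excluded
by name. RMSE is reported with denominator *n* (the plain root mean square
of residuals, the common convention in QSPR reporting; `rmse_denominator =
"n-2"` gives the residual standard error instead), and R² is the ordinary
coefficient of determination. `prediction_interval()` converts RMSE into
the multiplicative band $k \cdot 10^{\pm RMSE}$; 0.61 log units is a factor
of 4.07.

## Kinetics: from traces to rate constants and back

* `fit_first_order()` fits $b + a\,e^{-kt}$ (CD decay) or
  $A(1-e^{-kt})$ (H/D exchange) by `nls` (port algorithm, $k \ge 0$), with
  analytically seeded starts: the baseline from the trace tail, the rate
  from a log-linear regression of the baseline-subtracted signal. Seeded
  starts make convergence reproducible; `minpack.lm` is a fallback if the
  port fit fails. Non-convergence is an error carrying the initial guesses.
* `extract_kgb()` is OLS of $k_{obs}$ against [base]; the slope is
  $k_{gb}$, the intercept collects water/hydroxide contributions. A
  negative slope is returned with a warning flag, never silently clamped.
* `correct_hydrolysis()` subtracts a parallel first-order loss channel; a
  deficit within twice the combined standard error floors at zero with a
  warning, a larger deficit is an error.
* `protonation_correction()` divides by the reactive fraction;
  `temperature_correction()` is the closed-form Arrhenius factor with
  R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹.

## The physiological scenario

`blood_buffer()` is 0.15 M total phosphate, pH 7.2, pKa₂ 6.80, 310.15 K.
The pKa₂ value is the effective constant at physiological ionic strength
and gives 0.107 M dibasic phosphate; it is configurable, and the 24 h
predictions shift by roughly a percentage point per 0.05 pKa units. The
prediction pipeline applies **no additional temperature correction**: the
calibration is used as-is for physiological prediction, and
`temperature_correction()` exists for normalizing laboratory data measured
away from 37 °C. Risk classes bin the 24 h fraction at < 1 % (low),
1–10 % (medium, upper bound closed) and > 10 % (high); the bounds are
configuration, not chemistry.

```{r example}
predict_racemization(-48.8)
```

## Synthetic data: what it does and does not show

The generators (`gen_trace()`, `gen_buffer_series()`,
`gen_calibration_dataset()`) are pure functions of their parameters and a
seed, and emulate the *shape* of the real observables: log-spaced sampling
of exponential decays (CD traces are sampled densely early), relative
Gaussian error on buffer-series rate constants (5 % is typical of CD/NMR
kinetics), one shared energy value per stereocenter class with log-normal
scatter of members (0.39 log units, matching the calibration residuals).
They do not emulate instrument drift, baseline curvature, slow substrate
hydrolysis distorting late time points, or correlated errors within a
dilution series — so passing recovery tests demonstrates the estimators are
correct and unbiased under the stated noise model, not that real traces are
this clean.

Test problem sizes are chosen to make the statistical checks sharp but
quick: 50-point traces, 6-concentration dilution series, 12-class
calibrations, 200 replicates for bias checks and 500 for the
slope-recovery rate (±0.08 around −0.26 in ≥ 95 % of replicates under
0.39-log-unit noise).

## Known limitations

* Classification covers the sixteen shipped substituent types; anything
  else is `other` and blocks strict-mode scoring (lenient mode substitutes
  0 kcal/mol with a warning — i.e. unknown substituents are assumed
  non-stabilizing, which can only underestimate risk).
* The branch-distinguishability and aromaticity decisions are graph
  heuristics (WL refinement, Hückel counting); pathological symmetric
  graphs and exotic ring systems can fool them.
* One ionization per buffer; no acid- or specific-base-catalyzed pathways;
  no Eyring analysis of multi-temperature data.
* The provisional group table means absolute structure-only predictions
  are illustrative until the published ΔΔG(R,H,H) values are supplied.
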