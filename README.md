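# racemizr

Racemization-risk prediction for carbon stereogenic centers under
physiological conditions.

## The problem

Many chiral drug candidates carry a stereogenic carbon with a single, mildly
acidic α-hydrogen. In buffered aqueous media such centers racemize by
general-base catalysis: a buffer base removes the proton, a planar carbanion
forms, and reprotonation scrambles the configuration (an S~E~1 mechanism).
Because detecting racemization requires chiral analytics, the liability is
routinely overlooked — enantioselective syntheses are run for compounds that
scramble in hours in blood. `racemizr` is a screening tool for medicinal and
physical-organic chemists that quantifies this risk directly from structure
or from precomputed deprotonation energies.

## The model

For a stereogenic carbon C(H)(R₁)(R₂)(R₃), each substituent R contributes a
carbanion-stabilization energy ΔΔG(R,H,H) (kcal/mol, negative =
stabilizing). The group-contribution score is

    ΣΔΔG = ΔΔG(R₁,H,H) + ΔΔG(R₂,H,H) + ΔΔG(R₃,H,H)

with a **cross-conjugation correction**: when two or three substituents
stabilize the anion through charge delocalization, the most stabilizing one
counts in full and every further delocalizing contribution is scaled by a
factor (default 0.5), reflecting the reduced ability of a second π-acceptor
to delocalize the same charge.

Calibrated linear free-energy relationships map energies to second-order
rate constants for general-base-catalyzed racemization
(log₁₀ k~gb~, M⁻¹ s⁻¹):

| domain            | relationship                        | RMSE | R²   |
|-------------------|-------------------------------------|------|------|
| quantum-chemical  | log k~gb~ = −0.20·ΔΔG(R₁,R₂,R₃) − 14.28 | 0.61 | 0.68 |
| GC, non-aromatic  | log k~gb~ = −0.11·ΣΔΔG − 9.81       | 0.40 | 0.78 |
| GC, aromatic anion| log k~gb~ = −0.26·ΣΔΔG − 16.95      | 0.39 | 0.92 |

The RMSE translates into a multiplicative uncertainty 10^RMSE on k~gb~
(≈ 4 for the QM line). Physiologically, blood behaves like a 0.15 M
phosphate buffer at pH 7.2; with pKa₂ = 6.80 that is ≈ 0.107 M dibasic
phosphate, so

    k_obs = k_gb × [HPO₄²⁻],   t½ = ln 2 / k_obs,
    fraction racemized(t) = 1 − exp(−k_obs · t).

The package also implements the laboratory side of the chain: exponential
fits of CD-decay / H-D-exchange traces, buffer-dilution plots
(k_obs vs [base] → k~gb~), hydrolysis, protonation-state and Arrhenius
temperature corrections, calibration refits with class-mean aggregation,
and the Hammett σ/σ⁻ comparison used to diagnose carbanion character.

## Worked example

```r
library(racemizr)

# structure in, risk out
mol <- parse_smiles("O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1", "thalidomide")
analyze_molecule(mol)[[1]]
#> <stereocenter_report> atom 5 [type L]
#>   substituents: alkyl, imide, acidic_secondary_amide

# precomputed energy in, risk out
predict_racemization(-48.8)
#> <racemization_prediction> [gc_nonaromatic]
#>   input energy:     -48.8 kcal/mol
#>   log10 kgb:        -4.442  (kgb 3.61e-05 [1.44e-05, 9.08e-05] M^-1 s^-1)
#>   k_obs:            3.877e-06 s^-1
#>   half-life:        49.66 h
#>   racemized in 24 h: 28.5%  ->  risk high
```

Read: a center with ΣΔΔG = −48.8 kcal/mol is predicted to racemize with a
half-life of about 50 h in blood-equivalent buffer — 28.5% racemized within
a day, i.e. an enantioselective synthesis of such a compound buys very
little. The bracketed k~gb~ range is the 10^RMSE uncertainty band of the
calibration line.

Batch screening and fitting are available from the shell via the shipped
script (`system.file("cli", "racemizer", package = "racemizr")`):

```sh
racemizer predict --smiles-file mols.smi --out report.csv
racemizer predict --sigma-ddg -48.8 --mode gc-nonaromatic
racemizer fit trace --in trace.csv --out fit.json
racemizer fit buffer-series --in series.csv
```

## Notes and limits

- The shipped per-substituent ΔΔG(R,H,H) table is **provisional**
  (`provenance = "provisional"`); supply the published quantum-chemical
  values via `read_group_table()` for production screening.
- Quantum-chemical ΔΔG(R₁,R₂,R₃) values are inputs; the package never runs
  electronic-structure calculations.
- Only carbon centers with exactly one hydrogen are considered; no 3D/
  conformer handling, no tautomer enumeration, no non-carbon stereocenters.

See the methods vignette (`vignettes/racemization-risk.Rmd`) for the full
account of the model, its assumptions and the numerical choices.
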