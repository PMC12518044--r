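# dporTrace

Spectral unmixing and progress-curve kinetics for dark-operative
protochlorophyllide oxidoreductase (DPOR).

DPOR is the nitrogenase-like, two-component (BchL + BchNB) enzyme that
reduces protochlorophyllide (Pchlide, *S*) to chlorophyllide (Chlide, *P*)
in the dark branch of (bacterio)chlorophyll biosynthesis. In assay buffer
the substrate, the Pchlide:BchNB complex (*ES*) and the product have
overlapping Q-band features at 651, 633 and 670 nm, so no single wavelength
tracks one species. This package is for enzymologists and spectroscopists
who monitor such reactions by in-situ UV-vis: it decomposes every recorded
spectrum into species concentrations and extracts rate constants for
ES-complex formation and electron-transfer-driven product formation from
the resulting time courses.

## What it computes

Every spectrum on the 600–700 nm window is fitted with the
reference-spectrum mixture model

    f(λ) = p1·S_S(λ−p6) + p2·S_P(λ−p7) + p3·S_ES(λ−p8) + p4 + p5·λ^e

where `S_S`, `S_P`, `S_ES` are spline-smoothed single-species reference
spectra at known concentrations, `p1..p3` proportionality factors (so
`c_X = pX × c_ref_X`), `p4`/`p5` baseline and scatter terms, and `p6..p8`
wavelength shifts (fixed at 0 by default). The ES molar absorptivity is
calibrated by requiring conservation of total Pchlide
(`c_S + c_ES + c_P = const`) over a donor-free binding series.
Concentration traces are then fitted with the standard association forms

    one-phase:  y(t) = y0 + (plateau − y0)(1 − exp(−k·t))
    two-phase:  y(t) = y0 + span_f(1 − exp(−k_f·t)) + span_s(1 − exp(−k_s·t))

with AICc model selection, after truncating the ~10 s instrument dead time.
A deterministic simulator of `E + S ⇌ ES → E + P` (with ES pools, two-site
sequential binding and a single-turnover mode) plus a seeded synthetic
spectrum generator make every stage testable without instrument data, and
endpoint (acetone-quench) helpers convert A666 readings to specific
activity and turnover frequency.

## Worked example

Generate the pre-incubation (no electron donor) experiment at 0.5 µM BchNB
/ 20 µM Pchlide, unmix it, and fit the ES-formation trace:

```r
library(dporTrace)

gen <- generateExperiment(canonicalScenarios()$fig5, seed = 1, stage = 1)
cs  <- applyDeadTime(unmixSeries(gen$spectra, gen$refs), 10)
cs
#> ConcentrationSeries: 119 points, t = 10-600 s; 0 non-converged
#>   final: S 19.023, ES 1.011, P 0.000 uM (total 20.034)

conservationCheck(cs, expectedTotal = 20, relTol = 0.02)$pass
#> TRUE

fitOnePhase(obsTime(cs), speciesConcentration(cs, "ES"))
#> KineticFit [one_phase], n = 119, R^2 = 0.9679, AICc = -848.42
#>   y0         -0.0280958 (se 0.0395)
#>   plateau    1.00448 (se 0.00424)
#>   k          0.0238456 (se 0.00116)
```

Reading the output: free Pchlide falls while roughly 1 µM of ES forms (two
binding sites per 0.5 µM BchNB tetramer); the total stays at 20 µM, which
validates the decomposition; no product forms without the electron donor;
and the one-phase association fit recovers the ES-formation rate constant
k ≈ 0.024 s⁻¹ (generated at an observed 0.023 s⁻¹) with its standard
error. The endpoint helpers work the same way:

```r
tofFromSpecificActivity(3.01, 206000)  # nmol/min/mg × g/mol -> per hour
#> 37.2036
```

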