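# ablatesim

Three-dimensional transient simulation of continuous-wave laser ablation of
soft tissue, for researchers in biophotonics and thermal therapy who need to
predict coagulation and vaporization lesions from irradiation settings
(power, beam diameter, scan speed) rather than measure them ex vivo.

The package couples four models in a feedback loop:

1. **Monte Carlo photon transport** through a voxel lattice (Henyey–Greenstein
   scattering with g = 0.9, unpolarized Fresnel events at refractive-index
   mismatches, Russian roulette) yields the absorbed power density
   S(**r**, t) of a scanned collimated Gaussian beam.
2. **Enthalpy-method heat conduction** advances
   ∂H/∂t = k∇²T + S with an explicit 7-point finite-difference scheme;
   temperature follows T = H/(ρc_p) below boiling and is clamped at T_v
   across the latent-heat plateau ρc_pT_v ≤ H ≤ ρ(c_pT_v + L_v).
3. **Arrhenius damage kinetics** accumulate
   Ω = A ∫ exp{−E_a/(R T)} dt per voxel; Ω ≥ 1 (α = 1 − e^(−Ω) = 63 %)
   marks coagulation.
4. **Dynamic optical properties (DOP)**: each transport refresh, the reduced
   scattering of every voxel is updated as
   μ_s′(α) = (1 − α) μ_s,native′ + α μ_s,coagulated′, and voxels whose
   enthalpy reaches H_th = ρ(c_pT_v + L_v) are removed (turned to air),
   carving the vaporization crater.

Lesion metrics (vaporization and coagulation width, depth and area on the
central cross-section) and the validation statistics RMSPE and relative
difference are built in. The model and the numerical choices are described
in `vignette("laser-ablation-model")`.

## Worked example

The reference scenarios are two powers × three scan speeds: 50 W (0.5–1.0
mm/s, producing vaporization *and* coagulation) and 10 W (1.0–1.5 mm/s,
coagulation only), a 2.8 mm (1/e²) Gaussian beam scanned over the tissue
surface. Each full-scale scenario has a desk-scale twin (`*_scaled`, 0.25 mm
voxels, 4 mm scan) that runs in tens of seconds:

```r
library(ablatesim)

scenarios <- make_reference_scenarios()
sc <- scenarios[["low_10W_1mms_scaled"]]
result <- run_scenario(sc, seed = 1)
print(result)
#> <ablation_result> 10 W @ 1 mm/s (DOP), t = 7.05 s
#>   removed 0 voxels, coagulated 1705 voxels, T_max 100.0 C
lesion_metrics(result)
#>   vap_width vap_depth vap_area coag_width coag_depth coag_area
#> 1         0         0        0          4          2     6.625
```

At 10 W the surface reaches boiling but never accumulates the latent heat
needed for removal: no voxel is vaporized, while a coagulation lesion 4 mm
wide, 2 mm deep and 6.6 mm² in cross-section forms — the low-power regime.
Re-running with `dop = FALSE` (static native optics) grows the coagulation
area and, at 50 W, shrinks the crater: ignoring the scattering increase lets
light diffuse too deep.

The DOP calibration curve itself:

```r
make_dop_reference_curve()
#>   Omega alpha mu_s_prime
#> 1     0 0.000      1.000
#> 2     1 0.632      2.043
#> 3     2 0.865      2.427
#> 4     3 0.950      2.568
#> 5     4 0.982      2.620
#> 6     5 0.993      2.639
```

μ_s′ rises steeply up to the irreversible-damage threshold Ω = 1 and
saturates within 1 % of the fully coagulated value by Ω = 5.

A thin CLI wraps the same functions
(`Rscript inst/cli/ablate.R run <config.yaml>`, `baseline` for the
static-optics reference, `metrics <outdir>` to re-measure saved masks);
scenario configs are YAML, volumes are written as NIfTI with mm voxel
metadata.

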