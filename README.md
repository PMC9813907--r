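# bindkin

Protein–ligand binding kinetics from calorimetry and NMR relaxation
dispersion, with a diffusion-theory estimate of the success rate of complex
formation per protein–ligand encounter.

## The problem

Drug-like ligands are routinely solubilized in DMSO, leaving residual
cosolvent in binding assays. DMSO–water mixtures are substantially more
viscous than water (about 3× at 20% v/v), which slows translational
diffusion and can therefore depress the *association* rate of binding even
when the cosolvent never touches the binding site. `bindkin` implements the
complete analysis chain needed to quantify this effect for a two-state
binding system (the motivating case is a galectin-3 carbohydrate
recognition domain binding a micromolar-affinity synthetic ligand at
301 K, probed at 0–10% v/v DMSO):

1. **ITC** — global weighted fits of the single-site (Wiseman) isotherm to
   replicate titrations. The cumulative cell heat after injection *i* is
   *Q*ᵢ = ΔH°·V₀·[PL]ᵢ with [PL]ᵢ = (α − √(α² − 4 n Pᵢ Lᵢ))/2 and
   α = n Pᵢ + Lᵢ + K_d; the per-injection observable applies the perfusion
   displacement correction (Vᵢ/V₀)(Qᵢ + Qᵢ₋₁)/2 plus a heat-of-mixing
   offset. ΔG° = RT ln K_d and −TΔS° = ΔG° − ΔH° complete the
   thermodynamic profile.
2. **CPMG relaxation dispersion** — the Carver–Richards closed form for
   two-state exchange, R₂eff(ν_cpmg) with ψ = k_ex² − Δω²,
   ζ = −2Δω·k_ex·(1 − 2p_F) and the D± / η± auxiliary terms, fitted
   globally across residues and static fields (k_ex and optionally p_F
   shared; one exchange-free R₂⁰ per profile; Δω fixed per residue in ppm).
   Nested-model F-tests (α = 0.001) guard against fitting exchange to flat
   profiles, and parameter errors come from parametric Monte Carlo
   resampling (1000 synthetic data sets by default).
3. **Diffusion theory** — for two spheres with Stokes–Einstein diffusion,
   the Smoluchowski encounter rate is k_on,D = (2/3)(2 + R_L/R_P +
   R_P/R_L)·k_BT/η, i.e. 3.36 k_BT/η for R_L = 6 Å and R_P = 16 Å.
   Regressing the observed k_on = k_off/K_d (with k_off = k_ex·p_F) against
   1/η and comparing with the diffusion-limited slope gives
   ρ = k_s/k_dis = r/(1 − r) with r = k_on/k_on,D: the odds that a
   diffusive encounter matures into the bound complex. 1/ρ is the mean
   number of encounters per successful binding event.

A synthetic-data module generates ITC and CPMG data sets with the exact
experimental protocols (150 μM protein cell, 1.5 mM ligand syringe,
0.4 μL + 9×4 μL injections in two concatenated runs; two-field CPMG
schedules at 11.7 and 14.1 T with a 40 ms constant time), so the entire
pipeline is testable end to end without instrument data.

## Worked example

```r
library(bindkin)

report <- run_pipeline(pipeline_config(seed = 2, cpmg.mc_sets = 30L,
                                       regression.n_mc = 10000L))
print(report)
#> Binding-kinetics pipeline report (seed 2)
#>     0% DMSO: Kd =   5.6 uM, k_ex =  750.0 /s, k_on =  6.75 x10^6 /M/s [exchange]
#>     2% DMSO: Kd =   6.5 uM, k_ex =  649.5 /s, k_on =  4.97 x10^6 /M/s [exchange]
#>     6% DMSO: Kd =   7.4 uM, k_ex =  399.0 /s, k_on =  2.68 x10^6 /M/s [exchange]
#>    10% DMSO: Kd =  12.9 uM, k_ex =  369.3 /s, k_on =  1.43 x10^6 /M/s [exchange]
#>   slope(k_on vs 1/eta) = 0.0088 +/- 0.0002 (10^6/M/s) Pa s
#>   diffusion-limited slope = 8.41; rho = 0.10% (1 success per 956 encounters)
```

Reading the output: each condition line gives the fitted dissociation
constant from the ITC stage, the exchange rate sum k_ex = k_on[L] + k_off
from the CPMG stage (all four selected the exchange model over a flat
profile), and the derived on-rate. The on-rates fall with DMSO because the
solvent gets more viscous; their slope against inverse viscosity
(0.0088 (10⁶ M⁻¹s⁻¹)·Pa·s here) sits far below the diffusion-limited slope
of 8.41, so only about one encounter in a thousand (ρ ≈ 0.1%) leads to
productive binding.

Individual stages are exported too — e.g. `fit_single_site()` on a list of
`titration_experiment` objects, `fit_dispersion_global()` on
`dispersion_profile` objects (see `read_itc_csv()` / `read_cpmg_csv()` for
the CSV schemas), `derive_rate_constants()`, `regress_kon_vs_fluidity()`
and `success_rate()`.

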