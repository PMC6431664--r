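# memprobe

Analysis of small-molecule/lipid-bilayer interaction measurements: membrane
fluidity fluorometry, isothermal titration calorimetry (ITC) partitioning,
and structural observables of bilayer coordinate trajectories.

The package is aimed at membrane biophysicists who characterize how
amphiphilic solutes — e.g. natural herbicidal compounds such as fatty acids,
alkylamides, or alkylresorcinol-like lipids — insert into and perturb
phosphatidylcholine bilayers, and who want the three standard assays in one
reproducible, scriptable toolchain instead of instrument-vendor software.

## What it computes

**Fluorometry.** Laurdan generalized polarization from blank-subtracted
emission intensities,

    GP = (I440 − I490) / (I440 + I490),

with replicate shots averaged at the intensity level, and the gel-to-fluid
phase-transition temperature Tm obtained by fitting the descending logistic
`GP(T) = GP_fluid + (GP_gel − GP_fluid)/(1 + exp((T − Tm)/w))`. DPH
fluorescence anisotropy from polarized intensity quadruplets,

    r = (I_VV − G·I_VH) / (I_VV + 2·G·I_VH),   G = I_HV / I_HH,

with the instrumental G-factor measured per sample.

**ITC partitioning.** For lipid-vesicle-into-solute titrations, the
cumulative heat after *i* injections follows the one-constant partition
isotherm

    Σ δh_k = ΔH · V_cell · C_A⁰(i) · K·C_L⁰(i) / (1 + K·C_L⁰(i)),

where K is the partition constant (mM⁻¹) and ΔH the molar transfer enthalpy
of the solute from water to the bilayer. `fit_partition()` performs a
Levenberg–Marquardt fit over (K, ΔH) with log-parameterized K, selectable
concentration bookkeeping (volume-additive dilution by default), and
standard errors from the fit covariance. `derive_thermodynamics()` completes
the decomposition under a mole-fraction standard state:

    ΔG = −RT · ln(55.5 · K[M⁻¹]),   TΔS = ΔH − ΔG.

**Bilayer structure.** From GRO-style or XYZ coordinate frames with a JSON
topology sidecar: per-carbon deuterium order parameters
`S_CD = ⟨(3cos²θ − 1)/2⟩` with C–H vectors reconstructed from the
united-atom backbone (reported as −S_CD, 0.5 for perfectly ordered chains),
atomic-group distances from the bilayer centre of mass along z, and
phosphate-plane bilayer thickness.

**Synthetic data.** Every stage has a seeded generator
(`gen_gp_curve()`, `gen_polarized_quad()`, `gen_itc_thermogram()`,
`gen_bilayer_frames()`) that is its exact inverse in the noiseless limit,
so parameter-recovery round trips are testable end to end.

## Worked example

Simulate a sarmentine-like titration (75 µM solute in a 1.4565 mL cell,
5 mM lipid syringe, one discarded 2 µL injection + 28 × 10 µL at 600 s)
with 2 % heat noise, fit it, and decompose the thermodynamics at 26 °C:

```r
library(memprobe)

sim <- gen_itc_thermogram(K_mM = 1.69, dH_kJ_mol = 1.47, C_A0_uM = 75,
                          C_syringe_lipid_mM = 5, noise_cv = 0.02, seed = 42)
fit <- fit_partition(sim$experiment)
fit
#> Partition fit (dilution mode, ucal): converged
#>   K  = 1.7 +/- 0.0058 mM^-1
#>   dH = 1.474 +/- 0.0026 kJ/mol
#>   residual norm = 0.123 ucal over 28 points

derive_thermodynamics(fit, T_K = 299.15)
#> Transfer thermodynamics at 299.15 K (standard state 55.5 M):
#>   K   = 1.7 mM^-1
#>   dH  = +1.474 kJ/mol
#>   dG  = -28.491 kJ/mol
#>   TdS = +29.965 kJ/mol
```

The fitted K and ΔH recover the generating values within the noise, ΔG < 0
says partitioning is spontaneous, and TΔS ≫ ΔH says it is entropy-driven —
the classical hydrophobic-transfer signature.

A melting curve and a bilayer work the same way:

```r
plate <- gen_gp_curve(gp_noise_sd = 0.01, seed = 42)   # DPPC-like, Tm 41.5
estimate_tm(gp_table(plate))
#> Phase transition estimate (logistic):
#>   Tm = 41.509 degC, width = 0.715 degC
#>   GP plateaus: gel 0.601 -> fluid -0.203  (rms residual 0.0032)

g <- gen_bilayer_frames(n_lipids = 140, chain_length = 16, order_level = 0.8,
                        lipid_herbicide_ratio = 5, n_frames = 10, seed = 42)
head(order_parameters(g$trajectory, g$topology, "palmitoyl"), 3)
#>   carbon_index order_parameter          se n_frames
#> 1            1              NA          NA       10
#> 2            2        0.396991 0.004415919       10
#> 3            3        0.396991 0.004415919       10
bilayer_thickness(g$trajectory, g$topology)
#> Bilayer thickness (P-P): 4.259 +/- 0.0121 nm over 10 frames
```

A thin command-line wrapper over the same functions lives at
`inst/cli/memprobe.R` (subcommands `gp`, `anisotropy`, `itc-fit`, `order`,
`zprofile`, `run`), and `run_pipeline()` chains stages from a YAML
configuration into a merged JSON report with provenance.

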