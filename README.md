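# lnpsaxs

Model fitting for 1D small-angle X-ray scattering (SAXS) profiles of
mRNA-loaded lipid nanoparticles (LNPs).

LNP formulations differ structurally in how many concentric lipid bilayers
wrap the core: purely unilamellar particles show only a smooth polydisperse
sphere envelope in I(q), while multilamellar particles add an interference
bump near q ≈ 1 nm⁻¹ from bilayers stacked ~6 nm apart. `lnpsaxs` is for
formulation scientists and SAXS practitioners who want to turn reduced
(q, I, σ) curves into the quantities such studies tabulate: mean outer
diameter, multilamellar percentage, average layer number N_av, shell
electron-density profile, and reduced χ².

## The model

The form factor is a polydisperse core/tri-shell sphere. With the
homogeneous-sphere amplitude

    A(q, R) = 4π (sin qR − qR cos qR) / q³

the particle amplitude is the contrast-step sum
F(q) = Σᵢ Δρᵢ A(Rᵢ, q) over core + three 2 nm shells (polar / tail /
polar), P = F²/F(0)², averaged over a Gaussian core-size distribution with
σ/R_av = 0.2. Multilamellarity enters through a 1D paracrystal structure
factor with spacing disorder Δ = 0.01,

    S_N(q) = N + 2 Σₖ (N−k) cos(kqd) exp(−k q²d²Δ²/2),

normalized per layer and interpolated for fractional N. The measured
intensity is

    I(q) = scale · [(1 − f) + f · Ŝ(q)] · ⟨P⟩(q) + background,

where 100·f is the reported "multilayer %". Fitting is bounded
Levenberg–Marquardt with a coarse-scan initialization and multistart; see
`vignettes/lnp-saxs-model.Rmd` for assumptions, identifiability caveats
and numerical choices.

## Worked example

Simulate a strongly multilamellar formulation (outer Ø 84.8 nm, 72%
multilayer, N_av 2.3) at 2% counting noise, then refit it blind:

```r
library(lnpsaxs)
fx   <- table1_fixtures()$GV
prof <- simulate_profile(fx$particle, fx$stacking, fx$ip,
                         beamline_config(rng_seed = 7))
fit  <- fit_profile(prof, fit_config(rng_seed = 7))
summary(fit)
```

```
Multi-shell / paracrystal SAXS fit

Parameters:
                      estimate std_error  free
core_radius_mean     3.642e+01 1.304e-02  TRUE
rho_core             1.998e-01 6.966e-04  TRUE
rho_polar_in         1.000e+00        NA FALSE
rho_tail            -9.984e-01 2.335e-03  TRUE
rho_polar_out        9.960e-01 6.283e-03  TRUE
multilayer_fraction  7.192e-01 1.158e-03  TRUE
n_layers             2.301e+00 2.205e-03  TRUE
repeat_distance      6.301e+00 1.187e-03  TRUE
scale                1.002e+00 2.262e-03  TRUE
background           2.236e-07 8.507e-08  TRUE

Reduced chi^2: 1.002 on 393 points, 9 free parameters
Outer diameter 84.8 nm | multilayer 72% | N_av 2.30
```

Every generating value is recovered: diameter 84.8 nm (truth 84.8),
multilayer 72% (72), N_av 2.30 (2.3), repeat distance 6.30 nm (6.3), and
χ²ᵣ ≈ 1 says the fit is noise-consistent. The lamellar bump is confirmed
independently:

```r
detect_bump(prof)$detected
#> TRUE     (peak at q = 1.03 nm⁻¹, 252% above the unilamellar envelope)
```

`plot(fit)` shows data/fit and residuals;
`plot(electron_density_profile(fit$particle))` draws the radial
electron-density step profile. `run_recover("GV", n_seeds = 20)` repeats
simulate-and-refit across noise seeds and summarizes median recovery.

Assay helpers: `encapsulation_efficiency(120, 3)` → 97.5 (%) and
`hemolysis_percent(0.07, 0.05, 1.05)` → 2 (%).

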