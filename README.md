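# stimlimit

Analysis pipeline for **subretinal microelectrode stimulation within
electrochemical safety limits**, aimed at retinal-prosthetics and
neural-interface researchers who need to compare stimulating electrodes of
different diameters on a common, charge-limited footing.

Shrinking planar electrodes to the 10–30 μm diameters required for
high-acuity subretinal arrays shrinks the safe charge per pulse with the
geometric area. `stimlimit` quantifies what that limit leaves on the table,
in four parts:

1. **Electrochemistry** — charge storage capacity from cyclic voltammetry
   (time integral of anodic/cathodic current inside the −0.6…+0.8 V water
   window, per geometric area) and charge injection capacity (CIC) from
   biphasic-pulse voltage transients via the access-voltage decomposition
   E_m = ΔV − V_a, with the polarization read 10 μs after each phase and
   the limit refined by linear interpolation in charge. The per-phase
   charge budget is Q_max = CIC · πd²/4.
2. **Volume-conductor field model** — the static problem ∇·(σ∇V) = 0,
   E = −∇V for a disk injecting uniform current density: closed-form
   on-axis solutions (V(z) = I(√(z²+a²) − z)/(2πσa²)) plus a conservative
   axisymmetric finite-volume solver on a graded grid, verified against
   them. `activation_depth()` inverts the on-axis field at the 1000 V/m
   stimulation criterion; `required_current()` is its linear inverse.
3. **Spike-response statistics** — PSTHs, spontaneous-corrected evoked
   counts, charge thresholds at 50% response probability by
   lowest-crossing linear interpolation, half-max, and dynamic range
   DR = 10·log₁₀(max count within CIC / count at threshold), summarised
   per electrode diameter and protocol (single pulses vs 20-pulse 500 Hz
   trains).
4. **Synthetic data** — generators for CV scans, pulse transients and
   heterogeneous retinal ganglion cell populations with calibrated
   presets, so the whole pipeline runs and is tested without instrument
   data.

## Worked example

Charge limits for a 10 μm electrode, its field penetration, and a
simulated 60-cell population:

```r
library(stimlimit)

g <- electrode_geometry(10)
q <- max_injectable_charge(g, cic_mC_cm2 = 3.3)
q
#> [1] 2.591814

m <- volume_conductor(g, sigma_S_per_m = 0.2, domain = "fullspace",
                      domain_diameter_mm = 10)
activation_depth(m, I_A = q * 1e-9 / 1e-3)$depth_um
#> [1] 31.8204

arm <- simulate_population_study(rgc_population_preset(10), 60,
                                 protocol = "single", seed = 4010)
median(arm$cells$threshold_nC, na.rm = TRUE)
#> [1] 0.8616057
mean(!is.na(arm$cells$threshold_nC))
#> [1] 0.4333333
```

Reading: at the 3.3 mC/cm² injection limit a 10 μm disk carries at most
2.59 nC per phase (2.59 μA for a 1 ms phase), which drives the field above
the 1000 V/m activation criterion only to ~32 μm depth on axis at
σ = 0.2 S/m. The simulated population — calibrated to a 0.83 nC median
threshold and 47% responsive fraction — is recovered by the estimators
(0.86 nC, 43% at this seed and n).

The numbered scripts under `analysis/` run the three stages end to end and
write their tables to `results/`:

```sh
Rscript analysis/01_electrochemistry.R   # CSC, CIC, per-electrode budgets
Rscript analysis/02_field_model.R        # solver verification, depths, I(z)
Rscript analysis/03_populations.R        # thresholds, dynamic range, PSTH
```

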