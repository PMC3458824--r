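# skpentry

Analytics for how unfolded outer membrane proteins (OMPs) enter the cavity
of the trimeric periplasmic chaperone Skp. In *E. coli*, nascent β-barrel
proteins such as OmpC, OmpA and OmpF must cross the aqueous periplasm
unfolded; Skp catches them in a cage formed by three ~60 Å "tentacles"
whose Lys55 tips form a bottom mouth. The package implements the
quantitative chain used to dissect that uptake step — for experimentalists
fitting stopped-flow and FCS data, and for simulators analysing
coarse-grained entry trajectories:

* **Kinetics** — multi-exponential stopped-flow models
  `F(t) = F∞ + Σᵢ Aᵢ e^(−t/τᵢ)` (n ≤ 3) with deterministic multi-start
  least squares, AICc + runs-test order selection, half-time conversion
  `t½ = τ ln 2`, and directionality inference: fast-phase τ₁ ordered by
  label-site position with per-pair significance
  `|Δτ₁| > z √(SE²ₐ + SE²ᵦ)`.
* **FCS** — 2D single-species diffusion with relaxations,
  `G(τ) = (1/N)(1 + τ/τ_D)⁻¹(1 + Σᵢ aᵢ e^(−τ/τᵢ))`, and hydrodynamic
  mass from the cube law `M = M_ref (τ_D/τ_D,ref)³` against a dye
  reference, with a 1:1 stoichiometry check.
* **Sequence features** — charge/hydrophobicity profiles of OMP terminal
  fragments (negative {D,E}, positive {K,R,H}, hydrophobic
  {A,V,L,I,M,F,W,Y}), charge-neutralized mutants, termini comparison.
* **Trajectory analytics** — Kabsch superposition RMSD, gate open/closed
  states from inter-chain Lys55 distances, the signed axial entry
  coordinate ΔZ (positive = inside the cavity), salt-bridge events with
  4.5/6.0 Å hysteresis, and combined entry verdicts
  (entered / adhered_outside / escaped).
* **Synthetic data** — seeded generators for noisy traces, FCS curves and
  scripted bead-chain entry trajectories with exact ground-truth logs
  (five bundled scenarios under `inst/scenarios/`).

## Worked example

```r
library(skpentry)

# 1. Why does the N-terminus lead? Charge profiles of the OmpC termini:
profile_table(bundled_peptides()[c("OmpC_N", "OmpC_C")])
#>       id length n_hydrophobic n_charged n_negative n_positive
#> 1 OmpC_N     20             8         7          4          3
#> 2 OmpC_C     21            11         3          2          1

# 2. A triphasic stopped-flow trace at the study's time-constant regime:
tr <- gen_trace(1, c(-0.5, -0.2, 0.3), c(0.0826, 5, 200), noise_sd = 0.01,
                n_points = 300, duration = 1000, seed = 1)
select_model(tr)$fit
#> <exp_fit> 3 term(s), F_inf = 1.001, residual rms 0.00626
#>   tau_1 = 81.7 ms +/- 0.7 ms   A_1 = -0.4975 +/- 0.0016
#>   tau_2 = 4.85 s +/- 123.9 ms  A_2 = -0.2014 +/- 0.0019
#>   tau_3 = 199 s +/- 4.2 s      A_3 = +0.298 +/- 0.002

# 3. Entry direction from the published fast-phase constants (seconds):
infer_directionality(c("K55C", "E82C", "D128C"),
                     tau1 = c(0.0826, 0.125, 0.188),
                     se   = c(0.0055, 0.0078, 0.012))
#> <directionality_report>
#>   rank 1  K55C   tau1 = 82.6 ms +/- 5.5 ms
#>   rank 2  E82C   tau1 = 125.0 ms +/- 7.8 ms
#>   rank 3  D128C  tau1 = 188.0 ms +/- 12.0 ms
#>   ordering increasing; conclusion: bottom_first

# 4. A scripted entry trajectory, analysed end to end:
g <- gen_entry_trajectory(entry_scenario("n_first_entry", seed = 1))
entry_report(g$trajectory)
#> <entry_report> verdict: entered (terminus first: N_first)
#>   max dZ  NT +55.5 A, CT +17.6 A; gate open 70% of frames
#>   12 bridge events:
#>    Glu2–Arg71 (chain B) → Glu2–Arg71 (chain C) → Asp7–Lys55 (chain C) →
#>    Asp12–Arg71 (chain C) → Asp18–Lys55 (chain B) → Glu2–Arg91 (chain A)
```

Reading the output: the fast phase is quickest at the bottom mouth
(K55C), so the substrate meets the mouth first — Skp "swallows" the OMP
bottom-up; the trajectory report confirms the N-terminus crosses the
Lys55 plane first and climbs via an ordered ladder of salt bridges while
the gate stands open, closing after entry.

## Layout

```
R/              sequence, kinetics, fcs, trajectory/superpose/entry,
                synthetic, pipeline
inst/scenarios/ YAML scripts of the five bundled entry scenarios
inst/cli/       command-line wrapper
tests/testthat/ unit, property and acceptance suites (fixtures generated
                in code; dense-rotation RMSD oracle in helper-oracles.R)
vignettes/      methods vignette: models, defaults, design choices
scripts/        acceptance.R
```
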