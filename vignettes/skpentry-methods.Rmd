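---
title: "Models and methods behind skpentry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind skpentry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skpentry)
```

## The problem

Unfolded outer membrane proteins (OMPs) crossing the periplasm of
Gram-negative bacteria are protected by the trimeric chaperone Skp, whose
three ~60 Å α-helical "tentacles" enclose a central cavity with a bottom
"mouth" formed by the Lys55 tips. skpentry implements the quantitative
chain used to study how an unfolded substrate gets into that cavity:

* **stopped-flow kinetics** of dye-labelled Skp (self-quenching) and
  Skp–OMP FRET pairs, fitted with multi-exponential models to extract
  phase time constants and infer the direction of entry;
* **fluorescence correlation spectroscopy (FCS)** to estimate the
  hydrodynamic mass of chaperone–substrate complexes against a dye
  reference and check 1:1 stoichiometry;
* **peptide charge/hydrophobicity profiling** of terminal OMP fragments,
  the covariate that separates cavity-entering from non-entering peptides;
* **trajectory entry analytics** for coarse-grained simulations:
  superposition RMSD, mouth "gate" states from inter-chain Lys55
  distances, the signed axial entry coordinate ΔZ, salt-bridge events and
  a combined entry verdict;
* a **seeded synthetic-data generator** that produces every input the
  chain consumes, with exact ground truth, so the whole pipeline is
  testable without instrument or simulation output.

## Kinetic traces

A trace is modelled as

$$F(t) = F_\infty + \sum_{i=1}^{n} A_i\, e^{-t/\tau_i}, \qquad n \le 3,$$

with signed amplitudes ($A_i < 0$ for rising phases) and time constants
reported sorted ascending. Data earlier than the instrument dead time
(default 2.4 ms) are excluded from fits.

**Fitting protocol.** Multi-exponential least squares is notoriously
start-sensitive, so `fit_trace()` is a deterministic multi-start
procedure: time constants are scanned over a log-spaced grid from twice
the median sampling interval to the trace duration (all `choose(10, n)`
combinations); for each combination the baseline and amplitudes follow by
linear least squares; the best three starts are polished by
Levenberg–Marquardt with time constants parameterized on the log scale
(positivity for free). Standard errors come from the local curvature at
the optimum, with the delta method mapping log-scale errors back. The fit
is flagged *degenerate* when an amplitude is indistinguishable from zero
(below two standard errors, or below three times the residual RMS — the
second clause catches pure-noise traces whose fitted amplitude is
spuriously "significant").

**Order selection.** `select_model()` steps from one to at most three
terms and accepts the larger model only when the small-sample-corrected
AIC improves by more than 10 **and** the smaller model's residuals show
serial structure under a one-sided Wald–Wolfowitz runs test at level
0.05. Both thresholds are arguments; the defaults are deliberately
conservative so an extra exponential must both earn its parameters and
explain visible residual structure, mirroring the residual-based
reasoning used when choosing two- versus three-exponential fits of
stopped-flow data.

**Half-times and directionality.** `half_time()` converts via
$t_{1/2} = \tau \ln 2$ (a 128 s exchange half-time corresponds to
τ ≈ 184.7 s). `infer_directionality()` sorts fast-phase constants by the
axial rank of their label sites (Skp: K55C mouth → E82C waist → D128C
top; substrate: D25C → L139C → D290C from the N-terminus) and calls a
direction only when every adjacent pair differs by more than
$z\sqrt{SE_a^2+SE_b^2}$ (default $z = 2$) and the ordering is strictly
monotone; anything weaker is *inconclusive*. Published ± values are
treated as standard errors (values of this kind rarely distinguish fit
errors from replicate scatter) and $z = 2$ stands in for the unstated test
behind the ordinal claims.

## FCS

`fcs_model()` implements single-species two-dimensional diffusion with a
multiplicative relaxation factor,

$$G(\tau) = \frac{1}{N}\Bigl(1+\frac{\tau}{\tau_D}\Bigr)^{-1}
  \Bigl(1+\sum_i a_i e^{-\tau/\tau_i}\Bigr),$$

where $N$ is the mean occupancy of the confocal volume and $\tau_D$ the
translational diffusion time. The functional form is isolated in this one
function so an additive-relaxation convention could be swapped in without
touching the fitting code. Fitting mirrors the kinetics protocol
(diffusion-time grid × relaxation-time combinations, linear solve for the
amplitude block, bounded Levenberg–Marquardt refinement). Time scales are
bounded to the sampled lag range: a relaxation far below the shortest lag
is unidentifiable and, left free, silently biases $\tau_D$ — such fits
are instead flagged degenerate. Uniform weighting is the default, with
optional $1/G$ weighting, since the instrument noise model is unstated.

Mass inference uses the compact-species scaling
$M = M_{\mathrm{ref}} (\tau_D/\tau_{D,\mathrm{ref}})^3$ with a monomeric
dye reference (Cy3-maleimide, 0.767 kD), uncertainty propagated to first
order. No shape or hydration corrections are applied.
`stoichiometry_check()` compares a complex mass against the component sum
at a default 10% relative tolerance (85.8 kD against 39 + 50 kD deviates
by 3.6% and is consistent with 1:1 binding).

## Peptide profiling

The classification alphabet is fixed: negative {D, E}, positive
{K, R, H}, hydrophobic {A, V, L, I, M, F, W, Y}. No alphabet accompanies the published
per-fragment counts; this is the unique assignment that reproduces all
of them simultaneously (histidine must count as
positive for the OmpA fragment's three positive charges; glycine,
proline and threonine must be excluded from the hydrophobic set to give
8 and 11 hydrophobic residues for the OmpC N- and C-terminal fragments).
It is frozen and should not be changed silently. `neutralize_charges()`
builds the Ala/Asn charge-ablation mutants; `compare_termini()` orders
two fragments by total charge, the property that separates entering from
non-entering peptides.

## Trajectory analytics

Trajectories are fixed rosters of coarse beads — one backbone reference
bead per residue, plus charge-site beads carrying a ±1 sign — in
multi-frame PDB (beads as CA/CB atoms, charge sign in the B-factor
column) or XYZ with a JSON roster sidecar.

* **Cavity axis.** Reported entry coordinates are measured along a
  simulation-box axis, which a reusable tool cannot assume, so ΔZ is measured along the principal axis
  of the chaperone backbone cloud, recomputed per frame and oriented so
  the core ring (largest residue number) projects above the Lys55 ring.
  All analytics are therefore invariant under global rigid motion of each
  frame. When the gate is wide open the swung-out chain tilts this axis
  slightly (≤ ~1 Å in ΔZ for the bundled geometry), which can shift a
  zero-crossing frame by about one frame.
* **ΔZ reference.** The per-frame centroid of the three Lys55 backbone
  beads; a centroid is symmetric in the chains and robust to the mobile
  chain B. Positive ΔZ means above the mouth, i.e. inside the cavity.
* **Gate.** Pairwise Lys55 distances; *closed* requires at least two of
  the three pairs within `d_close` = 15 Å, so one chain swinging away
  (the open-mouth state) leaves the tight remaining pair but reads open.
* **Salt bridges.** Opposite-sign peptide–chaperone charge-site pairs
  bridge at `r_on` = 4.5 Å and break only above `r_off` = 6.0 Å. The
  hysteresis band suppresses chatter from thermal oscillation around a
  single cutoff; events per pair therefore alternate formed/broken.
  No distance criterion accompanies reported bridge series; these
  defaults follow common practice for side-chain charge-centroid distances and are arguments
  everywhere they matter.
* **RMSD.** `kabsch_superpose()` is an SVD Kabsch superposition with the
  determinant correction (proper rotations only). `rmsd_series()`
  superposes every frame on the whole-chaperone backbone and reports the
  RMSD of a selection *without* re-superposition, so per-chain series
  decompose the global deviation (a mobile chain B against quiet A/C);
  per-chain superposition is available as a flag since reported
  per-chain RMSDs can follow either convention.
* **Verdict.** *entered* requires both termini above the mouth throughout
  the final window (last 10% of frames); otherwise *adhered_outside* when
  at least one bridge is formed in every frame of that window; otherwise
  *escaped*. The terminus-first call is the terminus whose ΔZ first stays
  positive for five consecutive frames.

## The synthetic generator

The generator is kinematic, not dynamic: molecular dynamics is out of
scope, and scripted kinematics with exact ground truth is what the
analytics need for testing. Three tentacle chains span 60 Å from the
Lys55 mouth ring to the Asp128 core ring with side-to-side distance 25 Å
at and above the waist. The tips taper to radius 6.5 Å when closed
(pairwise 11.3 Å): tips in tight contact are what "closed" means here,
and this is also required for internal consistency of the 15 Å gate rule
— a mouth as wide as the waist would read open even when closed. The
open state swings chain B's lower half outward by 18 Å at the tip.

Peptides are bead chains (2 Å spacing, a collapsed-chain value chosen so
a 20-mer fits the cavity) that follow per-scenario motion scripts stored
as YAML configs under `inst/scenarios/`: `n_first_entry`,
`closed_gate_adhesion`, `side_approach`, `uncharged_escape`,
`c_term_escape` — mirroring, respectively, successful N-first
translocation with gate closure after entry, bridge-mediated adhesion
under a closed gate, failure to enter from the side, the charge-ablated
negative control, and the charge-poor C-terminal fragment's retreat.

Scheduled bridges pin the peptide's charge bead 2.8 Å from the partner
site, toward the axis (side-chain reach is not modelled, so a pinned bead
may sit away from its backbone bead); free charge beads are pushed clear
of every opposite-sign site. Jitter is Gaussian with SD 0.5 Å for
backbone beads and 0.1 Å for charge beads — charge sites jitter less
because neighbouring wall sites sit ~5 Å apart and the scheduled event
sequence must be unambiguous under the 4.5/6.0 Å hysteresis; for the same
reason the modelled chaperone charge sites are a sparse subset (K49, K55,
R71, E82, R91, D128 per chain). The generator re-runs the bridge detector
on its own output and refuses to return a trajectory whose event list
differs from the schedule, and it rejects infeasible schedules (a bridge
deep inside the cavity while the gate is closed and the peptide is still
outside). Scenario margins are chosen so the verdicts are robust to ±20%
changes of `d_close`, `r_on` and `r_off`.

Kinetic traces are the model plus additive Gaussian noise scaled to the
dynamic range (instrument-like); FCS curves get multiplicative noise
(shot-noise-like). Every generator is a pure function of its parameters
and seed.

**What passing tests do and do not show.** The generator reproduces the
*structure* of the real data — time-constant regimes spanning tens of
milliseconds to hundreds of seconds, decade-spanning FCS decays,
entry/adhesion/escape trajectories with gate and bridge dynamics — but
not photophysics (bleaching, triplet states), detector artifacts,
correlated instrument noise, force-field energetics or solvent. Green
tests certify the estimators and analytics against exactly known truth
under idealized noise; they do not certify instrument-specific
corrections, which are out of scope.

## Problem sizes and numerics

The bundled study conditions: traces of 300 log-spaced points over
0.0024–1000 s at 1% dynamic-range noise (the regime of the published
triphasic fits); FCS curves of 200 log-spaced lags over 10⁻⁷–0.1 s at 2%
multiplicative noise; trajectories of 150–200 frames with ~130 beads.
Stochastic properties use 100 replicates per regime and 25 seeds per
scenario. Optimizer tolerances are set to machine precision
(`ftol = ptol = 1e-15`) so noiseless round trips recover parameters to
~10⁻⁶ relative or better; ties in the multi-start are broken toward the
earlier (deterministically ordered) start. Degenerate inputs — flat
traces, collinear point sets, rosters missing a Lys55 bead, frames
missing a particle — raise errors or flags rather than silent results.

## Known limitations

* The exponential-order selector assumes roughly homoscedastic noise; a
  strongly intensity-dependent variance would need the weighted variant.
* Mass inference assumes compact, roughly spherical species; elongated
  complexes violate the cube law.
* The entry verdict is ΔZ- and bridge-based; a peptide hovering above the
  mouth plane but radially outside the cavity would need the radial
  coordinate, which the bundled scenarios avoid by construction.
* The PDB writer keeps the standard 0.001 Å coordinate precision; XYZ
  round trips are exact to 10⁻⁶ Å.
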