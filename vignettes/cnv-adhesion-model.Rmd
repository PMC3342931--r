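---
title: "A multicellular lattice model of choroidal neovascularization driven by adhesion failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multicellular lattice model of choroidal neovascularization driven by adhesion failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpotts)
```

## The model

Choroidal neovascularization (CNV) is the invasion of the outer retina
by capillaries sprouting from the choriocapillaris (CC).  `cnvpotts`
simulates this process with a three-dimensional Glazier–Graner–Hogeweg
(Cellular Potts) model of the CC–Bruch's membrane–RPE–photoreceptor
complex.  The central hypothesis embodied in the model is that CNV
initiation and its locus — sub-RPE (Type 1), sub-retinal (Type 2) or
combined (Type 3) — are controlled by graded failures of five adhesion
mechanisms: RPE–RPE labile adhesion and plastic coupling, RPE–BrM
labile adhesion and plastic coupling, and RPE–POS labile adhesion.

The lattice maps 2-µm voxels to generalized cells: Vascular cells of
the CC, activated endothelial Tip and Stalk cells, RPE cells,
photoreceptor outer/inner-segment compartments (POS/PIS), frozen
Bruch's-membrane (BrM) blocks, and Medium.  The effective energy sums

* **contact energies** over the 26-neighborhood (unit weights), encoding
  labile adhesion (more negative = stickier);
* a **volume constraint** `lambda_vol (v - V_t)^2` per cell;
* **breakable springs** between the centers of mass of junctionally
  coupled cells, `lambda/2 (l - r)^2`, released when stretched past
  twice their rest length or when the pair loses contact for 6 h —
  the plastic couplings of epithelial junctions and focal adhesions;
* **contact-inhibited chemotaxis**, `-lambda_chem (c(target) -
  c(source))`, applied when an endothelial cell advances into a
  non-endothelial voxel.

Metropolis index-copy dynamics accepts a proposed copy with probability
`min(1, exp(-dH/T))`; one Monte Carlo step (MCS) makes one attempt per
non-frozen voxel.  Boundaries are periodic laterally and fixed planes at
the choroidal base and the outer limiting membrane (OLM).

Four diffusing fields couple to the cells.  Oxygen enters at the CC and
is consumed in the PIS layer (RPE uptake is negligible).  RPE-derived
VEGF-A — secreted by the RPE, taken up by endothelium — is the survival
factor and chemoattractant for activated endothelium; short-diffusing
VEGF-A, secreted by all endothelium, mediates network self-organization.
The two VEGFs share a decay rate and differ five-fold in diffusion
length (50 µm vs 10 µm, a 25-fold ratio of diffusion constants).  MMP,
secreted by the tip cell, is nearly immobile (diffusion length under a
voxel) and stochastically converts BrM voxels to Medium with hazard
`rate * c * dt`.

A replica starts from the intact retina, optionally seeds a single Tip
cell in the CC at the lateral center, and runs for a simulated month
(mini preset) or year (full preset).  The tip degrades a roughly
one-cell-diameter hole through BrM and crosses it; after exactly 24 h it
differentiates into a Stalk cell and MMP secretion ceases.  Stalk cells
chemotax toward the RPE, grow at a rate proportional to local
RPE-derived VEGF-A unless contact-inhibited, and divide at a preset
doubling volume by a random plane through the center of mass.  CNV
*initiates* when the stalk-cell count first exceeds three.

## Quantification

Every 6 simulated hours a morphometric record is sampled from the
contact-area ledgers.  The morphometric weight

\[ MW = \frac{A(\text{stalk},\text{BrM})}
            {A(\text{stalk},\text{BrM}) + A(\text{stalk},\text{POS})} \]

locates the stalk population between BrM (MW → 1, sub-RPE) and the POS
(MW → 0, sub-retinal); it is undefined while stalk cells touch neither.
The stalk-weighted mean MW over the early and late windows (first and
last three months of a year, first and last quarters of shorter runs)
yields the early and late CNV types (Type 1 iff MW ≥ 0.75, Type 2 iff
MW ≤ 0.25, Type 3 otherwise) and hence one of nine dynamics classes
(S11, T12, P13, T21, S22, P23, T31, T32, S33).  The exceptional mid-MW
configuration in which stalk cells sit *between* RPE cells rather than
in either plane is flagged (`flag_interposed`) but still labeled
Type 3.

The 108 adhesion scenarios arise from the factorial of the five graded
parameters (RRl, ROl ∈ {3, 1}; RRp, RBl, RBp ∈ {3, 2, 1}; 3 = normal,
2 = moderately impaired, 1 = severely impaired).  Scenario ids follow
the lexicographic order, levels descending, with key priority
(RBl, ROl, RRl, RRp, RBp) — the unique lexicographic rule consistent
with every published id reference; it is validated anchor-by-anchor in
the test suite.  Level values: RPE–RPE contact energy −40/−18; RPE–BrM
−38/−28/−18; RPE–POS −16/−1; RPE–RPE and RPE–BrM spring stiffness
300/60/30.  `run_sweep()` manages replica batches over scenarios and
`fit_regression()` fits the response surface (five levels, all pairwise
products, ordinary least squares) for initiation probability, mean MW
or class frequencies; `project_symmetric()` tabulates it on the
symmetric reduction RRp = RRl, RBp = RBl.

## Parameters: what is fixed, what is calibrated

Anatomy and the adhesion tables are taken as published: layer
thicknesses (BrM 6 µm, RPE 12 µm, POS 30 µm, PIS 24 µm, OLM ≈ 67 µm
from the RPE face of BrM), the contact-energy table and the spring
ladder.  Everything else was hidden in the original implementation and
is recovered here by a fixed calibration protocol with four endpoints,
all of them published observations:

1. the intact all-normal retina is stable (no initiation, > 95% RPE–BrM
   coverage, POS never touches BrM) over a scaled month;
2. severe impairment of RPE–RPE labile adhesion alone makes initiation
   within a month (nearly) certain, with a sub-retinal early locus;
3. a free stalk cell at sub-RPE VEGF levels divides about every 12 h;
4. 24 h of tip-cell MMP secretion perforates BrM with a hole of roughly
   one cell diameter.

The calibrated values, chosen once against these endpoints and exposed
in `default_engine()` / `cell_type_catalog()`:

| parameter | value | role |
|---|---|---|
| temperature `T` | 14 | fluctuation amplitude; sets how often adhesive barriers are crossed thermally |
| `lambda_vol` | 5 | volume stiffness |
| interface tension | 56 | uniform addition to every unlike-pair contact energy (see below) |
| `spring_scale` | 0.1 | converts tabulated spring stiffness to lattice units |
| `lambda_chem` (RPE-VEGF) | 21500 (Stalk), 30000 (Tip) | chemotactic drive ≈ 60 (80 for the tip) energy units per voxel step at the intact VEGF gradient |
| `lambda_chem` (short VEGF, all EC) | 500 | network self-organization |
| MMP degradation rate | 2e-4 per (conc·s) | hole of ~1 cell diameter in 24 h |
| growth inhibition threshold | 0.28 | endothelial fraction of a stalk cell's boundary above which growth stops |
| growth pressure cap | 12 voxels | growth stalls while the volume deficit exceeds this (cells cannot press indefinitely) |
| survival threshold | 10% of intact apical [VEGF] | endothelial starvation level |

Three of these deserve comment.  *Interface tension*: taken literally
in the GGH Hamiltonian, an all-negative contact-energy table makes
every interface energetically favorable to roughen without bound, so
like-type cells interdigitate.  Adding a uniform constant to every
unlike pair (Medium–Medium excluded) preserves every pairwise adhesion
*difference* — the quantities the scenario gradings manipulate — while
giving boundaries a positive cost; 56 places the strongest adhesion
(RPE–RPE normal, −40) at an interface cost of 16 ≈ T.  *Spring scale*:
the stiffness ladder 300/60/30 has no published units; at face value
per voxel² it freezes all rearrangement (COM fluctuation 0.26 voxel),
so a global conversion factor is applied, keeping the ratios.  This is
consistent with the published observation that the plastic couplings
have only a minor effect on initiation.  *Pressure cap*: contact
inhibition alone cannot stop a confined cell whose target volume keeps
inflating — the `(v - V_t)^2` term would eventually crack any
interface.  The cap represents the inability of a cell to sustain
unbounded compressive stress; division then requires actual room to
double, which exists only along adhesively weakened interfaces.  This
mechanical compliance is what makes initiation scenario-dependent.

## Scale presets and problem sizes

The full preset (120 × 120 µm laterally, ~100 RPE cells, 12 months,
1 MCS = 1 simulated minute) reproduces the published study conditions;
a replica-year is an overnight computation.  The mini preset
(48 × 48 µm, 16 RPE cells, 64 photoreceptor columns, 1 month,
1 MCS = 4 simulated minutes) is the desk scale used by the test suite
and the acceptance protocol.  The coarser time resolution keeps cell
motility per simulated hour far above every fate timescale (24-h tip
lifetime, 12-h doubling, 6–12-h grace periods), which is the regime the
dynamics depend on.  Counts scale with area: the ~45-stalk-cell
confluent sub-RPE network of the reference domain corresponds to ~7–9
cells on the mini domain.

Fields are solved quasi-statically (successive over-relaxation to
steady state) at build time and every 6 simulated hours — their
relaxation times (minutes) are far below cell-movement timescales; the
explicit `step_field()` integrator exists for dynamic studies and is
validated against conservation and closed-form decay.  The MMP field is
re-solved every hour while a tip cell is active.

## The 1D oxygen profile

`oxygen_profile_1d()` gives the closed-form steady profile across the
outer retina: Dirichlet tensions at the CC face and the OLM, linear
through BrM, RPE and POS (no consumption), quadratic through the
uniformly consuming PIS, flux-continuous at interfaces.  "PO₂ at the
RPE" is evaluated at the RPE–POS interface: with PIS consumption
calibrated so that a CC tension of 80 mmHg yields 65 mmHg there,
dropping the CC to 60 mmHg yields ≈ 49.9 mmHg — reproducing both
published values, which is why the interface (rather than the RPE
midpoint) was adopted as the reading point.  The 3D solver agrees with
this profile within 2% on a laterally uniform retina (see the field
tests).

## What the synthetic scenes do and do not capture

The generated retina is an idealized hexahedral tissue: cuboidal RPE
cells on a flat BrM, photoreceptor columns on a square grid, a
deterministic ~70%-coverage CC labyrinth, no drusen or basal deposits,
no blood flow, no inflammation beyond its implicit encoding in the
adhesion levels, adhesion constant in time, and indefinite stalk-cell
proliferative capacity.  Passing tests therefore demonstrate that the
*adhesion-failure logic* — which interfaces open, where stalk cells
settle, when initiation occurs — behaves as published under these
idealized conditions; they do not validate quantitative rates against
any real retina.  Known limitations worth keeping in mind: scenario
discrimination rests on energy differences of order 20 per voxel face
against a fluctuation scale T = 16, so individual replicas near the
barrier occasionally cross it (the published sweep shows the same
stochasticity); on the mini domain this compresses the dynamic range of
the initiation probability — the weak-RPE-RPE scenario measures around
0.7–0.8 rather than 1.0, because an escaped stalk pair can stall as a
contact-inhibited clump below the four-cell initiation criterion — and
the periodic 48-µm repeat makes lateral confluence arrive sooner than
in the reference domain.

## Numerical choices

Copy proposals are drawn from the 6-neighborhood, contact energies from
the 26-neighborhood with unit weights.  Centers of mass are maintained
incrementally with periodic-image correction and audited against
brute-force recounts; `total_energy()` is a brute-force oracle used to
verify the incremental `delta_energy()` on randomized states to 1e-9
relative tolerance.  Junctions form when a pair's voxel-face contact
reaches 8 faces (32 µm²; the smallest intended anatomical junction is 9
faces, while transient fluctuation contacts stay below), with the rest
length set at formation.  Splitting uses a random plane through the
COM with a rank-based fallback for degenerate shapes.  Dying cells ramp
their target volume to zero over 6 h and are removed, avoiding
instantaneous holes.  Each replica runs on one deterministic RNG stream
derived from (base seed, scenario id, replica index); identical seeds
give bit-identical trajectories.
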