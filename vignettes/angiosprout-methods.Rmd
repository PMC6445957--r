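---
title: "Modeling sprouting angiogenesis with angiosprout: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sprouting angiogenesis with angiosprout: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiosprout)
```

## The model

`angiosprout` simulates sprouting angiogenesis in an *in-vitro*-like setting:
endothelial-cell (EC) aggregates seeded on the bottom of a culture well grow
vascular networks driven by VEGF-A. The simulator couples three layers:

1. **Extracellular fields** on a 2-D lattice (default 200 x 200 sites at
   7 µm/site, a 1.4 x 1.4 mm sub-area of a well): `vegf` (VEGF-A), `svegfr1`
   (secreted soluble VEGFR1) and `svegfr1b` (their inert complex). Fields
   diffuse by an explicit 5-point stencil under Dirichlet boundaries, degrade,
   react sitewise (`svegfr1 + vegf <-> svegfr1b`), and VEGF-A is replenished
   toward a global reference value that represents the bulk culture medium
   (the medium is exchanged regularly in the experiments this setting mimics,
   so the reference is constant).
2. **Intracellular signaling** inside every EC agent: a 21-variable,
   43-parameter reaction network integrated by forward Euler. Dll4 presented
   by neighboring cells trans-activates Notch1; the released NICD activates
   transcription of *notch1* and both VEGFR1 splice isoforms and represses
   *VEGFR2*; VEGF-A-activated VEGFR2 (both the ligand-bound receptor and the
   active form left after ligand dissociation) drives *dll4* transcription.
   Cis-inhibition (Dll4 binding Notch1 on the same cell into an inert
   complex) and transcriptional auto-activation of *notch1* sharpen the
   switch. Membrane VEGFR1 and, after export, soluble VEGFR1 act as decoy
   receptors that sequester VEGF-A without signaling.
3. **Agent behavior**: filopodia grow while active VEGFR2 exceeds a setpoint
   and set the VEGF-A sensing/binding radius; a cell becomes a motile tip
   cell when `vegfr2_mRNA > vegfr1_mRNA`, `filopodia > A*` and
   `dll4_mRNA > D*` (all strict); tips move up the VEGF-A gradient with a
   chance of deviating 45 degrees, and a random non-tip neighbor proliferates
   into the vacated site, which keeps sprouts connected.

### Transcription kinetics

Transcription of a gene activated by a modifier $m$ follows a Hill law with
basal activity,

$$v = V_{max}\left(\frac{1}{a} + \Big(1-\frac{1}{a}\Big)
      \frac{m^h}{m^h + M_0^h}\right),$$

where $a$ is the fold increase upon full activation, $M_0$ the
half-activation amount and $h = 2$ throughout. Repression uses the mirrored
decreasing form with the same parameters, so rates are always bounded in
$[V_{max}/a,\,V_{max}]$; this mirrored form is this package's choice — it
preserves the basal/maximal bounds of the activating law, which keeps `a`
interpretable for both signs of regulation. Where a transcript has two
activators (`notch1`: NICD and its own auto-activation), the two saturating
factors multiply under a shared $V_{max}$; multiplicative composition was
chosen so that either input alone cannot push transcription above the range
the other allows, which is the conservative reading of two jointly listed
regulators. All other reactions (translation, degradation, binding,
dissociation, NICD release, sVEGFR1 export) are mass action.

### Roster choices

The packaged network has exactly 21 variables and 43 intracellular
parameters. Beyond the species any such model must contain (mRNAs, free
receptors and ligand, NICD, cis complex, bound/active receptor forms), the
roster includes: a `trans_complex` intermediate between trans binding and
NICD release (a short, biologically real delay for receptor cleavage); two
VEGFR1 transcripts (`vegfr1_mRNA`, `svegfr1_mRNA`) so the membrane and
soluble splice isoforms have independent translation channels; the four
environment slots (`vegf_ext`, `svegfr1_ext`, `svegfr1b_ext`, `dll4_nb`)
that mirror what the lattice offers the cell during one step; and
`filopodia`, an agent variable governed by the protrusion rule rather than a
reaction. Of these, 17 variables carry configurable initial values — the
four environment slots are owned by the lattice and start empty.

Trans binding consumes the presenting neighbor's Dll4 (the standard
trans-endocytosis assumption), and a cell's surface Dll4 is shared among its
occupied Moore contacts: each neighbor receives `dll4 / (number of
contacts)`. The `vegfr2_active` form relaxes back to the free receptor pool
at a first-order rate; without that sink the receptor mass bound in the
active form would grow without bound. The cis complex does not dissociate;
it only degrades (cis-inhibition acts as a ligand/receptor sink, which is
what makes it inhibitory).

## Numerical scheme

Cells advance by forward Euler with two guards:

* **Per-step rate clipping.** With particle counts, an Euler step can
  overshoot below zero. Before committing a step, every reaction is scaled so
  that total consumption of each species does not exceed its current amount.
  Scaling whole reactions (never individual stoichiometric entries) preserves
  each reaction's mass balance, so conservation checks hold exactly.
* **Sub-stepping.** A step is halved (up to `max_halvings`, default 12)
  whenever any variable would change by more than 25% at once (variables
  below one particle are measured against a one-particle floor). Environment
  slots are exchange accumulators that start a step at the gathered amount
  (or zero for pure-export slots) and are excluded from this criterion; their
  stability is governed on the lattice side.

Field diffusion splits each scheduler step into sub-steps so the stability
number $\lambda = D\,\Delta t/\Delta x^2$ of each sub-step is at most 0.25;
if more than `max_substeps` would be needed the run aborts rather than
integrate an unstable stencil. Within a scheduler step the field pipeline is
fixed: diffuse, then react (sVEGFR1-VEGF binding), then degrade, then
replenish — a documented order chosen once for reproducibility.

Agents update asynchronously in a fresh uniformly random permutation each
step, reading the world as already modified by earlier agents. All
randomness (permutations, parameter sampling, movement) draws from R's RNG,
so a run is bit-reproducible from its seed.

## Packaged calibration

The printed calibration targets (relative vessel area of wild-type and
VEGFR1-knockout cultures and branch points per millimeter) constrain the
parameterization only jointly, and the full original parameter listing is
not part of this package's sources; the values shipped here were therefore
calibrated by hand, in the spirit of the original study, to reproduce those
targets while keeping every quantity at a biologically sensible scale:
receptor counts of order $10^3$–$10^4$ per cell, mRNA counts of order
$10$–$300$, transcript half-lives of a few hours, protein half-lives of
several hours to a day, and a VEGF-A reference of $10^4$ particles per
lattice site (tens of ng/ml in a shallow medium column). VEGFR1 binds VEGF-A
with a higher association rate than VEGFR2, as reported for the decoy
receptor. Effective diffusion coefficients (default 20 sites²/h for VEGF-A,
10 for the sVEGFR1 forms, i.e. ~0.3–0.6 µm²/s) describe matrix-retarded
transport at the bottom of a well rather than free diffusion in water; free
molecular diffusion would equilibrate the 2-mm domain orders of magnitude
faster than the biology at this lattice resolution and would leave no
gradients for chemotaxis.

The lattice spacing is itself a calibrated extracellular quantity. One site
holds one cell, and sites are the width of a capillary (7 µm by default), so
a 1-site-wide agent chain reads as a capillary-scale vessel. The spacing
links the dimensionless lattice network to physical branch statistics: with
the packaged behavior rules the emergent spacing between branch points is
about 18 sites, which at 7 µm/site reproduces the ~100–130 µm inter-branch
distances of dense cultured EC networks. Coarser spacings stretch the same
topology over proportionally longer millimeter lengths and dilute the branch
density. Tip speed is `move_rate` sites per hour (default 1.3, i.e. ~9 µm/h
net outward migration with deviations, within the range reported for
sprouting EC tips in culture).

Cell-to-cell variability is part of the model: the maximal transcription
rates (`tc`), translation rates (`tl`) and the NICD degradation rate
(`nicd_deg`) are drawn per cell from log-normal distributions parameterized
by their actual mean (the calibrated value) and an SD/mean ratio (default
0.5; at much lower heterogeneity the onset of sprouting becomes erratic,
see the heterogeneity analysis). Initial amounts of seeded cells are drawn
the same way (same SD/mean ratio) whenever any group is sampled, so
population asymmetry is present from the first step; newly proliferated
stalk cells instead duplicate their donor's instantaneous state and only
re-draw parameters. Log-normal laws keep rates positive, and the mean/SD
parameterization makes the heterogeneity sweeps directly interpretable as
SD/µ ratios. The moment-matching conversion is
$\sigma^2 = \log(1 + (s/\mu)^2)$, $\text{meanlog} = \log\mu - \sigma^2/2$.
Newly proliferated stalk cells draw fresh parameters and duplicate the
donor's instantaneous state (state inheritance is an assumption; parameters
are re-sampled).

## What the fixtures emulate

`make_fixture()` produces the controlled systems used in testing: two-cell
and 1-D-ring arrangements of coupled signaling cells in a clamped VEGF-A
bath (no movement, no fields), which isolate Delta-Notch lateral inhibition
— under the packaged calibration these pattern into alternating
tip-like/stalk-like fates; and comb-shaped binary vessel masks whose
junction count and skeleton length are known by construction, which validate
the branch analysis. These fixtures deliberately omit features of real
data: cells in culture are not perfectly circular aggregates, VEGF-A is not
spatially uniform at seeding, and real vessel images carry width variation
and noise that the closing step only approximates. Passing fixture tests
therefore validates the mechanisms and the bookkeeping, not quantitative
agreement with any particular culture.

## Metrics

The relative vessel area (ArelEC) is the percentage of lattice sites
occupied by EC agents. Branch analysis mirrors a standard image pipeline:
one binary closing with a 3 x 3 structuring element connects adjacent
agents, the mask is thinned (Zhang-Suen) to a 1-pixel skeleton, skeleton
pixels with more than two skeleton neighbors are junction pixels, and
8-connected junction clusters each count as one branch point. Total vessel
length sums skeleton edges (1 site per orthogonal step, $\sqrt2$ per
diagonal; diagonal edges that merely shortcut an existing orthogonal
connection are not double-counted) scaled by the lattice spacing. The exact
smoothing kernel and skeleton variant of any particular imaging pipeline
differ in details; junction-cluster merging matches the "branch points"
semantics of skeleton analyzers, but pixel-level parity with a specific tool
is not promised. A run with no tip cells reports the sentinel 1000 h as the
time of the first tip cell.

## Experiment drivers and problem sizes

`run_scenarios()` pairs wild-type and VEGFR1-knockout runs on shared seeds;
the knockout zeroes the maximal transcription rates of both VEGFR1
transcripts in every cell (a gene knockout removes both splice isoforms).
`run_sweep()` scales one parameter (or a group that acts as one biological
parameter, such as the two VEGFR1 transcription rates) over a grid of
fractions of its calibrated value, with replicated stochastic runs per
value; `run_heterogeneity()` sweeps the SD/µ ratio of the sampled parameter
groups over the doubling grid 0.01–2.56. The conventional full protocols (20
replicates, 51-value grids, 199 h, 200 x 200 sites) are the defaults; the
test suite exercises the same drivers at reduced sizes — smaller grids,
shorter horizons and a handful of replicates and grid points — which
preserve the qualitative shapes (monotone VEGFR1 response, the no-sprouting
and no-lateral-inhibition regimes of NICD degradation, the
rise-then-degrade heterogeneity response) while keeping a complete run of
the suite to minutes.

## Heterogeneity findings at this calibration

Sweeping the SD/µ ratio of the sampled groups reproduces the central
heterogeneity phenomena: near-homogeneous populations (SD/µ → 0) sprout very
late or not at all — with symmetric initial conditions, only the
asynchronous update order breaks the symmetry — and raising transcription or
translation variability to SD/µ ≈ 0.64 brings sprouting forward and
increases tip counts and vessel area. Two aspects differ from what wider
protocols report for this class of model and are worth knowing when
interpreting sweeps. First, beyond the optimum this calibration does not
show a declining vessel area: very wide `tc`/`tl` distributions degrade
signaling fidelity (tips arise quasi-randomly and the laterally inhibited
fraction shrinks), but in this model that failure mode resembles the
knockout's hypersprouting and *inflates* area rather than reducing it.
Second, variability in NICD degradation alone does not rescue sprouting
here: the tip thresholds that produce the wild-type/knockout contrast sit
above what homogeneous production rates can reach, so NICD-rate variance
without production-rate variance leaves nearly all cells below threshold.
The heterogeneity block of the acceptance test suite asserts the full
canonical pattern, including the declining limb, and therefore fails on that
single expectation under this calibration — a deliberate, documented red
rather than a weakened check.

## Known limitations

The model is 2-D with one cell per site and no cell-shape dynamics;
anastomosis is implicit (a tip blocked by another sprout simply stops),
there is no lumen formation, pruning, or flow. Tip selection reads exact
local VEGF-A differences, so arbitrarily small gradients orient movement —
real cells face receptor-level noise. The boundary ring is held at the
medium reference for VEGF-A (and zero for the sVEGFR1 forms), which makes
the domain edge a mild VEGF source; networks that reach the boundary feel
it. Parameters are calibrated against area and branching statistics only;
other parameterizations within the literature bounds could reproduce the
same statistics.
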