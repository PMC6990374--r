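---
title: "Modeling conduction block and re-entry in an idealized infarct border zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling conduction block and re-entry in an idealized infarct border zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Scar-related ventricular tachycardia is initiated when a premature beat
blocks at the mouth of a surviving conducting channel (isthmus) through an
infarct scar and re-enters from the opposite mouth. Two kinds of
border-zone (BZ) remodeling can create the substrate for that first block:

* **APD prolongation** — down-regulated repolarizing potassium currents
  lengthen the action potential, so the premature wavefront meets tissue
  that is still refractory;
* **conduction slowing** — reduced sodium-channel density (functional),
  gap-junction uncoupling (lower tissue conductivity), and infiltrating
  fibrosis (structural) depress excitability and conduction velocity, which
  both precipitates block at source-sink expansions and shortens the
  wavelength `CV x refractory period`, making any induced re-entry easier
  to sustain.

`infarctsim` implements the in-silico apparatus needed to compare these
substrates on a two-dimensional idealized infarct: a monodomain tissue
model with a human ventricular membrane model, a synthetic geometry and
fibrosis generator, S1-S2 vulnerability protocols, and automated
block/re-entry classification via the re-entry vulnerability index (RVI).

## Tissue and membrane model

Transmembrane voltage obeys the monodomain reaction-diffusion equation

$$\nabla\cdot(\sigma_m \nabla V_m) = \beta I_m,\qquad
  C_m \frac{\partial V_m}{\partial t} + I_{ion}(V_m,\eta) - I_{stim} = I_m,
  \qquad \frac{\partial\eta}{\partial t} = f(V_m,\eta)$$

with conductivity $\sigma_m$ (isotropic in 2D, 0.143 S/m in healthy
tissue), surface-to-volume ratio $\beta = 0.14\ \mu m^{-1}$, membrane
capacitance $C_m = 1\ \mu F/cm^2$, and the ten Tusscher-Panfilov (2006)
endocardial formulation for $I_{ion}$ and the 18 gating/concentration
variables $\eta$. Currents are expressed in the model's native pA/pF
scale; a stimulus of 100 uA/cm^2 for 1 ms is the standard pacing pulse.

Border-zone remodeling is applied only to isthmus (BZ-labelled) tissue:

| arm | parameter change | default |
|---|---|---|
| `prolonged_apd` | GKr to 20%, GKs to 30% of control | fixed |
| `reduced_ina`   | GNa scaled by `ina_scale` | 0.10-1.00 |
| conductivity    | BZ sigma scaled by `sigma_scale_bz` | 0.10-1.00 |
| fibrosis        | fraction of BZ elements made non-conducting | 0-0.90 |

The 2006 endocardial parameter set is used because the tissue of interest
is endocardial; the variant is recorded in every configuration echo. At
2 Hz steady pacing the control cell settles at an APD90 of about 277 ms;
the prolonged-APD cell reaches about 400 ms.

## Numerical scheme

* **Space**: vertex-centred finite volumes on the regular element grid
  (200 um spacing by default). Each face between two nodes collects half
  the diffusivity of each adjacent conducting element. Scar and fibrotic
  elements contribute nothing, which realises the no-flux internal
  boundary; the sheet boundary is no-flux by construction. The arithmetic
  (element-area) face average is essential rather than incidental: with a
  harmonic face average a single-element-wide conducting strand, or two
  conducting elements meeting at a corner node, would carry zero current,
  and dense fibrotic textures would disconnect far below the densities at
  which discrete myocyte lattices actually stop conducting. Corner-node
  ("diagonal") conduction is a real feature of node-coupled quadrilateral
  meshes and is what lets a 50%-fibrotic isthmus still conduct.
* **Time**: a single explicit step of `dt = 0.02 ms` advances reaction and
  diffusion together (no operator splitting). Hodgkin-Huxley gates use the
  Rush-Larsen exponential update with coefficients tabulated on a 0.05 mV
  voltage grid, which bounds gates in [0, 1] by construction;
  concentrations and the CaSS-gated variables advance by forward Euler.
  The diffusion stability bound at 200 um and the calibrated healthy
  diffusivity is about 0.098 ms, five times the default step. The
  production stepper is validated against an independent integration of
  the same equations in derivative form with `deSolve::lsoda` (adaptive
  stiff solver, no tables, no Rush-Larsen): a 1 s paced trace agrees to
  well under 1 mV RMS.
* **Reversal potentials** are refreshed every 25 steps (0.5 ms);
  intracellular concentrations drift far too slowly for this to matter at
  the 0.01 mV level.

### Conductivity calibration

The monodomain diffusivity is `D = cal * sigma / (beta * Cm)`. With
`cal = 1` the explicit scheme at 200 um conducts several percent below
the continuum velocity (spatial discretization error). Because the two
bulk conductivities of the tissue model are themselves stated as CV
calibration targets (0.6 m/s at 0.143 S/m, 0.4 m/s at 0.064 S/m), the
package fixes `cal = 1.20` once, balancing the residual error across the
two targets (both land within 3% of target; see
`analysis/02_cv_calibration.R`).
The sigma values themselves are never adjusted. CV follows the
square-root law in sigma within 5% on a 100 um / 0.01 ms grid over sigma
scalings 0.25-1.0; on the 200 um working grid the law degrades toward
low conductivity (around 10% low at the 0.25 scaling, see
`analysis/02_cv_calibration.R`) because the sodium upstroke then spans
only a few elements. For the same reason, halving the spatial and time
steps moves the healthy planar CV by about 7% — the expected behaviour
of explicit low-order schemes at this membrane stiffness, and the reason
the conductivity calibration is done at the working resolution.

### Event detection

Activation is the upward crossing of -20 mV; repolarization the downward
crossing of -74 mV, which is the 90%-repolarization level of the
endocardial action potential in tissue (rest about -86 mV, plateau about
+35 mV). Crossing times are refined by linear interpolation inside the
time step, so activation maps are accurate to well below `dt`. Capture
calls are insensitive to the threshold (a 40 mV shift moves activation
times by under 3 ms on a planar wave) and to the 150 ms capture window.

## Geometry and the fibrosis generator

`build_sheet(40, 200)` creates the 4 x 4 cm sheet (40,000 quadrilateral
elements). `add_idealized_scar()` labels two mirror-image scar segments
(half-ellipses with the flat side facing the channel) and the 4 mm
conducting isthmus of BZ tissue between them. The schematic this geometry
reproduces does not state the scar radii; the package default
(`scar_depth_mm = 16`, `scar_half_length_mm = 17`) fills most of the sheet
while leaving the mandated 2 mm healthy margins, producing a re-entrant
circuit (lateral corridor, top corridor, channel) long enough for the
blocked premature beat to find recovered tissue at the distal mouth — the
defining mechanism of isthmus-dependent re-entry. Circuit timing scales
with these radii, so absolute block/re-entry times — and with them the
exact S2 coupling interval at which block degenerates into re-entry — are
geometry-dependent even though the mechanisms are not. On the default
geometry the reduced-INa arm (scale 0.30) blocks and re-enters at the
standard 320 ms coupling interval; the prolonged-APD arm blocks at 320 ms
and exhibits its (narrow) re-entry window at a 340 ms interval, which is
the interval the mechanism demonstration uses for that arm. Sweeps always
use the fixed 320 ms interval.

`generate_fibrosis(grid, density, seed)` relabels
`round(density * n_BZ)` uniformly sampled BZ elements as non-conducting.
The sample count is exact (realized density within `1/n_BZ` of the
request), masks are reproducible per seed, and the caller's RNG stream is
never disturbed. Sampling is spatially uncorrelated; real post-infarction
fibrosis is patchy and anisotropic, so conclusions about *texture* are out
of reach — the generator emulates only the density-controlled random
topologies of the study design.

### The traversal assay

Whether a wavefront can cross a fibrotic isthmus is tested on a dedicated
geometry (`traversal_template()`) whose scar belt spans the full sheet
width. On the standard sheet the wavefront also travels around the scar,
so "tissue above the scar activated" would be true regardless of the
channel; with the full-width belt the channel is the only conducting path
and traversal is observable directly. Structural 4-neighbour percolation
of the myocyte lattice already fails near 50% fibrosis; conduction
survives slightly longer because corner-node coupling lets the wave cross
diagonal element contacts, and fails earlier than 8-neighbour percolation
would suggest because single-corner links are weak sources facing large
sinks. The assay asks the simulation, not the lattice.

## Protocols

Tissue is initialized from the 2 Hz / 100-beat steady state of each
region's cell (control for healthy tissue, remodeled for BZ), then paced
with three S1 at a 500 ms basic cycle length from a 1 mm band at the
bottom edge, followed by one S2 at the same electrode. The vulnerability
experiments use a fixed coupling interval of 320 ms, the interval at which
a premature beat still captures healthy myocardium (the measured capture
boundary is 310 ms, found by decrementing from 500 ms in 10 ms steps).
The boundary search reuses the S1-train prefix — states are checkpointed
at every candidate S2 time — so each candidate costs only a 180 ms
simulation.

## Classification

For each S1-S2 run the classifier applies, in order:

1. **INEXCITABLE** — the S1 train never activates the channel's centre
   cross-section band, which lies beyond electrotonic reach of either
   mouth, so the pathway carries no propagated activation from either
   end (the mouths themselves can be driven above threshold
   electrotonically even when the channel is completely inexcitable; an
   activation-order test would misfire instead on slow channels, where
   the wrap-around S1 wave legitimately enters the distal mouth and
   collides mid-channel); such runs are excluded from the probability
   denominators;
2. **re-entry** — sentinel nodes in healthy tissue beyond either mouth
   count activations occurring more than 50 ms after the last
   stimulus-driven wavefront has cleared the sheet (the latest
   first-activation within 400 ms of S2); each qualifying activation is
   one re-entrant cycle, and more than one cycle is *sustained* — this
   automates what was historically a visual judgment;
3. **block** — the minimum RVI of the S2 beat falls below 30% of the mean
   healthy-tissue APD of the last S1 beat *and* the S2 wavefront fails to
   transit the channel in the paced direction (transit is
   direction-resolved: channel entry, centre and exit must activate in
   that order — a blocked beat whose around-scar wave re-enters from the
   distal mouth also activates the channel, but top-down);
4. otherwise **NO_BLOCK**.

The RVI at a node d is `min over proximal neighbours p of
[rt(p) - at(d)]`, with "proximal" meaning `at(p) < at(d)` within a 2 mm
pairing radius. For the premature beat, tissue the S2 wavefront never
re-excites keeps its activation and recovery times from the S1 beat: the
"regaining of excitability of tissue just proximal" to a late-arriving
wavefront is its most recent repolarization, whichever beat produced it.
Without that backfill, a channel that blocks the S2 at both mouths would
be invisible to the metric. During uncomplicated propagation the RVI map tracks the
APD map (Pearson r > 0.9 on a homogeneous sheet and minima far above the
block threshold); negative values mark re-excitation of recovered tissue
behind a line of block. The pairing radius is exposed; minima move by
under 25 ms between 1 and 4 mm, well clear of the roughly 86 ms block
threshold.

Classification consumes only the crossing-event log, never the sampled
voltage traces, so it is invariant to the output sampling interval by
construction (and tested to be).

## The vulnerability sweep

`run_sweep()` runs one classified S1-S2 simulation per combination of
INa scale, BZ conductivity scale, fibrosis density and topology seed, and
`compute_pb()` aggregates block and re-entry probabilities with
inexcitable runs removed from numerator and denominator. Per-row fibrosis
seeds derive deterministically from a root seed, the density and the
replicate index, so any row is reproducible in isolation; rows are cached
on disk keyed by the full parameter tuple, making sweeps resumable.

The default sweep grid is reduced — scales {0.1, 0.25, 0.5, 1.0},
densities {0, 0.25, 0.5}, 3 seeds — and runs on the half-scale infarct
sheet (2 x 2 cm, half-scale scar, same 4 mm isthmus). The full 0.05-step
grid on the 4 x 4 cm sheet is a single flag away
(`sweep_spec(full_grid = TRUE)`) but amounts to thousands of multi-second
tissue simulations. The analysis scripts state the problem sizes used by
each experiment; the mechanism-demonstration runs use the full-size sheet
because circuit timing matters there, while monotonicity and structure
properties are established on the reduced grid. The half-scale sheet has
a re-entrant circuit much shorter than the wavelength, so blocked beats
abort their re-excitation attempt against refractory tissue: the reduced
sweep measures block statistics faithfully but yields essentially no
completed re-entries — re-entry statistics require the full-size
geometry. Passing the reduced-grid properties demonstrates mechanisms
and trends, not full-scale probability surfaces.

## Known limitations

* 2D isotropic monodomain only: no fibre anisotropy, no bidomain effects,
  no 3D scar topology.
* The ionic model is a single endocardial variant; no transmural
  heterogeneity, no drug or myofibroblast effects.
* Fibrosis is spatially uncorrelated; patchy/clustered textures would
  percolate and conduct differently at equal density.
* At this spatial resolution the channel still conducts a 500 ms-cycle
  beat with the sodium conductance at 10% of control, so complete
  pathway inexcitability arises here from fibrotic disconnection rather
  than from INa reduction alone; the INa level at which propagation
  fails outright is discretization- and model-variant-dependent.
* Scar radii are free parameters of the idealized geometry; absolute
  block/re-entry timings (and therefore the exact position of probability
  contours) depend on them, the mechanisms do not.
* The explicit single-rate stepper is simple and robust, but a factor ~5
  below its stability bound; implicit or adaptive schemes would be faster
  at equal accuracy and are out of scope.
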