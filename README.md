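# infarctsim

Monodomain simulation of conduction block and re-entry in idealized
infarct border zones.

## The problem

After a myocardial infarction, surviving strands of myocardium through the
scar — the isthmus, surrounded by the remodeled border zone (BZ) — form
the pathway of scar-related ventricular tachycardia. A premature beat that
*blocks* at one mouth of the isthmus and *re-enters* from the other
initiates the arrhythmia. Two remodeling phenotypes can create that
substrate:

* **APD prolongation** (down-regulated IKr/IKs): the premature wavefront
  meets still-refractory tissue;
* **conduction slowing** (reduced INa, gap-junction uncoupling via lower
  tissue conductivity, infiltrating fibrosis): depressed excitability
  precipitates block at source–sink expansions while the shortened
  wavelength `CV × refractory period` favours sustained re-entry.

`infarctsim` provides the apparatus for comparing these substrates in
silico on a 2D idealized infarct: tissue electrophysiology, synthetic
geometry and fibrosis, pacing protocols, and automated outcome
classification.

## What is inside

* **Membrane model** — ten Tusscher–Panfilov (2006) human ventricular
  myocyte, endocardial parameter set, with conductance-scaling remodeling
  (`remodeling_spec()`): prolonged APD (GKr→20%, GKs→30%) or reduced INa
  (scale 0.1–1.0). Rush–Larsen gate updates with tabulated coefficients;
  an independent `deSolve::lsoda` integration of the same equations in
  derivative form serves as the validation oracle (1 s paced traces agree
  to well under 1 mV RMS).
* **Monodomain solver** — `∇·(σ∇Vm) = β(Cm ∂Vm/∂t + Iion − Istim)` on a
  regular grid (200 µm), vertex-centred finite volumes, no-flux scar /
  fibrosis / boundary faces, explicit stepping at dt = 0.02 ms
  (compiled core). σ = 0.143 S/m conducts at 0.6 m/s, σ = 0.064 S/m at
  0.4 m/s (±3%).
* **Geometry / synthetic data** — 4 × 4 cm sheet (40,000 elements), two
  semicircular scar segments with a 4 mm conducting isthmus
  (`infarct_template()`), and seed-deterministic uniform fibrosis masks
  with exact density control (`generate_fibrosis()`).
* **Protocols** — 2 Hz × 100-beat steady-state initialization per region,
  three S1 at 500 ms cycle length plus one premature S2
  (`run_s1s2()`), capture detection, and a checkpointed coupling-interval
  decrement search (`find_min_capture_ci()`).
* **Metrics** — activation/repolarization/APD maps from sub-dt
  interpolated threshold crossings, conduction velocity, the re-entry
  vulnerability index `RVI(d) = min_p [rt(p) − at(d)]` over proximal
  neighbours p, and an outcome classifier
  (NO_BLOCK / BLOCK_NO_REENTRY / REENTRY_NONSUSTAINED /
  REENTRY_SUSTAINED / INEXCITABLE) using the 30 %-of-mean-APD RVI rule
  and sentinel-node cycle counting.
* **Vulnerability sweeps** — `run_sweep()` + `compute_pb()` produce block
  and re-entry probabilities `P = n/N` with inexcitable runs excluded.

## Worked example

Steady-state pacing of the control cell, then an S1–S2 run on the infarct
sheet with the sodium current of the isthmus reduced to 30 %:

```r
library(infarctsim)

ss <- pace_to_steady(cell_params(), frequency = 2, n_beats = 100)
tail(ss$apd_ms, 1)
#> [1] 277.2612        # steady APD90 (ms) at 2 Hz

g   <- infarct_template()   # 4 x 4 cm sheet, scar + 4 mm isthmus
rec <- run_s1s2(g, ci = 320,
                remodeling = remodeling_spec("reduced_ina", 0.30))
classify_outcome(rec)
#> $outcome
#> [1] "REENTRY_NONSUSTAINED"
#> $n_cycles
#> [1] 1
#> $mean_apd
#> [1] 286.622
#> $min_rvi
#> [1] -90.86419
#> $s2_transit
#> [1] FALSE
#> ...
```

The premature beat fails to transit the isthmus (`s2_transit = FALSE`),
the minimum RVI of the S2 beat is negative — the signature of
re-excitation behind the line of block — and the sentinel beyond the
distal mouth records one re-entrant cycle: block at the proximal mouth
followed by re-entry through the distal mouth. (This full-size run takes
about two minutes.)

The numbered drivers under `analysis/` run the complete set of
experiments — single-cell characterisation, CV calibration, the capture
boundary, the two mechanism demonstrations, fibrosis disconnection of the
isthmus, and the reduced-grid vulnerability sweep — writing their tables
under `results/`.

## Layout

```
R/, src/          package code (geometry, cell model, solver, protocols,
                  metrics, sweeps; compiled stepper under src/)
analysis/         numbered experiment drivers (01..06)
scripts/          acceptance.R
tests/testthat/   unit, property and acceptance tests
vignettes/        methods vignette (model, numerics, design choices)
```
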