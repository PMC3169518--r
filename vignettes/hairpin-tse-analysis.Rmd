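---
title: "Characterizing the folding transition state of a beta-hairpin peptide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing the folding transition state of a beta-hairpin peptide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpintse)
library(dplyr)
```

## The problem

Small peptides such as the 15-residue designed beta-hairpin with sequence
`SESYINPDGTWTVTE` fold with two-state kinetics: only a folded (F) and an
unfolded (U) population are detectable, separated by one free-energy
barrier whose top is the transition state (TS). `hairpintse` implements the
complete post-simulation analysis used to extract the transition-state
ensemble (TSE) from equilibrium folding trajectories of such a system and
to characterize it structurally and kinetically: order parameters, a
Boltzmann-inverted free-energy landscape with error bars, a grid-based
state decomposition, TS residence-time kinetics with path-scenario
classification, and distance-distribution analyses of the ensembles.

Because suitable microsecond trajectory data cannot be shipped with a
package, a synthetic trajectory generator with fully known ground truth is
a first-class component: every estimator in the pipeline is validated as a
parameter-recovery problem against the generator.

## Order parameters

Two native-topology progress variables drive the analysis.

**R parameter.** For the five native inter-strand C-alpha pairs of the
hairpin (E2–T14, S3–V13, Y4–T12, I5–W11, N6–T10),

$$R = \sum_{i=1}^{5} \frac{d_i^{\mathrm{nat}}}{d_i},$$

the sum of ratios between the native distance and the instantaneous
distance. R equals the pair count (5) in the native state and decays
towards small values as the strands separate. The functional form is the
simple sum-of-ratios reading consistent with both anchor values used
throughout (R of 5 in the native state; R near 2.1 in the unfolded basin);
this reading is stated explicitly in the documentation because variants of
the R coordinate exist in the literature.

**Fraction of native contacts Q.** A sidechain contact is formed when the
minimum distance between the heavy sidechain atoms of two residues is at
most 0.55 nm. The native contact list is derived from the reference frame
itself (never hard-coded), using a minimum sequence separation of 3 to
exclude trivial neighbours; glycine, which has no heavy sidechain atom, is
represented by its C-alpha. Q is the formed fraction of that list, so Q is
1 in the native state by construction.

An optional C-alpha RMSD (Kabsch superposition) supports a second
landscape on the RMSD–Q plane, used to quantify how sensitive the TSE is
to the choice of coordinates (`tse_overlap()`).

All distances are plain Euclidean distances in nm on whole-molecule
coordinates; trajectories from periodic simulations must be imaged onto
the molecule before import.

## Free-energy landscape

Frames pooled over all trajectories are binned on a 40 x 40 grid over the
order-parameter plane and converted to free energies by Boltzmann
inversion,

$$\Delta A_i = -RT \ln\left(p_i / p_{\mathrm{ref}}\right),$$

with R = 0.008314 kJ/(mol K), T = 300 K by default, and the reference cell
the most probable cell, so the global minimum is at zero and unoccupied
cells carry an explicit infinity, never a silent zero. The Q axis is fixed
to [0, 1]; other axes span the pooled data range (the grid resolution is
specified, not the bin edges, so basin *cell centers* are reproduced only
to within a bin width). Ties for the reference cell break to the lowest
bin index for reproducibility.

Errors use the subset scheme: trajectories are split into M = 3 disjoint
groups, each cell's free energy is recomputed within each subset anchored
to the *global* reference cell (keeping subsets on one scale; anchoring
each subset to its own mode was the alternative and is rejected because it
would mix basin-depth and mode-location variability), and the reported
sigma is the standard error of the mean across subsets. Cells unoccupied
in any subset are flagged unavailable rather than zero. Convergence of
individual cells is monitored by recomputing them from time-truncated data
(`convergence_trace()`), truncating every trajectory at the same elapsed
time.

## State decomposition

The folded state comprises the cells reachable from the global minimum by
8-connected flood fill over cells within 12 kJ/mol of it; the unfolded
state is grown the same way from the lowest local minimum not connected to
the folded basin within that cutoff (a candidate minimum must itself lie
within the 12 kJ/mol window — higher isolated minima are barrier-region
sampling noise, not basins). Every remaining occupied cell is TS: the
literal "everything at the top of the barrier" reading. Frames are
labelled by their grid cell.

Two refinements address known failure modes:

* **False folds.** A conformation can satisfy the folded-state definition
  on the order-parameter plane while having a clearly non-native turn.
  `refine_tse()` relabels any maximal F residence whose mean turn
  (N6–G9 C-alpha) distance exceeds 0.8 nm — a threshold placed between
  the native turn peak (~0.55–0.60 nm) and non-native geometries, exposed
  as a parameter because the underlying criterion is qualitative — and
  excludes the TS frames of the excursion that terminated in the false
  fold from the reported TSE.
* **Coordinate sensitivity.** `tse_overlap()` reports the fraction of
  reference-plane TS frames that are also TS under an alternative
  coordinate pair (directed overlap, with the R–Q labelling as the
  denominator), plus the symmetric Jaccard index, since "overlap" is
  ambiguous between the two.

## Path kinetics

Maximal TS runs flanked by basin states become path segments of four
classes: forward reactive U→TS→F, backward reactive F→TS→U, and
non-reactive U→TS→U / F→TS→F. TS runs touching a trajectory boundary are
discarded (unknown origin or destination). The residence time of a run of
k frames is k times the frame interval; this quantization matters when the
TS lifetime is comparable to the frame spacing (with 10 ps frames and a
~10 ps lifetime most excursions last one frame), and the tests quantify
the resulting bias against an exact geometric-distribution oracle.

The lifetime tau is the time constant of a monoexponential fit to the
residence-time histogram (bin width = one frame interval). The fit is
iteratively reweighted least squares on the log-linearized bin counts with
Poisson weights (`stats::glm` with log link); zero-count bins inside the
observed range are retained because dropping them biases the tail — and
hence tau — upward. The reported correlation is the Pearson r between
observed and fitted bin heights, the commitment fraction p_fold is the
fraction of excursions exiting to F, and the error on tau comes from the
same 3-subset scheme as the landscape errors. A mean-residence estimate
(the maximum-likelihood estimator for the discretized exponential, free of
the histogram-fit bias) is available via `method = "mle"`.

## Contact structure of the ensembles

Structural characterization uses five observables: the turn (N6–G9),
middle (Y4–T12) and end-to-end (S1–E15) C-alpha distances and the minimum
sidechain distances W11–P7 and W11–G9 (the sequence fixes residue 4 as
Tyr and 12 as Thr, so the middle pair is (4, 12) throughout).
Histograms are normalized frequencies with 0.02 nm bins — fine enough to
separate the folded middle peak (~0.54 nm) from the TSE middle peak
(~0.72 nm) — and are pooled frame-wise, so long excursions weigh more, as
in ensemble distributions. Per-path-class histograms of the TS frames
expose the folding nucleus: for the F→TS→F class the fraction of TS frames
with the middle contacts formed (C-alpha distance at most 0.6 nm, a
threshold between the folded and TSE peaks) is reported. The prior-to-TS
ensemble collects the frames within 1 ns before TS entry on forward
reactive paths, excluding frames already labelled TS or F, so it is
disjoint from the TSE by construction.

## The synthetic generator

`generator_config()` defines the study conditions; the generator is not a
tuning dial, and its defaults are fixed once:

* **Kinetics.** A discrete-time Markov chain at frame resolution: each
  state is left with per-frame probability dt/tau; a TS exit commits to F
  with probability p_fold, else U. Defaults: 6 trajectories of 2.5 us at
  10 ps frames, tau_TS = 10.2 ps, p_fold = 0.527. The basin lifetimes are
  not stated by the study this emulates; tau_U = 300 ps and tau_F = 600 ps
  were chosen once so that the stationary occupancy ratio places the
  unfolded basin minimum near 2 kJ/mol above the folded one at 300 K,
  matching the reported landscape. Discrete-time kinetics (rather than
  continuous-time with sub-frame events) matches what any analysis of
  frame-sampled data can observe and makes the geometric-residence oracle
  exact. The generator deliberately does not reproduce the real peptide's
  ~0.8 us folding time: basin lifetimes are compressed so that desk-scale
  runs contain enough folding events to exercise every estimator.
* **Fast-path emission.** `emit_series_only()` draws (Q, R) per frame from
  state-conditional Gaussians centred at (0.10, 2.10), (0.45, 3.50) and
  (0.85, 4.95) for U, TS and F. Basin widths (0.05 in Q, 0.25 in R) keep
  the basins well separated; the broader TS emission (0.12, 0.80) spreads
  the small TS population over many cells so that a typical TS-region cell
  sits near 14 kJ/mol, as in the reported landscape.
* **Geometry.** `emit_coordinates()` renders each frame from one of four
  noiseless templates (folded, TS, unfolded, folding-nucleus) plus
  isotropic Gaussian noise (0.02 nm). Templates are two flared antiparallel
  strands plus a turn, one C-alpha and one pseudo-sidechain atom per
  residue (glycine: C-alpha only, exercising the proxy rule). The strand
  separations and the solved turn-residue placement hit the configured
  turn/middle/end targets exactly: folded 0.55/0.54/0.42 nm, TS
  0.60/0.72/0.42 nm. (Reported TSE turn-peak values for this system vary
  between ~0.55 and ~0.60 nm; the generator uses F = 0.55 / TSE = 0.60,
  keeping the folded and TSE turn peaks distinct.) In the TS template the
  W11
  pseudo-sidechain is solved to sit 0.55 nm from both the P7 sidechain and
  the G9 C-alpha (the key-lock contact); in the nucleus template, used by
  a configurable 65% of F→TS→F excursions, the middle is closed and W11
  sits 0.30 nm from P7. Interpolation ramps (5 frames) into and out of the
  TS encode the mechanism — the open-chain template already has the turn
  residues close, so the turn is formed long before the ends meet, and the
  exit ramp closes the middle while releasing W11.
* **What it does not emulate.** No force field, solvent, or thermostat;
  no sub-frame recrossing; coordinate noise is isotropic and uncorrelated,
  unlike real thermal fluctuations. Passing tests therefore demonstrate
  estimator correctness under the assumed statistical structure, not
  agreement with any particular molecular system.

## Worked example

```{r pipeline}
cfg <- pipeline_config(
  generator_config(n_traj = 6, duration_us = 0.02, seed = 3),
  mode = "series"
)
report <- run_pipeline(cfg)
report
```

The fitted lifetime in this default report is *shorter* than the
configured 10.2 ps: at a 10 ps frame interval almost every TS visit lasts
a single frame, and the histogram fit can only see the quantized residence
law. The recovery tests therefore sample finely (0.25–1 ps frames), where
the quantization bias (about half a frame interval) is small; the
mean-residence (`"mle"`) estimator is unbiased at any sampling. This is a
real property of frame-sampled kinetics, documented rather than hidden.

```{r geometry}
gcfg <- pipeline_config(
  generator_config(n_traj = 3, duration_us = 0.01, seed = 6),
  mode = "geometry", min_events = 5
)
greport <- run_pipeline(gcfg)
greport$modal_distances
```

## Numerical choices and degenerate inputs

* Bin assignment is half-open with a right-closed final bin; frames
  outside the axis range raise an assignment error (impossible in-pipeline
  because the axes come from the same pooled data).
* A zero inter-strand distance (degenerate geometry), an empty native
  contact list, a collinear C-alpha set under superposition, a zero-width
  axis, fewer than 2 subset groups, fewer than 20 excursions for the
  lifetime fit, and a non-decaying residence histogram all raise typed
  errors rather than returning numbers.
* Mutually infeasible geometry targets (e.g. a key-lock placement whose
  anchor spheres do not intersect) raise a construction error naming the
  violated constraint.

## Problem sizes

The test-suite and validation runs use desk-scale problem sizes chosen as
the package's own defaults for its checks: landscape and state tests pool
(1–6) x 10^4 frames; kinetic recovery uses at least 2000 TS excursions per
condition (tau in {5, 10, 20} ps) at 0.25 ps sampling; the segmentation
oracle sweeps 10^4 random label strings. At these sizes the full suite
runs in about two minutes on one core.

## Limitations

* The TS definition is thermodynamic (barrier-top cells), validated
  kinetically through the monoexponential residence law — not by committor
  sampling, which is out of scope.
* The landscape is a raw histogram inversion: no reweighting, kernel
  smoothing, or enhanced-sampling estimators.
* Binary trajectory formats (XTC/DCD) are not read; any reader that can
  produce the tabular trajectory layout (or a multi-model PDB) can feed
  the pipeline.
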