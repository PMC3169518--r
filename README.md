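# hairpintse

Transition-state ensemble analysis for two-state peptide folding
trajectories.

Small peptides such as a designed 15-residue β-hairpin
(`SESYINPDGTWTVTE`) fold with two-state kinetics: a folded (F) and an
unfolded (U) population separated by a single free-energy barrier whose
top is the transition state (TS). Given equilibrium folding trajectories —
or the package's own synthetic generator with known ground truth —
`hairpintse` extracts and characterizes the transition-state ensemble
(TSE). It is aimed at molecular-simulation practitioners analysing
frame-sampled folding trajectories, and at method developers who want
every estimator in such a pipeline validated against an exactly known
generative model.

## What it computes

**Order parameters.** The inter-strand distance parameter
R = Σᵢ dᵢⁿᵃᵗ/dᵢ over the five native Cα pairs (E2–T14, S3–V13, Y4–T12,
I5–W11, N6–T10), which equals 5 in the native state; the fraction of
native sidechain contacts Q (minimum heavy-atom sidechain distance
≤ 0.55 nm, native list derived from the reference structure); optional
Cα RMSD with Kabsch superposition.

**Free-energy landscape.** Boltzmann inversion of the binned density on a
40 × 40 grid over the (Q, R) plane,
ΔA_i = −RT ln(p_i/p_ref), with the mode cell as reference, per-cell
convergence traces, and standard errors from M = 3 disjoint trajectory
subsets.

**State decomposition.** F and U are 8-connected flood fills within
12 kJ/mol of their basin minima; every other occupied cell is TS. The TSE
can be refined by excluding "false folds" (F-like cells with a non-native
turn) and compared across coordinate pairs (R–Q vs RMSD–Q overlap).

**Path kinetics.** TS excursions are segmented and classified
(U→TS→F, F→TS→U, U→TS→U, F→TS→F); the TS lifetime τ is a monoexponential
fit (Poisson-weighted least squares on the binned residence times) with
subset errors, and the commitment fraction p_fold counts excursions that
exit to F.

**Contact structure.** Distance distributions (turn N6–G9, middle Y4–T12,
end S1–E15, and the non-native W11–P7 / W11–G9 "key-lock" sidechain
contacts) for the TSE, the folded state, the per-path-class TS
subpopulations (including the folding-nucleus fraction of F→TS→F frames),
the 1 ns prior-to-TS ensemble, and per-excursion reactive time courses.

## Worked example

Recover the TS kinetics from synthetic trajectories with a configured
lifetime of 10 ps and folding commitment 0.527, sampled every 0.25 ps:

```r
library(hairpintse)
library(dplyr)

cfg <- generator_config(n_traj = 6, duration_us = 0.025,
                        frame_interval_ps = 0.25, tau_u = 50, tau_f = 50,
                        tau_ts = 10, p_fold = 0.527, seed = 1)
truth    <- simulate_states(cfg)
labels   <- select(truth$states, traj_id, time_ps, state)
segments <- segment_paths(labels, frame_interval = 0.25)
fit      <- fit_lifetime(segments, frame_interval = 0.25, n_groups = 3)
fit
#> <lifetime_fit> tau = 10.1 +/- 0.125 ps (wls, 2505 excursions)
#>   fit correlation = 0.9829; p_fold = 0.541, p_unfold = 0.459
```

The fitted τ = 10.1 ± 0.125 ps recovers the configured 10 ps lifetime,
and p_fold = 0.541 sits within sampling error of the configured 0.527
(binomial σ ≈ 0.010 at 2505 excursions).

The landscape route, on the order-parameter fast path:

```r
series <- emit_series_only(truth, cfg)
grid   <- subset_errors(build_landscape(series), series, 3)
find_basins(grid)
#> <state_defn> F seed (35, 29); U seed (5, 13); basin cut 12 kJ/mol
```

The folded seed cell sits at (Q ≈ 0.86, R ≈ 4.93) and the unfolded seed
in the cell containing (Q = 0.10, R = 2.10) — the imposed basin centres.
`autoplot(grid)` draws the ΔA surface; `tidy(grid)` and `glance(fit)`
return broom-style tibbles. `run_pipeline(pipeline_config(...))` chains
every stage and writes all intermediates plus a JSON/markdown report.

## Documentation

The methods vignette (`vignettes/hairpin-tse-analysis.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical choices and limitations.
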