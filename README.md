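# svrflow

Simulation and reconstruction of **slice-to-volume (SVR) 4D flow MRI** —
an approach to time-resolved volumetric blood-flow imaging that acquires
accelerated 2D spiral phase-contrast slices with a continuously swept slice
position (SWEEP) and fuses them into an isotropic, cardiac-resolved velocity
volume. Because the building blocks are 2D slices, blood benefits from
inflow enhancement and no contrast agent is needed; because the slice creeps
by a fraction of its thickness every TR, the slice direction is densely
sampled and super-resolution reconstruction to isotropic voxels is possible.

The package implements the whole chain with no scanner data required:

1. **Digital phantom** — pulsatile laminar vessels (including a bifurcation
   with an exact flow split) in a thorax-like scene, inflow enhancement,
   quasi-periodic cardiac triggers, complex receiver noise, and a
   second-order background phase field (`build_phantom()`,
   `sample_triggers()`, `inflow_signal()`).
2. **Acquisition** — golden-angle Archimedean spiral trajectory, four-way
   velocity-encoding interleave (V_o, V_TP, V_X, V_Y), SWEEP slice schedule,
   and exact non-uniform Fourier sampling (`design_spiral()`,
   `build_schedule()`, `simulate_sweep()`); plus a fully sampled,
   retrospectively gated 2D phase-contrast comparator
   (`simulate_2d_pcmri()`).
3. **CINE reconstruction** — overlapping slice windows (996 arms, 332
   shared at protocol scale), retrospective gating into ~50 ms cardiac bins,
   and compressed sensing with cyclic temporal total variation
   (30 iterations, weight 0.08) solved by proximal gradient with an exact TV
   prox (`reconstruct_cine_stack()`).
4. **SVR** — complex-valued slice-to-volume super-resolution through a
   Gaussian slice PSF with an edge-preserving Huber penalty (10 iterations,
   weight 0.01), to 1.2 mm isotropic (`reconstruct_svr()`).
5. **Flow quantification** — phase-difference velocity decoding
   (`v = VENC·Arg(x_k x̄_0)/π`), background-phase correction, automatic
   anti-aliasing, lumen segmentation, and mean flow / SNR / CNR
   (`make_flow_volume()`, `measure_vessel()`).
6. **Agreement** — paired-vessel linear regression with 95% CIs and
   Bland–Altman bias and limits of agreement, with plots
   (`agreement_report()`, `plot_agreement()`).

## Worked example

The bundled desk-scale experiment keeps the scanner reconstruction protocol
(TR 7.5 ms, VENC 150 cm/s, flip 15°, 4 mm slices swept at 0.005 mm/TR,
996/332-arm windows, TTV 0.08 × 30, SVR 0.01 × 10) on a 64 × 64 × 48 phantom
with six vessels, and runs in a few minutes on one core:

```r
library(svrflow)
cfg <- desk_experiment_config(seed = 1)
res <- run_experiment(cfg)
print(res$report)
```

```
Agreement over 6 vessel pairs (mL/s)
  regression: slope = 0.934 [0.750, 1.119], intercept = 0.08 [-0.13, 0.29], r^2 = 0.980
  Bland-Altman (2d_minus_svr): bias = -0.01, LoA [-0.14, 0.12]
```

Each pair is one vessel's cycle-mean flow measured twice: by the simulated
2D phase-contrast comparator and by the full SWEEP → CS → SVR chain. A slope
near 1 with high r² says the volumetric reconstruction reproduces the
slice-based reference across vessels spanning ~0.7–1.6 mL/s (the desk
phantom's pulmonary and systemic vessels); the Bland–Altman bias and limits
quantify the systematic and random disagreement in mL/s. `res$measurements`
additionally reports per-vessel SNR and CNR for both techniques, and
`plot_agreement(res$report)` draws the regression and Bland–Altman panels.
All intermediates (k-space archive, CINE stacks, NIfTI velocity volumes,
measurement tables, a manifest with stage timings) are persisted under
`cfg$output_dir`.

A command-line interface wraps the same stages
(`inst/cli/svrflow.R phantom|simulate|recon-cine|recon-svr|run-all
--config cfg.yaml`); YAML profiles are bundled under
`inst/extdata/profiles/` (`desk.yaml`, and `paper.yaml` for the full
scanner-scale protocol).

## Vignette

`vignettes/svr-4d-flow-methods.Rmd` documents the models (laminar phantom,
inflow, slice profile), the solvers (TV prox, majorize-minimize SVR step),
the numerical design decisions and their failure modes, and what the
simulation does and does not establish about real scanner data.
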