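---
title: "Simulated SVR 4D flow: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated SVR 4D flow: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`svrflow` simulates and reconstructs slice-to-volume (SVR) 4D flow
cardiovascular MRI end to end: a digital pulsatile-flow phantom stands in for
a pediatric thorax, a golden-angle spiral phase-contrast acquisition with a
continuously swept slice (SWEEP) produces raw k-space, compressed sensing
with cyclic temporal total variation (TTV) turns slice windows into
velocity-sensitive CINEs, iterative super-resolution fuses them into an
isotropic time-resolved velocity volume, and the flow/agreement stages
quantify vessel flows against a simulated fully sampled 2D phase-contrast
comparator. This vignette records the models, the numerical choices and their
rationale, and what the simulation does and does not establish about real
data.

## The phantom

Vessels are tubes around polyline centrelines with a laminar (Poiseuille)
axial profile, `v(r) = v_c (1 - (r/R)^2)`, scaled over the cardiac cycle by a
raised-cosine systolic pulse on a diastolic baseline. The parabolic profile
is the simplest physically sensible choice and gives the closed-form lumen
flow `pi R^2 v_c / 2` used as the analytic oracle throughout the tests.
A bifurcating vessel declares a parent and a flow fraction; the child's peak
velocity is derived so that mass is conserved exactly in the ground truth,
which turns flow conservation into a pipeline-level check rather than a
property of the phantom.

The scene is an elliptical tissue body with two low-signal lung regions (15%
of tissue signal) so that lumen-versus-lung CNR is measurable, air outside,
and a second-order in-plane background phase field applied to the
velocity-sensitive encodings only. Applying it to all four encodings
identically would cancel in the phase-difference decode and make the
correction untestable; physically, eddy-current phases differ per encoding
because the bipolar gradients differ.

Inflow enhancement uses a closed-form spin-replacement model: the
steady-state spoiled-GRE signal for static spins,
`sin a (1 - E1)/(1 - cos a E1)`, interpolated linearly toward the fully
relaxed `sin a` with the fraction of the slice replaced per TR
(`min(1, v TR / thickness)`). A Bloch simulation with spin histories is out
of scope; the model captures the feature that matters here - bright fast
blood, dim slow blood and tissue - and is monotone in speed by construction.

Cardiac triggers are quasi-periodic: R-R intervals are Gaussian with
fractional SD `rr_jitter_frac`, truncated at 3.9 SD so the trigger-train
invariant (intervals within `period (1 +/- 4 jitter)`) holds by construction.
The default period of 800 ms is a plausible pediatric resting value; heart
rates are configurable because the source cohort's rates are not public.

## Acquisition model

Every TR excites a Gaussian slice profile (FWHM = nominal thickness, also
the SVR point-spread function, for self-consistency), advances the slice by
`shift_per_tr_mm` (0.005 mm at scanner scale), rotates the spiral by the
golden angle (137.50776...&deg;, accumulated per TR), and cycles the velocity
encoding V_o, V_TP, V_X, V_Y. The signal is the slice-profile-weighted
complex sum over the slab of `magnitude x inflow scale x
exp(i (encoding phase + background phase))`, sampled along the rotated
Archimedean arm by an exact separable non-uniform DFT (two complex matrix
products per arm). At desk grid sizes this exact evaluation is faster than a
gridding NUFFT would be and removes interpolation error from every test;
the operator is unitary on a full Cartesian grid thanks to the symmetric
`1/sqrt(N)` normalisation.

The 2D comparator shares all of this physics but is fully sampled, so its
images are evaluated directly on the grid. Retrospective gating is emulated
by complex time-averaging over each cardiac bin (5 sub-samples): a real
segmented, gated scan averages the signal acquired across the bin, and
because inflow makes fast moments brighter, that average is
brightness-weighted. An instantaneous-snapshot comparator would be a
measurement no scanner can make and would spuriously disagree with the SWEEP
arm during rapid systolic transitions.

## CINE reconstruction

TRs are grouped into windows of `arms_per_window` (996 at protocol scale)
sharing `overlap_arms` (332), gated into uniform cardiac bins (count
`round(RR / 50 ms)` by default, nearest-bin assignment, cyclic), split by
encoding, and reconstructed by proximal gradient on

&nbsp;&nbsp;`0.5 sum_b ||W^1/2 (A_b x_b - y_b)||^2 + lambda sum |x(t) - x(t-1)|`

with cyclic temporal differences, radial density-compensation weights `W`
(ramp in `|k|`, unit mean; they make the weighted adjoint a usable starting
image and flatten the fidelity spectrum), a fixed step from a power-method
estimate of the per-bin operator norm, and an exact cyclic-TV proximal
operator computed by warm-started dual projected gradient. The TTV weight
0.08 is interpreted relative to `max |A^H W y|` and the solver runs exactly
30 iterations; both numbers are the reconstruction protocol.

Two properties of this objective are worth knowing. First, the L1 temporal
penalty pulls dim frames toward bright neighbours at transitions (soft
thresholding is biased); with strong inflow contrast this inflates diastolic
velocities slightly. The effect shrinks with more data per bin and more bins,
which is why the package's default experiment keeps the protocol's own
operating point (about 16 arms per encoding and bin, acceleration ~12,
~50 ms bins): at twice the protocol acceleration the chain leaves its
designed regime and velocity accuracy degrades visibly. Second, the recovery
benchmark compares against the fully sampled comparator band-limited to the
spiral's k-space disc; frequencies beyond `k_max` are unobservable by any
acquisition with that coverage and do not belong in a reconstruction error.

## Slice-to-volume reconstruction

Windows overlap in z, so the stack of CINEs oversamples the slice direction
with a known Gaussian PSF; SVR solves, per encoding and cardiac phase,

&nbsp;&nbsp;`0.5 ||S V - Y||^2 + mu sum_axes rho(grad V)`

with `S` the through-slice Gaussian matrix and `rho` a Huber penalty
(quadratic below 1% of the data maximum, linear above - edge-preserving).
SVR is complex-valued so signal phase survives into velocity decoding;
fusing decoded velocity maps instead would average wrapped phases
incoherently.

The solver is a majorize-minimize preconditioned descent: each step is
`V <- V - grad M^-1` with `M = S^T S + (12 mu + eps) I`, an upper bound on
the Hessian (`||grad operator||^2 <= 12`; Huber curvature at most 1). Because
`S` acts only along z, `M` is a small shared `nz x nz` matrix, each step
costs one Cholesky backsolve, and the objective is non-increasing by the
standard majorization argument. A fixed-step gradient method was considered
and rejected: the through-slice Gaussian at 4 mm FWHM has relative singular
values down to ~5e-5 on a 1.2 mm target grid, so in 10 iterations fixed-step
descent recovers almost none of the high-frequency content and cannot pass
the package's own inverse-crime and plate-resolution checks. With the
preconditioned step, `mu = 0` reaches the least-squares solution in a single
iteration, and the protocol's `mu = 0.01` for 10 iterations is a stable,
regularised inversion.

One consequence is documented rather than hidden: at the 2.4 mm plate
separation the slice PSF attenuates the distinguishing frequency by ~2e4, so
the data barely prefer two plates over one blob, and any positive `mu` makes
the edge-preserving penalty decide in favour of the smoother blob. The
super-resolution demonstration therefore runs with `mu = 0`; with measured
(noisy) slices the same inversion needs the Huber term, at the price of that
marginal resolution.

## Flow quantification

Velocity decoding is the standard phase difference against the
flow-compensated reference, `v_k = VENC Arg(x_k conj(x_0)) / pi`, per axis.
Background phase is fitted as a second-order in-plane polynomial to
static-tissue velocities by least squares and subtracted. Static tissue is
found automatically: signal above a noise-referenced floor (5x the 10th
percentile of time-mean magnitude - a fraction-of-maximum threshold fails
outright here because inflow makes blood an order of magnitude brighter than
tissue), time-mean speed below 15% of VENC, then a robust trim of voxels
inconsistent with a pilot fit (slow lumen rims leak through any velocity
threshold but are outliers against the smooth polynomial).

Anti-aliasing shifts voxels that differ from their 6-neighbourhood median
(4 in 2D) by more than VENC by `2 VENC` toward the median, iterated to a
fixed point with at most 10 passes, and reports the count of voxels still
inconsistent instead of raising an error - unresolvable aliasing is a
reported condition in practice, not a crash. Unwrapping is restricted to a
signal mask: air phase is uniformly random, so "unwrapping" it is
meaningless churn that can push spurious +/-2 VENC voxels against vessel
walls. The neighbourhood-median scheme is this package's stand-in for
unspecified vendor anti-aliasing and is labelled as such.

Lumen segmentation offers Otsu thresholding seeded at the vessel centreline
(single connected component, propagated to all phases) and a ground-truth
label mode. The end-to-end agreement experiment uses label masks as the
stand-in for the expert manual contouring used clinically: Otsu on
SVR-reconstructed magnitude, which is smoothed by regularisation, merges
neighbouring structures and measures contouring quality rather than flow
accuracy. The threshold mode is exercised and Dice-checked on the
high-contrast comparator where it is well posed.

Flow is `sum(v_perp) x pixel area / 1000` mL/s per phase, averaged over the
cycle. SNR and CNR follow the lumen-over-air and lumen-minus-lung-over-air
definitions with the Rayleigh correction `sqrt(2 - pi/2)` applied to the air
magnitude SD - the standard magnitude-noise correction, made explicit since
only "(corrected)" is specified clinically.

## Agreement analysis

Paired mean flows are compared by ordinary least squares of the SVR
measurement on the 2D measurement with t-based 95% CIs, and by Bland-Altman
with differences taken as 2D minus SVR (configurable) and limits at
`bias +/- 1.96 SD`. Mixed-effects modelling of SNR/CNR with participant
random effects is deliberately out of scope: it needs a cohort, not a
phantom.

## Study conditions and problem sizes

The bundled experiment (`desk_experiment_config()`, also
`inst/extdata/profiles/desk.yaml`) keeps every reconstruction-protocol
number at scanner scale - TR/TE 7.5/3 ms, flip 15&deg;, VENC 150 cm/s,
1.2 mm in-plane, 4 mm slices, 0.005 mm/TR, 996/332-arm windows, TTV 0.08 x
30 iterations, SVR 0.01 x 10 iterations, 1.2 mm isotropic output, ~50 ms
bins - and scales down only the scene: a 64 x 64 x 48 grid, a 24.9 mm sweep
(37 s of simulated scanning, 7 slice windows), six vessels including a 55/45
pulmonary bifurcation, receiver noise at 2% of tissue signal, 3% R-R jitter.
Velocities (45-100 cm/s peaks) and radii (4.2-6 mm) sit in the pediatric
great-vessel range. A run takes a few minutes on one core; the scanner-scale
profile (`paper.yaml`, 40 000 TRs over 200 mm) is provided for reference but
takes hours.

## What passing tests do and do not show

The phantom has rigid vessels, no respiratory or bulk motion, a single
uniform receive coil, no off-resonance, no T2* decay along the readout, and
slice positions known exactly from the SWEEP schedule (so SVR involves no
registration). Agreement between the two simulated techniques under these
conditions demonstrates the internal consistency and numerical correctness
of the reconstruction chain - operator adjointness, gating, regularised
inversions, decoding, correction and statistics - not clinical performance.
Conversely, effects that are genuinely physical are retained and measured
rather than idealised away: inflow-dependent contrast, gated temporal
averaging, undersampling artifacts, L1 regularisation bias, aliasing beyond
VENC, and Rayleigh-biased magnitude noise.
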