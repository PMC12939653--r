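---
title: "Models and methods behind angiotopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind angiotopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`angiotopo` simulates a closed loop in which MR angiography acquisition,
reconstruction, vascular-topology analysis and downstream physiological
proxies are coupled. This vignette explains each model, the parameters that
matter, and the choices made where the design was genuinely open. Everything
runs on synthetic data with known ground truth; no empirical claim here goes
beyond what the package's tests and `scripts/acceptance.R` compute.

## The vascular phantom

Phantoms are stochastic binary branching trees grown from a root near the
left image border: the trunk random-walks across the field with small
heading jitter (sd 0.10 rad per 0.5 mm step, with mild mean reversion), and
child branches split off at 35–65° with diameters tapered to 65–85% of the
parent. Collateral loops are cubic Bézier chords between interior points of
two distinct edges, departing perpendicular to each parent vessel; each
chord raises the cycle rank by exactly one, so β₀ = 1 and β₁ =
`n_collateral_loops` by construction. Resolvability constraints keep the
ground truth well defined at the imaging resolution: new centerlines are
truncated where they approach an existing segment (clearance about one
maximum diameter plus the point-spread width), chord interiors must enclose
a gap wider than the point-spread, and after rasterization the generator
verifies itself — the half-maximum segmentation must contain exactly
`n_collateral_loops` holes and the toolkit's default graph extraction of
the clean image must recover the ground-truth Betti numbers, otherwise the
draw is re-sampled (a loop thinner than the point-spread function is not an
imageable loop, so such draws do not define usable ground truth). The
intensity profile across each vessel is Gaussian with FWHM equal to the
local diameter, max-blended over vessels on a unit background; the default
vessel-to-background ratio is 4, typical of time-of-flight contrast.

Default study conditions, fixed before any comparison was run: 96×96 grid at
0.5 mm, 5 branches, 2 collateral loops, diameters 0.8–2.5 mm, k-space noise
σ = 0.05 (absolute, on unit-background images), ~70% acceleration with an 8%
fully sampled center band, and random samples restricted to a 65%
partial-Fourier region. The 96×96 grid (48 mm field) keeps a full
20-phantom closed-loop study at a few minutes per arm; the generator also
supports 192×192.

What the phantom does *not* emulate: MR relaxation and inflow enhancement,
coil sensitivities, partial-volume and pulsatility effects, 3-D geometry
(the generator is 2-D), and anatomically realistic branching statistics.
Passing tests therefore demonstrate correctness of the algorithms and the
direction of effects under controlled conditions, not clinical performance.

## Acquisition model and masks

Measurements are `y = F_M x + η` with a centered, unitary 2-D DFT and i.i.d.
complex Gaussian noise calibrated so `sqrt(E|η|²) = σ`. Motion is modelled
as a single rigid in-plane translation applied as a linear phase ramp to a
contiguous, randomly placed block of phase-encode lines; SNR reduction
(0–30%) attenuates the signal before noise is added.

Poisson-disc masks are built by dart throwing to saturation followed by
random thinning to the target density — the minimum-distance property holds
exactly and the achieved acceleration lands within ±2% absolute of the
target, else the call fails naming the maximum achievable density. The
center band is a contiguous block of phase-encode lines around DC, always
fully sampled. With `pf_fraction < 1` the random samples are confined to a
partial-Fourier region so that conjugate-symmetry completion has leverage.

## Reconstruction

`cs_reconstruct()` minimizes `½‖F_M x − y‖² + λ‖Ψx‖₁` by monotone FISTA
(MFISTA): the accelerated proximal-gradient candidate is rejected whenever
it would increase the objective, so the objective is non-increasing by
construction. With the unitary DFT the Lipschitz constant of the data term
is 1 and `step_size` must not exceed 1. Ψ is a 3-level orthonormal Haar
wavelet (the proximal step is exact soft-thresholding); identity and
finite-difference (Chambolle dual prox) transforms are available. λ defaults
to 2·10⁻³ for the unit-background phantoms — large enough to suppress
incoherent aliasing at 70% acceleration, small enough not to erase 1-voxel
vessels.

`reconstruct_full()` composes the priors: partial-Fourier completion runs
once as initialization (low-resolution phase from the center band, conjugate
fill, a few POCS refinements under the smooth-phase constraint); the Hankel
structured low-rank projection (window 16, rank 8, SVD truncation,
anti-diagonal averaging) can be interleaved every few iterations; a final
data-consistency projection makes the sampled k-space of the output equal
the measurements exactly when all weights are 1. Structured priors live
outside the ℓ₁ objective, so the monotonicity guarantee applies between,
not across, their applications. On the default phantoms the
partial-Fourier prior is the workhorse (≈ +1.5–3 dB over plain CS); the
Hankel projection is kept available and verified on its natural signal
class (sums of complex exponentials) but is disabled in the default study
configuration, where wavelet sparsity already captures the image structure
and hard rank truncation of k-space rows costs more than it stabilizes.

Per-sample confidence weights enter as `½‖W(F_M x − y)‖² + λ‖Ψx‖₁`; with
`W = I` this is exactly the unweighted solver, and zero weights are
algebraically identical to removing samples from the mask.

Stochastic realization ensembles re-solve the inverse problem K times under
controlled perturbations: fresh complex noise at `perturb_scale` times the
estimated measurement noise, and a log-uniform ±20% jitter of λ. This is
the "randomized regularization plus noise injection" route to uncertainty —
deterministic given the seed and free of learned components.

## Vascular topology

Graph extraction: Frangi-type multi-scale Hessian vesselness (scales 0.5–2
mm, blobness β = 0.5, scale-normalized derivatives, responses at a 3-pixel
border suppressed), hysteresis segmentation (default high threshold 0.12 of
the normalized response — low enough to keep junctions, where eigenvalue
symmetry depresses the tubularity score — with weak pixels above half the
threshold kept when connected to a strong core of at least three
above-threshold pixels; hysteresis stabilizes the graph against small
perturbations of the response around a single cut), Zhang–Suen thinning,
and tracing. Node pixels are those
whose 8-neighbourhood crossing number differs from 2 (robust to thinning
staircases), merged into junction clusters; edges carry the traced
centerline (lightly smoothed), its arclength, a diameter from the distance
transform, and a confidence equal to the mean vesselness along the
centerline. Pruning iteratively removes terminal spurs shorter than 2.5 mm
and acyclic components below that length, plus sub-threshold artifact
cycles (short self-loops and short parallel-edge pairs); edges on real
cycles are never removed.

Persistence is computed on the extracted graph as a 1-complex under the
superlevel-set filtration of edge confidence: edges enter as the threshold
decreases, dimension-0 classes merge by the elder rule (ties broken by edge
index; zero-persistence pairs are dropped), and each independent cycle
contributes an essential dimension-1 class born at the minimum confidence on
the cycle. Essential classes carry death = −∞ and are matched across
diagrams by birth; unmatched essential classes are penalized by their birth
(distance to 0). The Wasserstein distance between diagrams uses an exact
linear-assignment solve (shortest augmenting paths) over the standard
augmented cost matrix with L∞ ground metric and diagonal matching, order
q = 2. Correctness is pinned by brute-force oracles: threshold-sweep
recounts of β₀/β₁ for diagrams, and exhaustive matching enumeration for the
distance.

Betti deviation is normalized by the reference Betti total floored at 1;
branch completeness asks that ≥ 80% of a reference edge's centerline lie
within 1 mm of the reconstructed centerline (measured against the full
centerline point set, because the two graphs need not segment the network
identically); persistence stability is `1 − clamp(U/normalizer, 0, 1)` with
the reference total persistence as default normalizer. The composite macro
uncertainty uses the fixed weights (0.6, 0.25, 0.15).

## Adaptive acquisition

The expectation in the one-step lookahead objective is intractable, so the
policy uses the plug-in approximation: the current reconstruction stands in
for the unknown image when synthesizing a candidate's measurements.
Candidates add a fixed-size batch of unsampled locations drawn by
variable-density sampling biased toward under-covered radial annuli and
toward the Fourier magnitude of an image-space instability map (the
voxelwise standard deviation of the vesselness response across the
stochastic ensemble — a smooth proxy for unstable graph neighbourhoods).
Batch draws respect the acquisition geometry — only phase-encode lines the
acquisition already visits are eligible, so partial-Fourier row
restrictions stay intact — and enforce a blue-noise spacing constraint
within the batch and against the already-sampled set, so the grown mask
retains Poisson-disc incoherence.
Each candidate is scored by the drop in topology uncertainty estimated with
short surrogate reconstructions (default 12 iterations) and a small
ensemble (K = 3); ties resolve to the lowest candidate index, and all
randomness is seeded. The loop stops at the action budget or when U's
relative decrease falls below `tol_rel` (default 0.01); matched-acceleration
studies disable early stopping so both arms end at the same sampling
density.

## Cross-scale simulator

Flow: conductances `g = d⁴/(ℓ + 10⁻⁶)` (proportionality constant 1; only
ratios matter), Dirichlet boundary conditions (inlet pressure 1 at the
degree-1 node(s) nearest the declared inlet border, 0 at the remaining
terminals), sparse Laplacian solve, edge flow `g·Δp`. Velocities are
rasterized flow·tangent contributions, Gaussian-smoothed; the global
velocity scale is normalized so the fastest voxel moves ~1.5 mm/s, keeping
the transport problem well-conditioned across graphs whose absolute
conductances differ by orders of magnitude.

Transport uses explicit Euler with donor-cell upwind advection and a
flux-form 5-point diffusion stencil under zero-flux boundaries, so mass is
conserved to machine precision when decay and source vanish. The standard
parameters are D = 0.80 mm²/s, λ = 0.012 s⁻¹, Δt = 0.10 s, T = 60 s; the
joint explicit stability bound is dt ≤ 1/(4D/h² + (|uₓ|+|u_y|)/h + λ)
(≈ 0.078 s for pure diffusion at 0.5 mm spacing), so the cross-scale driver
shortens the step to 90% of the bound when needed while
`simulate_transport()` itself refuses unstable steps and names the maximum
admissible dt. The bolus enters as a Gaussian source footprint at
the inlet for 8 s. Perfusion endpoints are voxelwise peak, first-occurrence
time-to-peak, and trapezoidal AUC.

Viability integrates `dE/dt = αΦ − βΓ − γE` from E(0) = 0 with α = 1.10,
β = 0.85, γ = 0.06, and `P = 1/(1 + exp(−8(E − 0.20)))`. The supply Φ is the
AUC map normalized by its positive median; the demand is the bounded form
`Γ = min(2, 1 + deficit)` with the relative perfusion deficit measured
against the same reference. Uncertainty propagation runs the whole chain per
ensemble member and reports unbiased (n−1) variances: per-endpoint
voxelwise variance spatially averaged (`U_meso`), the voxelwise variance
map of P (`U_micro`), and its mean over the at-risk territory. The at-risk
territory itself is an open design point; here it is the perfusion-deficit
region — voxels whose lesioned AUC falls below 0.6 of the healthy median —
which reduces to a below-median-perfusion region when no healthy/lesioned
pair is available.

## Sensor layer

Synthetic streams share one clock: ECG at exactly 1000 Hz (Gaussian R-waves
on a drifting baseline), PPG and respiration at 100 Hz, and near-constant
scanner telemetry with Gaussian noise at plausible amplitudes. Instability
epochs inject high-variance bursts into the physiological channels.
Preprocessing is zero-phase (`filtfilt`): 0.5 Hz high-pass plus a 50 Hz
(configurable) notch for ECG, 8 Hz and 2 Hz low-pass for PPG and
respiration, z-scoring for telemetry. Channels are linearly interpolated
onto readout timestamps; the instability score is the per-channel robust
z-score (median/MAD) of a short-window rolling variance, clipped at a
saturation constant of 5 and combined across channels by maximum. The score
maps to weights by the affine rule `w = 1 − 0.3·s`, the simplest map
hitting the stated endpoints 1.0 (quiet) and 0.7 (maximal instability) —
moderate down-weighting rather than rejection. Weights are per
phase-encode line, matching how motion corruption enters k-space.

## Numerical and testing choices

All generators and solvers are pure functions of their arguments and a seed
(RNG state is saved and restored). Degenerate inputs have defined behavior:
empty segmentations yield empty graphs, empty diagrams have distance given
by diagonal/essential penalties alone, full masks short-circuit completion.
Problem sizes in the test-suite and acceptance studies (96×96 phantoms,
20-seed comparisons, 48×48 transport grids, K = 2–3 ensembles) were chosen
as the smallest sizes at which the studied effects are comfortably resolved.

One measurement subtlety is documented here because tests rely on it: a
pixel skeleton measures centerline length with systematic offsets — roughly
one parent radius of centerline is hidden inside the parent tube at every
bifurcation, and digitization noise of about a pixel acts at every terminal
and junction. The generator-consistency test therefore compares ground-truth
length against the skeleton length plus the junction correction, averaged
over seeds (the estimator is unbiased at the 2% level; individual seeds
scatter more).

Known limitations: 2-D only; no learned reconstruction components (the
reconstruction engine is purely classical); the Hankel prior is patch-wise
1-D rather than a global block lift; retrospective cardiac gating is reduced
to instability weighting; the cross-scale simulator is a lightweight
surrogate (no Navier–Stokes, no oxygen extraction) intended for uncertainty
propagation, not hemodynamic prediction.

A structural limitation of variance-based topology uncertainty deserves
emphasis: a vascular feature that is *consistently* absent from every
stochastic realization produces zero diagram variance and therefore no
uncertainty signal, so the adaptive policy cannot be guided toward it. The
measure flags fragile features, not confidently missing ones. In the
desk-scale studies this shows up as occasional runs in which the adaptive
arm loses a weak branch that a static blue-noise mask happens to capture;
under the default study conditions (70% acceleration, noise σ = 0.05,
resolvability-validated phantoms) plain compressed sensing itself preserves
topology in most runs, leaving the closed loop little measurable room for
improvement over a well-designed static mask. The benchmark functions
report these comparisons as measured.
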