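# angiotopo

Topology-aware adaptive compressed-sensing simulation for neurovascular
imaging, in R.

In accelerated MR angiography, pixelwise fidelity is a poor guide to what
matters clinically: whether thin vessels stay connected and collateral loops
survive reconstruction. `angiotopo` is a desk-scale, fully synthetic toolkit
for studying a closed acquisition–reconstruction loop that targets exactly
that failure mode. It couples:

- **Seeded vascular phantoms** with exact ground-truth centerline graphs
  (branching trees plus collateral chords, so the Betti numbers β₀ and β₁
  are known by construction), rendered as bright-vessel images and measured
  through a noisy Fourier (k-space) forward model with optional rigid-motion
  and SNR perturbations.
- **Compressed-sensing reconstruction**: the solver minimizes
  `½‖F_M x − y‖² + λ‖Ψx‖₁` by monotone accelerated proximal gradient
  (orthonormal Haar wavelet Ψ by default), with optional structured priors —
  data-consistency projection, patch-wise Hankel structured low-rank
  denoising, and partial-Fourier completion by phase-corrected conjugate
  symmetry — and per-sample confidence weighting
  `½‖W(Ax − y)‖² + λR(x)`.
- **Topology metrics on extracted vessel graphs**: multi-scale Hessian
  vesselness → threshold → thinning → graph, then superlevel-set persistence
  of edge confidence on the skeleton 1-complex. Summaries include the
  normalized Betti deviation Δβ, branch completeness BC, the ensemble
  Wasserstein uncertainty `U = E[d_W(PD(x̂⁽ᵏ⁾), PD(x̂))]`, persistence
  stability, and the composite
  `U_macro = w₁U + w₂(1 − BC) + w₃Δβ` with weights (0.6, 0.25, 0.15).
- **An adaptive acquisition policy** that proposes candidate k-space
  batches, scores each by the expected reduction of topology uncertainty
  using fast surrogate reconstructions and a plug-in synthesis of the
  candidate measurements, and grows the sampling mask greedily.
- **A macro–meso–micro cross-scale simulator**: Poiseuille-type conductances
  `g = d⁴/(ℓ + ε)`, Kirchhoff flow on the graph Laplacian, rasterized
  velocity fields, an advection–diffusion–reaction bolus model
  `∂c/∂t + ∇·(uc) = D∇²c − λc + S` (D = 0.80 mm²/s, λ = 0.012 s⁻¹,
  Δt = 0.10 s, T = 60 s), perfusion endpoints (peak, time-to-peak, AUC), an
  energy-based viability proxy `dE/dt = αΦ − βΓ − γE` with logistic survival
  `P = σ(8·(E − 0.20))`, and unbiased ensemble variances `U_meso`, `U_micro`
  propagated from reconstruction uncertainty.
- **A simulated sensor layer** (ECG 1000 Hz, PPG/respiration 100 Hz, scanner
  telemetry) with zero-phase preprocessing, shared-clock synchronization, a
  robust instability score, and the affine confidence map
  `w = 1 − 0.3·score ∈ [0.7, 1.0]` feeding the weighted reconstruction.

## Worked example

```r
library(angiotopo)

cfg <- experiment_config(seed = 4)        # 96x96 phantom, ~70% acceleration
res <- run_experiment(cfg)
res$metrics
#>      method seed acceleration  psnr_db      ssim       nmse betti_deviation branch_completeness
#> 1        cs    4    0.7057292 20.92594 0.7077165 0.03252275               0                   1
#> 2 cs_priors    4    0.7057292 22.24506 0.7222166 0.02400353               0                   1
#> 3  adaptive    4    0.7001953 23.46228 0.7634717 0.01813650               0                   1
```

At matched final acceleration (~70% of k-space never sampled), plain
compressed sensing reconstructs this phantom at 20.9 dB; the structured
priors gain ~1.3 dB; the closed loop reaches 23.5 dB at the same sampling
budget. All three preserve this phantom's topology (Δβ = 0 against the
densely-sampled reference graph, branch completeness 1); the aggregate
topology comparison over 20 seeded phantoms — where plain CS does break
features — is what `scripts/acceptance.R` recomputes. `res$loop$log`
records per-iteration uncertainty, acceleration and Betti deviation of the
adaptive run.

Lower-level entry points: `generate_vascular_phantom()`,
`poisson_disc_mask()`, `reconstruct_full()`, `extract_graph()`,
`superlevel_persistence()`, `wasserstein_distance()`, `run_closed_loop()`,
`simulate_cross_scale()`, `propagate_uncertainty()`, `generate_streams()`,
`confidence_weights()`. A thin command-line wrapper over
`generate_fixtures()` / `run_experiment()` / `run_benchmark()` is in
`inst/scripts/angiotopo-cli.R`. The methods vignette
(`vignettes/angiotopo-methods.Rmd`) documents the models, parameter choices
and limitations.

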