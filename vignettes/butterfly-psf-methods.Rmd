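---
title: "Butterfly networks for spatially variant PSFs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Butterfly networks for spatially variant PSFs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(butterflypsf)
```

## The problem

Bayesian imaging algorithms apply the instrument response — dominated by
the point spread function (PSF) — thousands of times inside an iterative
inference loop. A spatially *invariant* PSF is a circular convolution:
one FFT, a diagonal multiplication, an inverse FFT, `O(N log N)` work and
`O(N)` storage. Real telescopes and microscopes rarely oblige: their PSFs
change shape across the field of view, and the honest dense matrix costs
`O(N^2)` in both time and memory, which is prohibitive beyond modest
resolutions.

This package represents spatially variant PSFs with *butterfly
convolution operators* (BCOs): learnable linear operators with the wiring
of the radix-2 Cooley–Tukey FFT, so parameter count and runtime stay
`O(N log N)`, but with free per-layer parameters so the operator family is
much larger than circulant matrices. The operators are trained by maximum
a posteriori (MAP) estimation against simulated signal–response pairs and
then serve as the response in a Poisson-likelihood imaging model.

## The butterfly transform

A butterfly transform on `N = 2^n` entries is a product of `n` sparse
layers applied after a bit-reversal permutation of the input,

$$B = \Gamma_0\Phi_0\Theta_0\,\cdots\,\Gamma_{n-1}\Phi_{n-1}\Theta_{n-1},$$

where per layer `j`

* `Θ_j` mixes pairs of entries at stride `2^j` through a rotation-like
  2×2 block with one free angle `θ` per pair: `(a, b) ↦ (a cosθ + b sinθ,
  a sinθ − b cosθ)`; each block is real orthogonal.
* `Φ_j = diag(e^{iφ})` carries one free phase per entry.
* `Γ_j = diag(e^{γ})` carries one free log-amplitude per entry; any
  `γ ≠ 0` is exactly where the transform loses unitarity.

With `θ = π/4`, `γ = 0` and `φ` set to the Cooley–Tukey twiddle phases
(powers of `ω_N = e^{−2πi/N}`), `B` *is* the unitary discrete Fourier
transform; `fft_initialization()` returns precisely this configuration,
and the test suite pins it against a directly constructed DFT matrix at
`1e-10`. We fix the unitary normalization (`N^{−1/2}` overall): it is the
one the `Θ` parameterization produces at `γ = 0`, and it keeps the
initialization an isometry. The twiddle diagonal needed ahead of each
stride-`2L` stage is carried by the phase layer of the *preceding* stage,
which is what makes the per-layer order Θ, Φ, Γ compatible with the
standard decimation-in-time factorization. Bit reversal is applied to the
input; since conjugating the whole family by a fixed permutation does not
change the set of operators it can represent, this is a convention, fixed
(and asserted) only through the DFT-equivalence oracle.

Two designs cover 2D images on an `m × l` grid (both sizes powers of two):

* **flat** — the image is flattened column-major and one butterfly runs
  over all `N = m·l` entries: `log2(N)` layers with `N/2` angles and `N`
  phases/log-amplitudes each.
* **2D** — angles act axis-wise (one `θ` per row pair shared across all
  columns, and vice versa), while `Φ` and `Γ` stay full `m·l` diagonals;
  there are `max(log2 m, log2 l)` stages. This costs far fewer angle
  parameters and makes the initialization the separable unitary 2D DFT.

The flat design is strictly richer (its per-layer diagonals see the full
index space), which is exactly the trade the architecture comparison below
quantifies.

## Butterfly convolution operators and networks

A BCO sandwiches a free complex diagonal between a butterfly analysis and
synthesis pair:

$$O = B^\dagger \Lambda B \quad(\text{mirrored, shared parameters}),
\qquad O = B_1^\dagger \Lambda B_2 \quad(\text{non-mirrored}),$$

with `Λ = diag(e^{λ})`, `λ ∈ C^N` — the role the Fourier-transformed PSF
plays in the convolution theorem. With FFT-configured transforms and
`e^{λ} = √N · F k` (unitary DFT `F` of a kernel `k`) the operator is
exactly circular convolution with `k`; the circulant oracle test asserts
this to `1e-8`. BCOs compose into networks serially (`O_1 ⋯ O_n s`) or in
parallel (`(O_1 + ⋯ + O_n) s`, a plain unweighted sum). Since physical
responses are real images while a non-mirrored operator need not map real
to real, `network_apply()` returns the real part of the final vector.

Counting real degrees of freedom (one complex `λ` entry = two reals)
reproduces the reference architecture table exactly — e.g. one mirrored
flat BCO on 16×16 has `5120 + 512 = 5632` parameters, and the seven
presets `net1`–`net7` give 5632, 11264, 16896, 32256, 7872, 14208, 32256.
`count_parameters()` and `network_density()` expose this accounting.

At the *delta-peak initialization* (`fft_initialization()` plus `λ = 0`)
every BCO is exactly the identity: convolution with a unit delta. We
initialize `λ` at 0 rather than 1 because under `Λ = diag(e^λ)` a unit
spectrum — not a unit log-spectrum — makes the operator the identity.

## The synthetic spatially variant response

The ground truth the operators are trained against
(`svpsf_model()`, `apply_synthetic_response()`) blurs a point source at
pixel `z` with a rotationally symmetric Gaussian whose variance grows with
the source's relative distance from the image centre,

$$\sigma^2(\hat r) = \beta\,\hat r^2 + \eta,\qquad
\hat r = \lVert c - z\rVert_2 / r_{max} \in [0, 1],$$

defaults `β = 0.01`, `η = 10^{-5}`. Kernels use periodic boundaries
(minimal-image distances on the pixel torus) and the continuous
normalization `1/(2πσ²)` without discrete renormalization (a
`renormalize` flag flips this), so the near-singular central kernels
concentrate their mass in one pixel. Pixel coordinates are 0-based and
pixel-centred, the centre `c = ((m−1)/2, (l−1)/2)` is fractional for even
sizes, and `r_max` is the distance from `c` to the farthest pixel centre.

One unit choice deserves a note: `β` and `η` are variances in
*image-normalized* length units (the longer side of the image has length
1), converted to pixel units as `σ²_pix = σ² · max(m, l)²` when kernels
are evaluated. This keeps the parameters resolution-independent and is
the only reading under which the centre kernel is sub-pixel sharp while
border kernels blur over multiple pixels (σ ≈ 1.6 px at 16×16, ≈ 3.2 px
at 32×32) — the regime in which approximating the response is actually
hard and the imaging experiment shows centre/border asymmetry.

With `β = 0` the response degenerates to a single spatially invariant
kernel; the stack is then circulant and exactly representable by one
mirrored BCO, which gives the parameter-recovery test its known answer.

`build_response_stack()` materializes the response to a unit point source
at every pixel (a 16×16 grid gives 256 responses of 256 pixels) — this
stack is both the training target and the evaluation reference.

## MAP training

Training data are one signal–response pair per grid pixel: a point source
of brightness 40 and its simulated response (`training_pairs()`). The
joint Hamiltonian (negative log-posterior) combines a Gaussian likelihood
with diagonal noise covariance (default variance `10^{-6}` per data
pixel) and independent unit-variance Gaussian priors centred at the
delta-peak initialization:

$$H = \tfrac{1}{2\,\sigma_n^2}\sum_{\text{pairs, pixels}} (d - R s)^2
 + \tfrac{1}{2}\lVert p - \tilde p\rVert^2 .$$

`train_map()` minimizes `H` over all angles, phases, log-amplitudes and
spectra with a Newton-CG scheme:

* **gradients** come from hand-derived reverse-mode rules for each
  operator factor (the vector-Jacobian product of a butterfly program is
  its adjoint operator plus per-parameter accumulations);
* **curvature** uses the Gauss–Newton approximation — likelihood
  Jacobian products plus the prior identity — which keeps every CG system
  positive definite; forward-mode (JVP) rules supply the
  Jacobian-vector products;
* a backtracking (Armijo) line search guarantees the accepted-step loss
  trace is non-increasing, which the tests assert.

Numerical defaults: CG stops at a relative residual of `1e-5` times the
gradient norm or after `cg_max_iter` iterations (default 100; the test
suite uses 30, which trades a slightly slower per-step contraction for
cheaper steps), line search halves up to 40 times, and training is fully
deterministic (full-batch data, fixed initialization, no stochasticity).
A quasi-Newton fallback (`optimizer = "lbfgs"`) is available since the
reference procedure fixes only "Newton-CG" and not its internals.

The operator passes run through a compiled C++ engine; a plain-R
implementation of the same four passes (forward, tape, VJP, JVP) is kept
as the reference, and the suite asserts the two agree to round-off. On
one CPU core the full 16×16 reference run (Net4, 256 pairs, 300 Newton
steps) takes about five minutes; the 8×8 architecture comparison runs in
seconds. A 32×32 training to the ~1% error level uses the same code but
is a multi-hour computation, so the shipped tests assert the 16×16 run at
full scale and the architecture *ordering* on 8×8.

## Evaluating the approximation

For stacks `R_sim` (simulated) and `R_but` (butterfly), the per-position
relative error and the total error are

$$\hat\epsilon_z = \frac{\lVert R_{sim}[\delta_z] - R_{but}[\delta_z]
\rVert_2}{\lVert R_{sim}[\delta_z]\rVert_2},\qquad
\hat\zeta = \frac{\lVert R_{sim} - R_{but}\rVert_2}
{\lVert R_{sim}\rVert_2},$$

with plain Euclidean norms (root of the sum of squares — the ~1% result
scale is only consistent with the rooted norm). They satisfy, and the
tests check, `ζ̂ = 0` for a perfect representation, `ζ̂ = 1` for the zero
map, scale invariance, and the weighted-mean identity
`ζ̂² = Σ_z ε̂_z² w_z / Σ_z w_z` with `w_z = ‖R_sim[δ_z]‖²`.
`radial_error_histogram()` pairs each `ε̂_z` with its `r̂_z`; the wider
border kernels carry visibly larger errors than the sharp central ones.

Run at the reference scale, `bf_fit(svpsf_model(bf_grid(16)),
network_preset("net4", bf_grid(16)))` reaches `ζ̂` ≈ 1.2%, and the 8×8
surrogate reproduces the architecture ordering: more BCOs help
(net1 > net2 > net3), non-mirrored beats mirrored, flat beats 2D.

## Poisson imaging with a trained response

`reconstruct_map()` performs the downstream application: photon counts
`d` observed through the spatially variant response are inverted by MAP
with the trained operator standing in for the instrument. The model is
generative: a standard-normal latent field `ξ` maps through the
inverse-gamma quantile transform (`inverse_gamma_transform()`, shape
`α = 1`, scale `q = 1` by default) to a strictly positive signal `s(ξ)` —
heavy-tailed, as befits point sources — and the joint Hamiltonian

$$H(\xi) = \sum_i \big[\mu_i - d_i \ln \mu_i\big] +
\tfrac{1}{2}\lVert\xi\rVert^2,\qquad
\mu = \max(R\,s(\xi),\ 10^{-8}),$$

is minimized over `ξ` with the same Gauss–Newton CG machinery (`d/μ²`
curvature weights). The clip at `10^{-8}` is applied to the *rates* —
the predicted signal response — exactly where positivity is needed for
the Poisson likelihood, since a learned non-mirrored operator can output
small negative values. Points outside the representable range of the
quantile transform evaluate to `+∞` so the line search backs off rather
than erroring. The returned object carries the positive signal estimate,
the predicted rates, and the absolute data residuals `|d − μ̂|`; an
optional diagonal-curvature (Laplace) signal standard deviation is
available as a labelled approximation — it is a curvature summary at the
mode, not a sampled posterior.

On a seeded 15-source scene (brightness 900–1000) at 16×16, sources in
the central half of the field are recovered as local maxima exactly at
their true pixels; sources near the border, blurred over `σ ≈ 1.6` pixels
and subject to Poisson shot noise, are detected but typically land within
one pixel of the truth — the reconstruction ambiguity expected at the
image borders, visible in the residual diagnostics.

## What the synthetic generator does and does not emulate

The generator produces radially symmetric, smoothly varying Gaussian
blurs with periodic boundaries and exactly known ground truth. It does
not emulate detector effects (readout, vignetting, pixel cross-talk),
radially *asymmetric* PSFs of real optics, energy or time dependence, or
non-periodic field edges. Passing tests therefore demonstrate that the
operator family and the training machinery can represent and recover a
smooth spatially variant blur at the ~1% level under known conditions —
not that any particular real instrument is representable at that level,
although nothing in the parameterization exploits the synthetic model's
radial symmetry.

## Design choices that were genuinely open

* **Normalization of the realized FFT** — unitary (`N^{−1/2}`), the
  unique choice reachable with `γ = 0`; the `1/N` convention would
  require non-zero `γ` at initialization.
* **Bit reversal on the input side** — either side spans the same
  operator family; the choice is fixed by the DFT oracle test.
* **2D stage interleaving** — row stage, then column stage while any
  remain, then one full diagonal pair per stage; verified against the
  parameter-count table.
* **`λ` initialized at 0** (unit spectrum) so the initial operator is
  the identity.
* **Spectrum counting** — one complex `λ_j` as two real parameters; the
  only convention that reproduces every printed architecture count.
* **Gauss–Newton rather than full Newton curvature** — positive definite
  by construction, standard for least-squares Hamiltonians.
* **Inverse-gamma prior coupled through the quantile transform** of a
  standardized latent (the generative-model convention), rather than a
  direct density parameterization; the direct alternative would change
  the optimizer geometry but not the prior.
* **Archive format** — JSON text with 17-significant-digit doubles;
  round-trips are bit-exact and the files are human-readable.

## Known limitations

* Grids must be powers of two per axis (radix-2 wiring only; no
  split-radix or prime-factor variants, no learnable permutations).
* Posterior uncertainty is limited to the optional Laplace diagonal; no
  variational or sampling-based posterior is provided.
* Training materializes a full response-pair batch and a per-layer tape,
  so memory grows as `O(N^2)` with the grid — comfortable at 16×16 and
  32×32, not designed for 1024×1024 training (applying a trained
  operator, by contrast, stays `O(N log N)`).
* The per-pixel training set assumes the response to every point source
  is available, as it is for a simulated or calibrated instrument.
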