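---
title: "Methods: bias-free robust NMF for mitral valve segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias-free robust NMF for mitral valve segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valveseg)
```

## The model

An echocardiographic video is a nonnegative tensor $X^{3D} \in
\mathbb{R}_+^{s_x \times s_y \times t}$; vectorizing the spatial dimensions
row-major gives the pixels-by-frames matrix $X \in \mathbb{R}_+^{s \times t}$
with $s = s_x s_y$. The pipeline assumes

$$X = WH + S + N,$$

where $WH$ ($W \in \mathbb{R}_+^{s \times r}$, $H \in \mathbb{R}_+^{r
\times t}$, small rank $r$) captures the static background and the rigid,
periodic motion of the myocardium; $S \ge 0$ is spatially sparse and
captures the fast, non-rigidly moving valve; and $N$ is roughly Gaussian
observation noise. The natural estimator penalizes $\|X - WH - S\|_2^2 +
\lambda \|S\|_1$ under nonnegativity of all factors.

### Bregman debiasing

A plain $\ell_1$ penalty shrinks every recovered amplitude by about
$\lambda$ and, worse, lets the low-rank term swallow the valve as $\lambda$
grows. `bregman_rnmf()` therefore replaces $\|S\|_1$ by its Bregman distance
to a running subgradient $p$: each outer iteration applies, in order,

1. $S \leftarrow \sigma_\lambda(X - WH + \lambda p)$, with
   $\sigma_\lambda$ the nonnegative soft threshold (`soft_threshold_nonneg()`);
2. $p \leftarrow p + \tfrac{1}{\lambda} (X - WH - S)$;
3. one multiplicative update of $W$, then of $H$ (numerators of the form
   $\lvert A\rvert - A$ with $A = (S - X)H^\top$, which keeps the factors
   nonnegative);
4. normalization of the columns of $W$ to unit Euclidean norm, compensated
   in the rows of $H$ (removes the scale ambiguity without changing $WH$).

Wherever $S > 0$, step 2 forces $p = 1$, so step 1 no longer shrinks that
entry: detected amplitudes are recovered without the $\ell_1$ bias. The
scheme is initialized by plain multiplicative NMF with $S = 0$ (uniform
$(0,1]$ random factors from the configured seed) and is run for a fixed 100
outer iterations, relying on early stopping rather than convergence: run to
convergence the Bregman iteration would eventually also fit the noise. The
`freeze_p = TRUE` option keeps $p \equiv 0$ and reproduces classical
(biased) robust NMF; it exists purely as the ablation baseline.

`exclusion_rnmf()` adds $\mu_2 \langle WH, S\rangle$, discouraging the
low-rank and sparse parts from sharing pixels; with $\mu_2 = 0$ every update
line reduces algebraically to the plain scheme (this degeneracy is tested to
$10^{-10}$).

### Convex-relaxed segmentation

The binary valve mask is relaxed to $B \in [0,1]^{s \times t}$ minimizing

$$\tfrac12 \langle \Theta - \hat S, B\rangle + \lambda_1\,\mathrm{TV}(B) +
\lambda_2 \langle \mathbf 1, B\rangle + \lambda_3 \langle \hat W \hat H,
B\rangle,$$

equivalently $\tfrac12\langle\Theta_2 - \hat S, B\rangle + \lambda_1
\mathrm{TV}(B) + \lambda_2\langle\mathbf 1, B\rangle$ with the spatially
varying threshold $\Theta_2 = \Theta + 2\lambda_3 \hat W\hat H$: a pixel is
pushed toward 1 only where the sparse component exceeds the local threshold,
and the presence of muscle raises that threshold. TV is isotropic with
forward differences and replicate boundary, applied within each frame
(spatial only; no temporal coupling, following the printed discrete
operator). The saddle-point form is solved by the primal-dual hybrid
gradient iteration: dual ascent projected onto per-pixel discs of radius
$\lambda_1$, primal descent with the data gradient $\tfrac12(\Theta_2 -
\hat S) + \lambda_2$ followed by clipping to $[0,1]$, and extrapolation
$\bar b = 2b^{k+1} - b^k$. The printed update line of the original
algorithm contains an undefined symbol and is inconsistent with the energy;
this implementation uses the gradient of the stated smooth term, which
reproduces the stated energy (the identity of the two energy forms is
tested to $10^{-10}$). The relaxed mask is binarized by a strict threshold
at 0.5 (ties map to 0, an arbitrary but fixed convention).

**Step sizes and iterations.** $\tau = \sigma = 1/\sqrt 8$ (the forward
difference operator satisfies $\|D\|^2 \le 8$), 500 iterations by default;
neither is stated in the source account, both are config-overridable, and
configurations violating $\tau\sigma\|D\|^2 \le 1$ are rejected.

**Isotropic TV and thresholding.** For *anisotropic* discrete TV the coarea
formula is exact, so thresholding a relaxed minimizer yields an exact binary
minimizer; this is verified in the test suite against exhaustive enumeration
on small instances. For the *isotropic* TV used here (and in the source
account) the coarea formula holds only approximately: the test suite
contains a $3\times3$ instance whose relaxed minimizer is genuinely
fractional, with the binarized energy $\approx 4\cdot 10^{-3}$ above the
true binary minimum. The shipped default remains isotropic for fidelity;
the anisotropic option (`segmentation_config(tv = "anisotropic")`) exists
so the solver itself can be oracle-verified.

### Refinement

The sparse component is summed over frames (`temporal_projection()`); the
valve location is the mass-weighted centroid of this accumulation map,
iterated 11 times with pointwise multiplication by a centered isotropic
Gaussian of decreasing scale (`iterative_centroid()`), which suppresses
outlying bright structure. The schedule is geometric from $\max(s_x,s_y)/4$
down to $\max(s_x,s_y)/16$ — the source states only that the scale
decreases; the endpoints were chosen so the first Gaussian spans roughly the
sector and the last a valve-sized neighborhood, and both are
config-overridable. The binary mask is then split into 6-connected
spatiotemporal components (`connected_components_3d()`; face adjacency in
the row/col/frame lattice — temporal connectivity matters because open
leaflets form two spatial blobs that merge through the closing frames), and
only the component whose minimal *spatial* distance to the centroid is
smallest is kept (ties toward the smaller label; the frame coordinate is
ignored because the centroid is spatial).

### Windowing

`detect_window()` scans a fixed-size rectangle over the sparse component of
one exclusion-regularized factorization of the whole video and keeps the
position maximizing the covered energy $\sum S^2$ (a summed-area table makes
the scan linear in image size; ties break lexicographically). Segmentation
inputs are then restricted to the winning window. The window size is the
caller's knowledge of the valve's approximate extent; the stride defaults
to 1.

## Hyperparameters

| stage | parameter | default | meaning |
|---|---|---|---|
| muscle detection | $\lambda$ | 0.1 | sparsity weight |
| | rank $r$ | 2 | background rank |
| | outer iterations | 100 | Bregman early stopping |
| | init NMF iterations | 200 | warm start (free choice) |
| segmentation | $\Theta$ | 0.01 | base threshold |
| | $\lambda_1$ | 0.04 | TV (boundary length) weight |
| | $\lambda_2$ | 0.075 / 0.05 | area weight, automatic / windowed |
| | $\lambda_3$ | 1.0 | muscle-exclusion weight |
| windowing | $\mu_1$ | 1 | sparsity weight |
| | $\mu_2$ | 0.4 | exclusion weight |
| | rank | 5 | background rank |
| refinement | iterations | 11 | centroid attenuation rounds |

The windowed mode lowers $\lambda_2$ because the window already limits the
spatial extent, so the area penalty can be relaxed to capture more of the
valve.

## The phantom: a stated world

`generate_phantom()` builds videos with the exact additive structure the
model assumes, plus voxel-level ground truth:

* **Background**: an exact rank-$\le r$ tensor — a bright sector outline
  (side walls and outer arc of an apical view) with a constant temporal
  profile, plus smooth wall blobs modulated by slow nonnegative sinusoids
  (one cycle per clip), scaled to peak `bg_amplitude` (default 0.5).
* **Valve**: two thin leaflets hinged at one point, opening angle
  $\theta(t) = \theta_{\max}\lvert\sin(2\pi t/\text{period})\rvert$ with
  $\theta_{\max} = 0.9$ rad, rasterized as discs along the segment. Leaflet
  intensity tapers linearly from `valve_amplitude` at the hinge to 15% of
  it at the free edge — real leaflets are brightest near the annulus and
  fade toward the tip, and the taper gives the ground truth a graded
  difficulty that separates the debiased factorization from the frozen-p
  baseline.
* **Distractors**: optional bright moving blobs away from the hinge,
  mimicking a second (aortic) valve.
* **Noise**: i.i.d. Gaussian, clipped with the video to $[0,1]$.

Presets: `easy` (amplitude 0.9, noise 0.01), `noisy` (amplitude 0.8, noise
0.25 — on the order of the tapered faint half of the valve), `distractor`
(easy plus one distractor). All free parameters above were fixed once,
before the acceptance quantities were measured, and are part of the stated
world.

What the phantom does *not* emulate: multiplicative Rayleigh speckle,
scanline geometry, out-of-plane motion, intensity dropout. A green
end-to-end test therefore establishes that the pipeline recovers structure
under its own model assumptions — not clinical performance.

### Two properties the stated world does not meet

* **SVD equality.** One proposed phantom invariant asks that, without
  noise, the rank-$r$ SVD truncation error of the video equal
  $\|{\rm valve}\|_F$ to $10^{-6}$. This is unattainable for any phantom
  whose valve is nonnegative in time: the optimal rank-$r$ subspace always
  absorbs the valve's component inside the background's temporal span
  (here roughly half its energy, dominated by the quasi-static near-hinge
  region). The test asserts the attainable direction — truncation error
  bounded above by the valve energy, and exact rank when the valve is
  absent.
* **Windowing under heavy noise.** With i.i.d. noise at $\sigma = 0.25$
  the exclusion-RNMF energy map is noise-dominated and the window scan
  misses the valve, so "windowed beats automatic" fails on the `noisy`
  preset even though the automatic mode still works. The corresponding
  acceptance assertion is deliberately left failing rather than weakening
  the noise; the automatic mode's robustness (and the windowed mode's
  fragility) under unstructured noise is itself a finding worth keeping
  visible.

Similarly, the published hyperparameters on these phantoms reach mean f1
slightly below the aspirational 0.8/0.85 bars (about 0.78 automatic and
0.82 windowed, measured by the acceptance suite): the unrecoverable voxels
are the leaflet tips below the segmentation floor $\Theta + 2\lambda_2$ and
the quasi-static near-hinge region absorbed into $WH$. The bars were not
lowered and the phantom was not brightened; the assertions are left red
with this analysis.

## Numerical choices

* Multiplicative-update denominators carry an additive guard
  ($10^{-12}$); zero columns of $W$ are skipped by the normalization.
* $\lambda = 0$ disables shrinkage and the subgradient update (which would
  divide by $\lambda$); a warning marks the decomposition as non-unique.
* The Gaussian constant $1/(2\pi\sigma^2)$ in the centroid attenuation is
  kept although centroids are scale-invariant.
* Coordinates are 0-based `(row, col, frame)` throughout; the matrix view
  vectorizes pixels row-major.
* Determinism: every stochastic step draws from a private RNG stream
  seeded from its configuration, so identical inputs and seeds give
  bit-identical results.

## Limitations

Runtime is dominated by the factorization sweeps (100 outer plus 200
warm-start iterations in vectorized R) and the PDHG iterations (a compiled
loop); a 96x96x40 video takes a few seconds per mode. The method cannot
distinguish two valves in the field of view — the refinement keeps exactly
one spatiotemporal component, and the window scan follows the dominant
energy. Window size must be supplied by the caller in windowed mode.
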