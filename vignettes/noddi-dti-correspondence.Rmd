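---
title: "Methods: the DTI-NODDI correspondence and its failure modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-NODDI correspondence and its failure modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noddidti)
```

## The scientific question

Diffusion tensor imaging (DTI) and NODDI are fitted to the same
diffusion-weighted signals but make very different assumptions: DTI fits a
single Gaussian tensor; NODDI decomposes the voxel into Watson-dispersed
intra-neurite sticks, a tortuosity-coupled hindered compartment, and free
CSF. Under a zero-CSF assumption the NODDI parameters are an analytic
function of the tensor's MD and FA, so one can ask: *when does a plain
tensor fit, possibly "forced" onto high-b or multi-shell data, carry the
same microstructural information as the full NODDI fit in cortical gray
matter?* This package implements the full computational chain needed to
answer that at desk scale: forward simulation, tensor fitting, the analytic
conversion, a nonlinear least-squares NODDI estimator, and the sweep and
agreement experiments that expose the role of the b-shell scheme and of
CSF-fraction heterogeneity.

## The forward model

For a volume with b-value $b$ (s/mm²) and unit gradient $g$,

$$S/S_0 = (1 - V_{iso})\left[\nu A_{ic} + (1-\nu) A_{ec}\right]
          + V_{iso} e^{-b d_{iso}},$$

with $\nu$ the intra-neurite fraction of the non-CSF tissue, and all
diffusivities in mm²/s so that $b\,d$ is dimensionless.

* $A_{ic} = \int W(n;\mu,\kappa)\, e^{-b d_{par} (g^\top n)^2}\, dn$ over
  the sphere, with the Watson density $W \propto e^{\kappa (\mu^\top n)^2}$
  normalised through the Kummer function $M(1/2, 3/2, \kappa)$ (evaluated
  via the Dawson function $F$).
* $A_{ec} = e^{-b\, g^\top D_{ec} g}$ with the dispersion-averaged
  axially symmetric tensor: $d_\perp = d_{par}(1-\nu)$ (tortuosity), axial
  eigenvalue $d_\perp + (d_{par}-d_\perp)\tau$, radial
  $d_\perp + (d_{par}-d_\perp)(1-\tau)/2$. Its trace is
  $d_{par}(3-2\nu)$, independent of dispersion.
* $\tau(\kappa) = \langle (\mu^\top n)^2 \rangle =
  \frac{1}{2\sqrt{\kappa} F(\sqrt{\kappa})} - \frac{1}{2\kappa}$,
  rising from $1/3$ (isotropic) towards 1 (parallel), and
  $\mathrm{ODI} = (2/\pi)\arctan(1/\kappa)$.

### Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `d_par` | intrinsic parallel diffusivity | 1.1e-3 mm²/s | value optimised for cortical gray matter; also the constant in the conversion |
| `d_iso` | free-water diffusivity | 3.0e-3 mm²/s | standard free-water value at body temperature; not estimated |
| `kappa_max` | Watson concentration bound in the NLLS fit | 64 | ODI ≈ 0.01; tighter concentration is indistinguishable on 90-direction shells |
| κ cap in ODI→κ | "parallel fibers" saturation | 1e6 | keeps the inverse mapping finite as ODI → 0 |
| tSNR cutoff | parcel exclusion | 17 | screening threshold below which parcel estimates are judged unreliable |

## The DTI → NODDI conversion

With $V_{iso}=0$ the composite mean tensor is axially symmetric with

$$\lambda_\parallel - \lambda_\perp = d_{par}\,\nu(2-\nu)\,\frac{3\tau-1}{2},
\qquad \mathrm{MD} = \frac{d_{par}}{3}\left[1 + 2(1-\nu)^2\right].$$

Inverting: $\nu = 1 - \sqrt{(3\,\mathrm{MD}/d_{par} - 1)/2}$; the gap is
recovered from the tensor invariants as
$\Delta = \mathrm{FA}\sqrt{3\,\mathrm{MD}^2 / (1 - \tfrac{2}{3}\mathrm{FA}^2)}$
(exact for prolate axially symmetric tensors, since
$\sum_i \lambda_i^2 = 3\mathrm{MD}^2/(1-\tfrac23 \mathrm{FA}^2)$), giving
$\tau = \tfrac13\left(1 + 2\Delta/(d_{par}\nu(2-\nu))\right)$, then
$\kappa$ by monotone inversion of $\tau(\kappa)$ and ODI from $\kappa$.
The round-trip over $\nu \in \{0.1,\dots,0.9\}$,
$\kappa \in \{0.5,\dots,16\}$ is exact to machine precision in $\nu$ and to
the $10^{-9}$ inversion tolerance in ODI; the test suite asserts
(1e-6, 1e-4).

The $\nu$ used inside the dispersion step is the one recovered from MD
(self-consistent chain). The conversion sets $V_{iso} = 0$ by definition —
estimating CSF from a single tensor is out of scope, and that omission is
exactly the error mechanism the experiments quantify.

### Domain policy

Real (especially CSF-contaminated, low-b) tensors leave the model domain:

* MD > `d_par` ⇒ ν clamped to 0 with a `csf_suspect` flag (sweep tables
  stay dense instead of going `NaN`); MD < `d_par`/3 ⇒ ν = 1,
  `stick_limit` flag.
* τ above $1 - 10^{-9}$ ⇒ clamped, κ saturates at the cap, `tau_ceiling`
  flag.
* ν = 0 leaves dispersion undefined: ODI is reported missing
  (`odi_undefined`), never fabricated.

A note on the theoretical curves (`fig1_curves()`): with
`d_par = 1.1e-3 mm²/s` the zero-CSF identity bounds MD to
[`d_par`/3, `d_par`] ≈ [0.37, 1.1] µm²/ms, so the curves are drawn over
that valid domain; descriptions of such curves elsewhere sometimes quote MD
ranges in other units that fall outside it.

## Numerical choices

* **Spherical quadrature.** The Watson–stick integral uses a product grid:
  64-point Gauss–Legendre in $u=\cos\theta$ on [0, 1] (doubled by antipodal
  symmetry) × 48 midpoint nodes in φ (spectrally accurate for periodic
  integrands). Watson weights are normalised on the grid, so the density
  integrates to exactly 1 by construction; a separate check against the
  analytic normaliser rejects grids that are too coarse for the requested
  κ (1e-4 tolerance). At κ = 64 the grid agrees with a 160×96 reference to
  ~1e-15; beyond κ = 1e4 the density is effectively a delta and the stick
  closed form $e^{-b d_{par} (g^\top \mu)^2}$ is used directly.
* **Dawson function.** `pracma::erfi` below $x = 5$; the asymptotic series
  $\sum_k (2k-1)!!/(2^{k+1} x^{2k+1})$ above (erfi overflows past
  $x^2 > 709$).
* **Small-κ series.** Below κ = 2e-3, $\tau$ uses
  $1/3 + 4\kappa/45 + 8\kappa^2/945$: the closed form is 0/0 at κ = 0 and
  loses about seven digits to cancellation below κ ≈ 1e-2, while the
  second-order series stays within 1e-11 of quadrature at the switch.
* **τ inversion.** Monotone bracketing (`uniroot`) on [0, 1e6] with
  residual tolerance 1e-9; unconditional convergence was preferred over a
  faster Newton iteration.
* **Tensor fit.** Ordinary least squares on the log signal — the default
  behaviour of the standard tensor tools, and the appropriate choice for
  noiseless simulations where weighting is moot. b = 0 volumes enter as
  intercept-only rows so $\log S_0$ is estimated jointly. Negative
  eigenvalues (routine in forced fits of non-Gaussian signals) are kept
  for MD; only FA is clamped to [0, 1].
* **NODDI NLLS.** The intra-neurite attenuation depends on the gradient
  only through $|g^\top\mu|$, so per candidate κ it is tabulated once per
  shell on a 41-node grid in $|g^\top\mu|$ and interpolated with natural
  cubic splines (~1e-6 agreement with direct quadrature, well below the
  1e-3 recovery target). A coarse multi-start grid
  (ν ∈ {0.05, …, 0.95 step 0.15} × ODI ∈ {0.05, 0.2, 0.4, 0.7} ×
  V_iso ∈ {0, 0.2, 0.5} × 6 icosahedral orientation seeds) is scored by
  residual sum of squares — sharing the κ-profiles across starts makes this
  cheap — and the best start is refined by box-bounded
  Levenberg–Marquardt (`minpack.lm::nls.lm`). This replaces the
  dictionary/convex-optimisation solver used by accelerated NODDI
  implementations: the generative model is identical, the machinery far
  smaller, and at desk scale the fit converges to ~1e-7 on noiseless
  three-shell data. Known consequence: regularised dictionary solvers
  carry small characteristic biases that a direct NLLS fit will not
  reproduce.

## What the synthetic cortex emulates — and what it does not

`generate_cortex()` draws 360 parcels (180 per hemisphere) with clipped
Gaussian truths: ν around 0.25, ODI around 0.30 (cortical means),
$V_{iso} \sim N(0.09, 0.06^2)$ clipped to [0, 0.6] for gray matter
($N(0.21, 0.1^2)$ for the white-matter preset). A designated "sensory"
subset receives elevated ν and ODI, giving the maps nontrivial spatial
contrast; a designated 29-parcel subset is drawn below the tSNR cutoff so
the exclusion arithmetic (360 → 331) is exercisable. Heterogeneity is
expressed *across* parcels, matching the level-by-level logic of the
V_iso sweep; ν, ODI and V_iso are drawn independently by default (their
true cross-parcel covariance in cortex is unknown — an explicit modelling
choice, adjustable by passing a custom truth table).

Not emulated: surface geometry and ribbon partial-volume weighting,
registration, spatial autocorrelation between neighbouring parcels,
within-voxel heterogeneity beyond the three compartments, compartmental
T2 differences, and scanner artefacts. Passing tests therefore show that
the *computational chain* behaves as the theory predicts under the stated
generative model — not that in-vivo effect sizes are reproduced. In-vivo
headline correlation values from large cohorts are mirrored only
qualitatively (orderings and signs).

## Design choices in the experiments

* **Percent error** in the V_iso sweep is
  $100\,(x - x_{ref})/x_{ref}$ with $x_{ref}$ from the *same scheme and
  metric* at the reference level $V_{iso}=0.1$ — the natural reading of
  "percent change relative to the reference condition"; it makes every
  curve pass through zero at the reference.
* The sweep is noiseless throughout (the mechanism under study is model
  mismatch, not noise), holds μ fixed at +z (a rotation-invariance test
  guards against orientation leakage), and fits original NODDI on the
  three-shell set only by default; `noddi_schemes` exposes the refit on
  other schemes for exploration.
* Original-NODDI estimates on the full three-shell set serve as the gold
  standard in all agreement analyses.
* The fit functions return classed objects (`tensor_fit`, `noddi_fit`)
  with `print`/`coef`/`predict`/`residuals`/`simulate` methods, so the
  estimators compose with ordinary R modelling workflows.

## Problem sizes

The packaged experiments run at sizes chosen to keep a full desk replication
comfortable: 7 sweep levels × 7 schemes with one NLLS fit per level
(~3 s total on one core), correlation experiments at 100 parcels (~20 s
each), and the end-to-end pipeline at 100 parcels by default (360 parcels
runs in a few minutes, dominated by the per-parcel NLLS fits). Generator
moments are additionally checked at 10,000 parcels where only draws, not
fits, are needed.

## Known limitations

* Single-fiber Watson dispersion only: no crossing geometries, no Bingham
  asymmetry, no inter-compartment exchange.
* `d_par` and `d_iso` are fixed constants of the analysis, as in the
  standard cortical protocol; misspecification propagates directly into ν
  and the conversion.
* The NLLS fitter's multi-start grid is coarse by design; pathological
  noise realisations at very low SNR may converge to local optima (the
  multi-start objective and convergence code are reported with each fit).
* Single-shell NODDI fits are permitted but flagged: neurite density is
  poorly identified from one shell, and downstream analyses should treat
  the flag as missingness, which is how the correlation experiments report
  undefined cells.
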