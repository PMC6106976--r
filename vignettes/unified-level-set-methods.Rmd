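---
title: "Unified level set segmentation of liver and liver tumors: methods and design"
author: "UnifiedLSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified level set segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(UnifiedLSM)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the phantom
studies do and do not demonstrate. No number quoted here is asserted
anywhere except where the test suite or the acceptance script computes it.

## 1. The unified level set model

A segmentation is the set `{phi > 0}` of a scalar field evolved by
explicit gradient descent of

$$\varepsilon(\phi) = \mu D(\phi)
  + \lambda \int_\Omega g\,\delta_\epsilon(\phi)\,|\nabla\phi|\,dx
  + \alpha \int_\Omega g\,\mathrm{SPF}(I)\,H(-\phi)\,dx$$

with three ingredients:

* **Distance regularization** $D(\phi)$, the double-well potential of
  DRLSE. Its practical payoffs: no reinitialization, and a *binary step*
  initialization $\phi_0 = \omega(I_0 - 1/2)$ is admissible. $\omega \ge 2$
  is required; the default is $\omega = 4$.
* **Edge information**: the geodesic indicator
  $g = 1/(1 + |\nabla(G_\sigma * I)|^2)$, close to 1 in homogeneous tissue
  and collapsing across boundaries.
* **Region information**: the signed pressure force
  $\mathrm{SPF} = (I - (c_1+c_2)/2)\,/\,\max|I - (c_1+c_2)/2|$, where
  $c_1, c_2$ are the Chan–Vese means inside and outside the contour,
  recomputed from the current $\phi$ at every iteration (freezing them is
  the other defensible choice; recomputation is the Chan–Vese standard and
  is what the phantom tests pin down).

The balloon term $\alpha\,g\,\mathrm{SPF}\,\delta_\epsilon(\phi)$ is the
model's point: either channel can veto a leak. Dropping the SPF gives the
edge-only balloon $\alpha g$ (one-directional, leaks through boundary
gaps); dropping $g$ gives the region-only balloon $\alpha\,\mathrm{SPF}$
(blind to visible edges). Both ablations are implemented as `variant =
"edge"` / `"region"` of `evolveLevelSet()` and are compared against the
unified flow in the test suite.

**Sign and orientation.** Descent of the area term moves the contour so
that `{phi > 0}` converges onto the phase on the $c_1$ side of the
midpoint. The energy as written assumes a bright target. The package
multiplies the balloon by $\mathrm{sign}(c_1 - c_2)$ of the *initial*
partition, so the contour converges onto the phase resembling the initial
inside — bright liver and hypodense lesions are handled by one rule, and
$\alpha$ is a pure magnitude. This orientation rule is a design decision
(the source energies leave it open); the phantom tests pin the behavior.

**Numerics.** Central differences with $|\nabla\phi|$ floored at 1e-10;
the regularizer is discretized as
$\mathrm{div}((d_p-1)\nabla\phi) + \Delta\phi$ with the 4-neighbor
Laplacian; replicate padding at borders. Smoothed Dirac/Heaviside of width
$\epsilon = 1.5$ px. Time step $\Delta t = 1$ with $\mu = 0.04$
(stability requires $\mu\,\Delta t < 0.25$). An optional convergence
surrogate (stop when the zero-level mask changes by less than a tolerance
for a window of consecutive iterations) replaces interactive termination;
it is off by default, matching the fixed-iteration experiments.

**The intensity gain.** Images are stored normalized to [0, 1], but all
gradient-based operators (`gradientMagnitude`, `edgeIndicator`) multiply
intensities by `gain = 255` before differentiation. The calibrated
constants around them — the sigmoid center $\beta = 4$ and width
$\kappa = -1.5$, and an edge indicator that must actually brake a contour
— are only meaningful on the 8-bit gray scale this family of methods was
developed on: on [0, 1] data a unit step yields $|\nabla| \le 0.5$ and
both operators degenerate to near-constants. `gain = 1` recovers the
literal operators for testing.

**The indicator scale $\sigma = 0.5$.** The Gaussian scale of the edge
indicator is a free parameter here. With `gain = 255`, a contrast step
produces a *saturated valley* of $g \approx 0$ whose width grows with
$\sigma$; inside that valley every force proportional to $g$ is dead, and
the front can park 1–2 px short of the boundary (or need hundreds of
iterations to cross). $\sigma = 0.5$ — the same light smoothing scale the
preprocessing gradient filter uses — keeps the dead zone below a pixel
while still suppressing single-pixel noise, and was fixed once on that
argument.

## 2. Liver pipeline

1. **Hybrid preprocessing** (`preprocessPipeline`): Perona–Malik
   diffusion (exponential conductance, 4-neighbor explicit scheme,
   defaults 10 iterations, conductance 0.1 on [0,1] intensities, step
   0.125 — the concrete scheme is ours, the literature only asks for an
   edge-preserving filter); gradient magnitude at scale $\gamma = 0.5$;
   sigmoid conversion $f_s = 1/(1+\exp(-(f_M-\beta)/\kappa))$ with
   $\kappa = -1.5 < 0$, hence *decreasing* in the gradient — homogeneous
   interiors white, edges dark; binarization at $(\max f_s + \min
   f_s)/\theta$, $\theta \in [1.1, 1.5]$. Note the threshold *decreases*
   as $\theta$ grows, so binary masks are nested increasing in $\theta$ —
   the suite asserts exactly this literal property of the formula.
2. **Seeded region growing** (`regionGrow`): FIFO (breadth-first)
   candidate order, neighbors enqueued N, S, W, E, region mean updated
   incrementally, strict `<` criterion, 4-connectivity. Order and
   connectivity are fixed for determinism; on the binary image the output
   is provably the connected component of the seed for any threshold
   W in (0, 1], which is the robustness property that makes the
   interaction cheap (typically one seed per connected liver part).
3. **Refinement** (`refineLiver`): binary-step initialization from the
   rough mask, 100 unified iterations at $\alpha = 10$, $\lambda = 5$,
   $\mu = 0.04$, then hole filling (background components not reaching
   the image border; 4-connectivity).

## 3. Tumor pipeline

Work is restricted to a user rectangle (ROI, half-open 0-based pixel
coordinates) drawn close around the lesion.

**Local intensity clustering** (`evolveLic`) fits $I = b\,J + n$: $J$
piecewise constant $(c_1, c_2)$ on the two phases of $\phi$, $b$ a smooth
bias field, via the kernel-weighted clustering energy with a truncated
Gaussian neighborhood ($a = 1$, $\tau = 4$, $\rho = 3$). The $c$ and $b$
updates are the closed-form stationary points of that energy; the $\phi$
step is one explicit descent step of the full functional (length weight
$\nu = 1$, distance-regularization weight $\delta = 1$). Three
implementation decisions matter and are tested:

* *Zero-padded kernel convolutions.* The kernel support is truncated to
  the image domain. A symmetric kernel is then self-adjoint, which makes
  the closed-form updates exact minimizers of the discrete energy — the
  energy-descent tests hold to 1e-6. (With replicate padding they are
  slightly off and descent fails sporadically.)
* *Bootstrap.* The contour initialization is a seeded per-pixel ±1
  Rademacher field, which is symmetric between the phases: updating the
  phase constants immediately collapses them onto the global mean and the
  data force vanishes. The constants therefore start deliberately
  asymmetric (max, min of the ROI) and are held through a burn-in of half
  the iteration budget while the $\phi$ steps classify; the update order
  is $\phi \to c \to b$. The bias field starts from a coarse unit-mean
  low-pass of the ROI (standard practice in bias correction), so the
  burn-in classification threshold is bias-modulated rather than global —
  without this, a strong smooth bias masquerades as the two-phase
  structure.
* *Step size.* $\Delta t = 0.2$: 0.1 cannot sweep the contour across a
  64-px ROI within the 100-iteration budget, 0.3 is unstable for the
  explicit scheme.

The phase reported as tumor is the one whose mean differs most from the
ROI's 2-px border band (assumed parenchyma), handling hypodense and
hyperdense lesions alike.

A structural caveat the tests document: with kernel radius $\rho = 3$ far
below a 14-px lesion radius, a *soft* lesion margin lets the global
minimizer absorb part of the transition annulus into $b$ — bias recovery
to corr ≥ 0.99 is a property of exactly piecewise-constant scenes, and is
asserted on a sharp-margin phantom.

**HMRF-EM** (`hmrfEm`): two Gaussian classes, Potts pairwise prior
(8-neighborhood, weight 0.5 — the clique form is our choice, the
literature leaves it open), MAP labels by ICM in raster (column-major)
order with early exit, posterior-weighted parameter updates; 15 MAP / 15
EM iterations. Because the class likelihood is one *global* Gaussian per
class, the stage runs on the ROI divided by the clustering stage's bias
estimate (floored at 0.2) — on a 0.3-amplitude bias field the uncorrected
likelihood is badly misspecified and the refinement destroys the labels.
The indicator and the final evolution stay on the observed ROI.

**Enhanced edge indicator** (`enhancedEdgeIndicator`):
$g_{enh} = \max(g_{bin}, g)$, where $g_{bin}$ is the geodesic indicator
of the binary classification, min–max rescaled so the class-boundary band
is exactly 0 and class interiors exactly 1. The maximum therefore is 1
inside the classes (fast propagation) and equals the small-but-positive
raw $g$ on the band — crisp edges that never stop the contour dead. A
constant classification contributes a zero field, leaving $g$ unchanged.
Whether the "binary result" should enter as the raw mask or as an edge
map of it is not settled in the source material; the edge-map-with-rescale
construction is the one that keeps the maximum well-posed.

**Final unified evolution**: from a rectangle placed inside the lesion
(binary-step initialization), with $g_{enh}$, balloon magnitude
$\vartheta = 3$, $t = 200$ fixed iterations, no convergence surrogate. A
practical interaction note: with $\vartheta = 3$ and the weak SPF of a
low-contrast ROI, a very small rectangle can sit below the
balloon-versus-curvature threshold; the rectangle should be drawn
generously inside the lesion (the tests use 18x18 px inside a 28-px
lesion).

## 4. Evaluation

`volumeMetrics`: VOE = 100 (1 − |P∩R|/|P∪R|), RVD = 100 (|P|−|R|)/|R|
(signed — negative means undersegmentation). `surfaceMetrics`: boundary
pixels are foreground with a background 4-neighbor (the image border
counts as background), at pixel centers, distances in mm with anisotropic
spacing; ASD/RMSD/MSD are the mean/RMS/max over the pooled symmetric
nearest-distance set. `sliverScore`: per metric,
$\max(0,\,100 - 25\,|m|/m_{ref})$ — the linear map through the two anchor
points (0 → 100, reference → 75), with reference values VOE 6.4 %, RVD
4.7 %, ASD 1.0 mm, RMSD 1.8 mm, MSD 19 mm; RVD enters by absolute value
(so scores stay ≤ 100); the total is the mean of the five. All metric
implementations are checked against brute-force oracles (pixel counting;
all-pairs distances) to 1e-9 on random small masks.

## 5. Phantom studies: what they show and what they cannot

The generators render the difficulties the framework targets, with exact
ground truth, and every stochastic step is seed-reproducible.

**Liver phantom** (160x160 px, 1 mm pixels; background 0.15, liver disk
r = 42 at (80, 62), intensity 0.60; optional discrete parts, dark
vessels): the default conditions for the preprocessing / region-growing /
refinement chain.

**Comparison phantom** (`comparisonPhantomSpec`; background 0.25): two
boundary defects chosen to separate the three balloon variants by their
documented failure modes. (i) A hypodense organ (0.30, r = 22) reached
through a 28-px-wide arc where the edge is replaced by a 20-px linear
intensity ramp: no localized gradient, so only the SPF sign change can
stop a contour there. A 4-px-wide channel was considered and rejected —
its own transverse walls are strong edges, which defeats the purpose of
an "absent edge". (ii) A hyperdense organ (0.82, r = 28) in direct
sharp-edge contact: a strong edge with misleading region contrast. On
this phantom the unified flow contains both defects, the edge-only
balloon leaks through the ramp, and the region-only balloon crosses the
sharp contact — the VOE ordering asserted in the acceptance suite.

**Tumor phantoms** (`tumorPhantomPreset`): 64x64 ROI, parenchyma 0.55,
lesion r = 14, ground truth at the half-contrast radius. Lesion margins
are soft by default (4-px linear falloff; clinical margins are
indistinct). Three classes: *clean* (contrast 0.25, sharp margin, no
bias, noise 0.02), *lowcontrast* (contrast 0.10, bias amplitude 0.3,
noise 0.02), *ambiguous* (contrast 0.12, variable 2–10 px margin, a
60-degree sector with contrast faded to 30 %, bias 0.3, noise 0.03). The
superiority comparison against the single-information variants runs on
the two difficult classes and compares *mean* Dice over five noise seeds
per variant — a dataset-level comparison, matching how such orderings are
reported; on the ambiguous class individual seeds can flip.

What passing these tests does **not** show: performance on real CT. The
phantoms have exactly Gaussian noise, exactly multiplicative smooth bias,
and piecewise-near-constant anatomy; real slices add texture, partial
volume effects, streak artifacts, anatomy-dependent windowing, and
genuinely ambiguous pathology, and the trained constants (θ per CT
sequence, W, α, ϑ) were calibrated by the original experiments on real
data, not by these phantoms. The phantom studies validate the *mechanics*
— the formulas, the update rules, their stated invariants and their
comparative failure modes — at desk scale (problem sizes: 160x160 liver
scenes, 64x64 ROIs, 100–200 iterations; chosen as the smallest sizes at
which the geometric effects under study are comfortably resolved).

## 6. Known limitations

* 2D only; volumes are processed slice-wise by design.
* The SPF is a global statistic: its midpoint is distorted by strong
  within-ROI inhomogeneity, which is exactly why the tumor branch builds
  the enhanced indicator from bias-corrected labels.
* The clustering stage's bias estimate is untrustworthy *inside* lesions
  much larger than the kernel radius (see Section 3).
* ICM is a greedy MAP solver; with a poor initialization it inherits the
  EM literature's local-minimum caveats — the pipeline's whole point is
  that the clustering stage provides a good initialization.
* Interactive manual termination of the liver refinement is replaced by a
  fixed iteration budget plus an optional convergence surrogate.
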