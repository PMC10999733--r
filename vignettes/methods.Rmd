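---
title: "Methods: fiber orientation, curvature and twist on rotationally symmetric scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiber orientation, curvature and twist on rotationally symmetric scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fibertwist)
```

This vignette documents the models, conventions and numerical choices
behind `fibertwist`, in the spirit of a methods section: what is computed,
under which assumptions, and where the design was genuinely open.

## The measurement model

Tissues are grown on rotationally symmetric substrates: capillary bridges
(tissue on the outside, growing outwards) and their cast negatives, pores
(tissue on the inner wall, growing inwards). Both have negative Gaussian
curvature, so a fiber at a point can run along convex, concave or flat
directions depending on its orientation. The pipeline measures, per sample:

1. the in-plane fiber angle $\alpha$ on a maximum intensity projection
   (MIP) of the fluorescence stack, per evaluation window;
2. the fiber angle on the 3D surface, $\theta \in [0^\circ, 180^\circ)$,
   measured from the equatorial (circumferential) direction, obtained by
   pulling $\alpha$ back through the orthographic projection onto a
   rotationally symmetric surface model $r(z)$;
3. the normal curvature along the fiber direction via Euler's theorem,
   $k_\theta = \kappa_c \cos^2\theta + \kappa_m \sin^2\theta$;
4. per-sample histograms of $\theta$ and $k_\theta$ whose peak positions
   feed one- and two-sample $t$-tests across groups.

MIPs rather than full 3D orientation tensors are used deliberately: the
axial resolution of the stacks is several times worse than the lateral
one, and the exponential depth attenuation of the fluorescence makes the
MIP surface-dominated, so the MIP angle is effectively the angle of the
current tissue surface layer.

## Geometry and sign conventions

A surface of revolution is $X(z, \varphi) = (r(z)\cos\varphi,
r(z)\sin\varphi, z)$ with all lengths in µm and $z = 0$ at the neck
(profile extremum). The principal directions are meridional and
circumferential with

$$\kappa_m = -s\,\frac{r''}{(1 + r'^2)^{3/2}}, \qquad
  \kappa_c = \frac{s}{r\sqrt{1 + r'^2}},$$

where $s = +1$ for a bridge and $s = -1$ for a pore. The sign $s$ encodes
one global convention: the surface normal points *out of the tissue into
the culture medium*, and a direction along which the surface falls away
from that normal — a valley seen from the medium — has negative normal
curvature ("concave = negative"). At a bridge waist this gives
$\kappa_m < 0 < \kappa_c$; inside a pore the signs swap. The convention is
behavioural, chosen so that "fibers align along concave directions" means
$k_\theta < 0$ on both substrate types; it is applied as a global sign on
the second fundamental form rather than ad hoc per quantity.

Normal-curvature correctness is guarded by an independent oracle: the
curvature of the 3D curve cut by the plane spanned by the tangent
direction and the surface normal, measured by finite differences with
Richardson extrapolation, agrees with the Euler-theorem value to $10^{-5}$
relative on random (profile, $z$, $\theta$) draws.

## Constant-mean-curvature profiles

Tissue surfaces on such scaffolds approximately follow constant-mean
curvature (Delaunay) shapes, so the package offers a CMC solver as one
backend for the projection surface: with the normal taken away from the
axis, CMC profiles solve $r'' = (1 + r'^2)/r - 2H(1 + r'^2)^{3/2}$. The
solver shoots from the waist ($r(0) = r_0$, $r'(0) = 0$; fixed-step RK4)
and bisects on $r_0$ until $r(\pm d/2) = R$ to $10^{-8}$, returning the
outer (area-minimizing) Delaunay branch when two exist; a volume target is
handled by an outer bisection on $H$. Failures report the attainable
bracket. The solved half profile is mirrored and represented by splines of
$r$ and of the integrator's own $r'$ (a naive natural spline of $r$ alone
forces $r'' = 0$ at the domain ends and corrupts $H$ there).

For measured samples the default backend is instead a smoothing spline fit
to the MIP silhouette: per image row the half-width of the thresholded
(Otsu) foreground, with a running-median filter rejecting rows whose width
jumps away from the local trend (dust), and generalized cross-validation
choosing the smoothing level (residuals are typically about one pixel).
Tissue surfaces only approximately follow Delaunay shapes, so forcing an
exact CMC fit would bias curvatures; which surface to project onto (the
scaffold, a per-time-point fit, or a CMC idealization) is left to the
caller — both backends satisfy the same interface.

## Orientation estimation

The estimator for $\alpha$ is the 2D structure tensor: Gaussian
pre-smoothing (`grad_sigma`, default 1 px), fourth-order central
differences (the common 3-tap stencil biases the gradient *direction* by
more than a degree at stripe periods below ~10 px), tensor smoothing with
`window_sigma` (default 10 µm, roughly the scale of a stress-fiber
bundle), fiber axis from the minor eigenvector, coherence
$(\lambda_1 - \lambda_2)/(\lambda_1 + \lambda_2)$ as quality. Windows with
coherence below `coherence_floor` (default 0.2) are invalidated; weights
are coherence × normalized gradient energy. Window centres keep a border
of 2.5 window sigmas: replicate padding measurably corrupts the tensor
closer to the edge. The only intensity preprocessing is one global
normalization to $[0, 1]$ — never local contrast adjustment, which would
distort gradient energies.

The estimator itself is a replaceable design choice (ridge tracing or
spectral estimators would fit the same interface); a Fourier
power-spectrum oracle guards it to within 1° on single-orientation
fixtures, and rotation-equivariance tests pin it at 45°/90°/135°.

All angle arithmetic is axial: $\alpha$ and $\alpha + 180^\circ$ are the
same fiber, so means, differences and correlations are computed on doubled
angles throughout.

## Lifting $\alpha \to \theta$

The camera is orthographic (sample ≪ working distance). A pixel at
$(x, z)$ with $|x| < r(z)$ lifts to azimuth $\varphi = \arccos(x / r(z))$
on the visible hemisphere. In the orthonormal tangent basis
$(e_c, e_m)$ — circumferential direction chosen to project to $+x$,
meridional along increasing $z$ — the projection restricted to the tangent
plane is

$$M = \begin{pmatrix} \sin\varphi & r'\cos\varphi / \sqrt{1 + r'^2} \\
                      0 & 1/\sqrt{1 + r'^2} \end{pmatrix},$$

and the lift solves $M(c, m)^T = (\cos\alpha, \sin\alpha)^T$, giving
$\theta = \operatorname{atan2}(m, c)$ as an axial angle. $M$ degenerates
like $1/\sin\varphi$ at the silhouette; samples with condition number
above `cond_cap` (default 25) are discarded and counted in a QC record,
and the exclusion rules additionally drop $|x| > 0.85\, r(z)$ (edge
regions) and $|z| > 300$ µm from the neck. A forward-projection oracle
verifies the lift is the exact inverse to $10^{-6}$.

Inside views (opened pores) are the mirror image of outside views; since
mirroring is an isometry of the surface of revolution, the same formulas
lift each view in its own image frame, and the view enters only the
handedness call: outside, $\theta < 90^\circ$ is left-handed; inside,
$\theta > 90^\circ$ is. One $\theta \in [0^\circ, 180^\circ)$ convention
plus the view flag is used everywhere instead of extending $\theta$ beyond
180° for pores; the two phrasings are mod-180 equivalent and a single
convention keeps the statistics uniform.

## Twist, channel offset, co-alignment

Twist is the sum of wrapped axial step differences (each in
$(-90^\circ, 90^\circ]$) along a series ordered old → new tissue — for
both substrate types deep → surface, since both grow away from the
scaffold. A sign is declared only beyond a noise threshold (default 10°,
about five times the synthetic estimator bias); reversing the ordering
flips the sign exactly. Wrapping matters: a pore series going
$35^\circ \to 150^\circ$ crosses the axial wrap and is a $-65^\circ$
(negative) twist, not $+115^\circ$.

Depth 0 of a profile is the first slice whose mean ROI intensity exceeds
10% of the channel plateau, recorded in the output. The actin–collagen
signal offset is the difference of half-max onset depths, each half-max
relative to its channel's own plateau, making the measure invariant to
per-channel intensity rescaling; when comparing channels the collagen
profile is referenced to the *actin* onset so both share one depth axis.
Co-alignment is summarized by the mean absolute wrapped difference and a
Fisher–Lee circular correlation on doubled angles.

## Statistics

Per-sample histograms are weighted and area-normalized; $\theta$ bins are
circular with default width 4° (45 bins — fine enough to resolve the
~30° group differences, coarse enough for stable peaks at typical window
counts), $k_\theta$ bins default to $2.5 \times 10^{-4}$ µm⁻¹ spanning
±0.01 µm⁻¹; neither width is dictated by the source experiments, so both
are configurable. The *histogram peak* of each sample — tie-broken by the
(circular) mean of tied bin centres, optionally refined parabolically — is
the single number per biological sample entering all tests; fiber windows
are never pooled across samples for inference. Group histograms are
averaged per bin with the standard error across samples.

Tests are classical $t$-tests: one-sample against a reference (90° for
bridges, 180° for pores, and 0 µm⁻¹ for $k_\theta$), two-sample pooled
by default with Welch behind a flag, stars at 0.05/0.005/0.001. For
circular quantities the peaks are first linearized as wrapped axial
differences from the reference (or the pooled axial mean), so a pore
reference of 180° treats peaks just above 0° correctly. The $k_\theta$
reference deserves a note: one figure caption in the source material
states a reference of 0.1 µm⁻¹, which is two orders of magnitude outside
the curvature bins and inconsistent with the accompanying statement that
$k_\theta$ differs significantly *from zero*; it is treated as a typo for
0 µm⁻¹, and the reference is a parameter.

## The synthetic world

The renderer draws constant-$\theta$ loxodromes — not geodesics — on the
depth-offset surface: the measurement model assigns a single $\theta$ per
location, and a constant-angle curve is exactly the texture that model
describes. Fibers at depth $d$ below the surface live on the offset shell
$\rho_d(z) = r(z) \mp d/\sqrt{1 + r'^2}$ (the small axial component of the
offset is neglected; exact on cylinders). Each layer is a contiguous depth
interval with one true angle; fiber depths are uniform within the layer.
Rendering: midpoint integration of the loxodrome ODE, point splatting,
anisotropic Gaussian PSF (default 0.8 µm lateral / 2.0 µm axial, with the
1.5 µm fiber width added in quadrature), intensity
$\propto e^{-d/\ell}$ with attenuation length $\ell = 15$ µm (keeping the
MIP dominated by the top one or two cell layers), Poisson shot noise at
`poisson_gain` expected photons per unit intensity plus Gaussian read
noise. Default voxels are $0.63 \times 0.63 \times 1.2$ µm, the
light-sheet acquisition geometry. Renders are bitwise deterministic given
the seed, restore the caller's RNG state, and always carry their ground
truth.

Defaults the experiments do not pin down were chosen once: fiber density
0.003 µm⁻² (individual fibers resolvable; structure-tensor coherence
around 0.6, a plausible operating point for fluorescence texture) and
noise defaults to match. One exception is documented: fixtures for the
*channel-offset* estimator use 0.02 µm⁻² because that estimator reads the
intensity-vs-depth profile, and at sparse densities the profile is
dominated by single-fiber shot noise that no confluent tissue shows — the
dense packing is fixture realism for the intensity profile, not a
tolerance adjustment. Channel-offset fixtures also measure in a ROI
narrow in $x$: the camera axis is normal to the surface only near the
midline, and a wide ROI smears the onset over the surface sagitta.

What a green render-and-recover test establishes is that the estimator
chain is unbiased and appropriately precise *for this texture model*. It
does not establish robustness to light-sheet stripe artifacts, refractive
index mismatch, nuclei and debris, spatially varying SNR, or fiber
populations with mixed angles within one layer — none of which the
renderer emulates.

## Numerical choices and degenerate inputs

- CMC shooting: coarse 80-point waist scan and bisection at reduced RK4
  step count, secant polish at full resolution; boundary tolerance
  $10^{-8}$.
- Flat images yield all-invalid orientation fields, not exceptions; empty
  post-exclusion sample sets warn rather than error.
- Histogram values of $k_\theta$ outside the fixed bin range are clamped
  into the end bins (they are rare and would otherwise silently vanish).
- $t$-tests with zero variance return $t = 0, p = 1$ when the means agree
  exactly (identical-group fixtures) rather than NaN.
- Ties in `peak_value` use the circular mean of tied centres so that two
  adjacent tied bins resolve to their shared edge.

## Limitations

- Only surfaces of revolution; no lifting onto general meshes.
- MIP-based: no full-3D orientation tensor, by design.
- One twist event per depth profile is assumed by the twist summary (the
  sign of the summed wrapped change); multiple alternating twists would
  partially cancel.
- The reproduction of the source study's numeric group means requires its
  external microscopy deposit and is out of scope here; the package's
  claims are backed by the property-based suite on synthetic data.
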