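---
title: "Methods: along-tract maturation models on medial surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: along-tract maturation models on medial surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractmat)
```

This vignette is the package's own account of the statistical and
geometric machinery: the models and their assumptions, the parameters
that matter and why their defaults are what they are, what the
synthetic-cohort generator does and does not emulate, and the numerical
choices a maintainer would want written down. Everything quantitative
stated here is computed by the test suite or the acceptance script; the
vignette adds the reasoning.

## The medial model and inverse skeletonization

A tract is represented by its medial surface: a triangulated
2-manifold with boundary whose vertices `m` carry a radius `r` (mm), the
distance to the two tract boundaries. The boundary is reconstructed by
the Blum medial relation

$$U_\pm = -\nabla_M r \pm \sqrt{1 - \|\nabla_M r\|^2}\; n, \qquad
  b_\pm = m + r\,U_\pm,$$

where $\nabla_M r$ is the tangential (in-surface) gradient of the
radius and $n$ the unit vertex normal. The relation presumes medial
feasibility, $\|\nabla_M r\| \le 1$; `build_spokes()` flags and excludes
violating vertices instead of clamping them, because a silently clamped
spoke points somewhere the model does not define and would contaminate
the projection. The tangential gradient is estimated per vertex by a
weighted least-squares fit over the one-ring (edge vectors projected
into the tangent plane, inverse-length weights), which is exact for
affine radius fields on any mesh and robust on irregular ones.

Assumptions worth stating: the triangulation must be a connected
manifold (validated at construction), and the normal field must be
orientable; sheet-like tracts satisfy this, tubular ones (where the
medial locus degenerates toward a curve) are outside the model.

## Surface smoothing

Projected per-subject FA/MD maps are smoothed with iterative discrete
heat diffusion. The FWHM-to-time map comes from the planar Gaussian
kernel identity $\mathrm{fwhm} = \sqrt{16 \ln 2\,\tau}$, so an 8 mm
kernel corresponds to $\tau = 64/(16\ln 2) \approx 5.77$ mm².

The discrete Laplace–Beltrami operator is cotangent-weighted with
lumped (one-third incident area) vertex masses. A plain graph
("umbrella") Laplacian was considered and rejected: it carries no
length units, so a metric FWHM in millimetres cannot be realized on it
without an ad hoc scale, and on the package's right-triangulated grids
it is anisotropic (the diagonal edges bias diffusion along one
direction by a factor approaching $\sqrt 2$ in axis FWHM). The
cotangent operator reduces exactly to the 5-point planar stencil on
such grids and is the standard choice in cortical surface mapping. Its
negative weights on obtuse triangles are clamped to zero, keeping every
explicit Euler step a convex (max-principle, variance-non-increasing)
averaging. Steps satisfy the stability bound
$\Delta t \le 0.8 \cdot \min_i m_i / \deg_i$.

Missing vertices are excluded from the stencil; the local mass is
scaled by the observed weight fraction so diffusion speed among
observed vertices is preserved, and values never leak across missing
regions. The impulse-response test (unit impulse on a 0.5 mm grid,
8 mm kernel) verifies the empirical FWHM to within 10% in both grid
directions.

## Projection with maximum-FA selection

Tensors are sampled by component-wise trilinear interpolation at
equally spaced points along the full chord $b_- \to m \to b_+$ (both
spokes pooled, skeleton point included — the chord reading makes the
selection symmetric in the two boundaries). The sample with the largest
FA, subject to a 0.2 minimum, is selected and its FA *and its own* MD
recorded. Design details:

* **Sampling density.** Default 11 samples per half-spoke, densified
  automatically so the step never exceeds half the smallest voxel
  dimension; this bounds the interpolation error of the maximum well
  below measurement noise (the parabolic-profile test quantifies it).
* **Ties** go to the sample nearest the skeleton: deterministic, and
  favors the medial locus.
* **Out-of-bounds samples are skipped**, never zero-filled — zero
  filling would bias the maximum toward interior vertices.
* **Interpolation is linear, not Log-Euclidean.** At voxel scale the
  two differ at second order; the linear scheme is determinate,
  reproducible bit for bit, and oracle-checkable (exact on affine
  component fields).

Tensor volumes are read/written as 6-volume NIfTI with the
lower-triangular component order by default; the upper-triangular
dialect is accepted only behind an explicit flag, because the two
orders are indistinguishable from the data alone and guessing corrupts
off-diagonal terms silently. The affine uses sform with qform
fallback.

## Vertexwise growth models

At each vertex, for males and females independently:

* linear: $y = b + a\,\mathrm{age}$, ordinary least squares;
* exponential: $y = C + A e^{-\mathrm{age}/t}$ — asymptote $C$,
  amplitude $A$ ($A<0$ for increasing FA, $A>0$ for decreasing MD),
  time constant $t$ in years.

The exponential is linear in $(C, A)$ given $t$, so the profile SSE
over $t$ is a one-dimensional function that is cheap to evaluate
exactly. The fit minimizes it globally on the grid
$t \in \{0.5, 1.0, \dots, 50\}$ and polishes the best grid point by
golden-section search to a relative SSE tolerance of $10^{-10}$
(iteration cap 500), with $t$ bounded in $(0, 1000]$. A fit that runs
into the upper bound — the model's straight-line limit, which is what
exactly linear data produce — or exhausts the iteration cap is marked
non-converged and can never be selected; such vertices fall back to the
linear model. This grid-plus-polish scheme is globally reliable (the
profile SSE's basins are wider than the 0.5-year grid step at the noise
levels of interest) and is checked in the tests against an exhaustive
$\Delta t = 0.001$ profile oracle.

Standard errors come from the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$ with $\hat\sigma^2 = SSE/(n-3)$ and
$J = [1,\; e^{-a/t},\; A\,a\,e^{-a/t}/t^2]$. Goodness of fit is
reported as $r = \mathrm{sign}(a)\sqrt{1 - SSE/SST}$ for the linear
model and the sign-neutral $\sqrt{1 - SSE/SST}$ for the exponential
(the exponential's direction lives in the sign of $A$); the output
headers document this, since "correlation of fit" is otherwise
ambiguous for a nonlinear model.

Each model is tested against the constant-mean null with
$F = \frac{(SST-SSE)/(k-1)}{SSE/(n-k)}$, $k = 2$ or 3 — per-model
significance, not a nested linear-vs-exponential comparison, because
the pipeline reports separate significant-linear and
significant-exponential vertex sets. Flat data ($SST = 0$) return
$p = 1$ by convention. AIC uses the Gaussian form
$n\ln(SSE/n) + 2(k+1)$, counting the noise variance as a parameter; at
$n \approx 90$ the small-sample correction (AICc) would change AIC by
under 0.3 and never the comparison in practice, so plain AIC is used
and documented. Missing subjects are dropped listwise per vertex, and
vertices retaining fewer than 80% of a sex group are flagged rather
than imputed.

## Familywise correction and model selection

Vertexwise p values are Gaussianized, and the peak-level threshold
$z^*$ solves $\mathrm{E[EC]}(z) = \alpha$ with

$$\mathrm{E[EC]}(z) = P(Z>z) + R_2\,\frac{4\ln 2}{(2\pi)^{3/2}}\,
  z e^{-z^2/2}, \qquad R_2 = \mathrm{area}/\mathrm{fwhm}^2 ,$$

at $\alpha = 0.01$. Design choices, each of which trades a little
fidelity for determinism and testability:

* Gaussian EC densities on the z-transformed p map rather than native
  F-field densities: standard practice, simpler, slightly conservative
  in the relevant range.
* The boundary (1-dimensional) resel term is omitted; on the fixture
  sheet it contributes roughly 15% of E[EC], and since E[EC]
  overestimates the familywise rate of the discrete maximum anyway, the
  omission stays inside the calibration budget. The Monte-Carlo
  familywise test (2 000 smoothness-matched Gaussian null fields on a
  31 x 16 sheet of 60 x 30 mm) verifies the realized rate at or below
  0.02 for nominal 0.01.
* Resels use the nominal applied FWHM (8 mm), not residual-estimated
  smoothness, so thresholds are deterministic given the geometry.
* Correction is per tract surface, matching per-tract summary
  percentages; analyzing several surfaces jointly means pooling their
  resels, which the caller can do by summing areas.

Selection: where both models survive, smaller AIC wins; where one
survives, it is chosen; a non-converged exponential is never chosen.
A direction filter then removes vertices whose trend runs against
maturation — $A \ge 0$ (FA) or $A \le 0$ (MD) for the exponential, and
the analogous slope signs for the linear model. Applying the filter to
linear fits is an interpretation (the tract maps display only
maturation-consistent trends); it changes inclusion only, never the
estimates, which the tests assert.

## Maturation maps

For selected exponential vertices the plateau age is the age at which
90% of the remaining change from the youngest modeled age (6 years)
toward the asymptote is complete:

$$T = 6 + t\,\ln 10, \qquad se_T = \ln 10 \cdot se_t .$$

This reading — 90% of the *remaining change from age 6*, i.e.
$e^{-(T-6)/t} = 0.1$ — is adopted over the alternative "90% of the
asymptote value $0.9\,C$" because it is a pure function of $t$, its
error propagation is exact and linear, and it reproduces every
tabulated $(t, T)$ and $(se_t, se_T)$ pair in the published tract
tables to within the rounding of $t$; the $0.9\,C$ crossing depends on
$A$ and does not. Linearity also gives the exact aggregation identity
$\overline T = 6 + \ln 10\,\overline t$ used by the tract summaries,
whose tract-level $se_T$ is $\ln 10 \times$ the *mean of per-vertex*
standard errors — the convention self-consistent with the per-vertex
propagation (the alternative, the standard error of the mean, would be
several times smaller than the published tract-level values).

The yearly rate up to the plateau is
$|y(T) - y(6)|/(T - 6) = 0.9\,|A| e^{-6/t}/(t \ln 10)$ for exponential
vertices and $|a|$ for linear ones. Sexes are compared by the
one-standard-error overlap rule: plateau ages differ when
$[T - se_T,\, T + se_T]$ intervals are disjoint. Both the per-vertex
and the tract-level comparison use the same rule.

## The synthetic cohort generator

The generator exists so that every stage has data with known truth. It
emulates:

* structured medial sheets (flat, curved, arch) with constant, linear
  or bump radius fields;
* cross-sectional cohorts — default 178 subjects, 83 M / 95 F, ages
  uniform on 6–30 years (uniform because design coverage at the young
  end is what identifies small time constants; a truncated-normal
  preset with moment-matched parameters reproduces the published
  empirical age moments, 15.6 ± 6.1 / 16.0 ± 6.4 years, when realism
  matters more than identifiability);
* regionally varying growth fields. Default regions carry the
  published per-tract female FA (and MD) time constants and yearly
  rates, converted to amplitudes via
  $A = \Delta / (e^{-30/t} - e^{-6/t})$ where $\Delta$ is the total
  change over the window, with male time constants scaled by the
  published per-tract male/female ratios; one linear and one
  no-age-effect band complete the default design. Parameter maps are
  drawn per region and smoothed within region so their correlation
  length respects the 8 mm measurement smoothing;
* measurement noise: additive Gaussian on FA and MD after projection,
  SD 0.03 (FA) and 0.05 × 10⁻³ mm²/s (MD) — calibrated so vertexwise
  fit correlations at n ≈ 90 per sex land in the 0.4–0.7 band the
  tract tables report, making synthetic recovery experiments
  commensurate with the real analysis;
* full tensor volumes with the field embedded: prolate tensors (the
  unique $\lambda_1 > \lambda_2 = \lambda_3$ solution for a target
  FA/MD pair, solved in closed form) oriented along the surface
  tangent inside the medial envelope, isotropic background below the
  FA threshold outside.

What it does **not** emulate — and hence what green tests do not show
about real data: registration/normalization error between subjects,
Rician noise on raw diffusion-weighted images and its FA bias,
spatially correlated (subject-level) noise, partial-volume mixing at
tract boundaries beyond trilinear blending, crossing-fiber geometry,
and tubular tracts. Passing the round-trip and recovery tests says the
*pipeline arithmetic* is right, not that an 8 mm kernel or the 0.2 FA
threshold are optimal for any given acquisition.

## Degenerate inputs and tie-breaks, collected

* radius ≤ 0, non-manifold or disconnected meshes: constructor errors;
* medially infeasible vertices: flagged, excluded, counted;
* all samples out of volume or max FA < 0.2: vertex missing, never
  imputed;
* fewer than 3 (linear) / 4 (exponential) observations, or zero age
  variance: vertex marked unfittable;
* flat response: $F = 0$, $p = 1$; perfect fit: $SSE = 0 \to$ AIC
  $-\infty$, which still compares correctly;
* FA of the all-zero tensor: 0; negative eigenvalues clipped before FA;
* maximal-FA ties: nearest-skeleton sample;
* table rounding: half away from zero, so printed summaries are
  platform-independent.

## Problem sizes in the shipped tests

The suite runs on one CPU in a few minutes: recovery uses 500
exponential vertices × 90 subjects per sex; calibration uses 10 000
null vertices (F test) and 2 000 smoothed null fields on a 496-vertex
sheet (familywise rate); round trips use a 200-vertex sheet embedded in
a ~50 × 30 × 10 voxel volume. These sizes were chosen as the smallest
at which the Monte-Carlo error of each check is comfortably below the
tolerance it asserts.

## Known limitations

Sheet-like tracts only; nominal (not residual-estimated) smoothness in
the correction by default; AIC rather than AICc; component-wise tensor
interpolation; no longitudinal (within-subject) modeling — the
cross-sectional exponential describes the population mean trajectory,
not individual growth.
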