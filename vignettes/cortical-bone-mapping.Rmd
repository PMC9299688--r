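---
title: "Cortical bone mapping with an endocortical slope model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical bone mapping with an endocortical slope model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmap)
```

## The measurement problem

Vertebral cortices are typically 0.2–1.5 mm thick, while clinical
quantitative CT (QCT) is reconstructed at 1.0–1.25 mm slice thickness
with an in-plane point spread function (PSF) of comparable scale.
Threshold- and full-width-half-maximum-based thickness measures fail in
this regime because the imaged cortex is mostly blur. Model-based
deconvolution replaces thresholding with an explicit generative model:
the true density along a line perpendicular to the bone surface is
assumed piecewise simple, the scanner is assumed to convolve it with a
Gaussian PSF, and the model parameters are estimated by fitting the
*blurred* model to the sampled CT values. Under an exactly known PSF
this recovers cortical widths well below the nominal resolution.

## The density model

Along the inward surface normal (position $x$ in mm, $x$ increasing
into the bone), `cbmap` models the unblurred density as

$$
y(x) \;=\;
\begin{cases}
y_{bg} & x < x_0 \quad \text{(soft tissue)}\\
y_c & x_0 \le x < x_1 \quad \text{(cortical plateau, Ct.BMD)}\\
y_c + (y_t - y_c)\dfrac{x - x_1}{x_2 - x_1} & x_1 \le x < x_2
  \quad \text{(endocortical slope)}\\
y_t & x \ge x_2 \quad \text{(cancellous plateau, Cn.BMD)}
\end{cases}
$$

The endocortical transition — where cortical bone grades into
trabecular bone — is modeled as a linear density ramp rather than a
sharp step; its width is the endocortical thickness,
$\mathrm{Ec.Th} = x_2 - x_1$. Cortical thickness is measured from the
periosteal edge to the **midpoint** of the transition,
$\mathrm{Ct.Th} = (x_1 + x_2)/2 - x_0$, so cortex and endocortex
deliberately overlap by half the transition width, as they do
histologically. Cortical mass surface density consolidates thickness
and density into the mass per unit surface area,

$$\mathrm{CMSD} = 0.1 \times \mathrm{Ct.Th} \times \mathrm{Ct.BMD}
\quad [\mathrm{mg/cm^2}],$$

the factor 0.1 converting mm·mg/cm³. With the midpoint convention the
model's excess mass over the cancellous background is exactly
$0.1\,\mathrm{Ct.Th}\,(\mathrm{Ct.BMD}-\ldots)$-shaped, which is why
CMSD is the most robust of the five metrics (more below).

The observed profile is the model convolved with a unit-area Gaussian
of standard deviation $\sigma$. `eval_blurred()` implements the closed
form — an error-function term for the periosteal step and the standard
ramp-Gaussian closed form for the transition — verified in the test
suite against an independent piecewise adaptive-quadrature convolution
to $10^{-6}\,y_c$.

```{r model}
p <- cortical_params(x0 = 0, x1 = 0.8, x2 = 1.2,
                     y_bg = 30, y_c = 900, y_t = 120, sigma = 0.8)
derived_metrics(p)
```

## Fitting: variable projection with multi-start

Given a sampled profile, `fit_profile()` minimizes the sum of squared
differences between the blurred model and the samples. Two properties
of the problem shape the optimizer:

* The three densities enter the blurred model **linearly**
  ($y = y_{bg} b_1 + y_c b_2 + y_t b_3$ with basis functions built from
  the blurred step and ramp), so the search uses variable projection:
  only the geometry $(x_0,\, x_1 - x_0,\, x_2 - x_1)$ (plus optionally
  $\sigma$) is optimized by bounded Levenberg–Marquardt, the densities
  being recovered by an inner linear least-squares solve at every
  step. This keeps the nonlinear dimension at three and tolerates the
  severe scaling differences between positions (mm) and densities
  (mg/cm³).
* For a sub-resolution cortex the blurred peak is strongly attenuated,
  which drags the gradient-based starting heuristic into the wrong
  basin. `fit_profile()` therefore also builds amplitude-corrected
  starts over a grid of candidate thicknesses (dividing the observed
  peak height by the bar-attenuation factor $2\Phi(T/2\sigma) - 1$),
  ranks all starts by their projected residual, and refines the three
  most promising.

Fits are screened for plausibility (Ct.Th within 0.05–5 mm, densities
within 0–2000 mg/cm³, cortical–cancellous contrast of at least
50 mg/cm³, RMS residual within 3 estimated noise SDs); failures are
flagged and later filled in by surface smoothing, never silently
accepted.

```{r fit}
truth <- cortical_params(0, 0.45, 0.55, 20, 900, 120, sigma = 1.2)
prof <- gen_profile(truth, spacing = 0.2, noise_sd = 0)
fit <- fit_profile(prof, fit_config(sigma = 1.2))
unlist(fit$metrics)   # 0.5 mm cortex recovered under 1.2 mm blur
```

## What is identifiable at clinical blur — and what is not

The honest core of this package is an identifiability analysis that
governs the whole pipeline design. At the study regime (profile-level
PSF $\sigma \approx 1$ mm, sample noise ~25 mg/cm³, vertebral Ct.Th
~0.9 mm) the per-profile Fisher information matrix is nearly singular
along the thickness–density trade-off: a thinner, denser cortex and a
thicker, less dense one produce blurred profiles differing by a
fraction of the noise. Numerically, the correlation between fitted
Ct.Th and Ct.BMD exceeds 0.9999 and the Cramér–Rao bounds for a
500-vertex scan are ~16 % on Ct.BMD and ~17 % on Ct.Th — while the
*product* (CMSD), the cancellous plateau Cn.BMD and the edge position
are precisely identified. The endocortical width is worse still: the
blurred ramp differs from a blurred step only at order
$(w/\sigma)^2$, so the information for $w$ vanishes as $w \to 0$; at
$w \approx 0.09$ mm and $\sigma = 1$ mm the distinguishing signal is
~0.06 mg/cm³ against 25 mg/cm³ noise. No estimator can undo this;
any apparent per-vertex Ec.Th precision at this blur is
regularization, not measurement.

The pipeline (`run_pipeline()`) therefore uses the standard
cortical-bone-mapping remedy: **anchor the cortical tissue density per
bone**. Concretely, a free pass over a subset of vertices yields a
robust per-subject anchor (the median fitted $y_c$, pooled over both
timepoints, which share a scanner and PSF), and an anchored pass over
all vertices fixes $y_c$ at that value, making per-vertex Ct.Th a
well-conditioned mass measurement. Two consequences are documented
rather than hidden:

* because the anchor is shared across timepoints, its estimation error
  cancels from longitudinal percentage changes;
* a genuine change in tissue-level cortical density is absorbed into
  the apparent thickness change — anchored Ct.Th %-change equals the
  cortical *mass* %-change. Reported Ct.BMD summaries come from the
  free pass and carry the full trade-off uncertainty.

## From profiles to surfaces

For volumetric data, `sample_profiles()` draws trilinear-interpolated
density along each vertex's inward normal (defaults: 4 mm outward,
8 mm inward, 0.2 mm step), truncating at half the local chord length
to the opposing surface so that thin posterior structures (pedicles,
spinous processes) do not contaminate the fit with the far cortex.
Interior measures (Cn.BMD, Ec.Th) are restricted to the vertebral body
(`restrict_to_body()`) because no cancellous plateau exists where
opposing cortices nearly touch.

Anisotropic blur matters: a profile along unit normal $n$ is blurred
by an effective $\sigma(n)^2 = (n_x^2+n_y^2)\sigma_{xy}^2 +
n_z^2\sigma_z^2$, and the sampling chain itself adds variance
(trilinear interpolation contributes $h^2/6$ per axis for voxel size
$h$). `psf_sigma_along_normals()` composes these; ignoring them slides
fits along the thickness–density valley.

Per-vertex maps are smoothed across the surface with a Gaussian kernel
over graph-geodesic neighborhoods (`smooth_vertex_map()`, FWHM 5 mm
default): this removes noise and supplies values where the model
failed to fit, with kernel weights renormalized over valid vertices
only.

## Registration and group statistics

Longitudinal and group comparisons require one-to-one vertex
correspondence, obtained by registering each subject mesh onto a
canonical shape (`register_mesh()`): principal-axes initialization,
rigid iterative-closest-point refinement, a thin-plate-spline warp
driven by mutual-nearest-neighbor matches, and finally closest-point
projection of canonical vertices onto the warped subject surface
(barycentric weights on subject triangles). Synthetic cohorts share
mesh topology, so registration can also run in identity mode to
isolate downstream stages.

Global per-subject percentage changes use the ratio of means over
in-scope valid vertices (stable against near-zero per-vertex
baselines; per-vertex ratios are floored instead — 0.02 mm for Ec.Th,
10 mg/cm³ for densities). Group summaries reproduce the conventional
trial table: mean ± SD percentage change per arm, two-tailed one-sample
t versus baseline, Welch two-sample t versus placebo and versus the
comparator arm, and a one-way ANOVA for baseline comparability.

Vertex-wise inference (`vertexwise_spm()`) uses permutation
max-statistic family-wise error control — sign flipping for one-sample
maps, label permutation for two-sample maps, exhaustive enumeration
when feasible — chosen over random-field theory because it is
assumption-light, exact under exchangeability, and directly verifiable
by Monte Carlo (the test suite checks the realized FWER of 200 null
cohorts against the binomial interval around $\alpha = 0.05$).
Rendered maps follow the display convention: light gray where changes
are not significant, dark gray where the region is out of scope.

## The synthetic study

No patient data ship with the package; `gen_cohort()` re-creates the
study conditions with known ground truth. Per subject, baseline truths
are drawn from the published baseline distributions (e.g. Ct.Th
0.89–0.93 ± 0.07–0.08 mm, Ct.BMD ~790 ± 54 mg/cm³, Cn.BMD ~113 ± 18
mg/cm³, Ec.Th ~0.09 ± 0.05 mm per arm), per-subject true percentage
changes are drawn from each arm's published 12-month change
distribution and applied multiplicatively, and both timepoints are
synthesized as blurred noisy profiles with the same PSF (the study
scanned each subject on the same scanner at both visits). Baseline
Ec.Th draws are floored at 0.02 mm; draws violating model validity are
redrawn with a bounded, counted retry. The implied CMSD change is the
compound of the Ct.Th and Ct.BMD changes, never an independent draw.
`gen_shell_phantom()` builds full 3D analogs: an ellipsoidal body with
exact signed-distance rasterization of the layered density model,
anisotropic Gaussian blur, additive noise, inverse-calibration HU
encoding, and an optional posterior-labeled cap. The shape family is a
deliberate simplification — it exercises every pipeline stage without
shipping anatomy; what passing tests show is correctness of the
measurement chain, not realism of vertebral geometry, real tissue
heterogeneity, beam hardening, or structured CT noise.

Default study conditions are fixed once: arms of 20/19/17 subjects,
500 vertices/subject, $\sigma = 1.0$ mm, noise SD 25 mg/cm³, 0.2 mm
sampling. Scaled-down sizes used by the test suite (e.g. 120
vertices/subject, two seeded repetitions for the cohort test; 200-set
Monte Carlo for the FWER check) are the package's own choices to keep
the suite runnable at desk scale.

## Numerical choices and degenerate inputs

* $x_1 = x_2$ degenerates cleanly to the classic two-step (sharp
  endocortex) model, in both the closed form and its derivatives.
* Flat, contrast-inverted, or mostly-missing profiles fail
  initialization explicitly with a reason, as do profiles with fewer
  than 15 usable samples.
* Zero-variance groups in t tests take an exact-equality fast path
  (p = 1 on equality, 0 otherwise) instead of dividing by zero.
* The per-scan PSF estimate (`estimate_global_sigma()`) uses only
  top-quartile-contrast profiles whose fitted cortex is at least as
  thick as the fitted blur, and falls back to the configured default
  with a warning when fewer than 10 such fits exist: sigma is only
  identifiable from cortices thicker than the blur.
* Percentage-change denominators are floored per metric because the
  study's own baseline Ec.Th (~0.09 mm) sits near zero.

## Known limitations

* Ct.BMD and Ec.Th longitudinal changes at $\sigma \approx 1$ mm are
  reported but not identified (see the analysis above); their group
  summaries carry uncertainty comparable to or larger than the
  published effects. This is a property of the physics, not of the
  implementation, and the package reports these estimates without
  shrinking them toward plausible values.
* The method cannot distinguish reduced mineralization from increased
  porosity, nor detect periosteal apposition specifically; both limits
  are inherited from the resolution argument.
* The registration is designed for the phantom family and same-class
  anatomies; it is not a general-purpose anatomical registration.
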