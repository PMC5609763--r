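---
title: "Prior-knowledge AMARES fitting: model, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-knowledge AMARES fitting: model, conventions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsfit)
```

## The model and its assumptions

`mrsfit` fits the complex free-induction decay directly in the time
domain as a sum of `K` damped sinusoids,

$$\hat y_n = \sum_{k=1}^{K} a_k\, e^{i\varphi_k}\,
  e^{-d_k\,(1-g_k+g_k t_n)\,t_n}\, e^{i 2\pi f_k t_n},
  \qquad t_n = n\,\Delta t + t_0,$$

with additive complex white Gaussian noise whose real and imaginary
channels are independent with common standard deviation $\sigma$. The
lineshape interpolator $g_k$ selects exponential decay (Lorentzian line,
$g_k=0$), Gaussian decay ($g_k=1$), or a smooth mixture. Assumptions
worth stating explicitly:

* the baseline is fully described by the declared peaks — no
  macromolecule or broad-component model is added;
* $g_k$ is prior knowledge, held fixed during fitting, never a free
  parameter;
* $t_0$ (the receiver dead time) is a fixed acquisition constant; its
  first-order phase effect enters only through the time axis;
* noise is stationary and white; the residual-based $\sigma$ estimate
  relies on this.

## Units and conventions

Users declare prior knowledge in field units; the solver and Fisher
calculus run in model units. The conversions are fixed and documented
once here:

* **Chemical shift.** $f\,[\mathrm{Hz}] = (\delta - \delta_{\mathrm{ref}})
  \cdot f_0$ with $f_0$ in MHz; positive ppm maps to positive Hz. No
  sign flip is applied anywhere else.
* **Linewidth.** Prior knowledge is full width at half maximum of the
  *absorption* line in Hz. For a Lorentzian, $d = \pi\,\mathrm{lw}$; for
  a Gaussian, $d = (\pi\,\mathrm{lw})^2/(4\ln 2)$. For intermediate
  $g$ the damping interpolates linearly between the two pure conversions,
  which is exact at both endpoints, smooth, and invertible; its
  derivative enters the constraint Jacobian, so mixed lineshapes remain
  consistent in the CRLB calculus.
* **Phase.** Degrees in every user-facing file, table, and bound; radians
  internally. This split lives entirely inside `apply_constraints()`, so
  no other code path converts units.
* **Voxel indices.** 0-based internally (`voxel_to_patient(grid,
  c(0,0,0))` is the first voxel centre); 1-based in user-facing result
  tables.

## Prior knowledge and the constraint map

`compile_prior()` turns the declarative peak table into an affine map
$p = S x + o$ from free parameters $x$ (user units) to the full
per-component parameter vector $p$. Multiplets expand into components
placed symmetrically about the parent shift at spacings of the J-coupling
(a doublet sits at $\pm J/2$, a triplet at $-J, 0, +J$), with fixed
amplitude ratios (binomial by default) multiplying one free amplitude —
so a doublet contributes four free parameters, not eight. Grouped
quantities share one free parameter; per-peak offsets (`phase_offset`,
`shift_offset`, `base_linewidth`) become additive constants. Every row of
$S$ has at most one nonzero entry, which keeps the map separable and
makes constraint satisfaction exact by construction in every fitted
result, not just at convergence.

Two choices were genuinely open:

* **Bounds of shared parameters.** The intersection of the members'
  bounds, since any member's bound must hold; the start is the clipped
  mean of the members' starts. An empty intersection is a compile error
  rather than a silent preference for one peak.
* **Free parameters stay in user units.** The affine map is stated over
  ppm / Hz FWHM / degrees, and unit conversion is applied afterwards with
  its chain rule in `constraint_jacobian()`. The alternative — converting
  bounds into model units at compile time — produces the same fits but
  makes bounds, covariances and CRLBs unreadable; keeping user units
  means every reported number is directly interpretable.

The constraint representation is affine only. Arbitrary smooth
relationships can be layered on top by composing `apply_constraints()`
with a custom map and supplying the composed Jacobian to
`compute_crlb()`; everything shipped compiles to affine form.

## The two-step fit

`initialize_linear()` solves the complex linear least-squares problem for
amplitudes and phases with frequencies, dampings and lineshapes at their
starting values. Phase groups are honoured *after* an unconstrained
per-component solve: the shared phase is set to the amplitude-weighted
circular mean of the member phases minus their fixed offsets. This is
cheap, deterministic, and only a starting value — the nonlinear step
enforces the constraint exactly. A rank-deficient basis (e.g. two peaks
declared at the same frequency) falls back to the declared starts with a
logged warning.

The main step minimises the stacked real/imaginary time-domain residual
over the free parameters within their box bounds using bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) with the analytic model
Jacobian composed with the constraint Jacobian. This is the same
objective/bounds contract as a trust-region-reflective solver; the
package asserts the solver-independent contracts instead of internals —
monotone objective decrease, bounds satisfied exactly, noiseless recovery
to 1e-6 relative error. Tolerances default to `ftol = ptol = 1e-10` with
at most 1000 iterations, all configurable via `amares_options()`. All
`N` points are fitted — there is no frequency-window restriction and no
special weighting of the first point; dropping initial points is exposed
as `truncate_initial` (default 0), which advances the dead time
consistently. The fit is deterministic: no random restarts.

## Noise and uncertainty

A CRLB is only defined once a noise convention is fixed; the
package uses the per-channel residual standard deviation
$\hat\sigma^2 = \sum_n |r_n|^2 / (2N - n_{\mathrm{free}})$ and the Fisher
information $F = \mathrm{Re}(J^H J)/\sigma^2$, which is the exact Fisher
matrix for independent $N(0,\sigma^2)$ real and imaginary channels. The
pair of conventions is validated jointly by a Monte-Carlo property: over
500 seeded noise realizations of a two-peak model at SNR 50, the
empirical standard deviation of every estimate matches the mean CRLB
within 10%.

The free-parameter covariance is $C = (D^\top F D)^{-1}$ with $D$ the
constraint Jacobian; the full-parameter covariance $S C S^\top$ retains
all cross-covariances, so grouped parameters share identical CRLBs and
derived quantities get exact linear-combination variances. Box bounds are
ignored in the information matrix (the standard unconstrained-information
CRLB); estimates sitting on a bound are flagged instead, because a
bound-constrained "CRLB" would understate the uncertainty in a way that
is easy to misread. A singular $D^\top F D$ — typically two peaks
collapsing onto one frequency — falls back to a pseudo-inverse with a
conditioning warning and `ill_conditioned = TRUE`.

`derived_param_crlb()` evaluates arbitrary arithmetic expressions over
full-parameter labels and named constants and propagates $C$ through the
symbolic gradient (delta method). Gradients are compiled once per
(canonical expression, label set) and cached on disk under a content
hash, so reformatting an expression reuses the cache while changing the
label set (e.g. adding a metabolite) correctly recompiles; a counter
(`derived_compilations()`) makes cache behaviour testable, and the cache
file survives process restarts. An unwritable cache directory degrades
to in-memory caching with a warning.

## Synthetic data: what it emulates and what it does not

`simulate_fid()` adds seeded complex white Gaussian noise to the exact
model; `simulate_csi_phantom()` builds a CSI grid from a template peak
set (default: a two-peak ³¹P-like pair, amplitudes 10 and 5, linewidths
12 and 15 Hz at 120.3 MHz, 1024 points at 4 kHz bandwidth) scaled by a
smooth in-plane amplitude bump in [0.4, 1]. One root seed spawns
deterministic per-voxel substreams from the voxel's linear index, so any
voxel subset reproduces bit-identically in isolation. Ground truth
travels with the data (an attribute in memory, a `truth` section in
fixture files), so recovery tests need no side channel.

This emulates exactly the stated noise model and nothing more: no
macromolecule baselines, eddy-current or lineshape distortions, motion,
spatial contamination between voxels, or $B_0$ inhomogeneity. Passing
recovery tests therefore demonstrates correctness of the estimator under
its own assumptions — not robustness to the artefacts of real in-vivo
acquisitions, which is the usual division of labour for validating
fitting code.

Problem sizes used throughout tests and the acceptance script — 512–1024
point FIDs, two or three peaks, 8×8 single-slice phantoms, 100
finite-difference draws, 500 Monte-Carlo realizations — were chosen as
the smallest sizes at which each property is statistically meaningful
(e.g. a 500-sample SD estimate has ≈3% relative error, comfortably inside
the 10% Monte-Carlo band).

## Numerical choices and degenerate inputs

* Peak contributions are summed left-to-right so the model is *exactly*
  additive over peaks, a property the tests assert to machine precision.
* Linear-initialisation estimates are clipped into bounds; phases are
  wrapped by multiples of 360° into their bound interval first.
* An all-zero voxel fits to zero amplitudes with zero residual; since no
  noise level is estimable, the batch driver flags such voxels as
  non-converged rather than reporting CRLB-free estimates, and never lets
  one voxel abort a batch.
* Amplitude-at-zero: the analytic Jacobian computes the amplitude column
  at unit amplitude, so a zero-amplitude start is differentiable.
* The acceptance comparison for display truncation is made on the
  plotted arrays: each peak's display spectrum is evaluated on a fine
  frequency grid spanning exactly 2.5× its fitted FWHM (the grid is
  analytic, so "exactly" means machine precision, not bin resolution).

## DICOM scope

The importer reads Siemens MR spectroscopy DICOMs: explicit and implicit
VR little endian, CSA1 and CSA2 private-header dialects auto-detected
from the `SV10` magic, sample data as interleaved 32-bit float
real/imaginary pairs, DICOMDIR indexes, and geometry from the standard
position/orientation/spacing tags. Directory scans cache instance
metadata in the session temporary directory keyed by folder path, with
per-file size+mtime invalidation and silent rebuild of corrupt or
version-mismatched caches. The package also ships a synthetic
Siemens-style writer used by the test suite (two package-specific CSA
tags, `DeadTime_s` and `ReferenceShift_ppm`, carry metadata real headers
encode only indirectly); files from other vendors are out of scope, but
the reader sits behind a single entry point (`read_spectroscopy()`) so
vendor readers can be added without touching the fitting stack.

## Known limitations

* Lineshapes beyond the $g$-interpolation (true Voigt, measured
  reference lineshapes) are not supported.
* No water/reference scaling, saturation correction factors must be
  supplied by the user as constants in derived expressions.
* The noise estimator assumes white noise; apodised or filtered data
  will bias $\hat\sigma$ and hence the CRLBs.
* Multi-dataset constraints (shared linewidths across a saturation
  series, spatial smoothing of linewidths) are not implemented; the
  affine constraint map is per-fit.
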