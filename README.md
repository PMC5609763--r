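# mrsfit

Time-domain AMARES fitting of in-vivo magnetic resonance spectroscopy
(MRS) data in R, with Cramér–Rao uncertainty bounds, Siemens DICOM
spectroscopy import, and batch processing of chemical-shift-imaging (CSI)
voxel grids.

## Who this is for

In-vivo MRS quantifies metabolites — phosphocreatine, ATP, phosphodiesters
in ³¹P studies of heart and muscle, for example — from the complex
free-induction decay (FID) recorded by the scanner. Peak-area integration
in the spectrum is fragile when peaks overlap or SNR is low; the field's
standard remedy is prior-knowledge-constrained time-domain fitting
(AMARES). `mrsfit` implements that approach end to end for researchers
building their own automated processing pipelines: declarative prior
knowledge, a robust two-step fit, principled uncertainties (including for
derived quantities such as saturation-corrected amplitude ratios), and
batch drivers over CSI grids.

## The model

The FID is modelled as a sum of `K` exponentially damped sinusoids on the
time axis `t_n = n·Δt + t₀`:

```
ŷ_n = Σ_k  a_k · exp(i φ_k) · exp(−d_k (1 − g_k + g_k t_n) t_n) · exp(i 2π f_k t_n)
```

with amplitude `a_k`, phase `φ_k`, damping `d_k`, frequency `f_k`, and a
fixed lineshape parameter `g_k` (0 = Lorentzian, 1 = Gaussian); the data
are `y_n = ŷ_n + e_n` with complex white Gaussian noise `e_n`. Prior
knowledge — bounds, starting values, multiplet splittings with fixed
amplitude ratios, shared phases/linewidths/amplitudes, additive offsets —
is compiled into an affine constraint map `p = S·x + o` from a reduced
free-parameter vector `x`. Fitting proceeds in two steps: a linear
least-squares solve for amplitudes and phases at the starting frequencies
and dampings, then bounded nonlinear least squares over `x` on the stacked
real/imaginary time-domain residual with analytic Jacobians. Uncertainties
come from the constrained Fisher information `F = Re(Jᴴ J)/σ²`: the
free-parameter covariance is `C = (Dᵀ F D)⁻¹`, full-parameter covariance
`S C Sᵀ`, CRLB = square root of its diagonal, and the delta method
propagates `C` through arbitrary expressions of the parameters with
symbolically compiled, disk-cached gradients.

## Worked example

Simulate a two-peak ³¹P-like FID (PCr at 0 ppm, γ-ATP at −2.48 ppm,
SNR ≈ 100), fit it with deliberately wrong starting values, and read off
estimates and CRLBs:

```r
library(mrsfit)

meta  <- fid_meta(1024, dwell_time = 2.5e-4, transmitter_freq = 120.3)
truth <- sinusoids(amplitude = c(10, 5), phase = 0.3,
                   damping   = lw_to_damping(c(12, 15)),
                   frequency = ppm_to_hz(c(0, -2.48), 120.3))
fid <- simulate_fid(truth, meta, sigma = 0.1, seed = 7)

pk <- dplyr::bind_rows(
  peak_prior("PCR",       shift =  0.1, amplitude = 6, group_phase = "p0"),
  peak_prior("ATP_GAMMA", shift = -2.4, amplitude = 4, group_phase = "p0"))

fit <- fit_amares(fid, pk)
tidy(fit)
#> # A tibble: 8 × 5
#>   term         component quantity       estimate     crlb
#>   <chr>        <chr>     <chr>             <dbl>    <dbl>
#> 1 PCR_am       PCR       amplitude    10.0       0.0192
#> 2 PCR_ph       PCR       phase_deg    17.0       0.0994
#> 3 PCR_lw       PCR       linewidth_hz 12.0       0.0327
#> 4 PCR_cs       PCR       shift_ppm     0.0000675 0.000130
#> 5 ATP_GAMMA_am ATP_GAMMA amplitude     5.01      0.0215
#> 6 ATP_GAMMA_ph ATP_GAMMA phase_deg    17.0       0.0994
#> 7 ATP_GAMMA_lw ATP_GAMMA linewidth_hz 15.0       0.0911
#> 8 ATP_GAMMA_cs ATP_GAMMA shift_ppm    -2.48      0.000290
```

The true values (amplitudes 10 and 5, linewidths 12 and 15 Hz, shared
phase 0.3 rad = 17.2°, shifts 0 and −2.48 ppm) are recovered within their
CRLBs. The shared phase has one free parameter, so both rows show the same
phase estimate and CRLB. A derived quantity and its delta-method CRLB:

```r
derived_param_crlb(fit, "PCR_am / ATP_GAMMA_am")
#>   expression            value    crlb
#> 1 PCR_am / ATP_GAMMA_am  2.00 0.00952
```

`glance(fit)` summarises the fit (`rss = 20.3`, `noise_sigma = 0.0998`
against a true σ of 0.1, converged in 7 iterations). `plot_fit(fit,
"fit.png")` renders the spectrum, total fit, residual and per-peak traces
(each peak truncated to 2.5× its fitted FWHM for display);
`simulate_csi_phantom()` + `batch_fit()` + `plot_amplitude_map()` do the
same per voxel over a CSI grid. `scan_dicom_tree()` and
`read_spectroscopy()` import Siemens DICOM spectroscopy (CSA1/CSA2
headers); `write_fixture()`/`read_fixture()` provide a DICOM-free
plain-text interchange format.

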