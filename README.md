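# fluorspec

Vibrational line shapes of helical perfluoroalkyl chains, from molecular
trajectories and from ATR-FTIR spectra.

## The problem

Linear perfluoroalkyl chains (PFAS such as perfluorohexane, "F6") are
helical: backbone dihedrals sit at 163/197° rather than the planar-trans
180°, so each molecule is either a left- or a right-handed helix, and the
two interconvert on the picosecond scale. Because C–F stretching normal
modes are delocalized along the backbone, the transition dipole **μ**ₖ of a
mode rotates when the helicity reverses. The dipole correlation of the
vibration is then cut off by the reversal: writing the per-mode vibrational
dipole as μₖ(t) = **μ**ₖ^(h(t)) qₖ(t) with a telegraph helicity process h(t)
of per-direction flip rate k (lifetime τ_hel = 1/2k), the dipole power
spectrum S_μ̇μ̇(ω) is the normal-coordinate spectrum convolved with a
Lorentzian of angular FWHM 4k, while the "helicity-frozen" spectrum
|**μ**ₖ⁻|² S_q̇q̇(ω) is not:

    FWHM(S_μ̇μ̇) − FWHM(|μ⁻|² S_q̇q̇)  =  4k / (2πc)     [cm⁻¹]

Faster helicity reversal — as happens in a fluorous environment — therefore
means broader C–F stretching bands at constant integrated intensity. This
package implements the full analysis chain behind that statement, for
people analysing force-field MD trajectories of perfluoroalkyl systems
and/or concentration-dependent ATR-FTIR band shapes:

* **trajectory arm** — Welch/Wiener–Khinchin dipole power spectra and
  Green–Kubo susceptibilities (χ″(ω) = ω S_MM / (2·3Vε₀k_BT)); normal-mode
  analysis of supplied Hessians with Eckart projection and point-charge
  transition dipoles; projection of per-molecule motion onto dual-helicity
  normal-mode sets (Kabsch alignment, per-frame helicity from the
  overall-helicity dihedral); rigid-body/per-mode dipole decomposition;
  helicity-frozen spectra; event-aligned conditional autocorrelations;
  helicity-indicator lifetimes; dihedral free-energy profiles,
  trans/gauche classification and transition-state-theory rates.
* **experimental arm** — Kramers–Kronig phase separation of ATR spectra
  (90° global phase), continuous-wavelet peak detection
  (second-derivative-Lorentzian analyzing function, γ = 3–6 cm⁻¹),
  fixed-center Lorentzian deconvolution, band assignment/normalization to
  the ν_s(CF₂) reference, and concentration/chain-length trend tables.
* **synthetic generators** — helical spring-network reference structures
  with analytic Hessians, exact-propagator Langevin mode dynamics with
  telegraph helicity flips, Boltzmann dihedral samplers, and
  forward-modelled ATR spectra — so that every stage of the chain is
  testable against closed-form oracles.

See the vignette (`vignettes/line-broadening-mechanism.Rmd`) for the
models, conventions and numerical choices.

## Worked example

A dilute-vs-pure pair of synthetic datasets sharing identical oscillator
dynamics, differing only in the helicity flip rate (chosen so the
lifetimes are 2.9 ps and 1.5 ps):

```r
library(fluorspec)

cfg <- generator_config(mode_frequencies = 1220, mode_damping = 1,
                        dipole_rotation_angle = 180, dt = 2,
                        n_steps = 2^21, seed = 1)
series <- gen_concentration_series(cfg, flip_rates = c(1/(2*2.9), 1/(2*1.5)),
                                   labels = c(0.005, 1.0))

fit_at <- function(spec) {
  sel <- spec$nu >= 1140 & spec$nu <= 1300
  fit_lorentzians(spectrum_obj(spec$nu[sel], spec$values[sel], "dielectric"),
                  1220)
}
for (e in series) {
  ms   <- mode_spectra(e$data, window = "hann", n_segments = 32)
  fz   <- helicity_frozen_spectrum(e$data, e$data$modes_minus,
                                   window = "hann", n_segments = 32)
  full <- fit_at(ms$per_mode[[1]])
  froz <- fit_at(fz[[1]])
  tau  <- helicity_lifetime(e$data$theta, dt = cfg$dt)
  cat(sprintf(
    "x = %-5s  tau_hel = %4.2f ps   FWHM(full) = %5.2f cm^-1   FWHM(frozen) = %4.2f cm^-1   area ratio = %4.2f\n",
    e$label, tau$tau_integral_ps, full$fwhm, froz$fwhm, full$area / froz$area))
}
```

prints

```
x = 0.005  tau_hel = 2.74 ps   FWHM(full) =  8.44 cm^-1   FWHM(frozen) = 5.35 cm^-1   area ratio = 0.98
x = 1      tau_hel = 1.52 ps   FWHM(full) = 12.02 cm^-1   FWHM(frozen) = 5.35 cm^-1   area ratio = 0.98
```

Read: the helicity lifetime drops from ~2.9 ps to ~1.5 ps between the two
conditions; the full per-mode band broadens from 8.4 to 12.0 cm⁻¹ while
the helicity-frozen band (dipole rotation switched off) stays at the
intrinsic 5.3 cm⁻¹ width; the fitted band area is unchanged (ratio ≈ 1).
The widths match the analytic 4k/(2πc) broadening: 3.7 cm⁻¹ at x = 0.005
and 7.1 cm⁻¹ at x = 1 on top of the intrinsic width, up to single-trace
statistical scatter (the tests average over molecules for tight
comparisons).

Higher-level drivers `run_trajectory_workflow()` and `run_ftir_workflow()`
run the two canonical pipelines end-to-end and write summary/trend tables
plus a reproducibility manifest.

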