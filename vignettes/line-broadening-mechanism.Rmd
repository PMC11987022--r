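---
title: "Helicity-reversal line broadening of C-F stretching bands: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helicity-reversal line broadening of C-F stretching bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Linear perfluoroalkyl chains are helical: their backbone dihedrals sit not at
the planar-trans 180 degrees but at roughly 163/197 degrees (a 17 degree
twist per dihedral), giving two mirror-image conformers, a left- and a
right-handed helix. The two helices interconvert on the picosecond scale
("helicity reversal"). Because the C-F stretching normal modes are
delocalized along the backbone, their transition dipole moments rotate
slightly when the helicity reverses; a vibration's dipole correlation is
therefore cut off by the reversal, and faster reversal means broader
infrared lines. In a fluorous environment (high concentration of
fluorinated molecules) the reversal speeds up, so the C-F stretching band
widths become a spectroscopic marker of fluorous contact.

`fluorspec` implements both arms of this analysis:

* **trajectory arm** — power spectra and Green-Kubo susceptibilities from
  dipole time series (Wiener-Khinchin, Welch-averaged), normal-mode analysis
  of supplied Hessians (Eckart projection, point-charge transition dipoles),
  projection of per-molecule motion onto dual-helicity normal modes,
  rigid-body/vibrational dipole decomposition, helicity-indicator lifetimes,
  dihedral free-energy profiles, and conditional (event-aligned)
  autocorrelation functions;
* **experimental arm** — Kramers-Kronig phase separation of ATR spectra,
  continuous-wavelet peak detection, fixed-center Lorentzian deconvolution,
  band normalization, and concentration/chain-length trend tables.

Everything is exercised against synthetic generators whose statistical
structure matches the assumptions of the analysis, so each stage has an
analytic oracle.

# Units and conventions

Internal units are Angstrom, femtosecond, amu and elementary charge; all
spectra are reported on a wavenumber axis, `nu = omega / (2 pi c)` in
cm^-1. Dihedral angles follow the IUPAC signed convention in
(-180, 180]; a "twist" is the deviation of a dihedral from planar trans,
`twist = 180 - |phi|` (so a trans minimum at 163 degrees is a 17 degree
twist, and an overall helicity dihedral of +/-145 degrees is a 35 degree
overall twist).

The Fourier convention is `v~(omega) = integral v(t) exp(-i omega t) dt`;
the power spectrum of a vector series is `S(omega) = |v~(omega)|^2 / t_max`
summed over components, one-sided (negative frequencies folded), estimated
Welch-style with 50%-overlapping, Hann-windowed, per-segment-detrended
segments. With the rectangle window the estimator satisfies the discrete
Parseval identity exactly (`sum(S) dnu c = <v^2>`), which the tests use as
an oracle. Welch segment lengths are clamped to 5-smooth sizes because R's
mixed-radix FFT degrades badly on sizes with large prime factors.

The dielectric susceptibility uses the classical Green-Kubo/
fluctuation-dissipation form, `chi''(omega) = omega S_MM(omega) /
(2 * 3 V eps0 kB T)`, energy absorption `omega chi''(omega)`. Only
proportionality is used downstream, so an overall scale knob is exposed;
tests assert shape-level properties (Debye peak position for an
exponentially relaxing dipole, prefactor linearity in 1/V).

# Normal modes and projection

`compute_normal_modes()` takes the Hessian as input (units amu/fs^2) and
never evaluates a force field. Rigid translations and rotations are removed
by projecting onto the orthogonal complement of the six (five for linear
molecules) mass-weighted rigid vectors (Eckart conditions) rather than by
discarding the smallest eigenvalues — robust for floppy chains where the
softest internal mode can be close to zero. Mode vectors are orthonormal in
mass-weighted coordinates; Cartesian displacements are `eta_i / sqrt(m_i)`,
and the transition dipole of a mode is the point-charge dipole derivative
along it. With a fixed-point-charge model the transition dipole is
independent of the electrostatic environment, which is precisely why band
*intensities* are expected to be concentration-independent while band
*widths* are not.

`project_onto_modes()` assigns each frame a helicity from the sign of the
overall-helicity dihedral (deterministic, and matching how helicity is
characterized structurally), aligns the molecule to the reference of that
helicity, and takes mass-weighted scalar products with the mode vectors.
Two alignment metrics are offered:

* carbon-subset, unit-weight (default) — standard practice for these
  chains, and the configuration used for production analysis;
* all-atom, mass-weighted — the metric consistent with the Eckart
  projection. In this metric the mass-weighted cross-covariance between a
  mode-displaced frame and its reference is exactly symmetric, so the
  optimal rotation is the identity and a single-mode displacement is
  recovered exactly (to machine precision), which is what the exactness
  tests use.

A consequence worth stating: with a point-charge dipole (exactly linear in
coordinates), the dipole-decomposition residual is machine-zero in the
consistent metric and grows *linearly* with displacement amplitude in the
carbon metric (the subset fit's optimal rotation responds at first order to
the displacement). A quadratic residual would require an anharmonic dipole
surface, which this data model deliberately does not have.

# The broadening mechanism, analytically

The synthetic model drives each normal coordinate as an underdamped
Langevin oscillator (frequency `omega_0`, damping `gamma`, temperature `T`)
and flips the helicity as a telegraph process with per-direction rate `k`
(indicator autocorrelation `exp(-2 k t)`, lifetime `1/(2k)`). The
transition dipole rotates by an angle `theta` about the chain axis on each
reversal. Writing `mu(t) = mu^(h(t)) q(t)`, the dipole autocorrelation
factorizes into

```
C(t) = |mu|^2 C_q(t) [cos^2(theta/2) + sin^2(theta/2) exp(-2 k t)]
```

so the spectrum is a sum of an unbroadened line and a line convolved with a
Lorentzian of angular-frequency FWHM `4k`. At `theta = 180` degrees the
whole intensity is in the broadened component and

```
FWHM(S_mudot mudot) - FWHM(|mu^-|^2 S_qdot qdot) = 4 k / (2 pi c)   [cm^-1]
```

This closed form is the oracle for the central mechanism test. The
helicity-frozen spectrum `|mu^-|^2 S_qdot qdot` is exactly the hypothetical
spectrum with the dipole rotation switched off (`mu^- - mu^+ = 0`).
Telegraph modulation redistributes intensity within the band but does not
create any, so fitted band areas are constant across flip rates — the
integrated-intensity signature.

For the event-aligned conditional autocorrelation the same factorization
gives the post-event correlation scaled by `cos(theta)`: the analytic-signal
*envelope* collapses maximally at `theta = 90` degrees, while at
`theta = 180` degrees the raw correlation reverses sign with an unchanged
envelope. The tests assert this actual behavior (envelope collapse at 90,
sign reversal at 180, null at 0).

## Statistical design of the mechanism measurement

A single 2 ns trace estimates a FWHM difference of ~2 cm^-1 with ~30%
relative scatter at the lowest flip rate, so the mechanism measurement
averages spectra over independent molecules before fitting (32 molecules of
2^21 steps at `k = 0.1` ps^-1, fewer at faster rates where the broadening
is larger), exactly as a per-molecule trajectory analysis would. Band
parameters come from the shared fixed-center Lorentzian fitter, with the
center clamped at the known mode frequency. The oscillator random streams
are shared across flip rates (common random numbers) while the telegraph
streams are not: the concentration series differs *only* in flip kinetics,
which is the stated design of the mechanism (thermodynamics fixed, kinetics
varied), and it makes the intensity-constancy comparison sharp.

The Langevin sampler uses the exact Gaussian propagator of the linear SDE
(2x2 matrix exponential, stationary initialization), so equipartition
`<q^2> omega^2 = kB T` holds in law and the line shape has no integrator
bias at any time step; the time step is still required to resolve the
fastest mode (>= 10 steps per period) so that derivative spectra are
accurate near the band.

# Synthetic helical references

`gen_helical_references()` builds an idealized helical carbon backbone
(bond length 1.54 A, backbone angle 114.6 degrees) with two
pseudo-fluorine sites per carbon (charges C +0.30 e, F -0.15 e, exactly
neutral; masses 12.011 and 18.998 amu). Interior backbone dihedrals sit at
the 163-degree trans minimum; the two outermost dihedrals are solved
numerically so the C1-C2-C5-C6 helicity dihedral is exactly +/-145 degrees
(35 degree overall twist) — mirroring relaxed chain ends of optimized
perfluoroalkyl geometries. The minus reference is the exact mirror image.

The Hessian is a pairwise distance-spring network (backbone bonds, 1-3 and
1-4 backbone springs, C-F bonds, F-F and F-to-neighbor-carbon anchors).
Because every spring is at its rest length in the reference geometry, each
contributes the exact rank-1 block `k u u^T` and the Hessian is analytic.
Spring constants are chosen so that the C-F-dominated stretches land in
the 1000-1300 cm^-1 band (e.g. `k_CF = 0.42` amu/fs^2 gives
`sqrt(k/mu_CF)` near 1200 cm^-1); no claim is made that absolute
frequencies match any real force field. Note one honest consequence of the
simplified triatomic spring fixtures used in tests: chains with purely
axial springs have genuine zero-frequency bending modes, which the Eckart
projection correctly retains (they are internal motions, not rigid-body
ones).

# Conformational dynamics

The helicity indicator is the sign of the overall-helicity dihedral, with
ties (exactly 0 or 180 degrees) inheriting the previous frame. Sign
excursions shorter than the debounce window (default 100 fs) are barrier
recrossings and are absorbed, not counted. The lifetime is extracted both
by integrating the normalized indicator autocorrelation up to its first
crossing below 0.01 (default) and by an exponential fit; for a telegraph
process both converge to `1/(2k)`.

Free-energy profiles are Boltzmann inversions of dihedral histograms
(default 2 degree bins; halving the bin width moves a 4-5 kBT barrier by
well under 0.05 kBT on the synthetic double well), min-shifted to zero,
with empty bins flagged as `NA` rather than interpolated. The
transition-state rate is `nu_attempt exp(-dF/kBT)`; in `"auto"` mode the
attempt frequency comes from the harmonic curvature at the global minimum
(profile in kBT, angle in radians, unit effective inertia — meaningful in
ratios, which is how it is used). Candidate wells are filtered by
topographic prominence (1 kBT) because counting-noise dips near a barrier
top otherwise masquerade as minima and truncate the barrier.

The double-well dihedral sampler places minima at +/-145 degrees with the
stated barrier through the planar-trans crossing at 180 degrees and an
effectively forbidden cis crossing — the topology of the overall-helicity
dihedral landscape. All-trans classification uses the closed window
`|phi| in [120, 180]` per backbone dihedral (the trans minima at 163/197
sit comfortably inside; gauche states near 60/300 are excluded); the
window edge itself counts as trans. Gauche-containing frames are masked by
splitting the trajectory into contiguous trans segments of at least 512
frames rather than zero-filling, which would distort line shapes.

# The experimental arm

**Kramers-Kronig separation.** An ATR absorbance trace mixes the
transmission-like component (proportional to Im eps) with its dispersive
Hilbert conjugate. Since the two are a quadrature pair, a single global
phase rotation of the analytic signal recovers the absorptive part
(`Im eps = m cos(phi) - H(m) sin(phi)`, default phase 90 degrees; a
frequency-independent phase is used, and `phase_offset = "fit"` can
re-estimate it by minimizing the negative lobes of the recovered
component). The Hilbert operator acts on the unpadded, band-periodic grid:
the rotation is then exactly unitary and only the DC component is lost,
which is irrecoverable in principle (a pure dispersive trace carries no
memory of the absorptive baseline). The recovered spectrum is re-anchored
so the band-free window edges sit at zero; the residual error is the band
tail amplitude at the window edges, so the synthetic generator defaults to
a 900-1500 cm^-1 window that keeps it below half a percent.

**Peak detection.** Continuous wavelet transform with a second-derivative
Lorentzian analyzing function, `psi_gamma(x) = (2 gamma / pi)
(gamma^2 - 3 x^2) / (x^2 + gamma^2)^3`, on a 7-point gamma ladder spanning
3-6 cm^-1. Ridges are seeded at the *coarsest* scale — where broad, weak
bands have the best coefficient-to-noise ratio — and tracked toward the
finest scale; a peak must persist over at least 3 scales and exceed a
5x-MAD per-scale noise threshold. Each center is the coefficient-weighted
mean of quadratically refined ridge positions (a 3-point parabola is
noise-dominated for bands much broader than the wavelet; the quadratic is
fitted over a +/- gamma window instead). The 4-band test fixture places
bands at 1045, 1069, 1218 and 1276 cm^-1 with FWHM 10-25 cm^-1 and equal
peak heights, so that a single signal-to-noise ratio is well defined for
every band.

**Band quantification.** Spectra are fitted by sums of Lorentzians with
centers clamped exactly at the detected maxima; intensities (areas) and
bandwidths are free, bounded below by zero and by the grid spacing. An
optional linear baseline can be floated. Band labels are assigned by
nearest nominal center within 10 cm^-1 (1236 asymmetric out-of-plane CF3
stretch, 1220 in-plane, 1135 symmetric CF2 stretch, 1353 symmetric CF3,
~1020 CH3 rock); normalization divides areas by the symmetric-CF2
reference band, with the peak-height ratio carried alongside as the
alternative indicator for congested spectra. Trend tables fit straight
lines per band against mole fraction or chain length when at least three
labeled spectra are available.

# What the synthetic data do and do not show

The generators reproduce the statistical structure the analysis assumes:
harmonic mode dynamics with exponential damping, Markovian helicity flips
that are instantaneous state swaps, dipoles that are exactly linear in the
coordinates, additive Gaussian noise on spectra, and a strictly
kinetics-only concentration dependence. Passing tests therefore validate
the estimators and the mechanism's spectral signature — they do not
validate force-field accuracy, anharmonicity, collective (cross-molecular)
vibrations, finite crossing times of the helicity barrier, frequency
shifts with environment, or ATR penetration-depth physics beyond the
global-phase model. The microscopic origin of the flip-rate speed-up
(dissipative intermolecular coupling) is imposed, not modelled.

# Problem sizes

The default analysis scales were chosen so every stochastic tolerance has
comfortable statistical margin: mechanism measurements average 8-32
molecules of 2^21 steps (dt = 2 fs) per flip rate across a decade of
rates; lifetime checks use 100 ns telegraph traces at 25 fs sampling
(tens of thousands of flips); free-energy recoveries use 10^6 Boltzmann
samples; spectral-engine oracles use 2^14-step direct discrete transforms
and 64-segment Welch averages of 2^17-sample noise.
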