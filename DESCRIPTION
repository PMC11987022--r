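Package: fluorspec
Title: Vibrational Line Shapes of Helical Perfluoroalkyl Chains from
    Trajectories and ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking infrared line broadening of C-F
    stretching bands in fluorous environments to helicity-reversal dynamics
    of perfluoroalkyl chains. Computes dipole power spectra and dielectric
    susceptibilities from molecular-dynamics-style trajectories
    (Wiener-Khinchin/Green-Kubo), performs normal-mode analysis of supplied
    Hessians with Eckart projection and point-charge transition dipoles,
    projects per-molecule motion onto dual-helicity normal modes with
    rigid-body alignment, decomposes molecular dipoles into rigid-body and
    per-mode vibrational contributions, quantifies helicity lifetimes and
    dihedral free-energy profiles, and processes ATR-FTIR absorbance spectra
    (Kramers-Kronig phase separation, wavelet peak detection, fixed-center
    Lorentzian deconvolution, band normalization and trend tables). Includes
    synthetic generators (helical spring-network references, Langevin mode
    dynamics with telegraph helicity flips, forward-modelled ATR spectra)
    so the whole chain is testable against analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
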