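test_that("Kramers-Kronig separation inverts the forward ATR model", {
  osc <- data.frame(center = 1135, strength = 1, width = 15)
  ## noiseless: sub-0.5% round trip
  g <- gen_atr_spectrum(osc, mixing_phase = 90, snr = Inf)
  rec <- kk_separate(g$spectrum, 90)
  expect_lt(max(abs(rec$values - g$im_eps$values)) / max(g$im_eps$values),
            0.005)
  ## SNR 20: center within 0.5 cm^-1, area within 2% (mean over noise
  ## draws: the single-draw area estimator scatters ~1.4% at this SNR)
  res <- vapply(1:3, function(s) {
    g20 <- gen_atr_spectrum(osc, mixing_phase = 90, snr = 20, seed = 3 + s)
    rec20 <- kk_separate(g20$spectrum, 90)
    tab <- fit_lorentzians(rec20, 1135, baseline = TRUE)
    smax <- rec20$nu[which.max(fluorspec:::cwt_coeffs(rec20$values, 0.5, 5))]
    c(tab$area[1], smax)
  }, numeric(2))
  expect_equal(mean(res[1, ]), 1, tolerance = 0.02)
  expect_lt(abs(mean(res[2, ]) - 1135), 0.5)
  ## pure absorptive input (phase 0) passes through within 0.5%
  g0 <- gen_atr_spectrum(osc, mixing_phase = 0, snr = Inf)
  rec0 <- kk_separate(g0$spectrum, 0)
  expect_lt(max(abs(rec0$values - g0$im_eps$values)) / max(g0$im_eps$values),
            0.005)
  ## sign-flipped dispersive admixture: recovered after re-fitting the phase
  gneg <- gen_atr_spectrum(osc, mixing_phase = -90, snr = Inf)
  recf <- kk_separate(gneg$spectrum, phase_offset = "fit")
  expect_lt(max(abs(recf$values - gneg$im_eps$values)) / max(gneg$im_eps$values),
            0.01)
  ## non-ATR input: warned passthrough
  tsp <- experimental_spectrum(g$spectrum$nu, g$spectrum$absorbance,
                               "transmission")
  expect_warning(out <- kk_separate(tsp), "not an ATR")
  expect_equal(out$values, tsp$absorbance)
})

test_that("wavelet detection finds the C-F band peaks to sub-wavenumber accuracy", {
  osc <- four_band_oscillators()
  nu <- seq(950, 1400, 0.5)
  im <- Reduce(`+`, lapply(seq_len(nrow(osc)), function(i) {
    lorentzian(nu, osc$center[i], osc$width[i], osc$strength[i])
  }))
  set.seed(6)
  y <- im + rnorm(length(nu), sd = max(im) / 50)
  pk <- detect_peaks(experimental_spectrum(nu, y, "transmission"), c(3, 6))
  expect_equal(nrow(pk), 4)
  expect_true(all(abs(pk$center - osc$center) < 1))
  ## pure noise: empty list
  set.seed(7)
  flat <- experimental_spectrum(nu, rnorm(length(nu), sd = 0.01),
                                "transmission")
  expect_equal(nrow(detect_peaks(flat, c(3, 6))), 0)
  ## two bands 8 cm^-1 apart, FWHM 20: at most two centers, flagged
  y2 <- lorentzian(nu, 1200, 20) + lorentzian(nu, 1208, 20)
  pk2 <- detect_peaks(experimental_spectrum(nu, y2, "transmission"), c(3, 6))
  expect_true(nrow(pk2) %in% c(1, 2))
  if (nrow(pk2) == 2) expect_true(all(pk2$unresolved))
})

test_that("detection is translation-equivariant", {
  osc <- four_band_oscillators()
  nu <- seq(950, 1400, 0.5)
  im <- Reduce(`+`, lapply(seq_len(nrow(osc)), function(i) {
    lorentzian(nu, osc$center[i], osc$width[i], osc$strength[i])
  }))
  p1 <- detect_peaks(experimental_spectrum(nu, im, "transmission"), c(3, 6))
  p2 <- detect_peaks(experimental_spectrum(nu + 7.25, im, "transmission"),
                     c(3, 6))
  expect_equal(p2$center, p1$center + 7.25, tolerance = 1e-6)
})

test_that("constrained Lorentzian fits recover areas and widths", {
  nu <- seq(950, 1400, 0.5)
  ## single band, modest noise: 1% recovery
  set.seed(3)
  y <- lorentzian(nu, 1236, 15, 1) + rnorm(length(nu), sd = 2e-4)
  t1 <- fit_lorentzians(experimental_spectrum(nu, y, "transmission"), 1236)
  expect_equal(t1$area[1], 1, tolerance = 0.01)
  expect_equal(t1$fwhm[1], 15, tolerance = 0.01)
  expect_false(t1$degenerate[1])
  ## two overlapping bands separated by one FWHM: areas within 3%
  y2 <- lorentzian(nu, 1200, 18, 1) + lorentzian(nu, 1218, 18, 0.7)
  t2 <- fit_lorentzians(experimental_spectrum(nu, y2, "transmission"),
                        c(1200, 1218))
  expect_equal(t2$area, c(1, 0.7), tolerance = 0.03)
  ## zero spectrum: degenerate flag
  t0 <- fit_lorentzians(experimental_spectrum(nu, 0 * nu, "transmission"),
                        1200)
  expect_true(t0$degenerate[1])
  expect_lt(t0$area[1], 1e-6)
})

test_that("fits are scale-equivariant", {
  nu <- seq(1000, 1300, 0.5)
  y <- lorentzian(nu, 1150, 12, 1) + lorentzian(nu, 1250, 20, 0.5)
  ta <- fit_lorentzians(experimental_spectrum(nu, y, "transmission"),
                        c(1150, 1250))
  tb <- fit_lorentzians(experimental_spectrum(nu, 5 * y, "transmission"),
                        c(1150, 1250))
  expect_equal(tb$area, 5 * ta$area, tolerance = 1e-6)
  expect_equal(tb$fwhm, ta$fwhm, tolerance = 1e-6)
})

test_that("band assignment and normalization follow the reference band", {
  tab <- data.frame(center = c(1134.2, 1221.5, 1237.1, 1352.0, 1500),
                    fwhm = rep(10, 5), fwhm_se = NA, area = c(2, 3, 4, 1, 9),
                    area_se = NA, height = c(2, 3, 4, 1, 9) * 2 / (pi * 10),
                    assignment = NA_character_, degenerate = FALSE)
  class(tab) <- c("peak_table", "data.frame")
  tab <- assign_bands(tab)
  expect_equal(tab$assignment,
               c("nu_s(CF2)", "nu_a_IP(CF3)", "nu_a_OP(CF3)", "nu_s(CF3)",
                 "other"))
  ntab <- normalize_bands(tab, "nu_s(CF2)")
  expect_equal(ntab$norm_area, c(1, 1.5, 2, 0.5, 4.5))
  expect_equal(ntab$norm_area[1], 1)
  expect_equal(attr(ntab, "normalization_reference"), "nu_s(CF2)")
  expect_error(normalize_bands(tab, "rho_IP(CH3)"), "normalization error")
})

test_that("trend analysis recovers linear bandwidth growth", {
  mk <- function(N) {
    tab <- data.frame(center = c(1135, 1236), fwhm = c(12, 10 + 0.8 * N),
                      fwhm_se = NA, area = c(2, 3), area_se = NA,
                      height = 1, assignment = c("nu_s(CF2)", "nu_a_OP(CF3)"),
                      degenerate = FALSE)
    class(tab) <- c("peak_table", "data.frame")
    normalize_bands(tab, "nu_s(CF2)")
  }
  Ns <- c(4, 6, 8, 10, 12)
  tr <- trend_analysis(lapply(Ns, mk), Ns, label_name = "N")
  f <- tr$fits[tr$fits$assignment == "nu_a_OP(CF3)", ]
  expect_equal(f$fwhm_slope, 0.8, tolerance = 0.02)
  expect_gt(f$fwhm_r2, 0.999)
  ## constant series: slope indistinguishable from zero
  fc <- tr$fits[tr$fits$assignment == "nu_s(CF2)", ]
  expect_equal(fc$fwhm_slope, 0, tolerance = 1e-8)
  ## two points: series returned, fit omitted with a notice
  expect_message(tr2 <- trend_analysis(lapply(Ns[1:2], mk), Ns[1:2]),
                 "fewer than 3")
  expect_null(tr2$fits)
  expect_equal(nrow(tr2$series), 4)
})

test_that("JCAMP-DX XYDATA spectra parse", {
  dir <- withr::local_tempdir()
  jc <- file.path(dir, "s.jdx")
  writeLines(c("##TITLE=synthetic", "##JCAMP-DX=4.24", "##XUNITS=1/CM",
               "##YUNITS=ABSORBANCE", "##XFACTOR=1", "##YFACTOR=0.001",
               "##FIRSTX=1000", "##LASTX=1004", "##NPOINTS=5",
               "##XYDATA=(X++(Y..Y))",
               "1000 100 200 300", "1003 400 500",
               "##END="), jc)
  sp <- read_jcamp(jc)
  expect_equal(sp$nu, 1000:1004)
  expect_equal(sp$absorbance, c(0.1, 0.2, 0.3, 0.4, 0.5))
})
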