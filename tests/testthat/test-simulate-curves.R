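spec0 <- acquisition_spec()

test_that("acquisition spec enforces the dual-bolus dose ratio", {
  expect_error(acquisition_spec(main_dose = 0.05), "dilution")
  expect_silent(acquisition_spec(prebolus_dose = 0.005, main_dose = 0.05))
  expect_error(acquisition_spec(n_frames = 10), "n_frames")
  expect_error(acquisition_spec(noise_sd = -1), "noise_sd")
})

test_that("simulated AIF is zero before onset and dose-linear", {
  aif <- generate_aif(spec0, 0.075, onset = 5)
  expect_true(all(aif$signal[aif$t <= 5] == 0))
  expect_true(all(aif$signal >= 0))
  # single peak: non-decreasing up to the maximum, non-increasing after
  i <- which.max(aif$signal)
  expect_true(all(diff(aif$signal[1:i]) >= 0))
  expect_true(all(diff(aif$signal[i:length(aif$signal)]) <= 0))
  # doubling the dose doubles the curve point-wise (no saturation here)
  aif2 <- generate_aif(spec0, 0.15, onset = 5)
  expect_equal(aif2$signal, 2 * aif$signal, tolerance = 1e-12)
  expect_error(generate_aif(spec0, 0), "positive")
})

test_that("AIF area scales with dose: quadrature oracle on a fine grid", {
  fine <- acquisition_spec(frame_interval = 0.02, n_frames = 3000)
  lo <- generate_aif(fine, 0.0075)
  hi <- generate_aif(fine, 0.075)
  # trapezoidal quadrature, independent of the generator internals
  trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  ratio <- trapz(hi$t, hi$signal) / trapz(lo$t, lo$signal)
  expect_equal(ratio, 10, tolerance = 0.01)
})

test_that("saturation is compressive, bounded and linear at low signal", {
  t <- 0:39
  low <- signal_curve(t, seq(0, 0.5, length.out = 40))
  expect_equal(apply_saturation(low, 100)$signal, low$signal,
               tolerance = 0.01)
  hot <- signal_curve(t, rep(10000, 40))
  expect_equal(apply_saturation(hot, 100)$signal, rep(100, 40),
               tolerance = 1e-9)
  mid <- signal_curve(t, rep(60, 40))
  out <- apply_saturation(mid, 100)$signal
  expect_true(all(out < 60) && all(out > 0))
  # never increases signal anywhere
  any_curve <- signal_curve(t, abs(rnorm(40, 50, 30)))
  expect_true(all(apply_saturation(any_curve, 80)$signal <=
                    any_curve$signal + 1e-12))
})

test_that("tissue curve is the Fermi convolution of its AIF", {
  aif <- generate_aif(spec0, spec0$main_dose)
  # zero impulse response gives an identically zero curve
  p0 <- fermi_params(0, 0.2, 3)
  expect_equal(fermi_tissue_model(aif, p0), rep(0, length(aif$t)))
  # linearity: doubling R doubles the curve point-wise
  tr1 <- tissue_truth(1.0, k = 0.2, tau0 = 3)
  tr2 <- tissue_truth(2.0, k = 0.2, tau0 = 3)
  c1 <- generate_tissue_curve(aif, tr1, spec0)
  c2 <- generate_tissue_curve(aif, tr2, spec0)
  expect_equal(c2$signal, 2 * c1$signal, tolerance = 1e-9)
  # grid mismatch is an error
  other <- acquisition_spec(frame_interval = 2, n_frames = 30)
  expect_error(generate_tissue_curve(generate_aif(other, 0.075), tr1, spec0),
               "grid")
})

test_that("tissue_truth ties the amplitude to the flow convention", {
  tr <- tissue_truth(2.5, k = 0.3, tau0 = 4)
  expect_equal(tr$r / (exp(-tr$tau0 * tr$k) + 1), 2.5)
  expect_error(tissue_truth(-1), "mbf")
})

test_that("dual-bolus study has the dose and saturation structure", {
  truths <- list(`1_endo` = tissue_truth(2, taud = 2),
                 `1_epi` = tissue_truth(0.8, taud = 2))
  st <- generate_dual_bolus_study(spec0, truths, seed = 4)
  tab <- st$curves
  expect_setequal(unique(tab$region), c("AIF_pre", "AIF_main", "1_endo", "1_epi"))
  pre_peak <- max(tab$signal[tab$region == "AIF_pre"])
  main_peak <- max(tab$signal[tab$region == "AIF_main"])
  true_peak <- max(st$true_aif$signal)
  # pre-bolus peak is a tenth of the true full-dose peak (no saturation)
  expect_equal(pre_peak, true_peak / 10, tolerance = 0.02)
  # the measured main bolus is compressed below the true peak
  expect_lt(main_peak, true_peak)
  expect_error(generate_dual_bolus_study(spec0, list()), "at least one")
  # determinism under a fixed seed
  st2 <- generate_dual_bolus_study(spec0, truths, seed = 4)
  expect_identical(st$curves, st2$curves)
})

test_that("noiseless dual-bolus study round-trips through quantification", {
  truths <- list(`7_endo` = tissue_truth(2.0, k = 0.25, tau0 = 3, taud = 2),
                 `7_epi` = tissue_truth(3.0, k = 0.2, tau0 = 4, taud = 2))
  st <- generate_dual_bolus_study(spec0, truths, seed = 1)
  est <- quantify_perfusion(st$curves)
  expect_equal(est$mbf[est$region == "7_endo"], 2.0, tolerance = 0.02)
  expect_equal(est$mbf[est$region == "7_epi"], 3.0, tolerance = 0.02)
})
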