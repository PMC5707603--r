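test_that("simulated spectra peak at the template centers, reproducibly", {
  tpl <- spectrum_template(data.frame(center = 1580, width = 20, amplitude = 50))
  sp <- simulate_spectrum(tpl)
  expect_equal(sp$shifts[which.max(sp$intensities)], 1580)
  noisy <- spectrum_template(data.frame(center = 1580, width = 20, amplitude = 50),
                             noise_sd = 2)
  expect_identical(simulate_spectrum(noisy, seed = 8), simulate_spectrum(noisy, seed = 8))
  expect_error(simulate_spectrum(spectrum_template(
    data.frame(center = numeric(0), width = numeric(0), amplitude = numeric(0)))),
    "degenerate")
})

test_that("CNT-like templates encode the D and G bands into letters n and p", {
  set.seed(61)
  tpl <- cnt_template("MWCNT", "COOH", noise_sd = 0)
  sp <- simulate_spectrum(tpl)
  syms <- encode_sequence(sp, threshold = 1)$symbols
  expect_true(all(c("n", "p") %in% syms))
  # functionalization raises the D band relative to pristine
  set.seed(62)
  prist <- cnt_template("MWCNT", "0", noise_sd = 0, jitter_sd = 0)
  func <- cnt_template("MWCNT", "COOH", noise_sd = 0, jitter_sd = 0)
  d_at <- function(t) t$peaks$amplitude[t$peaks$center == 1350]
  expect_gt(d_at(func), d_at(prist))
})

test_that("flux profiles reproduce basal, pulse and uncoupler structure", {
  times <- seq(0, 1800, by = 10)
  flat <- flux_profile_params(basal = 40,
                              adp_pulses = data.frame(time = numeric(0),
                                                      amplitude = numeric(0),
                                                      tau = numeric(0)),
                              uncoupler_gain = 0)
  prof <- simulate_flux_profile(flat, times)
  expect_equal(prof$flux, rep(40, length(times)))
  # oxygen concentration is the negative cumulative integral of the flux
  expect_equal(diff(prof$oxygen), -40 * diff(times))

  std <- flux_profile_params(basal = 40, uncoupler_gain = 0.6)
  prof <- simulate_flux_profile(std, times)
  inside <- times >= 750 & times <= 1250
  expect_gt(mean(prof$flux[inside]), mean(prof$flux[!inside]))
  expect_error(flux_profile_params(basal = -1), "positive")
  expect_error(simulate_flux_profile(std, c(3, 2, 1)), "increasing")
})

test_that("a zero-coefficient noiseless study is constant at the intercept", {
  st <- simulate_study(n_cnts = 2, n_times = 5,
                       coefficients = ptml_coefficients(a0 = 7),
                       noise_frac = 0, seed = 71)
  expect_equal(st$cases$flux, rep(7, nrow(st$cases)))
})

test_that("the study emits readable files and closes the full pipeline", {
  st <- simulate_study(n_cnts = 4, n_times = 25, seed = 72, include_controls = TRUE)
  expect_true(any(st$cases$cnt_id == "0"))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  sp <- read_spectrum(file.path(dir, "CNT1.csv"))
  expect_s3_class(sp, "raman_spectrum")
  cases <- suppressMessages(read_case_table(file.path(dir, "cases.csv")))
  expect_equal(nrow(cases), nrow(st$cases))
  expect_equal(sort(unique(cases$cnt_id)), sort(unique(st$cases$cnt_id)))
  # simulate -> transform -> featurize -> train, end to end
  invs <- lapply(st$spectra, transform_spectrum, threshold = 1)
  ft <- assemble_feature_table(cases, invariant_table(invs))
  norm <- suppressWarnings(normalize_features(ft))
  filt <- remove_correlated(norm$table)
  res <- fit_models(filt$table, make_splits(nrow(filt$table), 2, seed = 72),
                    methods = "LM", seed = 72)
  expect_equal(nrow(res), 2L)
  expect_true(all(is.finite(res$R2_ts)))
})

test_that("noise scales with the generative signal as requested", {
  st <- simulate_study(n_cnts = 3, n_times = 40, noise_frac = 0.1, seed = 73)
  expect_equal(st$truth$noise_sd, 0.1 * sd(st$truth$signal))
  resid <- st$cases$flux - st$truth$signal
  expect_equal(sd(resid), st$truth$noise_sd, tolerance = 0.15)
})
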