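# The two-pass maternal-cancellation / fetal-denoising pipeline.

test_that("maternal estimate is accurate on a pure maternal signal", {
  rec <- small_mixture(duration = 20, seed = 31, fetal_gain = 0,
                       noise_snr = Inf, baseline = c(0, 0),
                       powerline = c(0, 0), eta_sd = 0)
  m <- suppressWarnings(estimate_mecg(rec$aecg))
  r_amp <- max(rec$maternal_clean$amplitude)
  rmse <- sqrt(mean((m$mecg$amplitude - rec$aecg$amplitude)^2))
  expect_lt(rmse, 0.02 * r_amp)
  expect_error(estimate_mecg(rec$aecg[0, ]), "empty")
})

test_that("maternal cancellation strictly helps recover the fetal trace", {
  rec <- small_mixture(duration = 20, seed = 32, baseline = c(0, 0),
                       powerline = c(0, 0))
  ex <- quiet_extract(rec$aecg, "enkf", seed = 1)
  fetal <- rec$fetal_clean$amplitude
  rmse_res <- sqrt(mean((ex$residual$amplitude - fetal)^2))
  rmse_raw <- sqrt(mean((rec$aecg$amplitude - fetal)^2))
  expect_lt(rmse_res, rmse_raw)
})

test_that("residual and maternal estimate reconstruct the input exactly", {
  rec <- small_mixture(duration = 20, seed = 33)
  ex <- quiet_extract(rec$aecg, "enkf", seed = 2)
  expect_identical(ex$residual$amplitude,
                   ex$preprocessed$amplitude - ex$mecg_hat$amplitude)
  expect_equal(ex$residual$amplitude + ex$mecg_hat$amplitude,
               ex$preprocessed$amplitude, tolerance = 1e-12)
  # all waveforms the same length as the input
  for (f in c("preprocessed", "mecg_hat", "residual", "fecg_hat")) {
    expect_equal(nrow(ex[[f]]), nrow(rec$aecg))
  }
})

test_that("extraction is reproducible under a fixed seed", {
  rec <- small_mixture(duration = 20, seed = 34)
  a <- quiet_extract(rec$aecg, "enkf", seed = 5)
  b <- quiet_extract(rec$aecg, "enkf", seed = 5)
  expect_identical(a$mecg_hat$amplitude, b$mecg_hat$amplitude)
  expect_identical(a$fecg_hat$amplitude, b$fecg_hat$amplitude)
  expect_identical(a$fqrs$sample, b$fqrs$sample)
})

test_that("fetal denoising pass cleans the residual", {
  # clean fetal ECG alone: the pass must approximately return its input
  p <- ecg_model_params(delta = 1e-3, eta_var = 0, obs_noise = c(phi = 0, s = 0))
  fet <- mcsharry_waves()
  fet$alpha <- fet$alpha * 0.25
  fet$b <- fet$b * 0.5
  pf <- ecg_model_params(waves = fet, delta = 1e-3, eta_var = 0,
                         obs_noise = c(phi = 0, s = 0))
  clean <- generate_beat_train(pf, duration = 20, hr = 140, noise = FALSE)
  out <- suppressWarnings(denoise_fecg(clean, extraction_config()))
  r_amp <- max(abs(clean$amplitude))
  expect_false(out$diagnostics$skipped)
  expect_lt(sqrt(mean((out$fecg$amplitude - clean$amplitude)^2)), 0.05 * r_amp)

  # fetal + white noise at 0 dB: SNR must improve
  set.seed(35)
  noise <- rnorm(nrow(clean), 0, sqrt(mean(clean$amplitude^2)))
  noisy <- annotated_signal(clean$amplitude + noise, fs = 1000,
                            peaks = signal_peaks(clean))
  out2 <- suppressWarnings(denoise_fecg(noisy, extraction_config()))
  snr <- function(x) mean(clean$amplitude^2) / mean((x - clean$amplitude)^2)
  expect_gt(snr(out2$fecg$amplitude), snr(noisy$amplitude))
})

test_that("an all-zero residual takes the warning pass-through path", {
  zero <- annotated_signal(rep(0, 5000), fs = 1000)
  expect_warning(out <- denoise_fecg(zero), "skipped")
  expect_true(out$diagnostics$skipped)
  expect_identical(out$fecg$amplitude, zero$amplitude)
})

test_that("maternal-only input degrades gracefully, not catastrophically", {
  rec <- small_mixture(duration = 20, seed = 36, fetal_gain = 0)
  ex <- quiet_extract(rec$aecg, "enkf", seed = 3)
  expect_s3_class(ex, "fecg_extraction")
  # scoring a degenerate case must not throw
  sc <- score_extraction(ex, rec$fetal_peaks)
  expect_true(is.finite(sc$f1) || sc$degenerate)
  m0 <- compute_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0))
  expect_true(m0$degenerate)
})

test_that("errors carry the failing stage name", {
  short <- annotated_signal(rnorm(500), fs = 1000)
  expect_error(quiet_extract(short, "enkf"), "\\[")
})

test_that("tidy and glance views of an extraction are well-formed", {
  rec <- small_mixture(duration = 20, seed = 37)
  ex <- quiet_extract(rec$aecg, "enkf", seed = 4)
  td <- tidy(ex)
  expect_setequal(unique(as.character(td$component)),
                  c("aecg", "preprocessed", "mecg_hat", "residual", "fecg_hat"))
  expect_equal(nrow(td), 5 * nrow(rec$aecg))
  g <- glance(ex)
  expect_equal(g$n_samples, nrow(rec$aecg))
  expect_equal(g$method, "enkf")
  p <- autoplot(ex, reference = rec$fetal_peaks)
  expect_s3_class(p, "ggplot")
})
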