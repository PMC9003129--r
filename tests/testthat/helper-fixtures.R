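# Shared fixture builders. Everything is generated in code at test time.

# A short noise-free single-heart train (fs in Hz, hr in bpm).
clean_train <- function(duration = 10, fs = 500, hr = 60) {
  p <- ecg_model_params(delta = 1 / fs, eta_var = 0, obs_noise = c(phi = 0, s = 0))
  generate_beat_train(p, duration = duration, hr = hr, noise = FALSE)
}

# A small standard mixture for pipeline tests.
small_mixture <- function(duration = 20, seed = 3, ...) {
  make_mixture(mixture_spec(duration = duration, seed = seed, ...))
}

quiet_extract <- function(...) suppressWarnings(extract_fecg(...))

expect_signal <- function(x, n = NULL) {
  expect_s3_class(x, "annotated_signal")
  if (!is.null(n)) expect_equal(nrow(x), n)
}
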