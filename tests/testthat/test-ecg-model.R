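# Dynamic ECG model: transition, observation, beat generation, parameter fit.

test_that("phase advances modulo 2*pi and z is untouched when all waves vanish", {
  waves <- mcsharry_waves()
  waves$alpha <- rep(0, 5)
  p <- ecg_model_params(waves = waves, omega = pi, delta = 1)
  st <- ecg_transition(list(theta = 3 * pi / 2, z = 1.3), p, eta = 0)
  expect_equal(st$theta, pi / 2)
  expect_equal(st$z, 1.3)
})

test_that("single-wave transition matches a term-by-term scalar oracle", {
  waves <- mcsharry_waves()
  waves$alpha <- c(0, 0, 30, 0, 0)   # only the R wave active
  p <- ecg_model_params(waves = waves, omega = 2 * pi, delta = 0.001)
  th_prev <- wrap_2pi(-0.05)
  st <- ecg_transition(list(theta = th_prev, z = 0), p, eta = 0)
  # independent scalar evaluation of the update
  th_k <- (th_prev + 2 * pi * 0.001) %% (2 * pi)
  d <- th_k - 0                       # R center at 0
  d <- ((d + pi) %% (2 * pi)) - pi
  z_oracle <- 0 - 30 * (2 * pi * 0.001 / 0.1^2) * d * exp(-d^2 / (2 * 0.1^2))
  expect_equal(st$theta, th_k)
  expect_equal(st$z, z_oracle, tolerance = 1e-12)
})

test_that("transition is deterministic and rejects non-finite input", {
  p <- ecg_model_params()
  st <- list(theta = 1, z = 0.2)
  expect_identical(ecg_transition(st, p, 0.1), ecg_transition(st, p, 0.1))
  expect_error(ecg_transition(list(theta = NaN, z = 0), p), "non-finite")
  expect_error(ecg_transition(st, p, eta = Inf), "non-finite")
})

test_that("observation adds noise and wraps the phase", {
  st <- list(theta = 2 * pi - 0.1, z = 0.5)
  expect_equal(ecg_observe(st), list(phi = st$theta, s = st$z))
  expect_equal(ecg_observe(st, u = 0.2)$phi, 0.1)
  expect_equal(ecg_observe(st, v = -0.2)$s, 0.3)
})

test_that("phase stays in [0, 2*pi) over many random transitions", {
  set.seed(1)
  p <- ecg_model_params(omega = 2 * pi * 1.7, delta = 0.003)
  th <- runif(1e5, -10, 10) %% (2 * pi)
  z <- rnorm(1e5)
  # vectorized loop body: one transition per random state
  th_next <- wrap_2pi(th + p$omega * p$delta)
  expect_true(all(th_next >= 0 & th_next < 2 * pi))
  for (i in seq_len(200)) {
    st <- ecg_transition(list(theta = th[i], z = z[i]), p, eta = rnorm(1))
    expect_true(st$theta >= 0 && st$theta < 2 * pi)
  }
})

test_that("noise-free constant-RR train has the promised peaks and periodicity", {
  p <- ecg_model_params(eta_var = 0, obs_noise = c(phi = 0, s = 0))
  s <- generate_beat_train(p, duration = 5, hr = 60, noise = FALSE)
  pk <- signal_peaks(s)
  expect_length(pk, 5)
  expect_equal(diff(pk), rep(1000L, 4))
  # consecutive beats are sample-for-sample identical after the first
  b2 <- s$amplitude[1001:2000]
  b3 <- s$amplitude[2001:3000]
  expect_equal(b2, b3, tolerance = 1e-10)
})

test_that("beat generation is reproducible under a fixed seed", {
  p <- ecg_model_params(eta_var = 1e-3, obs_noise = c(phi = 0, s = 1e-3))
  a <- generate_beat_train(p, duration = 3, hr = 75, seed = 42)
  b <- generate_beat_train(p, duration = 3, hr = 75, seed = 42)
  expect_identical(a$amplitude, b$amplitude)
  expect_error(generate_beat_train(p, duration = 1e-9), "at least one sample")
  expect_error(generate_beat_train(p, duration = 3, rr_series = c(1, -1)),
               "rr_series")
})

test_that("discrete z trace converges to the closed-form Gaussian sum", {
  # the recursion integrates G' along the phase path, so as delta shrinks the
  # trace must approach G(theta) up to its integration constant
  dev_for <- function(delta) {
    p <- ecg_model_params(delta = delta, eta_var = 0, obs_noise = c(phi = 0, s = 0))
    s <- generate_beat_train(p, duration = 3, hr = 60, noise = FALSE)
    phi <- wrap_2pi(2 * pi * s$time)   # constant RR = 1 s, R at t = 0
    closed <- gaussian_sum(phi)        # independent closed-form oracle
    dev <- s$amplitude - closed
    max(abs(dev - dev[1]))
  }
  d_coarse <- dev_for(1e-3)
  d_fine <- dev_for(1e-4)
  expect_lt(d_fine, 0.1)        # < 0.4% of the R amplitude
  expect_lt(d_fine, d_coarse)   # refinement shrinks the defect
})

test_that("fit recovers generating wave parameters from a phase-averaged beat", {
  pg <- ecg_model_params(delta = 1e-3, eta_var = 0, obs_noise = c(phi = 0, s = 0))
  tr <- generate_beat_train(pg, duration = 20, hr = 60, noise = FALSE)
  phs <- assign_phase(signal_peaks(tr), nrow(tr))
  mb <- phase_average(tr$amplitude, phs$phi)

  # fixed point: init at the truth returns the truth
  fit0 <- fit_beat_params(mb, pg)
  expect_equal(fit0$params$waves$alpha, mcsharry_waves()$alpha, tolerance = 0.01)

  # recovery from a +/- 10% perturbed initialization, within 1%
  set.seed(5)
  init <- pg
  init$waves$alpha <- init$waves$alpha * runif(5, 0.9, 1.1)
  init$waves$b <- init$waves$b * runif(5, 0.9, 1.1)
  init$waves$theta <- init$waves$theta + runif(5, -0.05, 0.05)
  fit <- fit_beat_params(mb, init)
  tw <- mcsharry_waves()
  fw <- fit$params$waves
  expect_lt(max(abs(fw$alpha - tw$alpha) / abs(tw$alpha)), 0.01)
  expect_lt(max(abs(fw$b - tw$b) / tw$b), 0.01)
  expect_lt(max(abs(wrap_pi(fw$theta - tw$theta))), 0.01)
  expect_true(fit$converged)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$residual_var, fit$residual_var)
})

test_that("degenerate flat beats are rejected", {
  flat <- tibble::tibble(phase = seq(0, 2 * pi, length.out = 100),
                         amplitude = rep(0, 100))
  expect_error(fit_beat_params(flat), "flat beat")
})

test_that("ecg model parameter validation catches bad fields", {
  expect_error(ecg_model_params(omega = -1), "omega")
  expect_error(ecg_model_params(delta = 0), "delta")
  expect_error(ecg_model_params(eta_var = -1), "eta_var")
  w <- mcsharry_waves(); w$b[2] <- 0
  expect_error(ecg_model_params(waves = w), "b must be")
  expect_error(ecg_model_params(waves = w[1:4, ]), "exactly")
})
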