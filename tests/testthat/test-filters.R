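# Kalman, extended Kalman and ensemble Kalman filters.

test_that("kf_predict matches identity, scalar and dense-matrix oracles", {
  # identity dynamics leave the belief unchanged
  m <- linear_model(diag(2), diag(2), matrix(0, 2, 2), diag(2))
  b <- kalman_belief(c(1, 2), diag(2))
  p <- kf_predict(b, m)
  expect_equal(p$x_pred, c(1, 2))
  expect_equal(p$P_pred, diag(2))

  # scalar arithmetic: F = 2, P = 1, Qu = 0.5 -> P_pred = 4.5
  ms <- linear_model(matrix(2), matrix(1), 0.5, 1)
  ps <- kf_predict(kalman_belief(1, 1), ms)
  expect_equal(drop(ps$P_pred), 4.5)

  # random 3x3 case against an explicit matrix-product oracle
  set.seed(2)
  F3 <- matrix(rnorm(9), 3); H3 <- matrix(rnorm(9), 3)
  Q <- crossprod(matrix(rnorm(9), 3)); R <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  m3 <- linear_model(F3, H3, Q, R)
  P0 <- crossprod(matrix(rnorm(9), 3))
  x0 <- rnorm(3)
  p3 <- kf_predict(kalman_belief(x0, P0), m3)
  expect_equal(p3$x_pred, drop(F3 %*% x0))
  expect_equal(p3$P_pred, (F3 %*% P0 %*% t(F3) + Q + t(F3 %*% P0 %*% t(F3) + Q)) / 2)
})

test_that("kf_update limits: ignored and perfect measurements", {
  m_big <- linear_model(matrix(1), matrix(1), 0.01, 1e12)
  b <- kf_update(kf_predict(kalman_belief(2, 1), m_big), m_big, y = 100)
  expect_equal(b$x_hat, 2, tolerance = 1e-6)   # measurement ignored

  m_zero <- linear_model(diag(2), diag(2), diag(2) * 0.1, matrix(0, 2, 2))
  b2 <- kf_update(kf_predict(kalman_belief(c(0, 0), diag(2)), m_zero),
                  m_zero, y = c(3, -1))
  expect_equal(b2$x_hat, c(3, -1), tolerance = 1e-10)  # exact measurement
})

test_that("kf posterior means equal an independent scalar textbook recursion", {
  set.seed(11)
  y <- cumsum(rnorm(50, 0, 0.1)) + rnorm(50, 0, sqrt(0.1))
  m <- linear_model(matrix(1), matrix(1), 0.01, 0.1)
  got <- run_filter(y, m, "kf", init = list(x0 = y[1], P0 = 0.1))
  # independently coded recursion
  mean_hat <- numeric(50); mu <- y[1]; P <- 0.1
  for (k in 1:50) {
    Pp <- P + 0.01
    K <- Pp / (Pp + 0.1)
    mu <- mu + K * (y[k] - mu)
    P <- (1 - K) * Pp
    mean_hat[k] <- mu
  }
  expect_equal(got$x1, mean_hat, tolerance = 1e-12)
})

test_that("gain from exact cross-covariances equals the standard form", {
  set.seed(3)
  F2 <- matrix(c(1, 0.1, 0, 0.9), 2); H2 <- matrix(c(1, 0, 0, 1), 2)
  m <- linear_model(F2, H2, diag(2) * 0.05, diag(2) * 0.2)
  b <- kf_update(kf_predict(kalman_belief(c(0, 1), diag(2)), m), m, c(0.5, 0.5))
  Pxy <- b$P_pred %*% t(H2)
  Pyy <- H2 %*% b$P_pred %*% t(H2) + m$Qw
  expect_equal(b$K, Pxy %*% solve(Pyy), tolerance = 1e-12)
})

test_that("kf covariance stays symmetric PSD over many random steps", {
  set.seed(4)
  m <- linear_model(matrix(c(0.9, 0.2, -0.1, 0.8), 2), diag(2),
                    diag(2) * 0.01, diag(2) * 0.1)
  b <- kalman_belief(c(0, 0), diag(2))
  for (k in seq_len(1000)) {
    b <- kf_update(kf_predict(b, m), m, rnorm(2))
  }
  expect_equal(b$P, t(b$P))
  expect_gte(min(eigen(b$P, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("ekf reduces exactly to the kf on a linear model", {
  set.seed(5)
  m <- linear_model(matrix(c(1, 0.05, 0, 1), 2), matrix(c(1, 0), 1, 2),
                    diag(2) * 0.01, matrix(0.2))
  y <- rnorm(30)
  kf <- run_filter(y, m, "kf", init = list(x0 = c(0, 0), P0 = diag(2)))
  ekf <- run_filter(y, m, "ekf", init = list(x0 = c(0, 0), P0 = diag(2)))
  expect_equal(as.matrix(ekf[, -1]), as.matrix(kf[, -1]), tolerance = 1e-10)
})

test_that("ecg model jacobian matches central finite differences", {
  set.seed(6)
  p <- ecg_model_params()
  h <- 1e-6
  for (i in seq_len(100)) {
    st <- list(theta = runif(1, 0, 2 * pi), z = rnorm(1))
    J <- ecg_jacobian(st, p)
    fd_th <- (ecg_transition(list(theta = st$theta + h, z = st$z), p)$z -
                ecg_transition(list(theta = st$theta - h, z = st$z), p)$z) / (2 * h)
    fd_z <- (ecg_transition(list(theta = st$theta, z = st$z + h), p)$z -
               ecg_transition(list(theta = st$theta, z = st$z - h), p)$z) / (2 * h)
    expect_lt(abs(J["z", "theta"] - fd_th), 1e-6)
    expect_lt(abs(J["z", "z"] - fd_z), 1e-6)
    expect_equal(J["theta", "theta"], 1)
    expect_equal(J["theta", "z"], 0)
  }
})

test_that("enkf trivial limits: uninformative and perfect observations", {
  set.seed(7)
  # h constant -> zero cross-covariance -> analysis equals forecast
  m_const <- state_space_model(f = function(x) x, h = function(x) 5,
                               Qu = matrix(0), Qw = matrix(0.1),
                               Dx = 1, Dy = 1)
  ens <- enkf_ensemble(matrix(rnorm(40), 40, 1))
  out <- enkf_step(ens, m_const, y = 7)
  expect_equal(max(abs(out$K_hat)), 0, tolerance = 1e-12)
  expect_equal(sort(out$members[, 1]),
               sort(ens$members[, 1] + 0), tolerance = 1e-10)

  # identity observation with zero noise collapses every member onto y
  m_id <- state_space_model(f = function(x) x, h = function(x) x,
                            Qu = matrix(0), Qw = matrix(0),
                            Dx = 1, Dy = 1)
  ens2 <- enkf_ensemble(matrix(rnorm(40, sd = 2), 40, 1))
  out2 <- enkf_step(ens2, m_id, y = 3)
  expect_equal(out2$members[, 1], rep(3, 40), tolerance = 1e-6)
  expect_equal(out2$mean_x, colMeans(out2$members))
})

test_that("enkf input validation", {
  expect_error(enkf_ensemble(matrix(1, 1, 1)), "at least 2")
  m <- state_space_model(f = function(x) x, h = function(x) x,
                         Qu = matrix(0.1), Qw = matrix(0.1), Dx = 1, Dy = 1)
  expect_error(run_filter(numeric(0), m, "enkf"), "empty")
})

test_that("large-ensemble enkf agrees with the exact kf on a linear model", {
  # scalar linear-Gaussian system; exact KF means as oracle, Monte Carlo
  # tolerance 3 * posterior sd / sqrt(N)
  set.seed(12)
  n <- 100; N <- 1e4
  x <- 0; y <- numeric(n)
  for (k in 1:n) { x <- x + rnorm(1, 0, 0.1); y[k] <- x + rnorm(1, 0, sqrt(0.1)) }
  m <- linear_model(matrix(1), matrix(1), 0.01, 0.1)
  kf_mean <- numeric(n); mu <- y[1]; P <- 0.1
  for (k in 1:n) {
    Pp <- P + 0.01; K <- Pp / (Pp + 0.1)
    mu <- mu + K * (y[k] - mu); P <- (1 - K) * Pp
    kf_mean[k] <- mu
  }
  en <- run_filter(y, m, "enkf", n_ensemble = N, seed = 2,
                   init = list(x0 = y[1], P0 = 0.1))
  expect_lt(mean(abs(en$x1 - kf_mean)), 3 * sqrt(P) / sqrt(N))
})

test_that("run_filter is deterministic under a fixed seed", {
  set.seed(13)
  m <- linear_model(matrix(1), matrix(1), 0.01, 0.1)
  y <- rnorm(30)
  a <- run_filter(y, m, "enkf", n_ensemble = 30, seed = 99)
  b <- run_filter(y, m, "enkf", n_ensemble = 30, seed = 99)
  expect_identical(a, b)
})

test_that("estimate uncertainty shrinks as observations accumulate", {
  # constant state, noisy observations: the spread of repeated estimates
  # at a later step is below the spread at an early step
  set.seed(14)
  m <- linear_model(matrix(1), matrix(1), 0, 1)
  ests_early <- ests_late <- numeric(30)
  for (r in 1:30) {
    y <- 2 + rnorm(40)
    out <- run_filter(y, m, "kf", init = list(x0 = y[1], P0 = 1))
    ests_early[r] <- out$x1[2]
    ests_late[r] <- out$x1[40]
  }
  expect_lt(sd(ests_late), sd(ests_early))
})

test_that("enkf beats the ekf on a strongly nonlinear observation map", {
  # quadratic observation: the EKF's single-point linearization is a poor
  # description, the sampled ensemble handles it better on average
  set.seed(8)
  fq <- function(x) 0.9 * x
  hq <- function(x) x^2 + 0.5 * x
  mod <- state_space_model(fq, hq, Qu = 0.3, Qw = 0.05, Dx = 1, Dy = 1,
                           jac_f = function(x) matrix(0.9),
                           jac_h = function(x) matrix(2 * x + 0.5))
  rmse_en <- rmse_ek <- numeric(50)
  for (r in 1:50) {
    x <- 1; xs <- ys <- numeric(60)
    for (k in 1:60) {
      x <- fq(x) + rnorm(1, 0, sqrt(0.3))
      xs[k] <- x
      ys[k] <- hq(x) + rnorm(1, 0, sqrt(0.05))
    }
    en <- run_filter(ys, mod, "enkf", n_ensemble = 200, seed = 1000 + r,
                     init = list(x0 = 1, P0 = 0.5))
    ek <- tryCatch(run_filter(ys, mod, "ekf", init = list(x0 = 1, P0 = 0.5)),
                   error = function(e) NULL)
    rmse_en[r] <- sqrt(mean((en$x1 - xs)^2))
    rmse_ek[r] <- if (is.null(ek)) NA else sqrt(mean((ek$x1 - xs)^2))
  }
  expect_lte(mean(rmse_en), mean(rmse_ek, na.rm = TRUE))
})

test_that("compiled ecg ekf matches an independent R implementation", {
  # an independently coded R loop of the same phase-wrapped EKF
  set.seed(9)
  p <- ecg_model_params(delta = 1 / 250, eta_var = 1e-4,
                        obs_noise = c(phi = 0.01, s = 0.05))
  tr <- generate_beat_train(p, duration = 4, hr = 60, seed = 21)
  phi_obs <- wrap_2pi(2 * pi * tr$time)
  omega <- rep(2 * pi, nrow(tr))
  got <- enkfecg:::ecg_ekf_cpp(phi_obs, tr$amplitude, omega, p$delta,
                               p$waves$alpha, p$waves$b, p$waves$theta,
                               q_theta = 1e-6, q_z = 1e-4,
                               r_phi = 0.01, r_z = 0.05,
                               theta0 = phi_obs[1], z0 = tr$amplitude[1],
                               p0 = 1)
  th <- phi_obs[1]; z <- tr$amplitude[1]
  P <- matrix(c(1, 0, 0, 1), 2)
  Qu <- diag(c(1e-6, 1e-4)); R <- diag(c(0.01, 0.05))
  z_ref <- th_ref <- numeric(nrow(tr))
  for (k in seq_len(nrow(tr))) {
    dth <- omega[k] * p$delta
    th_pred <- wrap_2pi(th + dth)
    z_pred <- z + dth * gaussian_sum_d1(th_pred, p$waves)
    A <- matrix(c(1, 0, dth * gaussian_sum_d2(th_pred, p$waves), 1), 2,
                byrow = TRUE)
    Pp <- A %*% P %*% t(A) + Qu
    S <- Pp + R
    K <- Pp %*% solve(S)
    innov <- c(wrap_pi(phi_obs[k] - th_pred), tr$amplitude[k] - z_pred)
    upd <- c(th_pred, z_pred) + drop(K %*% innov)
    th <- wrap_2pi(upd[1]); z <- upd[2]
    P <- (diag(2) - K) %*% Pp
    P[1, 2] <- P[2, 1] <- (P[1, 2] + P[2, 1]) / 2
    th_ref[k] <- th; z_ref[k] <- z
  }
  expect_equal(got$z_hat, z_ref, tolerance = 1e-8)
  expect_equal(got$theta_hat, th_ref, tolerance = 1e-8)
})

test_that("compiled ecg enkf tracks a noise-free beat train", {
  p <- ecg_model_params(delta = 1 / 250, eta_var = 0, obs_noise = c(phi = 0, s = 0))
  tr <- generate_beat_train(p, duration = 6, hr = 60, noise = FALSE)
  phi_obs <- wrap_2pi(2 * pi * tr$time)
  omega <- rep(2 * pi, nrow(tr))
  set.seed(10)
  got <- enkfecg:::ecg_enkf_cpp(phi_obs, tr$amplitude, omega, p$delta,
                                p$waves$alpha, p$waves$b, p$waves$theta,
                                q_theta = 1e-6, q_z = 1e-3,
                                r_phi = 0.01, r_z = 0.05, n_ens = 70,
                                theta0 = phi_obs[1], z0 = tr$amplitude[1],
                                perturb_literal = FALSE)
  rmse <- sqrt(mean((got$z_hat - tr$amplitude)^2))
  expect_lt(rmse, sqrt(0.05))  # below the assumed measurement-noise floor
})
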