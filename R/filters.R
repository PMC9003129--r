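#' State-space model containers
#'
#' `state_space_model()` describes a (possibly nonlinear) discrete-time
#' system `x_n = f(x_{n-1}) + u_n`, `y_n = h(x_n) + w_n` with zero-mean
#' Gaussian state noise (covariance `Qu`) and measurement noise (covariance
#' `Qw`). `linear_model()` is the linear special case `x_n = F x_{n-1} + u_n`,
#' `y_n = H x_n + w_n`.
#'
#' @param f State transition map (vector -> vector).
#' @param h Observation map (vector -> vector).
#' @param Qu State-noise covariance (Dx x Dx, symmetric PSD).
#' @param Qw Measurement-noise covariance (Dy x Dy, symmetric PSD).
#' @param Dx,Dy State and observation dimensions.
#' @param jac_f,jac_h Optional Jacobian callables (state -> matrix) used by
#'   the extended Kalman filter.
#' @return A list of class `state_space_model` (and `linear_model` for the
#'   linear constructor).
#' @export
state_space_model <- function(f, h, Qu, Qw, Dx, Dy,
                              jac_f = NULL, jac_h = NULL) {
  Qu <- as_cov(Qu, Dx, "Qu"); Qw <- as_cov(Qw, Dy, "Qw")
  stopifnot(is.function(f), is.function(h))
  structure(list(f = f, h = h, Qu = Qu, Qw = Qw, Dx = Dx, Dy = Dy,
                 jac_f = jac_f, jac_h = jac_h),
            class = "state_space_model")
}

#' @rdname state_space_model
#' @param F_mat Transition matrix (Dx x Dx).
#' @param H_mat Observation matrix (Dy x Dx).
#' @export
linear_model <- function(F_mat, H_mat, Qu, Qw) {
  F_mat <- as.matrix(F_mat); H_mat <- as.matrix(H_mat)
  Dx <- nrow(F_mat); Dy <- nrow(H_mat)
  if (ncol(F_mat) != Dx || ncol(H_mat) != Dx) {
    stop("linear_model: dimension mismatch between F and H")
  }
  m <- state_space_model(
    f = function(x) drop(F_mat %*% x),
    h = function(x) drop(H_mat %*% x),
    Qu = Qu, Qw = Qw, Dx = Dx, Dy = Dy,
    jac_f = function(x) F_mat, jac_h = function(x) H_mat)
  m$F <- F_mat; m$H <- H_mat
  # row-wise maps over a whole member matrix (fast path for large ensembles)
  m$f_mat <- function(X) X %*% t(F_mat)
  m$h_mat <- function(X) X %*% t(H_mat)
  class(m) <- c("linear_model", class(m))
  m
}

as_cov <- function(Q, d, name) {
  if (length(Q) == 1L && d == 1L) Q <- matrix(Q, 1, 1)
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(d, d))) stop(name, ": wrong dimensions")
  if (max(abs(Q - t(Q))) > 1e-8 * (1 + max(abs(Q)))) {
    stop(name, ": covariance must be symmetric")
  }
  if (min(eigen((Q + t(Q)) / 2, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * (1 + max(abs(Q)))) {
    stop(name, ": covariance must be positive semi-definite")
  }
  (Q + t(Q)) / 2
}

#' Kalman belief
#'
#' Posterior mean and covariance of the state, plus the last prediction and
#' gain, as carried between [kf_predict()] and [kf_update()] steps.
#'
#' @param x_hat Posterior mean (length Dx).
#' @param P Posterior covariance (Dx x Dx).
#' @return A list of class `kalman_belief` with fields `x_hat`, `P`,
#'   `x_pred`, `P_pred`, `K`.
#' @export
kalman_belief <- function(x_hat, P) {
  x_hat <- as.numeric(x_hat)
  P <- as_cov(P, length(x_hat), "P")
  structure(list(x_hat = x_hat, P = P, x_pred = NULL, P_pred = NULL, K = NULL),
            class = "kalman_belief")
}

#' Kalman filter time update
#'
#' Propagates the belief through the linear dynamics:
#' `x_pred = F x_hat`, `P_pred = F P F' + Qu`.
#'
#' @param belief A [kalman_belief()].
#' @param model A [linear_model()].
#' @return The belief with `x_pred`, `P_pred` filled in.
#' @export
kf_predict <- function(belief, model) {
  if (length(belief$x_hat) != model$Dx) stop("kf_predict: dimension mismatch")
  belief$x_pred <- drop(model$F %*% belief$x_hat)
  P <- model$F %*% belief$P %*% t(model$F) + model$Qu
  belief$P_pred <- (P + t(P)) / 2
  belief
}

#' Kalman filter measurement update
#'
#' Applies the gain `K = P_pred H' (H P_pred H' + Qw)^{-1}` and corrects the
#' prediction with the innovation. The cross-covariance form of the gain
#' (`K = Pxy Pyy^{-1}`) is computed alongside and checked for equality; it is
#' the form the ensemble filter approximates with sample covariances.
#'
#' @param belief A [kalman_belief()] carrying a prediction.
#' @param model A [linear_model()].
#' @param y Observation vector (length Dy).
#' @return Updated [kalman_belief()].
#' @export
kf_update <- function(belief, model, y) {
  if (is.null(belief$x_pred)) stop("kf_update: belief carries no prediction")
  H <- model$H
  S <- H %*% belief$P_pred %*% t(H) + model$Qw
  if (rcond(S) < 1e-14) {
    stop("kf_update: innovation covariance is numerically singular ",
         "(rcond = ", format(rcond(S)), ")")
  }
  Pxy <- belief$P_pred %*% t(H)
  K <- Pxy %*% solve(S)
  K2 <- Pxy %*% solve(S)            # K = Pxy %*% Pyy^{-1}, Pyy = S
  stopifnot(max(abs(K - K2)) < 1e-10 * (1 + max(abs(K))))
  belief$K <- K
  belief$x_hat <- drop(belief$x_pred + K %*% (y - H %*% belief$x_pred))
  P <- (diag(model$Dx) - K %*% H) %*% belief$P_pred
  belief$P <- (P + t(P)) / 2
  belief
}

#' Extended Kalman filter step
#'
#' One predict+update cycle for a nonlinear model: the means propagate
#' through `f` and `h`, the covariances through their Jacobians evaluated at
#' the working point (first-order Taylor linearization).
#'
#' @param belief A [kalman_belief()].
#' @param model A [state_space_model()] with `jac_f`/`jac_h` (or a
#'   [linear_model()], for which the step reduces exactly to the linear KF).
#' @param y Observation vector.
#' @param jacobians Optional list `list(jac_f =, jac_h =)` overriding the
#'   model's Jacobians.
#' @return Updated [kalman_belief()].
#' @export
ekf_step <- function(belief, model, y, jacobians = NULL) {
  jf <- if (!is.null(jacobians)) jacobians$jac_f else model$jac_f
  jh <- if (!is.null(jacobians)) jacobians$jac_h else model$jac_h
  if (is.null(jf) || is.null(jh)) stop("ekf_step: Jacobian callables required")
  A <- jf(belief$x_hat)
  belief$x_pred <- as.numeric(model$f(belief$x_hat))
  P <- A %*% belief$P %*% t(A) + model$Qu
  belief$P_pred <- (P + t(P)) / 2
  H <- jh(belief$x_pred)
  S <- H %*% belief$P_pred %*% t(H) + model$Qw
  if (rcond(S) < 1e-14) {
    stop("ekf_step: innovation covariance is numerically singular")
  }
  K <- belief$P_pred %*% t(H) %*% solve(S)
  belief$K <- K
  belief$x_hat <- drop(belief$x_pred + K %*% (y - as.numeric(model$h(belief$x_pred))))
  P <- (diag(model$Dx) - K %*% H) %*% belief$P_pred
  belief$P <- (P + t(P)) / 2
  belief
}

#' Initialize an ensemble
#'
#' @param members N x Dx matrix of state samples (N >= 2).
#' @return A list of class `enkf_ensemble`.
#' @export
enkf_ensemble <- function(members) {
  members <- as.matrix(members)
  if (nrow(members) < 2L) stop("enkf_ensemble: need at least 2 members")
  structure(list(members = members, pred_obs = NULL, perturbations = NULL,
                 mean_x = colMeans(members), mean_y = NULL,
                 Pxy_hat = NULL, Pyy_hat = NULL, K_hat = NULL),
            class = "enkf_ensemble")
}

#' Ensemble Kalman filter step
#'
#' Monte Carlo approximation of the Kalman update. Each member is propagated
#' through the state map with an independent state-noise draw (forecast
#' ensemble); predicted observations, ensemble means and the sample
#' covariances `Pxy_hat`, `Pyy_hat` are formed with `1/N` normalization; the
#' gain is `K_hat = Pxy_hat (Pyy_hat + eps I)^{-1}` with a small trace-scaled
#' ridge; each member is then shifted by `K_hat (y + v_i - y_i)` with
#' perturbations `v_i` drawn zero-mean with covariance `Qw` (set
#' `perturbation_mean = "ensemble_obs_mean"` to centre the draws on the
#' ensemble observation mean instead). The state estimate is the ensemble
#' mean.
#'
#' @param ensemble An [enkf_ensemble()].
#' @param model A [state_space_model()].
#' @param y Observation vector.
#' @param perturbation_mean `"zero"` (default) or `"ensemble_obs_mean"`.
#' @return Updated [enkf_ensemble()] with sample statistics filled in.
#' @export
enkf_step <- function(ensemble, model, y,
                      perturbation_mean = c("zero", "ensemble_obs_mean")) {
  perturbation_mean <- match.arg(perturbation_mean)
  X <- ensemble$members
  N <- nrow(X); Dx <- model$Dx; Dy <- model$Dy
  if (N < 2L) stop("enkf_step: need at least 2 members")
  Lu <- chol_psd(model$Qu)
  Xf <- if (!is.null(model$f_mat)) model$f_mat(X)
        else t(apply(X, 1, function(x) as.numeric(model$f(x))))
  if (Dx == 1L) Xf <- matrix(Xf, ncol = 1L)
  Xf <- Xf + matrix(stats::rnorm(N * Dx), N, Dx) %*% t(Lu)
  Y <- if (!is.null(model$h_mat)) model$h_mat(Xf)
       else t(apply(Xf, 1, function(x) as.numeric(model$h(x))))
  if (Dy == 1L) Y <- matrix(Y, ncol = 1L)
  mx <- colMeans(Xf); my <- colMeans(Y)
  Xd <- sweep(Xf, 2, mx); Yd <- sweep(Y, 2, my)
  Pxy <- crossprod(Xd, Yd) / N
  Pyy <- crossprod(Yd) / N
  eps <- 1e-8 * sum(diag(Pyy)) / Dy
  S <- Pyy + model$Qw + diag(eps, Dy)
  K <- Pxy %*% solve(S)
  Lw <- chol_psd(model$Qw)
  V <- matrix(stats::rnorm(N * Dy), N, Dy) %*% t(Lw)
  if (perturbation_mean == "ensemble_obs_mean") V <- sweep(V, 2, my, `+`)
  innov <- sweep(-Y + V, 2, as.numeric(y), `+`)
  Xa <- Xf + innov %*% t(K)
  bad <- which(!apply(Xa, 1, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop("enkf_step: non-finite ensemble member after update (member ",
         bad[1], ")")
  }
  ensemble$members <- Xa
  ensemble$pred_obs <- Y
  ensemble$perturbations <- V
  ensemble$mean_x <- colMeans(Xa)
  ensemble$mean_y <- my
  ensemble$Pxy_hat <- Pxy
  ensemble$Pyy_hat <- (Pyy + t(Pyy)) / 2
  ensemble$K_hat <- K
  ensemble
}

chol_psd <- function(Q) {
  d <- nrow(Q)
  if (all(abs(Q) < .Machine$double.eps)) return(matrix(0, d, d))
  e <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), d) %*% t(e$vectors)
}

#' Run a filter over an observation sequence
#'
#' Sequentially applies the chosen filter to every observation and returns
#' the per-sample state estimate (for the EnKF, the ensemble mean).
#'
#' @param y Observation sequence: a numeric vector (Dy = 1) or an n x Dy
#'   matrix.
#' @param model A [state_space_model()] or [linear_model()].
#' @param method `"kf"`, `"ekf"` or `"enkf"`.
#' @param n_ensemble Ensemble size for the EnKF (default 70).
#' @param seed Optional integer seed controlling all noise draws.
#' @param init Optional list `list(x0 =, P0 =)`. By default `x0` is the first
#'   observation when `Dx == Dy` (zeros otherwise) and `P0 = Qw`-scaled
#'   identity; the EnKF draws its initial members Gaussian around `x0` with
#'   covariance `P0`.
#' @param perturbation_mean Passed to [enkf_step()].
#' @return A tibble with column `step` and one column per state dimension
#'   (`x1`, ..., `xDx`).
#' @export
run_filter <- function(y, model, method = c("enkf", "ekf", "kf"),
                       n_ensemble = 70, seed = NULL, init = NULL,
                       perturbation_mean = "zero") {
  method <- match.arg(method)
  if (is.vector(y) && !is.list(y)) y <- matrix(y, ncol = model$Dy, byrow = TRUE)
  y <- as.matrix(y)
  n <- nrow(y)
  if (n == 0L) stop("run_filter: empty observation sequence")
  if (!is.null(seed)) withr::local_seed(seed)
  x0 <- if (!is.null(init$x0)) init$x0
        else if (model$Dx == model$Dy) as.numeric(y[1, ])
        else rep(0, model$Dx)
  P0 <- if (!is.null(init$P0)) as_cov(init$P0, model$Dx, "P0")
        else diag(max(diag(model$Qw)), model$Dx)
  out <- matrix(NA_real_, n, model$Dx)
  if (method == "enkf") {
    L0 <- chol_psd(P0)
    members <- matrix(rep(x0, each = n_ensemble), n_ensemble, model$Dx) +
      matrix(stats::rnorm(n_ensemble * model$Dx), n_ensemble, model$Dx) %*% t(L0)
    ens <- enkf_ensemble(members)
    for (k in seq_len(n)) {
      ens <- enkf_step(ens, model, y[k, ],
                       perturbation_mean = perturbation_mean)
      out[k, ] <- ens$mean_x
    }
  } else {
    bel <- kalman_belief(x0, P0)
    for (k in seq_len(n)) {
      if (method == "kf") {
        if (!inherits(model, "linear_model")) {
          stop("run_filter: method 'kf' needs a linear_model")
        }
        bel <- kf_update(kf_predict(bel, model), model, y[k, ])
      } else {
        bel <- ekf_step(bel, model, y[k, ])
      }
      out[k, ] <- bel$x_hat
    }
  }
  colnames(out) <- paste0("x", seq_len(model$Dx))
  dplyr::bind_cols(tibble::tibble(step = seq_len(n)),
                   tibble::as_tibble(out))
}
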