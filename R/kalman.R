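#' Process and measurement noise covariances
#'
#' Constant covariances of the zero-mean white process noise (state
#' equation) and measurement noise (pressure channel). The defaults are
#' the package's pinned calibration for the shipped Windkessel model at
#' 500 Hz: \code{Qproc = diag(1.58, 0.01)} and \code{Rmeas = 25} (i.e. a
#' 5 mmHg measurement noise standard deviation). These values are a
#' calibration choice of this package, fixed so the steady-state
#' pressure-state Kalman gain of the default model is about 0.22; they
#' are not published physiologic constants.
#'
#' @param Qproc 2x2 symmetric positive-semidefinite process-noise
#'   covariance, or a length-2 vector taken as its diagonal.
#' @param Rmeas scalar measurement-noise covariance, mmHg^2. Must be > 0.
#' @return An object of class \code{"kf_noise"}.
#' @export
noise_covariances <- function(Qproc = c(1.58, 0.01), Rmeas = 25) {
  if (is.vector(Qproc) && length(Qproc) == 2L) Qproc <- diag(Qproc)
  Qproc <- as.matrix(Qproc)
  if (!identical(dim(Qproc), c(2L, 2L)) || !all(is.finite(Qproc)))
    stop("Qproc must be a finite 2x2 matrix or a length-2 diagonal")
  if (max(abs(Qproc - t(Qproc))) > 1e-12 * (1 + max(abs(Qproc))))
    stop("Qproc must be symmetric")
  if (min(eigen(Qproc, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("Qproc must be positive semidefinite")
  if (!is.finite(Rmeas) || Rmeas <= 0)
    stop("Rmeas must be a positive scalar")
  structure(list(Qproc = Qproc, Rmeas = Rmeas), class = "kf_noise")
}

#' @export
print.kf_noise <- function(x, ...) {
  cat("Kalman noise covariances\n")
  cat("  Qproc diag:", format(diag(x$Qproc), digits = 7),
      " off-diag:", format(x$Qproc[1, 2], digits = 7), "\n")
  cat("  Rmeas     :", format(x$Rmeas, digits = 7), "mmHg^2\n")
  invisible(x)
}

#' Kalman prediction step
#'
#' Propagates the a posteriori state and covariance through the process
#' model with the known flow input:
#' \code{x_prior = A x_post + B u}, \code{P_prior = A P_post A' + Qproc}.
#'
#' @param model a \code{\link{wk_discretize}} state-space model.
#' @param x_post a posteriori state estimate, length-2.
#' @param P_post a posteriori 2x2 error covariance.
#' @param u known flow input sample, ml/s.
#' @param noise a \code{\link{noise_covariances}} object.
#' @return List with \code{x_prior} and \code{P_prior}.
#' @export
kf_predict <- function(model, x_post, P_post, u, noise) {
  stopifnot(inherits(model, "wk_dss"), inherits(noise, "kf_noise"))
  if (!all(is.finite(x_post)) || !all(is.finite(P_post)) || !is.finite(u))
    stop("non-finite input to kf_predict")
  x_prior <- drop(model$A %*% x_post + model$B * u)
  P_prior <- model$A %*% P_post %*% t(model$A) + noise$Qproc
  list(x_prior = x_prior, P_prior = (P_prior + t(P_prior)) / 2)
}

#' Kalman measurement update
#'
#' Blends the a priori estimate with the pressure measurement. The
#' innovation subtracts both the state-predicted output and the direct
#' feedthrough of the instantaneous flow:
#' \code{innovation = z - H x_prior - D u}. The gain
#' \code{K = P_prior H' / (H P_prior H' + Rmeas)} minimizes the a
#' posteriori error covariance; the covariance update uses the simple
#' form \code{(I - K H) P_prior} with post-hoc symmetrization, or the
#' Joseph form when \code{joseph = TRUE}.
#'
#' @inheritParams kf_predict
#' @param x_prior a priori state estimate, length-2.
#' @param P_prior a priori 2x2 error covariance (PSD).
#' @param z measured pressure sample, mmHg.
#' @param joseph use the Joseph-form covariance update.
#' @return List with \code{x_post}, \code{P_post}, \code{K} (length-2
#'   gain), \code{innovation} and \code{denoised} (the a posteriori
#'   output \code{H x_post + D u}).
#' @export
kf_update <- function(model, x_prior, P_prior, z, u, noise, joseph = FALSE) {
  stopifnot(inherits(model, "wk_dss"), inherits(noise, "kf_noise"))
  H <- model$H
  S <- drop(H %*% P_prior %*% t(H)) + noise$Rmeas
  if (!is.finite(S) || S <= 0)
    stop("innovation variance is not positive; invalid covariances")
  K <- drop(P_prior %*% t(H)) / S
  innovation <- z - drop(H %*% x_prior) - model$D * u
  x_post <- x_prior + K * innovation
  IKH <- diag(2) - K %*% H
  P_post <- if (joseph)
    IKH %*% P_prior %*% t(IKH) + (K %*% t(K)) * noise$Rmeas
  else
    IKH %*% P_prior
  P_post <- (P_post + t(P_post)) / 2
  list(x_post = x_post, P_post = P_post, K = K,
       innovation = innovation,
       denoised = drop(H %*% x_post) + model$D * u)
}

#' Run the Kalman filter over a flow/pressure record
#'
#' Alternates prediction and measurement update over aligned flow
#' (known input) and noisy pressure (measurement) waveforms, returning
#' the full per-sample trace and the denoised pressure waveform.
#'
#' By default the filter starts from \code{vC} equal to the first
#' measured pressure sample (reducing the initial transient), \code{iL}
#' = 0, and a weakly informative diagonal initial covariance.
#'
#' @param model a \code{\link{wk_discretize}} state-space model.
#' @param noise a \code{\link{noise_covariances}} object.
#' @param flow flow \code{\link{waveform}} (known input).
#' @param measured noisy pressure \code{\link{waveform}}; same length and
#'   sampling rate as \code{flow}, with \code{fs = 1/Ts}.
#' @param init_state initial state \code{c(vC, iL)}; default
#'   \code{c(z[1], 0)}.
#' @param init_cov initial 2x2 covariance; default \code{diag(1e3, 1e3)}.
#' @param joseph use the Joseph-form covariance update throughout.
#' @return An object of class \code{"kf_trace"}: list with matrices
#'   \code{x_prior}, \code{x_post} (n x 2), \code{K} (n x 2), vectors
#'   \code{innovation}, arrays \code{P_prior}, \code{P_post}
#'   (2 x 2 x n), and \code{denoised} (a pressure \code{waveform}).
#' @export
run_kalman <- function(model, noise, flow, measured,
                       init_state = NULL, init_cov = diag(1e3, 2),
                       joseph = FALSE) {
  stopifnot(inherits(model, "wk_dss"), inherits(noise, "kf_noise"),
            inherits(flow, "waveform"), inherits(measured, "waveform"))
  if (flow$quantity != "flow" || measured$quantity != "pressure")
    stop("expected a flow input and a pressure measurement")
  n <- length(flow$values)
  if (length(measured$values) != n)
    stop("flow and measured pressure must have equal length")
  if (abs(flow$fs - measured$fs) > 1e-9 * flow$fs)
    stop("flow and measured pressure must share a sampling rate")
  if (abs(flow$fs * model$Ts - 1) > 1e-9)
    stop("sampling rate does not match the model's Ts")
  if (!model$stable)
    warning("running the filter with an Euler-forward unstable model")
  u <- flow$values
  z <- measured$values
  if (is.null(init_state)) init_state <- c(z[1L], 0)

  x_prior <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("vC", "iL")))
  x_post  <- x_prior
  Kmat    <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("vC", "iL")))
  innov   <- numeric(n)
  P_prior <- array(NA_real_, c(2L, 2L, n))
  P_post  <- array(NA_real_, c(2L, 2L, n))
  den     <- numeric(n)

  x <- as.numeric(init_state)
  P <- as.matrix(init_cov)
  for (k in seq_len(n)) {
    if (k > 1L) {
      pr <- kf_predict(model, x, P, u[k - 1L], noise)
      x <- pr$x_prior; P <- pr$P_prior
    }
    x_prior[k, ] <- x
    P_prior[, , k] <- P
    up <- kf_update(model, x, P, z[k], u[k], noise, joseph = joseph)
    x <- up$x_post; P <- up$P_post
    x_post[k, ] <- x
    P_post[, , k] <- P
    Kmat[k, ] <- up$K
    innov[k] <- up$innovation
    den[k] <- up$denoised
  }
  structure(list(x_prior = x_prior, x_post = x_post, K = Kmat,
                 innovation = innov, P_prior = P_prior, P_post = P_post,
                 denoised = waveform(den, fs = measured$fs,
                                     t0 = measured$t0,
                                     quantity = "pressure")),
            class = "kf_trace")
}

#' @export
print.kf_trace <- function(x, ...) {
  n <- nrow(x$x_post)
  cat(sprintf("Kalman filter trace: %d samples\n", n))
  cat(sprintf("  final gain K = (%.5f, %.5f)\n",
              x$K[n, 1L], x$K[n, 2L]))
  cat(sprintf("  innovation sd = %.4g mmHg\n", stats::sd(x$innovation)))
  invisible(x)
}

#' Steady-state Kalman gain via Riccati iteration
#'
#' Iterates the covariance recursion of the filter (predict covariance,
#' gain, update covariance) from \code{P = 0} until convergence of the a
#' priori covariance, yielding the steady-state (Riccati fixed point)
#' gain. The time-varying gain of \code{\link{run_kalman}} converges to
#' this value geometrically for a stable model with constant noise.
#'
#' @param model a \code{\link{wk_discretize}} state-space model (stable).
#' @param noise a \code{\link{noise_covariances}} object.
#' @param tol convergence tolerance on the max absolute change of the a
#'   priori covariance per iteration.
#' @param max_iter iteration cap.
#' @return List with \code{K} (length-2 steady-state gain), \code{P_prior}
#'   (converged a priori covariance) and \code{iterations}.
#' @export
steady_state_gain <- function(model, noise, tol = 1e-12, max_iter = 100000L) {
  stopifnot(inherits(model, "wk_dss"), inherits(noise, "kf_noise"))
  if (!model$stable) stop("steady-state gain requires a stable model")
  A <- model$A; H <- model$H
  P <- diag(0, 2)
  for (i in seq_len(max_iter)) {
    M <- A %*% P %*% t(A) + noise$Qproc
    S <- drop(H %*% M %*% t(H)) + noise$Rmeas
    K <- drop(M %*% t(H)) / S
    Pn <- (diag(2) - K %*% H) %*% M
    Pn <- (Pn + t(Pn)) / 2
    Mn <- A %*% Pn %*% t(A) + noise$Qproc
    if (max(abs(Mn - M)) < tol) {
      return(list(K = drop(Mn %*% t(H)) / (drop(H %*% Mn %*% t(H)) + noise$Rmeas),
                  P_prior = Mn, iterations = i))
    }
    P <- Pn
  }
  stop(sprintf("Riccati iteration did not converge in %d iterations",
               max_iter))
}
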