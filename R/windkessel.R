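#' Four-element Windkessel parameters
#'
#' Constructs the static parameter set of the four-element electrical
#' Windkessel analog of aortic circulation: a characteristic aortic
#' impedance \code{r} in series with the parallel combination of arterial
#' compliance \code{C}, peripheral resistance \code{R} and blood inertance
#' \code{L}. Defaults are the systemic-circulation values estimated from
#' pig flow/pressure recordings that ship with the package.
#'
#' @param R peripheral resistance, mmHg/(ml/s). Must be > 0.
#' @param C arterial compliance, ml/mmHg. Must be > 0.
#' @param r characteristic aortic impedance, mmHg/(ml/s). Must be >= 0;
#'   \code{r = 0} degenerates the output to the compliance pressure alone.
#' @param L blood inertance, mmHg/(ml/s^2). Must be > 0.
#' @return An object of class \code{"wk_params"}.
#' @examples
#' windkessel_params()
#' windkessel_params(R = 1.2, C = 1.0, r = 0.05, L = 0.005)
#' @export
windkessel_params <- function(R = 1.72, C = 0.48, r = 0.105, L = 0.0059) {
  vals <- c(R = R, C = C, r = r, L = L)
  if (!all(is.finite(vals)))
    stop("Windkessel parameters must be finite numbers")
  if (R <= 0 || C <= 0 || L <= 0)
    stop("R, C and L must be strictly positive")
  if (r < 0)
    stop("aortic impedance r must be >= 0")
  structure(list(R = R, C = C, r = r, L = L), class = "wk_params")
}

#' @export
print.wk_params <- function(x, ...) {
  cat("Four-element Windkessel parameters\n")
  cat(sprintf("  R (peripheral resistance)  %8.4g mmHg/(ml/s)\n", x$R))
  cat(sprintf("  C (arterial compliance)    %8.4g ml/mmHg\n", x$C))
  cat(sprintf("  r (aortic impedance)       %8.4g mmHg/(ml/s)\n", x$r))
  cat(sprintf("  L (blood inertance)        %8.4g mmHg/(ml/s^2)\n", x$L))
  invisible(x)
}

#' Continuous-time Windkessel state derivatives
#'
#' Right-hand side of the two coupled ODEs of the four-element model.
#' The state is \code{(vC, iL)}: the pressure stored on the compliance
#' (mmHg) and the flow through the inertance (ml/s).
#'
#' @param params a \code{\link{windkessel_params}} object.
#' @param state numeric length-2 vector \code{c(vC, iL)}.
#' @param flow instantaneous aortic flow, ml/s.
#' @return Numeric length-2 vector \code{c(dvC_dt, diL_dt)} in
#'   (mmHg/s, (ml/s)/s).
#' @export
wk_derivatives <- function(params, state, flow) {
  stopifnot(inherits(params, "wk_params"))
  if (length(state) != 2L || !all(is.finite(state)) || !is.finite(flow))
    stop("state must be two finite numbers and flow a finite number")
  vC <- state[[1L]]; iL <- state[[2L]]
  c(dvC_dt = flow / params$C - vC / (params$R * params$C),
    diL_dt = (params$r / params$L) * (flow - iL))
}

#' Instantaneous Windkessel output pressure
#'
#' Output equation of the circuit: the aortic pressure is the drop across
#' the series impedance plus the compliance pressure,
#' \code{v = r (i - iL) + vC}.
#'
#' @inheritParams wk_derivatives
#' @return Aortic pressure sample, mmHg.
#' @export
wk_pressure <- function(params, state, flow) {
  stopifnot(inherits(params, "wk_params"))
  params$r * (flow - state[[2L]]) + state[[1L]]
}

#' Euler-forward discretization of the Windkessel model
#'
#' Discretizes the continuous model at sampling period \code{Ts} by the
#' Euler-forward rule, yielding the linear state-space form
#' \deqn{x(k+1) = A x(k) + B u(k), \qquad v(k) = H x(k) + D u(k)}
#' with state \code{x = (vC, iL)}, input \code{u} the aortic flow and
#' output \code{v} the aortic pressure. For this circuit \code{A} is
#' diagonal: the two states couple only through the shared flow input.
#'
#' The Euler-forward step is stable iff both diagonal entries of \code{A}
#' lie in (-1, 1), i.e. \code{Ts < 2 R C} and \code{Ts < 2 L / r}; a
#' warning is issued otherwise and the \code{stable} flag records it.
#'
#' @param params a \code{\link{windkessel_params}} object.
#' @param Ts sampling period, s. Must be > 0.
#' @return An object of class \code{"wk_dss"} with elements \code{A}
#'   (2x2), \code{B} (2x1), \code{H} (1x2), \code{D} (scalar feedthrough,
#'   equal to \code{r}), \code{Ts}, \code{stable} and \code{params}.
#' @examples
#' wk_discretize(windkessel_params(), Ts = 1 / 500)
#' @export
wk_discretize <- function(params, Ts) {
  stopifnot(inherits(params, "wk_params"))
  if (!is.finite(Ts) || Ts <= 0) stop("Ts must be a positive number")
  a1 <- 1 - Ts / (params$R * params$C)
  a2 <- 1 - Ts * params$r / params$L
  A <- diag(c(a1, a2))
  B <- matrix(c(Ts / params$C, Ts * params$r / params$L), 2L, 1L)
  H <- matrix(c(1, -params$r), 1L, 2L)
  # r = 0 freezes the (unforced) iL state at a2 = 1; bounded, so admitted
  stable <- abs(a1) < 1 && (params$r == 0 || abs(a2) < 1)
  if (!stable)
    warning(sprintf(
      "Euler-forward step unstable at Ts = %g (requires Ts < %g and Ts < %g)",
      Ts, 2 * params$R * params$C,
      if (params$r > 0) 2 * params$L / params$r else Inf))
  structure(list(A = A, B = B, H = H, D = params$r, Ts = Ts,
                 stable = stable, params = params),
            class = "wk_dss")
}

#' @export
print.wk_dss <- function(x, ...) {
  cat(sprintf("Discrete Windkessel state-space model (Ts = %g s, %s)\n",
              x$Ts, if (x$stable) "stable" else "UNSTABLE"))
  cat("  A diag:", format(diag(x$A), digits = 7), "\n")
  cat("  B     :", format(drop(x$B), digits = 7), "\n")
  cat("  H     :", format(drop(x$H), digits = 7), "  D:",
      format(x$D, digits = 7), "\n")
  invisible(x)
}

#' Uniformly sampled waveform series
#'
#' Container for a uniformly sampled physical signal; sample \code{k}
#' (0-based) is at time \code{t0 + k / fs}.
#'
#' @param values numeric sample vector (mmHg for pressure, ml/s for flow).
#' @param fs sampling rate, Hz. Must be > 0.
#' @param t0 start time, s.
#' @param quantity one of \code{"flow"}, \code{"pressure"}.
#' @return An object of class \code{"waveform"}.
#' @export
waveform <- function(values, fs, t0 = 0, quantity = c("pressure", "flow")) {
  quantity <- match.arg(quantity)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("waveform must contain at least one sample")
  if (anyNA(values) || !all(is.finite(values)))
    stop("waveform samples must be finite (no NaN/NA/Inf)")
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive number")
  structure(list(values = values, fs = fs, t0 = t0, quantity = quantity),
            class = "waveform")
}

#' Sample times of a waveform
#' @param w a \code{\link{waveform}}.
#' @return Numeric vector of sample times, s.
#' @export
waveform_times <- function(w) {
  stopifnot(inherits(w, "waveform"))
  w$t0 + (seq_along(w$values) - 1L) / w$fs
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform <%s>: %d samples @ %g Hz, t0 = %g s (%.3f s)\n",
              x$quantity, length(x$values), x$fs, x$t0,
              length(x$values) / x$fs))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$values)

#' Open-loop simulation of the discrete Windkessel model
#'
#' Iterates the discrete difference equations forward from an initial
#' state, driven by a measured or synthetic aortic-flow waveform, and
#' returns the synthesized pressure waveform together with the state
#' trajectory. This is the noise-free process model that the Kalman
#' filter assumes.
#'
#' @param model a \code{\link{wk_discretize}} state-space model.
#' @param flow a flow \code{\link{waveform}} with \code{fs == 1/Ts}.
#' @param init initial state \code{c(vC, iL)}; default \code{c(0, 0)}.
#' @param allow_unstable simulate even if the model's stability flag is
#'   off (default FALSE).
#' @return A list with \code{pressure} (a pressure \code{waveform} on the
#'   same time base as \code{flow}) and \code{states} (an n x 2 matrix
#'   with columns \code{vC}, \code{iL}).
#' @export
wk_simulate <- function(model, flow, init = c(0, 0), allow_unstable = FALSE) {
  stopifnot(inherits(model, "wk_dss"), inherits(flow, "waveform"))
  if (flow$quantity != "flow") stop("input waveform must be labelled 'flow'")
  if (abs(flow$fs * model$Ts - 1) > 1e-9)
    stop(sprintf("flow sampling rate %g Hz does not match model Ts = %g s",
                 flow$fs, model$Ts))
  if (!model$stable && !allow_unstable)
    stop("model is Euler-forward unstable; pass allow_unstable = TRUE to force")
  u <- flow$values
  n <- length(u)
  a <- diag(model$A)          # A is diagonal for this circuit
  b <- drop(model$B)
  r <- model$D
  states <- matrix(0, n, 2L, dimnames = list(NULL, c("vC", "iL")))
  p <- numeric(n)
  x <- as.numeric(init)
  for (k in seq_len(n)) {
    states[k, ] <- x
    p[k] <- r * (u[k] - x[2L]) + x[1L]
    x <- a * x + b * u[k]
  }
  list(pressure = waveform(p, fs = flow$fs, t0 = flow$t0,
                           quantity = "pressure"),
       states = states)
}
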