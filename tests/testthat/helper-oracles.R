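# Independent oracles and shared fixtures for the test suite.

table1_params <- function() windkessel_params(R = 1.72, C = 0.48,
                                              r = 0.105, L = 0.0059)

default_model <- function(Ts = 0.002) wk_discretize(table1_params(), Ts)

# RK4 integration of the continuous Windkessel ODEs; test oracle only.
# flow_fun: function of time t returning flow in ml/s.
rk4_simulate <- function(params, flow_fun, t_end, h, init = c(0, 0)) {
  f <- function(t, x) wk_derivatives(params, x, flow_fun(t))
  n <- round(t_end / h)
  out <- matrix(NA_real_, n + 1L, 2L)
  x <- init
  out[1L, ] <- x
  for (k in seq_len(n)) {
    t <- (k - 1L) * h
    k1 <- f(t, x)
    k2 <- f(t + h / 2, x + h / 2 * k1)
    k3 <- f(t + h / 2, x + h / 2 * k2)
    k4 <- f(t + h, x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[k + 1L, ] <- x
  }
  out
}

# scalar steady-state Riccati fixed point for x(k+1)=a x + w, z = h x + v:
# closed form for a = h = 1 (random walk)
scalar_riccati_gain <- function(q, r) {
  # M = a^2 M r/(M+r) + q with a=h=1  =>  M^2 - qM - qr = 0
  M <- (q + sqrt(q^2 + 4 * q * r)) / 2
  list(M = M, K = M / (M + r))
}

# a hand-made 2-state diagonal model whose first state reduces to the
# scalar system (a, h) and whose second state is inert
scalar_model <- function(a = 1, h = 1, D = 0) {
  structure(list(A = diag(c(a, 0)), B = matrix(c(0, 0), 2, 1),
                 H = matrix(c(h, 0), 1, 2), D = D, Ts = 1,
                 stable = TRUE,
                 params = NULL),
            class = "wk_dss")
}

expect_waveforms_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_equal(a$fs, b$fs)
  expect_equal(a$t0, b$t0)
  expect_identical(a$quantity, b$quantity)
}
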