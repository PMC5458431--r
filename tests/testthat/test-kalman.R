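test_that("noise covariance constructor validates shape and definiteness", {
  nz <- noise_covariances()
  expect_equal(diag(nz$Qproc), c(1.58, 0.01))
  expect_equal(nz$Rmeas, 25)
  expect_error(noise_covariances(Qproc = matrix(1:4, 2)), "symmetric")
  expect_error(noise_covariances(Qproc = diag(c(-1, 1))), "semidefinite")
  expect_error(noise_covariances(Rmeas = 0), "positive")
})

test_that("prediction propagates state and covariance through the model", {
  m <- default_model()
  nz <- noise_covariances(Qproc = diag(c(0, 0)), Rmeas = 1)
  # noiseless propagation of zero covariance stays zero
  pr <- kf_predict(m, c(1, 2), diag(0, 2), 5, nz)
  expect_equal(pr$P_prior, diag(0, 2))
  # identity dynamics leave the state alone
  mi <- scalar_model(a = 1, h = 1)
  mi$A <- diag(2)
  pr2 <- kf_predict(mi, c(3, -4), diag(2), 99, nz)
  expect_equal(pr2$x_prior, c(3, -4))
  # one predict equals one open-loop simulation step
  flow <- waveform(c(100, 100), fs = 500, quantity = "flow")
  sim <- wk_simulate(m, flow, init = c(172, 100))
  pr3 <- kf_predict(m, c(172, 100), diag(0, 2), 100, nz)
  expect_equal(unname(pr3$x_prior), unname(sim$states[2, ]),
               tolerance = 1e-14)
  expect_error(kf_predict(m, c(NA, 0), diag(2), 1, nz), "non-finite")
})

test_that("measurement update blends prior and measurement correctly", {
  m <- default_model()
  nz <- noise_covariances(Rmeas = 25)
  # zero prior covariance: model trusted, no correction
  up <- kf_update(m, c(120, 50), diag(0, 2), 300, 50, nz)
  expect_equal(up$K, c(0, 0))
  expect_equal(up$x_post, c(120, 50))
  # huge measurement noise: gain vanishes
  up2 <- kf_update(m, c(120, 50), diag(10, 2), 300, 50,
                   noise_covariances(Rmeas = 1e12))
  expect_lt(max(abs(up2$K)), 1e-9)
  # tiny measurement noise with H = (1, 0): first gain component -> 1
  ms <- scalar_model(a = 0.9, h = 1)
  up3 <- kf_update(ms, c(0, 0), diag(c(10, 0)), 7, 0,
                   noise_covariances(Qproc = diag(c(1, 0)), Rmeas = 1e-12))
  expect_equal(up3$K[1], 1, tolerance = 1e-9)
  expect_equal(up3$x_post[1], 7, tolerance = 1e-6)
})

test_that("scalar update reproduces the hand-computed Kalman step", {
  # 1-state reduction a=h=1, q=1, r=1: prior variance 1 -> posterior 0.5
  ms <- scalar_model(a = 1, h = 1)
  nz <- noise_covariances(Qproc = diag(c(1, 0)), Rmeas = 1)
  up <- kf_update(ms, c(0, 0), diag(c(1, 0)), 1, 0, nz)
  expect_equal(up$P_post[1, 1], 0.5)
  expect_equal(up$K[1], 0.5)
})

test_that("innovation includes the flow feedthrough", {
  m <- default_model()
  nz <- noise_covariances()
  x <- c(110, 40); u <- 90; z <- 123
  up <- kf_update(m, x, diag(5, 2), z, u, nz)
  expect_equal(up$innovation, z - (x[1] - 0.105 * x[2]) - 0.105 * u)
})

test_that("Joseph form agrees with the simple update at the optimal gain", {
  m <- default_model()
  nz <- noise_covariances()
  P <- matrix(c(4, 1, 1, 3), 2)
  a <- kf_update(m, c(100, 50), P, 120, 60, nz, joseph = FALSE)
  b <- kf_update(m, c(100, 50), P, 120, 60, nz, joseph = TRUE)
  expect_equal(a$P_post, b$P_post, tolerance = 1e-8)
  expect_equal(a$x_post, b$x_post)
})

test_that("zero-noise filter is self-consistent with the simulator", {
  m <- default_model()
  flow <- generate_flow(flow_spec(duration = 2))
  x0 <- c(120, 70)
  sim <- wk_simulate(m, flow, init = x0)
  nz <- noise_covariances(Qproc = diag(c(0, 0)), Rmeas = 1)
  # exact init and a perfect model: nothing to correct
  tr <- run_kalman(m, nz, flow, sim$pressure,
                   init_state = x0, init_cov = diag(0, 2))
  expect_lt(max(abs(tr$innovation)), 1e-9 * max(abs(sim$pressure$values)))
  expect_equal(tr$denoised$values, sim$pressure$values,
               tolerance = 1e-9)
})

test_that("enormous measurement noise reduces the filter to the model", {
  m <- default_model()
  ds <- make_dataset(flow_spec(duration = 2))
  sim_init <- c(table1_params()$R * mean(ds$flow$values),
                mean(ds$flow$values))
  sim <- wk_simulate(m, ds$flow, init = sim_init)
  nz <- noise_covariances(Qproc = diag(c(1e-12, 1e-12)), Rmeas = 1e12)
  tr <- run_kalman(m, nz, ds$flow, ds$noisy,
                   init_state = sim_init, init_cov = diag(0, 2))
  expect_equal(tr$denoised$values, sim$pressure$values, tolerance = 1e-4)
})

test_that("filtering Gaussian-corrupted pressure reduces the error", {
  cfg_model <- default_model()
  nz <- noise_covariances()
  ds <- make_dataset(flow_spec(duration = 4),
                     aspec = artifact_spec(gaussian_sigma = 5, seed = 11))
  tr <- run_kalman(cfg_model, nz, ds$flow, ds$noisy)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(tr$denoised$values, ds$clean$values),
            rmse(ds$noisy$values, ds$clean$values))
})

test_that("run_kalman validates alignment", {
  m <- default_model()
  nz <- noise_covariances()
  f <- waveform(rep(1, 10), fs = 500, quantity = "flow")
  p_short <- waveform(rep(1, 9), fs = 500, quantity = "pressure")
  p_fs <- waveform(rep(1, 10), fs = 250, quantity = "pressure")
  expect_error(run_kalman(m, nz, f, p_short), "equal length")
  expect_error(run_kalman(m, nz, f, p_fs), "sampling rate")
})

test_that("scalar Riccati fixed point matches the closed form", {
  # random-walk reduction a = h = 1, q = r = 1: M = (1+sqrt(5))/2,
  # gain M/(M+1) ~ 0.618
  ms <- scalar_model(a = 1, h = 1)
  nz <- noise_covariances(Qproc = diag(c(1, 0)), Rmeas = 1)
  ss <- steady_state_gain(ms, nz, tol = 1e-13)
  closed <- scalar_riccati_gain(1, 1)
  expect_equal(closed$M, (1 + sqrt(5)) / 2)
  expect_equal(ss$P_prior[1, 1], closed$M, tolerance = 1e-10)
  expect_equal(ss$K[1], closed$K, tolerance = 1e-10)
  expect_equal(ss$K[1], 0.618034, tolerance = 1e-6)
})

test_that("perfect process model drives the steady-state gain to zero", {
  ms <- scalar_model(a = 0.9, h = 1)
  nz <- noise_covariances(Qproc = diag(c(0, 0)), Rmeas = 1)
  ss <- steady_state_gain(ms, nz)
  expect_equal(ss$K[1], 0, tolerance = 1e-8)
})

test_that("steady-state gain matches the late time-varying gain", {
  m <- default_model()
  nz <- noise_covariances()
  ss <- steady_state_gain(m, nz, tol = 1e-12)
  ds <- make_dataset(flow_spec(duration = 2))
  tr <- run_kalman(m, nz, ds$flow, ds$noisy)
  n <- nrow(tr$K)
  expect_equal(unname(tr$K[n, ]), unname(ss$K), tolerance = 1e-8)
  # geometric convergence: gain error shrinks monotonically (log-scale)
  dev <- abs(tr$K[, 1] - ss$K[1])
  expect_lt(dev[200], dev[50])
  expect_lt(dev[500], dev[200])
  expect_lt(dev[n], 1e-10)
})

test_that("gain is bounded and monotone in measurement trust", {
  m <- default_model()
  gains <- vapply(c(1, 5, 25, 100, 400), function(Rm) {
    steady_state_gain(m, noise_covariances(Rmeas = Rm))$K[1]
  }, numeric(1))
  expect_true(all(gains >= 0 & gains <= 1))
  expect_true(all(diff(gains) < 0))  # noisier measurements, smaller gain
})

test_that("estimation error does not accumulate over a 2 s run", {
  m <- default_model()
  nz <- noise_covariances()
  ds <- make_dataset(flow_spec(duration = 2),
                     aspec = artifact_spec(gaussian_sigma = 5, seed = 3))
  tr <- run_kalman(m, nz, ds$flow, ds$noisy)
  err <- estimation_error(ds$noisy, tr$denoised, edge_window = 0.25)
  expect_lte(err$summary$late_early_ratio, 2)
})
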