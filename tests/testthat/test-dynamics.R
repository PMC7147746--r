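test_that("Nernst potential matches the closed form and is increasing", {
  expect_identical(nernst_potential(130), 0)
  expect_equal(nernst_potential(3), 26.6 * log(3 / 130))
  expect_equal(nernst_potential(3), -100.2533, tolerance = 1e-6)
  # finite-difference sensitivity at 7 mM is about 3.8 mV/mM
  h <- 1e-4
  slope <- (nernst_potential(7 + h) - nernst_potential(7 - h)) / (2 * h)
  expect_equal(slope, 26.6 / 7, tolerance = 1e-6)
  expect_equal(round(slope, 1), 3.8)
  K <- seq(0.5, 20, by = 0.1)
  expect_true(all(diff(nernst_potential(K)) > 0))
  expect_error(nernst_potential(0), "positive")
  expect_error(nernst_potential(-3), "positive")
})

test_that("pump flux has the stated midpoint, limits, bounds and monotonicity", {
  expect_equal(pump_current(3.5, 25, 0.2), 0.05)
  expect_equal(pump_current(1e3, 1e3, 0.2), 0.2)
  expect_equal(pump_current(3, 10, 0.2), 0.2 / ((1 + exp(0.5)) * (1 + exp(5))))
  expect_equal(pump_current(3, 10, 0.2), 5.05e-4, tolerance = 2e-3)
  K <- seq(-5, 30, by = 0.5); Na <- seq(-5, 60, by = 0.5)
  grid <- expand.grid(K = K, Na = Na)
  v <- pump_current(grid$K, grid$Na, 0.2)
  expect_true(all(v > 0 & v < 0.2))
  # monotone in each argument on the scan
  m <- matrix(v, nrow = length(K))
  expect_true(all(apply(m, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(m, 1, function(row) all(diff(row) > 0))))
})

test_that("firing rate is rectified, saturating and equals the tanh identity", {
  p <- model_parameters()
  expect_identical(firing_rate(p$V_th, p), 0)
  expect_identical(firing_rate(-1e3, p), 0)
  V <- seq(-100, p$V_th, by = 1)
  expect_true(all(firing_rate(V, p) == 0))
  expect_equal(firing_rate(1e4, p), p$nu_max)
  # V = V_th + k_v: bracket reduces to tanh(1)
  expect_equal(firing_rate(45, p), 100 * tanh(1), tolerance = 1e-12)
  expect_equal(firing_rate(45, p), 76.16, tolerance = 1e-4)
  V <- seq(-50, 150, by = 0.25)
  expect_true(all(diff(firing_rate(V, p)) >= 0))
  expect_true(all(firing_rate(V, p) <= p$nu_max))
})

test_that("input current assembles the three terms of the drive", {
  p <- model_parameters()
  # all contributions vanish at baseline
  expect_equal(input_current(p$V_K0, 0, 1, 0, p), 0)
  # potassium depolarisation alone: 26.6 * (ln(7/130) - ln(3/130))
  u <- input_current(nernst_potential(7), 0, 1, 0, p)
  expect_equal(u, 26.6 * log(7 / 3))
  expect_equal(u, 22.6, tolerance = 0.01)
  # synaptic drive alone: G * phi * (x_D - c_IE)
  u <- input_current(p$V_K0, 10, 1, 0, p, Gsyn_over_gL = 5)
  expect_equal(u, 5 * 10 * 0.5)
  # noise enters with amplitude sigma/g_L
  u <- input_current(p$V_K0, 0, 1, 2, p)
  expect_equal(u, 2 * p$sigma_over_gL)
})

test_that("local right-hand sides compose relaxation, pump and firing terms", {
  p <- model_parameters()
  # exact rest for the relaxation terms (pump excluded via rho = 0)
  p0 <- model_parameters(rho = 0)
  st <- list(K_o = p0$K_bath, Na_i = p0$Na_i0, V = 0, x_D = 1)
  d <- local_rhs(st, theta = 0, u = 0, p0)
  expect_equal(d$dK_o, 0)
  expect_equal(d$dNa_i, 0)
  expect_equal(d$dx_D, 0)
  # composed value: (7-3)/100 - 2*20*Ipump(3,10)
  st <- list(K_o = 3, Na_i = 10, V = 0, x_D = 1)
  d <- local_rhs(st, theta = 0, u = 0, p)
  expect_equal(d$dK_o, (7 - 3) / 100 - 40 * pump_current(3, 10, 0.2))
  expect_equal(d$dK_o, 0.0198, tolerance = 1e-3)
  # firing contribution is delta_K * theta
  d0 <- local_rhs(st, theta = 0, u = 0, p)
  d1 <- local_rhs(st, theta = 100, u = 0, p)
  expect_equal(d1$dK_o - d0$dK_o, 0.04 * 100)
  expect_error(local_rhs(st, theta = -1, u = 0, p), "non-negative")
})

test_that("deterministic ion fixed point agrees with long-run integration", {
  # with sigma = 0 and G_syn = 0 the (K_o, Na_i) subsystem relaxes to the
  # balance point of relaxation vs pump; compare a root-finder on the
  # 2-equation system against long integration of the engine
  p <- model_parameters(sigma_over_gL = 0, model_variant = 1)
  f <- function(z) {
    Ip <- pump_current(z[1], z[2], p$rho)
    c((p$K_bath - z[1]) / p$tau_K - 2 * p$gamma * Ip,
      (p$Na_i0 - z[2]) / p$tau_Na - 3 * Ip)
  }
  # damped Newton via numerical Jacobian
  z <- c(p$K_o0, p$Na_i0)
  for (it in 1:200) {
    J <- matrix(0, 2, 2); h <- 1e-7
    for (k in 1:2) {
      e <- c(0, 0); e[k] <- h
      J[, k] <- (f(z + e) - f(z - e)) / (2 * h)
    }
    step <- solve(J, -f(z))
    z <- z + step
    if (max(abs(step)) < 1e-13) break
  }
  expect_lt(max(abs(f(z))), 1e-12)

  dom <- build_domain(width = 0.375, height = 0.375, nx = 5, radius = 0,
                      Gsyn_center = 0, Gsyn_periphery = 0)
  st <- initial_state(dom, p)
  # firing stays off (V threshold never reached with zero drive terms)
  out <- step_state(st, dom, p, dt = 0.001, n_steps = 8e5)
  expect_lt(abs(out$K_o[3, 3] - z[1]), 1e-6)
  expect_lt(abs(out$Na_i[3, 3] - z[2]), 1e-6)
})

test_that("membrane potential follows the discrete exponential relaxation", {
  # sigma = 0, couplings off, fixed u = 0: V_n = V_0 (1 - dt/tau_m)^n
  p <- model_parameters(sigma_over_gL = 0, gK_leak_over_gL = 0,
                        Gsyn_over_gL = 0, model_variant = 1, D_K = 0)
  dom <- build_domain(width = 0.375, height = 0.375, nx = 5, radius = 0,
                      Gsyn_center = 0, Gsyn_periphery = 0)
  st <- initial_state(dom, p)
  st$V[] <- 12
  n <- 100
  out <- step_state(st, dom, p, dt = 0.001, n_steps = n)
  expect_equal(out$V[2, 2], 12 * (1 - 0.001 / p$tau_m)^n, tolerance = 1e-10)
})

test_that("parameter defaults carry the derived constants and units", {
  p <- model_parameters()
  expect_equal(p$V_K0, 26.6 * log(3 / 130))
  expect_equal(p$D_K, 4e-4)   # cm^2/s converted to mm^2/s
  expect_equal(p$tau_m, 0.01) # ms converted to s
  expect_error(model_parameters(tau_K = -1), "tau_K")
  expect_error(model_parameters(delta_x = 2), "delta_x")
  expect_error(model_parameters(model_variant = 5), "model_variant")
})
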