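short_cfg <- function(...) {
  sim_config(domain = list(width = 1.5, height = 1.5, nx = 20, radius = 0.3),
             total_time = 2, recording = list(snapshot_dt = 1), ...)
}

test_that("identical configuration and seed give bit-identical records", {
  cfg <- short_cfg(model = 2)
  a <- run_simulation(cfg, seed = 5)
  b <- run_simulation(cfg, seed = 5)
  expect_identical(a$probes, b$probes)
  expect_identical(a$snapshots$K_o, b$snapshots$K_o)
  c <- run_simulation(cfg, seed = 6)
  expect_false(identical(a$probes$S1$V, c$probes$S1$V))
})

test_that("combined model with zero diffusion reproduces the synaptic model", {
  cfg2 <- short_cfg(model = 2)
  cfg3 <- short_cfg(model = 3, parameters = list(D_K = 0))
  a <- run_simulation(cfg2, seed = 9)
  b <- run_simulation(cfg3, seed = 9)
  expect_identical(a$probes$S1$K_o, b$probes$S1$K_o)
  expect_identical(a$probes$S1$V, b$probes$S1$V)
})

test_that("noise modes behave as specified and share the seeded stream", {
  set.seed(1)
  h <- generate_noise("homogeneous", 8, 8)
  expect_equal(length(unique(as.vector(h))), 1)
  set.seed(2)
  x <- generate_noise("inhomogeneous", 80, 80)
  expect_lt(abs(mean(x)), 3 / 80)           # 3 standard errors
  expect_lt(abs(sd(x) - 1), 3 / sqrt(2 * (6400 - 1)) * 2)
  set.seed(3); a <- generate_noise("inhomogeneous", 10, 10)
  set.seed(3); b <- generate_noise("inhomogeneous", 10, 10)
  expect_identical(a, b)
})

test_that("sqrt-dt noise scaling coincides with per-step at dt = 1 ms", {
  cfg_a <- short_cfg(model = 2, noise = list(scaling = "per_step"))
  cfg_b <- short_cfg(model = 2, noise = list(scaling = "sqrt_dt"))
  a <- run_simulation(cfg_a, seed = 4)
  b <- run_simulation(cfg_b, seed = 4)
  expect_identical(a$probes$S1$V, b$probes$S1$V)
})

test_that("near-rest drift without noise stays within the pump-balance bound", {
  # sigma = 0, K_bath = K_o0, pump off: the state is an exact fixed point
  p <- model_parameters(sigma_over_gL = 0, K_bath = 3, rho = 0,
                        model_variant = 1)
  dom <- build_domain(width = 0.75, height = 0.75, nx = 10, radius = 0,
                      Gsyn_center = 0, Gsyn_periphery = 0,
                      Kbath_center = 3, Kbath_periphery = 3)
  st <- initial_state(dom, p)
  out <- step_state(st, dom, p, n_steps = 1000)
  expect_lt(max(abs(out$K_o - 3)), 1e-12)
  expect_lt(max(abs(out$Na_i - 10)), 1e-12)
  expect_identical(max(abs(out$V)), 0)
  # with the pump on, the residual drift over 1 s stays within the
  # resting pump-flux bound 2 * gamma * I_pump(3, 10)
  p2 <- model_parameters(sigma_over_gL = 0, K_bath = 3, model_variant = 1)
  out2 <- step_state(st, dom, p2, n_steps = 1000)
  bound <- 2 * p2$gamma * pump_current(3, 10, p2$rho) * 1.05
  expect_lt(max(abs(out2$K_o - 3)), bound)
})

test_that("pure diffusion conserves total potassium over many steps", {
  p <- model_parameters(sigma_over_gL = 0, rho = 0, tau_K = 1e9,
                        gK_leak_over_gL = 0, Gsyn_over_gL = 0,
                        model_variant = 1)
  dom <- build_domain(width = 1.5, height = 1.5, nx = 20, radius = 0,
                      Gsyn_center = 0, Gsyn_periphery = 0,
                      Kbath_center = 3, Kbath_periphery = 3)
  st <- initial_state(dom, p)
  st$K_o[10, 10] <- 50   # point perturbation
  total0 <- sum(st$K_o)
  one <- step_state(st, dom, p, n_steps = 1)
  expect_lt(abs(sum(one$K_o) - total0), 1e-10)
  out <- step_state(st, dom, p, n_steps = 10000)
  expect_lt(abs(sum(out$K_o) - total0) / total0, 1e-9)
  # perturbation spreads to neighbours
  expect_lt(out$K_o[10, 10], 50)
  expect_gt(out$K_o[12, 10], 3)
})

test_that("the engine's elliptic solve matches the R-level solvers", {
  # one step of model 2 from a state with a localised firing region; the
  # recorded phi must equal the direct solve of the connectivity equation
  p <- model_parameters(sigma_over_gL = 0)
  dom <- build_domain(width = 1.5, height = 1.2, nx = 20, radius = 0.3)
  st <- initial_state(dom, p)
  st$V[8:12, 8:10] <- 60   # drives nu = numax * tanh-like level
  out <- step_state(st, dom, p, n_steps = 1)
  # the phi attached to the final state is solved from the final nu field
  nu <- firing_rate(out$V, p)
  phi_direct <- solve_presynaptic_rate(nu, p$lambda_conn, dom$dx,
                                       method = "direct")
  expect_lt(max(abs(out$phi - phi_direct)) / max(phi_direct), 1e-8)
})

test_that("lesioned domains use the iterative path and pin phi to zero", {
  p <- model_parameters(sigma_over_gL = 0)
  dom <- build_domain(width = 1.5, height = 1.2, nx = 20, radius = 0.3)
  dom$lesion <- make_lesion_mask(dom, "complete_line", x = 1.0)
  st <- initial_state(dom, p)
  st$V[8:12, 8:10] <- 60
  out <- step_state(st, dom, p, n_steps = 1)
  nu <- firing_rate(out$V, p)
  phi_direct <- solve_presynaptic_rate(nu, p$lambda_conn, dom$dx,
                                       lesion = dom$lesion, method = "direct")
  expect_lt(max(abs(out$phi - phi_direct)) / max(phi_direct), 1e-6)
  expect_true(all(out$phi[dom$lesion$cells] == 0))
  # beyond a complete synaptic cut the presynaptic rate is exactly zero
  cut <- ceiling(1.0 / dom$dx)
  expect_true(all(out$phi[(cut + 1):dom$nx, ] == 0))
})

test_that("zero-duration runs return only the initial state", {
  cfg <- short_cfg(model = 2)
  cfg$total_time <- 0
  rec <- run_simulation(cfg, seed = 1)
  expect_equal(nrow(rec$probes$S1), 1)
  expect_equal(rec$probes$S1$t, 0)
  expect_equal(rec$probes$S1$K_o, 3)
  expect_equal(rec$probes$S1$phi, 0)  # solved from the initial (zero) rate
})

test_that("diverging fields abort with a diagnostic", {
  # a hugely unstable diffusion setup must be rejected up front
  expect_error(
    run_simulation(short_cfg(model = 1, parameters = list(D_K = 1))),
    "unstable")
  # and a finite-but-explosive parameter set aborts mid-run
  cfg <- short_cfg(model = 2,
                   parameters = list(delta_K = 1e307, sigma_over_gL = 1e5))
  cfg$total_time <- 5
  expect_error(run_simulation(cfg, seed = 1), "non-finite")
})

test_that("probe and snapshot cadences are honoured", {
  cfg <- sim_config(domain = list(width = 1.5, height = 1.5, nx = 20,
                                  radius = 0.3),
                    total_time = 2,
                    recording = list(probe_dt = 0.01, snapshot_dt = 0.5))
  rec <- run_simulation(cfg, seed = 1)
  expect_equal(nrow(rec$probes$S1), 201)
  expect_equal(diff(rec$probes$S1$t)[1], 0.01, tolerance = 1e-9)
  expect_equal(rec$snapshots$t, seq(0, 2, by = 0.5))
  expect_true(all(diff(rec$probes$S1$t) > 0))
})

test_that("strip capture records the potential along the configured line", {
  cfg <- sim_config(domain = list(width = 1.5, height = 1.5, nx = 20,
                                  radius = 0.3),
                    total_time = 1,
                    recording = list(snapshot_dt = 0, strip_x = 0.75,
                                     strip_window = c(0.2, 0.4)))
  rec <- run_simulation(cfg, seed = 1)
  expect_false(is.null(rec$strip))
  expect_equal(ncol(rec$strip$V), 20)
  expect_equal(range(rec$strip$t), c(0.2, 0.4), tolerance = 1e-6)
  pat <- space_time_pattern(rec)
  expect_s3_class(pat, "space_time_pattern")
})

test_that("records persist and reload through the CSV round trip", {
  cfg <- short_cfg(model = 2)
  rec <- run_simulation(cfg, seed = 12)
  dir <- withr::local_tempdir()
  write_record(rec, dir)
  back <- read_record(dir)
  expect_equal(back$seed, 12)
  expect_equal(back$probes$S1$K_o, rec$probes$S1$K_o, tolerance = 1e-6)
  ev <- detect_discharges(back$probes$S1)
  expect_s3_class(ev, "tbl_df")
})
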