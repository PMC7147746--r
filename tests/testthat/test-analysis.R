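test_that("discharge detector scores a square pulse exactly once", {
  tr <- square_pulse_trace(dt = 0.01, on = 20, off = 35)
  ev <- detect_discharges(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_t, 20, tolerance = 0.011)
  expect_equal(ev$duration, 15, tolerance = 0.03)
  expect_equal(ev$peak_K_o, 6)
  expect_true(ev$complete)

  flat <- tibble::tibble(t = seq(0, 10, 0.01), K_o = 3)
  expect_equal(nrow(detect_discharges(flat)), 0)
  expect_error(detect_discharges(tibble::tibble(t = 1, K_o = 3)), "two samples")
})

test_that("detector is invariant to time shifts and super-sampling", {
  tr <- square_pulse_trace(dt = 0.01)
  ev <- detect_discharges(tr)
  shifted <- dplyr::mutate(tr, t = t + 123.4)
  ev_s <- detect_discharges(shifted)
  expect_equal(ev_s$onset_t - 123.4, ev$onset_t, tolerance = 1e-9)
  expect_equal(ev_s$duration, ev$duration)

  fine <- tibble::tibble(t = seq(0, 60, 0.001),
                         K_o = ifelse(t >= 20 & t < 35, 6, 3))
  ev_f <- detect_discharges(fine)
  expect_equal(ev_f$onset_t, ev$onset_t, tolerance = 0.011)
  expect_equal(ev_f$duration, ev$duration, tolerance = 0.011)
})

test_that("hysteresis merges threshold chatter into one event", {
  t <- seq(0, 30, 0.01)
  # oscillates between 3.8 and 4.2 around the threshold inside one event
  K <- ifelse(t >= 10 & t < 20, 4 + 0.2 * sin(20 * t), 3)
  ev <- detect_discharges(tibble::tibble(t = t, K_o = K),
                          on_threshold = 4, off_hysteresis = 0.5)
  expect_equal(nrow(ev), 1)
})

test_that("two-point and synthetic-front speeds are recovered", {
  a <- tibble::tibble(distance = c(0, 2), t_arrive = c(0, 20))
  expect_equal(wavefront_speed(a, fit_range = c(0, 2))$speed, 0.1)
  expect_error(wavefront_speed(a[1, ], fit_range = c(0, 2)), "2 valid")

  dom <- build_domain()
  for (v in c(0.01, 0.035, 0.1, 1, 10)) {
    # snapshot cadence scaled so the front advances about half its width
    # per snapshot at every speed
    cad <- max(0.002, min(1, 0.075 / v))
    times <- seq(0, 3.2 / v, by = cad)
    rec <- synthetic_record(dom, times, expanding_front(v))
    fit <- wavefront_speed(front_arrival_times(rec, threshold = 4,
                                               window = range(times)))
    expect_lt(abs(fit$speed - v) / v, 0.02)
  }
})

test_that("arrival times of a translating pulse are spaced by distance/speed", {
  dom <- build_domain()
  times <- seq(0, 30, by = 1)
  rec <- synthetic_record(dom, times, expanding_front(0.1, w = 0.05))
  arr <- front_arrival_times(rec, threshold = 4, window = c(0, 30))
  a <- arr[!is.na(arr$t_arrive), ]
  d <- diff(a$t_arrive) / diff(a$distance)
  expect_equal(median(d), 1 / 0.1, tolerance = 0.05)
})

test_that("a stationary bump yields missing arrivals beyond its edge", {
  dom <- build_domain()
  times <- seq(0, 10, by = 1)
  bump <- function(r, t) 3 + 4 * (r <= 0.8)
  rec <- synthetic_record(dom, times, bump)
  arr <- front_arrival_times(rec, threshold = 4, window = c(0, 10))
  covered <- arr$distance <= 0.75
  # never-crossing positions are missing, not errors
  expect_true(all(is.na(arr$t_arrive[arr$distance > 0.85])))
})

test_that("burst inclination measures front slope in s/mm", {
  # synchronous bursts: vertical stripes, inclination ~ 0
  t <- seq(0, 0.4, by = 0.001)
  y <- seq(0.05, 1.55, by = 0.075)
  Vs <- matrix(0, length(t), length(y))
  for (b in c(0.1, 0.25)) Vs[t >= b & t < b + 0.02, ] <- 60
  pat <- structure(list(t = t, y = y, x = 0, V = Vs),
                   class = "space_time_pattern")
  inc <- burst_inclination(pat)
  expect_equal(nrow(inc), 2)
  expect_lt(max(inc$abs_inclination), 1e-9)

  # a wave at 0.1 mm/s along the strip: inclination 10 s/mm
  t2 <- seq(0, 20, by = 0.01)
  V2 <- matrix(0, length(t2), length(y))
  for (jj in seq_along(y)) V2[t2 >= y[jj] / 0.1, jj] <- 60
  pat2 <- structure(list(t = t2, y = y, x = 0, V = V2),
                    class = "space_time_pattern")
  inc2 <- burst_inclination(pat2)
  expect_equal(nrow(inc2), 1)
  expect_equal(inc2$inclination, 10, tolerance = 0.01)
})

test_that("synchrony delays: identical traces zero, shifted discharges offset", {
  t <- seq(0, 200, by = 0.01)
  base <- numeric(length(t))
  # an ictal episode of repeated bursts at 40-70 s
  for (b in seq(40, 70, by = 0.5)) base[t >= b & t < b + 0.2] <- 50
  tr <- dplyr::bind_rows(
    tibble::tibble(probe = "A", t = t, phi = base),
    tibble::tibble(probe = "B", t = t, phi = base))
  syn <- burst_synchrony(tr)
  expect_equal(syn$mean_abs_delay[syn$kind == "burst"], 0)
  expect_equal(syn$mean_abs_delay[syn$kind == "discharge"], 0)

  shifted <- numeric(length(t))
  for (b in seq(43, 73, by = 0.5)) shifted[t >= b & t < b + 0.2] <- 50
  tr2 <- dplyr::bind_rows(
    tibble::tibble(probe = "A", t = t, phi = base),
    tibble::tibble(probe = "B", t = t, phi = shifted))
  syn2 <- burst_synchrony(tr2)
  expect_equal(syn2$mean_delay[syn2$kind == "discharge"], 3, tolerance = 0.05)
  expect_error(burst_synchrony(tr[tr$probe == "A", ]), "2 probes")
})

test_that("closed-form magnitude estimates evaluate as printed", {
  expect_equal(electrodiffusion_speed(5e-4, 2 / 0.1), 1e-3)
  expect_equal(electrodiffusion_speed(5e-4, 0), 0)
  expect_equal(electrodiffusion_speed(5e-4, 40),
               2 * electrodiffusion_speed(5e-4, 20))
  expect_error(electrodiffusion_speed(-1, 1), "positive")

  expect_equal(round(nernst_sensitivity(7), 1), 3.8)
  expect_equal(round(nernst_sensitivity(10), 1), 2.7)
  expect_equal(round(nernst_sensitivity(130), 1), 0.2)
  expect_error(nernst_sensitivity(0), "positive")
})
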