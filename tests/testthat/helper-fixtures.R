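# Shared fixtures, built in code at test time.

# A minimal record-like object carrying synthetic snapshots, sufficient for
# the arrival-time / speed estimators.
synthetic_record <- function(domain, times, field_fun, field = "K_o") {
  arr <- array(0, dim = c(domain$nx, domain$ny, length(times)))
  cx <- (seq_len(domain$nx) - 0.5) * domain$dx
  cy <- (seq_len(domain$ny) - 0.5) * domain$dx
  r <- sqrt(outer(cx - domain$excitation_center[1],
                  cy - domain$excitation_center[2],
                  function(a, b) a^2 + b^2))
  for (k in seq_along(times)) arr[, , k] <- field_fun(r, times[k])
  snaps <- list(t = times)
  snaps[[field]] <- arr
  structure(list(snapshots = snaps, domain = domain), class = "sim_record")
}

# A radially expanding smooth potassium front: baseline 3 mM, amplitude
# 4 mM, front at radius v * (t - t0), width w.
expanding_front <- function(v, t0 = 0, w = 0.15, base = 3, amp = 4) {
  function(r, t) base + amp * 0.5 * (1 + tanh((v * (t - t0) - r) / w))
}

# Square potassium pulse trace for the discharge detector.
square_pulse_trace <- function(dt = 0.01, t_end = 60, on = 20, off = 35,
                               lo = 3, hi = 6) {
  t <- seq(0, t_end, by = dt)
  tibble::tibble(t = t, K_o = ifelse(t >= on & t < off, hi, lo))
}

# Tiny domain for operator tests.
tiny_domain <- function(nx = 16, ny = 12, dx = 0.075) {
  build_domain(width = nx * dx, height = ny * dx, nx = nx,
               radius = 0.1, center = c(nx * dx / 2, ny * dx / 2))
}
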