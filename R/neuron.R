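#' Parameters of the representative neuron-observer
#'
#' The adaptive quadratic integrate-and-fire neuron that converts the
#' population input current into a spiking membrane-potential trace:
#' `C_U dU/dt = g_U (U - U1)(U - U2) - w + u + I_a`, `tau_w dw/dt = -w`,
#' with reset `U -> V_reset`, `w -> w + delta_w` whenever `U > V_T`.
#'
#' @param g_U Quadratic conductance (nS/mV).
#' @param C_U Membrane capacitance (pF).
#' @param V_T Spike threshold (mV).
#' @param V_reset Reset potential (mV).
#' @param U1,U2 Quadratic-nullcline reversal potentials (mV), `U1 < U2`.
#' @param U0 Initial potential (mV).
#' @param I_a Tonic current (pA).
#' @param tau_w Adaptation time constant (ms).
#' @param delta_w Adaptation increment per spike (pA).
#' @return A named list of class `neuron_params`.
#' @export
neuron_parameters <- function(g_U = 1.5, C_U = 1050, V_T = 25, V_reset = -40,
                              U1 = -60, U2 = -40, U0 = -70, I_a = 116,
                              tau_w = 200, delta_w = 100) {
  if (U1 >= U2) abort("`U1` must be below `U2`")
  if (V_reset >= V_T) abort("`V_reset` must be below `V_T`")
  if (C_U <= 0 || g_U <= 0 || tau_w <= 0) {
    abort("conductance, capacitance and tau_w must be positive")
  }
  structure(list(g_U = g_U, C_U = C_U, V_T = V_T, V_reset = V_reset,
                 U1 = U1, U2 = U2, U0 = U0, I_a = I_a, tau_w = tau_w,
                 delta_w = delta_w), class = "neuron_params")
}

#' Drive the neuron-observer with a recorded input trace
#'
#' Explicit-Euler integration of the adaptive quadratic
#' integrate-and-fire neuron at the sample period of the input trace.
#' The population input current is recorded as `u / g_L` in mV; `gain`
#' converts it to a pA drive (the coupling scale between the
#' population-level and single-neuron descriptions is a free choice; the
#' default makes an ictal discharge elicit burst-clustered spiking).
#'
#' @param u_trace A data frame with columns `t` (s, uniformly sampled)
#'   and `u` (mV) -- e.g. a probe tibble from [run_simulation()].
#' @param params A [neuron_parameters()] object.
#' @param gain Drive conversion (pA per mV of `u/g_L`).
#' @return An object of class `spike_trace`: a tibble `t`, `U` (mV), `w`
#'   (pA), with the spike times (s) in `attr(, "spike_times")`.
#'   `tidy()` returns the tibble, `glance()` spike counts and rates.
#' @export
integrate_neuron <- function(u_trace, params = neuron_parameters(),
                             gain = 10) {
  if (is.null(u_trace$t) || is.null(u_trace$u)) {
    abort("`u_trace` needs columns `t` and `u`")
  }
  if (nrow(u_trace) == 0) abort("`u_trace` is empty")
  dt_s <- check_uniform(u_trace$t, "u_trace")
  dt <- dt_s * 1000 # integrate in ms (pF mV / ms = pA)
  n <- nrow(u_trace)
  drive <- gain * u_trace$u + params$I_a
  U <- numeric(n); w <- numeric(n)
  U[1] <- params$U0; w[1] <- 0
  spikes <- numeric(0)
  gU <- params$g_U; CU <- params$C_U; U1 <- params$U1; U2 <- params$U2
  tw <- params$tau_w
  for (k in seq_len(n - 1)) {
    Uk <- U[k]; wk <- w[k]
    Un <- Uk + dt * (gU * (Uk - U1) * (Uk - U2) - wk + drive[k]) / CU
    wn <- wk - dt * wk / tw
    if (Un > params$V_T) {
      spikes <- c(spikes, u_trace$t[k + 1])
      Un <- params$V_reset
      wn <- wn + params$delta_w
    }
    U[k + 1] <- Un; w[k + 1] <- wn
  }
  out <- tibble(t = u_trace$t, U = U, w = w)
  class(out) <- c("spike_trace", class(out))
  attr(out, "spike_times") <- spikes
  attr(out, "params") <- params
  out
}

#' @rdname tidy_ictalwave
#' @export
tidy.spike_trace <- function(x, ...) {
  tibble(t = x$t, U = x$U, w = x$w)
}

#' @rdname tidy_ictalwave
#' @export
glance.spike_trace <- function(x, ...) {
  sp <- attr(x, "spike_times")
  dur <- diff(range(x$t))
  tibble(n_spikes = length(sp),
         mean_rate = length(sp) / dur,
         mean_isi = if (length(sp) > 1) mean(diff(sp)) else NA_real_,
         duration = dur)
}

#' Resting potentials of the neuron-observer
#'
#' Roots of the zero-input, zero-adaptation current balance
#' `g_U (U - U1)(U - U2) + I_a + u = 0` via the quadratic formula. The
#' lower root is the stable resting potential; complex roots mean the
#' drive exceeds the saddle-node and the neuron spikes periodically.
#'
#' @param params A [neuron_parameters()] object.
#' @param u Constant drive (pA).
#' @return Numeric vector of 0 or 2 roots (mV), increasing order.
#' @export
neuron_fixed_points <- function(params = neuron_parameters(), u = 0) {
  # g U^2 - g (U1 + U2) U + g U1 U2 + Ia + u = 0
  a <- params$g_U
  b <- -params$g_U * (params$U1 + params$U2)
  cc <- params$g_U * params$U1 * params$U2 + params$I_a + u
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric(0))
  sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
}
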