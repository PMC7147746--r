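#' Potassium Nernst reversal potential
#'
#' Reversal potential of potassium from the extracellular concentration,
#' with the intracellular concentration held at 130 mM:
#' `V_K = 26.6 * log(K_o / 130)` mV.
#'
#' @param K_o Extracellular potassium concentration (mM); vectorised.
#' @return Reversal potential (mV).
#' @examples
#' nernst_potential(130) # 0
#' nernst_potential(3)   # about -100.3
#' @export
nernst_potential <- function(K_o) {
  if (!is.numeric(K_o) || any(!is.finite(K_o)) || any(K_o <= 0)) {
    abort("`K_o` must be finite and strictly positive (mM)")
  }
  26.6 * log(K_o / 130)
}

#' Na/K pump flux
#'
#' Sigmoidal pump activation in both the extracellular potassium and the
#' intracellular sodium concentration:
#' `I_pump = rho / ((1 + exp(3.5 - K_o)) * (1 + exp((25 - Na_i) / 3)))`.
#' The flux is bounded in (0, rho) and increasing in both arguments.
#'
#' @param K_o Extracellular potassium (mM); vectorised.
#' @param Na_i Intracellular sodium (mM); vectorised.
#' @param rho Maximum pump flux (mM/s).
#' @return Pump flux (mM/s).
#' @examples
#' pump_current(3.5, 25, 0.2) # rho / 4 = 0.05
#' @export
pump_current <- function(K_o, Na_i, rho = 0.2) {
  rho / ((1 + exp(3.5 - K_o)) * (1 + exp((25 - Na_i) / 3)))
}

#' Somatic firing rate
#'
#' Rectified sigmoidal input-output function of the population membrane
#' potential: `nu = nu_max * [2 / (1 + exp(-2 (V - V_th) / k_v)) - 1]_+`.
#' Zero for all `V <= V_th`, saturating at `nu_max`.
#'
#' @param V Membrane-potential deflection (mV); vectorised.
#' @param params An [model_parameters()] object (uses `nu_max`, `V_th`, `k_v`).
#' @return Firing rate (Hz).
#' @examples
#' p <- model_parameters()
#' firing_rate(p$V_th, p)       # 0
#' firing_rate(1e4, p)          # nu_max
#' @export
firing_rate <- function(V, params = model_parameters()) {
  pmax(params$nu_max * (2 / (1 + exp(-2 * (V - params$V_th) / params$k_v)) - 1), 0)
}

#' Total input current (per leak conductance)
#'
#' Assembles the input current `u / g_L` (mV): the potassium depolarising
#' current relative to the initial reversal potential, the depressing
#' excitatory minus non-depressing inhibitory synaptic drive, and the noise:
#' `u = gK_leak (V_K - V_K0) + G_syn phi (x_D - c_IE) + sigma xi`.
#'
#' The same `G_syn` factor multiplies excitation and inhibition, so the
#' per-cell excitability map scales both. All arguments are vectorised.
#'
#' @param V_K Potassium reversal potential (mV), from [nernst_potential()].
#' @param phi Presynaptic firing rate (Hz).
#' @param x_D Synaptic resource fraction in (0, 1].
#' @param xi Standard-normal noise draw (dimensionless; 0 for deterministic).
#' @param params An [model_parameters()] object.
#' @param Gsyn_over_gL Optional per-cell postsynaptic charge (mV s)
#'   overriding the scalar in `params` (the domain's excitability map).
#' @return Input current `u / g_L` (mV).
#' @export
input_current <- function(V_K, phi, x_D, xi = 0, params = model_parameters(),
                          Gsyn_over_gL = NULL) {
  G <- if (is.null(Gsyn_over_gL)) params$Gsyn_over_gL else Gsyn_over_gL
  params$gK_leak_over_gL * (V_K - params$V_K0) +
    G * phi * (x_D - params$c_IE) +
    params$sigma_over_gL * xi
}

#' Point-wise time derivatives of the slow and fast fields
#'
#' Right-hand sides of the local (non-diffusive) dynamics at one grid cell
#' or a vector of cells:
#' * `d K_o/dt = (K_bath - K_o)/tau_K - 2 gamma I_pump + delta_K theta`
#' * `d Na_i/dt = (Na_i0 - Na_i)/tau_Na - 3 I_pump + delta_Na theta`
#' * `d V/dt = (u - V)/tau_m` (with `u` already divided by `g_L`)
#' * `d x_D/dt = (1 - x_D)/tau_D - delta_x x_D theta`
#'
#' The lateral diffusion term of the potassium balance is a grid-level
#' operator and is added by the simulation engine, not here.
#'
#' @param state A data frame / tibble (or named list) with columns `K_o`,
#'   `Na_i`, `V`, `x_D` (one row per cell).
#' @param theta Firing rate driving the ionic balances (Hz): the somatic
#'   rate `nu` for the diffusion model, the presynaptic rate `phi` for the
#'   synaptic and combined models.
#' @param u Input current per leak conductance (mV), from [input_current()].
#' @param params An [model_parameters()] object.
#' @param K_bath Optional per-cell bath potassium (mM) overriding `params`.
#' @return A tibble with columns `dK_o`, `dNa_i`, `dV`, `dx_D` (per-second
#'   rates).
#' @export
local_rhs <- function(state, theta, u, params = model_parameters(),
                      K_bath = NULL) {
  if (any(theta < 0)) abort("`theta` must be non-negative (Hz)")
  Kb <- if (is.null(K_bath)) params$K_bath else K_bath
  Ip <- pump_current(state$K_o, state$Na_i, params$rho)
  tibble(
    dK_o  = (Kb - state$K_o) / params$tau_K - 2 * params$gamma * Ip +
      params$delta_K * theta,
    dNa_i = (params$Na_i0 - state$Na_i) / params$tau_Na - 3 * Ip +
      params$delta_Na * theta,
    dV    = (u - state$V) / params$tau_m,
    dx_D  = (1 - state$x_D) / params$tau_D - params$delta_x * state$x_D * theta
  )
}
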