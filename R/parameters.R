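#' Model parameters for the spatially extended Epileptor-2 system
#'
#' Constructs the full parameter set of the neural-mass model with ionic
#' dynamics. Defaults are the reference values of the model (the published
#' parameter table); every value can be overridden. Arguments are given in
#' the table's units; internally everything is converted to the package unit
#' system (seconds, millimetres, millivolts, millimolar, hertz), so
#' `tau_m` is stored in s and `D_K` in mm^2/s.
#'
#' The input current `u` is represented throughout as `u / g_L` in mV: the
#' leak conductance never appears alone in the model, only as the ratios
#' `sigma/g_L`, `G_syn/g_L` and `g_K,leak/g_L`.
#'
#' @param tau_K Extracellular-potassium relaxation time constant (s).
#' @param tau_Na Intracellular-sodium relaxation time constant (s).
#' @param tau_m Membrane time constant `C/g_L` (ms).
#' @param tau_D Synaptic-depression recovery time constant (s).
#' @param D_K Extracellular potassium diffusion coefficient (cm^2/s).
#' @param delta_K Potassium concentration increment per spike (mM).
#' @param delta_Na Sodium concentration increment per spike (mM).
#' @param delta_x Synaptic-resource decrement per spike (dimensionless).
#' @param sigma_over_gL Noise amplitude `sigma/g_L` (mV).
#' @param rho Maximum Na/K pump flux (mM/s).
#' @param gamma Extracellular/intracellular volume ratio (dimensionless).
#' @param Gsyn_over_gL Postsynaptic charge `G_syn/g_L` (mV s). Used as a
#'   scalar here; the simulation domain carries a per-cell map (elevated in
#'   the central excitation disk).
#' @param c_IE Inhibitory-to-excitatory conductance ratio (dimensionless).
#' @param gK_leak_over_gL Potassium leak conductance ratio (dimensionless).
#' @param K_o0 Initial extracellular potassium concentration (mM). Also
#'   fixes the reference reversal potential `V_K0`.
#' @param K_bath Bath potassium concentration (mM); the simulation domain
#'   may carry a per-cell map.
#' @param Na_i0 Initial (and resting) intracellular sodium concentration (mM).
#' @param nu_max Maximal somatic firing rate (Hz).
#' @param lambda_conn Characteristic length of cortical connectivity (mm).
#' @param V_th Firing threshold potential (mV).
#' @param k_v Gain of the firing-rate sigmoid (mV).
#' @param model_variant Propagation mechanism: 1 = potassium diffusion only
#'   (`theta = nu`), 2 = axo-dendritic synaptic spread only (`theta = phi`,
#'   no diffusion term), 3 = both combined (`theta = phi`, diffusion on).
#'
#' @return An object of class `epi_params`: a named list in internal units
#'   with the derived constant `V_K0 = 26.6 * log(K_o0 / 130)` (mV).
#' @examples
#' p <- model_parameters()
#' p$V_K0 # approximately -100.3 mV
#' @export
model_parameters <- function(tau_K = 100, tau_Na = 20, tau_m = 10, tau_D = 2,
                             D_K = 4e-6, delta_K = 0.04, delta_Na = 0.03,
                             delta_x = 0.01, sigma_over_gL = 25, rho = 0.2,
                             gamma = 20, Gsyn_over_gL = 5, c_IE = 0.5,
                             gK_leak_over_gL = 1.0, K_o0 = 3, K_bath = 7,
                             Na_i0 = 10, nu_max = 100, lambda_conn = 0.385,
                             V_th = 25, k_v = 20, model_variant = 2) {
  p <- list(
    tau_K = tau_K, tau_Na = tau_Na,
    tau_m = tau_m / 1000,            # ms -> s
    tau_D = tau_D,
    D_K = D_K * 100,                 # cm^2/s -> mm^2/s
    delta_K = delta_K, delta_Na = delta_Na, delta_x = delta_x,
    sigma_over_gL = sigma_over_gL, rho = rho, gamma = gamma,
    Gsyn_over_gL = Gsyn_over_gL, c_IE = c_IE,
    gK_leak_over_gL = gK_leak_over_gL,
    K_o0 = K_o0, K_bath = K_bath, Na_i0 = Na_i0,
    nu_max = nu_max, lambda_conn = lambda_conn,
    V_th = V_th, k_v = k_v,
    model_variant = as.integer(model_variant)
  )
  p$V_K0 <- 26.6 * log(p$K_o0 / 130)
  class(p) <- "epi_params"
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  pos <- c("tau_K", "tau_Na", "tau_m", "tau_D", "K_o0", "K_bath", "Na_i0",
           "nu_max", "lambda_conn", "k_v")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      abort(sprintf("parameter `%s` must be a single positive finite number", nm))
    }
  }
  if (p$D_K < 0) abort("parameter `D_K` must be non-negative")
  if (p$rho < 0) abort("parameter `rho` must be non-negative")
  if (p$c_IE < 0) abort("parameter `c_IE` must be non-negative")
  if (p$delta_x < 0 || p$delta_x > 1) abort("parameter `delta_x` must lie in [0, 1]")
  if (!p$model_variant %in% 1:3) abort("`model_variant` must be 1, 2 or 3")
  invisible(p)
}

#' @export
print.epi_params <- function(x, ...) {
  cat("<epi_params> spatially extended Epileptor-2 parameters (internal units)\n")
  cat(sprintf("  model variant %d (%s)\n", x$model_variant,
              switch(x$model_variant, "potassium diffusion", "synaptic spread",
                     "diffusion + synaptic spread")))
  flat <- unlist(x[setdiff(names(x), "model_variant")])
  print(round(flat, 6))
  invisible(x)
}
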