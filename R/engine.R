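#' Initial grid state
#'
#' The resting initial conditions of the model: extracellular potassium at
#' `K_o0`, intracellular sodium at `Na_i0`, zero membrane-potential
#' deflection, full synaptic resource. The presynaptic rate is not an
#' independent state variable (the connectivity equation is algebraic in
#' time); the engine solves it from the initial somatic rate.
#'
#' @param domain An [build_domain()] object.
#' @param params An [model_parameters()] object.
#' @return A named list of `nx x ny` matrices `K_o`, `Na_i`, `V`, `x_D`.
#' @export
initial_state <- function(domain, params = model_parameters()) {
  K0 <- if (identical(domain$init_K, "bath")) domain$Kbath_map else
    matrix(params$K_o0, domain$nx, domain$ny)
  list(K_o = K0,
       Na_i = matrix(params$Na_i0, domain$nx, domain$ny),
       V = matrix(0, domain$nx, domain$ny),
       x_D = matrix(1, domain$nx, domain$ny),
       t = 0)
}

#' Noise field for one time step
#'
#' Spatially homogeneous noise is a single standard-normal draw broadcast
#' to every cell (all cells share the same fluctuation, as in the standard
#' runs); inhomogeneous noise is an independent draw per cell. Consumes
#' the R RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param mode `"homogeneous"` or `"inhomogeneous"`.
#' @param nx,ny Grid dimensions.
#' @return An `nx x ny` matrix of N(0,1) values.
#' @export
generate_noise <- function(mode = c("homogeneous", "inhomogeneous"),
                           nx, ny) {
  mode <- match.arg(mode)
  if (mode == "homogeneous") matrix(rnorm(1), nx, ny)
  else matrix(rnorm(nx * ny), nx, ny)
}

engine_par_list <- function(params, domain) {
  c(params[c("tau_K", "tau_Na", "tau_m", "tau_D", "D_K", "delta_K",
             "delta_Na", "delta_x", "sigma_over_gL", "rho", "gamma",
             "c_IE", "gK_leak_over_gL", "K_o0", "K_bath", "Na_i0",
             "nu_max", "lambda_conn", "V_th", "k_v")],
    list(dx = domain$dx))
}

# per-cell reference reversal potential for the potassium depolarising term
vk0_map <- function(domain, params) {
  if (identical(domain$init_K, "bath")) 26.6 * log(domain$Kbath_map / 130)
  else matrix(params$V_K0, domain$nx, domain$ny)
}

# Eigendecomposition of the 1D second-difference operator on n cells with
# a Neumann (mirror) or Dirichlet (cut) condition at each end. Returns the
# orthonormal eigenvector matrix and eigenvalues of the stencil (in units
# of 1/dx^2 once scaled by the caller).
mixed_1d_basis <- function(n, left = c("neumann", "dirichlet"),
                           right = c("neumann", "dirichlet")) {
  left <- match.arg(left); right <- match.arg(right)
  if (n == 1) {
    d <- -(left == "dirichlet") - (right == "dirichlet")
    return(list(V = matrix(1, 1, 1), mu = d))
  }
  L <- diag(-2, n)
  L[cbind(1:(n - 1), 2:n)] <- 1
  L[cbind(2:n, 1:(n - 1))] <- 1
  if (left == "neumann") L[1, 1] <- -1
  if (right == "neumann") L[n, n] <- -1
  e <- eigen(L, symmetric = TRUE)
  list(V = e$vectors, mu = e$values)
}

# Per-block spectral factorisation of the screened-Poisson operator. An
# unlesioned sheet is one block; a complete vertical cut splits it into
# independent rectangles with a Dirichlet condition at the cut.
spectral_setup <- function(domain, params) {
  alpha <- (params$lambda_conn / domain$dx)^2
  by <- dct_basis(domain$ny)
  has_lesion <- domain$lesion$kind != "none"
  if (has_lesion && !is.null(domain$lesion$cut_after)) {
    # blade cut: two live blocks with a no-flux (Neumann) face at the cut
    c0 <- domain$lesion$cut_after
    blocks <- list()
    for (rng in list(c(1L, c0), c(c0 + 1L, domain$nx))) {
      bx <- mixed_1d_basis(rng[2] - rng[1] + 1L, "neumann", "neumann")
      blocks[[length(blocks) + 1]] <- list(
        i0 = rng[1] - 1L, Vx = bx$V,
        denom = 1 - alpha * outer(bx$mu, by$mu, "+"))
    }
    return(list(blocks = blocks, Vy = by$V))
  }
  if (!has_lesion) {
    masked <- rep(FALSE, domain$nx)
  } else {
    rs <- rowSums(domain$lesion$cells)
    if (!all(rs %in% c(0L, domain$ny))) {
      abort("spectral blocks require a full-height cut")
    }
    masked <- rs > 0
  }
  runs <- rle(!masked)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  blocks <- list()
  for (q in seq_along(runs$values)) {
    if (!runs$values[q]) next
    i0 <- starts[q]; i1 <- ends[q]
    bx <- mixed_1d_basis(
      i1 - i0 + 1L,
      left = if (i0 == 1L) "neumann" else "dirichlet",
      right = if (i1 == domain$nx) "neumann" else "dirichlet")
    blocks[[length(blocks) + 1]] <- list(
      i0 = i0 - 1L, # zero-based for the engine
      Vx = bx$V,
      denom = 1 - alpha * outer(bx$mu, by$mu, "+"))
  }
  list(blocks = blocks, Vy = by$V)
}

use_spectral_path <- function(domain, params) {
  if (params$model_variant == 1) return(FALSE)
  if (domain$lesion$kind == "none") return(TRUE)
  if (domain$lesion$kind != "complete_line") return(FALSE)
  if (!is.null(domain$lesion$cut_after)) return(TRUE)
  all(rowSums(domain$lesion$cells) %in% c(0L, domain$ny))
}

cut_after_idx <- function(domain) {
  if (is.null(domain$lesion$cut_after)) -1L else
    as.integer(domain$lesion$cut_after) - 1L  # zero-based interface
}

#' Advance the full system
#'
#' Low-level single-call integrator used by [run_simulation()] and
#' directly in tests: advances a grid state by `n_steps` explicit
#' Euler-Maruyama steps under the chosen model variant. Consumes the R
#' RNG stream (`set.seed()` for reproducibility).
#'
#' @param state A state list from [initial_state()] (or a previous call).
#' @param domain An [build_domain()] object.
#' @param params An [model_parameters()] object; `params$model_variant`
#'   selects the propagation mechanism.
#' @param dt Time step (s); must satisfy `D_K dt / dx^2 < 1/4` when the
#'   diffusion term is active.
#' @param n_steps Number of steps.
#' @param noise_mode,noise_scaling See [sim_config()].
#' @return The advanced state list (with the solved `phi` field attached).
#' @export
step_state <- function(state, domain, params = model_parameters(),
                       dt = 0.001, n_steps = 1,
                       noise_mode = "homogeneous",
                       noise_scaling = "per_step") {
  if (params$model_variant != 2 && params$D_K * dt / domain$dx^2 >= 0.25) {
    abort("explicit diffusion unstable: D_K * dt / dx^2 >= 1/4")
  }
  has_lesion <- domain$lesion$kind != "none"
  use_spectral <- use_spectral_path(domain, params)
  sp <- if (use_spectral) spectral_setup(domain, params) else
    list(blocks = list(), Vy = matrix(0, 1, 1))
  out <- .run_core(
    state$K_o, state$Na_i, state$V, state$x_D,
    engine_par_list(params, domain),
    domain$Gsyn_map, domain$Kbath_map, vk0_map(domain, params),
    matrix(as.integer(domain$lesion$cells), domain$nx, domain$ny),
    has_lesion, isTRUE(domain$lesion$blocks_diffusion),
    params$model_variant,
    noise_mode == "inhomogeneous",
    if (noise_scaling == "sqrt_dt") sqrt(0.001 / dt) else 1,
    dt, n_steps, state$t %||% 0,
    integer(0), integer(0), 0L, 0L,
    sp$blocks, sp$Vy, use_spectral, 1e-8, 5000L,
    cut_after_idx(domain),
    -1L, 0L, -1L)
  out$final
}

#' Run a full simulation
#'
#' Integrates the stochastic system from the resting initial conditions
#' for the configured duration, recording probe time series at every
#' probe-cadence step and periodic field snapshots. Identical
#' (configuration, seed) pairs give bit-identical records.
#'
#' @param config A [sim_config()] object (see also [preset_config()]).
#' @param seed Integer seed overriding `config$seed`; if both are `NULL` a
#'   seed is drawn and recorded.
#' @param quiet Suppress the progress message.
#' @return An object of class `sim_record` with elements
#'   \describe{
#'     \item{probes}{named list of tibbles, one per probe, with columns
#'       `t`, `K_o`, `Na_i`, `V`, `x_D`, `phi`, `nu`, `u`, `I_pump`.}
#'     \item{snapshots}{list with `t` and the `nx x ny x n` arrays `K_o`,
#'       `V`, `phi` and `nu_env` (the per-cell maximum of the somatic rate
#'       since the previous snapshot -- an alias-free burst envelope).}
#'     \item{strip}{if configured, the fine-cadence membrane potential
#'       along a vertical strip: list with `t`, `y` and matrix `V`.}
#'     \item{final}{the final grid state.}
#'     \item{seed, config, params, domain}{reproducibility metadata.}
#'   }
#' @examples
#' \donttest{
#' cfg <- sim_config(total_time = 5, recording = list(snapshot_dt = 1))
#' rec <- run_simulation(cfg, seed = 1)
#' rec$probes$S1
#' }
#' @export
run_simulation <- function(config = sim_config(), seed = NULL, quiet = TRUE) {
  res <- resolve_config(config)
  params <- res$params; domain <- res$domain
  seed <- as.integer(seed %||% config$seed %||% sample.int(.Machine$integer.max, 1))

  n_steps <- as.integer(round(config$total_time / config$dt))
  probe_every <- max(1L, as.integer(round(config$recording$probe_dt / config$dt)))
  snap_every <- if (is.null(config$recording$snapshot_dt) ||
                    config$recording$snapshot_dt <= 0) 0L else
    max(1L, as.integer(round(config$recording$snapshot_dt / config$dt)))

  strip_i <- -1L; strip_from <- 0L; strip_to <- -1L
  if (!is.null(config$recording$strip_x)) {
    strip_i <- as.integer(
      pmin(domain$nx, pmax(1, ceiling(config$recording$strip_x / domain$dx)))) - 1L
    w <- unlist(config$recording$strip_window %||% c(0, config$total_time))
    strip_from <- as.integer(round(w[1] / config$dt))
    strip_to <- as.integer(round(w[2] / config$dt))
  }

  has_lesion <- domain$lesion$kind != "none"
  use_spectral <- use_spectral_path(domain, params)
  sp <- if (use_spectral) spectral_setup(domain, params) else
    list(blocks = list(), Vy = matrix(0, 1, 1))

  st <- initial_state(domain, params)
  if (!quiet) {
    message(sprintf("ictalwave: model %d, %d x %d grid, %g s at dt = %g s, seed %d",
                    params$model_variant, domain$nx, domain$ny,
                    config$total_time, config$dt, seed))
  }
  set.seed(seed)
  t_wall <- system.time(
    out <- .run_core(
      st$K_o, st$Na_i, st$V, st$x_D,
      engine_par_list(params, domain),
      domain$Gsyn_map, domain$Kbath_map, vk0_map(domain, params),
      matrix(as.integer(domain$lesion$cells), domain$nx, domain$ny),
      has_lesion, isTRUE(domain$lesion$blocks_diffusion),
      params$model_variant,
      config$noise$mode == "inhomogeneous",
      if (config$noise$scaling == "sqrt_dt") sqrt(0.001 / config$dt) else 1,
      config$dt, n_steps, 0,
      domain$probes$i - 1L, domain$probes$j - 1L, probe_every,
      snap_every,
      sp$blocks, sp$Vy, use_spectral, 1e-8, 5000L,
      cut_after_idx(domain),
      strip_i, strip_from, strip_to)
  )

  n_rec <- out$n_rec
  fields <- c("K_o", "Na_i", "V", "x_D", "phi", "nu", "u", "I_pump")
  probes <- lapply(seq_len(nrow(domain$probes)), function(p) {
    m <- out$probes[seq_len(n_rec), , p, drop = TRUE]
    dim(m) <- c(n_rec, 8)
    colnames(m) <- fields
    dplyr::bind_cols(tibble(t = as.numeric(out$probe_t)), as_tibble(m))
  })
  names(probes) <- domain$probes$label

  snapshots <- NULL
  if (out$n_snap > 0) {
    keep <- seq_len(out$n_snap)
    snapshots <- list(
      t = as.numeric(out$snap_t),
      K_o = out$snap_K[, , keep, drop = FALSE],
      V = out$snap_V[, , keep, drop = FALSE],
      phi = out$snap_phi[, , keep, drop = FALSE],
      nu_env = out$snap_nu_env[, , keep, drop = FALSE]
    )
  }

  strip <- NULL
  if (out$n_strip > 0) {
    strip <- list(t = as.numeric(out$strip_t),
                  y = (seq_len(domain$ny) - 0.5) * domain$dx,
                  x = (strip_i + 0.5) * domain$dx,
                  V = out$strip_V[seq_len(out$n_strip), , drop = FALSE])
  }

  structure(list(
    probes = probes, snapshots = snapshots, strip = strip,
    final = out$final, seed = seed, config = config,
    params = params, domain = domain,
    model_variant = params$model_variant,
    probe_dt = probe_every * config$dt,
    snapshot_dt = snap_every * config$dt,
    cg_iterations = out$cg_iterations,
    elapsed = unname(t_wall["elapsed"])
  ), class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("<sim_record> model %d, %d x %d grid, T = %g s, seed %d\n",
              x$model_variant, x$domain$nx, x$domain$ny,
              x$config$total_time, x$seed))
  cat(sprintf("  probes: %s (every %g s); snapshots: %s\n",
              paste(names(x$probes), collapse = ", "), x$probe_dt,
              if (is.null(x$snapshots)) "none" else
                sprintf("%d at %g s cadence", length(x$snapshots$t),
                        x$snapshot_dt)))
  invisible(x)
}

#' @rdname tidy_ictalwave
#' @export
tidy.sim_record <- function(x, ...) {
  dplyr::bind_rows(x$probes, .id = "probe")
}

#' Broom-style summaries of ictalwave objects
#'
#' `tidy()` on a `sim_record` stacks the probe series into one long
#' tibble; `glance()` gives a one-row run summary. `tidy()` on a
#' `wavefront_fit` returns per-arrival data, `glance()` the fitted speed
#' and fit diagnostics.
#'
#' @param x A `sim_record` or `wavefront_fit` object.
#' @param ... Unused.
#' @name tidy_ictalwave
#' @return A tibble.
#' @export
glance.sim_record <- function(x, ...) {
  s1 <- x$probes[[1]]
  tibble(model_variant = x$model_variant,
         total_time = x$config$total_time,
         nx = x$domain$nx, ny = x$domain$ny, dx = x$domain$dx,
         seed = x$seed,
         peak_K_o = max(s1$K_o), peak_nu = max(s1$nu),
         elapsed = x$elapsed)
}
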