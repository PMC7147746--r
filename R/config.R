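config_defaults <- function() {
  list(
    domain = list(width = 6, height = 6, nx = 80, ny = NULL, center = NULL,
                  radius = 0.3, Gsyn_center = 5, Gsyn_periphery = 1,
                  Kbath_center = NULL, Kbath_periphery = NULL,
                  init_K = "uniform"),
    parameters = list(),
    model = 2,
    noise = list(mode = "homogeneous", scaling = "per_step"),
    lesion = list(kind = "none", x0 = NULL, y0 = NULL, x1 = NULL, y1 = NULL,
                  x = NULL, blocks_diffusion = FALSE, style = "cells"),
    recording = list(probe_dt = 0.001, snapshot_dt = 1,
                     strip_x = NULL, strip_window = NULL),
    probes = NULL,
    seed = NULL,
    total_time = 100,
    dt = 0.001
  )
}

param_names <- c("tau_K", "tau_Na", "tau_m", "tau_D", "D_K", "delta_K",
                 "delta_Na", "delta_x", "sigma_over_gL", "rho", "gamma",
                 "Gsyn_over_gL", "c_IE", "gK_leak_over_gL", "K_o0", "K_bath",
                 "Na_i0", "nu_max", "lambda_conn", "V_th", "k_v")

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown key(s) in [%s]: %s", block,
                  paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, user, keep.null = TRUE)
}

#' Simulation configuration
#'
#' Assembles and validates a full simulation configuration: domain
#' geometry, model-parameter overrides (by their published symbol names),
#' propagation-model variant, noise mode, lesion, recording cadences, seed
#' and duration. All defaults resolve to the reference parameter table and
#' the standard 6 x 6 mm / 80 x 80 geometry. Unknown keys are rejected.
#' The explicit-diffusion stability bound `D_K dt / dx^2 < 1/4` is
#' enforced at construction.
#'
#' @param domain Named list overriding the domain block (see
#'   [build_domain()]): `width`, `height`, `nx`, `ny`, `center`, `radius`,
#'   `Gsyn_center`, `Gsyn_periphery`, `Kbath_center`, `Kbath_periphery`
#'   (the bath values default to the `K_bath` parameter).
#' @param parameters Named list of parameter overrides accepted verbatim by
#'   their table symbols (`tau_K`, `D_K`, `lambda_conn`, ...); see
#'   [model_parameters()].
#' @param model Propagation mechanism 1 (diffusion), 2 (synaptic) or
#'   3 (combined).
#' @param noise List with `mode` (`"homogeneous"`: one shared N(0,1) draw
#'   per step; `"inhomogeneous"`: i.i.d. per cell) and `scaling`
#'   (`"per_step"`: the noise amplitude enters `u` directly each step,
#'   the model's reference convention at dt = 1 ms; `"sqrt_dt"`: draws
#'   scaled by `sqrt(dt_ref / dt)` with `dt_ref` = 1 ms, which makes the
#'   statistics dt-invariant and coincides with `"per_step"` at 1 ms).
#' @param lesion List with `kind` and the geometry fields of
#'   [make_lesion_mask()].
#' @param recording List with `probe_dt` (s), `snapshot_dt` (s; 0 disables
#'   snapshots), and optionally `strip_x` (mm) + `strip_window` (`c(t0, t1)`
#'   s) to capture the membrane potential along a full vertical strip at
#'   every time step inside the window (space-time burst diagrams).
#' @param probes Probe data frame (`label`, `x`, `y` in mm) or `NULL` for
#'   the default pair S1 (centre) and S2 (2 mm out).
#' @param seed Integer RNG seed; if `NULL` one is drawn at run time and
#'   recorded, so every run is replayable.
#' @param total_time Simulated duration (s).
#' @param dt Time step (s); default 0.001.
#' @return An object of class `sim_config` with all defaults resolved.
#' @examples
#' cfg <- sim_config(model = 1, total_time = 10)
#' describe_config(cfg)
#' @export
sim_config <- function(domain = list(), parameters = list(), model = 2,
                       noise = list(), lesion = list(), recording = list(),
                       probes = NULL, seed = NULL, total_time = 100,
                       dt = 0.001) {
  d <- config_defaults()
  cfg <- list(
    domain = merge_block(d$domain, domain, "domain"),
    parameters = merge_block(setNames(vector("list", length(param_names)),
                                      param_names),
                             parameters, "parameters"),
    model = as.integer(model),
    noise = merge_block(d$noise, noise, "noise"),
    lesion = merge_block(d$lesion, lesion, "lesion"),
    recording = merge_block(d$recording, recording, "recording"),
    probes = probes,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    total_time = total_time,
    dt = dt
  )
  cfg$parameters <- cfg$parameters[!vapply(cfg$parameters, is.null, TRUE)]
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

# Resolve a config into parameter and domain objects; run all checks.
resolve_config <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  if (!config$model %in% 1:3) abort("[model] must be 1, 2 or 3")
  if (!config$noise$mode %in% c("homogeneous", "inhomogeneous")) {
    abort("[noise] mode must be \"homogeneous\" or \"inhomogeneous\"")
  }
  if (!config$noise$scaling %in% c("per_step", "sqrt_dt")) {
    abort("[noise] scaling must be \"per_step\" or \"sqrt_dt\"")
  }
  if (config$dt <= 0 || config$total_time < 0) {
    abort("`dt` must be positive and `total_time` non-negative")
  }
  params <- do.call(model_parameters,
                    c(config$parameters, list(model_variant = config$model)))

  db <- config$domain
  dom <- build_domain(
    width = db$width, height = db$height, nx = db$nx, ny = db$ny,
    center = if (is.null(db$center)) NULL else unlist(db$center),
    radius = db$radius,
    Gsyn_center = db$Gsyn_center, Gsyn_periphery = db$Gsyn_periphery,
    Kbath_center = db$Kbath_center %||% params$K_bath,
    Kbath_periphery = db$Kbath_periphery %||% params$K_bath,
    init_K = db$init_K %||% "uniform",
    probes = config$probes
  )
  lb <- config$lesion
  if (!identical(lb$kind, "none")) {
    dom$lesion <- make_lesion_mask(dom, kind = lb$kind,
                                   x0 = lb$x0, y0 = lb$y0,
                                   x1 = lb$x1, y1 = lb$y1, x = lb$x,
                                   blocks_diffusion = lb$blocks_diffusion,
                                   style = lb$style %||% "cells")
  }

  if (params$model_variant != 2) {
    cfl <- params$D_K * config$dt / dom$dx^2
    if (cfl >= 0.25) {
      abort(sprintf(
        "explicit diffusion unstable: D_K * dt / dx^2 = %.3g >= 1/4 (key `D_K`/`dt`)",
        cfl))
    }
  }
  rec <- config$recording
  if (!is.null(rec$strip_x) &&
      (rec$strip_x < 0 || rec$strip_x > dom$width)) {
    abort("[recording] strip_x outside the domain")
  }
  list(params = params, domain = dom)
}

validate_config <- function(config) {
  invisible(resolve_config(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulation configuration from YAML
#'
#' Loads a YAML file with any subset of the sections `domain`,
#' `parameters`, `model`, `noise`, `lesion`, `recording`, `probes`,
#' `seed`, `total_time`, `dt`; unspecified values resolve to the reference
#' defaults. Unknown keys raise a descriptive error. An empty file yields
#' the pure default configuration (synaptic model on the standard
#' geometry).
#'
#' @param file Path to a YAML file.
#' @return A validated [sim_config()] object.
#' @seealso [preset_config()] for the bundled presets, [write_config()]
#'   for the lossless inverse.
#' @export
load_config <- function(file) {
  raw <- yaml::read_yaml(file)
  if (is.null(raw)) raw <- list()
  top <- c("domain", "parameters", "model", "noise", "lesion", "recording",
           "probes", "seed", "total_time", "dt")
  unknown <- setdiff(names(raw), top)
  if (length(unknown) > 0) {
    abort(sprintf("unknown top-level key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$probes)) {
    raw$probes <- dplyr::bind_rows(lapply(raw$probes, function(p) {
      # YAML 1.1 parses a bare `y` key as the boolean TRUE; undo that
      names(p)[names(p) %in% c("TRUE", "true")] <- "y"
      as_tibble(p)
    }))
  }
  args <- raw[intersect(top, names(raw))]
  do.call(sim_config, args)
}

#' Serialise a configuration to YAML
#'
#' Writes the fully resolved configuration; `load_config()` on the result
#' reproduces it losslessly.
#'
#' @param config A [sim_config()] object.
#' @param file Output path.
#' @export
write_config <- function(config, file) {
  x <- unclass(config)
  if (!is.null(x$probes)) {
    x$probes <- lapply(seq_len(nrow(x$probes)), function(r)
      as.list(x$probes[r, c("label", "x", "y")]))
  }
  yaml::write_yaml(x, file)
  invisible(file)
}

#' Bundled configuration presets
#'
#' Named, auditable YAML presets shipped with the package:
#' * `"standard"`: synaptic model (variant 2) on the standard 6 x 6 mm
#'   domain.
#' * `"diffusion"`: potassium-diffusion model (variant 1), same geometry.
#' * `"combined"`: both mechanisms (variant 3).
#' * `"strip"`: narrow 6 x 0.6 mm strip with the excitation disk at one
#'   end, used for wave-speed parameter sweeps.
#' * `"partial_lesion"`: synaptic model with a partial straight lesion
#'   (`phi = 0` on a segment) next to the excitation disk.
#' * `"complete_lesion"`: combined model with a full-height synaptic cut
#'   and the modified sensitivity parameters under which potassium
#'   diffusion alone can recruit the territory beyond the cut
#'   (`tau_K` = 10 s, `gK_leak/gL` = 3, zoned bath potassium 7/4 mM,
#'   spatially inhomogeneous noise, `D_K` = 2e-5 cm^2/s).
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [sim_config()] after the preset file
#'   is read (e.g. `total_time`, `seed`).
#' @return A validated [sim_config()] object.
#' @export
preset_config <- function(name = c("standard", "diffusion", "combined",
                                   "strip", "partial_lesion",
                                   "complete_lesion"), ...) {
  name <- match.arg(name)
  file <- system.file("presets", paste0(name, ".yaml"), package = "ictalwave",
                      mustWork = TRUE)
  cfg <- load_config(file)
  over <- list(...)
  if (length(over) > 0) {
    x <- unclass(cfg)
    for (nm in names(over)) {
      if (nm %in% c("domain", "parameters", "noise", "lesion", "recording")) {
        x[[nm]] <- utils::modifyList(x[[nm]], over[[nm]], keep.null = TRUE)
      } else {
        x[[nm]] <- over[[nm]]
      }
    }
    cfg <- do.call(sim_config, x[c("domain", "parameters", "model", "noise",
                                   "lesion", "recording", "probes", "seed",
                                   "total_time", "dt")])
  }
  cfg
}

#' Human-readable configuration summary
#'
#' Prints the resolved parameters, the derived constants (`V_K0`, `dx`),
#' and which coupling terms are active for the chosen model variant.
#'
#' @param config A [sim_config()] object.
#' @return The config, invisibly.
#' @export
describe_config <- function(config) {
  res <- resolve_config(config)
  p <- res$params; dom <- res$domain
  cat(sprintf("Model %d: %s\n", p$model_variant, switch(
    p$model_variant,
    "potassium diffusion (theta = nu; elliptic connectivity equation inactive)",
    "axo-dendritic synaptic spread (theta = phi; diffusion term inactive)",
    "combined (theta = phi; diffusion term active)")))
  cat(sprintf("Domain: %.3g x %.3g mm, %d x %d cells, dx = %.4g mm\n",
              dom$width, dom$height, dom$nx, dom$ny, dom$dx))
  cat(sprintf("Excitation disk: R = %.3g mm, G_syn/g_L = %.3g (periphery %.3g) mV s\n",
              dom$excitation_radius, max(dom$Gsyn_map), min(dom$Gsyn_map)))
  cat(sprintf("Derived: V_K0 = %.4g mV; D_K = %.3g mm^2/s; D_K dt/dx^2 = %.3g\n",
              p$V_K0, p$D_K, p$D_K * config$dt / dom$dx^2))
  cat(sprintf("Noise: %s, %s scaling, sigma/g_L = %.3g mV\n",
              config$noise$mode, config$noise$scaling, p$sigma_over_gL))
  cat(sprintf("Lesion: %s; T = %.4g s, dt = %.4g s, seed = %s\n",
              dom$lesion$kind, config$total_time, config$dt,
              if (is.null(config$seed)) "(drawn at run time)" else config$seed))
  flat <- unlist(p[setdiff(names(p), c("model_variant", "V_K0"))])
  cat("Parameters (internal units: s, mm, mV, mM, Hz):\n")
  print(round(flat, 6))
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> model %d, %g s at dt = %g s, %s noise, lesion: %s\n",
    x$model, x$total_time, x$dt, x$noise$mode, x$lesion$kind))
  invisible(x)
}
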