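#' Build the simulation domain
#'
#' Constructs the cortical-sheet geometry: a rectangular cell-centred grid
#' with a central circular excitation zone of elevated synaptic strength
#' (the source of epileptic discharges), per-cell maps of `G_syn/g_L` and
#' bath potassium, an optional lesion, and recording probes. Cell `(i, j)`
#' is centred at `((i - 1/2) dx, (j - 1/2) dx)`; disk membership is decided
#' by cell-centre distance.
#'
#' The default geometry is a 6 x 6 mm sheet on an 80 x 80 grid
#' (`dx = 0.075` mm) with an excitation disk of radius 0.3 mm at the
#' centre carrying `G_syn/g_L = 5` mV s against 1 mV s in the periphery.
#'
#' @param width,height Domain size (mm).
#' @param nx,ny Grid dimensions; `ny` defaults to `round(height / dx)` with
#'   `dx = width / nx`.
#' @param center Excitation-disk centre `c(x, y)` (mm); default the domain
#'   centre.
#' @param radius Excitation-disk radius (mm).
#' @param Gsyn_center,Gsyn_periphery Postsynaptic charge `G_syn/g_L`
#'   (mV s) inside and outside the disk.
#' @param Kbath_center,Kbath_periphery Bath potassium (mM) inside and
#'   outside the disk; equal by default (spatially uniform bath).
#' @param init_K `"uniform"`: the potassium field starts at the scalar
#'   `K_o0` and the reference reversal potential `V_K0` is the scalar
#'   Nernst value at `K_o0` (the standard runs). `"bath"`: each cell
#'   starts at its local bath concentration and `V_K0` is referenced to
#'   that local resting value -- the natural linearisation for zoned-bath
#'   setups, where a tissue equilibrated at an elevated bath is not
#'   standing-depolarised relative to it.
#' @param lesion A [make_lesion_mask()] object, or `NULL`.
#' @param probes A data frame with columns `label`, `x`, `y` (mm); default
#'   `S1` at the excitation centre and `S2` 2 mm from it toward a boundary.
#' @return An object of class `epi_domain`.
#' @examples
#' d <- build_domain()
#' sum(d$Gsyn_map > 1) # cells in the excitation disk
#' @export
build_domain <- function(width = 6, height = 6, nx = 80, ny = NULL,
                         center = NULL, radius = 0.3,
                         Gsyn_center = 5, Gsyn_periphery = 1,
                         Kbath_center = 7, Kbath_periphery = 7,
                         init_K = c("uniform", "bath"),
                         lesion = NULL, probes = NULL) {
  init_K = match.arg(init_K)
  if (width <= 0 || height <= 0 || nx < 3) abort("invalid domain geometry")
  dx <- width / nx
  if (is.null(ny)) ny <- max(3L, as.integer(round(height / dx)))
  height <- ny * dx
  if (is.null(center)) center <- c(width / 2, height / 2)
  if (radius < 0) abort("`radius` must be non-negative")
  if (center[1] - radius < 0 || center[1] + radius > width ||
      center[2] - radius < 0 || center[2] + radius > height) {
    abort("excitation disk must lie inside the domain")
  }

  cx <- (seq_len(nx) - 0.5) * dx
  cy <- (seq_len(ny) - 0.5) * dx
  r2 <- outer(cx - center[1], cy - center[2], function(a, b) a^2 + b^2)
  disk <- r2 <= radius^2

  Gsyn_map <- matrix(Gsyn_periphery, nx, ny)
  Gsyn_map[disk] <- Gsyn_center
  Kbath_map <- matrix(Kbath_periphery, nx, ny)
  Kbath_map[disk] <- Kbath_center

  if (is.null(probes)) {
    s2 <- c(min(center[1] + 2, width - dx / 2), center[2])
    probes <- tibble(label = c("S1", "S2"),
                     x = c(center[1], s2[1]), y = c(center[2], s2[2]))
  }
  probes <- as_tibble(probes)
  probes$i <- pmin(nx, pmax(1L, as.integer(ceiling(probes$x / dx))))
  probes$j <- pmin(ny, pmax(1L, as.integer(ceiling(probes$y / dx))))

  structure(list(
    nx = nx, ny = ny, dx = dx, width = width, height = height,
    excitation_center = center, excitation_radius = radius,
    disk = disk, Gsyn_map = Gsyn_map, Kbath_map = Kbath_map,
    init_K = init_K,
    lesion = if (is.null(lesion))
      structure(list(kind = "none", cells = matrix(FALSE, nx, ny),
                     blocks_diffusion = FALSE), class = "lesion_mask")
      else lesion,
    probes = probes
  ), class = "epi_domain")
}

#' @export
print.epi_domain <- function(x, ...) {
  cat(sprintf("<epi_domain> %.3g x %.3g mm, %d x %d cells (dx = %.4g mm)\n",
              x$width, x$height, x$nx, x$ny, x$dx))
  cat(sprintf("  excitation disk: R = %.3g mm at (%.3g, %.3g), %d cells elevated\n",
              x$excitation_radius, x$excitation_center[1],
              x$excitation_center[2], sum(x$Gsyn_map != x$Gsyn_map[1, 1])))
  cat(sprintf("  lesion: %s; probes: %s\n", x$lesion$kind,
              paste(x$probes$label, collapse = ", ")))
  invisible(x)
}

#' Probes along a ray from the excitation centre
#'
#' Convenience constructor for a line of probes radiating from the
#' excitation centre, used for wavefront arrival measurements.
#'
#' @param domain An [build_domain()] object (for geometry limits).
#' @param from,to,by Radial distances (mm) of the probes.
#' @param angle Direction in radians (0 = +x).
#' @return A probe tibble suitable for [build_domain()]'s `probes`.
#' @export
probe_ray <- function(domain, from = 0.5, to = 2.5, by = 0.25, angle = 0) {
  r <- seq(from, to, by = by)
  tibble(label = sprintf("r%.3g", r),
         x = domain$excitation_center[1] + r * cos(angle),
         y = domain$excitation_center[2] + r * sin(angle))
}
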