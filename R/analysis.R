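check_uniform <- function(t, what = "trace") {
  if (length(t) < 2) abort(sprintf("%s must contain at least two samples", what))
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * max(1, abs(dt[1])))) {
    abort(sprintf("%s must be uniformly sampled", what))
  }
  dt[1]
}

roll_mean <- function(x, k) {
  # centred running mean over k samples (k odd), O(n) via cumsum
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (k - 1L) %/% 2L
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Threshold-episode detector with hysteresis: open at upward crossings of
# `on`, close when the signal falls below `on - hyst`; episodes separated
# by less than min_gap are merged. Returns start/end sample indices.
episodes_hysteresis <- function(x, on, hyst, t, min_gap) {
  n <- length(x)
  up <- which(x[-1] >= on & x[-n] < on) + 1L
  if (x[1] >= on) up <- c(1L, up)
  down <- which(x[-1] < on - hyst & x[-n] >= on - hyst) + 1L
  starts <- integer(0); ends <- integer(0); complete <- logical(0)
  pos <- 1L
  while (length(up) > 0 && pos <= n) {
    s <- up[up >= pos]
    if (length(s) == 0) break
    s <- s[1]
    e <- down[down > s]
    if (length(e) == 0) {
      starts <- c(starts, s); ends <- c(ends, n); complete <- c(complete, FALSE)
      break
    }
    e <- e[1]
    starts <- c(starts, s); ends <- c(ends, e); complete <- c(complete, TRUE)
    pos <- e + 1L
  }
  if (length(starts) > 1 && min_gap > 0) {
    keep <- rep(TRUE, length(starts))
    for (i in seq_along(starts)[-1]) {
      j <- max(which(keep[seq_len(i - 1)]))
      if (t[starts[i]] - t[ends[j]] < min_gap) {
        ends[j] <- ends[i]; complete[j] <- complete[i]; keep[i] <- FALSE
      }
    }
    starts <- starts[keep]; ends <- ends[keep]; complete <- complete[keep]
  }
  list(starts = starts, ends = ends, complete = complete)
}

#' Detect ictal discharges in a potassium trace
#'
#' An ictal discharge (ID) opens when the extracellular potassium crosses
#' `on_threshold` upward and closes when it falls below
#' `on_threshold - off_hysteresis`; episodes separated by less than
#' `min_gap` are merged (bursts within one ID chatter around threshold).
#' The potassium level itself gates the discharge in this model, so the
#' 4 mM default matches the initiation threshold of the dynamics.
#'
#' @param trace A data frame with columns `t` (s) and `K_o` (mM),
#'   uniformly sampled -- e.g. one element of a `sim_record`'s `probes`.
#' @param on_threshold Onset threshold (mM).
#' @param off_hysteresis Hysteresis below the onset threshold (mM).
#' @param min_gap Minimum separation between distinct events (s).
#' @return A tibble with one row per event: `onset_t`, `offset_t`,
#'   `duration`, `onset_K_o`, `peak_K_o`, `interval` (onset-to-onset gap
#'   from the previous event, NA for the first) and `complete` (`FALSE`
#'   if the trace ended mid-event).
#' @export
detect_discharges <- function(trace, on_threshold = 4, off_hysteresis = 0.5,
                              min_gap = 5) {
  if (is.null(trace$t) || is.null(trace$K_o)) {
    abort("`trace` needs columns `t` and `K_o`")
  }
  check_uniform(trace$t)
  ep <- episodes_hysteresis(trace$K_o, on_threshold, off_hysteresis,
                            trace$t, min_gap)
  if (length(ep$starts) == 0) {
    return(tibble(onset_t = numeric(0), offset_t = numeric(0),
                  duration = numeric(0), onset_K_o = numeric(0),
                  peak_K_o = numeric(0), interval = numeric(0),
                  complete = logical(0)))
  }
  onset <- trace$t[ep$starts]
  offset <- trace$t[ep$ends]
  peak <- vapply(seq_along(ep$starts), function(i)
    max(trace$K_o[ep$starts[i]:ep$ends[i]]), numeric(1))
  tibble(onset_t = onset, offset_t = offset, duration = offset - onset,
         onset_K_o = trace$K_o[ep$starts], peak_K_o = peak,
         interval = c(NA_real_, diff(onset)), complete = ep$complete)
}

#' Discharge onsets from the firing-rate envelope
#'
#' Detects ictal-discharge onsets from sustained elevation of the somatic
#' firing rate rather than from the potassium threshold, and reads off
#' the potassium concentration at those moments. This gives an
#' independent measurement of the ignition threshold: the rate envelope
#' defines "the discharge started", the potassium value is the observed
#' concentration at ignition.
#'
#' @param trace A probe tibble with columns `t`, `nu` and `K_o`.
#' @param rate_threshold Smoothed-rate threshold (Hz).
#' @param window Smoothing window for the rate envelope (s).
#' @param min_duration Minimum sustained duration to count as an ID (s);
#'   filters out isolated interictal bursts.
#' @param min_gap Merge gap between episodes (s).
#' @return A tibble with `onset_t`, `offset_t` and `onset_K_o`.
#' @export
rate_onsets <- function(trace, rate_threshold = 10, window = 2,
                        min_duration = 5, min_gap = 10) {
  dt <- check_uniform(trace$t)
  sm <- roll_mean(trace$nu, round(window / dt))
  ep <- episodes_hysteresis(sm, rate_threshold, rate_threshold / 2,
                            trace$t, min_gap)
  keep <- which((trace$t[ep$ends] - trace$t[ep$starts]) >= min_duration)
  # the centred smoothing advances the episode edge by up to window/2; the
  # onset proper is the first raw burst inside the sustained episode
  onset_idx <- vapply(keep, function(q) {
    rows <- ep$starts[q]:ep$ends[q]
    hit <- rows[trace$nu[rows] >= rate_threshold]
    if (length(hit) > 0) hit[1] else ep$starts[q]
  }, integer(1))
  tibble(onset_t = trace$t[onset_idx],
         offset_t = trace$t[ep$ends[keep]],
         onset_K_o = trace$K_o[onset_idx])
}

ray_cells <- function(domain, angle = 0) {
  ctr <- domain$excitation_center
  rmax <- sqrt(domain$width^2 + domain$height^2)
  r <- seq(domain$dx, rmax, by = domain$dx)
  x <- ctr[1] + r * cos(angle)
  y <- ctr[2] + r * sin(angle)
  ok <- x > 0 & x < domain$width & y > 0 & y < domain$height
  r <- r[ok]; x <- x[ok]; y <- y[ok]
  tibble(distance = r, x = x, y = y,
         i = pmin(domain$nx, pmax(1L, as.integer(ceiling(x / domain$dx)))),
         j = pmin(domain$ny, pmax(1L, as.integer(ceiling(y / domain$dx)))))
}

first_crossing_time <- function(series, times, threshold, fresh = TRUE) {
  n <- length(series)
  if (fresh) {
    # require a genuine upward crossing: the cell must be observed below
    # threshold inside the window first, so levels left over from a
    # previous wave are not scored as arrivals
    k <- which(series[-1] >= threshold & series[-n] < threshold)
    if (length(k) == 0) return(NA_real_)
    k <- k[1] + 1L
  } else {
    idx <- which(series >= threshold)
    if (length(idx) == 0) return(NA_real_)
    k <- idx[1]
    if (k == 1) return(times[1])
  }
  t0 <- times[k - 1]; t1 <- times[k]
  v0 <- series[k - 1]; v1 <- series[k]
  if (v1 == v0) return(t1)
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Wavefront arrival times along a ray
#'
#' For each grid cell along a ray from the excitation centre, the first
#' time (linearly interpolated between snapshots) at which the chosen
#' field crosses `threshold` within one discharge window. The window for
#' wave `n` is derived from the threshold episodes of the field at the
#' excitation centre: it opens shortly before the n-th onset there and
#' closes before the next one, so successive waves are measured
#' separately. Positions the wave never reaches are reported with
#' `t_arrive = NA` (missing, not an error).
#'
#' @param record A `sim_record` with snapshots.
#' @param threshold Crossing threshold (mM for `K_o`).
#' @param wave Which discharge wave to measure (1 = first).
#' @param angle Ray direction in radians (0 = +x).
#' @param window Optional explicit time window `c(t0, t1)` (s) overriding
#'   the wave-derived one.
#' @param field Snapshot field to threshold (default `"K_o"`).
#' @return A tibble `distance` (mm), `x`, `y`, `t_arrive` (s), with the
#'   window and threshold stored as attributes.
#' @export
front_arrival_times <- function(record, threshold = 4, wave = 1, angle = 0,
                                window = NULL, field = "K_o") {
  if (is.null(record$snapshots)) abort("record has no snapshots")
  snaps <- record$snapshots[[field]]
  times <- record$snapshots$t
  dom <- record$domain
  if (is.null(window)) {
    ci <- pmax(1L, as.integer(ceiling(dom$excitation_center[1] / dom$dx)))
    cj <- pmax(1L, as.integer(ceiling(dom$excitation_center[2] / dom$dx)))
    centre <- snaps[ci, cj, ]
    ep <- episodes_hysteresis(centre, threshold, 0.5, times, 5)
    if (length(ep$starts) < wave) {
      abort(sprintf("only %d discharge wave(s) found at the centre; wave = %d requested",
                    length(ep$starts), wave))
    }
    t0 <- times[ep$starts[wave]] - 5
    t1 <- if (length(ep$starts) > wave) times[ep$starts[wave + 1]] - 5 else
      times[length(times)]
    window <- c(t0, t1)
  }
  sel <- times >= window[1] & times <= window[2]
  ray <- ray_cells(dom, angle)
  ray$t_arrive <- vapply(seq_len(nrow(ray)), function(q)
    first_crossing_time(snaps[ray$i[q], ray$j[q], sel], times[sel], threshold),
    numeric(1))
  out <- ray[, c("distance", "x", "y", "t_arrive")]
  attr(out, "threshold") <- threshold
  attr(out, "window") <- window
  out
}

#' Arrival times of the sustained-activity envelope
#'
#' Like [front_arrival_times()], but thresholds the slow outer envelope of
#' burst activity: the time-averaged somatic rate (`nu_env`, the per-cell
#' mean rate between snapshots), additionally smoothed by a running mean
#' over `smooth` consecutive snapshots. Individual bursts reach far into
#' the penumbra almost instantaneously, so the instantaneous rate is not a
#' front; the *sustained* rate marks actual recruitment into the
#' discharge, and its translation is the slow wave that a blood-volume /
#' intrinsic-optical-signal-like measure would see.
#'
#' @param record A `sim_record` with snapshots.
#' @param rate_threshold Time-averaged-rate threshold (Hz).
#' @param smooth Running-mean window, in snapshots.
#' @param wave,angle,window As in [front_arrival_times()].
#' @return An arrivals tibble as in [front_arrival_times()].
#' @export
envelope_arrival_times <- function(record, rate_threshold = 5, smooth = 3,
                                   wave = 1, angle = 0, window = NULL) {
  if (is.null(record$snapshots)) abort("record has no snapshots")
  env <- record$snapshots$nu_env
  n <- dim(env)[3]
  if (smooth > 1) {
    sm <- array(0, dim(env))
    cnt <- 0
    for (s in 0:(smooth - 1)) {
      idx <- pmax(1L, seq_len(n) - s)
      sm <- sm + env[, , idx, drop = FALSE]
      cnt <- cnt + 1
    }
    env <- sm / cnt
  }
  rec2 <- record
  rec2$snapshots$nu_env_s <- env
  if (is.null(window)) {
    # derive the window from the potassium wave at the centre, as for K fronts
    fa <- front_arrival_times(record, threshold = 4, wave = wave, angle = angle)
    window <- attr(fa, "window")
  }
  front_arrival_times(rec2, threshold = rate_threshold, wave = wave,
                      angle = angle, window = window, field = "nu_env_s")
}

#' Fit a wavefront speed to arrival times
#'
#' Least-squares fit of radial position against arrival time over a fitted
#' radial range (default 0.5-2.5 mm: past the initiation disk, clear of
#' the boundary). The slope is the front speed.
#'
#' @param arrivals An arrivals tibble from [front_arrival_times()] or
#'   [envelope_arrival_times()] (columns `distance`, `t_arrive`), or any
#'   data frame with those columns.
#' @param fit_range Radial range `c(min, max)` (mm) used in the fit.
#' @return An object of class `wavefront_fit` with elements `speed`
#'   (mm/s), `n`, `sigma` (residual standard error, mm), `fit_range`,
#'   `arrivals` and the underlying `lm` fit. `tidy()` returns the fitted
#'   arrivals, `glance()` a one-row summary.
#' @examples
#' a <- tibble::tibble(distance = c(0, 2), t_arrive = c(0, 20))
#' wavefront_speed(a, fit_range = c(0, 2))$speed # 0.1 mm/s
#' @export
wavefront_speed <- function(arrivals, fit_range = c(0.5, 2.5)) {
  d <- as_tibble(arrivals)
  d <- d[!is.na(d$t_arrive) & d$distance >= fit_range[1] &
           d$distance <= fit_range[2], ]
  if (nrow(d) < 2) abort("need at least 2 valid arrivals inside `fit_range`")
  fit <- lm(distance ~ t_arrive, data = d)
  structure(list(
    speed = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n = nrow(d),
    sigma = summary(fit)$sigma,
    fit_range = fit_range,
    arrivals = d,
    fit = fit
  ), class = "wavefront_fit")
}

#' @export
print.wavefront_fit <- function(x, ...) {
  cat(sprintf("<wavefront_fit> speed = %.4g mm/s (%d arrivals, %.3g-%.3g mm, resid. SE %.3g mm)\n",
              x$speed, x$n, x$fit_range[1], x$fit_range[2], x$sigma))
  invisible(x)
}

#' @rdname tidy_ictalwave
#' @export
tidy.wavefront_fit <- function(x, ...) {
  mutate(x$arrivals, fitted = x$intercept + x$speed * .data$t_arrive,
         residual = .data$distance - .data$fitted)
}

#' @rdname tidy_ictalwave
#' @export
glance.wavefront_fit <- function(x, ...) {
  tibble(speed = x$speed, n = x$n, sigma = x$sigma,
         r_squared = summary(x$fit)$r.squared,
         range_min = x$fit_range[1], range_max = x$fit_range[2])
}

#' Space-time diagram of the membrane potential along a strip
#'
#' Extracts the fine-cadence y-t diagram of the membrane potential over
#' the configured vertical region of interest (see `strip_x` /
#' `strip_window` in [sim_config()]). The stripes of near-simultaneous
#' depolarisation across y are the interictal-like bursts composing an
#' ictal discharge; their inclination measures the burst propagation
#' delay per millimetre.
#'
#' @param record A `sim_record` with a strip capture.
#' @param window Optional `c(t0, t1)` subset (s).
#' @return An object of class `space_time_pattern`: list with `t`, `y`
#'   and the `length(t) x length(y)` matrix `V`.
#' @export
space_time_pattern <- function(record, window = NULL) {
  if (is.null(record$strip)) {
    abort("record has no strip capture; set recording$strip_x / strip_window")
  }
  t <- record$strip$t; V <- record$strip$V
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    if (!any(sel)) abort("`window` outside the captured strip interval")
    t <- t[sel]; V <- V[sel, , drop = FALSE]
  }
  structure(list(t = t, y = record$strip$y, x = record$strip$x, V = V),
            class = "space_time_pattern")
}

#' Per-burst front inclination of a space-time pattern
#'
#' Segments the y-t diagram into bursts (intervals where the
#' across-strip maximum potential exceeds `threshold`) and fits, for each
#' burst, the onset time against y. The slope (s/mm) is the burst-front
#' inclination: 0 for synchronous (vertical) stripes, `1/v` for a front
#' travelling at speed `v` along the strip.
#'
#' @param pattern A [space_time_pattern()] object.
#' @param threshold Burst threshold on V (mV); default 25 (the firing
#'   threshold).
#' @param min_fraction Minimum fraction of strip cells that must
#'   participate for a burst to be scored.
#' @return A tibble with one row per burst: `t_start`, `t_end`,
#'   `inclination` (s/mm), `abs_inclination`, `n_cells`.
#' @export
burst_inclination <- function(pattern, threshold = 25, min_fraction = 0.5) {
  amp <- apply(pattern$V, 1, max)
  above <- amp >= threshold
  if (!any(above)) {
    return(tibble(t_start = numeric(0), t_end = numeric(0),
                  inclination = numeric(0), abs_inclination = numeric(0),
                  n_cells = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bs <- starts[r$values]; be <- ends[r$values]
  purrr::map_dfr(seq_along(bs), function(b) {
    rows <- bs[b]:be[b]
    onset <- vapply(seq_along(pattern$y), function(jj)
      first_crossing_time(pattern$V[rows, jj], pattern$t[rows], threshold,
                          fresh = FALSE),
      numeric(1))
    ok <- !is.na(onset)
    if (sum(ok) < max(2, min_fraction * length(onset))) return(NULL)
    slope <- unname(coef(lm(onset[ok] ~ pattern$y[ok]))[2])
    tibble(t_start = pattern$t[bs[b]], t_end = pattern$t[be[b]],
           inclination = slope, abs_inclination = abs(slope),
           n_cells = sum(ok))
  })
}

onset_times <- function(t, x, threshold, refractory) {
  n <- length(x)
  up <- which(x[-1] >= threshold & x[-n] < threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  keep <- c(TRUE, diff(t[up]) >= refractory)
  # enforce the refractory period sequentially
  out <- numeric(0); last <- -Inf
  for (tt in t[up]) {
    if (tt - last >= refractory) { out <- c(out, tt); last <- tt }
  }
  out
}

match_delays <- function(ta, tb, max_lag) {
  if (length(ta) == 0 || length(tb) == 0) return(numeric(0))
  d <- vapply(ta, function(tt) tb[which.min(abs(tb - tt))] - tt, numeric(1))
  d[abs(d) <= max_lag]
}

#' Burst and discharge synchrony between probes
#'
#' Compares event onsets between probe pairs at two time scales: the fast
#' interictal-like bursts (upward threshold crossings of the signal,
#' sub-second refractory) and the slow ictal-discharge onsets (sustained
#' elevation of the smoothed signal). In the synaptic model the bursts
#' are near-simultaneous across millimetres while discharge onsets lag by
#' seconds per millimetre -- the core core/penumbra timing signature.
#'
#' @param traces Long tibble with columns `probe`, `t` and the signal
#'   column (e.g. from `tidy(record)`).
#' @param value Name of the signal column (default `"phi"`).
#' @param burst_threshold Threshold for fast-burst onsets (signal units).
#' @param refractory Fast-burst refractory period (s).
#' @param max_lag Maximum pairing lag for fast bursts (s).
#' @param id_window Smoothing window for discharge onsets (s).
#' @param id_min_duration Minimum sustained duration of a discharge (s).
#' @param id_max_lag Maximum pairing lag for discharge onsets (s).
#' @return A tibble with one row per ordered probe pair and event kind:
#'   `probe_a`, `probe_b`, `kind` (`"burst"` or `"discharge"`), `n`,
#'   `mean_delay`, `mean_abs_delay`, `max_abs_delay` (s).
#' @export
burst_synchrony <- function(traces, value = "phi", burst_threshold = 10,
                            refractory = 0.2, max_lag = 1,
                            id_window = 2, id_min_duration = 5,
                            id_max_lag = 30) {
  if (is.null(traces$probe) || is.null(traces$t) || is.null(traces[[value]])) {
    abort(sprintf("`traces` needs columns `probe`, `t`, `%s`", value))
  }
  probes <- unique(traces$probe)
  if (length(probes) < 2) abort("need at least 2 probes")
  per <- lapply(probes, function(p) {
    d <- traces[traces$probe == p, ]
    d <- d[order(d$t), ]
    dt <- check_uniform(d$t, sprintf("probe %s", p))
    sm <- roll_mean(d[[value]], round(id_window / dt))
    ep <- episodes_hysteresis(sm, burst_threshold, burst_threshold / 2,
                              d$t, id_min_duration)
    keep <- (d$t[ep$ends] - d$t[ep$starts]) >= id_min_duration
    list(bursts = onset_times(d$t, d[[value]], burst_threshold, refractory),
         ids = d$t[ep$starts[keep]])
  })
  names(per) <- probes
  out <- list()
  for (a in seq_along(probes)) {
    for (b in seq_along(probes)) {
      if (a >= b) next
      for (kind in c("burst", "discharge")) {
        dd <- if (kind == "burst") {
          match_delays(per[[a]]$bursts, per[[b]]$bursts, max_lag)
        } else {
          match_delays(per[[a]]$ids, per[[b]]$ids, id_max_lag)
        }
        out[[length(out) + 1]] <- tibble(
          probe_a = probes[a], probe_b = probes[b], kind = kind,
          n = length(dd),
          mean_delay = if (length(dd)) mean(dd) else NA_real_,
          mean_abs_delay = if (length(dd)) mean(abs(dd)) else NA_real_,
          max_abs_delay = if (length(dd)) max(abs(dd)) else NA_real_)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Electrodiffusion transport speed estimate
#'
#' Order-of-magnitude speed at which an extracellular voltage gradient
#' would advect potassium ions: `v = u_K * V'`, converted to mm/s. With
#' typical mobility and local-field gradients this is a few micrometres
#' per second -- negligible against observed seizure propagation, which
#' justifies omitting electrodiffusion from the transport model.
#'
#' @param u_K Ion mobility (cm^2 / (s V)).
#' @param voltage_gradient Extracellular voltage gradient (mV per mm).
#' @return Speed (mm/s).
#' @examples
#' electrodiffusion_speed(5e-4, 20) # 1e-3 mm/s = 1 um/s
#' @export
electrodiffusion_speed <- function(u_K, voltage_gradient) {
  if (any(u_K <= 0)) abort("`u_K` must be positive")
  u_K * 100 * voltage_gradient / 1000
}

#' Sensitivity of a Nernst potential to its concentration
#'
#' `|dV/dc| = 26.6 / c` mV per mM: the leverage a 1 mM concentration
#' change has on the corresponding reversal potential. Used to justify
#' holding the high-concentration species (intracellular potassium,
#' extracellular sodium/chloride, all near 130 mM: 0.2 mV/mM) constant
#' while tracking the low-concentration ones (e.g. extracellular
#' potassium near 7 mM: 3.8 mV/mM).
#'
#' @param concentration Ion concentration (mM); vectorised.
#' @return Sensitivity (mV/mM).
#' @examples
#' nernst_sensitivity(c(7, 10, 130)) # 3.8, 2.7, 0.2 (approximately)
#' @export
nernst_sensitivity <- function(concentration) {
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    abort("`concentration` must be finite and positive (mM)")
  }
  26.6 / concentration
}
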