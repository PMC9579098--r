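# Parametric sound field: point sources (impulsive seismic shots, continuous
# vessel noise) with geometric-spreading + absorption propagation, evaluated
# as 30-s sound exposure levels (SEL_30s, dB re 1 uPa^2 s) and RMS sound
# pressure levels (SPL, dB re 1 uPa^2) at any position and time.

#' Energy sum of decibel levels
#'
#' Combines levels on the energy scale: `10 * log10(sum(10^(db/10)))`.
#' `NA`/`-Inf` entries contribute zero energy; an all-missing input returns
#' `NA`.
#'
#' @param db Numeric vector of decibel levels.
#' @return A single combined level (dB).
#' @export
sel_sum <- function(db) {
  db <- db[is.finite(db)]
  if (length(db) == 0L) return(NA_real_)
  m <- max(db)  # factor out the peak for numerical stability
  m + 10 * log10(sum(10^((db - m) / 10)))
}

#' Construct a parametric sound field
#'
#' The field holds per-source emission schedules and a one-slope propagation
#' law `RL(r) = SL - N * log10(r_m) - alpha * r_km`, with the range clamped
#' to the 1-m reference. Seismic sources emit impulses on a shot schedule
#' (source level = per-shot SEL at 1 m); vessel sources emit continuously
#' (source level = SEL over a 30-s window at 1 m). SPL is reported as
#' `SEL_30s - 10 * log10(30)`.
#'
#' @param shots data.frame of impulsive emissions: columns `source_id`,
#'   `time` (s), `x`, `y` (km), `sl` (per-shot SEL at 1 m, dB re 1 uPa^2 s).
#'   May have zero rows.
#' @param vessel_tracks data.frame of continuous sources sampled in time:
#'   columns `vessel_id`, `type`, `time` (s), `x`, `y` (km), `sl` (30-s SEL
#'   at 1 m). Positions are interpolated linearly in time. May have zero
#'   rows. Rows with `type == "seismic"` describe the shooting vessels'
#'   movement and are ignored as continuous sources.
#' @param spreading_n Geometric spreading coefficient N (dB per decade of
#'   range), default 20 (spherical).
#' @param absorption_db_km Linear absorption/scattering loss (dB/km),
#'   default 1.
#' @return An object of class `brs_sound_field`.
#' @export
sound_field <- function(shots = NULL, vessel_tracks = NULL,
                        spreading_n = 20, absorption_db_km = 1) {
  empty_shots <- data.frame(source_id = character(), time = numeric(),
                            x = numeric(), y = numeric(), sl = numeric())
  empty_ves <- data.frame(vessel_id = character(), type = character(),
                          time = numeric(), x = numeric(), y = numeric(),
                          sl = numeric())
  if (is.null(shots)) shots <- empty_shots
  if (is.null(vessel_tracks)) vessel_tracks <- empty_ves
  stopifnot(all(c("time", "x", "y", "sl") %in% names(shots)))
  if (nrow(vessel_tracks))
    stopifnot(all(c("vessel_id", "time", "x", "y", "sl") %in% names(vessel_tracks)))
  structure(list(shots = shots, vessel_tracks = vessel_tracks,
                 spreading_n = spreading_n,
                 absorption_db_km = absorption_db_km),
            class = "brs_sound_field")
}

#' @export
print.brs_sound_field <- function(x, ...) {
  nv <- if (nrow(x$vessel_tracks)) length(unique(x$vessel_tracks$vessel_id)) else 0L
  cat(sprintf(
    "Parametric sound field: %d shots, %d vessel source(s); RL = SL - %g log10(r) - %g r_km\n",
    nrow(x$shots), nv, x$spreading_n, x$absorption_db_km))
  invisible(x)
}

# Received level of a source of level `sl` at range `r_km`, clamped to the
# 1-m reference.
received_level <- function(sl, r_km, spreading_n, absorption_db_km) {
  r_m <- pmax(r_km * 1000, 1)
  sl - spreading_n * log10(r_m) - absorption_db_km * (r_m / 1000)
}

# Linear interpolation of a vessel's position at arbitrary times (constant
# extrapolation at the ends, NA outside an empty track).
interp_vessel <- function(track, times) {
  if (nrow(track) < 2L)
    return(data.frame(x = rep(track$x[1], length(times)),
                      y = rep(track$y[1], length(times))))
  data.frame(
    x = stats::approx(track$time, track$x, xout = times, rule = 2)$y,
    y = stats::approx(track$time, track$y, xout = times, rule = 2)$y)
}

#' Evaluate a sound field at a position and 30-s window
#'
#' Returns per-source-type and combined exposure for the window
#' `[time, time + window)`. Seismic SEL is the energy sum of every shot in
#' the window at its shot-time range; vessel SEL uses the mid-window range
#' per vessel, energy-summed over vessels; the combined level is the energy
#' sum of both types. A type with no active source gives `NA`.
#'
#' @param field A [sound_field()].
#' @param x,y Receiver position (km, station-local plane). Scalars or equal
#'   length vectors (one window per element).
#' @param time Window start time(s), s.
#' @param window Window length, s (default 30).
#' @return data.frame with columns `time`, `sel_seismic`, `sel_vessel`,
#'   `sel_total`, `spl_seismic`, `spl_vessel`, `spl_total` and `n_shots`.
#' @export
evaluate_sound_field <- function(field, x, y, time, window = 30) {
  stopifnot(inherits(field, "brs_sound_field"))
  n <- max(length(x), length(time))
  x <- rep_len(x, n); y <- rep_len(y, n); time <- rep_len(time, n)
  cont <- field$vessel_tracks
  cont <- if (nrow(cont)) cont[cont$type != "seismic" | is.na(cont$type), , drop = FALSE] else cont
  by_ves <- if (nrow(cont)) split(cont, cont$vessel_id) else list()

  sel_s <- sel_v <- rep(NA_real_, n)
  n_shots <- integer(n)
  for (i in seq_len(n)) {
    sh <- field$shots
    if (nrow(sh)) {
      inwin <- sh$time >= time[i] & sh$time < time[i] + window
      n_shots[i] <- sum(inwin)
      if (n_shots[i] > 0) {
        r <- sqrt((sh$x[inwin] - x[i])^2 + (sh$y[inwin] - y[i])^2)
        sel_s[i] <- sel_sum(received_level(sh$sl[inwin], r,
                                           field$spreading_n,
                                           field$absorption_db_km))
      }
    }
    if (length(by_ves)) {
      mid <- time[i] + window / 2
      lv <- vapply(by_ves, function(tr) {
        p <- interp_vessel(tr, mid)
        sl <- tr$sl[1]
        received_level(sl, sqrt((p$x - x[i])^2 + (p$y - y[i])^2),
                       field$spreading_n, field$absorption_db_km)
      }, numeric(1))
      sel_v[i] <- sel_sum(lv)
    }
  }
  tot <- vapply(seq_len(n), function(i) sel_sum(c(sel_s[i], sel_v[i])), numeric(1))
  spl_off <- 10 * log10(window)
  data.frame(time = time,
             sel_seismic = sel_s, sel_vessel = sel_v, sel_total = tot,
             spl_seismic = sel_s - spl_off, spl_vessel = sel_v - spl_off,
             spl_total = tot - spl_off, n_shots = n_shots)
}
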