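# Explanatory variables per bin: 30-s acoustic exposure steps along the
# whale path, cumulative SEL, vessel-geometry covariates, and the join that
# produces the analysis-ready bin table.

#' Exposure series along a whale path
#'
#' Evaluates the sound field at interpolated 30-s whale positions over the
#' span of the position series; per-source-type values are kept separate.
#'
#' @param positions data.frame with `time` (s), `x`, `y` (km) for one
#'   whale/track.
#' @param field A [sound_field()].
#' @param step_s Exposure step (s, default 30).
#' @return data.frame: `time`, `x`, `y`, `sel_seismic`, `sel_vessel`,
#'   `sel_total`, `spl_seismic`, `spl_vessel`, `spl_total`.
#' @export
exposure_series <- function(positions, field, step_s = 30) {
  tt <- seq(min(positions$time), max(positions$time), by = step_s)
  x <- stats::approx(positions$time, positions$x, xout = tt)$y
  y <- stats::approx(positions$time, positions$y, xout = tt)$y
  ex <- evaluate_sound_field(field, x, y, tt, window = step_s)
  cbind(data.frame(time = tt, x = x, y = y),
        ex[c("sel_seismic", "sel_vessel", "sel_total",
             "spl_seismic", "spl_vessel", "spl_total")])
}

#' Accumulate SEL along a track
#'
#' Energy-sum accumulation from the start of the track:
#' `cSEL_k = 10 log10(sum_{i<=k} 10^(SEL_i/10))`. Missing steps contribute
#' no energy; the result is missing until the first finite step.
#' Accumulation restarts at track boundaries, never at bin boundaries.
#'
#' @param sel Numeric vector of per-step SEL (dB), `NA` allowed.
#' @return Numeric vector of cumulative SEL (dB), same length.
#' @export
accumulate_csel <- function(sel) {
  n <- length(sel)
  out <- rep(NA_real_, n)
  acc <- 0; seen <- FALSE
  for (i in seq_len(n)) {
    if (is.finite(sel[i])) { acc <- acc + 10^(sel[i] / 10); seen <- TRUE }
    if (seen) out[i] <- 10 * log10(acc)
  }
  out
}

#' Vessel-geometry covariates at one epoch
#'
#' @param x,y Whale position (km).
#' @param heading_deg Whale movement azimuth (deg clockwise from north), or
#'   `NA`.
#' @param vessel_tracks Vessel positions (`vessel_id`, `type`, `time`, `x`,
#'   `y`); may be empty.
#' @param time Epoch (s).
#' @return One-row data.frame: `cv_dist_km` (closest vessel, any type),
#'   `sv_dist_km` (closest seismic vessel), `n_vessels`, `row_deg`
#'   (relative orientation of whale movement to the closest vessel, folded
#'   to `[0, 180]`). Empty fleet gives `NA` distances/ROW and count 0.
#' @export
vessel_covariates <- function(x, y, heading_deg, vessel_tracks, time) {
  if (is.null(vessel_tracks) || !nrow(vessel_tracks))
    return(data.frame(cv_dist_km = NA_real_, sv_dist_km = NA_real_,
                      n_vessels = 0L, row_deg = NA_real_))
  vp <- vessel_positions_at(vessel_tracks, time)
  d <- sqrt((vp$x - x)^2 + (vp$y - y)^2)
  j <- which.min(d)
  row <- if (is.na(heading_deg)) NA_real_ else
    fold180(heading_deg - azimuth_deg(vp$x[j] - x, vp$y[j] - y))
  js <- which(vp$type == "seismic")
  sv <- if (length(js)) min(d[js]) else NA_real_
  data.frame(cv_dist_km = d[j], sv_dist_km = sv,
             n_vessels = nrow(vp), row_deg = row)
}

#' Assemble the analysis-ready bin covariate table
#'
#' Joins per-bin exposure summaries, vessel geometry and environment onto a
#' movement-bin table. The bin-level SEL summary is the energy mean of the
#' bin's 30-s steps (21 per 10.5-min bin); cSEL is the accumulated value at
#' the bin end (accumulation restarting per track); vessel distances are
#' the bin minimum over the bin's epochs; depth and tide are taken at the
#' bin midpoint.
#'
#' @param mbins Output of [movement_bins()].
#' @param exposure Named list (by `track_id`) of [exposure_series()]
#'   outputs, or `NULL`.
#' @param vessel_tracks Vessel position data.frame or `NULL`.
#' @param env Environment list as from [simulate_environment()] (`tide`
#'   function, `depth` function), or `NULL`.
#' @param sel_summary `"energy_mean"` (default) or `"max"`.
#' @return `mbins` with added columns `seis_sel`, `ves_sel`, `seis_csel`,
#'   `ves_csel`, `cv_dist_km`, `sv_dist_km`, `n_vessels`, `depth_m`,
#'   `tide_m`, `hour`.
#' @export
assemble_bin_covariates <- function(mbins, exposure = NULL,
                                    vessel_tracks = NULL, env = NULL,
                                    sel_summary = c("energy_mean", "max")) {
  sel_summary <- match.arg(sel_summary)
  if (is.null(mbins) || !nrow(mbins)) return(mbins)
  n <- nrow(mbins)
  mbins$seis_sel <- mbins$ves_sel <- NA_real_
  mbins$seis_csel <- mbins$ves_csel <- NA_real_
  mbins$depth_m <- mbins$tide_m <- NA_real_

  summarize_sel <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    if (sel_summary == "max") max(v) else
      10 * log10(mean(10^(v / 10)))
  }

  if (!is.null(exposure)) {
    for (tid in unique(mbins$track_id)) {
      ex <- exposure[[tid]]
      if (is.null(ex)) next
      ex$csel_seis <- accumulate_csel(ex$sel_seismic)
      ex$csel_ves <- accumulate_csel(ex$sel_vessel)
      rows <- which(mbins$track_id == tid)
      for (i in rows) {
        k <- ex$time >= mbins$t_start[i] & ex$time < mbins$t_end[i]
        if (!any(k)) next
        mbins$seis_sel[i] <- summarize_sel(ex$sel_seismic[k])
        mbins$ves_sel[i] <- summarize_sel(ex$sel_vessel[k])
        last <- max(which(k))
        mbins$seis_csel[i] <- ex$csel_seis[last]
        mbins$ves_csel[i] <- ex$csel_ves[last]
      }
    }
  }

  if (!is.null(vessel_tracks) && nrow(vessel_tracks)) {
    # bin-minimum distances over the bin's 30-s epochs; count and ROW come
    # from the midpoint (already in mbins when vessels were passed to
    # movement_bins)
    for (i in seq_len(n)) {
      tt <- seq(mbins$t_start[i], mbins$t_end[i], by = 30)
      xt <- stats::approx(c(mbins$t_start[i], mbins$t_end[i]),
                          c(mbins$x_mid[i], mbins$x_mid[i]), xout = tt, rule = 2)$y
      # exposure positions are better when available; fall back to midpoint
      if (!is.null(exposure) && !is.null(exposure[[mbins$track_id[i]]])) {
        ex <- exposure[[mbins$track_id[i]]]
        k <- ex$time >= mbins$t_start[i] & ex$time <= mbins$t_end[i]
        if (any(k)) { tt <- ex$time[k]; xt <- ex$x[k]; yt <- ex$y[k] }
        else yt <- rep(mbins$y_mid[i], length(tt))
      } else yt <- rep(mbins$y_mid[i], length(tt))
      dmin <- Inf; smin <- Inf
      for (j in seq_along(tt)) {
        vp <- vessel_positions_at(vessel_tracks, tt[j])
        d <- sqrt((vp$x - xt[j])^2 + (vp$y - yt[j])^2)
        dmin <- min(dmin, d)
        if (any(vp$type == "seismic"))
          smin <- min(smin, d[vp$type == "seismic"])
      }
      mbins$cv_dist_km[i] <- if (is.finite(dmin)) dmin else NA_real_
      mbins$sv_dist_km[i] <- if (is.finite(smin)) smin else NA_real_
    }
    mbins$n_vessels <- length(unique(vessel_tracks$vessel_id))
  } else {
    mbins$n_vessels <- 0L
  }

  if (!is.null(env)) {
    mbins$depth_m <- env$depth(mbins$x_mid, mbins$y_mid)
    mbins$tide_m <- env$tide(mbins$t_mid)
  }
  mbins$hour <- (mbins$t_mid / 3600) %% 24
  mbins
}
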