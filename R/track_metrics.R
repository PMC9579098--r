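# Track standardization and movement response variables: 90-s resampling of
# raw position series and 10.5-min (7-step) bins of path metrics.

#' Resample a position series on a fixed-interval criterion
#'
#' Linear interpolation at exact `interval`-second epochs from the start of
#' each gap-free segment. Raw-fix gaps longer than `max_gap_s` split the
#' track into separate sub-tracks (suffix `.1`, `.2`, ...); interpolation
#' never extrapolates beyond the raw fixes.
#'
#' @param positions data.frame with columns `time` (s), `x`, `y` (km) and
#'   optionally `state` and `whale_id`; one whale per call.
#' @param interval Resampling interval, s (default 90, the standard step
#'   criterion for shore-based tracks).
#' @param max_gap_s Maximum tolerated raw gap before splitting (default
#'   600 s).
#' @return data.frame with columns `track_id`, `time`, `x`, `y`, `state`
#'   (state of the nearest raw fix, `NA` if absent); `NULL` with a warning
#'   for single-fix tracks.
#' @export
resample_track <- function(positions, interval = 90, max_gap_s = 600) {
  positions <- positions[order(positions$time), , drop = FALSE]
  if (nrow(positions) < 2L) {
    warning("track has fewer than 2 fixes; rejected")
    return(NULL)
  }
  wid <- if ("whale_id" %in% names(positions)) positions$whale_id[1] else "w"
  gaps <- diff(positions$time)
  seg <- cumsum(c(1L, as.integer(gaps > max_gap_s)))
  out <- list()
  for (s in unique(seg)) {
    p <- positions[seg == s, , drop = FALSE]
    if (nrow(p) < 2L) next
    tt <- seq(p$time[1], p$time[nrow(p)], by = interval)
    x <- stats::approx(p$time, p$x, xout = tt)$y
    y <- stats::approx(p$time, p$y, xout = tt)$y
    st <- if ("state" %in% names(p)) {
      idx <- vapply(tt, function(t0) which.min(abs(p$time - t0)), integer(1))
      p$state[idx]
    } else NA_character_
    out[[length(out) + 1L]] <- data.frame(
      track_id = paste0(wid, ".", s), time = tt, x = x, y = y, state = st)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "interval") <- interval
  res
}

# Azimuth (deg clockwise from north) of displacement (dx, dy).
azimuth_deg <- function(dx, dy) (atan2(dx, dy) * 180 / pi) %% 360

# Absolute angular difference folded to [0, 180].
fold180 <- function(a) {
  d <- abs(a) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Mean resultant length of angles (degrees).
mean_resultant_length <- function(deg) {
  r <- deg * pi / 180
  sqrt(mean(cos(r))^2 + mean(sin(r))^2)
}

#' Compute movement response variables over fixed bins
#'
#' Consecutive non-overlapping bins of `steps_per_bin` resampled steps
#' (default 7 x 90 s = 10.5 min; trailing partial bins are discarded). Per
#' bin:
#'
#' * `spd` — cumulative step length / bin duration (km/h);
#' * `lin` — linearity: net displacement / cumulative length, in `[0, 1]`;
#' * `rr` — reorientation rate: total absolute heading change / bin minutes
#'   (deg/min);
#' * `mdir` — mean resultant length of the step headings, in `[0, 1]`;
#' * `trk_r` — directionality index: mean resultant length of the turning
#'   angles, in `[0, 1]`;
#' * `range_km` — range index: maximum pairwise distance among the bin's
#'   positions;
#' * `dir_deg`, `cos_dir`, `sin_dir` — azimuth of the net displacement
#'   (deg clockwise from north) and its cosine/sine; undefined (NA) when
#'   the net displacement is zero;
#' * `shore_km` — distance from shore at the bin midpoint (if a shoreline
#'   is supplied);
#' * `row_cv`, `row_sv` — relative orientation of whale movement to the
#'   closest vessel of any type / closest seismic vessel at the bin
#'   midpoint: |net-movement azimuth - whale-to-vessel bearing| folded to
#'   `[0, 180]` (0 = toward, 180 = away);
#' * `state` — modal behavior state of the bin's positions (ties ->
#'   `"mixed"`).
#'
#' @param rtrack Output of [resample_track()] (or any data.frame with
#'   `track_id`, `time`, `x`, `y`, optional `state`).
#' @param vessel_tracks Optional vessel position data.frame (`vessel_id`,
#'   `type`, `time`, `x`, `y`) for the ROW variables.
#' @param shoreline Optional shoreline polyline (`x`, `y`).
#' @param steps_per_bin Steps per bin (default 7).
#' @param interval Step interval, s (default the `rtrack` attribute or 90).
#' @return data.frame, one row per bin, with the columns above plus
#'   `track_id`, `whale_id`, `bin`, `t_start`, `t_mid`, `t_end`.
#' @export
movement_bins <- function(rtrack, vessel_tracks = NULL, shoreline = NULL,
                          steps_per_bin = 7L, interval = NULL) {
  if (is.null(rtrack) || nrow(rtrack) < steps_per_bin + 1L)
    return(NULL)
  if (is.null(interval))
    interval <- attr(rtrack, "interval") %||% 90
  npos <- steps_per_bin + 1L
  out <- list()
  for (tid in unique(rtrack$track_id)) {
    tr <- rtrack[rtrack$track_id == tid, , drop = FALSE]
    nbins <- (nrow(tr) - 1L) %/% steps_per_bin
    if (nbins < 1L) next
    for (b in seq_len(nbins)) {
      i0 <- (b - 1L) * steps_per_bin + 1L
      p <- tr[i0:(i0 + steps_per_bin), , drop = FALSE]
      out[[length(out) + 1L]] <-
        cbind(data.frame(track_id = tid,
                         whale_id = sub("\\.[0-9]+$", "", tid),
                         bin = b),
              bin_metrics(p, vessel_tracks, shoreline, interval))
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Metrics for one bin of (steps_per_bin + 1) positions.
bin_metrics <- function(p, vessel_tracks, shoreline, interval) {
  n <- nrow(p)
  dur_min <- (p$time[n] - p$time[1]) / 60
  dx <- diff(p$x); dy <- diff(p$y)
  stepl <- sqrt(dx^2 + dy^2)
  cum <- sum(stepl)
  net <- sqrt((p$x[n] - p$x[1])^2 + (p$y[n] - p$y[1])^2)
  hd <- azimuth_deg(dx, dy)
  turns <- ((diff(hd) + 180) %% 360) - 180   # signed turning angles (-180, 180]
  d2max <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d2max <- max(d2max, (p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2)

  dir <- if (net > 0) azimuth_deg(p$x[n] - p$x[1], p$y[n] - p$y[1]) else NA_real_
  tmid <- (p$time[1] + p$time[n]) / 2
  xm <- stats::approx(p$time, p$x, xout = tmid)$y
  ym <- stats::approx(p$time, p$y, xout = tmid)$y

  row_cv <- row_sv <- cv_dist <- sv_dist <- NA_real_
  if (!is.null(vessel_tracks) && nrow(vessel_tracks)) {
    vp <- vessel_positions_at(vessel_tracks, tmid)
    d <- sqrt((vp$x - xm)^2 + (vp$y - ym)^2)
    j <- which.min(d)
    cv_dist <- d[j]
    if (!is.na(dir))
      row_cv <- fold180(dir - azimuth_deg(vp$x[j] - xm, vp$y[j] - ym))
    js <- which(vp$type == "seismic")
    if (length(js)) {
      jj <- js[which.min(d[js])]
      sv_dist <- d[jj]
      if (!is.na(dir))
        row_sv <- fold180(dir - azimuth_deg(vp$x[jj] - xm, vp$y[jj] - ym))
    }
  }
  shore <- if (!is.null(shoreline)) distance_from_shore(xm, ym, shoreline) else NA_real_

  state <- NA_character_
  if ("state" %in% names(p) && !all(is.na(p$state))) {
    tab <- table(p$state)
    mx <- which(tab == max(tab))
    state <- if (length(mx) > 1L) "mixed" else names(tab)[mx]
  }

  data.frame(t_start = p$time[1], t_mid = tmid, t_end = p$time[n],
             spd = cum / (dur_min / 60),
             lin = if (cum > 0) net / cum else 0,
             rr = sum(abs(turns)) / dur_min,
             mdir = mean_resultant_length(hd),
             trk_r = mean_resultant_length(turns),
             range_km = sqrt(d2max),
             dir_deg = dir,
             cos_dir = if (is.na(dir)) NA_real_ else cos(dir * pi / 180),
             sin_dir = if (is.na(dir)) NA_real_ else sin(dir * pi / 180),
             shore_km = shore,
             row_cv = row_cv, row_sv = row_sv,
             cv_dist_km = cv_dist, sv_dist_km = sv_dist,
             x_mid = xm, y_mid = ym,
             state = state)
}

# Positions of every vessel at one time (linear interpolation per vessel).
vessel_positions_at <- function(vessel_tracks, time) {
  sp <- split(vessel_tracks, vessel_tracks$vessel_id)
  do.call(rbind, lapply(sp, function(tr) {
    p <- interp_vessel(tr, time)
    data.frame(vessel_id = tr$vessel_id[1],
               type = if ("type" %in% names(tr)) tr$type[1] else "support",
               x = p$x, y = p$y)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
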