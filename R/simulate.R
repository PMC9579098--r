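# Synthetic-data generator: state-switching correlated-random-walk whale
# tracks with dive/surfacing respiration cycles, seismic line acquisition
# with shot schedules, support-vessel traffic, a parametric sound field,
# tide/bathymetry/shoreline environment, benthic prey fields, an injectable
# dose-response effect, and the theodolite observation process. Everything
# is reproducible from the configuration seed.

.BRS_STATES <- c("feeding", "feed_travel", "traveling", "mixed")

#' Default behavior-state transition matrix
#'
#' A reversible 4-state Markov matrix (per 30-s step) with stationary
#' distribution `pi` and switching intensity `eps`: off-diagonal
#' `P[i,j] = eps * pi[j]`, diagonal the complement. The default stationary
#' distribution matches a typical foraging-season activity budget on the
#' Sakhalin feeding grounds (26% feeding, 33% feeding/traveling, 30%
#' traveling, 11% mixed) and `eps = 0.02` gives mean state dwell times of
#' roughly half an hour.
#'
#' @param pi Stationary probabilities over
#'   (feeding, feed_travel, traveling, mixed); must sum to 1.
#' @param eps Switching intensity per step, in (0, 1].
#' @return A 4x4 row-stochastic matrix with dimnames.
#' @export
default_transition <- function(pi = c(0.26, 0.33, 0.30, 0.11), eps = 0.02) {
  stopifnot(length(pi) == 4L, abs(sum(pi) - 1) < 1e-12, eps > 0, eps <= 1)
  P <- eps * matrix(pi, 4, 4, byrow = TRUE)
  diag(P) <- 0
  diag(P) <- 1 - rowSums(P)
  dimnames(P) <- list(.BRS_STATES, .BRS_STATES)
  P
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param P Row-stochastic matrix.
#' @return Stationary probability vector (left eigenvector of eigenvalue 1).
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic study: behavior-state dynamics,
#' per-state movement and respiration regimes, seismic/vessel fleet
#' geometry, sound propagation, response injection, the observation station
#' and environment. Defaults emulate a nearshore shallow-shelf gray-whale
#' feeding ground monitored from a coastal tower during a summer seismic
#' survey: whales concentrated within a few km of a north-south shoreline,
#' a source vessel acquiring parallel lines offshore, and exposures spanning
#' roughly 55-170 dB re 1 uPa^2 s SEL_30s.
#'
#' Movement per state uses log-normal step speeds and wrapped-normal turning
#' angles; respiration alternates gamma-distributed dives with surfacings of
#' `1 + Poisson` blows separated by gamma inter-blow intervals. Feeding is
#' parameterized with longer dives and shorter inter-blow intervals than
#' traveling, the canonical benthic-foraging pattern.
#'
#' @param seed Integer seed; every generator call derives its stream from it.
#' @param duration_h Simulated duration (hours).
#' @param n_whales Number of whales.
#' @param step_s Internal movement/exposure step (s); default 30, matching
#'   the SEL_30s cadence.
#' @param state_transition 4x4 row-stochastic matrix over
#'   (feeding, feed_travel, traveling, mixed), per step.
#' @param initial_state Optional fixed initial state name; default samples
#'   from the stationary distribution.
#' @param speed_mean_kmh,speed_sdlog Per-state mean step speed (km/h) and
#'   log-sd of the log-normal speed distribution.
#' @param turn_sd_deg Per-state sd of the wrapped-normal turning angle
#'   (degrees per step); small = directional.
#' @param dive_mean_s,dive_shape Per-state mean dive duration (s) and the
#'   common gamma shape.
#' @param blows_per_surfacing Per-state mean number of blows per surfacing
#'   (>= 1).
#' @param ibi_mean_s,ibi_shape Per-state mean inter-blow interval (s) and
#'   common gamma shape.
#' @param n_seismic,n_support Fleet sizes.
#' @param line_length_km,n_lines,line_spacing_km,line_heading_deg,
#'   seismic_x0_km,seismic_y0_km Seismic racetrack geometry (lines parallel
#'   to `line_heading_deg`, offset along its normal, block anchored
#'   `seismic_x0_km` east / `seismic_y0_km` north of the station).
#' @param seismic_speed_kn,support_speed_kn Vessel speeds (knots).
#' @param shot_interval_s Shot interval while on-line (s).
#' @param seismic_sl Per-shot SEL at 1 m (dB re 1 uPa^2 s).
#' @param vessel_sl Continuous-source 30-s SEL at 1 m (dB re 1 uPa^2 s).
#' @param spreading_n,absorption_db_km Propagation law coefficients.
#' @param effect Injected dose-response: one of `"none"`, `"speed"`,
#'   `"heading"`, `"respiration"`.
#' @param effect_threshold_db,effect_slope Exposure threshold (dB SEL_30s)
#'   and linear slope per dB above it (log-speed per dB, heading weight per
#'   dB, or log-IBI per dB).
#' @param station_lat,station_lon,station_height_m,station_ref_azimuth_deg,
#'   station_max_range_km Observation station; heights of 10.8-23.7 m are
#'   typical of the towers this emulates.
#' @param obs_sigma_arcsec Theodolite angular noise sd (arc-seconds; 5 is
#'   the instrument-precision class used in the field).
#' @param misclass_rate Behavior-state misclassification rate of the
#'   observers (default 0).
#' @param fix_per Observation cadence: one fix per `"surfacing"` (default)
#'   or per `"blow"`.
#' @param tide_amp_m,tide_period_h Sinusoidal tide.
#' @param depth_gradient_m_km Shore-normal bathymetric gradient (m depth per
#'   km offshore); the default 2 m/km puts the 20-m isobath 10 km out.
#' @param whale_x_km,whale_y_km Ranges (km) for initial whale positions
#'   (offshore and alongshore).
#' @param domain_x_km,domain_y_km Reflecting movement domain.
#' @param prey_corr_km,prey_sdlog,prey_depth_slope Prey-field spatial
#'   correlation length, log-scale sd, and per-taxon depth trend multiplier.
#' @return Object of class `brs_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       duration_h = 6,
                       n_whales = 2L,
                       step_s = 30,
                       state_transition = default_transition(),
                       initial_state = NULL,
                       speed_mean_kmh = c(1.0, 2.0, 4.0, 1.5),
                       speed_sdlog = c(0.40, 0.35, 0.25, 0.40),
                       turn_sd_deg = c(60, 30, 10, 45),
                       dive_mean_s = c(280, 200, 150, 180),
                       dive_shape = 6,
                       blows_per_surfacing = c(4, 4, 3, 3.5),
                       ibi_mean_s = c(14, 17, 22, 18),
                       ibi_shape = 8,
                       n_seismic = 1L,
                       n_support = 1L,
                       line_length_km = 14,
                       n_lines = 8L,
                       line_spacing_km = 0.5,
                       line_heading_deg = 0,
                       seismic_x0_km = 8,
                       seismic_y0_km = -7,
                       seismic_speed_kn = 4.5,
                       support_speed_kn = 10,
                       shot_interval_s = 10,
                       seismic_sl = 226,
                       vessel_sl = 185,
                       spreading_n = 20,
                       absorption_db_km = 1.0,
                       effect = c("none", "speed", "heading", "respiration"),
                       effect_threshold_db = 140,
                       effect_slope = 0,
                       station_lat = 52.9, station_lon = 143.3,
                       station_height_m = 17,
                       station_ref_azimuth_deg = 0,
                       station_max_range_km = 12,
                       obs_sigma_arcsec = 5,
                       misclass_rate = 0,
                       fix_per = c("surfacing", "blow"),
                       tide_amp_m = 0.8, tide_period_h = 12.42,
                       depth_gradient_m_km = 2,
                       whale_x_km = c(0.5, 3), whale_y_km = c(-5, 5),
                       domain_x_km = c(0.05, 20), domain_y_km = c(-12, 12),
                       prey_corr_km = 3, prey_sdlog = 0.6,
                       prey_depth_slope = 0.03) {
  effect <- match.arg(effect)
  fix_per <- match.arg(fix_per)
  P <- as.matrix(state_transition)
  if (nrow(P) != 4L || ncol(P) != 4L || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-12))
    stop("state_transition must be a 4x4 row-stochastic matrix (rows sum to 1)")
  pos <- c(speed_mean_kmh, speed_sdlog, turn_sd_deg + 1e-12, dive_mean_s,
           dive_shape, blows_per_surfacing, ibi_mean_s, ibi_shape,
           step_s, shot_interval_s)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all rate/scale parameters must be finite and > 0")
  if (any(blows_per_surfacing < 1))
    stop("blows_per_surfacing must be >= 1")
  if (duration_h * 3600 < 630) stop("duration must cover at least one 10.5-min bin")
  if (seismic_speed_kn < 0 || support_speed_kn < 0)
    stop("vessel speeds must be >= 0")
  if (n_seismic < 0 || n_support < 0) stop("fleet sizes must be >= 0")
  cfg <- as.list(environment())
  cfg$state_transition <- P
  cfg$states <- .BRS_STATES
  structure(cfg, class = "brs_sim_config")
}

#' @export
print.brs_sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic study config: %d whale(s), %.1f h, %d seismic + %d support vessel(s), effect = %s (seed %d)\n",
    x$n_whales, x$duration_h, x$n_seismic, x$n_support, x$effect,
    as.integer(x$seed)))
  invisible(x)
}

# Derive a reproducible sub-seed (< 2^31) for a named stream.
sub_seed <- function(seed, stream, k = 0L) {
  base <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 1009L + base * 131L + as.integer(k) * 7919L) %% 2147483647L
}

station_from_config <- function(config) {
  brs_station("S1", config$station_lat, config$station_lon,
              config$station_height_m, config$station_ref_azimuth_deg,
              config$station_max_range_km)
}

#' Simulate one whale track
#'
#' State-switching correlated random walk at the configured step, with a
#' parallel dive/surfacing respiration process. Positions are km on the
#' station-local plane. The walk reflects at the configured domain
#' boundaries (shoreline and offshore/alongshore limits).
#'
#' @param config A [sim_config()].
#' @param whale_id Whale identifier (used in outputs and to derive the
#'   random stream, so different whales are independent).
#' @return Object of class `brs_track`: a list with `whale_id`, `steps`
#'   (data.frame: `time` s, `x`, `y` km, `state`, `at_surface`), `blows`
#'   (numeric event times), `surfacings` and `dives` (data.frames with
#'   `start`, `end`), and the generating config.
#' @export
simulate_whale_track <- function(config, whale_id = 1L) {
  stopifnot(inherits(config, "brs_sim_config"))
  set.seed(sub_seed(config$seed, "track", whale_id))
  n <- floor(config$duration_h * 3600 / config$step_s)
  P <- config$state_transition
  pi0 <- stationary_distribution(P)

  state <- integer(n)
  state[1] <- if (!is.null(config$initial_state))
    match(config$initial_state, .BRS_STATES) else sample.int(4L, 1L, prob = pi0)
  for (i in seq_len(n - 1L))
    state[i + 1L] <- sample.int(4L, 1L, prob = P[state[i], ])

  mu <- log(config$speed_mean_kmh) - config$speed_sdlog^2 / 2
  spd <- exp(stats::rnorm(n, mu[state], config$speed_sdlog[state]))     # km/h
  turn <- stats::rnorm(n, 0, config$turn_sd_deg[state]) * pi / 180
  heading <- (stats::runif(1, 0, 2 * pi) + cumsum(turn)) %% (2 * pi)
  stepl <- spd * config$step_s / 3600                                   # km

  x <- numeric(n + 1L); y <- numeric(n + 1L)
  x[1] <- stats::runif(1, config$whale_x_km[1], config$whale_x_km[2])
  y[1] <- stats::runif(1, config$whale_y_km[1], config$whale_y_km[2])
  xr <- config$domain_x_km; yr <- config$domain_y_km
  for (i in seq_len(n)) {
    dx <- stepl[i] * sin(heading[i]); dy <- stepl[i] * cos(heading[i])
    nx <- x[i] + dx; ny <- y[i] + dy
    if (nx < xr[1] || nx > xr[2]) { dx <- -dx; heading[i:n] <- (-heading[i:n]) %% (2 * pi) }
    if (ny < yr[1] || ny > yr[2]) { dy <- -dy; heading[i:n] <- (pi - heading[i:n]) %% (2 * pi) }
    x[i + 1L] <- x[i] + dx; y[i + 1L] <- y[i] + dy
  }
  times <- (0:n) * config$step_s

  # Respiration: alternate dives and surfacings from t = 0 until the end.
  t_end <- n * config$step_s
  blows <- numeric(0)
  surf <- list(); dives <- list()
  t <- 0
  state_at <- function(tt) state[pmin(n, floor(tt / config$step_s) + 1L)]
  repeat {
    s <- state_at(t)
    d <- stats::rgamma(1, shape = config$dive_shape,
                       scale = config$dive_mean_s[s] / config$dive_shape)
    d <- max(d, 5)
    dives[[length(dives) + 1L]] <- c(t, min(t + d, t_end))
    t <- t + d
    if (t >= t_end) break
    s <- state_at(t)
    nb <- 1L + stats::rpois(1, max(config$blows_per_surfacing[s] - 1, 0))
    gaps <- if (nb > 1L)
      stats::rgamma(nb - 1L, shape = config$ibi_shape,
                    scale = config$ibi_mean_s[s] / config$ibi_shape)
    else numeric(0)
    bt <- t + c(0, cumsum(gaps))
    bt <- bt[bt < t_end]
    if (length(bt) == 0L) break
    blows <- c(blows, bt)
    surf[[length(surf) + 1L]] <- c(bt[1], bt[length(bt)], length(bt))
    t <- bt[length(bt)]
    if (t >= t_end) break
  }
  surfacings <- if (length(surf))
    as.data.frame(do.call(rbind, surf)) else data.frame(V1 = numeric(), V2 = numeric(), V3 = numeric())
  names(surfacings) <- c("start", "end", "n_blows")
  dv <- as.data.frame(do.call(rbind, dives)); names(dv) <- c("start", "end")

  at_surface <- vapply(times, function(tt)
    any(surfacings$start <= tt & tt <= surfacings$end), logical(1))

  steps <- data.frame(time = times, x = x, y = y,
                      state = .BRS_STATES[c(state, state[n])],
                      at_surface = at_surface)
  structure(list(whale_id = whale_id, steps = steps, blows = blows,
                 surfacings = surfacings, dives = dv, config = config),
            class = "brs_track")
}

#' @export
print.brs_track <- function(x, ...) {
  cat(sprintf("Simulated whale track '%s': %d steps (%.1f h), %d blows, %d surfacings\n",
              as.character(x$whale_id), nrow(x$steps) - 1L,
              (nrow(x$steps) - 1L) * x$config$step_s / 3600,
              length(x$blows), nrow(x$surfacings)))
  invisible(x)
}

#' Simulate the vessel fleet and shot schedule
#'
#' Seismic source vessels acquire parallel lines at constant speed (shots at
#' the configured interval only while on-line, on a half-open time grid),
#' transiting between line ends without shooting; each seismic vessel works
#' its own block of lines. Support vessels follow independent smooth
#' random-waypoint paths. Positions are recorded at a 30-s AIS-like cadence.
#'
#' @param config A [sim_config()].
#' @return List with `vessel_tracks` (data.frame: `vessel_id`, `type`,
#'   `time`, `x`, `y`, `sl`) and `shots` (data.frame: `source_id`, `time`,
#'   `x`, `y`, `sl`).
#' @export
simulate_vessels <- function(config) {
  stopifnot(inherits(config, "brs_sim_config"))
  set.seed(sub_seed(config$seed, "vessels"))
  t_end <- config$duration_h * 3600
  cad <- 30
  grid <- seq(0, t_end, by = cad)
  tracks <- list(); shots <- list()

  hd <- config$line_heading_deg * pi / 180
  u <- c(sin(hd), cos(hd))          # along-line unit vector
  v <- c(cos(hd), -sin(hd))         # line-normal unit vector (east for N lines)
  spd <- config$seismic_speed_kn * 1.852 / 3600   # km/s

  for (k in seq_len(config$n_seismic)) {
    block <- (k - 1) * (config$n_lines * config$line_spacing_km + 3)
    p0 <- c(config$seismic_x0_km, config$seismic_y0_km) + block * v
    segs <- list()   # each: start point, end point, on_line flag
    for (j in seq_len(config$n_lines)) {
      a <- p0 + (j - 1) * config$line_spacing_km * v
      b <- a + config$line_length_km * u
      if (j %% 2 == 0) { tmp <- a; a <- b; b <- tmp }   # alternate direction
      segs[[length(segs) + 1L]] <- list(a = a, b = b, on = TRUE)
      if (j < config$n_lines) {
        nxt_a <- p0 + j * config$line_spacing_km * v
        nxt_b <- nxt_a + config$line_length_km * u
        if ((j + 1) %% 2 == 0) nxt_a <- nxt_b
        segs[[length(segs) + 1L]] <- list(a = b, b = nxt_a, on = FALSE)
      }
    }
    # walk the segment chain in time
    t0 <- 0
    pos_t <- function(tt) NULL  # filled below
    seg_t0 <- numeric(length(segs)); seg_len <- numeric(length(segs))
    for (j in seq_along(segs)) {
      seg_t0[j] <- t0
      seg_len[j] <- sqrt(sum((segs[[j]]$b - segs[[j]]$a)^2))
      t0 <- t0 + seg_len[j] / spd
    }
    total_t <- t0
    locate <- function(tt) {
      tt <- tt %% total_t
      j <- findInterval(tt, seg_t0)
      f <- (tt - seg_t0[j]) / (seg_len[j] / spd)
      p <- segs[[j]]$a + f * (segs[[j]]$b - segs[[j]]$a)
      list(x = p[1], y = p[2], on = segs[[j]]$on)
    }
    pg <- lapply(grid, locate)
    tracks[[length(tracks) + 1L]] <- data.frame(
      vessel_id = sprintf("seis%02d", k), type = "seismic", time = grid,
      x = vapply(pg, `[[`, numeric(1), "x"),
      y = vapply(pg, `[[`, numeric(1), "y"),
      sl = config$vessel_sl)
    st <- seq(0, t_end - 1e-9, by = config$shot_interval_s)
    st <- st[st < t_end]
    ps <- lapply(st, locate)
    on <- vapply(ps, `[[`, logical(1), "on")
    if (any(on))
      shots[[length(shots) + 1L]] <- data.frame(
        source_id = sprintf("seis%02d", k), time = st[on],
        x = vapply(ps[on], `[[`, numeric(1), "x"),
        y = vapply(ps[on], `[[`, numeric(1), "y"),
        sl = config$seismic_sl)
  }

  sspd <- config$support_speed_kn * 1.852 / 3600
  for (k in seq_len(config$n_support)) {
    # random-waypoint path within the nearshore band
    wp <- cbind(stats::runif(40, 1, 10), stats::runif(40, -9, 9))
    seglen <- sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-40, , drop = FALSE])^2))
    ct <- c(0, cumsum(seglen / sspd))
    px <- stats::approx(ct, wp[, 1], xout = pmin(grid, max(ct)), rule = 2)$y
    py <- stats::approx(ct, wp[, 2], xout = pmin(grid, max(ct)), rule = 2)$y
    tracks[[length(tracks) + 1L]] <- data.frame(
      vessel_id = sprintf("supp%02d", k), type = "support", time = grid,
      x = px, y = py, sl = config$vessel_sl)
  }

  vessel_tracks <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(vessel_id = character(), type = character(), time = numeric(),
               x = numeric(), y = numeric(), sl = numeric())
  shots <- if (length(shots)) do.call(rbind, shots) else
    data.frame(source_id = character(), time = numeric(), x = numeric(),
               y = numeric(), sl = numeric())
  rownames(vessel_tracks) <- NULL; rownames(shots) <- NULL
  list(vessel_tracks = vessel_tracks, shots = shots)
}

#' Simulate tide, bathymetry and shoreline
#'
#' Sinusoidal tide, a linear shore-normal depth gradient, and a straight
#' north-south shoreline at `x = 0`.
#'
#' @param config A [sim_config()].
#' @return List with `tide` (function of time s -> height m), `tide_series`
#'   (data.frame at 30-s cadence), `depth` (function of x, y -> depth m),
#'   and `shoreline` (data.frame `x`, `y` polyline, km).
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "brs_sim_config"))
  amp <- config$tide_amp_m; per <- config$tide_period_h * 3600
  tide <- function(t) amp * sin(2 * pi * t / per)
  grad <- config$depth_gradient_m_km
  depth <- function(x, y) pmax(0, grad * x)
  grid <- seq(0, config$duration_h * 3600, by = 30)
  list(tide = tide,
       tide_series = data.frame(time = grid, tide_m = tide(grid)),
       depth = depth,
       shoreline = data.frame(x = 0, y = seq(-15, 15, by = 1)))
}

#' Build the study sound field from config and fleet
#'
#' @param config A [sim_config()].
#' @param vessels Output of [simulate_vessels()].
#' @return A [sound_field()].
#' @export
study_sound_field <- function(config, vessels) {
  sound_field(shots = vessels$shots, vessel_tracks = vessels$vessel_tracks,
              spreading_n = config$spreading_n,
              absorption_db_km = config$absorption_db_km)
}

#' Inject a dose-response effect into a track
#'
#' Modifies a simulated track deterministically as a linear function of the
#' exposure excess above a threshold, emulating observed short-term
#' responses (increased speed, movement away from the source, lengthened
#' respiration intervals). Exposure is evaluated at the track's original
#' step positions.
#'
#' * `speed`: each step's log-speed increases by `slope * (SEL - thr)+`;
#'   positions are rebuilt from the scaled step vectors.
#' * `heading`: each step heading is pulled toward the bearing away from the
#'   closest vessel with weight `min(1, slope * (SEL - thr)+)`.
#' * `respiration`: inter-blow intervals within each surfacing are scaled by
#'   `exp(slope * (SEL - thr)+)` at the surfacing start.
#' * `none`: returns the track unchanged.
#'
#' The ground-truth effect is stored in `attr(track, "injected")` for
#' parameter-recovery tests.
#'
#' @param track A `brs_track`.
#' @param field A [sound_field()].
#' @param effect,threshold_db,slope Effect type and parameters; defaults
#'   taken from the track's config.
#' @return The modified `brs_track`.
#' @export
inject_response <- function(track, field,
                            effect = track$config$effect,
                            threshold_db = track$config$effect_threshold_db,
                            slope = track$config$effect_slope) {
  stopifnot(inherits(track, "brs_track"))
  if (!effect %in% c("none", "speed", "heading", "respiration"))
    stop("unknown effect type: ", effect)
  if (effect == "none") return(track)

  st <- track$steps
  n <- nrow(st) - 1L
  ex <- evaluate_sound_field(field, st$x[1:n], st$y[1:n], st$time[1:n])
  excess <- pmax(0, ex$sel_total - threshold_db)
  excess[is.na(excess)] <- 0

  if (effect == "speed") {
    dx <- diff(st$x); dy <- diff(st$y)
    sc <- exp(slope * excess)
    st$x <- st$x[1] + c(0, cumsum(dx * sc))
    st$y <- st$y[1] + c(0, cumsum(dy * sc))
  } else if (effect == "heading") {
    dx <- diff(st$x); dy <- diff(st$y)
    len <- sqrt(dx^2 + dy^2)
    vt <- field$vessel_tracks
    if (nrow(vt) == 0L) stop("heading effect needs at least one vessel in the field")
    for (i in seq_len(n)) {
      if (excess[i] <= 0) next
      vp <- do.call(rbind, lapply(split(vt, vt$vessel_id), function(tr) {
        p <- interp_vessel(tr, st$time[i]); c(p$x, p$y)
      }))
      d2 <- (vp[, 1] - st$x[i])^2 + (vp[, 2] - st$y[i])^2
      j <- which.min(d2)
      away <- atan2(st$x[i] - vp[j, 1], st$y[i] - vp[j, 2])
      hdg <- atan2(dx[i], dy[i])
      w <- min(1, slope * excess[i])
      newh <- atan2((1 - w) * sin(hdg) + w * sin(away),
                    (1 - w) * cos(hdg) + w * cos(away))
      dx[i] <- len[i] * sin(newh); dy[i] <- len[i] * cos(newh)
    }
    st$x <- st$x[1] + c(0, cumsum(dx))
    st$y <- st$y[1] + c(0, cumsum(dy))
  } else if (effect == "respiration") {
    sf <- track$surfacings
    if (nrow(sf)) {
      blows <- sort(track$blows)
      newb <- blows
      for (i in seq_len(nrow(sf))) {
        idx <- which(blows >= sf$start[i] & blows <= sf$end[i])
        if (length(idx) < 2L) next
        k <- pmax(1L, pmin(n, floor(sf$start[i] / track$config$step_s) + 1L))
        sc <- exp(slope * excess[k])
        g <- diff(blows[idx]) * sc
        newb[idx] <- blows[idx[1]] + c(0, cumsum(g))
        sf$end[i] <- newb[idx[length(idx)]]
      }
      track$blows <- newb
      track$surfacings <- sf
    }
  }
  track$steps <- st
  attr(track, "injected") <- list(effect = effect, threshold_db = threshold_db,
                                  slope = slope)
  track
}

# Interpolate a track's position at arbitrary times.
track_position <- function(track, times) {
  st <- track$steps
  data.frame(
    time = times,
    x = stats::approx(st$time, st$x, xout = times, rule = 2)$y,
    y = stats::approx(st$time, st$y, xout = times, rule = 2)$y)
}

# State at arbitrary times (nearest step).
track_state <- function(track, times) {
  st <- track$steps
  idx <- pmax(1L, pmin(nrow(st), round(times / track$config$step_s) + 1L))
  st$state[idx]
}

#' Simulate the theodolite observation of a track
#'
#' Emits one angular fix per surfacing (or per blow), by inverse geodesy
#' from the station plus Gaussian angular noise, with the behavior state
#' annotated from the true state (optionally misclassified). Whales beyond
#' the station's maximum tracking range are suppressed (counted, not an
#' error). A focal event log of blows and dive starts accompanies the
#' fixes.
#'
#' @param track A `brs_track`.
#' @param station A [brs_station()]; default built from the track's config.
#' @param tide Function of time (s) returning tide height (m); default the
#'   config's sinusoidal tide.
#' @param sigma_arcsec Angular noise sd (arc-seconds).
#' @param misclass_rate Probability a fix's state annotation is replaced by
#'   a random other state.
#' @param fix_per `"surfacing"` or `"blow"`.
#' @return List with `fixes` (data.frame: `station_id`, `time`,
#'   `vertical_deg`, `horizontal_deg`, `whale_id`, `state`, `tide_m`),
#'   `events` (data.frame: `whale_id`, `time`, `event` in blow/dive_start),
#'   and `n_suppressed` (fixes beyond range).
#' @export
observe_track <- function(track, station = NULL, tide = NULL,
                          sigma_arcsec = track$config$obs_sigma_arcsec,
                          misclass_rate = track$config$misclass_rate,
                          fix_per = track$config$fix_per) {
  stopifnot(inherits(track, "brs_track"))
  cfg <- track$config
  if (is.null(station)) station <- station_from_config(cfg)
  if (is.null(tide)) tide <- simulate_environment(cfg)$tide
  set.seed(sub_seed(cfg$seed, "observe",
                    if (is.numeric(track$whale_id)) track$whale_id else 0L))

  ft <- if (fix_per == "surfacing") track$surfacings$start else sort(track$blows)
  ft <- ft[ft <= max(track$steps$time)]
  pos <- track_position(track, ft)
  rng <- sqrt(pos$x^2 + pos$y^2)
  keep <- rng <= station$max_range_km & rng > 0
  n_sup <- sum(!keep)
  ft <- ft[keep]; pos <- pos[keep, , drop = FALSE]

  if (length(ft)) {
    tid <- tide(ft)
    ang <- position_to_angles(station, x = pos$x, y = pos$y, tide_m = tid)
    sdeg <- sigma_arcsec / 3600
    vert <- ang$vertical_deg + stats::rnorm(length(ft), 0, sdeg)
    horiz <- (ang$horizontal_deg + stats::rnorm(length(ft), 0, sdeg)) %% 360
    state <- track_state(track, ft)
    if (misclass_rate > 0) {
      flip <- stats::runif(length(state)) < misclass_rate
      state[flip] <- vapply(state[flip], function(s)
        sample(setdiff(.BRS_STATES, s), 1L), character(1))
    }
    fixes <- data.frame(station_id = station$id, time = ft,
                        vertical_deg = vert, horizontal_deg = horiz,
                        whale_id = track$whale_id, state = state,
                        tide_m = tid)
  } else {
    fixes <- data.frame(station_id = character(), time = numeric(),
                        vertical_deg = numeric(), horizontal_deg = numeric(),
                        whale_id = character(), state = character(),
                        tide_m = numeric())
  }
  events <- rbind(
    data.frame(whale_id = track$whale_id, time = sort(track$blows), event = "blow"),
    data.frame(whale_id = track$whale_id, time = track$dives$start, event = "dive_start"))
  events <- events[order(events$time, events$event), ]
  rownames(events) <- NULL
  list(fixes = fixes, events = events, n_suppressed = n_sup)
}

#' Simulate benthic prey point samples
#'
#' Log-normal per-taxon biomass fields with exponential spatial correlation
#' and a depth trend, sampled on a regular nearshore grid restricted to the
#' 20-m isobath (the interpolation domain of benthic surveys this
#' emulates). The total is the exact sum of the five taxa.
#'
#' @param config A [sim_config()].
#' @param spacing_km Grid spacing, default 1 km.
#' @param median_biomass Named per-taxon median biomass (g/m^2) at zero
#'   depth anomaly.
#' @return data.frame: `station`, `x`, `y`, `depth_m`, one column per taxon
#'   (amphipods, isopods, cumaceans, polychaetes, bivalves) and `total`.
#' @export
simulate_prey_samples <- function(config, spacing_km = 1,
                                  median_biomass = c(amphipods = 38,
                                                     isopods = 8,
                                                     cumaceans = 0.5,
                                                     polychaetes = 2.5,
                                                     bivalves = 18)) {
  stopifnot(inherits(config, "brs_sim_config"))
  set.seed(sub_seed(config$seed, "prey"))
  env <- simulate_environment(config)
  xmax <- min(config$domain_x_km[2], 20 / config$depth_gradient_m_km)
  gx <- seq(0.5, xmax - 0.25, by = spacing_km)
  gy <- seq(config$domain_y_km[1] + 1, config$domain_y_km[2] - 1, by = spacing_km)
  g <- expand.grid(x = gx, y = gy)
  d <- as.matrix(stats::dist(g))
  C <- exp(-d / config$prey_corr_km)
  L <- chol(C + diag(1e-10, nrow(C)))
  depth <- env$depth(g$x, g$y)
  out <- data.frame(station = sprintf("P%03d", seq_len(nrow(g))),
                    x = g$x, y = g$y, depth_m = depth)
  for (tx in names(median_biomass)) {
    z <- as.vector(t(L) %*% stats::rnorm(nrow(g))) * config$prey_sdlog
    out[[tx]] <- exp(log(median_biomass[[tx]]) +
                       config$prey_depth_slope * (depth - mean(depth)) + z)
  }
  out$total <- rowSums(out[names(median_biomass)])
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running every generator: environment, vessel fleet,
#' sound field, whale tracks (with the configured response injected), the
#' theodolite observation of every track, and prey samples.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `station`, `environment`, `vessels`, `field`,
#'   `tracks`, `observations` (per whale: fixes + focal events), and
#'   `prey`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "brs_sim_config"))
  env <- simulate_environment(config)
  vessels <- simulate_vessels(config)
  field <- study_sound_field(config, vessels)
  station <- station_from_config(config)
  tracks <- lapply(seq_len(config$n_whales), function(w) {
    tr <- simulate_whale_track(config, whale_id = w)
    inject_response(tr, field)
  })
  obs <- lapply(tracks, observe_track, station = station, tide = env$tide)
  prey <- simulate_prey_samples(config)
  list(config = config, station = station, environment = env,
       vessels = vessels, field = field, tracks = tracks,
       observations = obs, prey = prey)
}
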