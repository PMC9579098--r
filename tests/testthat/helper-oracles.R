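# Independent brute-force reference implementations used as oracles.
# These deliberately use different numerical routes (complex arithmetic for
# circular statistics, explicit loops, dense search) than the package code.

# --- movement metrics on one bin of positions (data.frame time, x, y) -----
oracle_bin_metrics <- function(p) {
  n <- nrow(p)
  dur_min <- (p$time[n] - p$time[1]) / 60
  steps <- complex(real = diff(p$x), imaginary = diff(p$y))
  cum <- sum(Mod(steps))
  net <- Mod(sum(steps))
  # azimuth clockwise from north of a displacement (dx, dy) = Arg of (dy + i dx)
  az <- function(z) (Arg(complex(real = Im(z), imaginary = Re(z))) * 180 / pi) %% 360
  hd <- vapply(steps, az, numeric(1))
  dturn <- diff(hd)
  turn <- ifelse(dturn > 180, dturn - 360, ifelse(dturn <= -180, dturn + 360, dturn))
  mrl <- function(deg) Mod(mean(exp(1i * deg * pi / 180)))
  rng <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    rng <- max(rng, Mod(complex(real = p$x[i] - p$x[j], imaginary = p$y[i] - p$y[j])))
  netz <- sum(steps)
  dir <- if (Mod(netz) > 0) az(netz) else NA_real_
  list(spd = cum / (dur_min / 60),
       lin = if (cum > 0) net / cum else 0,
       rr = sum(abs(turn)) / dur_min,
       mdir = mrl(hd),
       trk_r = mrl(turn),
       range_km = rng,
       dir_deg = dir,
       cos_dir = if (is.na(dir)) NA_real_ else cos(dir * pi / 180),
       sin_dir = if (is.na(dir)) NA_real_ else sin(dir * pi / 180))
}

# --- respiration: exhaustive segmentation scan ----------------------------
oracle_segment <- function(blows, dive_starts, thr = 60) {
  blows <- sort(blows)
  if (!length(blows)) return(NULL)
  groups <- list(); cur <- blows[1]
  for (b in blows[-1]) {
    last <- cur[length(cur)]
    split_here <- (b - last > thr) ||
      any(dive_starts > last & dive_starts < b)
    if (split_here) { groups[[length(groups) + 1L]] <- cur; cur <- b }
    else cur <- c(cur, b)
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}

# --- respiration bin metrics from raw blow groups -------------------------
oracle_resp_bins <- function(blows, dive_starts, bin_starts, bin_s = 630,
                             thr = 60) {
  grps <- oracle_segment(blows, dive_starts, thr)
  ns <- length(grps)
  if (ns < 2) return(NULL)
  out <- list()
  for (b in seq_along(bin_starts)) {
    t0 <- bin_starts[b]
    surf <- dive <- nb <- numeric(0); ibis <- c()
    for (i in seq_len(ns - 1)) {        # complete cycles only
      g <- grps[[i]]
      s <- max(g) - min(g)
      d <- min(grps[[i + 1]]) - max(g)
      mid <- min(g) + (s + d) / 2
      if (mid >= t0 && mid < t0 + bin_s) {
        surf <- c(surf, s); dive <- c(dive, d); nb <- c(nb, length(g))
        if (length(g) > 1) ibis <- c(ibis, mean(diff(g)))
        else ibis <- c(ibis, NA)
      }
    }
    if (!length(surf)) next
    out[[length(out) + 1L]] <- data.frame(
      bin = b,
      ri_s = if (all(is.na(ibis))) NA_real_ else mean(ibis, na.rm = TRUE),
      surface_s = mean(surf), dive_s = mean(dive),
      blows_per_surfacing = mean(nb),
      surface_rate = if (sum(surf) > 0) sum(nb) / (sum(surf) / 60) else NA_real_,
      dive_surface_rate = sum(nb) / ((sum(surf) + sum(dive)) / 60),
      pct_surface = 100 * sum(surf) / (sum(surf) + sum(dive)))
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

# --- direct GLS solve with given covariance -------------------------------
oracle_gls <- function(X, y, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# --- random raw tracks for metric equivalence -----------------------------
random_positions <- function(n, seed) {
  set.seed(seed)
  data.frame(time = (0:(n - 1)) * 90,
             x = cumsum(rnorm(n, 0, 0.08)),
             y = cumsum(rnorm(n, 0, 0.08)))
}

rel_err <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s == 0, d, d / s)
}

# --- tiny field: one continuous omnidirectional source --------------------
point_source_field <- function(x, y, sl, n = 20, alpha = 0, type = "support") {
  sound_field(vessel_tracks = data.frame(vessel_id = "v1", type = type,
                                         time = c(0, 1e7), x = x, y = y,
                                         sl = sl),
              spreading_n = n, absorption_db_km = alpha)
}
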