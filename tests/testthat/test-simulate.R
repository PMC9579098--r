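test_that("degenerate switching gives a straight constant-state track", {
  cfg <- sim_config(seed = 5, duration_h = 1, state_transition = diag(4),
                    initial_state = "traveling",
                    turn_sd_deg = c(1e-9, 1e-9, 1e-9, 1e-9))
  tr <- simulate_whale_track(cfg, 1)
  expect_true(all(tr$steps$state == "traveling"))
  # straight line: all headings equal -> collinear increments
  dx <- diff(tr$steps$x); dy <- diff(tr$steps$y)
  hd <- atan2(dx, dy)
  expect_lt(diff(range(hd)), 1e-6)
  # blows only inside surfacings
  sf <- tr$surfacings
  inside <- vapply(tr$blows, function(b)
    any(sf$start - 1e-9 <= b & b <= sf$end + 1e-9), logical(1))
  expect_true(all(inside))
})

test_that("state occupancy converges to the analytic stationary distribution", {
  P <- matrix(c(0.85, 0.05, 0.05, 0.05,
                0.05, 0.85, 0.05, 0.05,
                0.05, 0.05, 0.85, 0.05,
                0.05, 0.05, 0.05, 0.85), 4, 4, byrow = TRUE)
  cfg <- sim_config(seed = 9, duration_h = 1e5 * 30 / 3600,
                    state_transition = P, domain_x_km = c(-1e6, 1e6),
                    domain_y_km = c(-1e6, 1e6))
  tr <- simulate_whale_track(cfg, 1)
  occ <- table(factor(tr$steps$state[-nrow(tr$steps)],
                      levels = c("feeding", "feed_travel", "traveling", "mixed")))
  # oracle: eigen-decomposition stationary distribution (uniform here)
  e <- eigen(t(P))
  pi0 <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi0 <- pi0 / sum(pi0)
  n <- sum(occ)
  # 3 sigma of a binomial count, inflated for Markov autocorrelation
  # (integrated autocorrelation time for self-transition 0.85 is ~12)
  for (k in 1:4) {
    sd_k <- sqrt(n * pi0[k] * (1 - pi0[k]) * 12)
    expect_lt(abs(occ[k] - n * pi0[k]), 3 * sd_k)
  }
})

test_that("per-state empirical mean speeds match the configured means", {
  cfg <- sim_config(seed = 10, duration_h = 50,
                    speed_mean_kmh = c(1.0, 2.0, 4.0, 1.5),
                    domain_x_km = c(-1e6, 1e6), domain_y_km = c(-1e6, 1e6))
  tr <- simulate_whale_track(cfg, 1)
  st <- tr$steps
  stepl <- sqrt(diff(st$x)^2 + diff(st$y)^2)
  spd <- stepl / (cfg$step_s / 3600)
  for (k in c("feeding", "traveling")) {
    emp <- mean(spd[st$state[-nrow(st)] == k])
    cfgv <- cfg$speed_mean_kmh[match(k, c("feeding", "feed_travel", "traveling", "mixed"))]
    expect_lt(abs(emp - cfgv) / cfgv, 0.05)
  }
})

test_that("a single 10-km line at 8 km/h with 10-s shots yields 450 shots", {
  cfg <- sim_config(seed = 1, duration_h = 1.25, n_seismic = 1, n_support = 0,
                    n_lines = 1L, line_length_km = 10,
                    seismic_speed_kn = 8 / 1.852, shot_interval_s = 10)
  v <- simulate_vessels(cfg)
  expect_equal(nrow(v$shots), 450)
  expect_true(all(v$shots$time < 1.25 * 3600))
})

test_that("an empty fleet gives empty tracks and missing vessel covariates", {
  cfg <- sim_config(seed = 1, n_seismic = 0, n_support = 0)
  v <- simulate_vessels(cfg)
  expect_equal(nrow(v$vessel_tracks), 0)
  expect_equal(nrow(v$shots), 0)
  vc <- vessel_covariates(1, 1, 0, v$vessel_tracks, 100)
  expect_true(is.na(vc$cv_dist_km))
  expect_equal(vc$n_vessels, 0L)
})

test_that("closest-vessel series equals a brute-force pairwise minimum", {
  cfg <- sim_config(seed = 3, duration_h = 2, n_seismic = 2, n_support = 1)
  v <- simulate_vessels(cfg)
  set.seed(99)
  for (k in 1:10) {
    t0 <- runif(1, 0, 7000); wx <- runif(1, 0, 6); wy <- runif(1, -6, 6)
    vc <- vessel_covariates(wx, wy, NA, v$vessel_tracks, t0)
    # brute force: interpolate every vessel independently
    dmin <- Inf
    for (id in unique(v$vessel_tracks$vessel_id)) {
      tr <- v$vessel_tracks[v$vessel_tracks$vessel_id == id, ]
      px <- approx(tr$time, tr$x, xout = t0, rule = 2)$y
      py <- approx(tr$time, tr$y, xout = t0, rule = 2)$y
      dmin <- min(dmin, sqrt((px - wx)^2 + (py - wy)^2))
    }
    expect_equal(vc$cv_dist_km, dmin, tolerance = 1e-9)
  }
})

test_that("sound field follows the propagation law and energy additivity", {
  f <- point_source_field(0, 0, sl = 200, n = 20, alpha = 0)
  ex <- evaluate_sound_field(f, 1, 0, 0)  # r = 1000 m
  expect_equal(ex$sel_vessel, 200 - 20 * log10(1000), tolerance = 1e-9)

  # two equal co-located continuous sources -> +10 log10(2)
  vt <- data.frame(vessel_id = c("a", "a", "b", "b"), type = "support",
                   time = c(0, 1e6, 0, 1e6), x = 0, y = 0, sl = 170)
  f2 <- sound_field(vessel_tracks = vt, spreading_n = 20, absorption_db_km = 0)
  ex2 <- evaluate_sound_field(f2, 10, 0, 0)
  one <- 170 - 20 * log10(10000)
  expect_equal(ex2$sel_vessel, one + 10 * log10(2), tolerance = 1e-9)

  # k shots of X dB in a window -> X + 10 log10(k), against a direct sum
  for (k in c(1, 3, 7)) {
    sh <- data.frame(source_id = "s", time = seq(0, by = 2, length.out = k),
                     x = 2, y = 0, sl = 210)
    fs <- sound_field(shots = sh, spreading_n = 20, absorption_db_km = 0)
    exs <- evaluate_sound_field(fs, 0, 0, 0)
    X <- 210 - 20 * log10(2000)
    expect_equal(exs$sel_seismic, X + 10 * log10(k), tolerance = 1e-9)
    oracle <- 10 * log10(sum(rep(10^(X / 10), k)))
    expect_equal(exs$sel_seismic, oracle, tolerance = 1e-9)
  }
  # r = 0 clamps to the 1-m reference
  ex0 <- evaluate_sound_field(f, 0, 0, 0)
  expect_equal(ex0$sel_vessel, 200, tolerance = 1e-9)
})

test_that("inject_response: identity, exact speed shift, and heading bias", {
  cfg <- sim_config(seed = 21, duration_h = 2)
  tr <- simulate_whale_track(cfg, 1)
  f_uniform <- sound_field(
    vessel_tracks = data.frame(vessel_id = "v", type = "support",
                               time = c(0, 1e7), x = 0, y = 0, sl = 150),
    spreading_n = 0, absorption_db_km = 0)  # 150 dB everywhere

  expect_identical(inject_response(tr, f_uniform, effect = "none"), tr)

  s <- 0.02
  tr2 <- inject_response(tr, f_uniform, effect = "speed",
                         threshold_db = 140, slope = s)
  l1 <- sqrt(diff(tr$steps$x)^2 + diff(tr$steps$y)^2)
  l2 <- sqrt(diff(tr2$steps$x)^2 + diff(tr2$steps$y)^2)
  # constant excess of 10 dB -> log step lengths shift by exactly s * 10
  expect_equal(mean(log(l2) - log(l1)), s * 10, tolerance = 1e-9)
  expect_equal(attr(tr2, "injected")$slope, s)

  # heading bias away from a vessel due east -> mean movement westward
  f_east <- point_source_field(60, 0, sl = 400, n = 20, alpha = 0)
  tr3 <- inject_response(tr, f_east, effect = "heading",
                         threshold_db = 100, slope = 1)
  dx <- diff(tr3$steps$x); dy <- diff(tr3$steps$y)
  mean_dir <- (atan2(sum(dx), sum(dy)) * 180 / pi) %% 360
  expect_lt(abs(mean_dir - 270), 20)

  expect_error(inject_response(tr, f_uniform, effect = "levitate"), "unknown")
})

test_that("observation model: noiseless round trip, range cutoff, error propagation", {
  cfg <- sim_config(seed = 30, duration_h = 1, obs_sigma_arcsec = 0)
  tr <- simulate_whale_track(cfg, 1)
  ob <- observe_track(tr)
  st <- brs_station("S1", cfg$station_lat, cfg$station_lon, cfg$station_height_m)
  env <- simulate_environment(cfg)
  p <- fix_to_position(ob$fixes$vertical_deg, ob$fixes$horizontal_deg, st,
                       tide_m = ob$fixes$tide_m)
  truth <- whalebrs:::track_position(tr, ob$fixes$time)
  err_m <- sqrt((p$x - truth$x)^2 + (p$y - truth$y)^2) * 1000
  expect_lt(max(err_m), 1)

  # whale far beyond a low station's cutoff emits no fixes
  cfg2 <- sim_config(seed = 31, duration_h = 1, station_height_m = 10.8,
                     station_max_range_km = 6, whale_x_km = c(13, 13.5),
                     whale_y_km = c(-0.5, 0.5))
  tr2 <- simulate_whale_track(cfg2, 1)
  ob2 <- observe_track(tr2)
  expect_equal(nrow(ob2$fixes), 0)
  expect_gt(ob2$n_suppressed, 0)

  # 5 arc-sec angular noise at 5 km: radial scatter ~ R^2 sigma / h
  st5 <- brs_station("S", 52.9, 143.3, height_m = 20)
  ang <- position_to_angles(st5, x = 0, y = 5)
  set.seed(77)
  sdeg <- 5 / 3600
  vert <- ang$vertical_deg + rnorm(3000, 0, sdeg)
  pp <- fix_to_position(vert, rep(ang$horizontal_deg, 3000), st5)
  pred <- (5000^2) * (sdeg * pi / 180) / 20    # first-order propagation, m
  expect_equal(sd(pp$range_km * 1000), pred, tolerance = 0.2)
})

test_that("generators are bit-reproducible from the seed", {
  cfg <- sim_config(seed = 123, duration_h = 1)
  expect_identical(simulate_whale_track(cfg, 1), simulate_whale_track(cfg, 1))
  expect_identical(simulate_vessels(cfg), simulate_vessels(cfg))
  expect_identical(simulate_prey_samples(cfg), simulate_prey_samples(cfg))
})

test_that("prey samples: additivity, long-correlation limit, variogram recovery", {
  cfg <- sim_config(seed = 44)
  pr <- simulate_prey_samples(cfg)
  taxa <- c("amphipods", "isopods", "cumaceans", "polychaetes", "bivalves")
  expect_equal(pr$total, rowSums(pr[taxa]), tolerance = 1e-9)
  expect_true(all(pr[taxa] >= 0))
  expect_true(all(pr$depth_m <= 20 + 1e-9))

  # correlation length -> infinity gives an essentially constant field
  cfg2 <- sim_config(seed = 45, prey_corr_km = 1e9, prey_depth_slope = 0)
  pr2 <- simulate_prey_samples(cfg2)
  expect_lt(sd(log(pr2$amphipods)) / abs(mean(log(pr2$amphipods))), 0.01)

  # variogram range recovery on replicated Gaussian fields
  set.seed(46)
  true_range <- 2
  est <- replicate(12, {
    g <- expand.grid(x = seq(0, 11, by = 1), y = seq(0, 11, by = 1))
    d <- as.matrix(dist(g))
    L <- chol(exp(-d / true_range) + diag(1e-10, nrow(g)))
    z <- as.vector(t(L) %*% rnorm(nrow(g)))
    ev <- empirical_variogram(g$x, g$y, z)
    fit_variogram(ev, fix_nugget = 0)$range
  })
  expect_lt(abs(median(est) - true_range) / true_range, 0.25)
})
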