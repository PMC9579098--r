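test_that("IDW is exact at samples, symmetric, and matches a direct sum", {
  sx <- c(0, 1, 2); sy <- c(0, 0, 0); sz <- c(5, 7, 11)
  expect_equal(idw_interpolate(sx, sy, sz, 1, 0), 7)
  # two equidistant samples average
  expect_equal(idw_interpolate(c(0, 2), c(0, 0), c(10, 20), 1, 0), 15)
  set.seed(3)
  for (k in 1:20) {
    n <- sample(5:25, 1)
    sx <- runif(n, 0, 10); sy <- runif(n, 0, 10); sz <- rexp(n, 0.1)
    qx <- runif(1, 0, 10); qy <- runif(1, 0, 10)
    got <- idw_interpolate(sx, sy, sz, qx, qy, power = 2, k = Inf)
    d <- sqrt((sx - qx)^2 + (sy - qy)^2)
    w <- d^-2
    expect_equal(got, sum(w * sz) / sum(w), tolerance = 1e-9)
    expect_true(got >= min(sz) - 1e-12 && got <= max(sz) + 1e-12)
  }
})

test_that("kriging a constant field returns the constant with ~zero variance", {
  set.seed(6)
  sx <- runif(10, 0, 5); sy <- runif(10, 0, 5)
  kr <- krige_interpolate(sx, sy, rep(4.2, 10), sdepth = rep(3, 10),
                          x = c(1, 2.5), y = c(1, 4), depth = c(3, 3))
  expect_equal(kr$pred, c(4.2, 4.2), tolerance = 1e-6)
  expect_true(all(kr$var < 1e-6))
})

test_that("kriging predictions equal an independent linear-system solve", {
  set.seed(7)
  for (k in 1:5) {
    n <- sample(6:10, 1)
    sx <- runif(n, 0, 8); sy <- runif(n, 0, 8)
    sdep <- runif(n, 2, 18)
    sz <- 3 + 0.4 * sdep + rnorm(n)
    vgm <- list(nugget = 0, psill = 1.5, range = 3)
    qx <- runif(2, 0, 8); qy <- runif(2, 0, 8); qd <- runif(2, 2, 18)
    kr <- krige_interpolate(sx, sy, sz, sdep, qx, qy, qd, vgm = vgm)
    # oracle: rebuild trend + OK system from scratch with explicit loops
    tr <- lm(sz ~ sdep)
    res <- sz - fitted(tr)
    cov_fun <- function(h) ifelse(h == 0, 1.5, 1.5 * exp(-h / 3))
    A <- matrix(0, n + 1, n + 1)
    for (i in 1:n) for (j in 1:n)
      A[i, j] <- cov_fun(sqrt((sx[i] - sx[j])^2 + (sy[i] - sy[j])^2))
    A[n + 1, 1:n] <- 1; A[1:n, n + 1] <- 1
    for (q in 1:2) {
      b <- c(vapply(1:n, function(i)
        cov_fun(sqrt((sx[i] - qx[q])^2 + (sy[i] - qy[q])^2)), numeric(1)), 1)
      lam <- solve(A, b)
      pred <- coef(tr)[1] + coef(tr)[2] * qd[q] + sum(lam[1:n] * res)
      expect_equal(kr$pred[q], unname(pred), tolerance = 1e-8)
    }
    # exactness at a sample point under zero nugget
    kr0 <- krige_interpolate(sx, sy, sz, sdep, sx[1], sy[1], sdep[1], vgm = vgm)
    expect_equal(kr0$pred, sz[1], tolerance = 1e-6)
    expect_true(all(kr$var >= 0))
  }
})

test_that("regression kriging recovers a known depth trend", {
  set.seed(8)
  slopes <- ses <- numeric(10)
  for (r in 1:10) {
    g <- expand.grid(x = seq(0, 9, by = 1.5), y = seq(0, 9, by = 1.5))
    dep <- 2 * g$x + rnorm(nrow(g), 0, 0.3)
    z <- 1 + 0.5 * dep + rnorm(nrow(g), 0, 0.4)
    kr <- krige_interpolate(g$x, g$y, z, dep, 5, 5, 10)
    slopes[r] <- coef(kr$trend)[2]
    ses[r] <- sqrt(vcov(kr$trend)[2, 2])
  }
  covered <- mean(abs(slopes - 0.5) <= 2 * ses)
  expect_gte(covered, 0.7)
  expect_lt(abs(mean(slopes) - 0.5), 0.05)
})

test_that("per-bin maximum biomass respects the field and the depth domain", {
  const <- function(x, y) rep(7, length(x))
  pos <- data.frame(x = (0:7) * 0.1, y = 0)
  expect_equal(bin_max_biomass(pos, const), 7)
  # linear-gradient field peaks at the up-gradient endpoint
  grad <- function(x, y) 2 + 3 * x
  expect_equal(bin_max_biomass(pos, grad), 2 + 3 * 0.7)
  # brute-force pointwise maxima on random fields
  set.seed(9)
  for (k in 1:10) {
    f <- local({ a <- rnorm(3); function(x, y) a[1] + a[2] * x + a[3] * sin(y) })
    p <- data.frame(x = runif(8, 0, 5), y = runif(8, 0, 5))
    expect_equal(bin_max_biomass(p, f), max(f(p$x, p$y)), tolerance = 1e-12)
  }
  # positions beyond the 20-m isobath are excluded / missing
  depth <- function(x, y) 10 * x
  deep <- data.frame(x = rep(3, 8), y = 1:8)
  expect_true(is.na(bin_max_biomass(deep, const, depth_fun = depth)))
})

test_that("biomass ANOVA handles degenerate, hand-computed and shifted cases", {
  d0 <- data.frame(state = rep(c("feeding", "traveling"), each = 3),
                   amph = rep(5, 6))
  a0 <- biomass_anova(d0, "amph")
  expect_equal(a0$anova$F, 0); expect_equal(a0$anova$p, 1)

  # hand-computable 2-group table: groups (1,2,3) and (4,5,6)
  d1 <- data.frame(state = rep(c("a", "b"), each = 3), v = c(1, 2, 3, 4, 5, 6))
  a1 <- biomass_anova(d1, "v")
  # SSB = 3*(2-3.5)^2 + 3*(5-3.5)^2 = 13.5 (df 1); SSW = 4 (df 4) -> F = 13.5
  expect_equal(a1$anova$F, 13.5, tolerance = 1e-9)
  expect_equal(a1$anova$df, 1)
  expect_equal(unname(a1$medians["a", "v"]), 2)

  # feeding concentrated where amphipods are rich -> significant contrast
  set.seed(10)
  cfg <- sim_config(seed = 81)
  pr <- simulate_prey_samples(cfg)
  idw <- function(x, y) idw_interpolate(pr$x, pr$y, pr$amphipods, x, y)
  hi <- pr[pr$amphipods > quantile(pr$amphipods, 0.75), ]
  lo <- pr[pr$amphipods < quantile(pr$amphipods, 0.5), ]
  ih <- sample(nrow(hi), 40, TRUE); il <- sample(nrow(lo), 40, TRUE)
  bins <- rbind(
    data.frame(state = "feeding",
               amph = idw(jitter(hi$x[ih], amount = 0.2),
                          jitter(hi$y[ih], amount = 0.2))),
    data.frame(state = "traveling",
               amph = idw(jitter(lo$x[il], amount = 0.2),
                          jitter(lo$y[il], amount = 0.2))))
  a2 <- biomass_anova(bins, "amph")
  expect_lt(a2$anova$p, 0.01)
  expect_gt(median(bins$amph[bins$state == "feeding"]),
            median(bins$amph[bins$state == "traveling"]))
  expect_error(biomass_anova(data.frame(state = "x", v = 1:3), "v"), "2 behavior")
})
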