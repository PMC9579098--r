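test_that("response transforms hit their anchors and invert exactly", {
  expect_equal(transform_response(0.5, "logit"), 0)
  expect_equal(transform_response(1, "ln"), 0)
  expect_equal(transform_response(90, "cos"), 0, tolerance = 1e-12)
  expect_equal(transform_response(90, "sin"), 1)
  expect_error(transform_response(c(0.1, -2), "logit"), "\\[0, 1\\]")
  expect_error(transform_response(c(3, 0), "ln"), "position 2")
  set.seed(1)
  x <- runif(1000)
  y <- transform_response(x, "logit")
  expect_lt(max(abs(inv_transform_response(y, "logit", n = 1000) - x)), 1e-12)
  z <- rexp(1000)
  expect_lt(max(abs(inv_transform_response(transform_response(z, "ln"), "ln") - z)),
            1e-12)
  # logit squeeze keeps boundary values finite
  expect_true(all(is.finite(transform_response(c(0, 1, 0.5), "logit", n = 100))))
})

test_that("collinearity screen flags duplicates and spares independent columns", {
  set.seed(2)
  n <- 10000
  a <- rnorm(n)
  d <- data.frame(a = a, b = a, c = rnorm(n), d = rnorm(n))
  sc <- collinearity_screen(d)
  expect_true(any(sc$flagged$var1 == "a" & sc$flagged$var2 == "b"))
  expect_equal(sc$flagged$r[sc$flagged$var1 == "a" & sc$flagged$var2 == "b"], 1)
  expect_false(any(sc$flagged$var1 %in% c("c", "d") &
                     sc$flagged$var2 %in% c("c", "d")))
  expect_true(all(c("c", "d") %in% sc$retained))
  # constructed correlation 0.95 is flagged; preference keeps the named one
  x <- rnorm(n)
  y <- 0.95 * x + sqrt(1 - 0.95^2) * rnorm(n)
  d2 <- data.frame(sel = x, spl = y, other = rnorm(n))
  sc2 <- collinearity_screen(d2, prefer = "sel")
  expect_true(nrow(sc2$flagged) >= 1)
  expect_true("sel" %in% sc2$retained)
  expect_false("spl" %in% sc2$retained)
  # constant column is reported, not crashed on
  d3 <- data.frame(a = rnorm(n), k = rep(3, n))
  sc3 <- collinearity_screen(d3)
  expect_equal(sc3$constant, "k")
})

test_that("HT weights give equal track mass and sum to the bin count", {
  expect_equal(ht_weights(rep(c("a", "b", "c"), each = 4)), rep(1, 12))
  w <- ht_weights(c(rep("a", 1), rep("b", 9)))
  expect_equal(sum(w), 10, tolerance = 1e-12)
  expect_equal(sum(w[1]), 5)           # track of 1 bin carries mass N/J = 5
  expect_equal(sum(w[2:10]), 5)
  set.seed(3)
  ids <- sample(letters[1:7], 200, replace = TRUE)
  w2 <- ht_weights(ids)
  expect_equal(sum(w2), 200, tolerance = 1e-9)
  sums <- tapply(w2, ids, sum)
  expect_lt(diff(range(sums)), 1e-9)
})

test_that("all-equal weights reproduce the unweighted fit", {
  d <- simulate_response_data(n_tracks = 12, bins_range = c(8, 8),
                              beta = c(depth_m = 0.2), rho = 0.3, seed = 4)
  m_ht <- brs_model(y ~ state + depth_m, d, correlation = "ar1", weights = "ht")
  m_un <- brs_model(y ~ state + depth_m, d, correlation = "ar1", weights = "none")
  expect_equal(coef(m_ht), coef(m_un), tolerance = 1e-8)
  expect_equal(BIC(m_ht), BIC(m_un), tolerance = 1e-6)
})

test_that("a tiny balanced GLS fit equals the direct matrix solution", {
  d <- simulate_response_data(n_tracks = 2, bins_range = c(4, 4),
                              beta = c(depth_m = 0.3), rho = 0.4,
                              state_effects = c(0, 0, 0, 0), seed = 5)
  d$state <- NULL
  m <- brs_model(y ~ depth_m, d, correlation = "constant", weights = "none")
  rho <- coef(m$fit$modelStruct$corStruct, unconstrained = FALSE)
  R <- matrix(rho, 4, 4); diag(R) <- 1
  V <- matrix(0, 8, 8); V[1:4, 1:4] <- R; V[5:8, 5:8] <- R
  X <- cbind(1, m$data$depth_m)
  beta_hat <- oracle_gls(X, m$data$y, V)
  expect_equal(unname(coef(m)), as.vector(beta_hat), tolerance = 1e-6)
})

test_that("model summary flags significance and falls back gracefully", {
  d <- simulate_response_data(n_tracks = 25, bins_range = c(8, 10),
                              beta = c(depth_m = 0.5), rho = 0.3,
                              state_effects = c(0, 0.5, 1, 0.3), seed = 6)
  m <- brs_model(y ~ state + depth_m, d, correlation = "ar1")
  s <- summary(m)
  expect_true(all(c("term", "estimate", "se", "p", "sig") %in% names(s)))
  expect_true(s$sig[s$term == "depth_m"])
  expect_true("(Intercept)" %in% s$term)
  expect_true(is.finite(BIC(m)))
  expect_equal(m$correlation, "ar1")
  expect_equal(length(residuals(m)), nrow(d))
  expect_equal(length(predict(m)), nrow(d))
  # random-intercept variant runs and returns fixed effects
  m2 <- brs_model(y ~ state + depth_m, d, correlation = "constant",
                  random_intercept = TRUE)
  expect_true("depth_m" %in% names(coef(m2)))
})

test_that("BIC prefers AR1 residuals on autocorrelated data", {
  ok <- replicate(30, {
    d <- simulate_response_data(n_tracks = 25, bins_range = c(8, 12),
                                beta = c(depth_m = 0.1), rho = 0.5,
                                seed = sample.int(1e6, 1))
    m1 <- brs_model(y ~ state + depth_m, d, correlation = "ar1")
    m0 <- brs_model(y ~ state + depth_m, d, correlation = "none")
    BIC(m1) < BIC(m0)
  })
  expect_gte(mean(ok), 0.95)
})

test_that("stepwise BIC never beats and usually equals exhaustive search", {
  set.seed(7)
  for (k in 1:3) {
    d <- simulate_response_data(n_tracks = 20, bins_range = c(6, 10),
                                beta = c(depth_m = 0.3, z1 = 0.4),
                                rho = 0.3, n_noise = 3,
                                seed = sample.int(1e6, 1))
    cand <- c("depth_m", "z1", "z2", "z3")
    m <- bic_stepwise(y ~ state, natural = "depth_m",
                      impact = c("z1", "z2", "z3"), data = d,
                      correlation = "ar1")
    fit_bic <- function(terms) {
      f <- if (length(terms))
        stats::update(y ~ state, paste(". ~ . +", paste(terms, collapse = "+")))
      else y ~ state
      BIC(brs_model(f, d, correlation = "ar1", method = "ML"))
    }
    subsets <- unlist(lapply(0:4, function(s) combn(cand, s, simplify = FALSE)),
                      recursive = FALSE)
    best <- min(vapply(subsets, fit_bic, numeric(1)))
    step_bic <- fit_bic(attr(m, "selected"))
    expect_gte(step_bic, best - 1e-6)
    # the strong predictors should be found
    expect_true(all(c("depth_m", "z1") %in% attr(m, "selected")))
    path <- attr(m, "selection_path")
    expect_equal(path$action[1], "start")
    expect_true(all(diff(path$bic) <= 0.011))
  }
})

test_that("PCA scores match eigen-decomposition with a stable sign convention", {
  set.seed(8)
  # two perfectly correlated columns: first component holds all the variance
  a <- rnorm(200)
  p2 <- pca_scores(cbind(a, 2 * a + 3), n_components = 1)
  expect_equal(p2$var_frac[1], 1, tolerance = 1e-12)

  # independent standardized columns: near-isotropic variance fractions
  m <- matrix(rnorm(5 * 20000), ncol = 5)
  pi5 <- pca_scores(m, n_components = 3)
  expect_true(all(abs(pi5$var_frac - 0.2) < 0.02))

  # random matrices: eigenvalues match a direct eigen oracle
  for (k in 1:5) {
    mm <- matrix(rnorm(50 * 6), ncol = 6) %*% diag(runif(6, 0.5, 2))
    p <- pca_scores(mm)
    ev <- eigen(cor(mm))$values
    expect_equal(p$var_frac, ev / sum(ev), tolerance = 1e-9)
    expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)
    # sign convention: dominant loading positive
    expect_true(all(apply(p$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  }
  # missing rows preserved as NA scores
  mm <- matrix(rnorm(40), ncol = 4); mm[3, 2] <- NA
  p <- pca_scores(mm)
  expect_true(is.na(p$scores[3, 1]) && !is.na(p$scores[4, 1]))
  expect_error(pca_scores(cbind(a, a, a), n_components = 3), "non-degenerate")
})
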