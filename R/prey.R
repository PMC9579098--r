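# Benthic prey interpolation: inverse-distance weighting and regression
# kriging (linear depth trend + ordinary kriging of residuals under a
# WLS-fitted exponential variogram), per-bin biomass maxima, and the
# behavior-state ANOVA.

#' Inverse-distance-weighted interpolation
#'
#' `sum(w_i z_i) / sum(w_i)` with `w_i = d_i^-power` over the `k` nearest
#' samples; a query coinciding with a sample returns that sample's value
#' exactly.
#'
#' @param sx,sy,sz Sample coordinates (km) and values.
#' @param x,y Query coordinates (vectors).
#' @param power IDW power (default 2).
#' @param k Number of nearest neighbours used (default 12; `Inf` = all).
#' @return Numeric vector of predictions.
#' @export
idw_interpolate <- function(sx, sy, sz, x, y, power = 2, k = 12) {
  if (length(sx) == 0L) stop("empty sample set")
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    d <- sqrt((sx - x[i])^2 + (sy - y[i])^2)
    if (any(d == 0)) { out[i] <- sz[which(d == 0)[1]]; next }
    use <- order(d)[seq_len(min(k, length(d)))]
    w <- d[use]^(-power)
    out[i] <- sum(w * sz[use]) / sum(w)
  }
  out
}

#' Empirical semivariogram
#'
#' Classical (Matheron) estimator on distance bins.
#'
#' @param sx,sy,z Sample coordinates and values.
#' @param n_bins Number of distance bins (default 15).
#' @param max_dist Maximum pair distance used (default half the maximum
#'   pairwise distance).
#' @return data.frame: `dist` (bin mean distance), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(sx, sy, z, n_bins = 15, max_dist = NULL) {
  d <- as.matrix(stats::dist(cbind(sx, sy)))
  g <- 0.5 * outer(z, z, "-")^2
  iu <- upper.tri(d)
  dd <- d[iu]; gg <- g[iu]
  if (is.null(max_dist)) max_dist <- max(dd) / 2
  keep <- dd > 0 & dd <= max_dist
  dd <- dd[keep]; gg <- gg[keep]
  br <- seq(0, max_dist, length.out = n_bins + 1L)
  bin <- cut(dd, br, include.lowest = TRUE)
  out <- data.frame(dist = tapply(dd, bin, mean),
                    gamma = tapply(gg, bin, mean),
                    n_pairs = as.integer(table(bin)))
  out <- out[is.finite(out$dist) & out$n_pairs > 0, ]
  rownames(out) <- NULL
  out
}

#' Fit an exponential variogram model by weighted least squares
#'
#' Model `gamma(h) = nugget + psill * (1 - exp(-h / range))`, fitted to an
#' empirical variogram with weights `n_pairs / gamma_model^2` (Cressie-style
#' WLS). Falls back to moment-based defaults (nugget 0, psill = var(z),
#' range = a third of the maximum lag) if the optimizer fails.
#'
#' @param ev Output of [empirical_variogram()].
#' @param fix_nugget Optional fixed nugget (e.g. 0 for exact interpolation).
#' @return List `(nugget, psill, range, converged)`.
#' @export
fit_variogram <- function(ev, fix_nugget = NULL) {
  psill0 <- max(ev$gamma, 1e-8)
  range0 <- max(ev$dist) / 3
  obj <- function(par) {
    ng <- if (is.null(fix_nugget)) exp(par[1]) else fix_nugget
    ps <- exp(par[if (is.null(fix_nugget)) 2 else 1])
    rg <- exp(par[if (is.null(fix_nugget)) 3 else 2])
    m <- ng + ps * (1 - exp(-ev$dist / rg))
    sum(ev$n_pairs * (ev$gamma - m)^2 / pmax(m, 1e-10)^2)
  }
  p0 <- if (is.null(fix_nugget)) log(c(psill0 / 10, psill0, range0)) else
    log(c(psill0, range0))
  fit <- try(stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000)), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) {
    warning("variogram fit did not converge; using moment-based defaults")
    return(list(nugget = if (is.null(fix_nugget)) 0 else fix_nugget,
                psill = psill0, range = range0, converged = FALSE))
  }
  par <- fit$par
  if (is.null(fix_nugget))
    list(nugget = exp(par[1]), psill = exp(par[2]), range = exp(par[3]),
         converged = fit$convergence == 0)
  else
    list(nugget = fix_nugget, psill = exp(par[1]), range = exp(par[2]),
         converged = fit$convergence == 0)
}

# Exponential covariance implied by the variogram model (C(0) includes the
# nugget).
.vgm_cov <- function(h, vgm) {
  ifelse(h == 0, vgm$nugget + vgm$psill, vgm$psill * exp(-h / vgm$range))
}

#' Regression kriging with a depth covariate
#'
#' Removes a linear depth trend by ordinary least squares, kriges the
#' residuals by ordinary kriging under an exponential variogram (fitted by
#' WLS on the empirical variogram unless supplied), and adds the trend back
#' at the query points. With a zero nugget the predictor is exact at the
#' sample points. A singular kriging system is ridge-stabilized with a
#' warning.
#'
#' @param sx,sy,sz Sample coordinates (km) and values.
#' @param sdepth Depth (m) at the samples.
#' @param x,y,depth Query coordinates and depths.
#' @param vgm Optional variogram list `(nugget, psill, range)`; fitted from
#'   the residuals when `NULL`.
#' @param fix_nugget Passed to [fit_variogram()] (default 0: exact
#'   interpolation).
#' @return List with `pred` (predictions), `var` (kriging variance of the
#'   residual field, >= 0), `trend` (lm fit), `vgm` (variogram used).
#' @export
krige_interpolate <- function(sx, sy, sz, sdepth, x, y, depth,
                              vgm = NULL, fix_nugget = 0) {
  n <- length(sx)
  if (n < 5L) stop("kriging needs at least 5 samples")
  tr <- stats::lm(sz ~ sdepth)
  res <- stats::residuals(tr)
  if (is.null(vgm)) {
    ev <- empirical_variogram(sx, sy, res)
    vgm <- if (nrow(ev) >= 3 && stats::var(res) > 0)
      fit_variogram(ev, fix_nugget = fix_nugget)
    else list(nugget = fix_nugget, psill = max(stats::var(res), 1e-12),
              range = max(stats::dist(cbind(sx, sy))) / 3, converged = FALSE)
  }
  D <- as.matrix(stats::dist(cbind(sx, sy)))
  C <- .vgm_cov(D, vgm)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  ok <- try(solve(A), silent = TRUE)
  if (inherits(ok, "try-error")) {
    warning("singular kriging system; ridge-stabilized")
    A[seq_len(n), seq_len(n)] <- A[seq_len(n), seq_len(n)] + diag(1e-8 * (vgm$nugget + vgm$psill), n)
    ok <- solve(A)
  }
  sill <- vgm$nugget + vgm$psill
  pred <- numeric(length(x)); kv <- numeric(length(x))
  b_tr <- stats::coef(tr)
  b_tr[is.na(b_tr)] <- 0   # rank-deficient trend (e.g. constant depth)
  for (i in seq_along(x)) {
    h <- sqrt((sx - x[i])^2 + (sy - y[i])^2)
    c0 <- .vgm_cov(h, vgm)
    lam <- ok %*% c(c0, 1)
    pred[i] <- b_tr[1] + b_tr[2] * depth[i] + sum(lam[seq_len(n)] * res)
    kv[i] <- max(0, sill - sum(lam[seq_len(n)] * c0) - lam[n + 1L])
  }
  list(pred = pred, var = kv, trend = tr, vgm = vgm)
}

#' Per-bin maximum interpolated biomass
#'
#' Maximum of an interpolated biomass surface over a bin's resampled
#' positions; positions deeper than `max_depth_m` (outside the benthic
#' sampling domain) are excluded, and a bin with no in-domain position is
#' missing.
#'
#' @param positions data.frame of the bin's positions (`x`, `y`).
#' @param interpolator Function `(x, y) -> biomass`.
#' @param depth_fun Function `(x, y) -> depth (m)`, or `NULL` to skip the
#'   domain check.
#' @param max_depth_m Domain limit (default 20 m isobath).
#' @return Scalar maximum or `NA`.
#' @export
bin_max_biomass <- function(positions, interpolator, depth_fun = NULL,
                            max_depth_m = 20) {
  x <- positions$x; y <- positions$y
  if (!is.null(depth_fun)) {
    keep <- depth_fun(x, y) <= max_depth_m
    x <- x[keep]; y <- y[keep]
  }
  if (!length(x)) return(NA_real_)
  max(interpolator(x, y))
}

#' One-way ANOVA of prey biomass among behavioral states
#'
#' For each biomass column, a one-way ANOVA of biomass on behavior state
#' plus a state-by-taxon median table, mirroring how benthic availability
#' at whale locations is compared across feeding, feeding/traveling,
#' traveling and mixed behavior.
#'
#' @param data data.frame with a `state` column (>= 2 levels with >= 2 rows
#'   each) and one column per taxon.
#' @param taxa Character vector of biomass column names.
#' @return List with `anova` (data.frame: `taxon`, `df`, `F`, `p`) and
#'   `medians` (state x taxon matrix of group medians).
#' @export
biomass_anova <- function(data, taxa) {
  st <- factor(data$state)
  if (nlevels(st) < 2L) stop("need at least 2 behavior states")
  if (any(table(st) < 2L)) stop("every state needs at least 2 bins")
  res <- lapply(taxa, function(tx) {
    if (stats::var(data[[tx]]) == 0)   # degenerate: constant response
      return(data.frame(taxon = tx, df = nlevels(st) - 1L, F = 0, p = 1))
    fit <- stats::aov(data[[tx]] ~ st)
    an <- summary(fit)[[1]]
    data.frame(taxon = tx, df = an$Df[1], F = an$`F value`[1],
               p = an$`Pr(>F)`[1])
  })
  med <- sapply(taxa, function(tx) tapply(data[[tx]], st, stats::median))
  list(anova = do.call(rbind, res), medians = med)
}
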