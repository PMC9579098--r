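# Behavioral response models: response transforms, collinearity screening,
# inverse-probability (Horvitz-Thompson) bin weights, weighted GLS / mixed
# models with selectable within-track residual correlation, BIC stepwise
# covariate selection, and PCA-score responses.

#' Transform a response variable
#'
#' The transforms used for approximately-normal modeling of movement and
#' respiration responses: `logit` for `[0, 1]` indices (with the boundary
#' squeeze `x -> (x (n - 1) + 0.5) / n` so 0 and 1 stay finite), natural
#' `ln` for positive variables (speed, distances, respiration durations),
#' `cos`/`sin` for directions in degrees, `identity` otherwise.
#'
#' @param x Numeric vector.
#' @param kind One of `"logit"`, `"ln"`, `"identity"`, `"cos"`, `"sin"`.
#' @param n Squeeze sample size for `logit` (default `length(x)`).
#' @return Transformed vector.
#' @export
transform_response <- function(x, kind = c("identity", "logit", "ln", "cos", "sin"),
                               n = length(x)) {
  kind <- match.arg(kind)
  switch(kind,
    identity = x,
    logit = {
      if (any(x < 0 | x > 1, na.rm = TRUE))
        stop("logit transform requires values in [0, 1]")
      z <- (x * (n - 1) + 0.5) / n
      log(z / (1 - z))
    },
    ln = {
      bad <- which(x <= 0)
      if (length(bad))
        stop("ln transform of non-positive value at position ", bad[1])
      log(x)
    },
    cos = cos(x * pi / 180),
    sin = sin(x * pi / 180))
}

#' Invert a response transform
#'
#' Exact inverse of [transform_response()] for the invertible kinds.
#'
#' @inheritParams transform_response
#' @param y Transformed values.
#' @export
inv_transform_response <- function(y, kind = c("identity", "logit", "ln"),
                                   n) {
  kind <- match.arg(kind)
  switch(kind,
    identity = y,
    logit = {
      z <- 1 / (1 + exp(-y))
      (z * n - 0.5) / (n - 1)
    },
    ln = exp(y))
}

#' Screen covariates for collinearity
#'
#' Pairwise Pearson correlations among continuous covariates; pairs with
#' `|r|` above the threshold are flagged. The retained set is built
#' greedily: columns listed in `prefer` first (e.g. keeping SEL_30s and
#' cSEL over their SPL/PK duplicates), then the remaining columns in input
#' order, each kept only if not collinear with an already-kept column.
#' Constant columns (undefined r) are reported separately.
#'
#' @param data data.frame of candidate covariates (non-numeric columns
#'   ignored).
#' @param threshold Absolute-correlation threshold (default 0.60).
#' @param prefer Character vector of column names to retain preferentially.
#' @return List: `cor` (correlation matrix), `flagged` (data.frame `var1`,
#'   `var2`, `r`), `retained`, `constant`.
#' @export
collinearity_screen <- function(data, threshold = 0.60, prefer = NULL) {
  num <- data[vapply(data, is.numeric, logical(1))]
  if (ncol(num) < 2L) stop("need at least 2 continuous covariates")
  sds <- vapply(num, function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  constant <- names(num)[!is.na(sds) & sds == 0]
  live <- setdiff(names(num), constant)
  cm <- suppressWarnings(stats::cor(num[live], use = "pairwise.complete.obs"))
  iu <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(cm)[iu[, 1]],
                        var2 = colnames(cm)[iu[, 2]],
                        r = cm[iu])
  ordered <- c(intersect(prefer, live), setdiff(live, prefer))
  retained <- character(0)
  for (v in ordered) {
    if (!length(retained) || all(abs(cm[v, retained]) <= threshold, na.rm = TRUE))
      retained <- c(retained, v)
  }
  list(cor = cm, flagged = flagged, retained = retained, constant = constant)
}

#' Horvitz-Thompson style inverse-probability bin weights
#'
#' Each bin of track `j` (with `n_j` bins among `J` tracks and `N` bins in
#' total) receives weight `N / (J n_j)`: weights are inversely proportional
#' to the track's representation, every track carries equal total mass
#' `N / J`, and the weights sum to `N`.
#'
#' @param track_ids Vector of track identifiers, one per bin.
#' @return Numeric weight vector.
#' @export
ht_weights <- function(track_ids) {
  f <- factor(track_ids)
  nj <- table(f)
  N <- length(track_ids); J <- nlevels(f)
  as.numeric(N / (J * nj[f]))
}

#' Fit a weighted behavioral response model
#'
#' The central fitting function: a linear model for a (transformed)
#' response with within-track residual correlation, estimated by
#' generalized least squares (or, with a track-level random intercept, a
#' linear mixed model), with observations weighted by inverse-probability
#' track weights. Estimation is by REML by default (use ML to compare
#' models differing in fixed effects, as [bic_stepwise()] does).
#'
#' Residual correlation within tracks can be `"ar1"` (first-order
#' autoregressive over the bin sequence), `"constant"` (compound symmetry),
#' `"unstructured"` (general symmetric), or `"none"`. If the requested
#' structure fails to converge, the fit falls back along
#' unstructured/ar1 -> constant -> none with a warning.
#'
#' @param formula Model formula for the (already transformed) response.
#' @param data data.frame of bins; rows with missing model variables are
#'   dropped listwise (count recorded).
#' @param track Name of the track/follow grouping column (default
#'   `"track_id"`).
#' @param correlation Residual correlation structure (see above).
#' @param weights `"ht"` (default) for [ht_weights()] by track, `"none"`
#'   for unweighted, or a numeric vector of per-row weights (recycled after
#'   listwise deletion by name safety: supply full-length).
#' @param method `"REML"` (default) or `"ML"`.
#' @param random_intercept Add a track-level random intercept (fits via
#'   [nlme::lme()] instead of [nlme::gls()]).
#' @return Object of class `brs_model` with `print`, `summary`, `coef`,
#'   `vcov`, `confint`, `predict`, `residuals`, `fitted`, `logLik`, `BIC`
#'   and `plot` methods.
#' @export
brs_model <- function(formula, data, track = "track_id",
                      correlation = c("ar1", "constant", "unstructured", "none"),
                      weights = "ht", method = c("REML", "ML"),
                      random_intercept = FALSE) {
  correlation <- match.arg(correlation)
  method <- match.arg(method)
  if (!track %in% names(data)) stop("grouping column '", track, "' not in data")

  vars <- intersect(all.vars(formula), names(data))
  keep <- stats::complete.cases(data[vars])
  if (is.numeric(weights) && length(weights) != nrow(data))
    stop("numeric weights must have one entry per row of data")
  dd <- data[keep, , drop = FALSE]
  wnum <- if (is.numeric(weights)) as.numeric(weights)[keep] else NULL
  n_dropped <- sum(!keep)
  dd$.track <- factor(dd[[track]])
  ord <- order(dd$.track)
  dd <- dd[ord, , drop = FALSE]
  dd$.seq <- stats::ave(seq_len(nrow(dd)), dd$.track, FUN = seq_along)

  w <- if (identical(weights, "ht")) ht_weights(dd$.track)
  else if (identical(weights, "none")) rep(1, nrow(dd))
  else wnum[ord]
  dd$.w <- w
  dd$.iw <- 1 / w
  vf <- nlme::varFixed(~.iw)

  cs_for <- function(kind) switch(kind,
    ar1 = nlme::corAR1(form = ~.seq | .track),
    constant = nlme::corCompSymm(form = ~1 | .track),
    unstructured = nlme::corSymm(form = ~.seq | .track),
    none = NULL)

  chain <- switch(correlation,
    unstructured = c("unstructured", "constant", "none"),
    ar1 = c("ar1", "constant", "none"),
    constant = c("constant", "none"),
    none = "none")
  fit <- NULL; used <- NULL; notes <- character(0)
  for (k in chain) {
    fit <- if (random_intercept)
      try(nlme::lme(fixed = formula, data = dd, random = ~1 | .track,
                    correlation = cs_for(k), weights = vf, method = method,
                    control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                               msMaxIter = 200, returnObject = TRUE)),
          silent = TRUE)
    else
      try(nlme::gls(model = formula, data = dd, correlation = cs_for(k),
                    weights = vf, method = method,
                    control = nlme::glsControl(maxIter = 200, msMaxIter = 200,
                                               returnObject = TRUE)),
          silent = TRUE)
    if (!inherits(fit, "try-error")) { used <- k; break }
    notes <- c(notes, sprintf("correlation '%s' failed: %s", k,
                              conditionMessage(attr(fit, "condition"))))
  }
  if (inherits(fit, "try-error"))
    stop("model failed to converge under any correlation structure:\n",
         paste(notes, collapse = "\n"))
  if (length(notes)) warning(paste(notes, collapse = "; "),
                             "; fell back to '", used, "'")

  structure(list(fit = fit, formula = formula, data = dd, track = track,
                 correlation = used, requested_correlation = correlation,
                 weights_scheme = if (is.numeric(weights)) "custom" else weights,
                 method = method, random_intercept = random_intercept,
                 n = nrow(dd), n_dropped = n_dropped, notes = notes,
                 call = match.call()),
            class = "brs_model")
}

#' @export
print.brs_model <- function(x, ...) {
  cat("Behavioral response model (", if (x$random_intercept) "LME" else "GLS",
      ", correlation = ", x$correlation, ", weights = ", x$weights_scheme,
      ", ", x$method, ")\n", sep = "")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d bins in %d tracks (%d dropped for missingness); BIC = %.2f\n",
              x$n, nlevels(x$data$.track), x$n_dropped, stats::BIC(x$fit)))
  print(round(coef(x), 4))
  invisible(x)
}

#' Summarize a behavioral response model
#'
#' @param object A `brs_model`.
#' @param alpha Significance level for the flag column (default 0.05, the
#'   conventional reporting threshold for these coefficient tables).
#' @param ... Unused.
#' @return data.frame: `term`, `estimate`, `se`, `t`, `p`, `sig`.
#' @export
summary.brs_model <- function(object, alpha = 0.05, ...) {
  tt <- summary(object$fit)$tTable
  out <- data.frame(term = rownames(tt), estimate = tt[, 1], se = tt[, 2],
                    t = tt[, "t-value"], p = tt[, "p-value"],
                    sig = tt[, "p-value"] < alpha, row.names = NULL)
  attr(out, "bic") <- stats::BIC(object$fit)
  attr(out, "correlation") <- object$correlation
  class(out) <- c("summary.brs_model", "data.frame")
  out
}

#' @export
print.summary.brs_model <- function(x, ...) {
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 4); df$se <- round(df$se, 4)
  df$t <- round(df$t, 2); df$p <- signif(df$p, 3)
  print(df)
  cat(sprintf("BIC = %.2f (correlation: %s)\n", attr(x, "bic"),
              attr(x, "correlation")))
  invisible(x)
}

#' @export
coef.brs_model <- function(object, ...) {
  if (object$random_intercept) nlme::fixef(object$fit) else coef(object$fit)
}

#' @export
vcov.brs_model <- function(object, ...) stats::vcov(object$fit)

#' @export
confint.brs_model <- function(object, parm, level = 0.95, ...) {
  tt <- summary(object$fit)$tTable
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(tt[, 1] - z * tt[, 2], tt[, 1] + z * tt[, 2])
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.brs_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (object$random_intercept) stats::predict(object$fit, newdata, level = 0)
  else stats::predict(object$fit, newdata)
}

#' @export
residuals.brs_model <- function(object, type = "normalized", ...) {
  stats::residuals(object$fit, type = type)
}

#' @export
fitted.brs_model <- function(object, ...) stats::fitted(object$fit)

#' @export
logLik.brs_model <- function(object, ...) stats::logLik(object$fit)

#' @export
BIC.brs_model <- function(object, ...) stats::BIC(object$fit)

#' @export
plot.brs_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  r <- residuals(x)
  graphics::plot(fitted(x), r, xlab = "fitted", ylab = "normalized residual",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(r, main = "Normal Q-Q"); stats::qqline(r)
  invisible(x)
}

#' BIC stepwise covariate selection
#'
#' Forward-then-backward stepwise selection by BIC over candidate
#' covariates, natural candidates considered before impact candidates (so
#' environmental structure is absorbed before anthropogenic terms are
#' offered). Fits are compared by maximum likelihood; a term enters only if
#' it improves BIC by more than `tie` (ties resolved toward the smaller
#' model) and the backward pass removes any term whose deletion does not
#' worsen BIC by more than `tie`. The selected model is refit by REML.
#'
#' @param base Formula of the always-kept part (e.g. `y ~ state`).
#' @param natural,impact Character vectors of candidate term labels.
#' @param data,track,correlation,weights,random_intercept Passed to
#'   [brs_model()].
#' @param tie BIC tie tolerance (default 0.01).
#' @return The selected `brs_model` (REML refit) with attributes
#'   `selection_path` (data.frame of steps) and `selected` (term labels).
#' @export
bic_stepwise <- function(base, natural = character(0), impact = character(0),
                         data, track = "track_id",
                         correlation = c("ar1", "constant", "unstructured", "none"),
                         weights = "ht", random_intercept = FALSE,
                         tie = 0.01) {
  correlation <- match.arg(correlation)
  # listwise-delete over ALL variables once, so every candidate fit sees the
  # same rows and BICs are comparable
  allv <- unique(c(all.vars(base), unlist(lapply(c(natural, impact), function(tm)
    all.vars(stats::reformulate(tm)))), track))
  allv <- intersect(allv, names(data))
  data <- data[stats::complete.cases(data[allv]), , drop = FALSE]

  fit_ml <- function(terms) {
    f <- if (length(terms))
      stats::update(base, paste(". ~ . +", paste(terms, collapse = " + ")))
    else base
    m <- brs_model(f, data, track = track, correlation = correlation,
                   weights = weights, method = "ML",
                   random_intercept = random_intercept)
    list(model = m, bic = stats::BIC(m$fit))
  }

  current <- character(0)
  cur <- fit_ml(current)
  path <- data.frame(action = "start", term = "", bic = cur$bic)

  for (pool_name in c("natural", "impact")) {
    pool <- setdiff(if (pool_name == "natural") natural else impact, current)
    repeat {
      cand <- setdiff(pool, current)
      if (!length(cand)) break
      trials <- lapply(cand, function(tm)
        try(fit_ml(c(current, tm)), silent = TRUE))
      ok <- !vapply(trials, inherits, logical(1), "try-error")
      if (!any(ok)) break
      bics <- vapply(trials[ok], `[[`, numeric(1), "bic")
      j <- which.min(bics)
      if (bics[j] < cur$bic - tie) {
        current <- c(current, cand[ok][j])
        cur <- trials[ok][[j]]
        path <- rbind(path, data.frame(action = paste0("add_", pool_name),
                                       term = cand[ok][j], bic = cur$bic))
      } else break
    }
  }

  repeat {
    if (!length(current)) break
    trials <- lapply(current, function(tm)
      try(fit_ml(setdiff(current, tm)), silent = TRUE))
    ok <- !vapply(trials, inherits, logical(1), "try-error")
    if (!any(ok)) break
    bics <- vapply(trials[ok], `[[`, numeric(1), "bic")
    j <- which.min(bics)
    if (bics[j] < cur$bic + tie) {
      dropped <- current[ok][j]
      current <- setdiff(current, dropped)
      cur <- trials[ok][[j]]
      path <- rbind(path, data.frame(action = "drop", term = dropped,
                                     bic = cur$bic))
    } else break
  }

  final <- brs_model(cur$model$formula, data, track = track,
                     correlation = correlation, weights = weights,
                     method = "REML", random_intercept = random_intercept)
  attr(final, "selection_path") <- path
  attr(final, "selected") <- current
  final
}

#' Principal component scores of a response matrix
#'
#' Correlation-matrix PCA of complete-case rows, returning the first
#' `n_components` scores (to be used as additional model responses) and the
#' per-component variance fractions. Each loading vector is oriented so its
#' largest-magnitude element is positive.
#'
#' @param mat Numeric matrix or data.frame of response variables.
#' @param n_components Number of components returned (default 3).
#' @return List: `scores` (matrix, `NA` rows preserved), `loadings`,
#'   `var_frac` (all components), `complete` (logical row index).
#' @export
pca_scores <- function(mat, n_components = 3) {
  mat <- as.matrix(mat)
  cc <- stats::complete.cases(mat)
  m <- mat[cc, , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  if (sum(sds > 0) < n_components)
    stop("need at least ", n_components, " non-degenerate columns")
  m <- m[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  if (sum(pc$sdev^2 > 1e-10) < n_components)
    stop("need at least ", n_components, " non-degenerate columns ",
         "(correlation matrix has lower rank)")
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, "*")
  sc <- sweep(pc$x, 2, flip, "*")
  scores <- matrix(NA_real_, nrow(mat), n_components,
                   dimnames = list(NULL, paste0("PC", seq_len(n_components))))
  scores[cc, ] <- sc[, seq_len(n_components), drop = FALSE]
  list(scores = scores,
       loadings = rot[, seq_len(n_components), drop = FALSE],
       var_frac = pc$sdev^2 / sum(pc$sdev^2),
       complete = cc)
}

#' Simulate a bin-level response dataset with known truth
#'
#' Generates an analysis-ready bin table directly at the model level: per
#' track, covariates (behavior state, water depth, seismic SEL, closest
#' seismic-vessel distance, and `n_noise` pure-noise covariates) and a
#' response `b0 + state effect + X beta + AR1(rho) errors`. Used for
#' estimator validation: type-I error, CI coverage of an injected
#' dose-response slope, correlation-structure selection, and stepwise null
#' behavior.
#'
#' @param n_tracks Number of tracks.
#' @param bins_range Range of bins per track (sampled uniformly).
#' @param beta Named numeric vector of true coefficients over any of
#'   `depth_m`, `seis_sel`, `sv_dist_km`, `z1`, `z2`, ... (absent = 0).
#' @param state_effects Numeric length-4 vector of true state effects
#'   (feeding, feed_travel, traveling, mixed; first is reference 0 by
#'   convention).
#' @param b0 Intercept.
#' @param rho AR1 residual correlation within tracks.
#' @param sigma Residual sd.
#' @param n_noise Number of standard-normal noise covariates `z1..`.
#' @param seed Seed.
#' @return data.frame with attribute `truth`.
#' @export
simulate_response_data <- function(n_tracks = 30, bins_range = c(5, 15),
                                   beta = c(), state_effects = c(0, 0, 0, 0),
                                   b0 = 0, rho = 0.3, sigma = 1,
                                   n_noise = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  sizes <- bins_range[1]:bins_range[2]
  for (j in seq_len(n_tracks)) {
    nj <- if (length(sizes) == 1L) sizes else sample(sizes, 1)
    depth <- stats::rnorm(1, 10, 3) + stats::rnorm(nj, 0, 1)
    sel <- stats::rnorm(1, 125, 10) + stats::rnorm(nj, 0, 4)
    dist <- stats::runif(1, 2, 14) + stats::rnorm(nj, 0, 0.5)
    st <- sample(.BRS_STATES, nj, replace = TRUE,
                 prob = c(0.26, 0.33, 0.30, 0.11))
    e <- numeric(nj)
    e[1] <- stats::rnorm(1, 0, sigma)
    if (nj > 1) for (t in 2:nj)
      e[t] <- rho * e[t - 1] + stats::rnorm(1, 0, sigma * sqrt(1 - rho^2))
    d <- data.frame(track_id = sprintf("t%03d", j), bin = seq_len(nj),
                    state = st, depth_m = depth, seis_sel = sel,
                    sv_dist_km = pmax(0.5, dist))
    for (z in seq_len(n_noise)) d[[paste0("z", z)]] <- stats::rnorm(nj)
    lp <- b0 + state_effects[match(st, .BRS_STATES)]
    for (v in names(beta)) lp <- lp + beta[[v]] * d[[v]]
    d$y <- lp + e
    rows[[j]] <- d
  }
  out <- do.call(rbind, rows)
  out$state <- factor(out$state, levels = .BRS_STATES)
  rownames(out) <- NULL
  attr(out, "truth") <- list(beta = beta, state_effects = state_effects,
                             b0 = b0, rho = rho, sigma = sigma)
  out
}
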