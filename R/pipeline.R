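# End-to-end pipeline: simulate -> observe -> geolocate -> resample ->
# bin metrics -> covariates -> PCA -> response models, with a manifest of
# row counts and output checksums, optional stage caching, and the
# case-study timeline extraction.

obj_hash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

write_stage <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, paste0(name, ".csv"))
  # doubles at 17 significant digits so a re-read recovers them exactly
  # (stage caching depends on lossless round trips)
  out <- df
  for (cl in names(out))
    if (is.double(out[[cl]])) {
      v <- sprintf("%.17g", out[[cl]])
      v[is.na(out[[cl]])] <- NA
      out[[cl]] <- v
    }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full synthetic behavioral response pipeline
#'
#' Generates a synthetic study from `config`, pushes it through the whole
#' analysis chain (geolocation of theodolite fixes, 90-s resampling,
#' 10.5-min movement and respiration bins, acoustic/vessel/environment
#' covariates, movement and respiration PCA) and, optionally, fits BIC
#' stepwise response models for a default set of responses. Every stage's
#' row count and an md5 checksum of every written table go into the run
#' manifest, so reruns with the same config and seed are verifiably
#' bit-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory for stage CSVs and
#'   `manifest.json` (requires the jsonlite package for the manifest).
#' @param fit_models Fit default stepwise response models (default TRUE).
#' @param cache If TRUE and `out_dir` holds a manifest whose config hash
#'   matches, stages whose outputs exist are re-read instead of recomputed.
#' @return List: `study`, `positions`, `resampled`, `bins`
#'   (analysis-ready bin table with covariates and PC scores), `resp_bins`,
#'   `models` (list of `brs_model` or NULL), `pca`
#'   (movement/respiration loadings and variance fractions), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, fit_models = TRUE,
                         cache = FALSE) {
  stopifnot(inherits(config, "brs_sim_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cfg_hash <- obj_hash(unclass(config))

  cached <- NULL
  if (cache && !is.null(out_dir) &&
      file.exists(file.path(out_dir, "manifest.json")) &&
      requireNamespace("jsonlite", quietly = TRUE)) {
    mf <- jsonlite::fromJSON(file.path(out_dir, "manifest.json"))
    if (identical(mf$config_hash, cfg_hash)) cached <- mf
  }

  read_stage <- function(name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    if (!is.null(cached) && file.exists(path))
      utils::read.csv(path, stringsAsFactors = FALSE)
    else NULL
  }

  manifest <- list(seed = as.integer(config$seed), config_hash = cfg_hash,
                   stages = list(), checksums = list(), cached = character(0))

  # --- simulate ---------------------------------------------------------
  study <- simulate_study(config)
  env <- study$environment

  # --- geolocate fixes --------------------------------------------------
  positions <- read_stage("positions")
  if (is.null(positions)) {
    pos_list <- lapply(study$observations, function(ob) {
      fx <- ob$fixes
      if (!nrow(fx)) return(NULL)
      p <- fix_to_position(fx$vertical_deg, fx$horizontal_deg, study$station,
                           tide_m = fx$tide_m)
      data.frame(whale_id = fx$whale_id, time = fx$time, x = p$x, y = p$y,
                 lat = p$lat, lon = p$lon, state = fx$state)
    })
    positions <- do.call(rbind, pos_list)
    write_stage(positions, out_dir, "positions")
  } else manifest$cached <- c(manifest$cached, "positions")
  manifest$stages$n_fixes <- nrow(positions)

  # --- resample ---------------------------------------------------------
  resampled <- do.call(rbind, lapply(split(positions, positions$whale_id),
                                     resample_track))
  rownames(resampled) <- NULL
  attr(resampled, "interval") <- 90
  write_stage(resampled, out_dir, "resampled")
  manifest$stages$n_resampled <- nrow(resampled)

  # --- movement bins ----------------------------------------------------
  mbins <- movement_bins(resampled, vessel_tracks = study$vessels$vessel_tracks,
                         shoreline = env$shoreline)
  manifest$stages$n_movement_bins <- if (is.null(mbins)) 0L else nrow(mbins)

  # --- respiration bins (on each whale's movement-bin grid) -------------
  resp <- list()
  for (ob in study$observations) {
    ev <- ob$events
    if (!nrow(ev)) next
    wid <- ev$whale_id[1]
    cyc <- segment_cycles(ev)
    bstart <- if (!is.null(mbins)) mbins$t_start[mbins$whale_id == wid] else numeric(0)
    if (!length(bstart)) next
    rb <- respiration_bins(cyc, bstart)
    if (!is.null(rb)) { rb$whale_id <- wid; resp[[length(resp) + 1L]] <- rb }
  }
  resp_bins <- if (length(resp)) do.call(rbind, resp) else NULL
  manifest$stages$n_respiration_bins <- if (is.null(resp_bins)) 0L else nrow(resp_bins)

  # --- covariates -------------------------------------------------------
  bins <- NULL
  if (!is.null(mbins)) {
    exposure <- lapply(split(resampled, resampled$track_id), exposure_series,
                       field = study$field)
    bins <- assemble_bin_covariates(mbins, exposure,
                                    study$vessels$vessel_tracks, env)
    if (!is.null(resp_bins)) {
      key <- paste(bins$whale_id, bins$t_start)
      rkey <- paste(resp_bins$whale_id, resp_bins$t_start)
      idx <- match(key, rkey)
      for (cl in c("ri_s", "surface_s", "dive_s", "blows_per_surfacing",
                   "surface_rate", "dive_surface_rate", "pct_surface"))
        bins[[cl]] <- resp_bins[[cl]][idx]
    }
  }

  # --- PCA scores -------------------------------------------------------
  pca <- list()
  if (!is.null(bins) && nrow(bins) >= 8) {
    mv_cols <- c("spd", "lin", "rr", "mdir", "trk_r", "range_km",
                 "cos_dir", "sin_dir", "row_cv", "row_sv")
    mv_cols <- mv_cols[mv_cols %in% names(bins) &
                         vapply(bins[mv_cols], function(v) sum(!is.na(v)) > 3 &&
                                  stats::sd(v, na.rm = TRUE) > 0, logical(1))]
    if (length(mv_cols) >= 3) {
      p <- try(pca_scores(bins[mv_cols]), silent = TRUE)
      if (!inherits(p, "try-error")) {
        bins$mv_pc1 <- p$scores[, 1]; bins$mv_pc2 <- p$scores[, 2]
        bins$mv_pc3 <- p$scores[, 3]
        pca$movement <- p[c("loadings", "var_frac")]
      }
    }
    rs_cols <- c("ri_s", "surface_s", "dive_s", "blows_per_surfacing",
                 "surface_rate", "dive_surface_rate", "pct_surface")
    if (all(rs_cols %in% names(bins)) &&
        sum(stats::complete.cases(bins[rs_cols])) >= 8) {
      p <- try(pca_scores(bins[rs_cols]), silent = TRUE)
      if (!inherits(p, "try-error")) {
        bins$resp_pc1 <- p$scores[, 1]; bins$resp_pc2 <- p$scores[, 2]
        bins$resp_pc3 <- p$scores[, 3]
        pca$respiration <- p[c("loadings", "var_frac")]
      }
    }
  }
  write_stage(bins, out_dir, "bins")
  manifest$stages$n_bins <- if (is.null(bins)) 0L else nrow(bins)

  # --- response models --------------------------------------------------
  models <- NULL
  if (fit_models && !is.null(bins) && nrow(bins) >= 30 &&
      length(unique(bins$track_id)) >= 3) {
    md <- bins
    md$state <- factor(md$state, levels = .BRS_STATES)
    md$ln_spd <- transform_response(md$spd, "ln")
    md$lg_lin <- transform_response(md$lin, "logit")
    natural <- c("depth_m", "tide_m", "hour")
    impact <- intersect(c("seis_sel", "ves_csel", "sv_dist_km", "cv_dist_km"),
                        names(md))
    impact <- impact[vapply(md[impact], function(v) sum(!is.na(v)) > 10 &&
                              stats::sd(v, na.rm = TRUE) > 0, logical(1))]
    models <- list(
      speed = try(bic_stepwise(ln_spd ~ state, natural, impact, md),
                  silent = TRUE),
      linearity = try(bic_stepwise(lg_lin ~ state, natural, impact, md),
                      silent = TRUE))
    models <- Filter(function(m) !inherits(m, "try-error"), models)
  }

  if (!is.null(out_dir)) {
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE)
  }

  list(study = study, positions = positions, resampled = resampled,
       bins = bins, resp_bins = resp_bins, models = models, pca = pca,
       manifest = manifest)
}

#' Case-study timeline for one whale
#'
#' Aligned 30-s series of accumulated SEL, SEL_30s, SPL, closest vessel
#' distance, whale speed, and displacement (squared distance, km^2, from
#' the track's point of origin) — the standard individual-response timeline
#' for a whale during a source-vessel approach.
#'
#' @param result Output of [run_pipeline()] (or a list with `study`).
#' @param whale_id Whale identifier as used in the study.
#' @return data.frame: `time`, `x`, `y`, `sel_30s`, `csel`, `spl`,
#'   `cv_dist_km`, `speed_kmh`, `displacement_km2`.
#' @export
case_timeline <- function(result, whale_id) {
  study <- result$study
  ids <- vapply(study$tracks, function(tr) as.character(tr$whale_id), character(1))
  k <- match(as.character(whale_id), ids)
  if (is.na(k)) stop("unknown whale id: ", whale_id)
  tr <- study$tracks[[k]]
  st <- tr$steps
  ex <- evaluate_sound_field(study$field, st$x, st$y, st$time)
  csel <- accumulate_csel(ex$sel_total)
  vt <- study$vessels$vessel_tracks
  cv <- if (nrow(vt)) vapply(seq_len(nrow(st)), function(i) {
    vp <- vessel_positions_at(vt, st$time[i])
    min(sqrt((vp$x - st$x[i])^2 + (vp$y - st$y[i])^2))
  }, numeric(1)) else rep(NA_real_, nrow(st))
  stepl <- sqrt(diff(st$x)^2 + diff(st$y)^2)
  dt_h <- diff(st$time) / 3600
  speed <- c(NA, stepl / dt_h)
  disp <- (st$x - st$x[1])^2 + (st$y - st$y[1])^2
  data.frame(time = st$time, x = st$x, y = st$y,
             sel_30s = ex$sel_total, csel = csel, spl = ex$spl_total,
             cv_dist_km = cv, speed_kmh = speed, displacement_km2 = disp)
}
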