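# Respiration metrics: reconstruct surfacing/dive cycles from focal-follow
# event streams and average seven respiration response variables over
# 10.5-min bins.

#' Segment a focal event stream into surfacing/dive cycles
#'
#' A surfacing is a maximal run of blow events whose inter-blow gaps do not
#' exceed `dive_threshold_s` and that is not split by a `dive_start` event;
#' the interval between consecutive surfacings is a dive. Surfacing
#' duration is last blow minus first blow plus `terminal_allowance_s`.
#' Leading and trailing cycles truncated by the session limits are flagged
#' incomplete.
#'
#' @param events data.frame with columns `time` (s, strictly increasing
#'   within a type) and `event` (`"blow"` or `"dive_start"`); optionally
#'   `whale_id` (one whale per call).
#' @param dive_threshold_s Gap above which consecutive blows belong to
#'   different surfacings when no dive_start event separates them (default
#'   60 s).
#' @param terminal_allowance_s Extra surface time credited after the last
#'   blow of a surfacing (default 0).
#' @param session_end Optional session end time (s); the trailing cycle is
#'   flagged incomplete.
#' @return data.frame of cycles: `surf_start`, `surf_end`, `n_blows`,
#'   `surface_s`, `dive_s` (the dive *following* the surfacing; `NA` for
#'   the last), `mean_ibi_s` (mean inter-blow interval within the
#'   surfacing; `NA` for single-blow surfacings), `complete` (logical: the
#'   surfacing has a following dive and surfacing inside the session).
#'   Zero-row data.frame for an empty stream.
#' @export
segment_cycles <- function(events, dive_threshold_s = 60,
                           terminal_allowance_s = 0, session_end = NULL) {
  blows <- sort(events$time[events$event == "blow"])
  dives <- sort(events$time[events$event == "dive_start"])
  empty <- data.frame(surf_start = numeric(), surf_end = numeric(),
                      n_blows = integer(), surface_s = numeric(),
                      dive_s = numeric(), mean_ibi_s = numeric(),
                      complete = logical())
  if (length(blows) == 0L) return(empty)

  # split blows where the gap exceeds the threshold or a dive_start falls
  # strictly between consecutive blows
  if (length(blows) > 1L) {
    gap <- diff(blows)
    cut <- gap > dive_threshold_s
    if (length(dives))
      for (i in seq_along(gap))
        if (any(dives > blows[i] & dives < blows[i + 1L])) cut[i] <- TRUE
    grp <- cumsum(c(0L, as.integer(cut)))
  } else grp <- 0L

  sp <- split(blows, grp)
  cyc <- do.call(rbind, lapply(sp, function(b) {
    data.frame(surf_start = b[1], surf_end = b[length(b)] + terminal_allowance_s,
               n_blows = length(b),
               surface_s = b[length(b)] - b[1] + terminal_allowance_s,
               mean_ibi_s = if (length(b) > 1L) mean(diff(b)) else NA_real_)
  }))
  rownames(cyc) <- NULL
  ns <- nrow(cyc)
  cyc$dive_s <- c(if (ns > 1L) cyc$surf_start[-1L] - cyc$surf_end[-ns], NA_real_)
  cyc$complete <- c(rep(TRUE, ns - 1L), FALSE)
  if (!is.null(session_end) && ns > 0L && is.na(cyc$dive_s[ns]) &&
      session_end > cyc$surf_end[ns])
    cyc$dive_s[ns] <- NA_real_  # trailing dive truncated; stays incomplete
  cyc[c("surf_start", "surf_end", "n_blows", "surface_s", "dive_s",
        "mean_ibi_s", "complete")]
}

#' Average respiration variables over fixed bins
#'
#' Cycles are assigned to the bin containing their midpoint
#' (`(surf_start + surf_start + surface + dive)/2`); bins with no complete
#' cycle are omitted (never zero-filled). Per bin, over its cycles:
#'
#' * `ri_s` — respiration interval: mean inter-blow gap within surfacings;
#' * `surface_s`, `dive_s` — mean surfacing and dive durations;
#' * `blows_per_surfacing` — mean blow count;
#' * `surface_rate` — total blows / total surface minutes;
#' * `dive_surface_rate` — total blows / total (dive + surface) minutes;
#' * `pct_surface` — 100 * total surface / total (surface + dive).
#'
#' @param cycles Output of [segment_cycles()].
#' @param bin_starts Numeric vector of bin start times (s).
#' @param bin_s Bin length, s (default 630 = 10.5 min).
#' @return data.frame keyed by `bin` (index into `bin_starts`) and
#'   `t_start`, with the seven variables above and `n_cycles`.
#' @export
respiration_bins <- function(cycles, bin_starts, bin_s = 630) {
  cc <- cycles[cycles$complete & !is.na(cycles$dive_s), , drop = FALSE]
  if (!nrow(cc) && nrow(cycles) == 1L) {
    # degenerate session: one continuous surfacing, no dive at all
    cy <- cycles[1, ]
    mid <- cy$surf_start + cy$surface_s / 2
    b <- which(mid >= bin_starts & mid < bin_starts + bin_s)
    if (!length(b)) return(NULL)
    return(data.frame(bin = b[1], t_start = bin_starts[b[1]], n_cycles = 1L,
                      ri_s = cy$mean_ibi_s, surface_s = cy$surface_s,
                      dive_s = NA_real_,
                      blows_per_surfacing = cy$n_blows,
                      surface_rate = cy$n_blows / (cy$surface_s / 60),
                      dive_surface_rate = cy$n_blows / (cy$surface_s / 60),
                      pct_surface = 100))
  }
  if (!nrow(cc)) return(NULL)
  mid <- cc$surf_start + (cc$surface_s + cc$dive_s) / 2
  out <- list()
  for (b in seq_along(bin_starts)) {
    t0 <- bin_starts[b]
    k <- mid >= t0 & mid < t0 + bin_s
    if (!any(k)) next
    cb <- cc[k, , drop = FALSE]
    tot_surf <- sum(cb$surface_s); tot_dive <- sum(cb$dive_s)
    out[[length(out) + 1L]] <- data.frame(
      bin = b, t_start = t0, n_cycles = nrow(cb),
      ri_s = mean(cb$mean_ibi_s, na.rm = TRUE),
      surface_s = mean(cb$surface_s),
      dive_s = mean(cb$dive_s),
      blows_per_surfacing = mean(cb$n_blows),
      surface_rate = if (tot_surf > 0) sum(cb$n_blows) / (tot_surf / 60)
                     else NA_real_,   # all single-blow surfacings: undefined
      dive_surface_rate = sum(cb$n_blows) / ((tot_surf + tot_dive) / 60),
      pct_surface = 100 * tot_surf / (tot_surf + tot_dive))
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res$ri_s[is.nan(res$ri_s)] <- NA_real_
  rownames(res) <- NULL
  res
}
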