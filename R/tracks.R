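#' Kymograph track-pipeline configuration
#'
#' Physical constants and filtering thresholds used by the track pipeline.
#' The mean-speed classification threshold follows the strain under study:
#' 1.6 px/frame for wild-type recordings and 1.0 px/frame for the
#' kinesin-light-chain mutants, where slower overall transport moves the
#' local minimum between the retrograde and stationary speed peaks.
#'
#' @param pixel_size_um Micrometres per pixel (default 0.092).
#' @param frame_interval_s Seconds per camera frame (default 0.1563).
#' @param steps_per_frame Elementary model steps per frame (default 10, so
#'   tau = frame_interval / 10).
#' @param retro_threshold_px_per_frame Mean-speed threshold (pixels per
#'   frame spanned) above which a track counts as directed.
#' @param direction_sign Which position sign convention marks retrograde
#'   movement; kymograph orientation depends on how the line was drawn.
#' @param lags_s Lags (s) at which displacement histograms are extracted.
#' @param moment_lags_s Lags (s) for the empirical moment curves.
#' @param fpt_thresholds_um First-passage thresholds in micrometres
#'   (defaults 1.84 and 3.68, i.e. 20 and 40 pixels).
#' @param strain Optional shortcut: `"wild_type"` sets the 1.6 px/frame
#'   threshold, `"klc1"`/`"klc2"` set 1.0 px/frame.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.092,
                            frame_interval_s = 0.1563,
                            steps_per_frame = 10L,
                            retro_threshold_px_per_frame = 1.6,
                            direction_sign = c("negative_is_retrograde",
                                               "positive_is_retrograde"),
                            lags_s = c(1.563, 3.126),
                            moment_lags_s = 0.1563 * (1:35),
                            fpt_thresholds_um = c(1.84, 3.68),
                            strain = NULL) {
  direction_sign <- match.arg(direction_sign)
  if (!is.null(strain)) {
    strain <- match.arg(strain, c("wild_type", "klc1", "klc2"))
    retro_threshold_px_per_frame <- if (strain == "wild_type") 1.6 else 1.0
  }
  stopifnot(pixel_size_um > 0, frame_interval_s > 0, steps_per_frame >= 1,
            retro_threshold_px_per_frame > 0,
            all(lags_s > 0), all(moment_lags_s > 0),
            all(fpt_thresholds_um > 0))
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 steps_per_frame = as.integer(steps_per_frame),
                 retro_threshold_px_per_frame = retro_threshold_px_per_frame,
                 direction_sign = direction_sign,
                 lags_s = lags_s, moment_lags_s = moment_lags_s,
                 fpt_thresholds_um = fpt_thresholds_um),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys mirror the arguments of
#'   `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  keep <- intersect(names(x), names(formals(pipeline_config)))
  do.call(pipeline_config, x[keep])
}

.sign_retro <- function(config) {
  if (config$direction_sign == "negative_is_retrograde") -1 else 1
}

.lag_frames <- function(lag_s, config, what = "lag") {
  lf <- lag_s / config$frame_interval_s
  if (any(abs(lf - round(lf)) > 1e-6 * pmax(1, lf)))
    stop(sprintf("'%s' must be an integer multiple of the frame interval",
                 what))
  as.integer(round(lf))
}

# Run-length index bounds per track; assumes rows sorted by (track_id, frame)
.track_runs <- function(tracks) {
  r <- rle(as.character(tracks$track_id))
  end <- cumsum(r$lengths)
  list(id = r$values, start = end - r$lengths + 1L, end = end,
       length = r$lengths)
}

#' Read kymograph tracker output
#'
#' Reads the tabular dialect written by kymograph-tracing tools: a CSV with
#' header columns `track_id`, `frame` (integer, 0-based) and `x_px`
#' (sub-pixel position). Rows with missing or non-numeric entries are
#' dropped with a message; rows are sorted by track and frame.
#'
#' @param path CSV file path.
#' @param config A [pipeline_config()].
#' @return A data frame of class `kymo_tracks` with columns `track_id`
#'   (character), `frame` (integer), `x_px` (numeric).
#' @export
read_tracks <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  need <- c("track_id", "frame", "x_px")
  if (!all(need %in% names(header)))
    stop("track file must have columns track_id, frame, x_px")
  cls <- rep("NULL", ncol(header))
  names(cls) <- names(header)
  cls[need] <- "character"   # coerce after the fact so bad cells become NA
  df <- utils::read.csv(path, colClasses = cls)
  df <- df[need]
  if (nrow(df) == 0L) stop("track file is empty")
  df$frame <- suppressWarnings(as.numeric(df$frame))
  df$x_px <- suppressWarnings(as.numeric(df$x_px))
  bad <- !is.finite(df$frame) | !is.finite(df$x_px) | is.na(df$track_id) |
    abs(df$frame - round(df$frame)) > 1e-9
  if (any(bad)) {
    message(sprintf("read_tracks: dropped %d malformed row(s)", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid rows in track file")
  df$frame <- as.integer(round(df$frame))
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("kymo_tracks", "data.frame")
  df
}

#' Average out duplicated time points
#'
#' When a tracker reports two positions for the same track and frame
#' (simultaneous occupancy), the arithmetic mean of the positions replaces
#' the duplicates. Tracks without duplicates pass through unchanged.
#'
#' @param tracks A `kymo_tracks` data frame (sorted, as from
#'   [read_tracks()]).
#' @return A `kymo_tracks` data frame with one row per (track, frame).
#' @export
dedupe_timepoints <- function(tracks) {
  dup <- duplicated(tracks[c("track_id", "frame")])
  if (!any(dup)) return(tracks)
  key <- paste(tracks$track_id, tracks$frame, sep = "\r")
  sums <- rowsum(tracks$x_px, key)
  cnts <- rowsum(rep(1, nrow(tracks)), key)
  keep <- tracks[!dup, , drop = FALSE]
  kkey <- paste(keep$track_id, keep$frame, sep = "\r")
  keep$x_px <- sums[kkey, 1] / cnts[kkey, 1]
  keep <- keep[order(keep$track_id, keep$frame), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("kymo_tracks", "data.frame")
  keep
}

#' Classify tracks as retrograde, stationary or anterograde
#'
#' A track with net displacement `d` pixels over `F` frames spanned counts
#' as directed when `|d| >= threshold * F` (a mean-speed cut in px/frame;
#' the boundary uses `>=`). Directed tracks are labelled retrograde or
#' anterograde by the sign of `d` against the configured sign convention;
#' the rest are stationary. Single-point tracks are unclassified.
#'
#' @param tracks A deduplicated `kymo_tracks` data frame.
#' @param config A [pipeline_config()].
#' @return Data frame with one row per track: `track_id`, `n_points`,
#'   `frames_spanned`, `net_px`, `class` (factor with levels retrograde,
#'   stationary, anterograde, unclassified).
#' @export
classify_tracks <- function(tracks, config = pipeline_config()) {
  runs <- .track_runs(tracks)
  net <- tracks$x_px[runs$end] - tracks$x_px[runs$start]
  span <- tracks$frame[runs$end] - tracks$frame[runs$start]
  thr <- config$retro_threshold_px_per_frame
  d_retro <- .sign_retro(config) * net
  cls <- rep("stationary", length(net))
  # >= at the boundary, with a tolerance so exact-boundary tracks are not
  # lost to floating-point representation of pixel differences
  directed <- span > 0 & abs(net) >= thr * span - 1e-9 * pmax(1, span)
  cls[directed & d_retro > 0] <- "retrograde"
  cls[directed & d_retro < 0] <- "anterograde"
  cls[runs$length < 2L] <- "unclassified"
  data.frame(track_id = runs$id, n_points = runs$length,
             frames_spanned = as.integer(span), net_px = net,
             class = factor(cls, levels = c("retrograde", "stationary",
                                            "anterograde", "unclassified")))
}

.retro_ids <- function(tracks, config, labels) {
  if (is.null(labels)) labels <- classify_tracks(tracks, config)
  labels$track_id[labels$class == "retrograde"]
}

#' Displacement step counts at a fixed lag
#'
#' For every retrograde track spanning at least `lag_s` from its first
#' point, reads the position `lag_s` after the track origin and converts the
#' retrograde displacement to an integer step count
#' `k = round(d_px)` clamped to `[0, n]`, where `n = lag_s / tau` is the
#' number of elementary step attempts. Small anterograde excursions
#' (negative `d`) clamp to 0 and are counted in a warning; the model is
#' one-sided and reversal rates in these recordings are low. Lags are
#' measured from each track's first point only, not with sliding windows,
#' so samples are independent across tracks and counts shrink as the lag
#' grows.
#'
#' @param tracks A deduplicated `kymo_tracks` data frame.
#' @param lag_s Lag in seconds (integer multiple of the frame interval).
#' @param config A [pipeline_config()].
#' @param labels Optional precomputed [classify_tracks()] output.
#' @return Data frame `track_id`, `k`, `x_um` with attributes `n_trials`
#'   (`lag_s/tau`), `lag_s`, `n_clamped_negative`, `n_short`.
#' @export
displacements_at_lag <- function(tracks, lag_s, config = pipeline_config(),
                                 labels = NULL) {
  lf <- .lag_frames(lag_s, config)
  n_trials <- lf * config$steps_per_frame
  ids <- .retro_ids(tracks, config, labels)
  runs <- .track_runs(tracks)
  sel <- which(runs$id %in% ids)
  sgn <- .sign_retro(config)
  out_id <- character(length(sel))
  out_d <- rep(NA_real_, length(sel))
  n_short <- 0L
  for (ii in seq_along(sel)) {
    i <- sel[ii]
    s <- runs$start[i]; e <- runs$end[i]
    f0 <- tracks$frame[s]
    # contiguous frames are the common case; fall back to a search
    j <- s + lf
    if (j > e || tracks$frame[j] != f0 + lf) {
      j <- s - 1L + match(f0 + lf, tracks$frame[s:e])
      if (is.na(j)) { n_short <- n_short + 1L; next }
    }
    out_id[ii] <- runs$id[i]
    out_d[ii] <- sgn * (tracks$x_px[j] - tracks$x_px[s])
  }
  keep <- !is.na(out_d)
  out_id <- out_id[keep]; out_d <- out_d[keep]
  n_neg <- sum(out_d < -0.5)
  if (n_neg > 0)
    warning(sprintf("%d reversal displacement(s) clamped to 0", n_neg))
  k <- pmin(pmax(round(out_d), 0), n_trials)
  res <- data.frame(track_id = out_id, k = as.integer(k),
                    x_um = out_d * config$pixel_size_um)
  attr(res, "n_trials") <- as.integer(n_trials)
  attr(res, "lag_s") <- lag_s
  attr(res, "n_clamped_negative") <- n_neg
  attr(res, "n_short") <- n_short
  res
}

#' Empirical displacement moments across an ensemble
#'
#' Sample mean and unbiased variance of the retrograde displacement (in
#' micrometres, measured from each track's first point, without step
#' rounding) at each configured lag, across the retrograde-classified
#' tracks long enough to contribute. Lags with fewer than two contributing
#' tracks are omitted with a warning. Track counts per lag are
#' non-increasing in the lag.
#'
#' @param tracks A deduplicated `kymo_tracks` data frame.
#' @param config A [pipeline_config()]; lags come from `moment_lags_s`.
#' @param labels Optional precomputed [classify_tracks()] output.
#' @param params Optional [walk_params()]; attaches closed-form theory
#'   columns.
#' @return Data frame `lag_s`, `mean_um`, `var_um2`, `n_tracks` (plus
#'   `theory_mean_um`, `theory_var_um2` with `params`).
#' @export
empirical_moments <- function(tracks, config = pipeline_config(),
                              labels = NULL, params = NULL) {
  ids <- .retro_ids(tracks, config, labels)
  runs <- .track_runs(tracks)
  sel <- which(runs$id %in% ids)
  sgn <- .sign_retro(config)
  lags <- sort(config$moment_lags_s)
  lfs <- .lag_frames(lags, config, "moment_lags_s")
  disp <- matrix(NA_real_, nrow = length(sel), ncol = length(lags))
  for (ii in seq_along(sel)) {
    i <- sel[ii]
    s <- runs$start[i]; e <- runs$end[i]
    f <- tracks$frame[s:e] - tracks$frame[s]
    x <- sgn * (tracks$x_px[s:e] - tracks$x_px[s])
    m <- match(lfs, f)
    disp[ii, ] <- x[m]
  }
  n_per <- colSums(!is.na(disp))
  keep <- n_per >= 2L
  if (any(!keep))
    warning(sprintf("%d lag(s) dropped with fewer than 2 tracks",
                    sum(!keep)))
  px <- config$pixel_size_um
  mu <- colMeans(disp, na.rm = TRUE) * px
  v <- apply(disp, 2, stats::var, na.rm = TRUE) * px^2
  out <- data.frame(lag_s = lags, mean_um = mu, var_um2 = v,
                    n_tracks = n_per)[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(params)) {
    th <- betabinom_moments(out$lag_s, params)
    out$theory_mean_um <- th$mean_um
    out$theory_var_um2 <- th$var_um2
  }
  out
}

#' Empirical first passage times over a distance threshold
#'
#' For each retrograde track, the first frame time (counted from the track
#' origin) at which the cumulative retrograde displacement reaches
#' `threshold_um`; tracks that end first are censored (`NA` time). Censored
#' tracks are reported, not silently dropped, so downstream analyses can
#' account for them.
#'
#' @param tracks A deduplicated `kymo_tracks` data frame.
#' @param threshold_um Positive threshold distance in micrometres.
#' @param config A [pipeline_config()].
#' @param labels Optional precomputed [classify_tracks()] output.
#' @return Data frame `track_id`, `threshold_um`, `frames` (first-crossing
#'   frame offset, `NA` if censored), `t_s`, `censored`.
#' @export
empirical_fpt <- function(tracks, threshold_um, config = pipeline_config(),
                          labels = NULL) {
  if (threshold_um <= 0) stop("'threshold_um' must be positive")
  thr_px <- threshold_um / config$pixel_size_um
  ids <- .retro_ids(tracks, config, labels)
  runs <- .track_runs(tracks)
  sel <- which(runs$id %in% ids)
  sgn <- .sign_retro(config)
  frames <- integer(length(sel)); cens <- logical(length(sel))
  for (ii in seq_along(sel)) {
    i <- sel[ii]
    s <- runs$start[i]; e <- runs$end[i]
    d <- sgn * (tracks$x_px[s:e] - tracks$x_px[s])
    j <- match(TRUE, d >= thr_px)
    if (is.na(j)) {
      cens[ii] <- TRUE; frames[ii] <- NA_integer_
    } else {
      frames[ii] <- tracks$frame[s + j - 1L] - tracks$frame[s]
    }
  }
  data.frame(track_id = runs$id[sel],
             threshold_um = rep(threshold_um, length(sel)),
             frames = frames, t_s = frames * config$frame_interval_s,
             censored = cens)
}
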