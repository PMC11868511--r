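#' Generate a synthetic dataset into an output directory
#'
#' Wrapper around [generate_dataset()] that writes `tracks.csv` and
#' `tracks.manifest.json` into `outdir`. Identical config and seed produce
#' byte-identical files.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [generator_config()] or [strain_preset()] result.
#' @param seed Seed recorded in the manifest; overrides `config$seed`.
#' @return Invisibly, list with `csv` and `manifest` paths.
#' @export
run_generate <- function(outdir, config = strain_preset("wild_type"),
                         seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(outdir, "tracks.csv")
  if (is.null(seed)) seed <- config$seed
  generate_dataset(config, path = csv, seed = seed)
  invisible(list(csv = csv,
                 manifest = file.path(outdir, "tracks.manifest.json")))
}

#' Run the full track-analysis pipeline
#'
#' Reads a track CSV, deduplicates time points, classifies tracks, and
#' writes the classification, per-lag displacement step counts, empirical
#' moment curves and first-passage tables as CSV files, plus an advisory
#' PDF of diagnostic figures (displacement histograms with the fitted
#' beta-binomial overlay, moment curves against the closed-form theory,
#' first-passage histograms with the beta-negative-binomial overlay).
#'
#' @param tracks_csv Input track CSV.
#' @param outdir Output directory.
#' @param config A [pipeline_config()].
#' @param params Optional [walk_params()] used for theory overlays; when
#'   `NULL` the parameters are fitted to the first configured lag.
#' @param plots Write the PDF report?
#' @return Invisibly, a named list of output paths plus the fitted or
#'   supplied `params`.
#' @export
run_analyze <- function(tracks_csv, outdir, config = pipeline_config(),
                        params = NULL, plots = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tracks <- dedupe_timepoints(read_tracks(tracks_csv, config))
  labels <- classify_tracks(tracks, config)
  if (!any(labels$class == "retrograde"))
    stop("no retrograde tracks survive filtering")
  paths <- list()
  paths$classification <- file.path(outdir, "classification.csv")
  utils::write.csv(labels, paths$classification, row.names = FALSE)

  disp <- lapply(config$lags_s, function(lag)
    displacements_at_lag(tracks, lag, config, labels))
  disp_df <- do.call(rbind, lapply(disp, function(d)
    data.frame(track_id = d$track_id, lag_s = attr(d, "lag_s"),
               n_trials = attr(d, "n_trials"), k = d$k, x_um = d$x_um)))
  paths$displacements <- file.path(outdir, "displacements.csv")
  utils::write.csv(disp_df, paths$displacements, row.names = FALSE)

  if (is.null(params)) {
    d1 <- disp[[1]]
    fit <- fit_betabinom(d1$k, attr(d1, "n_trials"))
    params <- walk_params(coef(fit)[["alpha"]], coef(fit)[["beta"]],
                          step_size = config$pixel_size_um,
                          step_time = config$frame_interval_s /
                            config$steps_per_frame)
  }
  mom <- empirical_moments(tracks, config, labels, params = params)
  paths$moments <- file.path(outdir, "moments.csv")
  utils::write.csv(mom, paths$moments, row.names = FALSE)

  fpt_df <- do.call(rbind, lapply(config$fpt_thresholds_um, function(L)
    empirical_fpt(tracks, L, config, labels)))
  paths$fpt <- file.path(outdir, "fpt.csv")
  utils::write.csv(fpt_df, paths$fpt, row.names = FALSE)

  if (plots) {
    paths$report <- file.path(outdir, "report.pdf")
    grDevices::pdf(paths$report, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (lag in config$lags_s)
      plot_displacement_hist(disp_df$k[disp_df$lag_s == lag],
                             unique(disp_df$n_trials[disp_df$lag_s == lag]),
                             params, lag)
    plot_moment_curves(mom)
    for (L in config$fpt_thresholds_um) {
      fr <- fpt_df$frames[fpt_df$threshold_um == L & !fpt_df$censored]
      if (length(fr)) plot_fpt_hist(fr, L, params, config)
    }
  }
  invisible(c(paths, list(params = params)))
}

#' Fit the displacement distribution from a pipeline output file
#'
#' Reads the `displacements.csv` written by [run_analyze()], fits the
#' beta-binomial law at one lag (or jointly across all lags under a common
#' alpha, beta), prints a one-line summary and optionally writes the fit as
#' JSON with the schema `{"strain", "t_seconds", "n_trials", "alpha_hat",
#' "beta_hat", "neg_loglik", "n_samples", "converged"}`.
#'
#' @param displacements_csv Path to a displacements CSV (columns
#'   `track_id`, `lag_s`, `n_trials`, `k`, ...).
#' @param out_json Optional path for the JSON fit record.
#' @param lag_s Lag to fit (default: smallest present). Ignored with
#'   `joint = TRUE`.
#' @param joint Fit all lags jointly under one (alpha, beta)?
#' @param strain Free-text label stored in the JSON.
#' @return The `bbfit` object, invisibly.
#' @export
run_fit <- function(displacements_csv, out_json = NULL, lag_s = NULL,
                    joint = FALSE, strain = NA_character_) {
  if (!file.exists(displacements_csv))
    stop("no such file: ", displacements_csv)
  d <- utils::read.csv(displacements_csv)
  need <- c("lag_s", "n_trials", "k")
  if (!all(need %in% names(d)))
    stop("displacements file must have columns lag_s, n_trials, k")
  if (joint) {
    fit <- fit_betabinom(d$k, d$n_trials)
    t_fit <- sort(unique(d$lag_s))
    n_fit <- sort(unique(d$n_trials))
  } else {
    if (is.null(lag_s)) lag_s <- min(d$lag_s)
    dd <- d[abs(d$lag_s - lag_s) < 1e-9, , drop = FALSE]
    if (nrow(dd) == 0L) stop("no rows at the requested lag")
    fit <- fit_betabinom(dd$k, dd$n_trials[1])
    t_fit <- lag_s
    n_fit <- dd$n_trials[1]
  }
  cat(sprintf(
    "fit [%s] t=%s s: alpha=%.4g beta=%.4g (-logLik %.6g, n=%d%s)\n",
    ifelse(is.na(strain), "sample", strain),
    paste(t_fit, collapse = "+"), coef(fit)[["alpha"]],
    coef(fit)[["beta"]], fit$neg_loglik, fit$n_obs,
    if (fit$converged) "" else ", NOT converged"))
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(strain = strain, t_seconds = t_fit, n_trials = n_fit,
           alpha_hat = coef(fit)[["alpha"]],
           beta_hat = coef(fit)[["beta"]],
           neg_loglik = fit$neg_loglik, n_samples = fit$n_obs,
           converged = fit$converged),
      out_json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(fit)
}

#' Diagnostic figures
#'
#' Base-graphics panels used by [run_analyze()]: displacement histogram
#' with the beta-binomial overlay, empirical moment curves with the
#' closed-form mean/variance, and first-passage histogram with the
#' frame-aggregated beta-negative-binomial overlay. Advisory figures; all
#' quantitative checks run on the CSV outputs.
#'
#' @param k Integer step counts.
#' @param n_trials Attempts per observation.
#' @param params A [walk_params()].
#' @param lag_s Lag (s), used in the title.
#' @return The input, invisibly.
#' @export
plot_displacement_hist <- function(k, n_trials, params, lag_s) {
  graphics::hist(k, breaks = seq(-0.5, n_trials + 0.5, by = 1),
                 freq = FALSE, col = "grey85", border = "grey60",
                 xlab = "displacement (steps of one pixel)",
                 main = sprintf("Displacements at t = %g s", lag_s))
  kk <- 0:n_trials
  graphics::points(kk, dbetabinom(kk, n_trials, params$alpha, params$beta),
                   pch = 16, cex = 0.5, col = "firebrick")
  invisible(k)
}

#' @rdname plot_displacement_hist
#' @param moments Output of [empirical_moments()] with theory columns.
#' @export
plot_moment_curves <- function(moments) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(moments$lag_s, moments$mean_um, pch = 16, col = "firebrick",
                 xlab = "t (s)", ylab = "<x> (um)", main = "Mean")
  if (!is.null(moments$theory_mean_um))
    graphics::lines(moments$lag_s, moments$theory_mean_um)
  graphics::plot(moments$lag_s, moments$var_um2, pch = 16, col = "firebrick",
                 xlab = "t (s)", ylab = "var(x) (um^2)", main = "Variance",
                 log = "xy")
  if (!is.null(moments$theory_var_um2))
    graphics::lines(moments$lag_s, moments$theory_var_um2)
  invisible(moments)
}

#' @rdname plot_displacement_hist
#' @param frames First-crossing frames (uncensored).
#' @param threshold_um Threshold distance (um).
#' @param config A [pipeline_config()].
#' @export
plot_fpt_hist <- function(frames, threshold_um, params, config) {
  k <- round(threshold_um / config$pixel_size_um)
  fi <- config$frame_interval_s
  graphics::hist(frames * fi,
                 breaks = seq(0.5, max(frames) + 0.5, by = 1) * fi,
                 freq = FALSE, col = "grey85", border = "grey60",
                 xlab = "first passage time (s)",
                 main = sprintf("First passage, L = %g um", threshold_um))
  mm <- ceiling(k / config$steps_per_frame):max(frames)
  graphics::points(mm * fi,
                   dbnb_frames(mm, k, params$alpha, params$beta,
                               config$steps_per_frame) / fi,
                   pch = 16, cex = 0.5, col = "firebrick")
  invisible(frames)
}
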