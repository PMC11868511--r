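#' Configuration for the synthetic kymograph-track generator
#'
#' Describes a labelled mixture of the three behavioural classes seen in
#' the recordings: retrograde tracks driven by the heterogeneous random
#' walk (one beta-distributed movement probability per track, aggregated to
#' camera frames), stationary tracks jittering about a constant position,
#' and anterograde tracks drifting the opposite way at constant speed.
#' Localisation error is additive independent Gaussian noise per point.
#'
#' The class fractions in real recordings are not published; the defaults
#' (0.5 retrograde, 0.35 stationary, 0.15 anterograde) are a documented
#' choice, not a measurement. Track durations are uniform on
#' `track_length_frames` (default 10-500 frames, the acquisition cap).
#'
#' @param params A [walk_params()] for the retrograde class.
#' @param fractions Length-3 non-negative vector (retrograde, stationary,
#'   anterograde) summing to 1.
#' @param n_tracks Number of tracks to generate.
#' @param track_length_frames Length-2 integer range; durations are drawn
#'   uniformly from it.
#' @param noise_sigma_px Gaussian localisation noise sd per point, pixels
#'   (retrograde and anterograde tracks).
#' @param anterograde_speed_px_per_frame Constant drift speed of the
#'   anterograde class.
#' @param stationary_jitter_px Positional jitter sd of the stationary
#'   class.
#' @param steps_per_frame Elementary steps per camera frame.
#' @param seed Optional integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(params = walk_params(8.19, 12.95),
                             fractions = c(retrograde = 0.5,
                                           stationary = 0.35,
                                           anterograde = 0.15),
                             n_tracks = 1702L,
                             track_length_frames = c(10L, 500L),
                             noise_sigma_px = 0.5,
                             anterograde_speed_px_per_frame = 2,
                             stationary_jitter_px = 0.5,
                             steps_per_frame = 10L,
                             seed = NULL) {
  params <- .as_walk_params(params)
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-12,
            n_tracks >= 1, length(track_length_frames) == 2L,
            track_length_frames[1] >= 1,
            track_length_frames[2] >= track_length_frames[1],
            noise_sigma_px >= 0, anterograde_speed_px_per_frame > 0,
            stationary_jitter_px >= 0, steps_per_frame >= 1)
  names(fractions) <- c("retrograde", "stationary", "anterograde")
  structure(list(params = params, fractions = fractions,
                 n_tracks = as.integer(n_tracks),
                 track_length_frames = as.integer(track_length_frames),
                 noise_sigma_px = noise_sigma_px,
                 anterograde_speed_px_per_frame =
                   anterograde_speed_px_per_frame,
                 stationary_jitter_px = stationary_jitter_px,
                 steps_per_frame = as.integer(steps_per_frame),
                 seed = seed),
            class = "generator_config")
}

#' Generator presets for the three studied strains
#'
#' Returns a [generator_config()] whose retrograde class uses the
#' displacement-fit parameters of the given strain — wild type
#' (alpha 8.19, beta 12.95), the klc-1 null mutant (3.18, 4.15) or the
#' klc-2 reduced-function mutant (5.12, 12.87) — with the imaging constants
#' a = 0.092 um, tau = 0.01563 s, 10 steps per frame, and a track count
#' sized so the expected number of retrograde tracks matches the order of
#' the published histograms (851, 438 and 1118 at the 1.563 s lag).
#'
#' @param strain `"wild_type"`, `"klc1"` or `"klc2"`.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @examples
#' strain_preset("wild_type")$params
#' @export
strain_preset <- function(strain = c("wild_type", "klc1", "klc2"), ...) {
  strain <- match.arg(strain)
  ab <- switch(strain,
               wild_type = c(8.19, 12.95),
               klc1 = c(3.18, 4.15),
               klc2 = c(5.12, 12.87))
  n_retro <- switch(strain, wild_type = 851, klc1 = 438, klc2 = 1118)
  defaults <- list(params = walk_params(ab[1], ab[2]),
                   n_tracks = as.integer(round(n_retro / 0.5)))
  args <- utils::modifyList(defaults, list(...))
  cfg <- do.call(generator_config, args)
  attr(cfg, "strain") <- strain
  cfg
}

#' Generate a labelled synthetic kymograph-track dataset
#'
#' Draws a class for every track, simulates it at camera-frame resolution
#' and (optionally) writes the track table in the CSV dialect consumed by
#' [read_tracks()] plus a JSON manifest with the ground truth. Retrograde
#' tracks accumulate Binomial(`steps_per_frame`, p) pixel steps per frame —
#' the heterogeneous walk observed at frame resolution — moving in the
#' negative-x direction to match the pipeline's default sign convention.
#'
#' @param config A [generator_config()].
#' @param path Output CSV path, or `NULL` to skip writing.
#' @param manifest_path Output JSON manifest path (default: `path` with a
#'   `.manifest.json` suffix); `NULL` skips writing the manifest.
#' @param seed Seed; defaults to `config$seed`.
#' @return Invisibly, a list with `tracks` (the generated `kymo_tracks`
#'   data frame), `manifest` (list: config echo, seed, per-track `class`,
#'   `p_true`, `n_frames`), and the file paths written.
#' @export
generate_dataset <- function(config = generator_config(), path = NULL,
                             manifest_path = if (!is.null(path))
                               paste0(sub("\\.csv$", "", path),
                                      ".manifest.json"),
                             seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_tracks
  classes <- sample(c("retrograde", "stationary", "anterograde"), n,
                    replace = TRUE, prob = config$fractions)
  lens <- sample(seq.int(config$track_length_frames[1],
                         config$track_length_frames[2]),
                 n, replace = TRUE)
  p_true <- rep(NA_real_, n)
  is_retro <- classes == "retrograde"
  p_true[is_retro] <- stats::rbeta(sum(is_retro), config$params$alpha,
                                   config$params$beta)
  width <- max(5L, nchar(as.character(n)))
  ids <- sprintf("trk%0*d", width, seq_len(n))
  xs <- vector("list", n)
  for (i in seq_len(n)) {
    len <- lens[i]
    x0 <- stats::runif(1, 50, 150)
    xs[[i]] <- switch(
      classes[i],
      retrograde = x0 -
        cumsum(c(0L, stats::rbinom(len, config$steps_per_frame,
                                   p_true[i]))) +
        stats::rnorm(len + 1L, 0, config$noise_sigma_px),
      stationary = x0 + stats::rnorm(len + 1L, 0,
                                     config$stationary_jitter_px),
      anterograde = x0 +
        config$anterograde_speed_px_per_frame * (0:len) +
        stats::rnorm(len + 1L, 0, config$noise_sigma_px))
  }
  tracks <- data.frame(
    track_id = rep(ids, lens + 1L),
    frame = unlist(lapply(lens, function(l) 0:l), use.names = FALSE),
    x_px = unlist(xs, use.names = FALSE))
  class(tracks) <- c("kymo_tracks", "data.frame")
  manifest <- list(
    generator = list(alpha = config$params$alpha,
                     beta = config$params$beta,
                     step_size_um = config$params$step_size,
                     step_time_s = config$params$step_time,
                     fractions = as.list(config$fractions),
                     n_tracks = n,
                     noise_sigma_px = config$noise_sigma_px,
                     anterograde_speed_px_per_frame =
                       config$anterograde_speed_px_per_frame,
                     stationary_jitter_px = config$stationary_jitter_px,
                     steps_per_frame = config$steps_per_frame,
                     seed = seed),
    class_counts = as.list(table(factor(classes,
      levels = c("retrograde", "stationary", "anterograde")))),
    tracks = data.frame(track_id = ids, class = classes,
                        p_true = p_true, n_frames = lens + 1L))
  if (!is.null(path)) {
    utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
    if (!is.null(manifest_path))
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA, dataframe = "rows", na = "null")
  }
  invisible(list(tracks = tracks, manifest = manifest, path = path,
                 manifest_path = if (!is.null(path)) manifest_path))
}
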