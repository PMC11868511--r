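#' Simulate an ensemble of heterogeneous random walks
#'
#' Monte-Carlo generator of the model's trajectories. Each track draws a
#' movement probability `p` once — from the beta density in
#' `"heterogeneous"` mode, or fixed at `fixed_p` in `"fixed_p"` mode (the
#' homogeneous baseline used for limit checks) — and then performs `n_steps`
#' Bernoulli(p) step attempts of size `params$step_size` every
#' `params$step_time` seconds.
#'
#' @param n_tracks Number of tracks.
#' @param n_steps Elementary steps per track; must be a multiple of
#'   `frame_decimation`.
#' @param params A [walk_params()] object.
#' @param mode `"heterogeneous"` (p ~ Beta(alpha, beta) per track) or
#'   `"fixed_p"`.
#' @param fixed_p Movement probability used in `"fixed_p"` mode.
#' @param frame_decimation Elementary steps per output camera frame
#'   (default 10); used by [ensemble_moments()] frame output.
#' @param seed Optional integer seed; the full ensemble is reproducible
#'   bit-for-bit given the seed.
#' @return An object of class `walk_ensemble`: a list with `positions`
#'   (integer matrix, `n_steps + 1` rows of cumulative step counts starting
#'   at 0, one column per track), `p` (per-track movement probabilities),
#'   `params`, `mode`, `frame_decimation`, `seed`.
#' @examples
#' ens <- simulate_walks(50, 100, walk_params(8.19, 12.95), seed = 1)
#' ens
#' @export
simulate_walks <- function(n_tracks, n_steps, params,
                           mode = c("heterogeneous", "fixed_p"),
                           fixed_p = NULL, frame_decimation = 10L,
                           seed = NULL) {
  mode <- match.arg(mode)
  params <- .as_walk_params(params)
  stopifnot(n_tracks >= 1, n_steps >= 1, frame_decimation >= 1)
  if (n_steps %% frame_decimation != 0)
    stop("'n_steps' must be a multiple of 'frame_decimation'")
  if (!is.null(seed)) set.seed(seed)
  p <- if (mode == "heterogeneous") {
    stats::rbeta(n_tracks, params$alpha, params$beta)
  } else {
    if (is.null(fixed_p) || fixed_p < 0 || fixed_p > 1)
      stop("'fixed_p' must be supplied in [0, 1] for fixed_p mode")
    rep(fixed_p, n_tracks)
  }
  u <- matrix(stats::runif(n_steps * n_tracks), nrow = n_steps)
  steps <- u < rep(p, each = n_steps)
  positions <- rbind(0L, apply(steps, 2, cumsum))
  storage.mode(positions) <- "integer"
  dimnames(positions) <- NULL
  structure(list(positions = positions, p = p, params = params, mode = mode,
                 fixed_p = fixed_p, frame_decimation = frame_decimation,
                 seed = seed, n_tracks = n_tracks, n_steps = n_steps),
            class = "walk_ensemble")
}

#' @export
print.walk_ensemble <- function(x, ...) {
  cat(sprintf("walk_ensemble: %d tracks x %d steps (%s mode), tau = %g s, a = %g um\n",
              x$n_tracks, x$n_steps, x$mode,
              x$params$step_time, x$params$step_size))
  invisible(x)
}

#' Ensemble mean and variance of displacement
#'
#' Sample mean and (unbiased) variance of the displacement \eqn{x = k a}
#' across a simulated ensemble, at camera-frame resolution (every
#' `frame_decimation`-th step) or at every elementary step. When `params`
#' is supplied the closed-form moments ([betabinom_moments()]) are attached
#' for comparison.
#'
#' @param ensemble A [simulate_walks()] result.
#' @param params Optional [walk_params()] to attach theory columns.
#' @param at `"frames"` or `"steps"`.
#' @return Data frame with columns `t_s`, `n`, `mean_um`, `var_um2`,
#'   `n_tracks` (plus `theory_mean_um`, `theory_var_um2` when `params` is
#'   given).
#' @export
ensemble_moments <- function(ensemble, params = NULL,
                             at = c("frames", "steps")) {
  at <- match.arg(at)
  stopifnot(inherits(ensemble, "walk_ensemble"))
  if (ensemble$n_tracks < 2)
    stop("at least 2 tracks are needed for a variance")
  wp <- ensemble$params
  n_idx <- if (at == "frames") {
    seq.int(ensemble$frame_decimation, ensemble$n_steps,
            by = ensemble$frame_decimation)
  } else {
    seq_len(ensemble$n_steps)
  }
  pos <- ensemble$positions[n_idx + 1L, , drop = FALSE] * wp$step_size
  mu <- rowMeans(pos)
  v <- rowSums((pos - mu)^2) / (ensemble$n_tracks - 1)
  out <- data.frame(t_s = n_idx * wp$step_time, n = n_idx,
                    mean_um = mu, var_um2 = v,
                    n_tracks = ensemble$n_tracks)
  if (!is.null(params)) {
    th <- betabinom_moments(out$t_s, params)
    out$theory_mean_um <- th$mean_um
    out$theory_var_um2 <- th$var_um2
  }
  out
}

#' First passage over a step threshold in simulated tracks
#'
#' Smallest step index `n` at which a track's cumulative step count reaches
#' `k_threshold`; `NA` marks tracks that never reach it (censored).
#'
#' @param ensemble A [simulate_walks()] result.
#' @param k_threshold Threshold in steps, `>= 1`.
#' @return Integer vector (one entry per track), `NA` when censored.
#' @export
first_passage_steps <- function(ensemble, k_threshold) {
  stopifnot(inherits(ensemble, "walk_ensemble"), k_threshold >= 1)
  hit <- ensemble$positions >= k_threshold
  idx <- apply(hit, 2, function(z) match(TRUE, z))
  as.integer(idx - 1L)
}
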