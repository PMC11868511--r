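# Shared fixtures and independent oracles used across test files.

# Tiny kymo_tracks data frame built in code.
make_tracks <- function(track_id, frame, x_px) {
  df <- data.frame(track_id = track_id, frame = as.integer(frame),
                   x_px = x_px)
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("kymo_tracks", "data.frame")
  df
}

# A straight retrograde track under the default sign convention
# (negative x is retrograde): moves -speed_px per frame.
straight_track <- function(id, n_frames, speed_px, x0 = 100) {
  make_tracks(rep(id, n_frames + 1), 0:n_frames,
              x0 - speed_px * (0:n_frames))
}

# Independent quadrature oracle for the beta-binomial pmf:
# integral of binomial(k | n, p) * beta(p | a, b) dp. Split at 1/2 so each
# piece has at most one (integrable) endpoint singularity when a or b < 1.
bb_quadrature <- function(k, n, a, b) {
  f <- function(p) stats::dbinom(k, n, p) * stats::dbeta(p, a, b)
  stats::integrate(f, 0, 0.5, rel.tol = 1e-10, subdivisions = 500L)$value +
    stats::integrate(f, 0.5, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}

# Truncated-sum oracle for BNB first-passage moments over the step lattice.
bnb_sum_moments <- function(k, a, b, tau = 0.01563, n_max = 2e5) {
  n <- seq.int(k, n_max)
  pn <- dbnb(n, k, a, b)
  m <- sum(n * tau * pn)
  list(mass = sum(pn), mean = m, var = sum((n * tau - m)^2 * pn))
}

# Classification accuracy of a generated dataset against its manifest.
label_accuracy <- function(gen, config) {
  lab <- classify_tracks(gen$tracks, config)
  truth <- gen$manifest$tracks
  mean(as.character(lab$class[match(truth$track_id, lab$track_id)]) ==
         truth$class)
}

# Manifest labels recast as a classify_tracks()-shaped data frame, used to
# bypass the speed-threshold selection when a test needs the ground truth.
true_labels <- function(gen) {
  truth <- gen$manifest$tracks
  data.frame(track_id = truth$track_id,
             class = factor(truth$class,
                            levels = c("retrograde", "stationary",
                                       "anterograde", "unclassified")))
}

paper_pairs <- list(wild_type = c(8.19, 12.95),
                    klc1 = c(3.18, 4.15),
                    klc2 = c(5.12, 12.87))
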