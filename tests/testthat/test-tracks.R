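pc <- pipeline_config()

test_that("pipeline configuration: strain thresholds, units, YAML round
           trip", {
  expect_equal(pipeline_config(strain = "wild_type")$retro_threshold_px_per_frame, 1.6)
  expect_equal(pipeline_config(strain = "klc1")$retro_threshold_px_per_frame, 1.0)
  expect_equal(pipeline_config(strain = "klc2")$retro_threshold_px_per_frame, 1.0)
  expect_error(pipeline_config(pixel_size_um = -1))
  # px -> um -> px round trip
  x <- c(0.001, 1, 17.3, 400)
  expect_equal((x * pc$pixel_size_um) / pc$pixel_size_um, x,
               tolerance = 1e-12)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pixel_size_um = 0.1, retro_threshold_px_per_frame = 1.0,
                        fpt_thresholds_um = c(2, 4)), f)
  cfg <- read_pipeline_config(f)
  expect_equal(cfg$pixel_size_um, 0.1)
  expect_equal(cfg$fpt_thresholds_um, c(2, 4))
  expect_equal(cfg$frame_interval_s, 0.1563)
})

test_that("reading tracker output: ordering, malformed rows, errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_px",
               "t2,1,9.5", "t1,2,4.0", "t1,0,6.0", "t1,1,5.0",
               "t2,0,10.0", "t2,2,bad"), f)
  expect_message(tr <- read_tracks(f, pc), "malformed")
  expect_equal(nrow(tr), 5L)
  expect_equal(tr$track_id, c("t1", "t1", "t1", "t2", "t2"))
  expect_equal(tr$frame, c(0L, 1L, 2L, 0L, 1L))
  expect_equal(tr$x_px[1:3], c(6, 5, 4))
  writeLines(c("track_id,frame", "t1,0"), f)
  expect_error(read_tracks(f, pc), "columns")
  writeLines("track_id,frame,x_px", f)
  expect_error(read_tracks(f, pc), "empty")
  expect_error(read_tracks(tempfile(), pc), "no such file")
})

test_that("duplicated time points are averaged", {
  tr <- make_tracks(rep("a", 5), c(0, 3, 3, 4, 5), c(1, 10, 12, 7, 6))
  dd <- dedupe_timepoints(tr)
  expect_equal(dd$x_px[dd$frame == 3], 11)
  expect_equal(nrow(dd), 4L)
  tr3 <- make_tracks(rep("a", 4), c(0, 1, 1, 1), c(9, 1, 2, 6))
  expect_equal(dedupe_timepoints(tr3)$x_px, c(9, 3))
  # identity on clean input
  clean <- straight_track("a", 5, 1)
  expect_identical(dedupe_timepoints(clean), clean)
})

test_that("classification: boundary, symmetry, degenerate tracks", {
  # |d| = 3.2 px over 2 frames at threshold 1.6: boundary counts as directed
  tr <- make_tracks(rep(c("bnd", "flat", "one"), c(3, 3, 1)),
                    c(0, 1, 2, 0, 1, 2, 0),
                    c(10, 8.4, 6.8, 5, 5, 5, 2))
  lab <- classify_tracks(tr, pc)
  expect_equal(as.character(lab$class[lab$track_id == "bnd"]), "retrograde")
  expect_equal(as.character(lab$class[lab$track_id == "flat"]), "stationary")
  expect_equal(as.character(lab$class[lab$track_id == "one"]), "unclassified")
  # global offset leaves classes unchanged
  tr_off <- tr; tr_off$x_px <- tr_off$x_px + 500
  expect_equal(classify_tracks(tr_off, pc)$class, lab$class)
  # time reversal alone swaps retrograde and anterograde ...
  bnd <- make_tracks(rep("bnd", 3), 0:2, c(10, 8.4, 6.8))
  bnd_rev <- make_tracks(rep("bnd", 3), 0:2, rev(bnd$x_px))
  expect_equal(as.character(classify_tracks(bnd_rev, pc)$class),
               "anterograde")
  # ... and combined with a sign flip the label is restored
  bnd_rev_flip <- make_tracks(rep("bnd", 3), 0:2, -rev(bnd$x_px))
  expect_equal(as.character(classify_tracks(bnd_rev_flip, pc)$class),
               "retrograde")
  # the sign convention itself is configurable
  pc_pos <- pipeline_config(direction_sign = "positive_is_retrograde")
  tr_anti <- tr; tr_anti$x_px <- -tr_anti$x_px
  lab_anti <- classify_tracks(tr_anti, pc_pos)
  expect_equal(lab_anti$class, lab$class)
})

retro_label <- function(ids) {
  data.frame(track_id = ids,
             class = factor(rep("retrograde", length(ids)),
                            levels = c("retrograde", "stationary",
                                       "anterograde", "unclassified")))
}

test_that("displacement at lag: exact counts and edge cases", {
  lag10 <- 10 * pc$frame_interval_s
  tr <- straight_track("a", 12, 1)  # one retrograde pixel per frame
  d <- displacements_at_lag(tr, lag10, pc, labels = retro_label("a"))
  expect_equal(d$k, 10L)
  expect_equal(attr(d, "n_trials"), 100L)
  expect_equal(d$x_um, 10 * pc$pixel_size_um)
  # shorter than the lag: contributes nothing
  short <- straight_track("b", 5, 2)
  d2 <- displacements_at_lag(short, lag10, pc, labels = retro_label("b"))
  expect_equal(nrow(d2), 0L)
  expect_equal(attr(d2, "n_short"), 1L)
  expect_error(displacements_at_lag(tr, 0.8, pc), "multiple")
  # anterograde excursions clamp to zero with a counted warning
  rev_tr <- make_tracks(rep("c", 11), 0:10, c(100, 99, 98, 97, 96, 95,
                                              94, 93, 92, 91, 103))
  expect_warning(d3 <- displacements_at_lag(rev_tr, lag10, pc,
                                            labels = retro_label("c")),
                 "clamped")
  expect_equal(d3$k, 0L)
})

test_that("empirical moments: exact small cases and lag bookkeeping", {
  cfg <- pipeline_config(moment_lags_s = 0.1563 * c(2, 5, 10))
  # two tracks with displacements 0 and 2 um at every lag
  t1 <- straight_track("a", 10, 0)
  t1$x_px[-1] <- t1$x_px[1] - 2 / cfg$pixel_size_um   # jumps then holds
  t2 <- straight_track("b", 10, 0)
  both <- make_tracks(c(t1$track_id, t2$track_id), c(t1$frame, t2$frame),
                      c(t1$x_px, t2$x_px))
  lab <- data.frame(track_id = c("a", "b"),
                    class = factor(rep("retrograde", 2),
                                   levels = levels(classify_tracks(both, cfg)$class)))
  m <- empirical_moments(both, cfg, labels = lab)
  expect_equal(m$mean_um, rep(1, 3))
  expect_equal(m$var_um2, rep(2, 3))
  # identical tracks: zero variance
  same <- make_tracks(rep(c("a", "b"), each = 11),
                      rep(0:10, 2), rep(100 - (0:10), 2))
  m0 <- empirical_moments(same, cfg,
                          labels = data.frame(track_id = c("a", "b"),
                                              class = factor(rep("retrograde", 2))))
  expect_true(all(m0$var_um2 == 0))
  # longer lags cannot gain tracks
  gen <- generate_dataset(generator_config(n_tracks = 300L,
                                           noise_sigma_px = 0), seed = 31)
  mm <- empirical_moments(gen$tracks, pipeline_config(), true_labels(gen))
  expect_true(all(diff(mm$n_tracks) <= 0))
})

test_that("empirical first passage: exact times, censoring, bounds", {
  tr <- straight_track("a", 30, 1)
  f <- empirical_fpt(tr, 1.84, pc, labels = retro_label("a"))
  expect_equal(f$frames, 20L)
  expect_equal(f$t_s, 3.126)
  expect_false(f$censored)
  # physical lower bound t >= (z / a) * tau
  expect_gte(f$t_s, (1.84 / pc$pixel_size_um) *
               (pc$frame_interval_s / pc$steps_per_frame))
  stat <- make_tracks(rep("s", 31), 0:30, rep(50, 31))
  lab <- data.frame(track_id = "s", class = factor("retrograde"))
  f2 <- empirical_fpt(stat, 1.84, pc, labels = lab)
  expect_true(f2$censored)
  expect_true(is.na(f2$t_s))
  expect_error(empirical_fpt(tr, -1, pc), "positive")
})

test_that("pipeline on a synthetic ensemble matches the generative law", {
  cfg <- generator_config(n_tracks = 4000L, noise_sigma_px = 0)
  csv <- tempfile(fileext = ".csv")
  gen <- generate_dataset(cfg, path = csv, seed = 33)
  tr <- dedupe_timepoints(read_tracks(csv, pc))
  # file round trip: track count and rows match the manifest exactly
  expect_equal(length(unique(tr$track_id)), cfg$n_tracks)
  expect_equal(nrow(tr), sum(gen$manifest$tracks$n_frames))
  # displacement histogram at the reference lag follows the generator's law
  d <- displacements_at_lag(tr, 1.563, pc, labels = true_labels(gen))
  g <- gof_betabinom(d$k, attr(d, "n_trials"), 8.19, 12.95)
  expect_gt(g$p_value, 0.01)
  unlink(csv)
})
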