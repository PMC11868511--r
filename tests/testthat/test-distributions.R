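test_that("beta density is proper and matches closed forms", {
  expect_equal(beta_density(0.5, walk_params(1, 1)), 1)
  expect_equal(beta_density(0.5, walk_params(2, 2)), 1.5)
  expect_error(beta_density(1.2, walk_params(2, 2)), "0, 1")
  total <- integrate(beta_density, 0, 1,
                     params = walk_params(8.19, 12.95),
                     rel.tol = 1e-12)$value
  expect_lt(abs(total - 1), 1e-10)
})

test_that("conditional binomial displacement law: support and domain", {
  expect_equal(dbinom_walk(1, 1, 0.3), 0.3)
  expect_equal(dbinom_walk(1, 2, 0.5), 0.5)
  expect_equal(dbinom_walk(5, 2, 0.5), 0)   # beyond support, not an error
  expect_error(dbinom_walk(1, 2, 1.5), "0, 1")
  # enumeration oracle: running product evaluation of C(100,40) 0.4^40 0.6^60
  v <- 1
  for (i in 1:40) v <- v * (100 - 40 + i) / i * 0.4
  v <- v * 0.6^60
  expect_equal(dbinom_walk(40, 100, 0.4), v, tolerance = 1e-12)
  expect_equal(sum(dbinom_walk(0:100, 100, 0.37)), 1, tolerance = 1e-12)
})

test_that("beta-binomial pmf normalises and matches the quadrature oracle", {
  expect_equal(dbetabinom(0:3, 3, 1, 1), rep(0.25, 4))
  expect_equal(dbetabinom(1, 1, 8.19, 12.95), 8.19 / (8.19 + 12.95))
  expect_equal(dbetabinom(-1, 10, 2, 3), 0)
  expect_equal(dbetabinom(11, 10, 2, 3), 0)
  for (a in c(0.5, 1, 3.18, 8.19)) {
    for (b in c(0.5, 1, 4.15, 12.95)) {
      for (n in c(1L, 10L, 100L)) {
        expect_lt(abs(sum(dbetabinom(0:n, n, a, b)) - 1), 1e-10)
        for (k in unique(c(0L, n %/% 2L, n))) {
          expect_lt(abs(dbetabinom(k, n, a, b) - bb_quadrature(k, n, a, b)),
                    1e-8)
        }
      }
    }
  }
  expect_lt(abs(sum(dbetabinom(0:500, 500, 8.19, 12.95)) - 1), 1e-10)
})

test_that("closed-form displacement moments match pmf summation", {
  wp <- walk_params(8.19, 12.95)
  expect_equal(unlist(betabinom_moments(0, wp)[c("mean_um", "var_um2")]),
               c(mean_um = 0, var_um2 = 0))
  # symmetric beta: mean is half the maximal displacement
  m <- betabinom_moments(1.563, walk_params(3, 3))
  expect_equal(m$mean_um, 0.092 * 100 / 2)
  expect_error(betabinom_moments(-1, wp), "non-negative")
  expect_error(betabinom_moments(0.02, wp), "multiple")
  for (a in c(0.5, 1, 3.18, 8.19)) {
    for (b in c(0.5, 1, 4.15, 12.95)) {
      for (n in c(1L, 10L, 100L)) {
        wp2 <- walk_params(a, b)
        mm <- betabinom_moments(n * wp2$step_time, wp2)
        k <- 0:n
        pk <- dbetabinom(k, n, a, b)
        mu <- sum(k * pk) * wp2$step_size
        v <- sum((k * wp2$step_size - mu)^2 * pk)
        expect_equal(mm$mean_um, mu, tolerance = 1e-8)
        if (v > 0) expect_equal(mm$var_um2, v, tolerance = 1e-8)
      }
    }
  }
})

test_that("homogeneous limit: beta-binomial converges to the binomial", {
  for (p in c(0.3, 0.4)) {
    s <- 1e6
    tv <- 0.5 * sum(abs(dbetabinom(0:50, 50, p * s, (1 - p) * s) -
                          dbinom(0:50, 50, p)))
    expect_lt(tv, 1e-3)
  }
})

test_that("population heterogeneity makes the variance quadratic in time", {
  quad_coef <- function(a, b, wp = walk_params(a, b)) {
    a * b / ((a + b)^2 * (1 + a + b)) * wp$step_size^2 / wp$step_time^2
  }
  for (a in c(0.5, 3.18, 8.19))
    for (b in c(0.5, 4.15, 12.95))
      expect_gt(quad_coef(a, b), 0)
  # and vanishes in the homogeneous limit at fixed mean p
  expect_lt(quad_coef(0.4e6, 0.6e6) / quad_coef(0.4, 0.6), 1e-5)
})

test_that("first-passage pmf: closed forms, support, propriety", {
  n <- 1:4
  expect_equal(dbnb(n, 1, 1, 1), 1 / (n * (n + 1)))
  expect_equal(dbnb(1, 1, 8.19, 12.95), 8.19 / (8.19 + 12.95))
  expect_equal(dbnb(3, 5, 2, 2), 0)  # cannot arrive before k steps
  pairs <- c(paper_pairs, list(heavy = c(3, 1)))
  for (ab in pairs) {
    for (k in c(1L, 5L, 20L, 40L)) {
      n_max <- dcvwalk:::.bnb_truncation(k, ab[1], ab[2], tol = 1e-12)
      mass <- sum(dbnb(seq.int(k, n_max), k, ab[1], ab[2]))
      expect_gte(mass, 1 - 1e-8)
    }
  }
  # cumulative matches the density sum
  expect_equal(pbnb(60, 20, 8.19, 12.95),
               sum(dbnb(20:60, 20, 8.19, 12.95)))
})

test_that("first-passage moments match the truncated-sum oracle and the
           +1-factor variant does not", {
  # alpha=3, beta=1, k=1: direct integration gives mean 3/2 tau and
  # variance 9/4 tau^2
  wp31 <- walk_params(3, 1)
  expect_equal(bnb_mean(wp31$step_size, wp31), 1.5 * wp31$step_time)
  expect_equal(bnb_var(wp31$step_size, wp31), 2.25 * wp31$step_time^2)
  o <- bnb_sum_moments(1, 3, 1, tau = wp31$step_time)
  expect_equal(bnb_var(wp31$step_size, wp31), o$var, tolerance = 1e-3)
  wp <- walk_params(8.19, 12.95)
  o <- bnb_sum_moments(20, 8.19, 12.95, tau = wp$step_time)
  expect_equal(bnb_mean(1.84, wp), o$mean, tolerance = 1e-6)
  expect_equal(bnb_var(1.84, wp), o$var, tolerance = 1e-6)
  expect_equal(bnb_mean(1.84, wp), 0.8756, tolerance = 1e-4)
  plus_one <- 12.95 * wp$step_time^2 * 20 * (20 + 8.19 + 1) *
    (8.19 + 12.95 + 1) / ((8.19 - 2) * (8.19 - 1)^2)
  expect_gt(abs(plus_one - o$var) / o$var, 0.05)
  # existence conditions
  expect_error(bnb_mean(0.092, walk_params(1, 2)), "does not exist")
  expect_error(bnb_var(0.092, walk_params(2, 2)), "does not exist")
  # beta -> 0 limit: deterministic walk
  expect_equal(bnb_mean(1.84, walk_params(5, 1e-12)), 20 * 0.01563,
               tolerance = 1e-10)
  expect_lt(bnb_var(1.84, walk_params(5, 1e-12)), 1e-10)
})

test_that("frame-aggregated first-passage law sums the step-level mass", {
  p_frames <- dbnb_frames(2:30, 20, 8.19, 12.95, steps_per_frame = 10)
  expect_equal(sum(p_frames), pbnb(300, 20, 8.19, 12.95), tolerance = 1e-12)
  expect_equal(dbnb_frames(1, 20, 8.19, 12.95, 10), 0)  # below z/a steps
  # with one step per frame the law reduces to the step-level pmf
  expect_equal(dbnb_frames(5:20, 5, 3.18, 4.15, steps_per_frame = 1),
               dbnb(5:20, 5, 3.18, 4.15))
})

test_that("walk parameter validation and JSON round trip", {
  expect_error(walk_params(-1, 2), "positive")
  expect_error(walk_params(2, 0), "positive")
  expect_error(walk_params(2, 2, step_size = 0), "positive")
  wp <- walk_params(5.12, 12.87)
  expect_equal(n_steps_for(c(1.563, 3.126), wp), c(100L, 200L))
  expect_error(n_steps_for(0.99 * 0.01563, wp), "multiple")
  f <- tempfile(fileext = ".json")
  write_walk_params(wp, f)
  wp2 <- read_walk_params(f)
  expect_identical(wp2[c("alpha", "beta", "step_size", "step_time")],
                   wp[c("alpha", "beta", "step_size", "step_time")])
})
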