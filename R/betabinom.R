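#' Beta density of the movement probability
#'
#' Density of the per-vesicle movement probability `p`,
#' \eqn{f(p) = B^{-1}(\alpha,\beta) p^{\alpha-1}(1-p)^{\beta-1}}.
#' Thin wrapper around [stats::dbeta()] taking a [walk_params()] object and
#' enforcing the unit-interval domain.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param params A [walk_params()] object (only `alpha`, `beta` are used).
#' @return Density values.
#' @examples
#' beta_density(0.5, walk_params(2, 2))  # 1.5
#' @export
beta_density <- function(p, params) {
  params <- .as_walk_params(params)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'p' must lie in [0, 1]")
  stats::dbeta(p, params$alpha, params$beta)
}

#' Displacement law conditional on a fixed movement probability
#'
#' For a vesicle with a fixed (non-random) movement probability `p`, the
#' number of successful steps after `n` attempts is binomial:
#' \eqn{P(k \mid n, p) = \binom{n}{k} p^k (1-p)^{n-k}}. This is the
#' homogeneous ("fixed-p") limit of the model; the heterogeneous law is
#' [dbetabinom()]. Evaluated by [stats::dbinom()], which works in log space.
#'
#' @param k Step counts (0..n; values outside the support give 0).
#' @param n Number of step attempts.
#' @param p Movement probability in `[0, 1]`.
#' @param log Return log probabilities?
#' @return Probabilities (or log probabilities).
#' @examples
#' dbinom_walk(1, 1, 0.3)  # 0.3
#' @export
dbinom_walk <- function(k, n, p, log = FALSE) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'p' must lie in [0, 1]")
  stats::dbinom(k, n, p, log = log)
}

#' Beta-binomial displacement distribution
#'
#' Probability mass function of the vesicle displacement after `size` step
#' attempts when the per-vesicle movement probability is beta-distributed:
#' \deqn{\bar P(k \mid n) = \binom{n}{k}
#'   \frac{B(k+\alpha,\, n-k+\beta)}{B(\alpha,\beta)},}
#' the mixture of [dbinom_walk()] over [beta_density()]. The physical
#' displacement is \eqn{x = k a} at time \eqn{t = n \tau}.
#'
#' Evaluation is entirely in log space via `lchoose()`/`lbeta()`
#' (log-gamma), so `size` in the hundreds does not overflow.
#'
#' @param x Integer step counts `k` (values outside `0..size` give 0).
#' @param size Number of step attempts `n`. Recycled against `x`.
#' @param alpha,beta Positive beta-density shape parameters.
#' @param log Return log probabilities?
#' @return Probabilities (or log probabilities).
#' @examples
#' dbetabinom(0:3, 3, 1, 1)         # uniform 0.25
#' dbetabinom(1, 1, 8.19, 12.95)    # alpha / (alpha + beta)
#' @export
dbetabinom <- function(x, size, alpha, beta, log = FALSE) {
  stopifnot(alpha > 0, beta > 0)
  m <- max(length(x), length(size))
  x <- rep_len(x, m); size <- rep_len(size, m)
  lp <- rep(-Inf, m)
  ok <- is.finite(x) & abs(x - round(x)) < 1e-7 & x >= 0 & x <= size
  if (any(!ok & is.finite(x)))
    lp[!ok] <- -Inf
  xo <- round(x[ok]); no <- size[ok]
  lp[ok] <- lchoose(no, xo) + lbeta(xo + alpha, no - xo + beta) -
    lbeta(alpha, beta)
  if (log) lp else exp(lp)
}

#' @rdname dbetabinom
#' @param nn Number of random draws.
#' @export
rbetabinom <- function(nn, size, alpha, beta) {
  stats::rbinom(nn, size, stats::rbeta(nn, alpha, beta))
}

#' Mean and variance of the displacement
#'
#' Closed-form moments of the beta-binomial displacement \eqn{x = k a} at
#' time \eqn{t = n\tau}:
#' \deqn{\langle x\rangle = \frac{\alpha}{\alpha+\beta}\frac{a t}{\tau},
#' \qquad
#' \mathrm{var}(x) = \frac{\alpha\beta}{(\alpha+\beta)(1+\alpha+\beta)}
#'   \frac{a^2 t}{\tau}
#'  + \frac{\alpha\beta}{(\alpha+\beta)^2(1+\alpha+\beta)}
#'   \frac{a^2 t^2}{\tau^2}.}
#' The quadratic term is strictly positive for any finite
#' \eqn{\alpha,\beta>0}: population heterogeneity in `p` makes the walk
#' superdiffusive (ballistic, \eqn{\mathrm{var}(x)\sim t^2}), and the term
#' vanishes only in the homogeneous limit \eqn{\alpha+\beta\to\infty}.
#'
#' @param t Times in seconds (non-negative multiples of `params$step_time`).
#' @param params A [walk_params()] object.
#' @return A data frame with columns `t_s`, `n`, `mean_um`, `var_um2`.
#' @examples
#' betabinom_moments(c(0, 1.563, 3.126), walk_params(8.19, 12.95))
#' @export
betabinom_moments <- function(t, params) {
  params <- .as_walk_params(params)
  n <- as.numeric(n_steps_for(t, params))
  a <- params$step_size
  al <- params$alpha; be <- params$beta
  s <- al + be
  mean_um <- al / s * a * n
  var_um2 <- al * be / (s * (1 + s)) * a^2 * n +
    al * be / (s^2 * (1 + s)) * a^2 * n^2
  data.frame(t_s = t, n = n, mean_um = mean_um, var_um2 = var_um2)
}
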