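#' Beta-negative-binomial first-passage-time distribution
#'
#' Law of the number of step attempts `x = n` at which the walk first reaches
#' `size = k` successful steps (displacement threshold \eqn{z = k a}, first
#' passage time \eqn{t = n\tau}), when the movement probability is
#' beta-distributed:
#' \deqn{\bar F(n \mid k) = \binom{n-1}{k-1}
#'   \frac{B(k+\alpha,\, n-k+\beta)}{B(\alpha,\beta)},
#'   \qquad n = k, k+1, \ldots}
#' the beta mixture of the negative-binomial first-passage law. Evaluated in
#' log space. The right tail is heavy (power law \eqn{\sim n^{-(\alpha+1)}}),
#' so moments exist only for large enough `alpha`; see [bnb_mean()].
#'
#' @param x Trial counts `n` (values below `size` or non-integer give 0).
#' @param size Threshold in steps, `k >= 1`.
#' @param alpha,beta Positive beta-density shape parameters.
#' @param log Return log probabilities?
#' @return Probabilities (or log probabilities).
#' @examples
#' dbnb(1:4, 1, 1, 1)      # 1/(n(n+1)): 1/2, 1/6, 1/12, 1/20
#' dbnb(1, 1, 8.19, 12.95) # alpha/(alpha+beta): success on first attempt
#' @export
dbnb <- function(x, size, alpha, beta, log = FALSE) {
  stopifnot(alpha > 0, beta > 0, size >= 1)
  m <- max(length(x), length(size))
  x <- rep_len(x, m); size <- rep_len(size, m)
  lp <- rep(-Inf, m)
  ok <- is.finite(x) & abs(x - round(x)) < 1e-7 & x >= size
  xo <- round(x[ok]); ko <- round(size[ok])
  lp[ok] <- lchoose(xo - 1, ko - 1) + lbeta(ko + alpha, xo - ko + beta) -
    lbeta(alpha, beta)
  if (log) lp else exp(lp)
}

#' @rdname dbnb
#' @param q Upper trial count: `pbnb()` returns
#'   \eqn{P(n \le q)} by direct summation from `size` to `q`.
#' @export
pbnb <- function(q, size, alpha, beta) {
  stopifnot(length(size) == 1L)
  vapply(q, function(qi) {
    if (qi < size) return(0)
    sum(dbnb(seq.int(size, floor(qi)), size, alpha, beta))
  }, numeric(1))
}

# Truncation point for partial sums over the heavy BNB tail: grow n until the
# power-law tail estimate  n * pmf(n) / alpha  (survival of an n^-(alpha+1)
# density) drops below tol, capped at 1e6 * size.
.bnb_truncation <- function(size, alpha, beta, tol = 1e-12) {
  n <- max(1000, 50 * size)
  cap <- 1e6 * size
  repeat {
    tail_est <- n * dbnb(n, size, alpha, beta) / alpha
    if (tail_est < tol || n >= cap) return(min(n, cap))
    n <- n * 4
  }
}

#' First-passage distribution at camera-frame resolution
#'
#' A track sampled every `steps_per_frame` elementary steps first shows the
#' threshold crossing at frame \eqn{m = \lceil n/\mathrm{spf} \rceil}, where
#' `n` is the (unobserved) step at which the crossing happened. Because the
#' one-sided walk is non-decreasing, the frame-resolution first-passage law
#' is exactly the [dbnb()] mass aggregated over each frame's step window.
#'
#' @param frame Frame indices `m >= 1` (frames since the track origin).
#' @param size Threshold in steps (pixels), `k >= 1`.
#' @param alpha,beta Positive beta-density shape parameters.
#' @param steps_per_frame Elementary steps per camera frame (default 10,
#'   i.e. tau = 0.01563 s against a 0.1563 s frame interval).
#' @return Probabilities P(first-crossing frame = m).
#' @export
dbnb_frames <- function(frame, size, alpha, beta, steps_per_frame = 10L) {
  stopifnot(steps_per_frame >= 1, size >= 1)
  vapply(frame, function(m) {
    if (m < 1 || abs(m - round(m)) > 1e-7) return(0)
    m <- round(m)
    lo <- max(size, (m - 1L) * steps_per_frame + 1L)
    hi <- m * steps_per_frame
    if (hi < lo) return(0)
    sum(dbnb(lo:hi, size, alpha, beta))
  }, numeric(1))
}

#' Moments of the first passage time
#'
#' Closed-form mean and variance of the time \eqn{t = n\tau} at which the
#' displacement first reaches the threshold \eqn{z} (with \eqn{k = z/a}
#' steps):
#' \deqn{\langle t\rangle = \frac{\tau z}{a}\,
#'   \frac{\alpha+\beta-1}{\alpha-1}, \qquad \alpha > 1,}
#' \deqn{\mathrm{var}(t) = \beta\,\frac{\tau^2 z}{a}\,
#'   \frac{(z/a+\alpha-1)(\alpha+\beta-1)}{(\alpha-2)(\alpha-1)^2},
#'   \qquad \alpha > 2.}
#' For \eqn{\alpha \le 1} the mean does not exist and for
#' \eqn{\alpha \le 2} the variance does not exist (heavy power-law tail).
#'
#' Note on the variance: a mis-printed variant of this formula circulates
#' with factors \eqn{(z/a+\alpha+1)(\alpha+\beta+1)}. That variant fails a
#' brute-force check against the truncated sum
#' \eqn{\sum_n (n\tau - \langle t\rangle)^2 \bar F(n)} (e.g. at
#' \eqn{\alpha=3,\beta=1,k=1} direct integration gives 9/4, not 25/4), so the
#' \eqn{-1} form — the standard beta-negative-binomial variance — is
#' implemented here.
#'
#' @param z Threshold distance in micrometres (positive multiple of
#'   `params$step_size`).
#' @param params A [walk_params()] object.
#' @return `bnb_mean()`: mean first passage time in seconds;
#'   `bnb_var()`: its variance in seconds squared.
#' @examples
#' bnb_mean(1.84, walk_params(8.19, 12.95))  # ~0.8756 s
#' @export
bnb_mean <- function(z, params) {
  params <- .as_walk_params(params)
  k <- .steps_for_distance(z, params)
  if (params$alpha <= 1)
    stop("mean of the first-passage time does not exist for alpha <= 1")
  params$step_time * k * (params$alpha + params$beta - 1) / (params$alpha - 1)
}

#' @rdname bnb_mean
#' @export
bnb_var <- function(z, params) {
  params <- .as_walk_params(params)
  k <- .steps_for_distance(z, params)
  al <- params$alpha; be <- params$beta
  if (al <= 2)
    stop("variance of the first-passage time does not exist for alpha <= 2")
  # standard BNB variance, (k+alpha-1)(alpha+beta-1) factors; see docs above
  be * params$step_time^2 * k * (k + al - 1) * (al + be - 1) /
    ((al - 2) * (al - 1)^2)
}

.steps_for_distance <- function(z, params, tol = 1e-6) {
  if (any(z <= 0)) stop("threshold distance must be positive")
  k <- z / params$step_size
  if (any(abs(k - round(k)) > tol * pmax(1, k)))
    stop("'z' is not an integer multiple of the step size")
  round(k)
}
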