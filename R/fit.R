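#' Negative log-likelihood of a displacement sample
#'
#' \eqn{-\sum_i \log \bar P(k_i \mid n_i)} under the beta-binomial
#' displacement law. An empty sample gives 0 (empty sum).
#'
#' @param k Integer step counts.
#' @param size Number of step attempts per observation (scalar or vector
#'   recycled against `k`); observations may come from different elapsed
#'   times, each with its own `n = t / tau`.
#' @param alpha,beta Positive beta-density shape parameters.
#' @return The negative log-likelihood (finite for alpha, beta > 0 when all
#'   counts are inside their support).
#' @examples
#' neg_loglik_betabinom(1, 1, 1, 1)  # -log(0.5)
#' @export
neg_loglik_betabinom <- function(k, size, alpha, beta) {
  if (length(k) == 0L) return(0)
  size <- rep_len(size, length(k))
  if (any(k < 0 | k > size))
    stop("all counts must lie in [0, size]")
  -sum(dbetabinom(k, size, alpha, beta, log = TRUE))
}

#' Method-of-moments starting values for the beta-binomial
#'
#' Standard beta-binomial moment estimates used to initialise the optimiser:
#' with \eqn{\hat\pi} the mean success fraction and \eqn{\hat\rho} the
#' intra-class correlation solved from the sample variance,
#' \eqn{\alpha_0 = \hat\pi(1/\hat\rho - 1)},
#' \eqn{\beta_0 = (1-\hat\pi)(1/\hat\rho - 1)}. Underdispersed or degenerate
#' samples (where the beta mixture is not identified) fall back to `(1, 1)`
#' with a warning.
#'
#' @inheritParams neg_loglik_betabinom
#' @return Named vector `c(alpha, beta)`.
#' @export
momest_betabinom <- function(k, size) {
  size <- rep_len(size, length(k))
  if (length(k) < 2L) {
    warning("fewer than 2 observations; falling back to (1, 1)")
    return(c(alpha = 1, beta = 1))
  }
  n <- mean(size)
  pi_hat <- sum(k) / sum(size)
  s2 <- stats::var(k)
  fallback <- function(msg) {
    warning(paste0(msg, "; falling back to (1, 1)"))
    c(alpha = 1, beta = 1)
  }
  if (!is.finite(s2) || s2 <= 0)
    return(fallback("zero sample variance"))
  if (pi_hat <= 0 || pi_hat >= 1)
    return(fallback("all counts at the support boundary"))
  rho <- (s2 / (n * pi_hat * (1 - pi_hat)) - 1) / (n - 1)
  if (!is.finite(rho) || rho <= 0)
    return(fallback("sample not overdispersed relative to the binomial"))
  s <- 1 / rho - 1
  if (s <= 0)
    return(fallback("overdispersion too extreme for a proper beta"))
  c(alpha = pi_hat * s, beta = (1 - pi_hat) * s)
}

#' Fit the heterogeneous random walk by maximum likelihood
#'
#' Estimates the beta-density shape parameters (alpha, beta) of the
#' heterogeneous random walk from a sample of integer displacement step
#' counts, by minimising [neg_loglik_betabinom()]. This is the package's
#' central fitting routine: the fitted parameters describe the population
#' heterogeneity of the per-vesicle movement probability and, through
#' [betabinom_moments()] and [dbnb()], predict the displacement moment
#' growth and the first-passage-time distribution with no further fitting.
#'
#' Optimisation is performed in `(log alpha, log beta)` by default
#' (positivity without explicit constraints), boxed to `[-7, 7]`, starting
#' from [momest_betabinom()] and using `stats::optim(method = "L-BFGS-B")`.
#' Standard errors come from the numerically differentiated observed
#' information at the optimum (natural scale) and are approximate.
#'
#' Observations may mix different trial counts `size` (displacements read at
#' different lags): the joint likelihood is then the sum over observations
#' under one common (alpha, beta). [fit_betabinom_joint()] is a convenience
#' wrapper that concatenates a list of per-lag samples.
#'
#' @inheritParams neg_loglik_betabinom
#' @param start Optional starting values `c(alpha, beta)`; default
#'   [momest_betabinom()] (its underdispersion warning is suppressed here —
#'   the MLE itself is still well defined).
#' @param parameterization Optimise in `"log"` (default) or `"natural"`
#'   parameter space; both converge to the same optimum and the option
#'   exists to verify exactly that.
#' @param min_obs Minimum number of observations required (default 10).
#' @param control Passed to [stats::optim()].
#' @return An object of class `bbfit` with components `coefficients`
#'   (`alpha`, `beta`), `se`, `vcov`, `neg_loglik`, `converged`, `n_obs`,
#'   `k`, `size`, `start`, `call`. Methods: `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `predict`, `simulate`, `residuals`, `plot`.
#' @examples
#' set.seed(1)
#' k <- rbetabinom(2000, 100, 8.19, 12.95)
#' fit <- fit_betabinom(k, 100)
#' fit
#' confint_3se <- coef(fit) + 3 * outer(fit$se, c(-1, 1))
#' @export
fit_betabinom <- function(k, size, start = NULL,
                          parameterization = c("log", "natural"),
                          min_obs = 10L, control = list()) {
  parameterization <- match.arg(parameterization)
  cl <- match.call()
  if (any(abs(k - round(k)) > 1e-7))
    stop("'k' must contain integer step counts")
  k <- round(k)
  size <- rep_len(size, length(k))
  if (length(k) < min_obs)
    stop(sprintf("at least %d observations are required", min_obs))
  if (any(k < 0 | k > size))
    stop("all counts must lie in [0, size]")
  if (all(k == 0) || all(k == size))
    stop("beta density degenerate: all counts at the same support boundary")
  if (is.null(start))
    start <- suppressWarnings(momest_betabinom(k, size))
  start <- pmin(pmax(start, exp(-7)), exp(7))
  # tight L-BFGS-B tolerance so different parameterizations land on the
  # same optimum to well below reporting precision
  if (is.null(control$factr)) control$factr <- 1e5
  nll <- function(par) neg_loglik_betabinom(k, size, par[1], par[2])
  if (parameterization == "log") {
    opt <- stats::optim(log(start), function(lp) nll(exp(lp)),
                        method = "L-BFGS-B", lower = -7, upper = 7,
                        control = control)
    est <- exp(opt$par)
  } else {
    opt <- stats::optim(start, nll, method = "L-BFGS-B",
                        lower = exp(-7), upper = exp(7), control = control)
    est <- opt$par
  }
  names(est) <- c("alpha", "beta")
  H <- try(stats::optimHess(est, nll), silent = TRUE)
  vc <- matrix(NA_real_, 2, 2, dimnames = list(names(est), names(est)))
  se <- c(alpha = NA_real_, beta = NA_real_)
  if (!inherits(H, "try-error")) {
    vci <- try(solve(H), silent = TRUE)
    if (!inherits(vci, "try-error") && all(diag(vci) > 0)) {
      vc <- vci
      dimnames(vc) <- list(names(est), names(est))
      se <- sqrt(diag(vc))
    }
  }
  structure(list(coefficients = est, se = se, vcov = vc,
                 neg_loglik = opt$value, converged = opt$convergence == 0L,
                 optim_counts = opt$counts, n_obs = length(k),
                 k = k, size = size, start = start,
                 parameterization = parameterization, call = cl),
            class = "bbfit")
}

#' @rdname fit_betabinom
#' @param samples A non-empty list of samples, each a list (or data frame)
#'   with elements `k` and `size`.
#' @param ... Passed on to [fit_betabinom()].
#' @export
fit_betabinom_joint <- function(samples, ...) {
  if (!is.list(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty list of k/size samples")
  k <- unlist(lapply(samples, function(s) s$k), use.names = FALSE)
  size <- unlist(lapply(samples, function(s) rep_len(s$size, length(s$k))),
                 use.names = FALSE)
  fit_betabinom(k, size, ...)
}

#' @export
print.bbfit <- function(x, digits = 4, ...) {
  cat("Beta-binomial heterogeneous walk fit\n")
  cat(sprintf("  alpha = %.*g (se %.*g), beta = %.*g (se %.*g)\n",
              digits, x$coefficients[1], digits, x$se[1],
              digits, x$coefficients[2], digits, x$se[2]))
  cat(sprintf("  -logLik = %.*g on %d observations%s\n", digits + 2,
              x$neg_loglik, x$n_obs,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @export
coef.bbfit <- function(object, ...) object$coefficients

#' @export
vcov.bbfit <- function(object, ...) object$vcov

#' @export
logLik.bbfit <- function(object, ...) {
  structure(-object$neg_loglik, df = 2L, nobs = object$n_obs,
            class = "logLik")
}

#' @export
summary.bbfit <- function(object, ...) {
  est <- object$coefficients
  z <- est / object$se
  tab <- cbind(Estimate = est, `Std. Error` = object$se, `z value` = z)
  s <- sum(est)
  out <- list(coefficients = tab, neg_loglik = object$neg_loglik,
              n_obs = object$n_obs, converged = object$converged,
              mean_p = est[[1]] / s, icc = 1 / (1 + s),
              corr = if (all(is.finite(object$se)))
                object$vcov[1, 2] / prod(object$se) else NA_real_,
              call = object$call)
  class(out) <- "summary.bbfit"
  out
}

#' @export
print.summary.bbfit <- function(x, digits = 4, ...) {
  cat("Beta-binomial heterogeneous walk fit\n\nCall: ")
  print(x$call)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nMean movement probability <p> = %.4f", x$mean_p))
  cat(sprintf("\nOverdispersion (intra-track correlation) rho = %.4f", x$icc))
  if (is.finite(x$corr))
    cat(sprintf("\ncor(alpha, beta) = %.3f", x$corr))
  cat(sprintf("\n-logLik = %.6g on %d observations%s\n",
              x$neg_loglik, x$n_obs,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' Predict from a fitted heterogeneous walk
#'
#' @param object A [fit_betabinom()] result.
#' @param size Number of step attempts to predict at; defaults to the fit's
#'   common trial count (an error if the fit mixed several).
#' @param type `"pmf"` (data frame over `k = 0..size`), `"mean"` or
#'   `"variance"` (in steps).
#' @param ... Unused.
#' @export
predict.bbfit <- function(object, size = NULL,
                          type = c("pmf", "mean", "variance"), ...) {
  type <- match.arg(type)
  if (is.null(size)) {
    u <- unique(object$size)
    if (length(u) != 1L)
      stop("fit mixes several trial counts; supply 'size'")
    size <- u
  }
  al <- object$coefficients[[1]]; be <- object$coefficients[[2]]
  switch(type,
    pmf = data.frame(k = 0:size,
                     prob = dbetabinom(0:size, size, al, be)),
    mean = al / (al + be) * size,
    variance = size * al * be * (al + be + size) /
      ((al + be)^2 * (al + be + 1)))
}

#' @export
simulate.bbfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  al <- object$coefficients[[1]]; be <- object$coefficients[[2]]
  out <- as.data.frame(
    replicate(nsim, rbetabinom(object$n_obs, object$size, al, be)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
residuals.bbfit <- function(object, type = c("pearson"), ...) {
  type <- match.arg(type)
  u <- unique(object$size)
  if (length(u) != 1L)
    stop("binned residuals are defined for a common trial count")
  obs <- tabulate(object$k + 1L, nbins = u + 1L)
  expd <- object$n_obs *
    dbetabinom(0:u, u, object$coefficients[[1]], object$coefficients[[2]])
  r <- (obs - expd) / sqrt(pmax(expd, .Machine$double.eps))
  names(r) <- 0:u
  r
}

#' @export
plot.bbfit <- function(x, main = "Displacement step counts", ...) {
  u <- unique(x$size)
  if (length(u) != 1L)
    stop("plotting requires a common trial count")
  graphics::hist(x$k, breaks = seq(-0.5, u + 0.5, by = 1), freq = FALSE,
                 col = "grey85", border = "grey60",
                 xlab = "steps k", main = main, ...)
  pmf <- predict(x, type = "pmf")
  graphics::points(pmf$k, pmf$prob, pch = 16, col = "firebrick", cex = 0.6)
  graphics::legend("topright", legend = "fitted beta-binomial",
                   pch = 16, col = "firebrick", bty = "n")
  invisible(x)
}

# Greedy left-to-right merge of categories until each bin's expected count
# reaches min_expected; the unfinished remainder folds into the last bin.
.chisq_binned <- function(obs, prob, n_est = 0L, min_expected = 5) {
  stopifnot(length(obs) == length(prob))
  N <- sum(obs)
  prob <- prob / sum(prob)
  expd <- N * prob
  bo <- numeric(0); be <- numeric(0); co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expd[i]
    if (ce >= min_expected) {
      bo <- c(bo, co); be <- c(be, ce); co <- 0; ce <- 0
    }
  }
  if (ce > 0) {
    if (!length(bo)) stop("too few observations to form bins")
    bo[length(bo)] <- bo[length(bo)] + co
    be[length(be)] <- be[length(be)] + ce
  }
  df <- length(bo) - 1L - n_est
  if (df < 1) stop("too few bins for a chi-square test")
  stat <- sum((bo - be)^2 / be)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_bins = length(bo))
}

#' Goodness of fit of a beta-binomial to a step-count sample
#'
#' Binned chi-square test (adjacent categories merged until every bin's
#' expected count reaches `min_expected`) plus the total-variation distance
#' between the empirical frequencies and the model pmf.
#'
#' @param k Integer step counts, or a `bbfit` object (then `size`, `alpha`,
#'   `beta` are taken from the fit and `n_est` defaults to 2 because the
#'   parameters were estimated from this very sample).
#' @param size Common trial count.
#' @param alpha,beta Model parameters to test against.
#' @param n_est Number of parameters estimated from this sample (degrees of
#'   freedom correction); 0 when testing externally supplied parameters.
#' @param min_expected Minimum expected count per merged bin.
#' @return List with `statistic`, `df`, `p_value`, `n_bins`, `tv_distance`.
#' @export
gof_betabinom <- function(k, size = NULL, alpha = NULL, beta = NULL,
                          n_est = NULL, min_expected = 5) {
  if (inherits(k, "bbfit")) {
    fit <- k
    u <- unique(fit$size)
    if (length(u) != 1L) stop("goodness of fit requires a common trial count")
    size <- u
    alpha <- fit$coefficients[[1]]; beta <- fit$coefficients[[2]]
    if (is.null(n_est)) n_est <- 2L
    k <- fit$k
  } else if (is.null(n_est)) n_est <- 0L
  stopifnot(!is.null(size), !is.null(alpha), !is.null(beta))
  if (any(k < 0 | k > size)) stop("counts outside [0, size]")
  obs <- tabulate(k + 1L, nbins = size + 1L)
  prob <- dbetabinom(0:size, size, alpha, beta)
  res <- .chisq_binned(obs, prob, n_est = n_est, min_expected = min_expected)
  res$tv_distance <- 0.5 * sum(abs(obs / sum(obs) - prob))
  res
}

#' Goodness of fit of the frame-resolution first-passage law
#'
#' Chi-square comparison of observed first-crossing frames against the
#' beta-negative-binomial law aggregated to camera frames
#' ([dbnb_frames()]). If `horizon_frames` is given, both the data (which the
#' caller restricts to tracks observed at least that long) and the model are
#' conditioned on crossing within the horizon, which removes the length-bias
#' of finite tracks; otherwise the model tail beyond the largest observed
#' frame is lumped into the last category.
#'
#' @param frames Integer first-crossing frames (counted from each track's
#'   origin; censored tracks excluded beforehand).
#' @param size Threshold in steps (pixels).
#' @param alpha,beta Model parameters (typically from the displacement fit).
#' @param steps_per_frame Elementary steps per frame.
#' @param horizon_frames Optional conditioning horizon (frames).
#' @param n_est,min_expected As in [gof_betabinom()].
#' @return List with `statistic`, `df`, `p_value`, `n_bins`, `tv_distance`.
#' @export
gof_fpt <- function(frames, size, alpha, beta, steps_per_frame = 10L,
                    horizon_frames = NULL, n_est = 0L, min_expected = 5) {
  m0 <- ceiling(size / steps_per_frame)
  if (any(frames < m0)) stop("first-crossing frames below the physical bound")
  if (is.null(horizon_frames)) {
    mmax <- max(frames)
    prob <- dbnb_frames(m0:mmax, size, alpha, beta, steps_per_frame)
    prob[length(prob)] <- prob[length(prob)] +
      max(0, 1 - pbnb(mmax * steps_per_frame, size, alpha, beta))
  } else {
    if (any(frames > horizon_frames)) stop("frames beyond the horizon")
    mmax <- horizon_frames
    prob <- dbnb_frames(m0:mmax, size, alpha, beta, steps_per_frame)
    prob <- prob / sum(prob)
  }
  obs <- tabulate(frames - m0 + 1L, nbins = mmax - m0 + 1L)
  res <- .chisq_binned(obs, prob, n_est = n_est, min_expected = min_expected)
  res$tv_distance <- 0.5 * sum(abs(obs / sum(obs) - prob / sum(prob)))
  res
}
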