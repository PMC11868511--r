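#' Parameters of the heterogeneous random walk
#'
#' Bundles the four constants shared by every distribution, the simulator and
#' the fitting routines. A vesicle attempts one elementary step of size
#' `step_size` every `step_time` seconds and succeeds with probability `p`;
#' `p` varies between vesicles and follows a beta density
#' \deqn{f(p) = B^{-1}(\alpha,\beta)\, p^{\alpha-1} (1-p)^{\beta-1}.}
#' `alpha` quantifies the level of successful movement (higher means more
#' mobile vesicles), `beta` the degree of failure (higher means more
#' immobilisation).
#'
#' The defaults tie the lattice to the imaging setup for dense-core vesicles
#' in the ALA neurite: one camera pixel (0.092 um) per step and one tenth of
#' the 0.1563 s frame interval per step, so a lag of 1.563 s corresponds to
#' exactly 100 elementary steps.
#'
#' @param alpha Positive beta-density shape parameter.
#' @param beta Positive beta-density shape parameter.
#' @param step_size Elementary step size \eqn{a} in micrometres.
#'   Default `0.092`.
#' @param step_time Elementary step duration \eqn{\tau} in seconds.
#'   Default `0.01563`.
#'
#' @return An object of class `walk_params`: a list with elements `alpha`,
#'   `beta`, `step_size`, `step_time`.
#' @examples
#' wp <- walk_params(8.19, 12.95)
#' wp
#' n_steps_for(1.563, wp)  # 100
#' @seealso [dbetabinom()], [dbnb()], [simulate_walks()], [fit_betabinom()]
#' @export
walk_params <- function(alpha, beta, step_size = 0.092, step_time = 0.01563) {
  for (nm in c("alpha", "beta", "step_size", "step_time")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  if (alpha <= 0 || beta <= 0)
    stop("'alpha' and 'beta' must be positive (proper beta density)")
  if (step_size <= 0) stop("'step_size' must be positive")
  if (step_time <= 0) stop("'step_time' must be positive")
  structure(
    list(alpha = alpha, beta = beta,
         step_size = step_size, step_time = step_time),
    class = "walk_params"
  )
}

#' @export
print.walk_params <- function(x, ...) {
  cat("Heterogeneous random walk parameters\n")
  cat(sprintf("  alpha = %.4g, beta = %.4g  (mean movement probability %.4f)\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  cat(sprintf("  step size a = %g um, step time tau = %g s\n",
              x$step_size, x$step_time))
  invisible(x)
}

.as_walk_params <- function(x) {
  if (inherits(x, "walk_params")) return(x)
  if (is.list(x) && all(c("alpha", "beta") %in% names(x))) {
    return(walk_params(x$alpha, x$beta,
                       step_size = if (!is.null(x$step_size)) x$step_size
                                   else if (!is.null(x$step_size_um)) x$step_size_um
                                   else 0.092,
                       step_time = if (!is.null(x$step_time)) x$step_time
                                   else if (!is.null(x$step_time_s)) x$step_time_s
                                   else 0.01563))
  }
  stop("cannot interpret 'params'; use walk_params()")
}

#' Number of elementary steps elapsed at a given time
#'
#' Converts an observation time to the number of step attempts
#' \eqn{n = t/\tau}, checking that `t` sits on the step-time lattice.
#'
#' @param t Time in seconds (non-negative, a multiple of `params$step_time`
#'   within a small rounding tolerance).
#' @param params A [walk_params()] object.
#' @param tol Relative tolerance for the lattice check.
#' @return Integer vector of step counts.
#' @examples
#' n_steps_for(c(1.563, 3.126), walk_params(8.19, 12.95))
#' @export
n_steps_for <- function(t, params, tol = 1e-6) {
  params <- .as_walk_params(params)
  if (any(t < 0)) stop("'t' must be non-negative")
  n <- t / params$step_time
  if (any(abs(n - round(n)) > tol * pmax(1, n)))
    stop("'t' is not an integer multiple of the step time")
  as.integer(round(n))
}

#' Read and write walk parameters as JSON
#'
#' Serialises a [walk_params()] object to the JSON schema
#' `{"alpha", "beta", "step_size_um", "step_time_s"}` and back.
#'
#' @param params A [walk_params()] object.
#' @param path File path.
#' @return `read_walk_params()` returns a `walk_params` object;
#'   `write_walk_params()` returns `path` invisibly.
#' @export
write_walk_params <- function(params, path) {
  params <- .as_walk_params(params)
  jsonlite::write_json(
    list(alpha = params$alpha, beta = params$beta,
         step_size_um = params$step_size, step_time_s = params$step_time),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_walk_params
#' @export
read_walk_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  walk_params(x$alpha, x$beta,
              step_size = x$step_size_um, step_time = x$step_time_s)
}
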