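#' Define an ODE model of a perturbation experiment
#'
#' An `ssfit_model` bundles the vector field, observation map, their
#' Jacobians and bookkeeping needed to fit dx/dt = f(x, theta, u),
#' y = h(x, theta, u) to perturbation data whose initial condition is the
#' steady state of the unperturbed (control) system, 0 = f(x_s, theta, u_c).
#'
#' All model functions receive parameters on the *natural* scale.
#' Optimization takes place on the scale given by `parameter_scale`
#' (`"linear"` or `"log10"` per parameter); `bounds` are on that
#' optimization scale.
#'
#' For nonautonomous models the vector field may depend on time through a
#' fourth argument `t`. The steady-state machinery always evaluates the
#' *control* vector field, i.e. `f` frozen at `t = 0` — the algebraic
#' constraint applies to the unperturbed autonomous system.
#'
#' @param name model label.
#' @param n_x,n_theta,n_u,n_y state, parameter, input and observable
#'   dimensions.
#' @param f vector field `function(x, theta, u, t)` (a 3-argument
#'   autonomous version is accepted and wrapped); returns length `n_x`.
#' @param h observation map `function(x, theta, u)`, returns length `n_y`.
#' @param dfdx,dfdtheta Jacobians of `f` with respect to state and
#'   parameters, shapes `(n_x, n_x)` and `(n_x, n_theta)`, same argument
#'   convention as `f`.
#' @param dhdx,dhdtheta Jacobians of `h`, shapes `(n_y, n_x)` and
#'   `(n_y, n_theta)`.
#' @param x_s_analytic optional analytic steady-state map
#'   `function(theta, u)` returning length `n_x`; used by the
#'   unconstrained (gold-standard) method and by diagnostics.
#' @param parameter_scale character vector, `"linear"` or `"log10"` per
#'   parameter (recycled if length 1).
#' @param bounds numeric `n_theta x 2` matrix of finite lower/upper bounds
#'   on the optimization scale.
#' @param theta_names,state_names,obs_names optional labels.
#' @param sigma_param index of the parameter holding the noise variance
#'   sigma^2 when it is estimated, or `NA` when all noise standard
#'   deviations are fixed in the data.
#'
#' @return an object of class `ssfit_model`.
#' @export
ode_model <- function(name, n_x, n_theta, n_u, n_y, f, h, dfdx, dfdtheta,
                      dhdx, dhdtheta, x_s_analytic = NULL,
                      parameter_scale = "log10", bounds = NULL,
                      theta_names = NULL, state_names = NULL,
                      obs_names = NULL, sigma_param = NA_integer_) {
  stopifnot(n_x >= 1, n_theta >= 1, n_u >= 0, n_y >= 1)
  parameter_scale <- rep_len(parameter_scale, n_theta)
  if (!all(parameter_scale %in% c("linear", "log10")))
    stop("parameter_scale entries must be 'linear' or 'log10'")
  if (is.null(bounds)) {
    bounds <- default_bounds(parameter_scale)
  }
  bounds <- as.matrix(bounds)
  if (!all(dim(bounds) == c(n_theta, 2L)))
    stop("bounds must be an n_theta x 2 matrix")
  if (!all(is.finite(bounds)) || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be finite with lower < upper")
  model <- structure(list(
    name = name,
    n_x = n_x, n_theta = n_theta, n_u = n_u, n_y = n_y,
    f = timed_fn(f), h = h,
    dfdx = timed_fn(dfdx), dfdtheta = timed_fn(dfdtheta),
    dhdx = dhdx, dhdtheta = dhdtheta,
    x_s_analytic = x_s_analytic,
    parameter_scale = parameter_scale,
    bounds = bounds,
    theta_names = theta_names %||% paste0("theta", seq_len(n_theta)),
    state_names = state_names %||% paste0("x", seq_len(n_x)),
    obs_names = obs_names %||% paste0("y", seq_len(n_y)),
    sigma_param = sigma_param
  ), class = "ssfit_model")
  model
}

# wrap an autonomous function(x, theta, u) so it also accepts t
timed_fn <- function(fn) {
  if (length(formals(fn)) >= 4L) return(fn)
  function(x, theta, u, t = 0) fn(x, theta, u)
}

default_bounds <- function(parameter_scale) {
  lb <- ifelse(parameter_scale == "log10", -5, 1e-5)
  ub <- ifelse(parameter_scale == "log10", 5, 1e5)
  cbind(lb, ub)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ssfit_model <- function(x, ...) {
  cat(sprintf("<ssfit_model> %s: n_x=%d, n_theta=%d, n_u=%d, n_y=%d\n",
              x$name, x$n_x, x$n_theta, x$n_u, x$n_y))
  cat(sprintf("  analytic steady state: %s; sigma estimated: %s\n",
              if (is.null(x$x_s_analytic)) "no" else "yes",
              if (is.na(x$sigma_param)) "no" else
                sprintf("yes (theta[%d] = sigma^2)", x$sigma_param)))
  invisible(x)
}

#' Map parameters between the optimization and the natural scale
#'
#' @param model an `ssfit_model`.
#' @param theta parameter vector on the source scale.
#' @return the transformed parameter vector.
#' @export
theta_to_natural <- function(model, theta) {
  ifelse(model$parameter_scale == "log10", 10^theta, theta)
}

#' @rdname theta_to_natural
#' @export
theta_to_optim <- function(model, theta) {
  ifelse(model$parameter_scale == "log10", log10(theta), theta)
}

# diagonal of d theta_natural / d theta_optim at a natural-scale theta
scale_chain <- function(model, theta_nat) {
  ifelse(model$parameter_scale == "log10", theta_nat * log(10), 1)
}

#' Check coded Jacobians against finite differences
#'
#' Compares `dfdx`/`dfdtheta` (and `dhdx`/`dhdtheta`) with central finite
#' differences of `f` (`h`) at randomly sampled admissible points.
#'
#' @param model an `ssfit_model`.
#' @param n_points number of random points.
#' @param rel_tol relative tolerance.
#' @param seed RNG seed used for the sampled points.
#' @return `TRUE` invisibly; stops with a message on disagreement.
#' @export
check_model_jacobians <- function(model, n_points = 5, rel_tol = 1e-5,
                                  seed = 1L) {
  with_seed(seed, {
    for (k in seq_len(n_points)) {
      theta <- theta_to_natural(model, random_point_in_bounds(model))
      x <- stats::runif(model$n_x, 0.05, 0.95)
      u <- stats::runif(max(model$n_u, 1), 0, 2)[seq_len(model$n_u)]
      t <- stats::runif(1, 0, 2)
      jx <- model$dfdx(x, theta, u, t)
      jt <- model$dfdtheta(x, theta, u, t)
      fx <- num_jacobian(function(z) model$f(z, theta, u, t), x)
      ft <- num_jacobian(function(z) model$f(x, z, u, t), theta)
      check_close(jx, fx, rel_tol, "dfdx")
      check_close(jt, ft, rel_tol, "dfdtheta")
      hx <- num_jacobian(function(z) model$h(z, theta, u), x)
      ht <- num_jacobian(function(z) model$h(x, z, u), theta)
      check_close(model$dhdx(x, theta, u), hx, rel_tol, "dhdx")
      check_close(model$dhdtheta(x, theta, u), ht, rel_tol, "dhdtheta")
    }
  })
  invisible(TRUE)
}

check_close <- function(a, b, rel_tol, what) {
  scale <- max(abs(b), 1)
  if (max(abs(a - b)) > rel_tol * scale)
    stop(sprintf("%s disagrees with finite differences (max abs err %.3g)",
                 what, max(abs(a - b))))
}

# central finite-difference Jacobian of vector-valued fn at z
num_jacobian <- function(fn, z, eps = NULL) {
  z <- as.numeric(z)
  f0 <- as.numeric(fn(z))
  J <- matrix(0, length(f0), length(z))
  for (i in seq_along(z)) {
    h <- eps %||% (1e-6 * max(abs(z[i]), 1))
    zp <- z; zm <- z
    zp[i] <- z[i] + h; zm[i] <- z[i] - h
    J[, i] <- (as.numeric(fn(zp)) - as.numeric(fn(zm))) / (2 * h)
  }
  J
}

random_point_in_bounds <- function(model) {
  stats::runif(model$n_theta, model$bounds[, 1], model$bounds[, 2])
}

# evaluate code with a local RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
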