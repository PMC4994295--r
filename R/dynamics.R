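# package-local mutable state: ODE simulation counter
.ssfit_state <- new.env(parent = emptyenv())
.ssfit_state$n_sims <- 0L

reset_sim_counter <- function() assign("n_sims", 0L, envir = .ssfit_state)
sim_count <- function() get("n_sims", envir = .ssfit_state)
bump_sim_counter <- function()
  assign("n_sims", get("n_sims", envir = .ssfit_state) + 1L,
         envir = .ssfit_state)

#' Simulate a model trajectory, optionally with forward sensitivities
#'
#' Integrates dx/dt = f(x, theta, u, t) from `x0` and evaluates the
#' observables y = h(x, theta, u) at the requested times. When
#' `sensitivities = TRUE` the forward sensitivity system
#' dS/dt = (df/dx) S + (df/dtheta), S(0) = 0, is integrated alongside,
#' together with the sensitivity with respect to the initial condition
#' (identity initial condition), so that both the parameter and the
#' initial-condition derivatives of the observables are available.
#'
#' @param model an `ssfit_model`.
#' @param theta parameters on the natural scale.
#' @param x0 initial state, length `n_x`.
#' @param u input vector held fixed over the simulation.
#' @param times nonnegative, strictly increasing output times.
#' @param sensitivities logical; augment with the sensitivity system.
#' @param rtol,atol integrator tolerances.
#' @param ode_method deSolve integration method (default `"lsoda"`).
#' @return an `ssfit_trajectory`: `times`, state matrix `x`
#'   (`n_t x n_x`), observables `y` (`n_t x n_y`), and when requested the
#'   sensitivity arrays `S` (`n_t x n_x x n_theta`), `Sx0`
#'   (`n_t x n_x x n_x`), `dydtheta` (`n_t x n_y x n_theta`, partial
#'   derivative at fixed `x0`) and `dydx0` (`n_t x n_y x n_x`).
#' @export
simulate_trajectory <- function(model, theta, x0, u, times,
                                sensitivities = FALSE,
                                rtol = 1e-8, atol = 1e-10,
                                ode_method = "lsoda") {
  stopifnot(length(x0) == model$n_x, all(times >= 0),
            !is.unsorted(times, strictly = TRUE))
  n_x <- model$n_x; n_th <- model$n_theta
  if (length(times) == 1 && times[1] == 0) {
    # degenerate request: the state at t = 0 is the initial condition
    out <- list(times = times, x = matrix(x0, 1, n_x),
                y = matrix(model$h(x0, theta, u), 1, model$n_y))
    if (sensitivities) {
      out$S <- array(0, dim = c(1, n_x, n_th))
      out$Sx0 <- array(diag(n_x), dim = c(1, n_x, n_x))
      Hx <- model$dhdx(x0, theta, u)
      out$dydtheta <- array(model$dhdtheta(x0, theta, u),
                            dim = c(1, model$n_y, n_th))
      out$dydx0 <- array(Hx, dim = c(1, model$n_y, n_x))
    }
    return(structure(out, class = "ssfit_trajectory"))
  }
  prepend0 <- times[1] > 0
  tt <- if (prepend0) c(0, times) else times

  if (!is.null(model$compiled)) {
    state0 <- if (sensitivities)
      c(x0, rep(0, n_x * n_th), as.numeric(diag(n_x)))
    else as.numeric(x0)
    parms <- pack_parms(model, theta, u, sens = sensitivities)
    bump_sim_counter()
    # "rk45c"/"roswc": the package's own embedded explicit RK45 and
    # linearly-implicit Rosenbrock-W integrators, safe to call from
    # inside another solver's right-hand side
    sol <- if (ode_method == "rk45c")
      .Call("ssfit_rk45", parms, state0, as.numeric(tt),
            as.numeric(rtol), as.numeric(atol), PACKAGE = "ssfit")
    else if (ode_method == "roswc")
      .Call("ssfit_rosw", parms, state0, as.numeric(tt),
            as.numeric(rtol), as.numeric(atol), PACKAGE = "ssfit")
    else
      suppressWarnings(
        deSolve::ode(y = state0, times = tt, func = "ssfit_derivs",
                     parms = parms, dllname = "ssfit",
                     initfunc = "ssfit_init", method = ode_method,
                     rtol = rtol, atol = atol))
    return(trajectory_from_solution(model, sol, times, tt, prepend0,
                                    theta, u, sensitivities))
  }

  if (!sensitivities) {
    state0 <- as.numeric(x0)
    rhs <- function(t, state, parms) {
      list(model$f(state, theta, u, t))
    }
  } else {
    state0 <- c(x0, rep(0, n_x * n_th), as.numeric(diag(n_x)))
    rhs <- function(t, state, parms) {
      x <- state[seq_len(n_x)]
      St <- matrix(state[n_x + seq_len(n_x * n_th)], n_x, n_th)
      Sx <- matrix(state[n_x + n_x * n_th + seq_len(n_x * n_x)], n_x, n_x)
      Jx <- model$dfdx(x, theta, u, t)
      list(c(model$f(x, theta, u, t),
             Jx %*% St + model$dfdtheta(x, theta, u, t),
             Jx %*% Sx))
    }
  }

  bump_sim_counter()
  sol <- suppressWarnings(
    deSolve::ode(y = state0, times = tt, func = rhs, parms = NULL,
                 method = ode_method, rtol = rtol, atol = atol))
  trajectory_from_solution(model, sol, times, tt, prepend0, theta, u,
                           sensitivities)
}

# pack model id, dimensions, flags, theta and u into the fixed-size
# parameter vector expected by the compiled rhs
pack_parms <- function(model, theta, u, sens = FALSE, freeze = FALSE) {
  parms <- c(model$compiled$id, model$n_x, model$n_theta, model$n_u,
             as.integer(sens), as.integer(freeze), theta, u)
  if (length(parms) > 128)
    stop("model too large for the compiled parameter block")
  c(parms, rep(0, 128 - length(parms)))
}

trajectory_from_solution <- function(model, sol, times, tt, prepend0,
                                     theta, u, sensitivities) {
  n_x <- model$n_x; n_th <- model$n_theta
  istate <- attr(sol, "istate")
  if (nrow(sol) < length(tt) || any(!is.finite(sol)) ||
      (!is.null(istate) && istate[1] < 0))
    stop(sprintf("integration of model '%s' failed near t = %.6g",
                 model$name, sol[nrow(sol), 1]))
  if (prepend0) sol <- sol[-1, , drop = FALSE]
  n_t <- length(times)
  xmat <- matrix(sol[, 1 + seq_len(n_x)], n_t, n_x)

  ymat <- matrix(0, n_t, model$n_y)
  for (j in seq_len(n_t))
    ymat[j, ] <- model$h(xmat[j, ], theta, u)

  out <- list(times = times, x = xmat, y = ymat)
  if (sensitivities) {
    S <- array(sol[, 1 + n_x + seq_len(n_x * n_th)],
               dim = c(n_t, n_x, n_th))
    Sx0 <- array(sol[, 1 + n_x + n_x * n_th + seq_len(n_x * n_x)],
                 dim = c(n_t, n_x, n_x))
    dydtheta <- array(0, dim = c(n_t, model$n_y, n_th))
    dydx0 <- array(0, dim = c(n_t, model$n_y, n_x))
    for (j in seq_len(n_t)) {
      Hx <- model$dhdx(xmat[j, ], theta, u)
      dydtheta[j, , ] <- Hx %*% matrix(S[j, , ], n_x, n_th) +
        model$dhdtheta(xmat[j, ], theta, u)
      dydx0[j, , ] <- Hx %*% matrix(Sx0[j, , ], n_x, n_x)
    }
    out$S <- S; out$Sx0 <- Sx0
    out$dydtheta <- dydtheta; out$dydx0 <- dydx0
  }
  structure(out, class = "ssfit_trajectory")
}

# control-condition vector field and Jacobians (nonautonomous terms frozen
# at t = 0: the steady-state constraint applies to the unperturbed system)
f_control <- function(model, x, theta, u) model$f(x, theta, u, 0)
dfdx_control <- function(model, x, theta, u) model$dfdx(x, theta, u, 0)
dfdtheta_control <- function(model, x, theta, u) model$dfdtheta(x, theta, u, 0)

#' Compute a steady state of the control system
#'
#' Solves 0 = f(x_s, theta, u) for the control (autonomous) vector field.
#' Strategy `"simulate"` integrates the system over geometrically growing
#' horizons until the vector-field norm falls below `tol`; `"newton"` runs
#' a damped Newton-Raphson iteration from `x_guess`; `"hybrid"` (default)
#' simulates into the basin and polishes with Newton-Raphson.
#'
#' @param model an `ssfit_model`.
#' @param theta parameters, natural scale.
#' @param u control input.
#' @param x_guess starting state (defaults to 0.5 in every component).
#' @param tol residual tolerance on `||f||_2`.
#' @param strategy `"hybrid"`, `"simulate"` or `"newton"`.
#' @return an `ssfit_steady_state`: `x_s`, `residual_norm`, sensitivity
#'   matrix `S` (when computable), `converged`, `strategy_used`.
#' @export
compute_steady_state <- function(model, theta, u, x_guess = NULL,
                                 tol = 1e-9,
                                 strategy = c("hybrid", "simulate", "newton")) {
  strategy <- match.arg(strategy)
  stopifnot(tol > 0)
  x <- as.numeric(x_guess %||% rep(0.5, model$n_x))
  stopifnot(all(is.finite(x)), length(x) == model$n_x)
  fnorm <- function(z) sqrt(sum(f_control(model, z, theta, u)^2))

  res0 <- fnorm(x)
  if (res0 < tol)
    return(ss_result(model, theta, u, x, res0, TRUE, "none"))

  used <- strategy
  if (strategy == "newton") {
    nr <- newton_polish(model, theta, u, x, tol)
    if (!nr$converged) {  # singular or stalled Newton: fall back to simulation
      sim <- simulate_to_steady(model, theta, u, x, tol)
      nr <- list(x = sim$x, residual = sim$residual,
                 converged = sim$converged)
      used <- "newton+simulate"
    }
    return(ss_result(model, theta, u, nr$x, nr$residual, nr$converged, used))
  }

  # simulate (optionally followed by Newton polishing)
  coarse <- if (strategy == "hybrid") max(tol, min(1e-4, sqrt(tol))) else tol
  sim <- simulate_to_steady(model, theta, u, x, coarse)
  x <- sim$x; res <- sim$residual; converged <- sim$converged
  if (strategy == "hybrid" && res >= tol) {
    nr <- newton_polish(model, theta, u, x, tol)
    if (nr$converged || nr$residual < res) {
      x <- nr$x; res <- nr$residual; converged <- nr$converged
    }
    if (!converged) {  # Newton failed: push the simulation further
      sim <- simulate_to_steady(model, theta, u, x, tol)
      if (sim$residual < res) { x <- sim$x; res <- sim$residual }
      converged <- sim$converged
    }
  }
  ss_result(model, theta, u, x, res, converged && res < tol, strategy)
}

ss_result <- function(model, theta, u, x, residual, converged, used) {
  S <- NULL
  if (converged)
    S <- tryCatch(steady_state_sensitivity(model, theta, x, u),
                  error = function(e) NULL)
  structure(list(x_s = x, residual_norm = residual, S = S,
                 converged = converged, strategy_used = used),
            class = "ssfit_steady_state")
}

# integrate the control system over horizons tau * 10^k until ||f|| < tol
# or progress stalls; tau from the fastest decaying mode when computable
simulate_to_steady <- function(model, theta, u, x, tol, max_decades = 9) {
  ev <- tryCatch(eigen(dfdx_control(model, x, theta, u),
                       only.values = TRUE)$values,
                 error = function(e) NULL)
  rate <- if (!is.null(ev)) min(abs(Re(ev))) else 0
  tau <- if (is.finite(rate) && rate > 1e-12) 1 / rate else 1
  rhs <- function(t, state, parms) list(f_control(model, state, theta, u))
  res_prev <- sqrt(sum(f_control(model, x, theta, u)^2))
  t_done <- 0
  for (k in 0:max_decades) {
    t_next <- tau * 10^k
    bump_sim_counter()
    sol <- tryCatch(suppressWarnings(
      if (!is.null(model$compiled))
        deSolve::ode(y = x, times = c(t_done, t_next),
                     func = "ssfit_derivs",
                     parms = pack_parms(model, theta, u, freeze = TRUE),
                     dllname = "ssfit", initfunc = "ssfit_init",
                     method = "lsoda", rtol = 1e-10, atol = 1e-12)
      else
        deSolve::ode(y = x, times = c(t_done, t_next), func = rhs,
                     parms = NULL, method = "lsoda",
                     rtol = 1e-10, atol = 1e-12)),
      error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < 2 || any(!is.finite(sol)))
      return(list(x = x, residual = res_prev, converged = FALSE))
    x <- as.numeric(sol[nrow(sol), -1])
    t_done <- t_next
    res <- sqrt(sum(f_control(model, x, theta, u)^2))
    if (res < tol) return(list(x = x, residual = res, converged = TRUE))
    if (res > 0.9 * res_prev && k >= 3)  # stalled: not decaying to 0
      return(list(x = x, residual = res, converged = FALSE))
    res_prev <- res
  }
  list(x = x, residual = res_prev, converged = FALSE)
}

# damped Newton-Raphson on f(., theta, u) = 0; accepts only residual decrease
newton_polish <- function(model, theta, u, x, tol,
                          max_iter = 50, max_halvings = 30) {
  res <- sqrt(sum(f_control(model, x, theta, u)^2))
  for (it in seq_len(max_iter)) {
    if (res < tol) return(list(x = x, residual = res, converged = TRUE))
    J <- dfdx_control(model, x, theta, u)
    step <- tryCatch(solve(J, -f_control(model, x, theta, u)),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(x = x, residual = res, converged = FALSE))
    accepted <- FALSE
    alpha <- 1
    for (hv in 0:max_halvings) {
      x_new <- x + alpha * step
      res_new <- sqrt(sum(f_control(model, x_new, theta, u)^2))
      if (is.finite(res_new) && res_new < res) {
        x <- x_new; res <- res_new; accepted <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!accepted) return(list(x = x, residual = res, converged = FALSE))
  }
  list(x = x, residual = res, converged = res < tol)
}

#' Steady-state parameter sensitivity
#'
#' On the steady-state manifold the forward sensitivity system is
#' stationary and reduces to the linear system
#' (df/dx) S = -(df/dtheta), whose solution S = dx_s/dtheta is computed
#' here by a direct solve (no explicit inverse).
#'
#' @param model an `ssfit_model`.
#' @param theta parameters, natural scale.
#' @param x_s a state on (or numerically near) the steady-state manifold.
#' @param u control input.
#' @return the `n_x x n_theta` sensitivity matrix.
#' @export
steady_state_sensitivity <- function(model, theta, x_s, u) {
  J <- dfdx_control(model, x_s, theta, u)
  if (!all(is.finite(J))) stop("non-finite Jacobian at steady state")
  if (kappa(J, exact = FALSE) > 1e12)
    stop("steady-state Jacobian is singular or ill-conditioned ",
         "(condition estimate > 1e12); exponential stability is lost - ",
         "consider steady_state_sensitivity_pinv()")
  solve(J, -dfdtheta_control(model, x_s, theta, u))
}

#' Pseudoinverse steady-state sensitivity
#'
#' Generalization of [steady_state_sensitivity()] to points off the
#' manifold: S_hat = -(df/dx)^+ (df/dtheta) with the Moore-Penrose
#' pseudoinverse. Where the Jacobian is invertible this coincides with the
#' exact solve.
#'
#' @inheritParams steady_state_sensitivity
#' @param x state, not required to satisfy the steady-state constraint.
#' @param rcond singular values below `rcond` times the largest are
#'   treated as zero.
#' @return the `n_x x n_theta` matrix S_hat.
#' @export
steady_state_sensitivity_pinv <- function(model, theta, x, u,
                                          rcond = 1e-12) {
  J <- dfdx_control(model, x, theta, u)
  P <- dfdtheta_control(model, x, theta, u)
  sv <- svd(J)
  keep <- sv$d > rcond * max(sv$d, 0)
  if (!any(keep)) return(matrix(0, model$n_x, model$n_theta))
  dinv <- ifelse(keep, 1 / sv$d, 0)
  -(sv$v %*% (dinv * (t(sv$u) %*% P)))
}

#' Continue a steady state along a parameter direction
#'
#' Integrates the manifold flow dx_s/dr = S(theta + r dtheta, x_s, u)
#' dtheta from an on-manifold point, tracking the steady state along the
#' straight parameter path theta + r dtheta, r in [0, r_end]. Up to
#' integrator accuracy the endpoint is the steady state at the shifted
#' parameters.
#'
#' @inheritParams steady_state_sensitivity
#' @param dtheta parameter direction (natural scale).
#' @param r_end path length.
#' @return the continued steady state at `theta + r_end * dtheta`.
#' @export
steady_state_continuation <- function(model, theta, x_s, u, dtheta,
                                      r_end = 1) {
  rhs <- function(r, state, parms) {
    th <- theta + r * dtheta
    S <- steady_state_sensitivity(model, th, state, u)
    list(as.numeric(S %*% dtheta))
  }
  sol <- deSolve::ode(y = as.numeric(x_s), times = c(0, r_end), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  as.numeric(sol[nrow(sol), -1])
}

#' Export a trajectory as a tidy data frame
#'
#' @param trajectory an `ssfit_trajectory`.
#' @param model the model that produced it (for observable names).
#' @param experiment experiment label attached to every row.
#' @return a data frame with columns `experiment`, `time`, `observable`,
#'   `value`.
#' @export
trajectory_to_df <- function(trajectory, model, experiment = "e1") {
  n_t <- length(trajectory$times)
  data.frame(
    experiment = experiment,
    time = rep(trajectory$times, model$n_y),
    observable = rep(model$obs_names, each = n_t),
    value = as.numeric(trajectory$y),
    stringsAsFactors = FALSE
  )
}
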