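#' Negative log-likelihood of a perturbation dataset
#'
#' For independent Gaussian noise the negative log-likelihood of the
#' data given parameters theta and per-experiment initial steady states
#' x_s^e is
#' J = 1/2 sum_e sum_j sum_i ((ybar_ij^e - y_i^e(t_j)) / sigma_ij^e)^2,
#' plus the normalizing terms sum log(sqrt(2 pi) sigma) whenever any
#' sigma is estimated (they are constant, and therefore omitted, when
#' all sigma are fixed). Each y^e is obtained by simulating the model
#' from x_s^e under the experiment's perturbation input.
#'
#' @param model an `ssfit_model`.
#' @param dataset an `ssfit_dataset`.
#' @param theta parameters on the natural scale.
#' @param xs_list list with one initial state vector per experiment (in
#'   the order of `dataset$experiments`).
#' @param ... tolerances passed to [simulate_trajectory()].
#' @return the scalar objective value J.
#' @export
negloglik <- function(model, dataset, theta, xs_list, ...) {
  objective_evaluation(model, dataset, theta, xs_list,
                       gradients = FALSE, ...)$J
}

#' Objective value and partial gradients
#'
#' Evaluates J together with its partial derivatives with respect to the
#' parameters (at fixed initial states) and with respect to each
#' experiment's initial state, using the forward sensitivity system.
#' These are the ingredients of the reduced (total) gradient
#' dJ/dtheta = dJ/dtheta|_partial + sum_e (dJ/dx_s^e) (dx_s^e/dtheta).
#'
#' @inheritParams negloglik
#' @return an `ssfit_objective` list: `J`, `dJ_dtheta` (partial, natural
#'   scale), `dJ_dxs` (list of per-experiment vectors), and the
#'   per-experiment sensitivity trajectories in `trajectories`.
#' @export
objective_gradients <- function(model, dataset, theta, xs_list, ...) {
  objective_evaluation(model, dataset, theta, xs_list,
                       gradients = TRUE, ...)
}

objective_evaluation <- function(model, dataset, theta, xs_list,
                                 gradients = FALSE, rtol = 1e-8,
                                 atol = 1e-10, ode_method = "lsoda") {
  exps <- dataset$experiments
  stopifnot(length(xs_list) == length(exps))
  obs_split <- split_observations(dataset)
  sigma_free_any <- anyNA(dataset$observations$sigma)
  if (sigma_free_any && is.na(model$sigma_param))
    stop("dataset marks sigma as free but the model has no sigma parameter")
  sp <- model$sigma_param

  J <- 0
  dJ_dtheta <- numeric(model$n_theta)
  dJ_dxs <- vector("list", length(exps))
  trajs <- vector("list", length(exps))

  for (e in seq_along(exps)) {
    ex <- exps[[e]]
    traj <- tryCatch(
      simulate_trajectory(model, theta, xs_list[[e]], ex$u_perturbed,
                          ex$time_points, sensitivities = gradients,
                          rtol = rtol, atol = atol,
                          ode_method = ode_method),
      error = function(err)
        stop(sprintf("experiment '%s': %s", ex$id, conditionMessage(err))))
    trajs[[e]] <- traj
    obs <- obs_split[[e]]
    dJ_dxs[[e]] <- numeric(model$n_x)
    for (k in seq_len(obs$n)) {
      i <- obs$observable[k]; j <- obs$time_index[k]
      sig2 <- if (is.na(obs$sigma[k])) theta[sp] else obs$sigma[k]^2
      if (sig2 <= 0)
        stop("zero noise scale: the likelihood is undefined")
      r <- obs$value[k] - traj$y[j, i]
      J <- J + 0.5 * r^2 / sig2
      if (sigma_free_any) J <- J + 0.5 * log(2 * pi * sig2)
      if (gradients) {
        w <- r / sig2
        dJ_dtheta <- dJ_dtheta - w * traj$dydtheta[j, i, ]
        dJ_dxs[[e]] <- dJ_dxs[[e]] - w * traj$dydx0[j, i, ]
        if (is.na(obs$sigma[k]))
          dJ_dtheta[sp] <- dJ_dtheta[sp] - 0.5 * r^2 / sig2^2 +
            0.5 / sig2
      }
    }
  }
  structure(list(J = J,
                 dJ_dtheta = if (gradients) dJ_dtheta else NULL,
                 dJ_dxs = if (gradients) dJ_dxs else NULL,
                 trajectories = trajs),
            class = "ssfit_objective")
}

#' Reduced (total) objective gradient
#'
#' Chain-rule contraction of the partial gradients with the steady-state
#' sensitivities:
#' dJ/dtheta = dJ/dtheta|_partial + sum_e S_e^T (dJ/dx_s^e).
#'
#' @param partials an `ssfit_objective` from [objective_gradients()].
#' @param S_list list of `n_x x n_theta` steady-state sensitivity
#'   matrices, one per experiment.
#' @return the total gradient vector (natural scale).
#' @export
reduced_gradient <- function(partials, S_list) {
  g <- partials$dJ_dtheta
  if (length(S_list) != length(partials$dJ_dxs))
    stop("S_list and dJ_dxs length mismatch")
  for (e in seq_along(S_list)) {
    S <- S_list[[e]]
    if (!all(dim(S) == c(length(partials$dJ_dxs[[e]]), length(g))))
      stop("sensitivity matrix shape mismatch")
    g <- g + as.numeric(t(S) %*% partials$dJ_dxs[[e]])
  }
  g
}

#' Fisher information matrix
#'
#' Gauss-Newton approximation to the Hessian of the negative
#' log-likelihood, computed from first-order total observable
#' sensitivities:
#' F = sum over data of (1/sigma^2) (dy/dtheta)(dy/dtheta)^T,
#' where dy/dtheta is the total derivative including the chain through
#' the steady-state initial condition. Symmetric positive semi-definite
#' by construction. When sigma^2 is an estimated parameter its
#' information 1/(2 sigma^4) per datum is added on the diagonal.
#'
#' @inheritParams negloglik
#' @param S_list per-experiment steady-state sensitivities
#'   (`n_x x n_theta`); use matrices of zeros for initial states that are
#'   treated as free of the parameters.
#' @param partials optional precomputed [objective_gradients()] result
#'   (reused to avoid re-simulating).
#' @return the `n_theta x n_theta` Fisher information matrix.
#' @export
fisher_information <- function(model, dataset, theta, xs_list, S_list,
                               partials = NULL, ...) {
  if (is.null(partials))
    partials <- objective_gradients(model, dataset, theta, xs_list, ...)
  obs_split <- split_observations(dataset)
  sp <- model$sigma_param
  F <- matrix(0, model$n_theta, model$n_theta)
  for (e in seq_along(partials$trajectories)) {
    traj <- partials$trajectories[[e]]
    obs <- obs_split[[e]]
    for (k in seq_len(obs$n)) {
      i <- obs$observable[k]; j <- obs$time_index[k]
      sig2 <- if (is.na(obs$sigma[k])) theta[sp] else obs$sigma[k]^2
      g <- traj$dydtheta[j, i, ] +
        as.numeric(traj$dydx0[j, i, ] %*% S_list[[e]])
      F <- F + tcrossprod(g) / sig2
      if (is.na(obs$sigma[k]))
        F[sp, sp] <- F[sp, sp] + 1 / (2 * sig2^2)
    }
  }
  (F + t(F)) / 2
}
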