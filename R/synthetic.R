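#' Generate a synthetic perturbation dataset
#'
#' Emulates the statistical structure of a perturbation experiment: for
#' each experiment the model is placed at the steady state of the
#' control input (computed to residual 1e-12, or analytically when the
#' model provides a map), simulated under the perturbation input at the
#' requested time points, and the observables are corrupted with
#' independent Gaussian noise of standard deviation `sigma` added on the
#' observable scale (after any scaling parameters).
#'
#' @param model an `ssfit_model`.
#' @param theta_true generating parameters, natural scale.
#' @param experiments list of [experiment_spec()] objects.
#' @param sigma noise standard deviation: scalar or per-observable
#'   vector of length `n_y`.
#' @param seed RNG seed for the noise draws.
#' @param noise_free if `TRUE`, no noise is added (sigma is still
#'   recorded in the dataset).
#' @param sigma_free if `TRUE`, the recorded sigma column is `NA`,
#'   marking the noise scale as a parameter to estimate.
#' @return an `ssfit_dataset` with attributes `theta_true` and `model_name`.
#' @export
generate_dataset <- function(model, theta_true, experiments, sigma,
                             seed = 1L, noise_free = FALSE,
                             sigma_free = FALSE) {
  sigma <- rep_len(sigma, model$n_y)
  stopifnot(all(sigma >= 0))
  rows <- list()
  for (ex in experiments) {
    xs <- if (!is.null(model$x_s_analytic))
      model$x_s_analytic(theta_true, ex$u_control)
    else {
      ss <- compute_steady_state(model, theta_true, ex$u_control,
                                 tol = 1e-12)
      if (!ss$converged)
        stop(sprintf("no steady state at theta_true for experiment '%s'",
                     ex$id))
      ss$x_s
    }
    traj <- simulate_trajectory(model, theta_true, xs, ex$u_perturbed,
                                ex$time_points)
    for (i in seq_len(model$n_y))
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = ex$id, observable = i, time = ex$time_points,
        value = traj$y[, i], sigma = sigma[i])
  }
  obs <- do.call(rbind, rows)
  if (!noise_free)
    obs$value <- obs$value +
      with_seed(seed, stats::rnorm(nrow(obs), sd = obs$sigma))
  if (sigma_free) obs$sigma <- NA_real_
  ds <- perturbation_dataset(experiments, obs)
  attr(ds, "theta_true") <- theta_true
  attr(ds, "model_name") <- model$name
  ds
}

#' The conversion-process toy dataset
#'
#' One experiment for the conversion model: control input u_c = 1,
#' perturbation input u = 0.4, observation times t = (0, 0.1, 0.5, 1,
#' 2), generating parameters theta = (4, 1), unit noise variance. The
#' default is the noise-free variant (residuals vanish exactly at the
#' generating parameters); `noisy = TRUE` adds seeded unit-variance
#' Gaussian noise.
#'
#' @param noisy add noise?
#' @param seed seed for the noisy variant.
#' @return an `ssfit_dataset` (attribute `theta_true` = c(4, 1)).
#' @export
toy_fixture <- function(noisy = FALSE, seed = 1L) {
  model <- build_conversion_model()
  ex <- experiment_spec("toy", u_control = 1, u_perturbed = 0.4,
                        time_points = c(0, 0.1, 0.5, 1, 2))
  generate_dataset(model, theta_true = c(4, 1), experiments = list(ex),
                   sigma = 1, seed = seed, noise_free = !noisy)
}

# documented generating parameters of the synthetic Raf/MEK/ERK fixture
# (time unit: minutes; rates chosen so the release transient spans the
# 0-120 min sampling window and both inhibitors act within their dose)
raf_true_theta <- function(hypothesis, K1 = 0.2, n_blots = 1) {
  kin <- c(k1_0 = 0.03, k1_1 = 0.6, tau1 = 10, tau2 = 30, k2 = 0.1,
           k3Raf0 = 0.3, K2 = 1, k4 = 0.08, k5MEK0 = 0.3, K3 = 1,
           k6 = 0.08)
  if (hypothesis == "H1") kin <- c(kin, K1 = K1)
  c(kin, stats::setNames(rep(2, n_blots), paste0("s1_", seq_len(n_blots))),
    stats::setNames(rep(2, n_blots), paste0("s2_", seq_len(n_blots))))
}

#' Synthetic Raf/MEK/ERK perturbation dataset
#'
#' Emulates the Western-blot study design: three conditions — control,
#' Raf-inhibitor (sorafenib) and MEK-inhibitor (UO126) — all released
#' from the same S-phase-arrest steady state at t = 0 and observed as
#' per-blot scaled relative pMEK and pERK levels. The generating
#' parameters are documented package constants (see the vignette); under
#' H1 the feedback constant `feedback_strength` (= K1 relative to the
#' total ERK abundance, smaller = stronger feedback) defaults to 0.2,
#' well inside the identifiable range.
#'
#' @param hypothesis `"H1"` (negative feedback) or `"H2"` (none).
#' @param feedback_strength K1 of the generating model (H1 only).
#' @param seed RNG seed for the noise.
#' @param n_blots number of replicate blots.
#' @param sigma noise standard deviation on the observable scale.
#' @param noise_free skip the noise.
#' @return an `ssfit_dataset` with attributes `theta_true`,
#'   `model_name`, `hypothesis`.
#' @export
raf_fixture <- function(hypothesis = c("H1", "H2"),
                        feedback_strength = 0.2, seed = 1L, n_blots = 1,
                        sigma = 0.05, noise_free = FALSE) {
  hypothesis <- match.arg(hypothesis)
  model <- build_raf_mek_erk_model(hypothesis, n_blots = n_blots)
  theta <- raf_true_theta(hypothesis, K1 = feedback_strength,
                          n_blots = n_blots)
  times <- c(0, 5, 10, 20, 30, 45, 60, 90, 120)
  exps <- list(
    experiment_spec("control", c(0, 0), c(0, 0), times),
    experiment_spec("sorafenib", c(0, 0), c(5, 0), times),
    experiment_spec("UO126", c(0, 0), c(0, 5), times))
  ds <- generate_dataset(model, theta, exps, sigma = sigma, seed = seed,
                         noise_free = noise_free)
  attr(ds, "hypothesis") <- hypothesis
  ds
}
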