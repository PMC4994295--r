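#' Conversion-process model
#'
#' Reversible conversion A <-> B under mass conservation
#' (\[A\] + \[B\] = 1) and mass-action kinetics, with forward rate
#' theta1 * u driven by the input and backward rate theta2. In the
#' remaining coordinate x = \[A\]:
#' dx/dt = theta2 - (theta1 u + theta2) x, y = x, with analytic steady
#' state x_s = theta2 / (theta1 u + theta2).
#'
#' The parameters are optimized on the linear scale (the flow
#' illustrations for this process evolve in the linear parameters),
#' bounds \[1e-2, 1e2\].
#'
#' @return an `ssfit_model` with 1 state, 2 parameters, 1 input.
#' @export
build_conversion_model <- function() {
  ode_model(
    name = "conversion",
    n_x = 1, n_theta = 2, n_u = 1, n_y = 1,
    f = function(x, theta, u) theta[2] - (theta[1] * u + theta[2]) * x,
    h = function(x, theta, u) x,
    dfdx = function(x, theta, u)
      matrix(-(theta[1] * u + theta[2]), 1, 1),
    dfdtheta = function(x, theta, u)
      matrix(c(-u * x, 1 - x), 1, 2),
    dhdx = function(x, theta, u) matrix(1, 1, 1),
    dhdtheta = function(x, theta, u) matrix(0, 1, 2),
    x_s_analytic = function(theta, u)
      theta[2] / (theta[1] * u + theta[2]),
    parameter_scale = "linear",
    bounds = cbind(c(1e-2, 1e-2), c(1e2, 1e2)),
    theta_names = c("theta1", "theta2"),
    state_names = "A", obs_names = "A"
  ) |> with_compiled(1L)
}

#' NGF-induced ERK phosphorylation model
#'
#' Two-state model of TrkA receptor activation (x1) and ERK
#' phosphorylation (x2) in response to the NGF input u:
#' dx1/dt = k1 u (k3\[TrkA\]0 - x1) - k2 x1,
#' dx2/dt = (x1 + k4)(s\[ERK\]0 - x2) - k5 x2, y = x2.
#' The composite products k3\[TrkA\]0 and s\[ERK\]0 are single
#' identifiable parameters. The noise variance sigma^2 is estimated and
#' appended as the seventh parameter,
#' theta = (k1, k2, k3\[TrkA\]0, k4, s\[ERK\]0, k5, sigma^2), all on
#' log10 scale with natural-scale bounds \[1e-5, 1e5\].
#'
#' The analytic steady state
#' x_s1 = k3\[TrkA\]0 k1 u / (k1 u + k2),
#' x_s2 = s\[ERK\]0 (x_s1 + k4) / (x_s1 + k4 + k5)
#' exists and is exponentially stable for all positive parameters.
#'
#' @return an `ssfit_model` with 2 states, 7 parameters, 1 input.
#' @export
build_ngf_erk_model <- function() {
  ode_model(
    name = "ngf_erk",
    n_x = 2, n_theta = 7, n_u = 1, n_y = 1,
    f = function(x, theta, u) {
      k1 <- theta[1]; k2 <- theta[2]; k3T <- theta[3]
      k4 <- theta[4]; sE <- theta[5]; k5 <- theta[6]
      c(k1 * u * (k3T - x[1]) - k2 * x[1],
        (x[1] + k4) * (sE - x[2]) - k5 * x[2])
    },
    h = function(x, theta, u) x[2],
    dfdx = function(x, theta, u) {
      k1 <- theta[1]; k2 <- theta[2]; k4 <- theta[4]
      sE <- theta[5]; k5 <- theta[6]
      matrix(c(-k1 * u - k2, sE - x[2],
               0, -(x[1] + k4) - k5), 2, 2)
    },
    dfdtheta = function(x, theta, u) {
      k1 <- theta[1]; k4 <- theta[4]; sE <- theta[5]
      J <- matrix(0, 2, 7)
      J[1, 1] <- u * (theta[3] - x[1])
      J[1, 2] <- -x[1]
      J[1, 3] <- k1 * u
      J[2, 4] <- sE - x[2]
      J[2, 5] <- x[1] + k4
      J[2, 6] <- -x[2]
      J
    },
    dhdx = function(x, theta, u) matrix(c(0, 1), 1, 2),
    dhdtheta = function(x, theta, u) matrix(0, 1, 7),
    x_s_analytic = function(theta, u) {
      k1 <- theta[1]; k2 <- theta[2]; k3T <- theta[3]
      k4 <- theta[4]; sE <- theta[5]; k5 <- theta[6]
      xs1 <- k3T * k1 * u / (k1 * u + k2)
      c(xs1, sE * (xs1 + k4) / (xs1 + k4 + k5))
    },
    parameter_scale = "log10",
    bounds = cbind(rep(-5, 7), rep(5, 7)),
    theta_names = c("k1", "k2", "k3TrkA0", "k4", "sERK0", "k5", "sigma2"),
    state_names = c("TrkA_active", "pERK"), obs_names = "pERK",
    sigma_param = 7L
  ) |> with_compiled(2L)
}

#' Raf/MEK/ERK signaling model after release from S-phase arrest
#'
#' Three-state nonautonomous model in relative phosphorylation levels
#' x1 = \[pRaf\]/\[Raf\]0, x2 = \[pMEK\]/\[MEK\]0,
#' x3 = \[pERK\]/\[ERK\]0:
#' dx1/dt = k1max(t) xi (1 - x1) - k2 x1,
#' dx2/dt = k3\[Raf\]0 K2 / (K2 + \[sora\]) x1 (1 - x2) - k4 x2,
#' dx3/dt = k5\[MEK\]0 K3 / (K3 + \[UO126\]) x2 (1 - x3) - k6 x3,
#' with upstream drive k1max(t) = k10 + k11 (1 - exp(-t/tau1))
#' exp(-t/tau2) and inputs u = (\[sora\], \[UO126\]) (Raf and MEK
#' inhibitor concentrations).
#'
#' Hypothesis H1 includes negative feedback from pERK onto Raf
#' phosphorylation, xi = K1 / (K1 + x3), where K1 is the feedback
#' constant expressed relative to \[ERK\]0 (the identifiable composite in
#' the relative-state formulation); H2 sets xi = 1. Observables are
#' per-blot scaled phosphorylation levels y1b = s1b x2, y2b = s2b x3 for
#' blots b = 1..n_blots, with composite scaling parameters absorbing the
#' total abundances.
#'
#' Cells are arrested before release, so the steady-state machinery
#' evaluates the vector field at t = 0 where k1max(0) = k10; no analytic
#' steady-state map is attached (it is computed numerically). Parameters
#' are on log10 scale, natural-scale bounds \[1e-2, 1e2\]:
#' rate constants outside two decades of the sampling window's time
#' scale are indistinguishable on this design.
#'
#' @param hypothesis `"H1"` (feedback) or `"H2"` (no feedback).
#' @param n_blots number of replicate blots per condition.
#' @return an `ssfit_model` with 3 states, 2 inputs, `2 * n_blots`
#'   observables and 11 (H2) or 12 (H1) kinetic parameters plus
#'   `2 * n_blots` scaling parameters.
#' @export
build_raf_mek_erk_model <- function(hypothesis = c("H1", "H2"),
                                    n_blots = 1) {
  hypothesis <- match.arg(hypothesis)
  h1 <- hypothesis == "H1"
  kin_names <- c("k1_0", "k1_1", "tau1", "tau2", "k2", "k3Raf0", "K2",
                 "k4", "k5MEK0", "K3", "k6", if (h1) "K1")
  n_kin <- length(kin_names)
  i_s1 <- n_kin + seq_len(n_blots)
  i_s2 <- n_kin + n_blots + seq_len(n_blots)
  n_th <- n_kin + 2 * n_blots
  n_y <- 2 * n_blots

  k1max <- function(theta, t)
    theta[1] + theta[2] * (1 - exp(-t / theta[3])) * exp(-t / theta[4])
  xi <- function(theta, x)
    if (h1) theta[12] / (theta[12] + x[3]) else 1

  f <- function(x, theta, u, t) {
    a2 <- theta[6] * theta[7] / (theta[7] + u[1])
    a3 <- theta[9] * theta[10] / (theta[10] + u[2])
    c(k1max(theta, t) * xi(theta, x) * (1 - x[1]) - theta[5] * x[1],
      a2 * x[1] * (1 - x[2]) - theta[8] * x[2],
      a3 * x[2] * (1 - x[3]) - theta[11] * x[3])
  }

  dfdx <- function(x, theta, u, t) {
    a2 <- theta[6] * theta[7] / (theta[7] + u[1])
    a3 <- theta[9] * theta[10] / (theta[10] + u[2])
    km <- k1max(theta, t)
    J <- matrix(0, 3, 3)
    J[1, 1] <- -km * xi(theta, x) - theta[5]
    if (h1)
      J[1, 3] <- -km * (1 - x[1]) * theta[12] / (theta[12] + x[3])^2
    J[2, 1] <- a2 * (1 - x[2])
    J[2, 2] <- -a2 * x[1] - theta[8]
    J[3, 2] <- a3 * (1 - x[3])
    J[3, 3] <- -a3 * x[2] - theta[11]
    J
  }

  dfdtheta <- function(x, theta, u, t) {
    J <- matrix(0, 3, n_th)
    xiv <- xi(theta, x)
    e1 <- exp(-t / theta[3]); e2 <- exp(-t / theta[4])
    # k1max partials
    J[1, 1] <- xiv * (1 - x[1])
    J[1, 2] <- (1 - e1) * e2 * xiv * (1 - x[1])
    J[1, 3] <- -theta[2] * e1 * (t / theta[3]^2) * e2 * xiv * (1 - x[1])
    J[1, 4] <- theta[2] * (1 - e1) * e2 * (t / theta[4]^2) * xiv * (1 - x[1])
    J[1, 5] <- -x[1]
    if (h1)
      J[1, 12] <- k1max(theta, t) * (1 - x[1]) *
        x[3] / (theta[12] + x[3])^2
    # MEK layer
    q2 <- theta[7] / (theta[7] + u[1])
    J[2, 6] <- q2 * x[1] * (1 - x[2])
    J[2, 7] <- theta[6] * u[1] / (theta[7] + u[1])^2 * x[1] * (1 - x[2])
    J[2, 8] <- -x[2]
    # ERK layer
    q3 <- theta[10] / (theta[10] + u[2])
    J[3, 9] <- q3 * x[2] * (1 - x[3])
    J[3, 10] <- theta[9] * u[2] / (theta[10] + u[2])^2 * x[2] * (1 - x[3])
    J[3, 11] <- -x[3]
    J
  }

  h <- function(x, theta, u)
    c(theta[i_s1] * x[2], theta[i_s2] * x[3])

  dhdx <- function(x, theta, u) {
    J <- matrix(0, n_y, 3)
    J[seq_len(n_blots), 2] <- theta[i_s1]
    J[n_blots + seq_len(n_blots), 3] <- theta[i_s2]
    J
  }

  dhdtheta <- function(x, theta, u) {
    J <- matrix(0, n_y, n_th)
    for (b in seq_len(n_blots)) {
      J[b, i_s1[b]] <- x[2]
      J[n_blots + b, i_s2[b]] <- x[3]
    }
    J
  }

  ode_model(
    name = paste0("raf_mek_erk_", tolower(hypothesis)),
    n_x = 3, n_theta = n_th, n_u = 2, n_y = n_y,
    f = f, h = h, dfdx = dfdx, dfdtheta = dfdtheta,
    dhdx = dhdx, dhdtheta = dhdtheta,
    x_s_analytic = NULL,
    parameter_scale = "log10",
    bounds = cbind(rep(-2, n_th), rep(2, n_th)),
    theta_names = c(kin_names, paste0("s1_", seq_len(n_blots)),
                    paste0("s2_", seq_len(n_blots))),
    state_names = c("pRaf_rel", "pMEK_rel", "pERK_rel"),
    obs_names = c(paste0("pMEK_b", seq_len(n_blots)),
                  paste0("pERK_b", seq_len(n_blots)))
  ) |> with_compiled(if (h1) 3L else 4L)
}

# mark a zoo model as having a compiled rhs in src/ssfit_models.c
with_compiled <- function(model, id) {
  model$compiled <- list(id = id)
  model
}

#' Look up a model of the built-in zoo by name
#'
#' @param name one of `"conversion"`, `"ngf_erk"`, `"raf_mek_erk_h1"`,
#'   `"raf_mek_erk_h2"`.
#' @param ... passed on to the model builder (e.g. `n_blots`).
#' @return an `ssfit_model`.
#' @export
model_by_name <- function(name, ...) {
  switch(name,
    conversion = build_conversion_model(),
    ngf_erk = build_ngf_erk_model(),
    raf_mek_erk_h1 = build_raf_mek_erk_model("H1", ...),
    raf_mek_erk_h2 = build_raf_mek_erk_model("H2", ...),
    stop(sprintf("unknown model '%s'", name))
  )
}
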