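test_that("simulation matches the conversion model closed form", {
  # x(t) = x_s + (x0 - x_s) exp(-(theta1 u + theta2) t), rate 2.6
  th <- c(4, 1); u <- 0.4; x0 <- 0.2
  xs <- 1 / 2.6
  tr <- simulate_trajectory(conv_model, th, x0, u, c(0, 0.5, 2))
  expect_equal(tr$x[1, 1], x0)
  expect_equal(tr$x[2, 1], xs + (x0 - xs) * exp(-2.6 * 0.5),
               tolerance = 1e-8)
  expect_equal(tr$x[3, 1], xs + (x0 - xs) * exp(-2.6 * 2),
               tolerance = 1e-8)
  # y(0) = h(x0) for a single time point
  tr0 <- simulate_trajectory(ngf_model, random_ngf_theta(), c(0.3, 0.4),
                             0.5, 0)
  expect_equal(tr0$y[1, 1], 0.4)
})

test_that("forward sensitivities match finite differences", {
  th <- c(k1 = 0.5, k2 = 0.3, k3T = 2, k4 = 0.1, sE = 1.5, k5 = 0.7,
          s2 = 0.01)
  x0 <- c(0.2, 0.5); u <- 0.8; times <- c(0, 1, 3)
  tr <- simulate_trajectory(ngf_model, th, x0, u, times,
                            sensitivities = TRUE)
  # S(0) = 0 (x0 independent of theta), dx/dx0 (0) = identity
  expect_equal(max(abs(tr$S[1, , ])), 0)
  expect_equal(matrix(tr$Sx0[1, , ], 2, 2), diag(2))
  for (i in seq_along(th)) {
    fd <- vapply(seq_along(times), function(j) {
      hh <- 1e-6 * max(abs(th[i]), 1)
      tp <- th; tm <- th
      tp[i] <- th[i] + hh; tm[i] <- th[i] - hh
      (simulate_trajectory(ngf_model, tp, x0, u, times)$x[j, 2] -
         simulate_trajectory(ngf_model, tm, x0, u, times)$x[j, 2]) /
        (2 * hh)
    }, numeric(1))
    expect_lt(rel_err(tr$S[, 2, i], fd), 1e-4)
  }
})

test_that("steady-state computation converges for every strategy", {
  for (strat in c("hybrid", "simulate", "newton")) {
    ss <- compute_steady_state(conv_model, c(4, 1), 1, x_guess = 0.9,
                               tol = 1e-9, strategy = strat)
    expect_true(ss$converged)
    expect_lt(ss$residual_norm, 1e-9)
    expect_equal(ss$x_s, 0.2, tolerance = 1e-8)
  }
  # a guess already on the manifold is returned unchanged
  ss0 <- compute_steady_state(conv_model, c(4, 1), 1, x_guess = 0.2)
  expect_identical(ss0$x_s, 0.2)
  expect_identical(ss0$strategy_used, "none")
  # idempotence: feeding the output back changes nothing beyond tol
  set.seed(4)
  thn <- random_ngf_theta()
  ss1 <- compute_steady_state(ngf_model, thn, 0.5, tol = 1e-10)
  ss2 <- compute_steady_state(ngf_model, thn, 0.5, x_guess = ss1$x_s,
                              tol = 1e-10)
  expect_identical(ss2$x_s, ss1$x_s)
  expect_identical(ss2$strategy_used, "none")
})

test_that("numeric steady state matches the NGF closed form", {
  set.seed(77)
  for (k in 1:4) {
    th <- random_ngf_theta(); u <- 0.5
    ss <- compute_steady_state(ngf_model, th, u, tol = 1e-12)
    expect_true(ss$converged)
    expect_equal(ss$x_s, ngf_model$x_s_analytic(th, u),
                 tolerance = 1e-8)
  }
})

test_that("steady-state sensitivity matches the printed closed form", {
  S <- steady_state_sensitivity(conv_model, c(4, 1), 0.2, 1)
  expect_equal(as.numeric(S), c(-0.04, 0.16), tolerance = 1e-12)
  # finite differences of the steady-state map over theta
  th <- c(4, 1)
  fd <- fd_grad(function(z)
    compute_steady_state(conv_model, z, 1, tol = 1e-13)$x_s, th)
  expect_lt(rel_err(as.numeric(S), fd), 1e-5)
  # NGF: matrix-valued check against FD of the analytic map
  thn <- c(0.5, 0.3, 2, 0.1, 1.5, 0.7, 0.01)
  xsn <- ngf_model$x_s_analytic(thn, 0.8)
  Sn <- steady_state_sensitivity(ngf_model, thn, xsn, 0.8)
  for (i in 1:7) {
    hh <- 1e-6 * max(abs(thn[i]), 1)
    tp <- thn; tm <- thn
    tp[i] <- thn[i] + hh; tm[i] <- thn[i] - hh
    fdc <- (ngf_model$x_s_analytic(tp, 0.8) -
              ngf_model$x_s_analytic(tm, 0.8)) / (2 * hh)
    expect_lt(rel_err(Sn[, i], fdc), 1e-5)
  }
})

test_that("pseudoinverse sensitivity generalizes the exact solve", {
  # on-manifold: identical to the exact solve
  Sp <- steady_state_sensitivity_pinv(conv_model, c(4, 1), 0.2, 1)
  expect_equal(as.numeric(Sp), c(-0.04, 0.16), tolerance = 1e-10)
  # all-zero Jacobian: S_hat = 0
  m0 <- ode_model("flat", 2, 2, 1, 1,
    f = function(x, theta, u) c(theta[1], theta[2]),
    h = function(x, theta, u) x[1],
    dfdx = function(x, theta, u) matrix(0, 2, 2),
    dfdtheta = function(x, theta, u) diag(2),
    dhdx = function(x, theta, u) matrix(c(1, 0), 1, 2),
    dhdtheta = function(x, theta, u) matrix(0, 1, 2),
    parameter_scale = "linear", bounds = cbind(c(-1, -1), c(1, 1)))
  expect_equal(steady_state_sensitivity_pinv(m0, c(1, 1), c(0, 0), 0),
               matrix(0, 2, 2))
  # random full-rank system: pseudoinverse equals solve()
  set.seed(9)
  th <- ssfit:::raf_true_theta("H1")
  mr <- build_raf_mek_erk_model("H1")
  xs <- compute_steady_state(mr, th, c(0, 0), tol = 1e-12)$x_s
  expect_equal(steady_state_sensitivity_pinv(mr, th, xs, c(0, 0)),
               steady_state_sensitivity(mr, th, xs, c(0, 0)),
               tolerance = 1e-10)
})

test_that("zero-parameter-effect models have zero sensitivity", {
  m <- ode_model("decay", 1, 1, 1, 1,
    f = function(x, theta, u) -x + 1,
    h = function(x, theta, u) x,
    dfdx = function(x, theta, u) matrix(-1, 1, 1),
    dfdtheta = function(x, theta, u) matrix(0, 1, 1),
    dhdx = function(x, theta, u) matrix(1, 1, 1),
    dhdtheta = function(x, theta, u) matrix(0, 1, 1),
    parameter_scale = "linear", bounds = cbind(0, 1))
  expect_equal(steady_state_sensitivity(m, 0.5, 1, 0),
               matrix(0, 1, 1))
})

test_that("manifold continuation reproduces the steady state", {
  set.seed(13)
  # conversion model
  th <- c(4, 1); u <- 1
  dth <- c(0.8, -0.3)
  xs_end <- steady_state_continuation(conv_model, th,
                                      conv_model$x_s_analytic(th, u), u,
                                      dth, r_end = 1)
  expect_equal(xs_end, conv_model$x_s_analytic(th + dth, u),
               tolerance = 1e-8)
  # NGF model, random direction
  thn <- c(0.5, 0.3, 2, 0.1, 1.5, 0.7, 0.01)
  dthn <- runif(7, -0.02, 0.02) * thn
  xs0 <- ngf_model$x_s_analytic(thn, 0.6)
  xs_end <- steady_state_continuation(ngf_model, thn, xs0, 0.6, dthn)
  expect_equal(xs_end, ngf_model$x_s_analytic(thn + dthn, 0.6),
               tolerance = 1e-7)
})

test_that("simulation failure is reported with the model name", {
  mbad <- ode_model("blowup", 1, 1, 1, 1,
    f = function(x, theta, u) x^2,
    h = function(x, theta, u) x,
    dfdx = function(x, theta, u) matrix(2 * x, 1, 1),
    dfdtheta = function(x, theta, u) matrix(0, 1, 1),
    dhdx = function(x, theta, u) matrix(1, 1, 1),
    dhdtheta = function(x, theta, u) matrix(0, 1, 1),
    parameter_scale = "linear", bounds = cbind(0, 1))
  expect_error(
    suppressWarnings(simulate_trajectory(mbad, 1, 2, 0, c(0, 10))),
    "blowup")
})

test_that("trajectories export to a tidy data frame", {
  tr <- simulate_trajectory(conv_model, c(4, 1), 0.2, 0.4, c(0, 1))
  df <- trajectory_to_df(tr, conv_model, "e1")
  expect_equal(names(df), c("experiment", "time", "observable", "value"))
  expect_equal(nrow(df), 2)
  expect_equal(df$value[1], 0.2)
})
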