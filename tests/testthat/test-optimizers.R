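toy <- toy_fixture()
theta_star <- c(4, 1)
xs_star_c <- conv_model$x_s_analytic(theta_star, 1)

test_that("all four methods recover the toy generating parameters", {
  runs <- list(
    optimize_unconstrained(conv_model, toy, c(1, 1)),
    optimize_hybrid(conv_model, toy, c(1, 1)),
    optimize_constrained(conv_model, toy, c(1, 1), list(0.5)),
    optimize_simulation_based(conv_model, toy, c(1, 1), list(0.9),
                              lambda = 100, descent = "gradient",
                              eps_tol = 1e-9),
    optimize_simulation_based(conv_model, toy, c(1, 1), list(0.9),
                              lambda = 100, descent = "newton",
                              eps_tol = 1e-9))
  for (r in runs) {
    expect_equal(r$final$theta_natural, theta_star, tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_lt(r$J_final, 1e-10)
  }
  # method equivalence: same optimum within 1e-6
  J <- vapply(runs, function(r) r$J_final, numeric(1))
  expect_lt(max(J) - min(J), 1e-6)
})

test_that("starting at the optimum terminates immediately", {
  r <- optimize_unconstrained(conv_model, toy, theta_star)
  expect_lt(r$iterations, 3)
  expect_lt(r$J_final, 1e-12)
  rh <- optimize_hybrid(conv_model, toy, theta_star,
                        xs_guess = list(xs_star_c))
  expect_lt(rh$iterations, 3)
})

test_that("accepted runs never increase the objective", {
  set.seed(19)
  for (k in 1:3) {
    th0 <- runif(2, 0.1, 20)
    J0 <- negloglik(conv_model, toy, th0,
                    list(conv_model$x_s_analytic(th0, 1)))
    r <- optimize_unconstrained(conv_model, toy, th0)
    expect_lte(r$J_final, J0 + 1e-12)
  }
})

test_that("hybrid final states lie on the steady-state manifold", {
  r <- optimize_hybrid(conv_model, toy, c(2, 3), eps_tol = 1e-9)
  expect_lt(max(r$constraint_residuals), 1e-9)
  expect_equal(r$final$xs[[1]],
               conv_model$x_s_analytic(r$final$theta_natural, 1),
               tolerance = 1e-6)
})

test_that("hybrid reduced gradient equals the analytic reduced gradient", {
  ds <- toy_fixture(noisy = TRUE, seed = 2)
  for (th in list(c(2, 0.5), c(5, 2), c(1.2, 1.2))) {
    oa <- ssfit:::make_reduced_objective(conv_model, ds, "analytic")
    oh <- ssfit:::make_reduced_objective(conv_model, ds, "retract",
                                         eps_tol = 1e-12)
    ga <- oa$gr(th); gh <- oh$gr(th)
    expect_lt(rel_err(gh, ga), 1e-6)
    fd <- fd_grad(function(z) oa$fn(z), th)
    expect_lt(rel_err(ga, fd), 1e-4)
  }
})

test_that("constrained runs reach feasible near-stationary points", {
  r <- optimize_constrained(conv_model, toy, c(2, 2),
                            list(conv_model$x_s_analytic(c(2, 2), 1)))
  expect_lt(max(r$constraint_residuals), 1e-6)
  # stationarity of theta |-> J(theta, x_s(theta)) at the final point
  g <- ssfit:::make_reduced_objective(conv_model, toy,
                                      "analytic")$gr(r$final$theta)
  expect_lt(max(abs(g)), 1e-4)
  expect_true(is.numeric(r$constraint_residuals))
})

test_that("empty datasets reduce both baselines to no-ops", {
  ds0 <- perturbation_dataset(list(), data.frame(
    experiment = character(), observable = integer(), time = numeric(),
    value = numeric(), sigma = numeric()))
  ru <- optimize_unconstrained(conv_model, ds0, c(2, 2))
  rc <- optimize_constrained(conv_model, ds0, c(2, 2), list())
  expect_equal(ru$J_final, 0)
  expect_equal(rc$J_final, 0)
})

test_that("flow right-hand side matches hand-derived values", {
  # retraction term only: lambda * f at an off-manifold state
  d <- flow_rhs(conv_model, toy, c(4, 1), list(0.3), lambda = 10,
                descent = "none")
  expect_equal(d$dxs[[1]], 10 * (1 - 5 * 0.3), tolerance = 1e-12)
  expect_equal(d$dtheta, c(0, 0))
  # at the optimum on the manifold the full rhs vanishes
  d0 <- flow_rhs(conv_model, toy, theta_star, list(xs_star_c),
                 lambda = 100, descent = "gradient")
  expect_lt(d0$max_norm, 1e-7)
  # gradient mode descends: directional derivative of J along dtheta <= 0
  set.seed(41)
  for (k in 1:3) {
    th <- runif(2, 0.5, 8)
    xs <- conv_model$x_s_analytic(th, 1)
    for (desc in c("gradient", "newton")) {
      d <- flow_rhs(conv_model, toy, th, list(xs), lambda = 0,
                    descent = desc)
      red <- ssfit:::make_reduced_objective(conv_model, toy,
                                            "analytic")$gr(th)
      expect_lte(sum(red * d$dtheta), 1e-12)
    }
  }
})

test_that("lambda = 0 flows from on-manifold starts stay on the manifold", {
  th0 <- c(2, 2)
  xs0 <- conv_model$x_s_analytic(th0, 1)
  r <- optimize_simulation_based(conv_model, toy, th0, list(xs0),
                                 lambda = 0, descent = "gradient",
                                 settings = list(r_max_decade = 3))
  resid <- apply(r$path, 1, function(row)
    abs(conv_model$f(row["toy.A"], row[c("theta1", "theta2")], 1)))
  expect_lt(max(resid), 1e-6)
})

test_that("large-lambda flows show the two-phase pattern", {
  r <- optimize_simulation_based(conv_model, toy, c(1, 1), list(0.9),
                                 lambda = 100, descent = "gradient")
  expect_identical(r$exit_status, "converged")
  resid <- apply(r$path, 1, function(row)
    abs(conv_model$f(row["toy.A"], row[c("theta1", "theta2")], 1)))
  dist <- sqrt((r$path$theta1 - 4)^2 + (r$path$theta2 - 1)^2)
  r_manifold <- r$path$r[which(resid < 1e-6)[1]]
  r_theta <- r$path$r[which(dist < 1e-2)[1]]
  expect_lt(r_manifold, r_theta)
})

test_that("flows return to a perturbed optimum (local stability)", {
  set.seed(55)
  th0 <- theta_star + runif(2, -0.05, 0.05)
  xs0 <- conv_model$x_s_analytic(th0, 1) + runif(1, -0.01, 0.01)
  # a moderate retraction suffices for a near-manifold perturbation and
  # keeps the flow well inside the stiff solver's comfort zone
  r <- optimize_simulation_based(conv_model, toy, th0, list(xs0),
                                 lambda = 10, descent = "gradient",
                                 eps_tol = 1e-9)
  expect_lt(sqrt(sum((r$final$theta_natural - theta_star)^2)), 1e-4)
})
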