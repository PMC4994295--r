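toy_ds <- toy_fixture()

test_that("perfect fits give zero objective and zero gradients", {
  xs <- list(conv_model$x_s_analytic(c(4, 1), 1))
  expect_equal(negloglik(conv_model, toy_ds, c(4, 1), xs), 0,
               tolerance = 1e-14)
  ev <- objective_gradients(conv_model, toy_ds, c(4, 1), xs)
  expect_equal(ev$dJ_dtheta, c(0, 0), tolerance = 1e-7)
  expect_equal(ev$dJ_dxs[[1]], 0, tolerance = 1e-7)
})

test_that("single unit residual with unit sigma gives J = 1/2", {
  ex <- experiment_spec("e", 1, 0.4, 0)
  obs <- data.frame(experiment = "e", observable = 1, time = 0,
                    value = 0.2 + 1, sigma = 1)
  ds <- perturbation_dataset(list(ex), obs)
  expect_equal(negloglik(conv_model, ds, c(4, 1), list(0.2)), 0.5,
               tolerance = 1e-12)
})

test_that("partial gradients match joint finite differences", {
  ds <- toy_fixture(noisy = TRUE, seed = 3)
  th <- c(3, 1.4); xs <- 0.35
  ev <- objective_gradients(conv_model, ds, th, list(xs))
  fd <- fd_grad(function(z)
    negloglik(conv_model, ds, z[1:2], list(z[3])), c(th, xs))
  expect_lt(rel_err(c(ev$dJ_dtheta, ev$dJ_dxs[[1]]), fd), 1e-4)
})

test_that("reduced gradient contracts the chain rule as printed", {
  # identity contraction example
  partials <- structure(list(dJ_dtheta = c(0, 0),
                             dJ_dxs = list(c(1, 2))),
                        class = "ssfit_objective")
  expect_equal(reduced_gradient(partials, list(diag(2))), c(1, 2))
  # all-zero sensitivities leave the partial gradient unchanged
  expect_equal(reduced_gradient(partials, list(matrix(0, 2, 2))),
               c(0, 0))
  expect_error(reduced_gradient(partials, list(matrix(0, 3, 3))),
               "shape mismatch")
})

test_that("reduced gradient matches finite differences through x_s(theta)", {
  ds <- toy_fixture(noisy = TRUE, seed = 5)
  th <- c(3, 1.4)
  xs <- conv_model$x_s_analytic(th, 1)
  ev <- objective_gradients(conv_model, ds, th, list(xs))
  S <- steady_state_sensitivity(conv_model, th, xs, 1)
  red <- reduced_gradient(ev, list(S))
  fd <- fd_grad(function(z)
    negloglik(conv_model, ds, z, list(conv_model$x_s_analytic(z, 1))),
    th)
  expect_lt(rel_err(red, fd), 1e-4)
  # and the hand-derived toy form: residual-weighted total sensitivities
  tr <- ev$trajectories[[1]]
  hand <- c(0, 0)
  for (j in 1:5) {
    r <- ds$observations$value[j] - tr$y[j, 1]
    dy_tot <- tr$dydtheta[j, 1, ] + tr$dydx0[j, 1, ] %*% S
    hand <- hand - r * as.numeric(dy_tot)
  }
  expect_equal(red, hand, tolerance = 1e-10)
})

test_that("objective is invariant under record reordering", {
  ds <- toy_fixture(noisy = TRUE, seed = 8)
  th <- c(2, 0.7); xs <- list(0.4)
  J1 <- negloglik(conv_model, ds, th, xs)
  ds2 <- perturbation_dataset(ds$experiments,
                              ds$observations[rev(seq_len(5)), ])
  J2 <- negloglik(conv_model, ds2, th, xs)
  expect_equal(J1, J2, tolerance = 1e-14)
})

test_that("estimated sigma contributes value and gradient terms", {
  th <- c(0.5, 0.3, 2, 0.1, 1.5, 0.7, 0.04)
  ds <- ngf_dataset(th)
  obs <- ds$observations
  obs$sigma <- NA_real_  # estimate sigma^2 = theta[7]
  ds <- perturbation_dataset(ds$experiments, obs)
  xs <- lapply(ds$experiments, function(e)
    ngf_model$x_s_analytic(th, e$u_control))
  n <- nrow(ds$observations)
  # at a perfect fit J reduces to the normalizing constant
  expect_equal(negloglik(ngf_model, ds, th, xs),
               n * 0.5 * log(2 * pi * th[7]), tolerance = 1e-9)
  # gradient including the sigma component matches finite differences
  th2 <- th * c(1.2, 0.9, 1.1, 1, 0.95, 1.05, 1.3)
  ev <- objective_gradients(ngf_model, ds, th2, xs)
  fd <- fd_grad(function(z) negloglik(ngf_model, ds, z, xs), th2,
                eps = 1e-7)
  expect_lt(rel_err(ev$dJ_dtheta, fd), 1e-4)
})

test_that("Fisher information is the PSD sum of outer products", {
  # no data -> zero matrix
  ds0 <- perturbation_dataset(
    list(experiment_spec("e", 1, 0.4, c(0, 1))),
    data.frame(experiment = character(), observable = integer(),
               time = numeric(), value = numeric(), sigma = numeric()))
  F0 <- fisher_information(conv_model, ds0, c(4, 1), list(0.2),
                           list(matrix(0, 1, 2)))
  expect_equal(F0, matrix(0, 2, 2))
  # toy problem: F from the trajectory equals the hand-built sum
  xs <- conv_model$x_s_analytic(c(4, 1), 1)
  S <- steady_state_sensitivity(conv_model, c(4, 1), xs, 1)
  ev <- objective_gradients(conv_model, toy_ds, c(4, 1), list(xs))
  Fm <- fisher_information(conv_model, toy_ds, c(4, 1), list(xs),
                           list(S), partials = ev)
  hand <- matrix(0, 2, 2)
  for (j in 1:5) {
    g <- ev$trajectories[[1]]$dydtheta[j, 1, ] +
      as.numeric(ev$trajectories[[1]]$dydx0[j, 1, ] %*% S)
    hand <- hand + tcrossprod(g)
  }
  expect_equal(Fm, hand, tolerance = 1e-12)
  expect_equal(Fm, t(Fm))
  expect_gt(min(eigen(Fm, only.values = TRUE)$values), -1e-10)
  # randomized PSD property on the NGF model
  set.seed(31)
  for (k in 1:3) {
    th <- random_ngf_theta()
    ds <- ngf_dataset(th)
    xsl <- lapply(ds$experiments, function(e)
      ngf_model$x_s_analytic(th, e$u_control))
    Sl <- lapply(ds$experiments, function(e)
      steady_state_sensitivity(ngf_model, th,
                               ngf_model$x_s_analytic(th, e$u_control),
                               e$u_control))
    Fk <- fisher_information(ngf_model, ds, th, xsl, Sl)
    expect_gt(min(eigen(Fk, only.values = TRUE)$values), -1e-10)
  }
})
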