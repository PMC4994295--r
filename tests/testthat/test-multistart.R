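test_that("Latin hypercube starts stratify every dimension", {
  b <- cbind(c(-2, 0, 10), c(2, 1, 20))
  n <- 8
  s <- sample_starts(b, n, seed = 4)
  expect_equal(dim(s), c(n, 3))
  for (d in 1:3) {
    expect_true(all(s[, d] > b[d, 1] & s[, d] < b[d, 2]))
    stratum <- floor((s[, d] - b[d, 1]) / (b[d, 2] - b[d, 1]) * n)
    expect_setequal(stratum, 0:(n - 1))  # one point per stratum
  }
  expect_identical(sample_starts(b, n, seed = 4), s)
  expect_false(identical(sample_starts(b, n, seed = 5), s))
  expect_error(sample_starts(cbind(1, 1), 3), "degenerate")
})

test_that("likelihood-ratio classification uses the chi-square threshold", {
  # qchisq(0.95, 1) = 3.841459: 2*dJ = 6 rejected, 3.8 accepted
  J <- c(10, 10 + 1.9, 10 + 3)
  flags <- classify_convergence(J, alpha = 0.05, df = 1)
  expect_identical(flags, c(TRUE, TRUE, FALSE))
  expect_true(classify_convergence(c(5, 5))[2])
  # monotone in alpha: lowering alpha never de-converts
  for (a in c(0.01, 0.001)) {
    f2 <- classify_convergence(J, alpha = a)
    expect_true(all(f2[flags]))
  }
  # joint comparison against an external best
  expect_identical(classify_convergence(11.9, J_best = 10), TRUE)
  expect_identical(classify_convergence(12, J_best = 10), FALSE)
})

test_that("consistency diagnostic compares both steady-state criteria", {
  ds <- toy_fixture()
  run <- optimize_hybrid(conv_model, ds, c(2, 2), eps_tol = 1e-9)
  cns <- consistency_check(conv_model, ds, run)
  expect_true(cns$vectorfield_ok)
  expect_true(cns$steadystate_ok)
  # fabricated violation: on-manifold state perturbed by 1e-3
  bad <- run
  bad$final$xs[[1]] <- run$final$xs[[1]] + 1e-3
  bad$constraint_residuals <- vapply(seq_along(ds$experiments),
    function(e) abs(conv_model$f(bad$final$xs[[e]],
                                 run$final$theta_natural, 1)),
    numeric(1))
  cns_bad <- consistency_check(conv_model, ds, bad)
  expect_false(cns_bad$steadystate_ok)
  # unconstrained runs: both criteria coincide by construction
  ru <- optimize_unconstrained(conv_model, ds, c(2, 2))
  cns_u <- consistency_check(conv_model, ds, ru)
  expect_identical(cns_u$vectorfield_ok, cns_u$steadystate_ok)
})

test_that("performance metrics summarize runs as documented", {
  fake <- list(runs = list(), J_sorted = c(1, 2, 3),
               converged_flags = c(TRUE, TRUE, FALSE),
               fraction_converged = 2 / 3, total_time = 6,
               time_per_converged_start = 3)
  pm <- performance_metrics(fake)
  expect_equal(pm$fraction_converged, 2 / 3)
  expect_equal(pm$time_per_converged_start, 3)
  expect_true(!is.unsorted(pm$waterfall))
  fake$converged_flags <- c(FALSE, FALSE, FALSE)
  fake$fraction_converged <- 0
  fake$time_per_converged_start <- Inf
  expect_identical(performance_metrics(fake)$time_per_converged_start,
                   Inf)
})

test_that("multi-start harness reuses identical starts across methods", {
  ds <- toy_fixture()
  ms <- run_multistart(conv_model, ds,
                       methods = c("unconstrained", "hybrid"),
                       n_starts = 4, seed = 9)
  s1 <- t(vapply(ms$methods$unconstrained$runs,
                 function(r) r$start$theta, numeric(2)))
  s2 <- t(vapply(ms$methods$hybrid$runs,
                 function(r) r$start$theta, numeric(2)))
  expect_equal(s1[order(s1[, 1]), ], s2[order(s2[, 1]), ],
               tolerance = 1e-12)
  expect_equal(ms$J_best,
               min(vapply(ms$methods$unconstrained$runs,
                          function(r) r$J_final, numeric(1))),
               tolerance = 1e-9)
  expect_true(!is.unsorted(ms$methods$hybrid$J_sorted))
  expect_error(run_multistart(conv_model, ds, methods = "nope"),
               "unknown method")
})

test_that("information criteria follow their definitions", {
  ic0 <- information_criteria(0, 0, 5)
  expect_equal(unname(ic0), c(0, 0))
  ic <- information_criteria(1, 2, 10)
  expect_equal(ic[["BIC"]], 2 + 2 * log(10))
  expect_equal(ic[["AIC"]], 6)
  # a hypothesis difference is just the BIC difference
  b1 <- information_criteria(10, 5, 50)[["BIC"]]
  b2 <- information_criteria(12, 4, 50)[["BIC"]]
  expect_equal(b2 - b1, 2 * 2 - log(50))
})
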