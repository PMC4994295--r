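test_that("noise-free generation reproduces the model output exactly", {
  ds <- toy_fixture()
  expect_equal(nrow(ds$observations), 5)
  expect_equal(ds$observations$value[1], 0.2, tolerance = 1e-10)
  xs <- conv_model$x_s_analytic(c(4, 1), 1)
  tr <- simulate_trajectory(conv_model, c(4, 1), xs, 0.4,
                            c(0, 0.1, 0.5, 1, 2))
  expect_equal(ds$observations$value, tr$y[, 1], tolerance = 1e-10)
  # sigma = 0 with noise on also reproduces the model output
  ex <- ds$experiments[[1]]
  ds0 <- generate_dataset(conv_model, c(4, 1), list(ex), sigma = 0,
                          seed = 2, noise_free = FALSE)
  expect_equal(ds0$observations$value, tr$y[, 1], tolerance = 1e-10)
})

test_that("toy fixture matches its documented configuration", {
  ds <- toy_fixture()
  expect_length(ds$experiments, 1)
  ex <- ds$experiments[[1]]
  expect_equal(ex$u_control, 1)
  expect_equal(ex$u_perturbed, 0.4)
  expect_equal(ex$time_points, c(0, 0.1, 0.5, 1, 2))
  expect_true(all(ds$observations$sigma == 1))
  expect_equal(attr(ds, "theta_true"), c(4, 1))
  # J = 0 at the generating parameters
  expect_equal(negloglik(conv_model, ds, c(4, 1),
                         list(conv_model$x_s_analytic(c(4, 1), 1))),
               0, tolerance = 1e-14)
  # seeded noisy variant is reproducible
  expect_identical(toy_fixture(noisy = TRUE, seed = 7)$observations,
                   toy_fixture(noisy = TRUE, seed = 7)$observations)
  expect_false(identical(
    toy_fixture(noisy = TRUE, seed = 7)$observations$value,
    toy_fixture(noisy = TRUE, seed = 8)$observations$value))
})

test_that("noise draws have the configured standard deviation", {
  ex <- experiment_spec("e", 1, 0.4, 0)
  vals <- vapply(1:2000, function(s)
    generate_dataset(conv_model, c(4, 1), list(ex), sigma = 0.3,
                     seed = s)$observations$value, numeric(1))
  expect_lt(abs(sd(vals) - 0.3) / 0.3, 0.03)
  expect_lt(abs(mean(vals) - 0.2), 0.025)  # ~3 standard errors

})

test_that("Raf fixture encodes the three-condition Western-blot design", {
  ds <- raf_fixture("H1", seed = 1)
  expect_length(ds$experiments, 3)
  ucs <- t(vapply(ds$experiments, function(e) e$u_control, numeric(2)))
  expect_true(all(ucs == 0))  # all conditions share the arrest steady state
  ups <- t(vapply(ds$experiments, function(e) e$u_perturbed, numeric(2)))
  expect_true(any(ups[, 1] > 0) && any(ups[, 2] > 0))
  expect_identical(raf_fixture("H1", seed = 3)$observations,
                   raf_fixture("H1", seed = 3)$observations)
})

test_that("UO126 decouples pMEK only in the absence of feedback", {
  # H2: control and UO126 pMEK trajectories coincide (x2 is upstream)
  mh2 <- build_raf_mek_erk_model("H2")
  th2 <- ssfit:::raf_true_theta("H2")
  ds2 <- raf_fixture("H2", noise_free = TRUE)
  obs2 <- ds2$observations
  pmek_ctrl <- obs2$value[obs2$experiment == "control" &
                            obs2$observable == 1]
  pmek_uo <- obs2$value[obs2$experiment == "UO126" &
                          obs2$observable == 1]
  expect_equal(pmek_uo, pmek_ctrl, tolerance = 1e-8)
  # H1 with strong feedback: UO126 raises pMEK above control
  ds1 <- raf_fixture("H1", feedback_strength = 0.2, noise_free = TRUE)
  obs1 <- ds1$observations
  pmek_ctrl1 <- obs1$value[obs1$experiment == "control" &
                             obs1$observable == 1]
  pmek_uo1 <- obs1$value[obs1$experiment == "UO126" &
                           obs1$observable == 1]
  expect_true(all(pmek_uo1[-1] > pmek_ctrl1[-1]))
})

test_that("generated datasets round-trip through the TSV writer", {
  ds <- raf_fixture("H1", seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$observations$value, ds$observations$value,
               tolerance = 1e-15)
  expect_equal(back$observations$sigma, ds$observations$sigma)
  expect_equal(names(back$experiments), names(ds$experiments))
  for (id in names(ds$experiments)) {
    expect_equal(back$experiments[[id]]$u_perturbed,
                 ds$experiments[[id]]$u_perturbed)
    expect_equal(back$experiments[[id]]$time_points,
                 ds$experiments[[id]]$time_points)
  }
})

test_that("fitting the generator's own noise-free data recovers theta", {
  ds <- toy_fixture()
  r <- optimize_hybrid(conv_model, ds, c(2, 0.5))
  expect_equal(r$final$theta_natural, c(4, 1), tolerance = 1e-3,
               ignore_attr = TRUE)
})
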