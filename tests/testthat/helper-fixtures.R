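# shared fixtures and numeric helpers

conv_model <- build_conversion_model()
ngf_model <- build_ngf_erk_model()

# finite-difference gradient of a scalar function
fd_grad <- function(fn, z, eps = 1e-6) {
  vapply(seq_along(z), function(i) {
    h <- eps * max(abs(z[i]), 1)
    zp <- z; zm <- z
    zp[i] <- z[i] + h; zm[i] <- z[i] - h
    (fn(zp) - fn(zm)) / (2 * h)
  }, numeric(1))
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)

# a positive random NGF parameter vector away from bound edges
random_ngf_theta <- function() 10^stats::runif(7, -1, 1)

# quick noise-free dataset for the NGF model (sigma fixed, not estimated)
ngf_dataset <- function(theta, sigma = 0.05) {
  exps <- list(
    experiment_spec("low", u_control = 0, u_perturbed = 0.2,
                    time_points = c(0, 0.5, 1, 2, 4)),
    experiment_spec("high", u_control = 0, u_perturbed = 1,
                    time_points = c(0, 0.5, 1, 2, 4)))
  generate_dataset(ngf_model, theta, exps, sigma = sigma,
                   noise_free = TRUE)
}
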