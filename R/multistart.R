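#' Latin hypercube sample of optimizer starting points
#'
#' Samples `n_starts` points on the optimization scale: each dimension
#' is partitioned into `n_starts` equal strata with exactly one point
#' per stratum, randomly permuted across dimensions. Reproducible under
#' `seed`.
#'
#' @param bounds `n_theta x 2` matrix of lower/upper bounds
#'   (optimization scale).
#' @param n_starts number of starting points (>= 1).
#' @param seed RNG seed.
#' @return `n_starts x n_theta` matrix of starts.
#' @export
sample_starts <- function(bounds, n_starts, seed = 1L) {
  bounds <- as.matrix(bounds)
  stopifnot(n_starts >= 1, ncol(bounds) == 2)
  if (any(!is.finite(bounds)) || any(bounds[, 1] >= bounds[, 2]))
    stop("degenerate bounds")
  d <- nrow(bounds)
  with_seed(seed, {
    u <- lhs::randomLHS(n_starts, d)
    sweep(sweep(u, 2, bounds[, 2] - bounds[, 1], `*`), 2, bounds[, 1],
          `+`)
  })
}

#' Classify multi-start runs as converged by a likelihood-ratio test
#'
#' A run counts as converged when its final objective cannot be rejected
#' against the best objective found: 2 (J_final - J_best) <=
#' chi^2 quantile(1 - alpha, df). When runs from several methods are
#' compared jointly, pass the global best as `J_best`.
#'
#' @param runs list of `ssfit_run` objects, or a numeric vector of final
#'   objective values.
#' @param alpha significance level (default 0.05).
#' @param df degrees of freedom of the reference chi^2 distribution
#'   (default 1: two point estimates of the same model are compared).
#' @param J_best reference optimum; default the minimum over `runs`.
#' @return logical vector of convergence flags.
#' @export
classify_convergence <- function(runs, alpha = 0.05, df = 1,
                                 J_best = NULL) {
  J <- if (is.numeric(runs)) runs else
    vapply(runs, function(r) r$J_final, numeric(1))
  if (!length(J)) stop("no runs to classify")
  J_best <- J_best %||% min(J, na.rm = TRUE)
  thr <- stats::qchisq(1 - alpha, df = df)
  ifelse(is.finite(J), 2 * (J - J_best) <= thr, FALSE)
}

#' Steady-state consistency diagnostic for a finished run
#'
#' Evaluates, at the run's final point, (i) whether the solver's own
#' convergence signal holds — the vector-field criterion
#' ||f(x_s, theta, u_c)||_2 < eps_f for every experiment — and (ii)
#' whether the estimated steady states are actually close to the true
#' steady-state map, ||x_s - x_s(theta, u_c)||_2 < eps_x, with the
#' reference computed analytically when the model provides a closed form
#' and by a high-accuracy numeric computation (tolerance 1e-12)
#' otherwise. For a reliable optimizer the two criteria agree.
#'
#' @param model an `ssfit_model`.
#' @param dataset the fitted `ssfit_dataset` (for the control inputs).
#' @param run an `ssfit_run`.
#' @param eps_f,eps_x tolerances (default 1e-6 each).
#' @return list with logicals `vectorfield_ok` and `steadystate_ok`
#'   (`NA` if the reference steady state could not be computed) and the
#'   per-experiment residuals and deviations.
#' @export
consistency_check <- function(model, dataset, run, eps_f = 1e-6,
                              eps_x = 1e-6) {
  theta <- run$final$theta_natural
  exps <- dataset$experiments
  resid <- run$constraint_residuals
  dx <- rep(NA_real_, length(exps))
  for (e in seq_along(exps)) {
    xs_hat <- run$final$xs[[e]]
    if (is.null(xs_hat)) next
    uc <- exps[[e]]$u_control
    ref <- if (!is.null(model$x_s_analytic))
      model$x_s_analytic(theta, uc)
    else {
      ss <- tryCatch(compute_steady_state(model, theta, uc,
                                          x_guess = xs_hat, tol = 1e-12),
                     error = function(err) NULL)
      if (!is.null(ss) && ss$converged) ss$x_s else NULL
    }
    if (!is.null(ref)) dx[e] <- sqrt(sum((xs_hat - ref)^2))
  }
  list(vectorfield_ok = all(is.finite(resid)) && all(resid < eps_f),
       steadystate_ok = if (anyNA(dx) && length(dx)) NA else
         all(dx < eps_x),
       residuals = resid, steady_state_deviation = dx)
}

#' Run a multi-start comparison of optimization methods
#'
#' Draws a common Latin hypercube start set (identical across methods;
#' the constrained and simulation-based methods additionally receive
#' common random state starts) and runs each requested method from every
#' start.
#'
#' @param model an `ssfit_model`.
#' @param dataset an `ssfit_dataset`.
#' @param methods character vector among `"unconstrained"`,
#'   `"constrained"`, `"hybrid"`, `"sim-gradient"`, `"sim-newton"`.
#' @param n_starts number of common starts.
#' @param seed seed for the start set.
#' @param alpha likelihood-ratio significance level.
#' @param lambda,mu,eps_tol settings forwarded to the methods (eps_tol
#'   to the hybrid retraction and, via `eps_tol_flow`, the flow
#'   stopping rule).
#' @param eps_tol_flow convergence tolerance of the simulation-based
#'   flow.
#' @param eps_feasible feasibility tolerance on the per-experiment
#'   constraint residual ||f||_2: the reference optimum of the
#'   likelihood-ratio classification is the best objective among
#'   feasible runs, and only feasible runs can count as converged.
#' @param settings optimizer settings list forwarded to every method;
#'   `settings$time_limit` (seconds) additionally caps each individual
#'   run, recording runs that exceed it as failed.
#' @return an `ssfit_multistart`: per-method lists of runs (each sorted
#'   by final objective), global `J_best`, per-method convergence flags,
#'   fractions, timings and consistency tables.
#' @export
run_multistart <- function(model, dataset, methods = "hybrid",
                           n_starts = 10, seed = 1L, alpha = 0.05,
                           lambda = 100, mu = NULL, eps_tol = 1e-9,
                           eps_tol_flow = 1e-6, eps_feasible = 1e-6,
                           settings = list()) {
  known <- c("unconstrained", "constrained", "hybrid", "sim-gradient",
             "sim-newton")
  if (!all(methods %in% known))
    stop("unknown method(s): ",
         paste(setdiff(methods, known), collapse = ", "))
  starts <- sample_starts(model$bounds, n_starts, seed = seed)
  E <- length(dataset$experiments)
  # common state starts, drawn from the same seeded stream
  xs_starts <- with_seed(seed + 1L, lapply(seq_len(n_starts), function(s)
    replicate(E, stats::runif(model$n_x), simplify = FALSE)))

  time_limit <- settings$time_limit %||% Inf
  all_runs <- list()
  for (m in methods) {
    runs <- vector("list", n_starts)
    for (s in seq_len(n_starts)) {
      th0 <- starts[s, ]
      if (is.finite(time_limit)) {
        setTimeLimit(elapsed = time_limit, transient = TRUE)
        on.exit(setTimeLimit(), add = TRUE)
      }
      runs[[s]] <- tryCatch(switch(m,
        unconstrained = optimize_unconstrained(model, dataset, th0,
                                               settings),
        hybrid = optimize_hybrid(model, dataset, th0,
                                 xs_guess = xs_starts[[s]],
                                 eps_tol = eps_tol, settings = settings),
        constrained = optimize_constrained(model, dataset, th0,
                                           xs_starts[[s]], settings),
        `sim-gradient` = optimize_simulation_based(
          model, dataset, th0, xs_starts[[s]], lambda = lambda,
          descent = "gradient", eps_tol = eps_tol_flow,
          settings = settings),
        `sim-newton` = optimize_simulation_based(
          model, dataset, th0, xs_starts[[s]], lambda = lambda,
          descent = "newton", mu = mu, eps_tol = eps_tol_flow,
          settings = settings)),
        error = function(err) structure(list(
          method = m, start = list(theta = th0), final = list(),
          J_final = Inf, iterations = 0L, n_ode_simulations = 0L,
          wall_time = 0, constraint_residuals = rep(NA_real_, E),
          exit_status = paste("error:", conditionMessage(err))),
          class = "ssfit_run"))
      setTimeLimit()
    }
    all_runs[[m]] <- runs
  }

  # reference optimum: best objective among *feasible* final points —
  # a low objective bought by violating the steady-state constraint is
  # not a maximum-likelihood estimate of the constrained problem
  flat <- unlist(all_runs, recursive = FALSE)
  feas_all <- vapply(flat, function(r)
    all(is.finite(r$constraint_residuals)) &&
      all(r$constraint_residuals < eps_feasible), logical(1))
  J_all <- vapply(flat, function(r) r$J_final, numeric(1))
  J_best <- if (any(feas_all)) min(J_all[feas_all], na.rm = TRUE) else
    suppressWarnings(min(J_all, na.rm = TRUE))
  per_method <- lapply(all_runs, function(runs) {
    J <- vapply(runs, function(r) r$J_final, numeric(1))
    ord <- order(J)
    runs <- runs[ord]
    feas <- vapply(runs, function(r)
      all(is.finite(r$constraint_residuals)) &&
        all(r$constraint_residuals < eps_feasible), logical(1))
    flags <- classify_convergence(runs, alpha = alpha,
                                  J_best = J_best) & feas
    consist <- lapply(runs, function(r)
      tryCatch(consistency_check(model, dataset, r),
               error = function(e) list(vectorfield_ok = NA,
                                        steadystate_ok = NA)))
    total_time <- sum(vapply(runs, function(r) r$wall_time, numeric(1)))
    list(runs = runs, J_sorted = sort(J), converged_flags = flags,
         feasible_flags = feas,
         fraction_converged = mean(flags),
         total_time = total_time,
         time_per_converged_start =
           if (sum(flags) > 0) total_time / sum(flags) else Inf,
         consistency_table = data.frame(
           vectorfield_ok = vapply(consist, function(cns)
             isTRUE(cns$vectorfield_ok), logical(1)),
           steadystate_ok = vapply(consist, function(cns)
             isTRUE(cns$steadystate_ok), logical(1))))
  })
  structure(list(methods = per_method, J_best = J_best,
                 n_starts = n_starts, seed = seed, alpha = alpha),
            class = "ssfit_multistart")
}

#' @export
print.ssfit_multistart <- function(x, ...) {
  cat(sprintf("<ssfit_multistart> %d starts, J_best = %.6g\n",
              x$n_starts, x$J_best))
  for (m in names(x$methods)) {
    pm <- x$methods[[m]]
    cat(sprintf("  %-14s converged %5.1f%%  time %7.2fs  per-converged %s\n",
                m, 100 * pm$fraction_converged, pm$total_time,
                if (is.finite(pm$time_per_converged_start))
                  sprintf("%.2fs", pm$time_per_converged_start) else "Inf"))
  }
  invisible(x)
}

#' Summary performance metrics of one method's multi-start runs
#'
#' @param method_result one entry of `ssfit_multistart$methods`.
#' @return list with `fraction_converged`, `total_time`,
#'   `time_per_converged_start` (infinite when no start converged) and
#'   the sorted final objective values `waterfall`.
#' @export
performance_metrics <- function(method_result) {
  list(fraction_converged = method_result$fraction_converged,
       total_time = method_result$total_time,
       time_per_converged_start = method_result$time_per_converged_start,
       waterfall = method_result$J_sorted)
}

#' Compare the Raf/MEK/ERK feedback hypotheses on one dataset
#'
#' Fits both model hypotheses — H1 (negative feedback of pERK on Raf
#' phosphorylation) and H2 (no feedback) — to the same perturbation
#' dataset with the hybrid method from a common Latin hypercube start
#' set, and compares them by BIC and AIC. Because H1 nests H2 (K1 ->
#' infinity), each hypothesis is additionally warm-started from the
#' other's best fit (embedding K1 at its upper bound, or dropping it),
#' the standard safeguard against one member of a nested pair losing
#' the comparison through a local optimum alone.
#'
#' @param dataset an `ssfit_dataset` of the three-condition Raf design.
#' @param n_starts Latin hypercube starts per hypothesis.
#' @param seed seed for the start set.
#' @param eps_tol hybrid retraction accuracy.
#' @param settings optimizer settings for each fit.
#' @param n_blots number of replicate blots in the observation layout.
#' @param n_scan size of the Latin hypercube cloud screened by
#'   objective value before the local fits (a cheap basin pre-scan).
#' @return a list with the per-hypothesis fit table (`J`, `n_params`,
#'   `BIC`, `AIC`) and `delta_bic` = BIC(H2) - BIC(H1) (positive values
#'   favor the feedback hypothesis).
#' @export
select_raf_hypothesis <- function(dataset, n_starts = 3, seed = 1L,
                                  eps_tol = 1e-13,
                                  settings = list(maxit = 400),
                                  n_blots = 1, n_scan = 40) {
  models <- list(H1 = build_raf_mek_erk_model("H1", n_blots = n_blots),
                 H2 = build_raf_mek_erk_model("H2", n_blots = n_blots))
  fit_from <- function(m, th0) {
    optimize_hybrid(m, dataset, th0, eps_tol = eps_tol,
                    settings = settings)
  }
  best <- list()
  for (h in names(models)) {
    m <- models[[h]]
    # pre-scan a larger start cloud by objective value and run the
    # local fits from the most promising points only
    cloud <- sample_starts(m$bounds, n_scan, seed = seed)
    scan_obj <- make_reduced_objective(m, dataset, "retract",
                                       eps_tol = 1e-6)
    Jscan <- vapply(seq_len(n_scan), function(s)
      tryCatch(scan_obj$fn(cloud[s, ]), error = function(e) Inf),
      numeric(1))
    keep <- order(Jscan)[seq_len(n_starts)]
    runs <- lapply(keep, function(s) fit_from(m, cloud[s, ]))
    J <- vapply(runs, function(r) r$J_final, numeric(1))
    best[[h]] <- runs[[which.min(J)]]
  }
  # cross warm starts through the nesting (K1 -> infinity recovers H2):
  # embedding H2's best at the K1 upper bound starts H1 at exactly H2's
  # objective, so J(H1) <= J(H2) holds structurally; a second embed at
  # moderate K1 sits off the flat weak-feedback direction, giving the
  # optimizer a usable gradient into a feedback regime if one fits
  k1_pos <- which(models$H1$theta_names == "K1")
  th_h2 <- best$H2$final$theta
  for (k1_level in c(models$H1$bounds[k1_pos, 2], 0)) {  # log10 scale
    cand <- fit_from(models$H1,
                     append(th_h2, k1_level, after = k1_pos - 1))
    if (cand$J_final < best$H1$J_final) best$H1 <- cand
  }
  cand_h2 <- fit_from(models$H2, best$H1$final$theta[-k1_pos])
  if (cand_h2$J_final < best$H2$J_final) best$H2 <- cand_h2

  n <- n_datapoints(dataset)
  tab <- do.call(rbind, lapply(names(models), function(h) {
    ic <- information_criteria(best[[h]]$J_final,
                               models[[h]]$n_theta, n)
    data.frame(hypothesis = h, J = best[[h]]$J_final,
               n_params = models[[h]]$n_theta,
               BIC = ic[["BIC"]], AIC = ic[["AIC"]])
  }))
  list(table = tab, fits = best,
       delta_bic = tab$BIC[tab$hypothesis == "H2"] -
         tab$BIC[tab$hypothesis == "H1"])
}

#' Information criteria for model comparison
#'
#' BIC = 2 J + n_params log(n_datapoints); AIC = 2 J + 2 n_params, with
#' J the full negative log-likelihood (normalizing constants included
#' when noise parameters are estimated).
#'
#' @param J negative log-likelihood at the optimum.
#' @param n_params number of estimated parameters.
#' @param n_datapoints number of data points.
#' @return named vector with elements `BIC` and `AIC`.
#' @export
information_criteria <- function(J, n_params, n_datapoints) {
  stopifnot(n_datapoints >= 1)
  c(BIC = 2 * J + n_params * log(n_datapoints),
    AIC = 2 * J + 2 * n_params)
}
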