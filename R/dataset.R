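#' Specify a perturbation experiment
#'
#' A perturbation experiment rests at the steady state of the control
#' input `u_control` for t < 0 and is simulated under `u_perturbed` for
#' t >= 0, observed at `time_points`.
#'
#' @param id experiment label.
#' @param u_control input vector of the pre-perturbation (control)
#'   condition.
#' @param u_perturbed input vector applied from t = 0 on.
#' @param time_points strictly increasing nonnegative observation times.
#' @return an `ssfit_experiment`.
#' @export
experiment_spec <- function(id, u_control, u_perturbed, time_points) {
  time_points <- as.numeric(time_points)
  if (any(time_points < 0) || is.unsorted(time_points, strictly = TRUE))
    stop("time_points must be nonnegative and strictly increasing")
  if (length(u_control) != length(u_perturbed))
    stop("u_control and u_perturbed must have the same length")
  structure(list(id = as.character(id),
                 u_control = as.numeric(u_control),
                 u_perturbed = as.numeric(u_perturbed),
                 time_points = time_points),
            class = "ssfit_experiment")
}

#' Assemble a perturbation dataset
#'
#' @param experiments list of [experiment_spec()] objects.
#' @param observations data frame with columns `experiment` (id),
#'   `observable` (integer index), `time`, `value` and `sigma` (noise
#'   standard deviation; `NA` marks sigma as a free parameter of the
#'   model).
#' @return an `ssfit_dataset`.
#' @export
perturbation_dataset <- function(experiments, observations) {
  ids <- vapply(experiments, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate experiment ids")
  names(experiments) <- ids
  obs <- as.data.frame(observations)
  needed <- c("experiment", "observable", "time", "value", "sigma")
  if (!all(needed %in% names(obs)))
    stop("observations must have columns ",
         paste(needed, collapse = ", "))
  obs$experiment <- as.character(obs$experiment)
  if (!all(obs$experiment %in% ids))
    stop("observation references unknown experiment id")
  for (k in seq_len(nrow(obs))) {
    tp <- experiments[[obs$experiment[k]]]$time_points
    if (!any(abs(tp - obs$time[k]) < 1e-12))
      stop(sprintf("observation %d: time %.6g not in experiment '%s'",
                   k, obs$time[k], obs$experiment[k]))
  }
  if (any(!is.na(obs$sigma) & obs$sigma < 0))
    stop("fixed sigma values must be nonnegative")
  if (anyDuplicated(obs[, c("experiment", "observable", "time")]))
    stop("duplicate (experiment, observable, time) records")
  ds <- structure(list(experiments = experiments, observations = obs),
                  class = "ssfit_dataset")
  # objective evaluations index observations per experiment thousands of
  # times; resolve the split and the time indices once
  ds$obs_split <- compute_obs_split(ds)
  ds
}

#' @export
print.ssfit_dataset <- function(x, ...) {
  cat(sprintf("<ssfit_dataset> %d experiment(s), %d observation(s)\n",
              length(x$experiments), nrow(x$observations)))
  for (e in x$experiments)
    cat(sprintf("  %s: u_c=(%s) -> u=(%s), %d time points\n", e$id,
                paste(signif(e$u_control, 4), collapse = ","),
                paste(signif(e$u_perturbed, 4), collapse = ","),
                length(e$time_points)))
  invisible(x)
}

n_datapoints <- function(dataset) nrow(dataset$observations)

# per-experiment observation tables with time indices resolved; plain
# lists of vectors (cheaper to index than data frames in hot loops)
compute_obs_split <- function(dataset) {
  lapply(dataset$experiments, function(e) {
    obs <- dataset$observations[dataset$observations$experiment == e$id, ,
                                drop = FALSE]
    list(observable = obs$observable,
         time = obs$time,
         value = obs$value,
         sigma = obs$sigma,
         time_index = vapply(obs$time, function(t)
           which.min(abs(e$time_points - t)), integer(1)),
         n = nrow(obs))
  })
}

split_observations <- function(dataset) {
  dataset$obs_split %||% compute_obs_split(dataset)
}
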