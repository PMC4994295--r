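#' Write a perturbation dataset to TSV (+ JSON conditions file)
#'
#' The observations go to a tab-separated file with header
#' `experiment observable time value sigma`; the experiment conditions
#' (control and perturbation inputs, time points) go to a JSON companion
#' file, by default `<path>.conditions.json`.
#'
#' @param dataset an `ssfit_dataset`.
#' @param path TSV output path.
#' @param conditions_path JSON companion path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path,
                          conditions_path = paste0(path,
                                                   ".conditions.json")) {
  obs <- dataset$observations[, c("experiment", "observable", "time",
                                  "value", "sigma")]
  utils::write.table(format(obs, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  cond <- lapply(dataset$experiments, function(e)
    list(id = e$id, u_control = e$u_control,
         u_perturbed = e$u_perturbed, time_points = e$time_points))
  jsonlite::write_json(unname(cond), conditions_path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a perturbation dataset from TSV (+ JSON conditions file)
#'
#' Inverse of [write_dataset()]. Malformed rows are reported with their
#' line number; duplicate records and negative sigma are rejected. A
#' missing `sigma` column with `sigma_estimate = TRUE` marks the noise
#' scale as a free parameter.
#'
#' @param path TSV path.
#' @param conditions_path JSON companion path.
#' @param sigma_estimate accept a missing sigma column and mark sigma
#'   free.
#' @return an `ssfit_dataset`.
#' @export
read_dataset <- function(path,
                         conditions_path = paste0(path,
                                                  ".conditions.json"),
                         sigma_estimate = FALSE) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  if (!file.exists(conditions_path))
    stop("conditions file not found: ", conditions_path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  needed <- c("experiment", "observable", "time", "value")
  if (!all(needed %in% names(raw)))
    stop("dataset header must contain ", paste(needed, collapse = ", "))
  if (!"sigma" %in% names(raw)) {
    if (!sigma_estimate)
      stop("dataset has no sigma column ",
           "(pass sigma_estimate = TRUE to treat sigma as a parameter)")
    raw$sigma <- NA_character_
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) &
                   !(raw[[col]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value on line %d: '%s'",
                   col, bad[1] + 1L, raw[[col]][bad[1]]))
    v
  }
  obs <- data.frame(experiment = raw$experiment,
                    observable = as.integer(num("observable")),
                    time = num("time"), value = num("value"),
                    sigma = num("sigma"))
  if (any(!is.na(obs$sigma) & obs$sigma < 0)) {
    bad <- which(!is.na(obs$sigma) & obs$sigma < 0)[1]
    stop(sprintf("negative sigma on line %d", bad + 1L))
  }
  cond <- jsonlite::read_json(conditions_path, simplifyVector = TRUE)
  exps <- lapply(seq_len(nrow(cond)), function(k)
    experiment_spec(cond$id[k], unlist(cond$u_control[k]),
                    unlist(cond$u_perturbed[k]),
                    unlist(cond$time_points[k])))
  perturbation_dataset(exps, obs)
}

#' Serialize an optimizer run (or any result list) to JSON
#'
#' Numbers are written at full precision (17 significant digits) so the
#' record reloads to an equal in-memory structure.
#'
#' @param record a list (e.g. an `ssfit_run` or a summary).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(record, path) {
  rec <- record
  rec$path <- NULL  # flow paths can be large; persist the summary only
  rec <- c(list(tool = "ssfit",
                version = as.character(utils::packageVersion("ssfit")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           unclass(rec))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, na = "string")
  invisible(path)
}

#' @rdname write_run_record
#' @export
read_run_record <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
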