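#' Read a mechanism schedule from YAML or JSON
#'
#' A schedule file is a list of event entries whose keys match the
#' [mechanism_event()] arguments (`kind` is required). Validation errors
#' identify the offending entry.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param label optional label; defaults to the file name.
#' @return an [odna_schedule()].
#' @export
read_schedule <- function(path, label = basename(path)) {
  entries <- read_config_list(path)
  if (!is.list(entries) || length(entries) == 0)
    stop("schedule file must contain a non-empty list of events: ", path)
  allowed <- names(formals(mechanism_event))
  events <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    if (!is.list(e) || is.null(e$kind))
      stop(sprintf("schedule entry %d: missing required key 'kind'", i))
    bad <- setdiff(names(e), allowed)
    if (length(bad))
      stop(sprintf("schedule entry %d: unknown key(s) %s", i,
                   paste(bad, collapse = ", ")))
    tryCatch(do.call(mechanism_event, e), error = function(err)
      stop(sprintf("schedule entry %d: %s", i, conditionMessage(err)),
           call. = FALSE))
  })
  odna_schedule(events, label = label)
}

#' Read simulation parameters from YAML or JSON
#'
#' Keys match the [sim_params()] arguments; missing keys take the default
#' parameterisation.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [sim_params()].
#' @export
read_sim_params <- function(path) {
  entries <- read_config_list(path)
  if (!is.list(entries)) stop("parameter file must contain a mapping: ", path)
  allowed <- names(formals(sim_params))
  bad <- setdiff(names(entries), allowed)
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  do.call(sim_params, entries)
}

read_config_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyVector = TRUE)
  } else {
    stop("unrecognised config extension (expected .yaml/.yml/.json): ", path)
  }
}

#' Write a heteroplasmy dataset (plus ground truth, if any) to disk
#'
#' Writes the standard CSV format; if the dataset carries a generative
#' `truth` attribute (synthetic data), a sidecar JSON file with the ground
#' truth and seed is written next to it.
#'
#' @param data a [heteroplasmy_dataset()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_heteroplasmy <- function(data, path) {
  stopifnot(inherits(data, "heteroplasmy_dataset"))
  raw <- attr(data, "raw_records")
  if (is.null(raw)) raw <- as.data.frame(data)
  write.csv(raw, path, row.names = FALSE, quote = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    side <- sub("\\.csv$", "", path)
    jsonlite::write_json(list(truth = truth, seed = attr(data, "seed")),
                         paste0(side, "_truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
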