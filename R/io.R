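# Plain-text interchange: session count tables as CSV, run configuration
# as YAML or JSON.

#' Read and write session count tables
#'
#' T-maze tables have columns `session_id`, `n_bright`, `n_dark`,
#' `n_elevator`, `n_total`; countercurrent tables have `session_id`,
#' `tube_0 ... tube_k`, `n_total`. Both round-trip losslessly.
#'
#' @param sessions For writing: a list of session objects
#'   (`tmaze_session`/`tmaze_counts` or `cpp_session`/`cpp_counts`).
#' @param path CSV file path.
#' @return Readers return a data frame; writers return `path` invisibly.
#' @export
write_tmaze_csv <- function(sessions, path) {
  if (inherits(sessions, c("tmaze_session", "tmaze_counts")))
    sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    if (inherits(s, "tmaze_session")) s <- as_tmaze_counts(s)
    data.frame(session_id = s$session_id, n_bright = s$n_bright,
               n_dark = s$n_dark, n_elevator = s$n_elevator,
               n_total = s$n_total, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tmaze_csv
#' @export
read_tmaze_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("session_id", "n_bright", "n_dark", "n_elevator", "n_total")
  if (!all(need %in% names(df)))
    stop("T-maze CSV must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname write_tmaze_csv
#' @export
write_cpp_csv <- function(sessions, path) {
  if (inherits(sessions, c("cpp_session", "cpp_counts")))
    sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    if (inherits(s, "cpp_session")) s <- as_cpp_counts(s)
    counts <- as.list(s$counts)
    names(counts) <- paste0("tube_", seq_along(counts) - 1L)
    cbind(data.frame(session_id = s$session_id, stringsAsFactors = FALSE),
          as.data.frame(counts), data.frame(n_total = s$n_total))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tmaze_csv
#' @export
read_cpp_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!any(grepl("^tube_[0-9]+$", names(df))) || !"n_total" %in% names(df))
    stop("countercurrent CSV must have tube_0..tube_k and n_total columns")
  df
}

#' Write fly trait tables
#'
#' @param flies A [sample_flies()] data frame.
#' @param path CSV file path.
#' @export
write_traits_csv <- function(flies, path) {
  utils::write.csv(flies, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' A configuration file (YAML if the yaml package is available and the
#' extension says so, JSON otherwise) resolving a population model, the
#' paradigm parameters, replicate counts and the seed; see
#' [reproduce_analyses()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list. The `model` entry, when present, is converted to
#'   a [population_model()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$model)) cfg$model <- do.call(population_model, cfg$model)
  cfg
}
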