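dyad_schema <- c("child_id", "group_id", "community", "condition", "position",
                 "age_years", "sex", "feature", "y_matches", "n_max")
chain_schema <- c("child_id", "group_id", "community", "condition", "position",
                  "transition_stage", "original_block_id", "feature",
                  "transmitted")

check_schema <- function(df, schema, what) {
  miss <- setdiff(schema, names(df))
  if (length(miss)) {
    stop(what, " is missing columns: ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Read and write the dyad and chain tables
#'
#' Plain UTF-8 CSV with a header; columns are validated against the declared
#' schema on both read and write.
#'
#' @param path file path.
#' @param df table to write.
#' @return The table, invisibly for the writers.
#' @name tables
NULL

#' @rdname tables
#' @export
read_dyad_table <- function(path) {
  check_schema(utils::read.csv(path, stringsAsFactors = FALSE),
               dyad_schema, "dyad table")
}

#' @rdname tables
#' @export
write_dyad_table <- function(df, path) {
  check_schema(df, dyad_schema, "dyad table")
  utils::write.csv(df[, dyad_schema], path, row.names = FALSE)
  invisible(df)
}

#' @rdname tables
#' @export
read_chain_table <- function(path) {
  check_schema(utils::read.csv(path, stringsAsFactors = FALSE),
               chain_schema, "chain table")
}

#' @rdname tables
#' @export
write_chain_table <- function(df, path) {
  check_schema(df, chain_schema, "chain table")
  utils::write.csv(df[, chain_schema], path, row.names = FALSE)
  invisible(df)
}

run_to_list <- function(run) {
  list(builder = attr(run, "builder"),
       blocks = lapply(seq_len(nrow(run)), function(i) {
         list(shape_class = run$shape_class[i], color = run$color[i])
       }))
}

list_to_run <- function(x) {
  marble_run(vapply(x$blocks, `[[`, character(1), "shape_class"),
             vapply(x$blocks, `[[`, character(1), "color"),
             builder = x$builder)
}

#' Write a run archive to JSON
#'
#' The archive stores the experimenter's initial run and, per group, the
#' ordered list of child runs, each as a list of `{shape_class, color}`
#' blocks with its builder id.
#'
#' @param archive named list of groups (each a list of [marble_run()]s).
#' @param initial the initial [marble_run()].
#' @param path output path.
#' @export
write_run_archive <- function(archive, initial, path) {
  payload <- list(
    initial = run_to_list(initial),
    groups = lapply(archive, function(runs) lapply(runs, run_to_list))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a run archive from JSON
#'
#' @param path archive path written by [write_run_archive()].
#' @return A list with elements `initial` and `archive`.
#' @export
read_run_archive <- function(path) {
  payload <- jsonlite::read_json(path)
  list(initial = list_to_run(payload$initial),
       archive = lapply(payload$groups,
                        function(runs) lapply(runs, list_to_run)))
}

#' Serialize the generative parameters to YAML
#' @param params a [true_params()].
#' @param path output path.
#' @export
write_true_params <- function(params, path) {
  x <- unclass(params)
  # named atomic vectors serialize as YAML maps only as lists
  x$baseline <- as.list(x$baseline)
  x$exclusion_rates <- as.list(x$exclusion_rates)
  x$chain_probs <- NULL   # stratum-level overrides do not round-trip
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read generative parameters from YAML
#' @param path YAML file written by [write_true_params()].
#' @return A [true_params()] object.
#' @export
read_true_params <- function(path) {
  x <- yaml::read_yaml(path)
  x$baseline <- unlist(x$baseline)
  x$exclusion_rates <- unlist(x$exclusion_rates)
  do.call(true_params, x[setdiff(names(x), character(0))])
}
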