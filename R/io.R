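## Long-format CSV exchange: columns cell_id, replicate_id, condition,
## channel, time_h, intensity, plus optional event columns mitosis_times,
## sphase_times (semicolon-joined hour lists) and release_time.

TRACK_COLUMNS <- c("cell_id", "replicate_id", "condition", "channel",
                   "time_h", "intensity")
EVENT_COLUMNS <- c("mitosis_times", "sphase_times", "release_time")

fmt_hours <- function(x) {
  if (!length(x) || all(is.na(x))) return("")
  paste(format(x, digits = 15, trim = TRUE, scientific = FALSE),
        collapse = ";")
}

parse_hours <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Convert a cohort to a long-format data frame
#'
#' One row per sample, deterministically ordered by replicate, cell,
#' channel, time; event lists serialized as semicolon-joined hour strings
#' repeated on every row of their trace.
#'
#' @param cohort A [new_cohort()] object.
#' @return A `data.frame` in the exchange schema.
#' @export
cohort_tracks <- function(cohort) {
  if (!length(cohort$traces)) {
    df <- data.frame(cell_id = character(0), replicate_id = character(0),
                     condition = character(0), channel = character(0),
                     time_h = numeric(0), intensity = numeric(0),
                     mitosis_times = character(0), sphase_times = character(0),
                     release_time = numeric(0), stringsAsFactors = FALSE)
    return(df)
  }
  parts <- lapply(cohort$traces, function(tr) {
    n <- length(tr$times)
    data.frame(cell_id = rep(tr$cell_id, n),
               replicate_id = rep(tr$replicate_id, n),
               condition = rep(tr$condition, n),
               channel = rep(tr$channel, n),
               time_h = tr$times, intensity = tr$values,
               mitosis_times = rep(fmt_hours(tr$mitosis_times), n),
               sphase_times = rep(fmt_hours(tr$sphase_times), n),
               release_time = rep(tr$release_time, n),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  ord <- order(df$replicate_id, df$cell_id, df$channel, df$time_h,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a cohort to a long-format CSV file
#'
#' Two writes of the same cohort produce byte-identical files; an empty
#' cohort writes a header-only file.
#'
#' @param cohort A [new_cohort()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(cohort, path) {
  df <- cohort_tracks(cohort)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("I/O error: cannot open ", path))
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "",
                   eol = "\n")
  invisible(path)
}

#' Read a cohort from a long-format CSV file
#'
#' Builds one trace per (cell, channel) pair, with rows sorted by time and
#' event columns parsed into hour lists. Raises a schema error when a
#' mandatory column is missing, a duplication error on repeated
#' (cell, channel, time) rows and a sampling error when the time step is
#' non-uniform beyond the 1e-9 h tolerance.
#'
#' @param path CSV file path.
#' @return A [new_cohort()] object.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character",
                                       replicate_id = "character"))
  missing <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing))
    stop("schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (ev in c("mitosis_times", "sphase_times"))
    if (is.null(df[[ev]])) df[[ev]] <- "" else
      df[[ev]] <- as.character(df[[ev]])
  if (is.null(df$release_time)) df$release_time <- NA_real_
  key <- interaction(df$replicate_id, df$cell_id, df$channel, drop = TRUE)
  traces <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    if (anyDuplicated(g$time_h))
      stop(sprintf("duplication error: repeated (cell, channel, time) in %s/%s",
                   g$cell_id[1], g$channel[1]))
    new_trace(cell_id = g$cell_id[1], replicate_id = g$replicate_id[1],
              condition = g$condition[1], channel = g$channel[1],
              times = g$time_h, values = g$intensity,
              mitosis_times = parse_hours(g$mitosis_times[1]),
              sphase_times = parse_hours(g$sphase_times[1]),
              release_time = g$release_time[1])
  })
  names(traces) <- NULL
  ord <- order(vapply(traces, function(tr) tr$replicate_id, character(1)),
               vapply(traces, function(tr) tr$cell_id, character(1)),
               vapply(traces, function(tr) tr$channel, character(1)),
               method = "radix")
  new_cohort(traces[ord])
}

#' Read an analysis configuration from JSON
#'
#' The JSON document mirrors [analysis_config()]; unknown keys are
#' rejected with a schema error naming the offending key.
#'
#' @param path JSON file path.
#' @return A validated `hes_config` object.
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("schema error: unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to JSON
#'
#' @param config An `hes_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
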