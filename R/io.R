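# On-disk formats: task JSON, raw-event TSV, summary text, batch tables.
# All writers use fixed 6-significant-digit float formatting and UTF-8 so
# output is deterministic byte-for-byte.

#' Read / write a task specification
#'
#' The canonical on-disk task format is JSON with fields `name`, `width`,
#' `height`, optional `background_image`, and `stimuli`, an array of objects
#' `{id, x, y, role, subtype?}`. Round-trips losslessly.
#'
#' @param path File path.
#' @return `read_task()` returns a [task_spec]; `write_task()` returns the
#'   path invisibly.
#' @export
read_task <- function(path) {
  if (!file.exists(path)) stop("task file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("task file '", path,
                                           "' is not valid JSON: ",
                                           conditionMessage(e)))
  for (field in c("width", "height", "stimuli")) {
    if (is.null(obj[[field]])) {
      stop("task file '", path, "' lacks required field '", field, "'")
    }
  }
  stim <- as.data.frame(obj$stimuli, stringsAsFactors = FALSE)
  task_spec(obj$width, obj$height, stim,
            name = if (is.null(obj$name)) tools::file_path_sans_ext(basename(path))
                   else obj$name,
            background_image = obj$background_image)
}

#' @param task A [task_spec].
#' @rdname read_task
#' @export
write_task <- function(task, path) {
  stopifnot(inherits(task, "task_spec"))
  obj <- list(name = task$name, width = task$width, height = task$height,
              stimuli = task$stimuli)
  if (!is.null(task$background_image)) {
    obj$background_image <- task$background_image
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(6),
                       pretty = TRUE)
  invisible(path)
}

#' Read / write a raw event log
#'
#' Event logs are TSV with the header `index	t_ms	x	y`, one row per
#' pointer-down event with milliseconds since task onset and pixel
#' coordinates — the raw click (or touch) times and coordinates of a
#' session, and the simulator's output format.
#'
#' @param path File path.
#' @return `read_events()` returns the validated event data frame;
#'   `write_events()` returns the path invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  req <- c("index", "t_ms", "x", "y")
  if (!identical(names(df)[seq_along(req)], req)) {
    stop("event file '", path, "' must start with header: ",
         paste(req, collapse = "\t"))
  }
  for (cc in req) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !df[[cc]] %in% c("NA", ""))
    if (length(bad) > 0) {
      stop("non-numeric value in '", path, "' at row ", bad[1],
           ", column '", cc, "'")
    }
    df[[cc]] <- v
  }
  validate_events(df[, req])
}

#' @param events Event data frame (`index`, `t_ms`, `x`, `y`).
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("index\tt_ms\tx\ty", con)
  if (nrow(events) > 0) {
    writeLines(paste(fmt_num(events$index), fmt_num(events$t_ms),
                     fmt_num(events$x), fmt_num(events$y), sep = "\t"), con)
  }
  invisible(path)
}

#' Write a session summary text file
#'
#' A simple tab-separated key/value text file, one measure per row with a
#' stable key order, openable in spreadsheet and statistics software.
#' Missing measures are rendered as `NA` with the reason in a third column.
#'
#' @param report A [measure_report][analyze].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_summary <- function(report, path) {
  stopifnot(inherits(report, "measure_report"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("measure\tvalue\tnote", con)
  for (k in report_keys()) {
    v <- report[[k]]
    reason <- missing_reason(v)
    val <- if (is.numeric(v)) fmt_num(as.numeric(v)) else as.character(v)
    if (is.na(val)) val <- "NA"
    writeLines(paste(k, val,
                     if (!is.null(reason)) reason else "", sep = "\t"), con)
  }
  invisible(path)
}

#' Batch-analyze a set of sessions
#'
#' Analyzes every event log matching a glob against a task (a single task
#' JSON applied to all sessions, or a directory holding one `<stem>.json`
#' per `<stem>.tsv`) and writes one wide TSV row per session, columns equal
#' to the single-session summary keys. Corrupt sessions are logged and
#' skipped; the run continues.
#'
#' @param task_path Task JSON file, or a directory of per-session task files.
#' @param events_glob Glob for event TSV files, e.g. `"data/*.tsv"`.
#' @param out_table Output TSV path.
#' @param time_limit_s Optional time limit applied to every session.
#' @return Invisibly, a list with the result data frame (`table`) and a
#'   character vector of per-file failure messages (`failures`).
#' @export
batch_analyze <- function(task_path, events_glob, out_table,
                          time_limit_s = NULL) {
  files <- sort(Sys.glob(events_glob))
  if (length(files) == 0) stop("no event files match: ", events_glob)
  single_task <- !dir.exists(task_path)
  if (single_task) shared_task <- read_task(task_path)
  rows <- list()
  failures <- character(0)
  for (f in files) {
    res <- tryCatch({
      task <- if (single_task) shared_task else {
        stem <- tools::file_path_sans_ext(basename(f))
        read_task(file.path(task_path, paste0(stem, ".json")))
      }
      events <- read_events(f)
      report <- analyze(task, assign_events(task, events,
                                            time_limit_s = time_limit_s))
      df <- as.data.frame(report)
      df <- cbind(session = tools::file_path_sans_ext(basename(f)), df)
      df
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    paste0(f, ": ", conditionMessage(res)))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(failures) > 0) {
    message("batch_analyze: ", length(failures), " session(s) failed:\n  ",
            paste(failures, collapse = "\n  "))
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(session = character())
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(out[num], fmt_num)
  write.table(out, out_table, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(list(table = tab, failures = failures))
}
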