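# Domain types shared by every module. Everything is a light S3 object over
# base data frames so that results drop straight into spreadsheets and stats
# packages.

#' Construct a cancellation task specification
#'
#' A `task_spec` describes the search array: canvas size in pixels (origin at
#' the top-left, y increasing downward, matching screen/event coordinates) and
#' the stimuli with their roles. At least one target is required, and when two
#' or more targets exist their leftmost and rightmost x must differ so the
#' center of cancellation can be standardized.
#'
#' @param width,height Canvas size in pixels.
#' @param stimuli Data frame with columns `id` (unique integers), `x`, `y`
#'   (pixel centers within the canvas), `role` (`"target"` or `"distractor"`)
#'   and optionally `subtype` (free-form label such as the gap orientation of
#'   a Landolt C).
#' @param name Task name used in reports and file names.
#' @param background_image Optional path to a background image (scanned task).
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(width, height, stimuli, name = "task",
                      background_image = NULL) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  stimuli <- as.data.frame(stimuli, stringsAsFactors = FALSE)
  req <- c("id", "x", "y", "role")
  missing_cols <- setdiff(req, names(stimuli))
  if (length(missing_cols) > 0) {
    stop("task stimuli lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"subtype" %in% names(stimuli)) stimuli$subtype <- NA_character_
  stimuli <- stimuli[, c("id", "x", "y", "role", "subtype")]
  stimuli$id <- as.integer(stimuli$id)
  if (anyDuplicated(stimuli$id)) {
    stop("duplicate stimulus id(s): ",
         paste(unique(stimuli$id[duplicated(stimuli$id)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(stimuli$role), c("target", "distractor"))
  if (length(bad_role) > 0) {
    offenders <- stimuli$id[stimuli$role %in% bad_role]
    stop("unknown role for stimulus id(s) ",
         paste(offenders, collapse = ", "), ": ",
         paste(bad_role, collapse = ", "))
  }
  out_of_bounds <- which(stimuli$x < 0 | stimuli$x > width |
                         stimuli$y < 0 | stimuli$y > height)
  if (length(out_of_bounds) > 0) {
    stop("stimulus outside canvas at row ", out_of_bounds[1],
         " (id ", stimuli$id[out_of_bounds[1]], ")")
  }
  tx <- stimuli$x[stimuli$role == "target"]
  if (length(tx) < 1) stop("task must contain at least one target")
  if (length(tx) >= 2 && max(tx) == min(tx)) {
    stop("leftmost and rightmost target x coincide; ",
         "horizontal standardization is impossible")
  }
  structure(
    list(name = name, width = as.numeric(width), height = as.numeric(height),
         stimuli = stimuli, background_image = background_image),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  n_t <- sum(x$stimuli$role == "target")
  n_d <- sum(x$stimuli$role == "distractor")
  cat(sprintf("<task_spec> '%s': %g x %g px, %d targets, %d distractors%s\n",
              x$name, x$width, x$height, n_t, n_d,
              if (is.null(x$background_image)) "" else
                sprintf(", background '%s'", x$background_image)))
  invisible(x)
}

#' Targets of a task
#' @param task A [task_spec].
#' @return Data frame of the target stimuli.
#' @export
task_targets <- function(task) {
  stopifnot(inherits(task, "task_spec"))
  task$stimuli[task$stimuli$role == "target", , drop = FALSE]
}

# Validate a raw event log: one row per pointer-down event, ordered in time.
# Returns the log with canonical column order and types.
validate_events <- function(events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req <- c("index", "t_ms", "x", "y")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    stop("event log lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  events <- events[, req]
  if (nrow(events) == 0) return(events)
  for (cc in req) {
    if (!is.numeric(events[[cc]])) {
      stop("non-numeric value in event column '", cc, "'")
    }
  }
  if (any(events$t_ms < 0)) {
    stop("negative timestamp at row ", which(events$t_ms < 0)[1])
  }
  dec <- which(diff(events$t_ms) < 0)
  if (length(dec) > 0) {
    stop("decreasing timestamp at row ", dec[1] + 1L)
  }
  events
}

#' Construct a cancellation sequence
#'
#' The object all measures consume: the task, the ordered cancellations with
#' revisit annotations, the events that hit no target, and the session
#' duration. Usually produced by [assign_events()] rather than directly.
#'
#' @param task A [task_spec].
#' @param cancellations Data frame with columns `index`, `t_ms`, `x`, `y`
#'   (the raw event), `stimulus_id` (the cancelled target), `target_x`,
#'   `target_y` (its center), `revisit_kind` (`"none"`, `"immediate"`,
#'   `"delayed"`), `intervening_count`.
#' @param unassigned Data frame of raw events that hit no target (misses and,
#'   when excluded, distractor false alarms; column `hit_role` says which).
#' @param total_duration_s Session duration in seconds (time of the last
#'   event, or the configured time limit).
#' @return An object of class `cancellation_sequence`.
#' @export
cancellation_sequence <- function(task, cancellations, unassigned = NULL,
                                  total_duration_s = 0) {
  stopifnot(inherits(task, "task_spec"))
  cancellations <- as.data.frame(cancellations, stringsAsFactors = FALSE)
  if (nrow(cancellations) > 0) {
    target_ids <- task_targets(task)$id
    bad <- setdiff(cancellations$stimulus_id, target_ids)
    if (length(bad) > 0) {
      stop("cancellation refers to non-target stimulus id(s): ",
           paste(bad, collapse = ", "))
    }
    if (is.unsorted(cancellations$t_ms)) {
      stop("cancellations must preserve event order")
    }
  }
  if (is.null(unassigned)) {
    unassigned <- data.frame(index = integer(), t_ms = numeric(),
                             x = numeric(), y = numeric(),
                             hit_role = character())
  }
  structure(
    list(task = task, cancellations = cancellations,
         unassigned = as.data.frame(unassigned),
         total_duration_s = as.numeric(total_duration_s)),
    class = "cancellation_sequence"
  )
}

#' @export
print.cancellation_sequence <- function(x, ...) {
  n <- nrow(x$cancellations)
  cat(sprintf(
    "<cancellation_sequence> task '%s': %d cancellations (%d revisits), %d unassigned events, %.1f s\n",
    x$task$name, n,
    if (n) sum(x$cancellations$revisit_kind != "none") else 0L,
    nrow(x$unassigned), x$total_duration_s))
  invisible(x)
}

# Mean distance from each stimulus (or each target) to its nearest neighbor.
# The scale unit for the standardized inter-cancellation distance and the
# default hit radius / heatmap kernel width.
mean_nn_distance <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2) return(NA_real_)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards. Keeps every generator deterministic per seed
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Fixed float formatting (6 significant digits) so every writer is
# deterministic byte-for-byte.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15,
                formatC(x, format = "d"),
                formatC(x, digits = 6, format = "g")))
}
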