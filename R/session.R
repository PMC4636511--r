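# Resolve raw pointer events against a task: hit-testing and revisit
# classification.

#' Default hit radius for a task
#'
#' Half the mean nearest-neighbor distance between stimuli, so the radius
#' adapts to stimulus density and neighboring stimuli cannot both claim a
#' click halfway between them.
#'
#' @param task A [task_spec].
#' @return Radius in pixels.
#' @export
default_hit_radius <- function(task) {
  d <- mean_nn_distance(task$stimuli[, c("x", "y")])
  if (is.na(d)) return(min(task$width, task$height) / 10)
  d / 2
}

#' Resolve raw events into a cancellation sequence
#'
#' Each event is assigned to the nearest stimulus within `hit_radius`
#' (exact distance ties go to the lower stimulus id). Events on targets
#' become cancellations, in event order, with revisits classified; events on
#' distractors are false alarms and events on no stimulus are misses — both
#' kept in `unassigned` and excluded from every measure, since the
#' cancellation path is determined by cancelled targets only.
#'
#' @param task A [task_spec].
#' @param events Raw event log: data frame with columns `index`, `t_ms`,
#'   `x`, `y`, time-ordered.
#' @param hit_radius Hit radius in pixels; default [default_hit_radius()].
#' @param time_limit_s Optional time limit in seconds; events after it are
#'   dropped and the session duration set to the limit.
#' @return A [cancellation_sequence].
#' @export
assign_events <- function(task, events, hit_radius = NULL,
                          time_limit_s = NULL) {
  stopifnot(inherits(task, "task_spec"))
  events <- validate_events(events)
  if (is.null(hit_radius)) hit_radius <- default_hit_radius(task)
  stopifnot(hit_radius > 0)
  if (!is.null(time_limit_s)) {
    events <- events[events$t_ms <= time_limit_s * 1000, , drop = FALSE]
  }
  empty_canc <- data.frame(index = integer(), t_ms = numeric(),
                           x = numeric(), y = numeric(),
                           stimulus_id = integer(),
                           target_x = numeric(), target_y = numeric(),
                           revisit_kind = character(),
                           intervening_count = integer())
  if (nrow(events) == 0) {
    return(cancellation_sequence(task, empty_canc,
                                 total_duration_s =
                                   if (is.null(time_limit_s)) 0
                                   else time_limit_s))
  }
  stim <- task$stimuli
  # nearest stimulus per event; ties resolved toward the lower id
  stim <- stim[order(stim$id), ]
  hit_id <- vapply(seq_len(nrow(events)), function(i) {
    d2 <- (stim$x - events$x[i])^2 + (stim$y - events$y[i])^2
    j <- which.min(d2)  # which.min takes the first minimum -> lowest id
    if (sqrt(d2[j]) <= hit_radius) stim$id[j] else NA_integer_
  }, integer(1))
  hit_role <- stim$role[match(hit_id, stim$id)]
  is_canc <- !is.na(hit_id) & hit_role == "target"
  canc <- events[is_canc, , drop = FALSE]
  if (nrow(canc) > 0) {
    canc$stimulus_id <- hit_id[is_canc]
    m <- match(canc$stimulus_id, stim$id)
    canc$target_x <- stim$x[m]
    canc$target_y <- stim$y[m]
  } else {
    canc <- empty_canc
  }
  unass <- events[!is_canc, , drop = FALSE]
  unass$hit_role <- ifelse(is.na(hit_id[!is_canc]), "none", "distractor")
  duration <- if (!is.null(time_limit_s)) time_limit_s else
    max(events$t_ms) / 1000
  seq <- cancellation_sequence(task, canc, unass, duration)
  classify_revisits(seq)
}

#' Classify revisits in a cancellation sequence
#'
#' First touch of a target is `"none"`; cancelling the same target as the
#' immediately preceding cancellation is an `"immediate"` revisit; returning
#' to a previously cancelled target after cancelling others is a `"delayed"`
#' revisit. `intervening_count` records how many cancellations occurred since
#' the previous cancellation of the same target (0 for immediate revisits),
#' supporting the intervening-targets statistic used in spatial working
#' memory accounts of revisiting.
#'
#' @param seq A [cancellation_sequence].
#' @return The sequence with `revisit_kind` and `intervening_count` filled.
#' @export
classify_revisits <- function(seq) {
  stopifnot(inherits(seq, "cancellation_sequence"))
  cc <- seq$cancellations
  n <- nrow(cc)
  kind <- character(n)
  interv <- integer(n)
  if (n > 0) {
    for (i in seq_len(n)) {
      prev <- which(cc$stimulus_id[seq_len(i - 1)] == cc$stimulus_id[i])
      if (length(prev) == 0) {
        kind[i] <- "none"
        interv[i] <- 0L
      } else {
        last_prev <- max(prev)
        interv[i] <- i - last_prev - 1L
        kind[i] <- if (last_prev == i - 1L) "immediate" else "delayed"
      }
    }
  }
  cc$revisit_kind <- kind
  cc$intervening_count <- interv
  seq$cancellations <- cc
  seq
}
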