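# The quantitative measure roster: spatial bias (omissions, center of
# cancellation, first marking), search organization (standardized
# inter-cancellation distance, intersections, best R, standardized angle),
# and general performance (timing, search speed, Q score).
#
# Measures that are undefined for a given session (too few cancellations,
# degenerate geometry) return an explicit missing value carrying a reason,
# never a silent zero.

na_value <- function(reason) structure(NA_real_, reason = reason)

#' Reason a measure is missing
#' @param x A measure value.
#' @return The reason string, or `NULL` when the value is present.
#' @export
missing_reason <- function(x) attr(x, "reason", exact = TRUE)

# Cancellations that define the search path: immediate revisits collapse
# onto the previous point and are excluded everywhere path geometry is used.
path_cancellations <- function(seq) {
  cc <- seq$cancellations
  cc[cc$revisit_kind != "immediate", , drop = FALSE]
}

#' Omission counts
#'
#' Targets never cancelled, in total and per half of the search array. The
#' halves are split at the vertical midline halfway between the leftmost and
#' rightmost target centers; a target exactly on the midline counts left.
#'
#' @param task A [task_spec].
#' @param seq A [cancellation_sequence].
#' @return Named list `total`, `left`, `right`.
#' @export
omission_counts <- function(task, seq) {
  tg <- task_targets(task)
  omitted <- tg[!tg$id %in% seq$cancellations$stimulus_id, , drop = FALSE]
  midline <- (min(tg$x) + max(tg$x)) / 2
  left <- sum(omitted$x <= midline)
  list(total = nrow(omitted), left = left, right = nrow(omitted) - left)
}

#' Revisit counts
#' @param seq A [cancellation_sequence] with revisits classified.
#' @return Named list `total`, `immediate`, `delayed`.
#' @export
revisit_counts <- function(seq) {
  k <- seq$cancellations$revisit_kind
  list(total = sum(k != "none"),
       immediate = sum(k == "immediate"),
       delayed = sum(k == "delayed"))
}

#' Center of cancellation
#'
#' The mean position of the cancelled targets along one axis, standardized
#' so that -1 is the leftmost and +1 the rightmost target (vertically: -1
#' topmost, +1 bottommost). Captures the attentional gradient of neglect:
#' strongly positive horizontal values indicate leftward neglect.
#'
#' By default the mean runs over all non-immediate-revisit cancellations
#' (delayed revisits are genuine cancellations on the path);
#' `unique_targets = TRUE` averages each cancelled target once instead.
#'
#' @param task A [task_spec].
#' @param seq A [cancellation_sequence].
#' @param axis `"horizontal"` or `"vertical"`.
#' @param unique_targets Average over unique cancelled targets instead of
#'   cancellations.
#' @return Dimensionless value in `[-1, 1]`, or a missing value.
#' @export
center_of_cancellation <- function(task, seq,
                                   axis = c("horizontal", "vertical"),
                                   unique_targets = FALSE) {
  axis <- match.arg(axis)
  tg <- task_targets(task)
  coord <- if (axis == "horizontal") tg$x else tg$y
  lo <- min(coord); hi <- max(coord)
  if (hi == lo) {
    return(na_value(paste0("all targets share one ", axis, " coordinate")))
  }
  cc <- path_cancellations(seq)
  if (nrow(cc) == 0) return(na_value("no cancellations"))
  pos <- if (axis == "horizontal") cc$target_x else cc$target_y
  if (unique_targets) pos <- pos[!duplicated(cc$stimulus_id)]
  mean(2 * (pos - lo) / (hi - lo) - 1)
}

#' Build the inter-cancellation path segments
#'
#' One segment per consecutive pair of non-immediate-revisit cancellations.
#' Each carries the Euclidean length `s` (pixels), elapsed time `t`
#' (seconds), vertical displacement magnitude `delta_y` (pixels) and the
#' inter-cancellation angle `gamma = arcsin(delta_y / s)` in degrees, in
#' `[0, 90]`. Zero-length segments are never materialized.
#'
#' @param seq A [cancellation_sequence].
#' @return Data frame with columns `x0`, `y0`, `x1`, `y1`, `s`, `t`,
#'   `delta_y`, `gamma`.
#' @export
path_segments <- function(seq) {
  cc <- path_cancellations(seq)
  empty <- data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), s = numeric(), t = numeric(),
                      delta_y = numeric(), gamma = numeric())
  if (nrow(cc) < 2) return(empty)
  i <- seq_len(nrow(cc) - 1)
  seg <- data.frame(
    x0 = cc$target_x[i], y0 = cc$target_y[i],
    x1 = cc$target_x[i + 1], y1 = cc$target_y[i + 1],
    t = (cc$t_ms[i + 1] - cc$t_ms[i]) / 1000)
  seg$s <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2)
  seg <- seg[seg$s > 0, , drop = FALSE]
  if (nrow(seg) == 0) return(empty)
  seg$delta_y <- abs(seg$y1 - seg$y0)
  seg$gamma <- asin(pmin(1, seg$delta_y / seg$s)) * 180 / pi
  rownames(seg) <- NULL
  seg[, c("x0", "y0", "x1", "y1", "s", "t", "delta_y", "gamma")]
}

#' Mean inter-cancellation distance
#' @param segments Segments from [path_segments()].
#' @return Mean segment length in pixels, or a missing value.
#' @export
mean_icd <- function(segments) {
  if (nrow(segments) == 0) return(na_value("fewer than 2 cancellations"))
  mean(segments$s)
}

#' Standardized inter-cancellation distance
#'
#' The mean inter-cancellation distance divided by the mean distance between
#' each target and its nearest neighboring target. Dividing by the task's
#' own spatial scale makes the measure comparable across tasks with
#' different inter-target spacing; low values reflect organized search that
#' steps between nearby targets.
#'
#' @param task A [task_spec].
#' @param segments Segments from [path_segments()].
#' @return Dimensionless ratio, or a missing value.
#' @export
standardized_icd <- function(task, segments) {
  tg <- task_targets(task)
  if (nrow(tg) < 2) return(na_value("fewer than 2 targets"))
  m <- mean_icd(segments)
  if (is.na(m)) return(m)
  m / mean_nn_distance(tg[, c("x", "y")])
}

#' Session timing
#' @param seq A [cancellation_sequence].
#' @param segments Segments from [path_segments()].
#' @return Named list `duration_s` (total time on task) and `mean_ict_s`
#'   (mean inter-cancellation time, the latency index).
#' @export
timing <- function(seq, segments) {
  list(duration_s = seq$total_duration_s,
       mean_ict_s = if (nrow(segments) == 0)
         na_value("fewer than 2 cancellations") else mean(segments$t))
}

#' Search speed
#'
#' The mean over consecutive cancellation pairs of distance over time,
#' `mean(s_i / t_i)`, in pixels per second.
#'
#' @param segments Segments from [path_segments()].
#' @return Pixels per second, or a missing value; simultaneous cancellations
#'   (a zero inter-cancellation time) are an error.
#' @export
search_speed <- function(segments) {
  if (nrow(segments) == 0) return(na_value("fewer than 2 cancellations"))
  if (any(segments$t <= 0)) {
    stop("simultaneous cancellations: inter-cancellation time of 0")
  }
  mean(segments$s / segments$t)
}

#' Q score
#'
#' Combined speed-accuracy index: the squared number of cancelled targets
#' divided by the product of the total number of targets and the time on
#' task, `Q = N_cor^2 / (N_tar * t_tot)`.
#'
#' @param n_cancelled_targets Uniquely cancelled targets (correct responses).
#' @param n_targets Total targets in the task.
#' @param duration_s Total time spent on the task, seconds.
#' @return Dimensionless Q score.
#' @export
q_score <- function(n_cancelled_targets, n_targets, duration_s) {
  stopifnot(n_targets >= 1)
  if (duration_s <= 0) stop("task duration must be positive")
  n_cancelled_targets^2 / (n_targets * duration_s)
}

#' Cancellation path self-intersections
#'
#' Counts unordered pairs of path segments whose interiors properly cross at
#' a single point. The crossing point is found from the segment pair's
#' determinant system (a nonzero denominator, with the point strictly
#' interior to both segments); shared endpoints of consecutive segments and
#' parallel or collinear overlaps contribute nothing. The intersection rate
#' divides the count by the number of cancellations that are not immediate
#' revisits.
#'
#' @param segments Segments from [path_segments()].
#' @param n_path_cancellations Number of non-immediate-revisit
#'   cancellations (the rate denominator); defaults to
#'   `nrow(segments) + 1` when segments exist.
#' @return List with `count`, `points` (data frame of crossing coordinates
#'   `x`, `y`) and `rate`.
#' @export
path_intersections <- function(segments,
                               n_path_cancellations = NULL) {
  n_seg <- nrow(segments)
  if (is.null(n_path_cancellations)) {
    n_path_cancellations <- if (n_seg > 0) n_seg + 1L else 0L
  }
  pts_x <- numeric(0)
  pts_y <- numeric(0)
  if (n_seg >= 2) {
    x0 <- segments$x0; y0 <- segments$y0
    rx <- segments$x1 - x0; ry <- segments$y1 - y0
    pair <- which(upper.tri(matrix(0, n_seg, n_seg)), arr.ind = TRUE)
    i <- pair[, 1]; j <- pair[, 2]
    denom <- rx[i] * ry[j] - ry[i] * rx[j]
    scale2 <- pmax(abs(rx[i]), abs(ry[i])) * pmax(abs(rx[j]), abs(ry[j]))
    qx <- x0[j] - x0[i]; qy <- y0[j] - y0[i]
    tt <- (qx * ry[j] - qy * rx[j]) / denom
    uu <- (qx * ry[i] - qy * rx[i]) / denom
    tol <- 1e-9
    # parallel/collinear pairs (denominator ~ 0) have no single crossing
    hit <- abs(denom) > 1e-12 * scale2 &
      tt > tol & tt < 1 - tol & uu > tol & uu < 1 - tol
    hit[is.na(hit)] <- FALSE
    pts_x <- (x0[i] + tt * rx[i])[hit]
    pts_y <- (y0[i] + tt * ry[i])[hit]
  }
  count <- length(pts_x)
  rate <- if (n_path_cancellations > 0) count / n_path_cancellations
          else na_value("no cancellations")
  list(count = count,
       points = data.frame(x = pts_x, y = pts_y),
       rate = rate)
}

#' Best R
#'
#' The search-organization index of Mark and colleagues: the highest
#' absolute Pearson correlation between cancellation rank number and either
#' the horizontal or the vertical cancellation position. An organized sweep
#' in one general direction yields a best R near 1; unsystematic search
#' yields low values. Computed over non-immediate-revisit cancellations.
#'
#' @param seq A [cancellation_sequence].
#' @return Named list `r_best`, `r_hor`, `r_ver` (missing values when fewer
#'   than 3 usable cancellations or no positional variance on either axis).
#' @export
best_r <- function(seq) {
  cc <- path_cancellations(seq)
  if (nrow(cc) < 3) {
    na <- na_value("fewer than 3 cancellations")
    return(list(r_best = na, r_hor = na, r_ver = na))
  }
  rank <- seq_len(nrow(cc))
  r_hor <- if (stats::sd(cc$target_x) == 0) NA_real_
           else cor(rank, cc$target_x)
  r_ver <- if (stats::sd(cc$target_y) == 0) NA_real_
           else cor(rank, cc$target_y)
  if (is.na(r_hor) && is.na(r_ver)) {
    na <- na_value("no positional variance on either axis")
    return(list(r_best = na, r_hor = na, r_ver = na))
  }
  list(r_best = max(abs(r_hor), abs(r_ver), na.rm = TRUE),
       r_hor = r_hor, r_ver = r_ver)
}

#' Standardized inter-cancellation angle
#'
#' Per segment the angle gamma = arcsin(|delta_y| / d), in degrees in
#' `[0, 90]`; the standardized angle is the mean of `|2 * gamma / 90 - 1|`.
#' Horizontal (0 degrees) and vertical (90 degrees) steps both score 1,
#' diagonal 45-degree steps score 0, so a high value indicates the
#' axis-aligned movement characteristic of organized search — including
#' organized paths (e.g. inward spirals) that best R underrates.
#'
#' @param segments Segments from [path_segments()].
#' @return Named list `mean_angle_deg` and `standardized` in `[0, 1]`.
#' @export
standardized_angle <- function(segments) {
  if (nrow(segments) == 0) {
    na <- na_value("fewer than 2 cancellations")
    return(list(mean_angle_deg = na, standardized = na))
  }
  list(mean_angle_deg = mean(segments$gamma),
       standardized = mean(abs(2 * segments$gamma / 90 - 1)))
}

#' First marking
#'
#' The first cancelled target's position in standardized search-array space:
#' the bounding box of the targets is mapped to the unit square with (0,0)
#' the top left and (1,1) the bottom right, making starting positions
#' comparable across task types and sizes. Organized adult search typically
#' starts top-left.
#'
#' @param task A [task_spec].
#' @param seq A [cancellation_sequence].
#' @return Named list `x_std`, `y_std` in `[0, 1]` and `quadrant`
#'   (`"top-left"`, `"top-right"`, `"bottom-left"`, `"bottom-right"`).
#' @export
first_marking <- function(task, seq) {
  cc <- seq$cancellations
  if (nrow(cc) == 0) {
    na <- na_value("no cancellations")
    return(list(x_std = na, y_std = na, quadrant = NA_character_))
  }
  tg <- task_targets(task)
  xr <- range(tg$x); yr <- range(tg$y)
  x_std <- if (diff(xr) > 0) (cc$target_x[1] - xr[1]) / diff(xr) else 0.5
  y_std <- if (diff(yr) > 0) (cc$target_y[1] - yr[1]) / diff(yr) else 0.5
  quadrant <- paste0(if (y_std <= 0.5) "top" else "bottom", "-",
                     if (x_std <= 0.5) "left" else "right")
  list(x_std = x_std, y_std = y_std, quadrant = quadrant)
}

#' Analyze a session: the full measure report
#'
#' Computes every supported measure from a cancellation sequence and returns
#' them in one flat record. Degenerate inputs never error: measures that are
#' undefined for the session are reported as missing values with reasons.
#'
#' @param task A [task_spec].
#' @param seq A [cancellation_sequence].
#' @param coc_unique_targets Passed to [center_of_cancellation()].
#' @return An object of class `measure_report`: a named list of measure
#'   values (see [write_summary()] for the full key roster).
#' @export
#' @examples
#' task <- generate_landolt_task(seed = 1)
#' log <- simulate_session(task, simulation_config(seed = 1))
#' analyze(task, assign_events(task, log))
analyze <- function(task, seq, coc_unique_targets = FALSE) {
  stopifnot(inherits(task, "task_spec"), inherits(seq, "cancellation_sequence"))
  tg <- task_targets(task)
  cc <- seq$cancellations
  segments <- path_segments(seq)
  om <- omission_counts(task, seq)
  rv <- revisit_counts(seq)
  tm <- timing(seq, segments)
  ints <- path_intersections(segments,
                             n_path_cancellations = nrow(path_cancellations(seq)))
  br <- best_r(seq)
  ang <- standardized_angle(segments)
  fm <- first_marking(task, seq)
  n_cor <- length(unique(cc$stimulus_id))
  speed <- tryCatch(search_speed(segments),
                    error = function(e) na_value(conditionMessage(e)))
  report <- list(
    task_name = task$name,
    n_targets = nrow(tg),
    n_cancellations = nrow(cc),
    n_cancelled_targets = n_cor,
    false_alarms = sum(seq$unassigned$hit_role == "distractor"),
    omissions_total = om$total,
    omissions_left = om$left,
    omissions_right = om$right,
    revisits_total = rv$total,
    revisits_immediate = rv$immediate,
    revisits_delayed = rv$delayed,
    coc_horizontal = center_of_cancellation(task, seq, "horizontal",
                                            coc_unique_targets),
    coc_vertical = center_of_cancellation(task, seq, "vertical",
                                          coc_unique_targets),
    duration_s = tm$duration_s,
    mean_ict_s = tm$mean_ict_s,
    q_score = if (seq$total_duration_s > 0)
      q_score(n_cor, nrow(tg), seq$total_duration_s)
      else na_value("zero task duration"),
    mean_icd_px = mean_icd(segments),
    standardized_icd = standardized_icd(task, segments),
    search_speed = speed,
    cancellation_rate = if (seq$total_duration_s > 0)
      nrow(cc) / seq$total_duration_s else na_value("zero task duration"),
    mean_angle_deg = ang$mean_angle_deg,
    standardized_angle = ang$standardized,
    best_r = br$r_best,
    best_r_horizontal = br$r_hor,
    best_r_vertical = br$r_ver,
    intersections_count = ints$count,
    intersections_rate = ints$rate,
    first_x_std = fm$x_std,
    first_y_std = fm$y_std,
    first_quadrant = fm$quadrant
  )
  attr(report, "intersection_points") <- ints$points
  class(report) <- "measure_report"
  report
}

#' @export
print.measure_report <- function(x, ...) {
  cat("<measure_report>", x$task_name, "\n")
  df <- as.data.frame(x)
  for (k in names(df)) {
    v <- df[[k]]
    cat(sprintf("  %-22s %s\n", k,
                if (is.numeric(v)) fmt_num(v) else as.character(v)))
  }
  invisible(x)
}

#' Flatten a measure report to a one-row data frame
#' @param x A [measure_report][analyze].
#' @param row.names,optional,... Ignored (S3 signature).
#' @return One-row data frame, one column per measure.
#' @export
as.data.frame.measure_report <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  vals <- lapply(unclass(x), function(v) {
    attributes(v) <- NULL
    v
  })
  as.data.frame(vals, stringsAsFactors = FALSE)
}

# Stable key order and missing-value reasons for writers.
report_keys <- function() {
  c("task_name", "n_targets", "n_cancellations", "n_cancelled_targets",
    "false_alarms", "omissions_total", "omissions_left", "omissions_right",
    "revisits_total", "revisits_immediate", "revisits_delayed",
    "coc_horizontal", "coc_vertical", "duration_s", "mean_ict_s", "q_score",
    "mean_icd_px", "standardized_icd", "search_speed", "cancellation_rate",
    "mean_angle_deg", "standardized_angle", "best_r", "best_r_horizontal",
    "best_r_vertical", "intersections_count", "intersections_rate",
    "first_x_std", "first_y_std", "first_quadrant")
}
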