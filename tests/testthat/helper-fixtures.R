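# Shared fixtures: build tasks and cancellation sequences from bare
# coordinate lists, and an independent brute-force crossing oracle.

# Task whose targets sit exactly at the given coordinates (ids in row
# order). When all x coincide a far-away spare target is added (never
# visited) so horizontal standardization stays defined.
fixture_task <- function(coords, width = NULL, height = NULL,
                         distractors = NULL) {
  coords <- as.data.frame(coords)
  names(coords) <- c("x", "y")
  n <- nrow(coords)
  stim <- data.frame(id = seq_len(n), x = coords$x, y = coords$y,
                     role = "target")
  if (n >= 2 && diff(range(coords$x)) == 0) {
    stim <- rbind(stim, data.frame(id = n + 1L, x = max(coords$x) + 500,
                                   y = coords$y[1], role = "target"))
  }
  if (!is.null(distractors)) {
    distractors <- as.data.frame(distractors)
    names(distractors) <- c("x", "y")
    stim <- rbind(stim, data.frame(id = max(stim$id) + seq_len(nrow(distractors)),
                                   x = distractors$x, y = distractors$y,
                                   role = "distractor"))
  }
  if (is.null(width)) width <- max(stim$x) + 100
  if (is.null(height)) height <- max(stim$y) + 100
  task_spec(width, height, stim, name = "fixture")
}

# Cancellation sequence visiting the listed points in order, 1 s apart,
# via the real event-assignment path (clicks exactly on target centers).
fixture_sequence <- function(coords, task = NULL, dt_s = 1) {
  coords <- as.data.frame(coords)
  names(coords) <- c("x", "y")
  if (is.null(task)) task <- fixture_task(unique(coords))
  n <- nrow(coords)
  events <- data.frame(index = seq_len(n),
                       t_ms = seq_len(n) * dt_s * 1000,
                       x = coords$x, y = coords$y)
  assign_events(task, events, hit_radius = 1e-6 + 1)
}

# Independent crossing oracle: orientation (CCW) predicate over all
# unordered segment pairs of the polyline through `coords`. Counts proper
# interior crossings only, exactly the semantics under test but via a
# different primitive than the implementation's parametric solve.
oracle_crossings <- function(coords) {
  coords <- as.matrix(coords)
  keep <- c(TRUE, rowSums((coords[-1, , drop = FALSE] -
                           coords[-nrow(coords), , drop = FALSE])^2) > 0)
  coords <- coords[keep, , drop = FALSE]
  n <- nrow(coords) - 1
  if (n < 2) return(0L)
  ccw <- function(a, b, c) {
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p1 <- coords[i, ]; p2 <- coords[i + 1, ]
      p3 <- coords[j, ]; p4 <- coords[j + 1, ]
      if (ccw(p1, p2, p3) * ccw(p1, p2, p4) < 0 &&
          ccw(p3, p4, p1) * ccw(p3, p4, p2) < 0) {
        count <- count + 1L
      }
    }
  }
  count
}

# Grid-layout task used across measure tests: r x c targets with the given
# spacing, no jitter.
fixture_grid_task <- function(n_rows, n_cols, spacing = 100,
                              origin = c(100, 100)) {
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  fixture_task(data.frame(x = origin[1] + (g$col - 1) * spacing,
                          y = origin[2] + (g$row - 1) * spacing))
}
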