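# Landolt-C style layout generation and task import.

#' Compute the stimulus grid for a display
#'
#' Chooses the number of rows and columns for a given display resolution and
#' stimulus count: among all grids with at least `n_stimuli` cells, the one
#' wasting fewest cells wins; ties are broken by the cell aspect ratio closest
#' to the display aspect ratio, then by preferring more columns. Deterministic.
#'
#' @param width,height Display size in pixels.
#' @param n_stimuli Number of stimuli the grid must hold.
#' @param margin Margin in pixels kept free on every side.
#' @return List with `n_rows`, `n_cols`, `cell_w`, `cell_h` (pixels) and
#'   `margin`.
#' @export
compute_grid <- function(width, height, n_stimuli, margin = 0) {
  stopifnot(n_stimuli >= 1)
  usable_w <- width - 2 * margin
  usable_h <- height - 2 * margin
  if (usable_w <= 0 || usable_h <= 0) {
    stop("non-positive usable area after margins (",
         usable_w, " x ", usable_h, " px)")
  }
  aspect <- usable_w / usable_h
  best <- NULL
  for (r in seq_len(n_stimuli)) {
    cc <- ceiling(n_stimuli / r)
    cell_aspect <- (usable_w / cc) / (usable_h / r)
    cand <- c(waste = r * cc - n_stimuli,
              dev = abs(cell_aspect - aspect),
              neg_cols = -cc, r = r, c = cc)
    if (is.null(best) ||
        cand["waste"] < best["waste"] ||
        (cand["waste"] == best["waste"] && cand["dev"] < best["dev"]) ||
        (cand["waste"] == best["waste"] && cand["dev"] == best["dev"] &&
         cand["neg_cols"] < best["neg_cols"])) {
      best <- cand
    }
  }
  n_rows <- as.integer(best["r"])
  n_cols <- as.integer(best["c"])
  list(n_rows = n_rows, n_cols = n_cols,
       cell_w = usable_w / n_cols, cell_h = usable_h / n_rows,
       margin = margin)
}

#' Assign target cells evenly over columns
#'
#' Targets are placed pseudo-randomly but evenly over the width of the array:
#' per-column target counts differ by at most one (exactly `n_targets /
#' n_cols` each when divisible), and the rows within a column are drawn
#' without replacement under the seed.
#'
#' @param n_targets Number of targets.
#' @param n_rows,n_cols Grid dimensions.
#' @param seed Integer seed; identical arguments and seed give identical
#'   assignments.
#' @return Data frame with columns `row`, `col`, one row per target cell.
#' @export
assign_targets_evenly <- function(n_targets, n_rows, n_cols, seed = 1) {
  if (n_targets > n_rows * n_cols) {
    stop("capacity error: ", n_targets, " targets need more than the ",
         n_rows * n_cols, " available cells (", n_rows, " x ", n_cols, ")")
  }
  base <- n_targets %/% n_cols
  extra <- n_targets %% n_cols
  if (base + (extra > 0) > n_rows) {
    stop("capacity error: a column would need ", base + 1L,
         " targets but only ", n_rows, " rows exist")
  }
  with_seed(seed, {
    counts <- rep(base, n_cols)
    if (extra > 0) {
      counts[sample.int(n_cols, extra)] <- base + 1L
    }
    cells <- lapply(seq_len(n_cols), function(cc) {
      k <- counts[cc]
      if (k == 0) return(NULL)
      data.frame(row = sort(sample.int(n_rows, k)), col = cc)
    })
    do.call(rbind, cells)
  })
}

#' Generate a Landolt-C style cancellation task
#'
#' Stimuli (circles whose gap orientation separates targets from distractors)
#' are laid out in rows and columns computed from the display resolution, each
#' offset from its cell center by a random spatial jitter. Targets are spread
#' evenly over the columns; distractors fill randomly chosen remaining cells,
#' split between subtypes (by default half without a gap, half with the gap on
#' the bottom, against targets with the gap on top).
#'
#' @param width,height Display size in pixels (default 1280 x 1024).
#' @param n_targets Number of targets (default 64).
#' @param distractor_ratio Distractors per target (default 2, i.e. a 1:2
#'   target:distractor ratio giving 128 distractors at the defaults).
#' @param jitter Maximum offset from the cell center, as a fraction of the
#'   cell size per axis, in `[0, 0.5)`. Default 0.2.
#' @param seed Integer seed; the layout is deterministic per seed.
#' @param margin Margin in pixels; default 2\% of each dimension.
#' @param name Task name.
#' @param target_subtype,distractor_subtypes Labels for stimulus subtypes;
#'   `distractor_subtypes` is a named numeric vector of proportions.
#' @return A [task_spec].
#' @export
#' @examples
#' task <- generate_landolt_task(1280, 1024, n_targets = 64,
#'                               distractor_ratio = 2, seed = 1)
#' task
generate_landolt_task <- function(width = 1280, height = 1024,
                                  n_targets = 64, distractor_ratio = 2,
                                  jitter = 0.2, seed = 1,
                                  margin = NULL, name = "landolt_c",
                                  target_subtype = "gap_top",
                                  distractor_subtypes = c(no_gap = 0.5,
                                                          gap_bottom = 0.5)) {
  stopifnot(n_targets >= 1, distractor_ratio >= 0,
            jitter >= 0, jitter < 0.5)
  n_distractors <- round(n_targets * distractor_ratio)
  n_stimuli <- n_targets + n_distractors
  if (is.null(margin)) margin <- 0.02 * c(width, height)
  margin <- rep(margin, length.out = 2)
  grid <- compute_grid_xy(width, height, n_stimuli, margin)
  n_cells <- grid$n_rows * grid$n_cols
  if (n_cells < n_stimuli) {
    stop("capacity error: ", n_stimuli, " stimuli require more than ",
         n_cells, " cells")
  }
  target_cells <- assign_targets_evenly(n_targets, grid$n_rows, grid$n_cols,
                                        seed = seed)
  layout <- with_seed(seed + 1L, {
    all_cells <- expand.grid(row = seq_len(grid$n_rows),
                             col = seq_len(grid$n_cols))
    key <- paste(all_cells$row, all_cells$col)
    tkey <- paste(target_cells$row, target_cells$col)
    free <- all_cells[!key %in% tkey, , drop = FALSE]
    cells <- cbind(target_cells, role = "target")
    if (n_distractors > 0) {
      dist_cells <- free[sample.int(nrow(free), n_distractors), , drop = FALSE]
      cells <- rbind(cells, cbind(dist_cells, role = "distractor"))
    }
    cells <- cells[order(cells$row, cells$col), ]
    cx <- margin[1] + (cells$col - 0.5) * grid$cell_w
    cy <- margin[2] + (cells$row - 0.5) * grid$cell_h
    jx <- runif(nrow(cells), -jitter, jitter) * grid$cell_w
    jy <- runif(nrow(cells), -jitter, jitter) * grid$cell_h
    sub <- character(nrow(cells))
    sub[cells$role == "target"] <- target_subtype
    nd <- sum(cells$role == "distractor")
    if (nd > 0) {
      props <- distractor_subtypes / sum(distractor_subtypes)
      counts <- floor(props * nd)
      rem <- nd - sum(counts)
      if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
      sub[cells$role == "distractor"] <-
        sample(rep(names(props), counts))
    }
    data.frame(id = seq_len(nrow(cells)), x = cx + jx, y = cy + jy,
               role = cells$role, subtype = sub,
               cell_row = cells$row, cell_col = cells$col,
               stringsAsFactors = FALSE)
  })
  task <- task_spec(width, height, layout[, c("id", "x", "y", "role", "subtype")],
                    name = name)
  attr(task, "grid") <- grid
  attr(task, "cells") <- layout[, c("id", "cell_row", "cell_col")]
  task
}

# Grid with independent x/y margins (helper for generate_landolt_task).
compute_grid_xy <- function(width, height, n_stimuli, margin) {
  g <- compute_grid(width - 2 * margin[1], height - 2 * margin[2],
                    n_stimuli, margin = 0)
  g$margin <- margin
  g
}

#' Import an externally defined task
#'
#' Reads a coordinate file (the task JSON schema, see [read_task()]) that
#' marks targets and distractors on a scanned task image, and scales the
#' coordinates from the file's native size to the requested display size —
#' the image is scaled proportionally per axis, exactly as the task is when
#' displayed.
#'
#' @param coords_file Path to a task JSON file with the native `width`,
#'   `height` and the marked stimuli.
#' @param image_file Optional path to the background image (stored in the
#'   spec and drawn under path plots).
#' @param width,height Display size to scale to; default the file's native
#'   size (no rescaling).
#' @return A [task_spec] at the display size.
#' @export
import_task <- function(coords_file, image_file = NULL,
                        width = NULL, height = NULL) {
  task <- read_task(coords_file)
  if (is.null(width)) width <- task$width
  if (is.null(height)) height <- task$height
  sx <- width / task$width
  sy <- height / task$height
  stim <- task$stimuli
  stim$x <- stim$x * sx
  stim$y <- stim$y * sy
  task_spec(width, height, stim, name = task$name,
            background_image = if (!is.null(image_file)) image_file
                               else task$background_image)
}
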