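# Visual outputs: Gaussian-kernel heatmaps scaled to optimal performance,
# cancellation-path plots, best-R rank plots, and the single-page A4 PDF
# summary.

#' Default heatmap kernel width for a task
#'
#' Half the mean nearest-neighbor distance between targets, so kernels of
#' neighboring targets blend into a continuous field without washing out
#' lateralized structure.
#' @param task A [task_spec].
#' @return Kernel standard deviation in pixels.
#' @export
default_heatmap_sigma <- function(task) {
  tg <- task_targets(task)
  d <- mean_nn_distance(tg[, c("x", "y")])
  if (is.na(d)) return(min(task$width, task$height) / 10)
  d / 2
}

#' Gaussian-kernel heatmap scaled to optimal performance
#'
#' Adds an isotropic Gaussian kernel at each supplied location (cancelled
#' targets, omitted targets, or path intersection points) and scales the
#' resulting field to the field an optimal performance would produce — a
#' kernel on every target. With the default scalar normalization the
#' all-targets field peaks at exactly 1, making heatmaps comparable between
#' individuals and tasks; elementwise normalization divides bin-by-bin
#' instead.
#'
#' @param task A [task_spec].
#' @param points Data frame or matrix of kernel centers (`x`, `y` in
#'   pixels); e.g. cancelled target centers, omitted targets, or the
#'   `intersection_points` attribute of a [measure_report][analyze].
#' @param sigma_px Kernel standard deviation, pixels; default
#'   [default_heatmap_sigma()].
#' @param bin_px Bin size in pixels per axis (grid resolution).
#' @param normalize `"scalar"` (divide by the maximum of the optimal field)
#'   or `"elementwise"` (divide bin-by-bin, zero where the optimal field is
#'   negligible).
#' @return A matrix of class `cancellation_heatmap` (rows = y bins, columns
#'   = x bins) with attributes `x`, `y` (bin centers), `raw` (unnormalized
#'   field) and `optimal` (the all-targets field).
#' @export
cancellation_heatmap <- function(task, points, sigma_px = NULL, bin_px = 8,
                                 normalize = c("scalar", "elementwise")) {
  stopifnot(inherits(task, "task_spec"), bin_px > 0)
  normalize <- match.arg(normalize)
  if (is.null(sigma_px)) sigma_px <- default_heatmap_sigma(task)
  stopifnot(sigma_px > 0)
  gx <- seq(bin_px / 2, task$width, by = bin_px)
  gy <- seq(bin_px / 2, task$height, by = bin_px)
  field_of <- function(px, py) {
    if (length(px) == 0) {
      return(matrix(0, nrow = length(gy), ncol = length(gx)))
    }
    ax <- exp(-outer(gx, px, "-")^2 / (2 * sigma_px^2))
    ay <- exp(-outer(gy, py, "-")^2 / (2 * sigma_px^2))
    ay %*% t(ax)
  }
  points <- as.data.frame(points)
  raw <- field_of(points$x, points$y)
  tg <- task_targets(task)
  optimal <- field_of(tg$x, tg$y)
  peak <- max(optimal)
  field <- if (normalize == "scalar") {
    raw / peak
  } else {
    out <- raw / pmax(optimal, 1e-12)
    out[optimal < 1e-6 * peak] <- 0
    out
  }
  structure(field, x = gx, y = gy, raw = raw, optimal = optimal,
            sigma_px = sigma_px, normalize = normalize,
            class = c("cancellation_heatmap", "matrix"))
}

# Draw a heatmap on the current device (y increasing downward, as on
# screen).
draw_heatmap <- function(hm, main = "") {
  gx <- attr(hm, "x"); gy <- attr(hm, "y")
  pal <- colorRampPalette(c("#ffffff", "#ffe082", "#ff8f00", "#d32f2f"))(64)
  zmax <- max(hm, 1e-9)
  image(gx, gy, t(unclass(hm)), ylim = rev(range(gy)), col = pal,
        zlim = c(0, zmax), useRaster = TRUE, asp = 1,
        xlab = "x (px)", ylab = "y (px)", main = main)
}

#' @export
plot.cancellation_heatmap <- function(x, main = "cancellation heatmap", ...) {
  draw_heatmap(x, main = main)
  invisible(x)
}

# Draw the cancellation path on the current device.
draw_path <- function(task, seq, main = task$name) {
  stim <- task$stimuli
  plot.new()
  plot.window(xlim = c(0, task$width), ylim = c(task$height, 0), asp = 1)
  title(main = main, xlab = "x (px)", ylab = "y (px)")
  axis(1); axis(2)
  bg <- task$background_image
  if (!is.null(bg) && file.exists(bg) &&
      grepl("\\.png$", bg, ignore.case = TRUE) &&
      requireNamespace("png", quietly = TRUE)) {
    rasterImage(png::readPNG(bg), 0, task$height, task$width, 0)
  }
  is_t <- stim$role == "target"
  points(stim$x[!is_t], stim$y[!is_t], pch = 1, col = "grey70", cex = 0.8)
  points(stim$x[is_t], stim$y[is_t], pch = 1, col = "grey30", cex = 1.0)
  cc <- path_cancellations(seq)
  if (nrow(cc) > 0) {
    lines(cc$target_x, cc$target_y, col = "#1565c0", lwd = 1.5)
    points(cc$target_x, cc$target_y, pch = 16, col = "#1565c0", cex = 0.7)
    points(cc$target_x[1], cc$target_y[1], pch = 17, col = "#2e7d32",
           cex = 1.4)  # start marker
    dr <- cc$revisit_kind == "delayed"
    if (any(dr)) {
      points(cc$target_x[dr], cc$target_y[dr], pch = 0, col = "#c62828",
             cex = 1.4)
    }
  }
}

#' Plot the cancellation path
#'
#' Targets, distractors and the cancellation path in cancellation order,
#' with a start marker and delayed revisits highlighted; drawn over the
#' task's background image when one is set (PNG).
#'
#' @param task A [task_spec].
#' @param seq A [cancellation_sequence].
#' @param file Output PNG path; `NULL` draws on the current device.
#' @param width,height Figure size in pixels.
#' @return The file path (or `NULL`), invisibly.
#' @export
plot_path <- function(task, seq, file = NULL, width = 900, height = 740) {
  if (!is.null(file)) {
    png(file, width = width, height = height)
    on.exit(dev.off())
  }
  draw_path(task, seq)
  invisible(file)
}

# Draw the two best-R rank panels on the current device.
draw_best_r <- function(seq) {
  cc <- path_cancellations(seq)
  br <- best_r(seq)
  rank <- seq_len(nrow(cc))
  panel <- function(pos, r, lab) {
    plot(rank, pos, pch = 16, col = "#1565c0",
         xlab = "cancellation rank", ylab = lab,
         main = sprintf("R = %s", fmt_num(round(as.numeric(r), 3))))
    if (!is.na(r) && stats::sd(pos) > 0) {
      abline(stats::lm(pos ~ rank), col = "#c62828", lwd = 1.5)
    }
  }
  panel(cc$target_x, br$r_hor, "horizontal position (px)")
  panel(cc$target_y, br$r_ver, "vertical position (px)")
}

#' Best-R rank plots
#'
#' Two scatter panels of cancellation rank number against the horizontal
#' and vertical cancellation position, with fitted lines and the two
#' Pearson correlations annotated.
#'
#' @param seq A [cancellation_sequence] with at least 3 usable
#'   cancellations (otherwise skipped with a message).
#' @param file Output PNG path; `NULL` draws on the current device.
#' @param width,height Figure size in pixels.
#' @return The file path, invisibly; `NULL` when skipped.
#' @export
plot_best_r <- function(seq, file = NULL, width = 900, height = 450) {
  if (nrow(path_cancellations(seq)) < 3) {
    message("plot_best_r: skipped (fewer than 3 usable cancellations)")
    return(invisible(NULL))
  }
  if (!is.null(file)) {
    png(file, width = width, height = height)
    on.exit(dev.off())
  }
  op <- par(mfrow = c(1, 2))
  on.exit(par(op), add = TRUE, after = FALSE)
  draw_best_r(seq)
  invisible(file)
}

#' Render the single-page A4 PDF summary
#'
#' One A4 portrait page: a metadata header (task name, date, duration), the
#' full measure table, the cancellation path plot and the cancellation
#' heatmap — the printable session record for a patient file.
#'
#' @param report A [measure_report][analyze].
#' @param task A [task_spec].
#' @param seq A [cancellation_sequence].
#' @param path Output PDF path.
#' @param include_heatmap Draw the cancellation heatmap panel.
#' @return The path, invisibly.
#' @export
render_pdf <- function(report, task, seq, path, include_heatmap = TRUE) {
  stopifnot(inherits(report, "measure_report"))
  pdf(path, width = 8.27, height = 11.69, paper = "a4",
      title = paste("cancellation report:", task$name))
  on.exit(dev.off())
  layout(matrix(c(1, 1, 2, 3, 2, 4), nrow = 3, byrow = TRUE),
         heights = c(0.9, 2.2, 2.2))
  # header
  op <- par(mar = c(0, 1, 1, 1))
  plot.new(); plot.window(0:1, 0:1)
  text(0, 0.85, "Cancellation task report", adj = 0, cex = 1.6, font = 2)
  text(0, 0.55, sprintf("Task: %s    Date: %s", task$name,
                        format(Sys.Date())), adj = 0, cex = 1.0)
  text(0, 0.3, sprintf("Duration: %s s    Cancellations: %d / %d targets",
                       fmt_num(report$duration_s), report$n_cancellations,
                       report$n_targets), adj = 0, cex = 1.0)
  # measure table
  par(mar = c(1, 1, 1, 1))
  plot.new(); plot.window(0:1, 0:1)
  keys <- setdiff(report_keys(), "task_name")
  ys <- seq(0.98, 0.02, length.out = length(keys))
  for (i in seq_along(keys)) {
    v <- report[[keys[i]]]
    reason <- missing_reason(v)
    val <- if (is.numeric(v)) fmt_num(round(as.numeric(v), 4))
           else as.character(v)
    if (is.na(val)) val <- "NA"
    text(0, ys[i], keys[i], adj = 0, cex = 0.62)
    text(0.62, ys[i], val, adj = 1, cex = 0.62)
    if (!is.null(reason)) text(0.66, ys[i], reason, adj = 0, cex = 0.5,
                               col = "grey40")
  }
  # figures
  par(mar = c(3.5, 3.5, 2, 1), mgp = c(2, 0.7, 0))
  draw_path(task, seq, main = "cancellation path")
  if (include_heatmap) {
    cc <- path_cancellations(seq)
    hm <- cancellation_heatmap(task, cc[, c("target_x", "target_y"), drop = FALSE] |>
                                 setNames(c("x", "y")))
    draw_heatmap(hm, main = "cancellation heatmap")
  } else {
    plot.new()
  }
  par(op)
  invisible(path)
}
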