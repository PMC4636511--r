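# Synthetic participant simulator: raw event logs with controllable search
# strategy, lateralized omission gradient, revisiting behavior and timing.
# Serves as the test harness standing in for patient data.

#' Simulation configuration
#'
#' Defaults emulate a conventional administration: a 2-minute time limit and
#' a healthy-adult inter-cancellation time around 1.2 s (lognormal, right-
#' skewed, strictly positive). The omission gradient makes each target be
#' skipped with probability `omission_base + omission_slope * x_std`
#' (clamped to `[0, 1]`), where `x_std` is the target's standardized
#' horizontal position; a leftward-neglect gradient is
#' `omission_base = g, omission_slope = -g`.
#'
#' @param strategy Search strategy: `"serpentine_horizontal"` (row-wise
#'   boustrophedon), `"serpentine_vertical"`, `"spiral_inward"` (peeling the
#'   convex boundary of the remaining targets), or `"random"`.
#' @param omission_base,omission_slope Omission probability intercept and
#'   slope over standardized x.
#' @param p_immediate_revisit Probability of duplicating a click
#'   (cancelling the same target twice in a row).
#' @param p_delayed_revisit Probability, per cancellation, of returning to a
#'   uniformly chosen earlier-cancelled target.
#' @param time_meanlog,time_sdlog Lognormal parameters of the
#'   inter-cancellation interval in seconds.
#' @param pointer_noise_px Standard deviation of the isotropic Gaussian
#'   click scatter around the target center, pixels.
#' @param time_limit_s Session time limit in seconds (`NULL` for none);
#'   default 120, the conventional 2-minute administration.
#' @param seed Integer seed; identical config and task give identical logs.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(strategy = c("serpentine_horizontal",
                                           "serpentine_vertical",
                                           "spiral_inward", "random"),
                              omission_base = 0, omission_slope = 0,
                              p_immediate_revisit = 0,
                              p_delayed_revisit = 0,
                              time_meanlog = 0.1, time_sdlog = 0.35,
                              pointer_noise_px = 5,
                              time_limit_s = 120, seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(p_immediate_revisit >= 0, p_immediate_revisit <= 1,
            p_delayed_revisit >= 0, p_delayed_revisit <= 1,
            time_sdlog >= 0, pointer_noise_px >= 0)
  structure(list(strategy = strategy, omission_base = omission_base,
                 omission_slope = omission_slope,
                 p_immediate_revisit = p_immediate_revisit,
                 p_delayed_revisit = p_delayed_revisit,
                 time_meanlog = time_meanlog, time_sdlog = time_sdlog,
                 pointer_noise_px = pointer_noise_px,
                 time_limit_s = time_limit_s, seed = as.integer(seed)),
            class = "simulation_config")
}

# Convex boundary ring of a point set, including points collinear on hull
# edges (chull drops those, which would reduce a grid ring to its corners).
# Returned as indices ordered clockwise on a y-down screen, starting from
# the top-left-most point.
convex_ring <- function(px, py) {
  n <- length(px)
  if (n <= 2) return(order(px + py))
  hull <- chull(px, py)
  scale <- max(diff(range(px)), diff(range(py)), 1)
  tol <- 1e-9 * scale
  ring <- integer(0)
  on_ring <- rep(FALSE, n)
  on_ring[hull] <- TRUE
  h <- c(hull, hull[1])
  for (k in seq_along(hull)) {
    a <- h[k]; b <- h[k + 1]
    ring <- c(ring, a)
    ex <- px[b] - px[a]; ey <- py[b] - py[a]
    len2 <- ex^2 + ey^2
    if (len2 == 0) next
    cand <- which(!on_ring)
    if (length(cand) > 0) {
      tt <- ((px[cand] - px[a]) * ex + (py[cand] - py[a]) * ey) / len2
      perp <- abs((px[cand] - px[a]) * ey - (py[cand] - py[a]) * ex) /
        sqrt(len2)
      mid <- cand[perp <= tol & tt > 0 & tt < 1]
      if (length(mid) > 0) {
        mid <- mid[order(((px[mid] - px[a]) * ex + (py[mid] - py[a]) * ey))]
        on_ring[mid] <- TRUE
        ring <- c(ring, mid)
      }
    }
  }
  start <- which.min(px[ring] + py[ring])
  ring <- c(ring[start:length(ring)], ring[seq_len(start - 1)])
  # traverse clockwise on screen: the first step should move rightward
  if (length(ring) > 2 && px[ring[2]] < px[ring[length(ring)]]) {
    ring <- c(ring[1], rev(ring[-1]))
  }
  ring
}

# Row (or column) bands for serpentine orders: cut the sorted coordinate at
# gaps larger than twice the mean gap. Exact for jittered grids; for
# unstructured layouts it still yields a deterministic banding.
coordinate_bands <- function(v) {
  o <- order(v)
  sv <- v[o]
  g <- diff(sv)
  band <- integer(length(v))
  if (length(g) == 0 || all(g == 0)) {
    band[] <- 1L
  } else {
    breaks <- g > 2 * mean(g)
    band[o] <- cumsum(c(1L, as.integer(breaks)))
  }
  band
}

#' Target visiting order for a search strategy
#'
#' `serpentine_horizontal`: rows top-to-bottom, alternating left-to-right
#' and right-to-left (the efficient boustrophedon sweep); transposed for
#' `serpentine_vertical`. `spiral_inward`: repeatedly peel the convex
#' boundary ring of the remaining targets, clockwise from the top-left-most
#' — an organized path that yields a low best R but a high standardized
#' angle. `random`: a seeded permutation.
#'
#' @param task A [task_spec].
#' @param strategy Strategy name, as in [simulation_config()].
#' @param seed Seed (used by `"random"` only).
#' @return Integer vector of target ids, each exactly once.
#' @export
strategy_order <- function(task, strategy = "serpentine_horizontal",
                           seed = 1) {
  tg <- task_targets(task)
  ids <- tg$id
  if (nrow(tg) == 1) return(ids)
  switch(strategy,
    serpentine_horizontal = {
      band <- coordinate_bands(tg$y)
      ord <- integer(0)
      for (b in sort(unique(band))) {
        sel <- which(band == b)
        sel <- sel[order(tg$x[sel])]
        if (b %% 2 == 0) sel <- rev(sel)
        ord <- c(ord, sel)
      }
      ids[ord]
    },
    serpentine_vertical = {
      band <- coordinate_bands(tg$x)
      ord <- integer(0)
      for (b in sort(unique(band))) {
        sel <- which(band == b)
        sel <- sel[order(tg$y[sel])]
        if (b %% 2 == 0) sel <- rev(sel)
        ord <- c(ord, sel)
      }
      ids[ord]
    },
    spiral_inward = {
      remaining <- seq_len(nrow(tg))
      ord <- integer(0)
      while (length(remaining) > 0) {
        ring <- convex_ring(tg$x[remaining], tg$y[remaining])
        ring <- remaining[ring]
        ord <- c(ord, ring)
        remaining <- setdiff(remaining, ring)
      }
      ids[ord]
    },
    random = with_seed(seed, ids[sample.int(length(ids))]),
    stop("unknown strategy: ", strategy)
  )
}

#' Simulate a cancellation session
#'
#' Visits the targets in strategy order; each target is independently
#' omitted according to the lateral omission gradient; clicks land at the
#' target center plus isotropic Gaussian pointer noise; inter-click
#' intervals are lognormal and accumulate from task onset; immediate
#' revisits duplicate the current click and delayed revisits insert a
#' return to a uniformly chosen earlier-cancelled target; the log is
#' truncated at the time limit.
#'
#' @param task A [task_spec].
#' @param config A [simulation_config()].
#' @return Raw event log: data frame with columns `index`, `t_ms`, `x`, `y`.
#' @export
simulate_session <- function(task, config = simulation_config()) {
  stopifnot(inherits(task, "task_spec"), inherits(config, "simulation_config"))
  tg <- task_targets(task)
  xr <- range(tg$x)
  x_std <- if (diff(xr) > 0) (tg$x - xr[1]) / diff(xr) else rep(0.5, nrow(tg))
  names(x_std) <- as.character(tg$id)
  order_ids <- strategy_order(task, config$strategy, config$seed)
  with_seed(config$seed, {
    clicks <- list()
    visited <- integer(0)
    for (id in order_ids) {
      p_omit <- min(1, max(0, config$omission_base +
                             config$omission_slope * x_std[[as.character(id)]]))
      if (runif(1) < p_omit) next
      row <- tg[tg$id == id, ]
      pos <- c(row$x, row$y) + rnorm(2, 0, config$pointer_noise_px)
      clicks[[length(clicks) + 1]] <- c(pos, id)
      visited <- c(visited, id)
      if (config$p_immediate_revisit > 0 &&
          runif(1) < config$p_immediate_revisit) {
        clicks[[length(clicks) + 1]] <- c(pos, id)  # duplicate the click
      }
      if (config$p_delayed_revisit > 0 && length(visited) > 1 &&
          runif(1) < config$p_delayed_revisit) {
        back_id <- visited[sample.int(length(visited) - 1, 1)]
        back <- tg[tg$id == back_id, ]
        bpos <- c(back$x, back$y) + rnorm(2, 0, config$pointer_noise_px)
        clicks[[length(clicks) + 1]] <- c(bpos, back_id)
      }
    }
    n <- length(clicks)
    if (n == 0) {
      return(data.frame(index = integer(), t_ms = numeric(),
                        x = numeric(), y = numeric()))
    }
    t_s <- cumsum(rlnorm(n, config$time_meanlog, config$time_sdlog))
    m <- do.call(rbind, clicks)
    log <- data.frame(index = seq_len(n), t_ms = round(t_s * 1000),
                      x = round(m[, 1], 1), y = round(m[, 2], 1))
    if (!is.null(config$time_limit_s)) {
      log <- log[log$t_ms <= config$time_limit_s * 1000, , drop = FALSE]
      log$index <- seq_len(nrow(log))
    }
    # clamp pointer noise into the canvas
    log$x <- pmin(pmax(log$x, 0), task$width)
    log$y <- pmin(pmax(log$y, 0), task$height)
    log
  })
}
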