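# The quantitative measure roster, tested against hand-derived values and
# independent oracles.

test_that("omissions split at the target midline, left inclusive", {
  pts <- data.frame(x = c(100, 200, 800, 900), y = rep(100, 4))
  task <- fixture_task(pts)
  # only the right two cancelled: midline at 500, omissions (2, 2, 0)
  seq <- fixture_sequence(pts[3:4, ], task = task)
  expect_identical(omission_counts(task, seq),
                   list(total = 2L, left = 2L, right = 0L))
  # everything cancelled
  seq <- fixture_sequence(pts, task = task)
  expect_identical(omission_counts(task, seq)$total, 0L)
  # nothing cancelled on a balanced layout: split is symmetric
  task64 <- generate_landolt_task(1280, 1024, 64, 0, 0, seed = 1)
  empty <- assign_events(task64, data.frame(index = integer(),
                                            t_ms = numeric(), x = numeric(),
                                            y = numeric()))
  om <- omission_counts(task64, empty)
  expect_identical(om$total, 64L)
  expect_identical(om$left, 32L)
  expect_identical(om$right, 32L)
  expect_identical(om$total, om$left + om$right)
})

test_that("revisit counts aggregate the classification", {
  pts <- data.frame(x = c(100, 200, 300), y = rep(100, 3))
  task <- fixture_task(pts)
  s <- fixture_sequence(pts[c(1, 2, 1, 1), ], task = task)
  expect_identical(revisit_counts(s),
                   list(total = 2L, immediate = 1L, delayed = 1L))
  expect_identical(revisit_counts(fixture_sequence(pts, task = task)),
                   list(total = 0L, immediate = 0L, delayed = 0L))
  expect_identical(revisit_counts(fixture_sequence(pts[c(1, 1), ], task = task)),
                   list(total = 1L, immediate = 1L, delayed = 0L))
})

test_that("center of cancellation maps the extreme targets to -1 and +1", {
  pts <- data.frame(x = c(0, 50, 100), y = c(0, 50, 100))
  task <- fixture_task(pts)
  # only the leftmost target
  expect_equal(center_of_cancellation(task, fixture_sequence(pts[1, ],
                                                             task = task)),
               -1)
  # x = 0 and x = 50 map to -1 and 0: mean -0.5
  expect_equal(center_of_cancellation(task, fixture_sequence(pts[1:2, ],
                                                             task = task)),
               -0.5)
  # a symmetric layout cancelled in full averages to 0 on both axes
  grid <- fixture_grid_task(4, 8)
  tg <- task_targets(grid)
  full <- fixture_sequence(tg[, c("x", "y")], task = grid)
  expect_equal(center_of_cancellation(grid, full, "horizontal"), 0)
  expect_equal(center_of_cancellation(grid, full, "vertical"), 0)
  # vertical convention: topmost -1
  expect_equal(center_of_cancellation(task, fixture_sequence(pts[1, ],
                                                             task = task),
                                      "vertical"), -1)
  # no cancellations: missing with a reason
  none <- fixture_sequence(pts[0, ], task = task)
  v <- center_of_cancellation(task, none)
  expect_true(is.na(v))
  expect_match(missing_reason(v), "no cancellations")
  # unique-target averaging collapses revisits
  rev_seq <- fixture_sequence(pts[c(1, 2, 1), ], task = task)
  expect_equal(center_of_cancellation(task, rev_seq, unique_targets = TRUE),
               -0.5)
  expect_equal(center_of_cancellation(task, rev_seq), (-1 + 0 - 1) / 3)
})

test_that("path segments carry distance, time and angle; immediate revisits vanish", {
  # 3-4-5 triangle, 2 s apart
  s <- fixture_sequence(data.frame(x = c(0, 3), y = c(0, 4)), dt_s = 2)
  seg <- path_segments(s)
  expect_identical(nrow(seg), 1L)
  expect_equal(seg$s, 5)
  expect_equal(seg$t, 2)
  # A, A leaves no segment
  pts <- data.frame(x = c(100, 200), y = c(100, 100))
  s <- fixture_sequence(pts[c(1, 1), ], task = fixture_task(pts))
  expect_identical(nrow(path_segments(s)), 0L)
  # 45-degree step: delta_y = 10, d = sqrt(200), gamma = 45
  s <- fixture_sequence(data.frame(x = c(0, 10), y = c(0, 10)))
  seg <- path_segments(s)
  expect_equal(seg$delta_y, 10)
  expect_equal(seg$s, sqrt(200))
  expect_equal(seg$gamma, 45)
})

test_that("standardized ICD divides by the mean nearest-neighbor distance", {
  # stepping to nearest neighbors on a uniform grid gives exactly 1
  grid <- fixture_grid_task(1, 5, spacing = 100)
  tg <- task_targets(grid)
  seq <- fixture_sequence(tg[, c("x", "y")], task = grid)
  seg <- path_segments(seq)
  expect_equal(mean_icd(seg), 100)
  expect_equal(standardized_icd(grid, seg), 1)
  # identical path shape at 100 px vs 250 px spacing: same standardized ICD
  shape <- c(1, 11, 3, 14, 6, 2, 16)  # an arbitrary fixed visiting order
  for (k in c(1, 2.5)) {
    g <- fixture_grid_task(4, 4, spacing = 100 * k)
    tg <- task_targets(g)
    sq <- fixture_sequence(tg[shape, c("x", "y")], task = g)
    sic <- standardized_icd(g, path_segments(sq))
    if (k == 1) ref <- sic else expect_equal(sic, ref)
  }
  # single 200-px segment over mean NN distance 100
  g <- fixture_grid_task(1, 3, spacing = 100)
  tg <- task_targets(g)
  sq <- fixture_sequence(tg[c(1, 3), c("x", "y")], task = g)
  expect_equal(standardized_icd(g, path_segments(sq)), 2)
})

test_that("timing reports duration and the mean inter-cancellation time", {
  pts <- data.frame(x = c(0, 100, 200), y = c(0, 0, 0))
  task <- fixture_task(pts)
  events <- data.frame(index = 1:3, t_ms = c(0, 1000, 4000),
                       x = pts$x, y = pts$y)
  seq <- assign_events(task, events, hit_radius = 10)
  tm <- timing(seq, path_segments(seq))
  expect_equal(tm$duration_s, 4)
  expect_equal(tm$mean_ict_s, 2)  # segment times 1 s and 3 s
  one <- fixture_sequence(pts[1, ], task = task)
  tm <- timing(one, path_segments(one))
  expect_true(is.na(tm$mean_ict_s))
  expect_gt(tm$duration_s, 0)
})

test_that("search speed is the mean of per-segment distance over time", {
  seg <- data.frame(s = c(100, 200), t = c(1, 2))
  expect_equal(search_speed(seg), 100)
  expect_equal(search_speed(data.frame(s = 50, t = 5)), 10)
  seg <- data.frame(s = rep(42, 7), t = rep(3, 7))
  expect_equal(search_speed(seg), 14)
  expect_error(search_speed(data.frame(s = 10, t = 0)), "simultaneous")
})

test_that("Q score combines accuracy and speed", {
  expect_equal(q_score(64, 64, 80), 0.8)
  expect_equal(q_score(0, 64, 50), 0)
  expect_equal(q_score(10, 10, 4), 2.5)  # N == N_tar reduces to N / t
  expect_error(q_score(5, 10, 0), "duration")
})

test_that("intersections: crossing and non-crossing worked examples", {
  crossing <- data.frame(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  s <- fixture_sequence(crossing)
  res <- path_intersections(path_segments(s), 4)
  expect_identical(res$count, 1L)
  expect_equal(res$rate, 0.25)
  expect_equal(unlist(res$points), c(x = 5, y = 5))
  monotone <- data.frame(x = c(0, 10, 20, 30), y = c(0, 0, 5, 0))
  res <- path_intersections(path_segments(fixture_sequence(monotone)), 4)
  expect_identical(res$count, 0L)
  expect_equal(res$rate, 0)
})

test_that("intersections match the brute-force CCW oracle on random paths", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    coords <- data.frame(x = round(runif(n, 0, 500), 1),
                         y = round(runif(n, 0, 400), 1))
    coords <- unique(coords)
    if (nrow(coords) < 4 || diff(range(coords$x)) == 0) next
    s <- fixture_sequence(coords)
    got <- path_intersections(path_segments(s))$count
    expect_identical(got, oracle_crossings(as.matrix(coords)),
                     info = paste("rep", rep))
  }
})

test_that("collinear overlapping segments contribute no intersections", {
  # back-and-forth along one line: every pair overlaps collinearly
  s <- fixture_sequence(data.frame(x = c(0, 100, 20, 80), y = rep(50, 4)))
  expect_identical(path_intersections(path_segments(s))$count, 0L)
})

test_that("best R reflects linear search progressions", {
  # strictly left-to-right equal steps
  s <- fixture_sequence(data.frame(x = seq(0, 400, by = 100),
                                   y = rep(100, 5)))
  br <- best_r(s)
  expect_equal(br$r_best, 1)
  expect_equal(abs(br$r_hor), 1)
  # serpentine 4x8: vertical rank correlation high, horizontal near 0
  g <- fixture_grid_task(4, 8)
  tg <- task_targets(g)
  ord <- strategy_order(g, "serpentine_horizontal")
  sq <- fixture_sequence(tg[match(ord, tg$id), c("x", "y")], task = g)
  br <- best_r(sq)
  expect_gt(abs(br$r_ver), 0.9)
  expect_lt(abs(br$r_hor), 0.2)
  expect_equal(br$r_best, abs(br$r_ver))
  # too few cancellations
  two <- fixture_sequence(tg[1:2, c("x", "y")], task = g)
  expect_true(is.na(best_r(two)$r_best))
  expect_match(missing_reason(best_r(two)$r_best), "fewer than 3")
})

test_that("an inward spiral scores low on best R but high on standardized angle", {
  g <- fixture_grid_task(6, 8)
  tg <- task_targets(g)
  ord <- strategy_order(g, "spiral_inward")
  sq <- fixture_sequence(tg[match(ord, tg$id), c("x", "y")], task = g)
  br <- best_r(sq)
  ang <- standardized_angle(path_segments(sq))
  expect_lt(br$r_best, 0.6)
  expect_gt(ang$standardized, 0.8)
})

test_that("standardized angle: axis-aligned paths score 1, diagonals 0", {
  horiz <- fixture_sequence(data.frame(x = seq(0, 300, 100), y = rep(0, 4)))
  ang <- standardized_angle(path_segments(horiz))
  expect_equal(ang$standardized, 1)
  expect_equal(ang$mean_angle_deg, 0)
  diag45 <- fixture_sequence(data.frame(x = c(0, 100, 200),
                                        y = c(0, 100, 200)))
  ang <- standardized_angle(path_segments(diag45))
  expect_equal(ang$standardized, 0)
  expect_equal(ang$mean_angle_deg, 45)
  vert <- fixture_sequence(data.frame(x = rep(0, 3), y = c(0, 100, 200)))
  expect_equal(standardized_angle(path_segments(vert))$standardized, 1)
  # one horizontal + one 45-degree step average to 0.5
  mix <- fixture_sequence(data.frame(x = c(0, 100, 200), y = c(0, 0, 100)))
  expect_equal(standardized_angle(path_segments(mix))$standardized, 0.5)
})

test_that("first marking standardizes into the target bounding box", {
  g <- fixture_grid_task(3, 3, spacing = 100, origin = c(50, 50))
  tg <- task_targets(g)
  fm <- first_marking(g, fixture_sequence(tg[1, c("x", "y")], task = g))
  expect_equal(c(fm$x_std, fm$y_std), c(0, 0))
  expect_identical(fm$quadrant, "top-left")
  fm <- first_marking(g, fixture_sequence(tg[5, c("x", "y")], task = g))
  expect_equal(c(fm$x_std, fm$y_std), c(0.5, 0.5))
  fm <- first_marking(g, fixture_sequence(tg[9, c("x", "y")], task = g))
  expect_equal(c(fm$x_std, fm$y_std), c(1, 1))
  expect_identical(fm$quadrant, "bottom-right")
})

test_that("analyze populates the full report and its conservation invariants", {
  task <- generate_landolt_task(1280, 1024, 32, 1, 0.2, seed = 3)
  log <- simulate_session(task, simulation_config(
    strategy = "random", omission_base = 0.2, p_delayed_revisit = 0.2,
    p_immediate_revisit = 0.1, seed = 5, time_limit_s = NULL))
  r <- analyze(task, assign_events(task, log))
  expect_s3_class(r, "measure_report")
  expect_identical(r$omissions_total, r$omissions_left + r$omissions_right)
  expect_identical(r$omissions_total, r$n_targets - r$n_cancelled_targets)
  expect_identical(r$revisits_total, r$revisits_immediate + r$revisits_delayed)
  expect_true(r$coc_horizontal >= -1 && r$coc_horizontal <= 1)
  expect_true(r$standardized_angle >= 0 && r$standardized_angle <= 1)
  expect_true(r$best_r >= 0 && r$best_r <= 1)
  expect_gte(r$q_score, 0)
  expect_gte(r$intersections_rate, 0)
  # empty session: organization measures missing, all targets omitted
  empty <- assign_events(task, data.frame(index = integer(),
                                          t_ms = numeric(), x = numeric(),
                                          y = numeric()))
  r0 <- analyze(task, empty)
  expect_identical(r0$omissions_total, 32L)
  for (k in c("coc_horizontal", "mean_icd_px", "best_r",
              "standardized_angle", "search_speed", "first_x_std")) {
    expect_true(is.na(r0[[k]]), info = k)
    expect_type(missing_reason(r0[[k]]), "character")
  }
  # perfect noiseless serpentine
  log <- simulate_session(task, simulation_config(
    pointer_noise_px = 0, seed = 1, time_limit_s = NULL))
  rp <- analyze(task, assign_events(task, log))
  expect_identical(rp$omissions_total, 0L)
  expect_identical(rp$revisits_total, 0L)
  expect_identical(rp$intersections_count, 0L)
  expect_gt(rp$best_r, 0.95)
})

test_that("uniform scaling leaves dimensionless measures unchanged, mean ICD scales", {
  task <- generate_landolt_task(800, 640, 24, 1, 0.2, seed = 6)
  log <- simulate_session(task, simulation_config(
    strategy = "random", seed = 7, pointer_noise_px = 0,
    time_limit_s = NULL))
  seq1 <- assign_events(task, log)
  r1 <- analyze(task, seq1)
  k <- 2.5
  stim <- task$stimuli
  stim$x <- stim$x * k; stim$y <- stim$y * k
  task2 <- task_spec(task$width * k, task$height * k, stim)
  log2 <- log
  log2$x <- log2$x * k; log2$y <- log2$y * k
  r2 <- analyze(task2, assign_events(task2, log2))
  for (kk in c("standardized_icd", "best_r", "standardized_angle",
               "intersections_count", "intersections_rate",
               "coc_horizontal", "coc_vertical", "first_x_std",
               "first_y_std")) {
    expect_equal(as.numeric(r2[[kk]]), as.numeric(r1[[kk]]),
                 tolerance = 1e-9, info = kk)
  }
  expect_equal(r2$mean_icd_px, k * r1$mean_icd_px)
})

test_that("intersection count is invariant to translation and 90-degree rotation", {
  set.seed(7)
  coords <- data.frame(x = runif(10, 0, 300), y = runif(10, 0, 300))
  base <- path_intersections(path_segments(fixture_sequence(coords)))$count
  shifted <- data.frame(x = coords$x + 1234, y = coords$y + 987)
  expect_identical(
    path_intersections(path_segments(fixture_sequence(shifted)))$count, base)
  rotated <- data.frame(x = coords$y, y = 300 - coords$x + 300)
  expect_identical(
    path_intersections(path_segments(fixture_sequence(rotated)))$count, base)
})

test_that("mirroring the array about the vertical midline negates horizontal CoC", {
  task <- generate_landolt_task(800, 640, 24, 0, 0.2, seed = 9)
  log <- simulate_session(task, simulation_config(
    strategy = "random", omission_base = 0.6, omission_slope = -0.6,
    pointer_noise_px = 0, seed = 10, time_limit_s = NULL))
  seq1 <- assign_events(task, log)
  coc1 <- center_of_cancellation(task, seq1)
  stim <- task$stimuli
  stim$x <- task$width - stim$x
  task2 <- task_spec(task$width, task$height, stim)
  log2 <- log
  log2$x <- task$width - log2$x
  coc2 <- center_of_cancellation(task2, assign_events(task2, log2))
  expect_equal(coc2, -coc1, tolerance = 1e-9)
})
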