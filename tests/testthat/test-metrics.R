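test_that("steps of the 3-4-5 track match the hand calculation", {
  s <- compute_steps(track_345())
  expect_equal(nrow(s), 2L)
  expect_equal(s$step_length, c(5, 10))
  expect_equal(s$dt, c(30, 60))  # gap-aware: frames 1 -> 3 span 60 min
  expect_equal(s$speed, c(1 / 6, 1 / 6))
  expect_equal(s$angle_deg, rep(atan2(4, 3) * 180 / pi, 2))
})

test_that("degenerate tracks produce the documented step records", {
  stat <- tt(data.frame(spot_id = 1:2, track_id = 1L, x = 5, y = 5, frame = 0:1))
  s <- compute_steps(stat)
  expect_equal(s$step_length, 0)
  expect_equal(s$speed, 0)
  expect_true(is.na(s$angle_deg))

  single <- tt(data.frame(spot_id = 1L, track_id = 1L, x = 0, y = 0, frame = 0L))
  expect_equal(nrow(compute_steps(single)), 0L)
})

test_that("track metrics reproduce the hand-computed fixtures", {
  m <- track_metrics(track_345())
  expect_equal(m$accumulated_distance, 15)
  expect_equal(m$euclidean_distance, 15)
  expect_equal(m$directionality_ratio, 1)
  expect_equal(m$mean_speed, 15 / 90)
  expect_equal(m$net_direction_deg, atan2(12, 9) * 180 / pi)

  zig <- tt(data.frame(spot_id = 1:3, track_id = 1L, x = c(0, 3, 6),
                       y = c(0, 4, 0), frame = 0:2))
  mz <- track_metrics(zig)
  expect_equal(mz$accumulated_distance, 10)
  expect_equal(mz$euclidean_distance, 6)
  expect_equal(mz$directionality_ratio, 0.6)

  stat <- tt(data.frame(spot_id = 1:2, track_id = 1L, x = 1, y = 1, frame = 0:1))
  ms <- track_metrics(stat)
  expect_equal(ms$accumulated_distance, 0)
  expect_true(is.na(ms$directionality_ratio))
  expect_true(is.na(ms$net_direction_deg))
})

test_that("euclidean <= accumulated with equality only for straight tracks", {
  for (seed in 1:5) {
    m <- track_metrics(random_track_table(n_tracks = 15, n_frames = 12,
                                          seed = seed))
    expect_true(all(m$euclidean_distance <= m$accumulated_distance + 1e-9))
  }
  straight <- tt(straight_track(1L, 0.3, 10, angle_deg = 37))
  ms <- track_metrics(straight)
  expect_equal(ms$euclidean_distance, ms$accumulated_distance)
})

test_that("dt-weighted mean of instantaneous speeds equals mean_speed exactly", {
  tab <- random_track_table(n_tracks = 20, n_frames = 15, seed = 11)
  s <- compute_steps(tab)
  m <- track_metrics(tab)
  for (id in m$track_id[m$n_points >= 2]) {
    si <- s[s$track_id == id, ]
    expect_equal(sum(si$speed * si$dt) / sum(si$dt),
                 m$mean_speed[m$track_id == id])
  }
})

test_that("metrics are invariant under global translation and rotation", {
  tab <- random_track_table(n_tracks = 8, n_frames = 10, seed = 3)
  phi <- 34 * pi / 180
  rot <- data.frame(
    spot_id = tab$spot_id, track_id = tab$track_id,
    x = 100 + cos(phi) * tab$x - sin(phi) * tab$y,
    y = -50 + sin(phi) * tab$x + cos(phi) * tab$y,
    frame = tab$frame)
  tab2 <- tt(rot)
  m1 <- track_metrics(tab)
  m2 <- track_metrics(tab2)
  expect_equal(m1$accumulated_distance, m2$accumulated_distance)
  expect_equal(m1$euclidean_distance, m2$euclidean_distance)
  expect_equal(m1$mean_speed, m2$mean_speed)
  expect_equal(m1$directionality_ratio, m2$directionality_ratio)
  # angles shift by exactly the rotation
  s1 <- compute_steps(tab)
  s2 <- compute_steps(tab2)
  shift <- normalize_angle_deg(s2$angle_deg - s1$angle_deg)
  expect_equal(shift, rep(34, nrow(s1)))
})

test_that("instantaneous series aggregates steps ending at each frame", {
  two <- rbind(straight_track(1L, 0.2, 6), straight_track(2L, 0.2, 6, y0 = 30))
  ser <- instantaneous_series(tt(two))
  expect_equal(ser$frame, 1:5)
  expect_equal(ser$n_cells, rep(2L, 5))
  expect_equal(ser$mean_speed, rep(0.2, 5))
  expect_equal(ser$sem_speed, rep(0, 5))

  one <- instantaneous_series(tt(straight_track(1L, 0.2, 4)))
  expect_true(all(is.na(one$sem_speed)))  # n < 2: SEM undefined

  # a track appearing from frame 10 adds to the census from frame 11 on
  late <- straight_track(3L, 0.1, 6, y0 = 60)
  late$frame <- late$frame + 10L
  late$spot_id <- late$spot_id + 500L
  ser2 <- instantaneous_series(tt(rbind(two, late)))
  expect_equal(ser2$n_cells[ser2$frame <= 5], rep(2L, 5))
  expect_equal(ser2$n_cells[ser2$frame >= 11], rep(1L, 5))
})

test_that("polar distribution follows the half-open bin convention", {
  h <- polar_distribution(c(90, 90, -90, -90), n_bins = 4)
  expect_equal(h$bin_edges_deg, c(-180, -90, 0, 90, 180))
  expect_equal(h$probabilities, c(0, 0.5, 0, 0.5))
  expect_equal(h$n_angles, 4L)
  # 180 closes the final bin; -180 wraps to 180
  h2 <- polar_distribution(c(180, -180), n_bins = 4)
  expect_equal(h2$probabilities, c(0, 0, 0, 1))

  empty <- polar_distribution(numeric(0), n_bins = 6)
  expect_equal(empty$probabilities, rep(0, 6))
  expect_equal(empty$n_angles, 0L)

  expect_error(polar_distribution(1:3, n_bins = 1), "n_bins")
})

test_that("polar probabilities sum to 1 for any bin count", {
  set.seed(5)
  for (nb in c(2, 7, 24, 36)) {
    h <- polar_distribution(runif(500, -180, 180), n_bins = nb)
    expect_equal(sum(h$probabilities), 1, tolerance = 1e-12)
  }
})

test_that("uniform angles fill polar bins evenly", {
  set.seed(99)
  n <- 10000
  h <- polar_distribution(runif(n, -180, 180), n_bins = 24)
  p0 <- 1 / 24
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(h$probabilities - p0) < 5 * se))
})

test_that("speed binning partitions tracks at the quartiles", {
  spots <- do.call(rbind, lapply(1:8, function(i)
    straight_track(i, i, 5, y0 = i * 100)))
  sb <- bin_by_speed(tt(spots), n_bins = 4)
  got <- lapply(sb$bins, `[[`, "track_ids")
  expect_equal(got, list(1:2, 3:4, 5:6, 7:8))
  expect_true(all(vapply(sb$bins, function(b) b$n_tracks, numeric(1)) == 2))

  # degenerate: identical speeds all land in one bin without error
  same <- do.call(rbind, lapply(1:5, function(i)
    straight_track(i, 0.5, 5, y0 = i * 100)))
  sb2 <- bin_by_speed(tt(same), n_bins = 4)
  sizes <- vapply(sb2$bins, function(b) b$n_tracks, numeric(1))
  expect_equal(sum(sizes), 5)
  expect_equal(sum(sizes > 0), 1L)

  expect_error(bin_by_speed(tt(spots), edges = c(1, 3, 2, 5)), "increasing")
})

test_that("every speed class shows contact guidance on a biased substrate", {
  sim <- simulate_spheroid(sim_config(n_cells_initial = 120, release_rate = 0,
                                      n_frames = 30, fiber_bias_kappa = 3,
                                      persistence_kappa = 0, p_detach = 0,
                                      cohesion_radius = 200, seed = 21))
  sb <- bin_by_speed(sim$table, n_bins = 4)
  for (b in sb$bins) {
    if (b$n_tracks == 0) next
    centers <- (b$histogram$bin_edges_deg[-1] +
                  b$histogram$bin_edges_deg[-25]) / 2
    # alignment order of the binned distribution about the fiber axis
    s_bin <- sum(b$histogram$probabilities * cos(2 * (centers - 90) * pi / 180))
    expect_gt(s_bin, 0.5)
  }
})

test_that("alignment order matches its closed forms", {
  expect_equal(alignment_order(rep(37, 50), 37), 1)
  expect_equal(alignment_order(c(0, 90), 0), 0)  # parallel + perpendicular
  expect_true(is.na(alignment_order(numeric(0), 0)))

  set.seed(12)
  u <- runif(10000, -180, 180)
  expect_lt(abs(alignment_order(u, 45)), 0.02)
})

test_that("alignment order is axially symmetric", {
  set.seed(8)
  a <- runif(200, -180, 180)
  flip <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  b <- ifelse(flip, a + 180, a)
  expect_equal(alignment_order(a, 30), alignment_order(b, 30))
})
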