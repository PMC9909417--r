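test_that("classify_frame reproduces the hand-computed example", {
  cls <- classify_frame(data.frame(x = c(0, 10, 100), y = 0), threshold = 40)
  expect_equal(cls$label, c("group", "group", "single"))
  expect_equal(cls$nn_distance, c(10, 10, 90))
})

test_that("boundary and degenerate cases follow the stated conventions", {
  # exactly at the threshold counts as group (strict inequality)
  cls <- classify_frame(data.frame(x = c(0, 40), y = 0), threshold = 40)
  expect_equal(cls$label, c("group", "group"))
  # a lone nucleus is single with undefined neighbour distance
  lone <- classify_frame(data.frame(x = 5, y = 5), threshold = 40)
  expect_equal(lone$label, "single")
  expect_true(is.na(lone$nn_distance))
  expect_error(classify_frame(data.frame(x = 0, y = 0), threshold = 0),
               "positive")
})

test_that("classification matches the brute-force all-pairs oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:120, 1)
    x <- runif(n, 0, 400)
    y <- runif(n, 0, 400)
    th <- runif(1, 5, 120)
    got <- classify_frame(data.frame(x = x, y = y), threshold = th)
    want <- brute_classify(x, y, th)
    expect_equal(got$label, want$label)
    expect_equal(got$nn_distance, want$nn, tolerance = 1e-12)
  }
})

test_that("nearest-neighbour distances are symmetrically consistent", {
  set.seed(4)
  cls <- classify_frame(data.frame(x = runif(60, 0, 300),
                                   y = runif(60, 0, 300)), threshold = 40)
  d <- cls$nn_distance
  # if a's nearest neighbour is at distance d, some cell has nn <= d;
  # check the global two-sided bound: min nn is attained by a mutual pair
  expect_equal(min(d), sort(d)[2], tolerance = 1e-12)
})

test_that("classification is invariant to rigid motion and input order", {
  set.seed(17)
  n <- 50
  pts <- data.frame(x = runif(n, 0, 200), y = runif(n, 0, 200),
                    spot_id = seq_len(n))
  base <- classify_frame(pts, threshold = 35)
  phi <- 1.1
  rot <- data.frame(x = 77 + cos(phi) * pts$x - sin(phi) * pts$y,
                    y = -3 + sin(phi) * pts$x + cos(phi) * pts$y,
                    spot_id = pts$spot_id)
  expect_equal(classify_frame(rot, threshold = 35)$label, base$label)
  perm <- sample(n)
  shuffled <- classify_frame(pts[perm, ], threshold = 35)
  expect_equal(shuffled$label[order(shuffled$spot_id)],
               base$label[order(base$spot_id)])
})

test_that("raising the threshold can only shrink the single set", {
  set.seed(23)
  for (rep in 1:10) {
    tab <- random_track_table(n_tracks = sample(5:25, 1), n_frames = 6,
                              seed = 1000 + rep, field = 250)
    sweep <- threshold_sweep(tab, c(30, 50, 100))
    for (f in unique(sweep$frame)) {
      s30 <- sweep$single_ids[sweep$threshold == 30 & sweep$frame == f][[1]]
      s50 <- sweep$single_ids[sweep$threshold == 50 & sweep$frame == f][[1]]
      s100 <- sweep$single_ids[sweep$threshold == 100 & sweep$frame == f][[1]]
      expect_true(all(s100 %in% s50))
      expect_true(all(s50 %in% s30))
    }
  }
})

test_that("dispersion time series censuses every frame", {
  cluster <- data.frame(spot_id = 1:3, track_id = 1:3,
                        x = c(0, 10, 20), y = 0, frame = 0L)
  later <- rbind(
    data.frame(spot_id = 4:6, track_id = 1:3, x = c(0, 10, 20), y = 0,
               frame = 1L),
    data.frame(spot_id = 7L, track_id = 4L, x = 220, y = 0, frame = 1L))
  d <- dispersion_timeseries(tt(rbind(cluster, later)), threshold = 40)
  expect_equal(d$frame, 0:1)
  expect_equal(d$n_total, c(3L, 4L))
  expect_equal(d$n_single, c(0L, 1L))
  expect_equal(d$ratio, c(0, 0.25))
  expect_equal(d$single_ids[[2]], 7L)
})

test_that("threshold_sweep with one threshold equals the plain series", {
  tab <- random_track_table(n_tracks = 10, n_frames = 5, seed = 6)
  sw <- threshold_sweep(tab, 40)
  ts <- dispersion_timeseries(tab, 40)
  expect_equal(sw$n_single, ts$n_single)
  expect_equal(sw$ratio, ts$ratio)
})

test_that("class-split statistics separate fast singles from slow groups", {
  # three clustered slow tracks and one detached fast track
  group <- do.call(rbind, lapply(1:3, function(i)
    straight_track(i, 0.1, 6, x0 = 0, y0 = i * 10)))
  single <- straight_track(9L, 0.4, 6, x0 = 500, y0 = 0)
  tab <- tt(rbind(group, single))
  cls <- classify_table(tab, threshold = 60)
  split <- split_metrics_by_class(tab, cls)
  s <- split$series
  expect_equal(unique(s$mean_speed[s$label == "single"]), 0.4)
  expect_equal(unique(s$mean_speed[s$label == "group"]), 0.1)
  expect_equal(unique(s$n[s$label == "group"]), 3L)
})

test_that("with no single cells the group series equals the unsplit series", {
  group <- do.call(rbind, lapply(1:3, function(i)
    straight_track(i, 0.2, 5, y0 = i * 10)))
  tab <- tt(group)
  cls <- classify_table(tab, threshold = 100)
  split <- split_metrics_by_class(tab, cls)
  expect_true(all(split$series$label == "group"))
  ser <- instantaneous_series(tab)
  expect_equal(split$series$mean_speed, ser$mean_speed)
  expect_equal(split$series$n, ser$n_cells)
})

test_that("class-split speeds satisfy the weighted-mean identity per frame", {
  for (seed in c(2, 9)) {
    tab <- random_track_table(n_tracks = 20, n_frames = 8, seed = seed,
                              field = 300)
    cls <- classify_table(tab, threshold = 45)
    split <- split_metrics_by_class(tab, cls)
    ser <- instantaneous_series(tab)
    for (f in ser$frame) {
      sf <- split$series[split$series$frame == f, ]
      expect_equal(sum(sf$n * sf$mean_speed),
                   ser$n_cells[ser$frame == f] * ser$mean_speed[ser$frame == f])
    }
  }
})

test_that("steps without a covering classification raise an integrity error", {
  tab <- tt(straight_track(1L, 0.2, 5))
  cls <- classify_table(tab, 40)
  cls <- cls[cls$frame != 3L, ]
  expect_error(split_metrics_by_class(tab, cls), "frame 3")
})

test_that("overlay frames are deterministic and colour-coded at known pixels", {
  group <- data.frame(spot_id = 1:2, track_id = 1:2,
                      x = c(40, 60), y = 50, frame = 0L)
  single <- data.frame(spot_id = 3L, track_id = 3L, x = 300, y = 250,
                       frame = 0L)
  spots <- rbind(group, single,
                 transform(rbind(group, single), frame = 1L,
                           spot_id = spot_id + 10L),
                 transform(rbind(group, single), frame = 2L,
                           spot_id = spot_id + 20L))
  tab <- tt(spots)
  cls <- classify_table(tab, threshold = 40)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- render_overlay(tab, cls, d1, width = 200)
  p2 <- render_overlay(tab, cls, d2, width = 200)
  expect_length(p1, 3L)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  img <- png::readPNG(p1[1])
  h <- dim(img)[1]
  to_px <- function(xw, yw, xr, yr, w) {
    sc <- (w - 1) / diff(xr)
    c(col = round((xw - xr[1]) * sc) + 1, row = h - round((yw - yr[1]) * sc))
  }
  xr <- range(tab$x) + c(-20, 20)
  yr <- range(tab$y) + c(-20, 20)
  pg <- to_px(40, 50, xr, yr, 200)
  ps <- to_px(300, 250, xr, yr, 200)
  expect_equal(as.numeric(img[pg["row"], pg["col"], 1:3]), rep(0.5, 3),
               tolerance = 0.01)
  expect_equal(as.numeric(img[ps["row"], ps["col"], 1:3]), c(0.84, 0.16, 0.16),
               tolerance = 0.01)
  # background stays white away from everything
  expect_equal(as.numeric(img[h - 4, dim(img)[2] - 4, 1:3]), c(1, 1, 1))
})

test_that("a time point with no nuclei still renders a stamped blank frame", {
  spots <- rbind(data.frame(spot_id = 1:2, track_id = 1:2, x = c(0, 30),
                            y = 0, frame = 0L),
                 data.frame(spot_id = 3:4, track_id = 1:2, x = c(0, 30),
                            y = 0, frame = 2L))
  tab <- tt(spots)
  cls <- classify_table(tab, 40)
  d <- withr::local_tempdir()
  p <- render_overlay(tab, cls, d, width = 120)
  expect_length(p, 3L)  # frames 0, 1, 2
  img <- png::readPNG(p[2])
  # stamp present (some dark pixels), nothing else drawn
  expect_true(any(img[1:20, , 1] < 0.5))
  expect_true(all(img[30:nrow(img), , ] == 1))
})
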