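prj <- default_projection()

# fixes at given local (UTC+1) clock times around a planar point
make_fixes <- function(bird, local_times, x = 0, y = 0, jitter = 0) {
  ts <- as.POSIXct(local_times, tz = "Etc/GMT-1")
  n <- length(ts)
  xx <- x + if (jitter > 0) rnorm(n, 0, jitter) else rep(0, n)
  yy <- y + if (jitter > 0) rnorm(n, 0, jitter) else rep(0, n)
  ll <- unproject_xy(cbind(xx, yy), prj)
  data.frame(bird_id = bird, timestamp = ts, lon = ll[, 1], lat = ll[, 2],
             x = xx, y = yy)
}

test_that("night extraction keeps dusk-to-dawn fixes and takes medians", {
  # civil dusk on 1 Dec 2020 is ~17:20 local, dawn on 2 Dec ~07:22 local
  fx <- rbind(
    make_fixes("A", c("2020-12-01 16:00:00",  # before dusk: excluded
                      "2020-12-01 18:00:00", "2020-12-01 19:00:00",
                      "2020-12-01 20:00:00")),
    make_fixes("A", "2020-12-02 07:00:00"))   # before dawn: joins night Dec 1
  nl <- extract_night_locations(fx)
  expect_equal(nrow(nl), 1)
  expect_equal(nl$night_date, as.Date("2020-12-01"))
  expect_equal(nl$n_fixes, 4L)
})

test_that("an odd count of collinear fixes yields the middle fix as median", {
  fx <- make_fixes("A", paste("2020-12-01", c("18:00:00", "19:00:00", "20:00:00")))
  fx$x <- c(0, 50, 400); fx$y <- 2 * fx$x + 1
  nl <- extract_night_locations(fx)
  expect_equal(nl$x, 50)
  expect_equal(nl$y, 101)
})

test_that("hand-built three-bird fixture reproduces hand-computed medians", {
  fx <- rbind(
    make_fixes("A", paste("2020-12-05", c("18:00:00", "19:00:00"))),
    make_fixes("B", paste("2020-12-05", c("18:00:00", "19:00:00", "20:00:00"))),
    make_fixes("C", "2020-12-05 20:00:00"))
  fx$x <- c(10, 30, 100, 120, 140, -5)
  fx$y <- c(0, 6, 9, 9, 15, 2)
  nl <- extract_night_locations(fx)
  expect_equal(nl$x[nl$bird_id == "A"], 20)   # mean of two = median
  expect_equal(nl$y[nl$bird_id == "A"], 3)
  expect_equal(nl$x[nl$bird_id == "B"], 120)
  expect_equal(nl$x[nl$bird_id == "C"], -5)
})

test_that("interval assignment follows the Nov 1 calendar blocking", {
  nights <- data.frame(
    bird_id = "A",
    night_date = as.Date(c("2019-11-01", "2019-11-05", "2019-11-06",
                           "2019-12-31", "2020-01-30", "2020-01-31")),
    x = 0, y = 0, n_fixes = 1L)
  ann <- assign_intervals(nights)
  expect_equal(ann$interval_index, c(1L, 1L, 2L, 13L, 19L, 19L))
  expect_true(all(ann$winter_id == 2019L))
  # out-of-window nights are dropped with a message
  nights2 <- rbind(nights, data.frame(bird_id = "A",
                                      night_date = as.Date("2020-03-15"),
                                      x = 0, y = 0, n_fixes = 1L))
  expect_message(ann2 <- assign_intervals(nights2), "dropped")
  expect_equal(nrow(ann2), nrow(nights))
})

block_nights <- function(df) {
  df$n_fixes <- 1L
  assign_intervals(df)
}

test_that("twelve birds within 300 m on one night are all communal", {
  set.seed(1)
  nights <- block_nights(data.frame(
    bird_id = sprintf("B%02d", 1:12),
    night_date = as.Date("2020-11-16"),
    x = runif(12, 0, 120), y = runif(12, 0, 120)))
  det <- detect_attendance(nights)
  expect_true(all(det$units$attendance == 1))
  expect_true(all(det$units$n_neighbours == 11))
})

test_that("a single neighbour is below the communal threshold", {
  nights <- block_nights(data.frame(
    bird_id = rep(c("A", "B"), each = 5),
    night_date = rep(seq(as.Date("2020-11-01"), by = "day", length.out = 5), 2),
    x = rep(c(0, 100), each = 5), y = 0))
  det <- detect_attendance(nights)
  expect_true(all(det$units$n_neighbours == 1))
  expect_true(all(det$units$attendance == 0))
})

test_that("cross-night matching counts non-simultaneous neighbours, same-night does not", {
  nights <- block_nights(data.frame(
    bird_id = c("A", "A", "B", "C"),
    night_date = as.Date(c("2020-11-02", "2020-11-04", "2020-11-01", "2020-11-03")),
    x = c(0, 0, 100, 150), y = 0))
  cross <- detect_attendance(nights, detection_config(matching = "cross_night"))
  same <- detect_attendance(nights, detection_config(matching = "same_night"))
  a_cross <- cross$units[cross$units$bird_id == "A", ]
  a_same <- same$units[same$units$bird_id == "A", ]
  expect_equal(a_cross$n_neighbours, 2L)
  expect_equal(a_cross$attendance, 1L)
  expect_equal(a_same$n_neighbours, 0L)
  expect_equal(a_same$attendance, 0L)
})

test_that("a pair exactly at the radius counts as inside (closed ball)", {
  nights <- block_nights(data.frame(
    bird_id = c("A", "B", "C"), night_date = as.Date("2020-11-16"),
    x = c(0, 300, -300), y = 0))
  det <- detect_attendance(nights)
  expect_equal(det$units$n_neighbours[det$units$bird_id == "A"], 2L)
  expect_equal(det$units$attendance[det$units$bird_id == "A"], 1L)
})

test_that("detection matches the brute-force oracle on random fixtures", {
  for (seed in 1:4) {
    nights <- make_random_nights(n_birds = 15, nights_per_bird = 8, seed = seed)
    for (matching in c("cross_night", "same_night")) {
      det <- detect_attendance(nights, detection_config(matching = matching))
      oracle <- brute_force_attendance(nights, 300, 2, matching)
      expect_equal(det$units$n_neighbours, oracle$n_neighbours)
      expect_equal(det$units$attendance, oracle$attendance)
    }
  }
})

test_that("attendance is monotone in radius, window and min_others", {
  nights <- make_random_nights(n_birds = 25, nights_per_bird = 12, seed = 9)
  det300 <- detect_attendance(nights, detection_config(radius = 300))
  det600 <- detect_attendance(nights, detection_config(radius = 600))
  expect_true(all(det600$units$n_neighbours >= det300$units$n_neighbours))
  expect_true(all(det600$units$attendance >= det300$units$attendance))
  det_m3 <- detect_attendance(nights, detection_config(min_others = 3))
  expect_true(all(det_m3$units$attendance <= det300$units$attendance))
  # shrinking the window cannot create attendance (cross-night containment)
  n1 <- assign_intervals(nights[, setdiff(names(nights),
                                          c("winter_id", "interval_index", "interval_t"))],
                         window = 1)
  det_w1 <- detect_attendance(n1, detection_config(window = 1))
  per_bird_w1 <- tapply(det_w1$units$attendance, det_w1$units$bird_id, sum)
  per_bird_w5 <- tapply(det300$units$attendance * 5, det300$units$bird_id, sum)
  expect_true(all(per_bird_w1 <= per_bird_w5[names(per_bird_w1)]))
})

test_that("roost-site clustering is single linkage", {
  nights <- data.frame(
    bird_id = c("A", "B", "C"), night_date = as.Date("2020-12-01"),
    x = c(0, 250, 500), y = 0, n_fixes = 1L)
  sites <- cluster_roost_sites(nights)
  expect_equal(nrow(sites), 1)        # chain A-B-C links despite A-C = 500 m
  expect_equal(sites$n_tagged, 3L)
  expect_equal(sites$x, 250)
  nights2 <- rbind(nights, data.frame(bird_id = "D",
                                      night_date = as.Date("2020-12-01"),
                                      x = 10000, y = 0, n_fixes = 1L))
  sites2 <- cluster_roost_sites(nights2)
  expect_equal(nrow(sites2), 2)
  expect_equal(sites2$n_tagged[sites2$member_ids == "D"], 1L)
})

test_that("study-area weights follow the scaled margin-distance formula", {
  area <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  nights <- block_nights(data.frame(
    bird_id = c("A", "B", "C"), night_date = as.Date("2020-11-16"),
    x = c(500, 2000, 1500), y = 500))
  det <- detect_attendance(nights)
  units <- compute_weights(det$units, det$nights, area)
  w <- units$weight[match(c("A", "B", "C"), units$bird_id)]
  expect_equal(w, c(1, 0, 0.5), tolerance = 1e-12)
  # all inside: everyone gets weight 1
  inside <- block_nights(data.frame(
    bird_id = c("A", "B"), night_date = as.Date("2020-11-16"),
    x = c(100, 900), y = 500))
  det_i <- detect_attendance(inside)
  expect_true(all(compute_weights(det_i$units, det_i$nights, area)$weight == 1))
})

test_that("sensitivity sweep is monotone over its grid", {
  nights <- make_random_nights(n_birds = 18, nights_per_bird = 10, seed = 3)
  raw <- nights[, c("bird_id", "night_date", "x", "y", "n_fixes")]
  sw <- sensitivity_sweep(raw, radii = c(150, 300, 600), windows = c(1, 5),
                          min_others_grid = c(1, 2, 3))
  expect_equal(nrow(sw), 18)
  for (w in unique(sw$window)) for (m in unique(sw$min_others)) {
    s <- sw[sw$window == w & sw$min_others == m, ]
    expect_true(all(diff(s$attendance_rate[order(s$radius)]) >= 0))
  }
  for (r in unique(sw$radius)) for (w in unique(sw$window)) {
    s <- sw[sw$radius == r & sw$window == w, ]
    expect_true(all(diff(s$attendance_rate[order(s$min_others)]) <= 0))
  }
  expect_error(sensitivity_sweep(raw, radii = numeric()), "empty")
})
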