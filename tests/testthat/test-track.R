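fake_frame <- function(x, y, cls = 1L) {
  data.frame(centroid_x_um = x, centroid_y_um = y, cls = cls)
}

test_that("a stationary detection yields one full-length track", {
  frames <- replicate(5, fake_frame(30, 40, 2L), simplify = FALSE)
  tr <- link_tracks(frames, tracker_params())
  expect_length(tr, 1L)
  expect_equal(nrow(tr[[1]]$members), 5L)
  expect_false(tr[[1]]$dynamic)
})

test_that("detections beyond 5 um of the anchor are not linked", {
  frames <- list(fake_frame(30, 40), fake_frame(30, 46),  # 6 um away
                 fake_frame(30, 40), fake_frame(30, 40), fake_frame(30, 40))
  tr <- link_tracks(frames, tracker_params(require_full_length = FALSE))
  expect_equal(nrow(tr[[1]]$members), 4L)  # frame 2 unmatched
  tr2 <- link_tracks(frames, tracker_params())
  expect_length(tr2, 0L)
  # 4.9 um is linked
  frames[[2]] <- fake_frame(30, 44.9)
  tr3 <- link_tracks(frames, tracker_params())
  expect_equal(nrow(tr3[[1]]$members), 5L)
})

test_that("unmatched detections start no new tracks and tracks never share detections", {
  frames <- list(fake_frame(30, 40),
                 fake_frame(c(30, 90), c(40, 90)),
                 fake_frame(c(30, 90), c(40, 90)),
                 fake_frame(30, 40), fake_frame(30, 40))
  tr <- link_tracks(frames, tracker_params(require_full_length = FALSE))
  expect_length(tr, 1L)
  used <- do.call(rbind, lapply(tr, function(t) t$members[, c("frame", "det_index")]))
  expect_false(any(duplicated(used)))
})

test_that("greedy linking equals exhaustive minimum-distance matching on sparse instances", {
  set.seed(99)
  for (trial in 1:6) {
    n <- sample(4:8, 1)
    # anchors with pairwise spacing >= 12 um
    repeat {
      anchors <- cbind(runif(n, 10, 118), runif(n, 10, 118))
      if (min(dist(anchors)) >= 12) break
    }
    frames <- list(fake_frame(anchors[, 1], anchors[, 2]))
    pos <- anchors
    for (k in 2:5) {
      pos <- pos + matrix(runif(2 * n, -1, 1), n, 2)  # drift <= 1 um/frame
      perm <- sample(n)                               # detector order varies
      frames[[k]] <- fake_frame(pos[perm, 1], pos[perm, 2])
    }
    greedy <- link_tracks(frames, tracker_params())
    oracle <- brute_force_tracks(frames)
    expect_length(greedy, n)
    for (tr in greedy) {
      i <- tr$members$det_index[1]
      for (k in 2:5)
        expect_equal(tr$members$det_index[tr$members$frame == k],
                     oracle[[k - 1]][i])
    }
  }
})

test_that("dynamic calls require both classes in the sequence", {
  expect_equal(classify_dynamics(c(2, 2, 1, 2, 2)), "dynamic")
  expect_equal(classify_dynamics(c(2, 2, 2, 2, 2)), "static")
  expect_equal(classify_dynamics(c(1, 1, 1, 1, 1)), "static")
  expect_error(classify_dynamics(integer(0)), "empty")
})

test_that("frame count mismatches are rejected", {
  frames <- replicate(4, fake_frame(30, 40), simplify = FALSE)
  expect_error(link_tracks(frames, tracker_params(frame_count = 5L)), "frames")
})

test_that("target selection honors policy and capture radius", {
  det <- data.frame(centroid_x_um = c(64 + 5, 64 + 30),
                    centroid_y_um = c(64, 64), cls = c(2L, 2L))
  one <- select_targets(det, "center_only", qualify = "class2")
  expect_equal(nrow(one), 1L)
  expect_equal(one$x_um, 69)
  all_t <- select_targets(det, "anywhere", qualify = "class2")
  expect_equal(nrow(all_t), 2L)
  none <- select_targets(det[0, ], "anywhere")
  expect_equal(nrow(none), 0L)
  # dynamic tracks qualify in video mode
  frames <- list(fake_frame(60, 60, 2L), fake_frame(60, 60, 1L),
                 fake_frame(60, 60, 2L), fake_frame(60, 60, 2L),
                 fake_frame(60, 60, 2L))
  tracks <- link_tracks(frames, tracker_params())
  tg <- select_targets(tracks, "center_only")
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$reason, "dynamic")
})

test_that("pulsing detection probability matches the closed-form phase integral", {
  frame_times <- seq(0, 48, by = 12)
  mc_prob <- function(period, n = 4000) {
    set.seed(7)
    phases <- runif(n, 0, 2 * pi)
    mean(vapply(phases, function(ph) {
      osc <- list(mode = "pulsing", period_s = period, phase = ph)
      cls <- vapply(frame_times, function(t)
        if (membrane_fraction(osc, t)$m > 0.5) 2L else 1L, 0L)
      classify_dynamics(cls) == "dynamic"
    }, logical(1)))
  }
  # at period 24 every 12-s sampling alternates halves: always dynamic
  expect_equal(pulsing_dynamic_probability(24, frame_times), 1)
  expect_equal(mc_prob(24), 1)
  # a slow pulser whose samples cluster in phase has a nontrivial probability
  p150 <- pulsing_dynamic_probability(150, frame_times)
  expect_gt(p150, 0); expect_lt(p150, 1)
  expect_lt(abs(mc_prob(150) - p150), 3 * sqrt(p150 * (1 - p150) / 4000))
  # pole-to-pole and circling stay class 2 throughout: never called dynamic
  for (mode in c("pole_to_pole", "circling")) {
    osc <- list(mode = mode, period_s = 24, phase = 1, axis_angle = 0)
    ms <- vapply(frame_times, function(t) membrane_fraction(osc, t)$m, 0)
    expect_true(all(ms > 0.5))
  }
})

test_that("track output writers produce CSV and JSON summaries", {
  frames <- replicate(5, fake_frame(c(30, 80), c(30, 80), c(2L, 1L)),
                      simplify = FALSE)
  tracks <- link_tracks(frames, tracker_params())
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_tracks(tracks, csv, js)
  flat <- read.csv(csv)
  expect_equal(nrow(flat), 10L)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(summ), 2L)
})
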