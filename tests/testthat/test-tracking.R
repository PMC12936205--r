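test_that("stationary well-separated features give one full track each", {
  feats <- data.frame(frame = rep(1:10, each = 2),
                      x = rep(c(10, 40), 10), y = rep(c(10, 40), 10),
                      intensity = 1)
  tr <- link(feats, search_range = 5, memory = 2)
  expect_equal(length(unique(tr$track)), 2)
  expect_true(all(table(tr$track) == 10))
})

test_that("predictive linking preserves identities where nearest-neighbour swaps", {
  t <- 0:19
  feats <- rbind(
    data.frame(frame = t + 1, x = 5 + 2 * t, y = 5 + 2 * t, intensity = 1),
    data.frame(frame = t + 1, x = 5 + 2 * t, y = 44 - 2 * t, intensity = 1))
  ends_of_start <- function(tracks) {
    d <- tracks[order(tracks$frame), ]
    id <- d$track[d$frame == 1 & d$y == 5]
    last <- d[d$track == id, ]
    unlist(last[nrow(last), c("x", "y")], use.names = FALSE)
  }
  pred <- link(feats, search_range = 5, memory = 2, predictive = TRUE)
  expect_equal(ends_of_start(pred), c(43, 43))
  # the zero-velocity (nearest-neighbour) oracle swaps at the crossing
  nn <- link(feats, search_range = 5, memory = 2, predictive = FALSE)
  expect_false(identical(ends_of_start(nn), c(43, 43)))
})

test_that("linking partitions the features (no feature in two tracks)", {
  fix <- tiny_movie("primary")
  feats <- detect_features(fix$movie$tcr, geometry = fix$gt$geometry)
  tr <- link(feats)
  expect_equal(nrow(tr), nrow(feats))
  expect_false(any(duplicated(tr[, c("frame", "x", "y")])))
})

test_that("noiseless re-detection of generator paths reproduces them exactly", {
  gt <- tiny_gt("primary", seed = 21)
  feats <- data.frame(frame = gt$clusters$frame, x = gt$clusters$x,
                      y = gt$clusters$y, intensity = 1)
  tr <- link(feats, search_range = 5, memory = 2)
  key_truth <- paste(gt$clusters$frame, round(gt$clusters$x, 6),
                     round(gt$clusters$y, 6))
  key_out <- paste(tr$frame, round(tr$x, 6), round(tr$y, 6))
  truth_id <- gt$clusters$cluster[match(key_out, key_truth)]
  # every linked track corresponds to exactly one true cluster, fully
  by_track <- split(truth_id, tr$track)
  expect_true(all(vapply(by_track, function(v) length(unique(v)) == 1,
                         logical(1))))
  expect_equal(length(by_track), length(unique(gt$clusters$cluster)))
})

test_that("the motility filter keeps the 3.5-px boundary case", {
  tr <- rbind(
    data.frame(track = 1, frame = 1:5, x = 10, y = 10, intensity = 1),
    data.frame(track = 2, frame = 1:5, x = 10 + (0:4) * 2.5, y = 10,
               intensity = 1),
    data.frame(track = 3, frame = 1:5, x = 10 + (0:4) * 0.875, y = 10,
               intensity = 1))
  kept <- unique(filter_motile(tr)$track)
  expect_false(1 %in% kept)       # stationary: removed
  expect_true(2 %in% kept)        # 10 px displacement: kept
  expect_true(3 %in% kept)        # exactly 3.5 px: kept
})

test_that("direction classification is antisymmetric under time reversal", {
  g <- flat_geometry()
  out <- data.frame(frame = 1:5, x = g$center[1] + seq(20, 40, 5),
                    y = g$center[2])
  expect_equal(classify_direction(out, g), "anterograde")
  rev <- out; rev$frame <- rev(rev$frame)
  expect_equal(classify_direction(rev, g), "retrograde")
})

test_that("direction labels are invariant to rotation about the centre", {
  g <- flat_geometry()
  set.seed(42)
  for (i in 1:10) {
    r <- cumsum(c(runif(1, 12, 30), runif(7, -3, 3)))
    a <- runif(1, -pi, pi)
    tr <- data.frame(frame = 1:8, x = g$center[1] + r * cos(a),
                     y = g$center[2] + r * sin(a))
    lab <- classify_direction(tr, g)
    phi <- runif(1, -pi, pi)
    rot <- tr
    dx <- tr$x - g$center[1]; dy <- tr$y - g$center[2]
    rot$x <- g$center[1] + dx * cos(phi) - dy * sin(phi)
    rot$y <- g$center[2] + dx * sin(phi) + dy * cos(phi)
    expect_equal(classify_direction(rot, g), lab)
  }
})

test_that("track speed converts pixel steps to nm/s", {
  tr <- data.frame(frame = 1:10, x = 1:10, y = 3)
  expect_equal(track_speed(tr, 41.6, 1), 41.6)
  expect_equal(track_speed(tr, 41.6, 0.5), 83.2)
  still <- data.frame(frame = 1:10, x = 5, y = 5)
  expect_equal(track_speed(still, 41.6, 1), 0)
  expect_error(track_speed(still[1, ], 41.6, 1), "2 points")
})

test_that("radial normalization maps the annulus onto [0, 1]", {
  g <- flat_geometry(cell_radius = 40, csmac_radius = 10)
  expect_equal(radial_normalize(g$center[1] + 10, g$center[2], g), 0)
  expect_equal(radial_normalize(g$center[1] + 40, g$center[2], g), 1)
  expect_equal(radial_normalize(g$center[1], g$center[2] + 25, g), 0.5)
  bad <- g; bad$csmac_radius <- bad$cell_radius
  expect_error(radial_normalize(1, 1, bad), "degenerate")
})

test_that("directional summary fractions and counts are consistent", {
  g <- flat_geometry()
  mk <- function(id, r0, r1) data.frame(track = id, frame = 1:2,
                                        x = g$center[1] + c(r0, r1),
                                        y = g$center[2], intensity = id)
  tracks <- do.call(rbind, c(lapply(1:4, function(i) mk(i, 15, 25)),
                             lapply(5:10, function(i) mk(i, 25, 15))))
  ts <- summarize_tracks(tracks, g, 41.6, 1)
  df <- directional_fraction(ts)
  expect_equal(df$anterograde_fraction, 0.4)
  expect_equal(df$n_anterograde + df$n_retrograde + df$n_tie, df$n_tracks)
})

test_that("intensity histograms are probability densities per direction", {
  g <- flat_geometry()
  set.seed(3)
  tracks <- do.call(rbind, lapply(1:30, function(i) {
    dir <- if (i %% 2) 1 else -1
    data.frame(track = i, frame = 1:3,
               x = g$center[1] + 20 + dir * (0:2) * 3,
               y = g$center[2], intensity = runif(1, 50, 250))
  }))
  ts <- summarize_tracks(tracks, g, 41.6, 1)
  h <- intensity_density(ts, bins = 10)
  for (d in names(h)) {
    w <- diff(h[[d]]$bin_edges)
    expect_equal(sum(h[[d]]$density * w), 1, tolerance = 1e-9)
  }
})
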