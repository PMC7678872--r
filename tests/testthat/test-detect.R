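test_that("single spike on a flat trace is called exactly once", {
  tr <- rep(100, 200)
  tr[61] <- 150                               # baseline + 50, sd ~ 0
  p <- detect_peaks(tr)
  expect_equal(nrow(p), 1)
  expect_equal(p$frame, 60L)                  # 0-based
  expect_equal(p$amplitude, 50)
  # strictly constant trace: no local maximum, no peaks
  expect_equal(nrow(detect_peaks(rep(5, 100))), 0)
  expect_error(detect_peaks(c(1, NA, 3)), "finite")
  expect_error(detect_peaks(rep(1, 10)), "shorter")
})

test_that("peak calls match a brute-force oracle on noisy spike trains", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 3000
    tr <- rnorm(n, 100, 1)
    spikes <- sample(30:(n - 30), 40)
    tr[spikes] <- tr[spikes] + runif(40, 4, 12)   # SNR ~ 4-12
    got <- detect_peaks(tr)
    expect_equal(got$frame, oracle_peaks(tr))
  }
})

test_that("min-separation keeps the larger of two close peaks", {
  tr <- rep(0, 100)
  tr[50] <- 30
  tr[52] <- 40                                # within 3 frames of frame 49
  p <- detect_peaks(tr, min_separation_frames = 3)
  expect_equal(p$frame, 51L)
  p2 <- detect_peaks(tr, min_separation_frames = 2)
  expect_equal(p2$frame, c(49L, 51L))
})

test_that("spillover rule removes same-frame lower neighbours only", {
  # 30 x 10 mask -> 3 vertically stacked squares; 1-2 and 2-3 adjacent,
  # 1-3 not adjacent
  g <- partition_grid(matrix(TRUE, 30, 10))
  expect_equal(nrow(g$squares), 3)
  pk <- function(sq, fr, amp) data.frame(square_id = sq, frame = fr,
                                         amplitude = amp)
  # neighbours A(100) and B(60): B removed
  out <- reject_spillover(pk(c(1, 2), c(7, 7), c(100, 60)), g)
  expect_equal(out$square_id, 1)
  # same-frame peaks in non-adjacent squares: both kept
  out2 <- reject_spillover(pk(c(1, 3), c(7, 7), c(100, 60)), g)
  expect_equal(out2$square_id, c(1, 3))
  # equal amplitudes in neighbours: lower square id survives
  out3 <- reject_spillover(pk(c(2, 3), c(4, 4), c(80, 80)), g)
  expect_equal(out3$square_id, 2)
  # chain A(100)-B(80)-C(60): B removed by A, C removed by B's raw peak
  out4 <- reject_spillover(pk(c(1, 2, 3), c(9, 9, 9), c(100, 80, 60)), g)
  expect_equal(out4$square_id, 1)
  # different frames never interact
  out5 <- reject_spillover(pk(c(1, 2), c(3, 4), c(100, 60)), g)
  expect_equal(nrow(out5), 2)
  expect_error(reject_spillover(pk(9, 1, 10), g), "unknown square")
})

test_that("spillover rejection matches brute-force rule on random peak sets", {
  g <- partition_grid(matrix(TRUE, 40, 40))   # 4 x 4 grid
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    pk <- data.frame(square_id = sample(16, n, replace = TRUE),
                     frame = sample(1:4, n, replace = TRUE),
                     amplitude = sample(seq(10, 100, 10), n, replace = TRUE))
    pk <- pk[!duplicated(pk[, c("square_id", "frame")]), ]
    got <- reject_spillover(pk, g)
    want <- oracle_spillover(pk, g)
    expect_equal(got[, c("square_id", "frame", "amplitude")],
                 want[order(want$frame, want$square_id), ],
                 ignore_attr = TRUE)
    # never increases the count; isolated peaks always survive
    expect_lte(nrow(got), nrow(pk))
  }
})

test_that("a noise-free flash yields exactly one event at the right place", {
  geom <- tiny_geometry()
  grid <- partition_grid(geom$mask)
  # an interior event, well inside one square
  ev <- make_events(frame = 30, x_px = 14.2, y_px = 13.6, amplitude = 400)
  mov <- render_clean(ev, geom, 100)
  det <- detect_events(mov, geom)
  expect_equal(nrow(det), 1)
  expect_equal(det$frame, 30L)
  expect_equal(det$square_id, locate_square(grid, 14.2, 13.6))

  # a flash centred on a grid corner (PSF split over 4 squares):
  # spillover rejection must leave exactly one surviving event
  corner_x <- grid$origin[2] + 10 - 0.5
  corner_y <- grid$origin[1] + 10 - 0.5
  ev2 <- make_events(frame = 30, x_px = corner_x, y_px = corner_y,
                     amplitude = 400)
  det2 <- detect_events(render_clean(ev2, geom, 100), geom)
  expect_equal(nrow(det2), 1)
  expect_equal(det2$frame, 30L)
})

test_that("rate normalization follows the events/100um^2/min definition", {
  expect_equal(normalize_rate(6, 100, 60)$rate_per_100um2_min, 6)
  expect_equal(normalize_rate(5, 200, 120)$rate_per_100um2_min, 1.25)
  expect_equal(normalize_rate(0, 57, 33)$rate_per_100um2_min, 0)
  # exact scaling laws
  r <- normalize_rate(12, 150, 90)$rate_per_100um2_min
  expect_equal(normalize_rate(12, 300, 90)$rate_per_100um2_min, r / 2)
  expect_equal(normalize_rate(12, 150, 180)$rate_per_100um2_min, r / 2)
  expect_error(normalize_rate(3, 0, 60), "positive")
  expect_error(normalize_rate(3, 100, -5), "positive")
})

test_that("truth matching is exact on perfect detections and flags empties", {
  geom <- tiny_geometry()
  grid <- partition_grid(geom$mask)
  truth <- make_events(c(10, 40, 70), c(10.2, 20.1, 15.5),
                       c(12.3, 18.8, 22.9), c(300, 280, 320))
  det <- detect_events(render_clean(truth, geom, 100), geom)
  m <- match_to_truth(det, truth, grid)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)

  none <- det[0, ]
  m0 <- match_to_truth(none, truth, grid)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_true(m0$no_detections)
})

test_that("greedy matching is near-optimal on random small instances", {
  skip_if_not_installed("igraph")
  geom <- cell_geometry(matrix(TRUE, 30, 30))
  grid <- partition_grid(geom$mask)
  set.seed(5)
  for (rep in 1:15) {
    nt <- sample(2:6, 1); nd <- sample(2:6, 1)
    truth <- make_events(sample(0:20, nt, TRUE), runif(nt, 1, 29),
                         runif(nt, 1, 29), rep(100, nt))
    truth$event_id <- seq_len(nt)
    det <- data.frame(event_id = seq_len(nd),
                      square_id = sample(grid$squares$id, nd, TRUE),
                      frame = sample(0:20, nd, TRUE), amplitude = 100)
    m <- match_to_truth(det, truth, grid, frame_tolerance = 2)
    # brute-force optimal bipartite matching over the compatibility graph
    tr_sq <- locate_square(grid, truth$x_px, truth$y_px)
    edges <- integer(0)
    for (i in seq_len(nd)) for (j in seq_len(nt)) {
      if (tr_sq[j] %in% c(det$square_id[i],
                          grid$neighbors[[det$square_id[i]]]) &&
          abs(det$frame[i] - truth$frame[j]) <= 2) {
        edges <- c(edges, i, nd + j)
      }
    }
    opt <- if (length(edges)) {
      gph <- igraph::make_bipartite_graph(
        rep(c(FALSE, TRUE), c(nd, nt)), edges)
      igraph::max_bipartite_match(gph)$matching_size
    } else 0
    expect_lte(m$n_matched, opt)
    expect_gte(m$n_matched, ceiling(opt / 2))   # greedy maximal bound
  }
})
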