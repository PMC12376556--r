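test_that("contact uses the radial inequality with inclusive boundary", {
  pts <- aligned_radial_points(c(15, 12, 9, 8, 11, 14))
  expect_equal(contact_frames(pts, 10), c(3L, 4L))

  # boundary equality counts as contact
  expect_equal(contact_frames(aligned_radial_points(c(12, 10, 11)), 10), 2L)
  # all outside
  expect_equal(contact_frames(aligned_radial_points(c(12, 11, 13)), 10),
               integer(0))

  unaligned <- data.frame(cell_id = "u", frame = 0:1, x = 0:1, y = 0)
  expect_error(contact_frames(unaligned, 10), class = "rmtrack_usage_error")
  expect_error(contact_frames(pts, -1), class = "rmtrack_validation_error")
})

test_that("segment_track reproduces the worked partitions", {
  seg <- segment_track(aligned_radial_points(c(15, 12, 9, 8, 11, 14)), 10)
  expect_equal(seg$approach_idx, 1:2)
  expect_equal(seg$within_idx, 3:4)
  expect_equal(seg$reverse_idx, 5:6)
  expect_true(seg$contacted)

  # excursion between first and last contact is absorbed into within
  seg2 <- segment_track(aligned_radial_points(c(15, 9, 12, 9, 14)), 10)
  expect_equal(seg2$within_idx, 2:4)
  expect_equal(seg2$reverse_idx, 5L)
  expect_equal(seg2$approach_idx, 1L)

  # never-contacting track is all approach
  seg3 <- segment_track(aligned_radial_points(c(15, 12, 11)), 10)
  expect_false(seg3$contacted)
  expect_equal(seg3$approach_idx, 1:3)
  expect_equal(seg3$within_idx, integer(0))
  expect_equal(seg3$reverse_idx, integer(0))

  # first point already inside: empty approach, still eligible for rM
  seg4 <- segment_track(aligned_radial_points(c(5, 8, 12, 14)), 10)
  expect_equal(seg4$approach_idx, integer(0))
  expect_equal(seg4$within_idx, 1:2)
  expect_equal(seg4$reverse_idx, 3:4)
})

test_that("segment index sets partition every simulated track", {
  sim <- simulate_trackset(simulation_params(n_cells = 60, n_frames = 80, seed = 17))
  ats <- align_to_spheroid(sim$tracks)
  for (p in split_tracks_for_test(ats)) {
    seg <- segment_track(p, ats$spheroid$radius)
    all_idx <- c(seg$approach_idx, seg$within_idx, seg$reverse_idx)
    expect_equal(sort(all_idx), seq_len(nrow(p)))          # exhaustive, disjoint
    expect_equal(all_idx, sort(all_idx))                   # ordered
    for (i in list(seg$approach_idx, seg$within_idx, seg$reverse_idx))
      if (length(i) > 1) expect_equal(diff(i), rep(1L, length(i) - 1L))  # contiguous
    if (!seg$contacted) {
      expect_equal(seg$approach_idx, seq_len(nrow(p)))
      expect_equal(length(seg$within_idx) + length(seg$reverse_idx), 0L)
    }
  }
})

test_that("rM labels require contact, a real exit, and the minimum distance", {
  sph <- spheroid_geometry(0, 0, 10)
  mk <- function(r, id) data.frame(cell_id = id, frame = seq_along(r) - 1L,
                                   x = r, y = 0)
  ts <- track_set(rbind(mk(c(15, 12, 9, 8, 11, 14), "out"),
                        mk(c(15, 12, 9, 8, 7, 6), "stays"),
                        mk(c(15, 12, 9, 8, 11), "one_pt_exit")),
                  frame_interval = 1, spheroid = sph)
  lab <- classify_reverse_migrated(ts)
  expect_equal(lab$rm[lab$cell_id == "out"], TRUE)
  expect_equal(lab$rm[lab$cell_id == "stays"], FALSE)        # ends inside
  expect_equal(lab$rm[lab$cell_id == "one_pt_exit"], FALSE)  # reverse < 2 points

  # the minimum-distance threshold shrinks the rM set monotonically
  rm_at <- function(mrd) sum(classify_reverse_migrated(
    ts, min_reverse_displacement = mrd)$rm)
  counts <- vapply(c(0, 2, 4, 4.01, 100), rm_at, numeric(1))
  expect_equal(counts, c(1, 1, 1, 0, 0))  # "out" ends at r = 14, excess 4
  expect_true(all(diff(counts) <= 0))
})

test_that("short tracks are flagged and never labeled rM", {
  ts <- track_set(data.frame(cell_id = "dot", frame = 0L, x = 0, y = 0),
                  frame_interval = 1, spheroid = spheroid_geometry(0, 0, 10))
  lab <- classify_reverse_migrated(ts)
  expect_false(lab$rm)
  expect_true(lab$flagged)
})

test_that("growing the radius weakly grows the contacted set", {
  sim <- simulate_trackset(simulation_params(n_cells = 30, n_frames = 60, seed = 23))
  contacted_at <- function(r) {
    sph <- spheroid_geometry(0, 0, r)
    sum(classify_reverse_migrated(sim$tracks, spheroid = sph)$contacted)
  }
  counts <- vapply(c(25, 50, 100, 150), contacted_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("classifier recovers simulator ground truth under clean geometry", {
  sim <- simulate_trackset(simulation_params(
    n_cells = 120, n_frames = 150, dwell_frames_mean = 5, p_rm = 0.3, seed = 47))
  lab <- classify_reverse_migrated(sim$tracks, min_reverse_displacement = 50)
  expect_equal(lab$rm[match(sim$truth$cell_id, lab$cell_id)],
               sim$truth$rm_label)
})

test_that("cohort metrics carry labels and match brute-force recomputation", {
  sim <- simulate_trackset(simulation_params(n_cells = 25, n_frames = 70, seed = 61))
  ts <- sim$tracks
  m <- cohort_segment_metrics(ts)
  expect_setequal(unique(m$segment), c("approach", "within", "reverse", "whole"))
  expect_equal(sum(m$segment == "whole"), 25)
  expect_true(all(m$n_steps >= 1))

  # independent recomputation straight from raw coordinates
  ats <- align_to_spheroid(ts)
  for (p in split_tracks_for_test(ats)) {
    seg <- segment_track(p, ats$spheroid$radius)
    for (lab in c("approach", "within", "reverse")) {
      i <- seg[[paste0(lab, "_idx")]]
      row <- m[m$cell_id == p$cell_id[1] & m$segment == lab, ]
      if (length(i) < 2) {
        expect_equal(nrow(row), 0)
      } else {
        o <- oracle_segment(p$x[i], p$y[i], p$frame[i], ts$frame_interval)
        expect_equal(row$d_total, o$d_total, tolerance = 1e-9)
        expect_equal(row$disp, o$disp, tolerance = 1e-9)
        expect_equal(row$str, o$str, tolerance = 1e-9)
        expect_equal(row$mean_velocity, o$mean_velocity, tolerance = 1e-9)
      }
    }
  }

  # labels agree between the metrics table and the classifier
  lab <- classify_reverse_migrated(ts)
  expect_equal(m$rm, unname(setNames(lab$rm, lab$cell_id)[m$cell_id]))

  # with p_rm = 0 no reverse rows are labeled rM
  sim0 <- simulate_trackset(simulation_params(n_cells = 15, n_frames = 80,
                                              p_rm = 0, seed = 3))
  m0 <- cohort_segment_metrics(sim0$tracks)
  expect_false(any(m0$rm))
})
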