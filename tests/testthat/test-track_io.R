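test_that("read_tracks converts pixels to um and sorts by frame", {
  df <- data.frame(track_id = 1, frame = c(1, 0, 2),
                   x = c(3, 0, 3), y = c(4, 0, 9))
  f <- write_track_csv(df)

  ts1 <- read_tracks(f, pixel_size = 1, frame_interval = 1)
  expect_s3_class(ts1, "track_set")
  expect_equal(ts1$points$frame, 0:2)
  expect_equal(ts1$points$x, c(0, 3, 3))
  expect_equal(ts1$points$y, c(0, 4, 9))
  expect_equal(ts1$points$time, c(0, 1, 2))

  # linear pixel scaling
  ts2 <- read_tracks(f, pixel_size = 2, frame_interval = 1)
  expect_equal(ts2$points$x, c(0, 6, 6))
  expect_equal(ts2$points$y, c(0, 8, 18))

  # permutation invariance over file rows
  shuf <- write_track_csv(df[c(3, 1, 2), ])
  expect_equal(read_tracks(shuf, pixel_size = 1, frame_interval = 1)$points,
               ts1$points)
})

test_that("read_tracks supports dialects, TSV, and headerless files", {
  df <- data.frame(Cell = c("a", "a", "b"), Slice = c(0, 1, 0),
                   X = c(1, 2, 5), Y = c(1, 1, 5))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  ts <- read_tracks(f, dialect = track_dialect("Cell", "Slice", "X", "Y"),
                    pixel_size = 1.5, frame_interval = 3)
  expect_equal(track_ids(ts), c("a", "b"))
  expect_equal(get_track(ts, "b")$x, 7.5)
  expect_equal(get_track(ts, "a")$time, c(0, 3))

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("a,0,1,2", "a,1,3,4"), f2)
  ts2 <- read_tracks(f2, dialect = track_dialect("V1", "V2", "V3", "V4"),
                     pixel_size = 1, frame_interval = 1, header = FALSE)
  expect_equal(ts2$points$x, c(1, 3))
})

test_that("read_tracks raises named, classed errors on malformed input", {
  f <- write_track_csv(data.frame(track_id = 1, frame = 0:1, x = 0:1, y = 0:1))
  expect_error(
    read_tracks(f, dialect = track_dialect(y = "Y_px"),
                pixel_size = 1, frame_interval = 1),
    "Y_px", class = "rmtrack_format_error")

  dup <- write_track_csv(data.frame(track_id = c(1, 1), frame = c(3, 3),
                                    x = 0:1, y = 0:1))
  expect_error(read_tracks(dup, pixel_size = 1, frame_interval = 1),
               "duplicate.*'1', 3", class = "rmtrack_integrity_error")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x,y", "1,0,0,0", "1,1,oops,0"), bad)
  expect_error(read_tracks(bad, pixel_size = 1, frame_interval = 1),
               "row 2", class = "rmtrack_parse_error")

  expect_error(read_tracks(f, pixel_size = 0, frame_interval = 1),
               class = "rmtrack_validation_error")
  expect_error(read_tracks(f, pixel_size = 1, frame_interval = 1, delim = ";"),
               class = "rmtrack_error")
})

test_that("track sets round-trip through write_tracks/read_tracks", {
  withr::local_seed(11)
  pts <- do.call(rbind, lapply(1:3, function(i) random_track_df(paste0("c", i), 15)))
  ts <- track_set(pts, frame_interval = 0.5, pixel_size = 2,
                  spheroid = spheroid_geometry(10, -5, 30))
  f <- tempfile(fileext = ".csv")
  meta <- tempfile(fileext = ".json")
  write_tracks(ts, f, meta)

  back <- read_tracks(f, dialect = track_dialect(track_id = "cell_id"),
                      pixel_size = 1, frame_interval = 0.5)
  expect_equal(back$points$x, ts$points$x, tolerance = 1e-12)
  expect_equal(back$points$y, ts$points$y, tolerance = 1e-12)
  expect_equal(back$points$cell_id, ts$points$cell_id)

  m <- jsonlite::read_json(meta)
  expect_equal(m$frame_interval, 0.5)
  expect_equal(m$spheroid$radius, 30)
})

test_that("write_metrics_table round-trips values below 1e-9 relative error", {
  sim <- simulate_trackset(simulation_params(n_cells = 4, n_frames = 30, seed = 3))
  metrics <- cohort_segment_metrics(sim$tracks)
  f <- tempfile(fileext = ".csv")
  write_metrics_table(metrics, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(metrics))
  for (col in c("d_total", "disp", "str", "mean_velocity"))
    expect_equal(back[[col]], metrics[[col]], tolerance = 1e-12)

  # empty table still writes a header
  f2 <- tempfile(fileext = ".csv")
  write_metrics_table(metrics[0, ], f2)
  expect_equal(nrow(utils::read.csv(f2)), 0)
  expect_true(length(readLines(f2)) == 1L)

  expect_error(write_metrics_table(metrics, file.path(tempdir(), "no/such/dir/x.csv")),
               class = "rmtrack_io_error")
})

test_that("validate_trackset reports broken invariants without raising", {
  good <- track_set(data.frame(cell_id = "a", frame = 0:2, x = 0:2, y = 0),
                    frame_interval = 1)
  expect_equal(nrow(validate_trackset(good)), 0)

  # repeated frame: constructor is bypassed by editing the points in place
  bad <- good
  bad$points$frame <- c(0L, 5L, 5L)
  bad$points$time <- c(0, 5, 5)
  v <- validate_trackset(bad)
  expect_true(any(v$rule == "strictly increasing frames" & v$cell_id == "a"))

  bad2 <- good
  bad2$frame_interval <- 0
  v2 <- validate_trackset(bad2)
  expect_true(any(grepl("frame_interval", v2$rule)))

  # single-point track: info flag only, not an invariant violation
  single <- track_set(data.frame(cell_id = "s", frame = 0L, x = 0, y = 0),
                      frame_interval = 1)
  v3 <- validate_trackset(single)
  expect_true(all(v3$severity == "info"))
  expect_true(any(grepl("kinematics", v3$rule)))

  bad4 <- good
  bad4$points$x[2] <- NaN
  expect_true(any(validate_trackset(bad4)$rule == "coordinates finite"))
})
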