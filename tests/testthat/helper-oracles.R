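# Independent brute-force oracles: plain element-wise loops over raw
# coordinates, sharing no code with the package implementation.

oracle_step_distances <- function(x, y) {
  n <- length(x)
  out <- numeric(n - 1L)
  for (i in 2:n)
    out[i - 1L] <- sqrt((x[i - 1L] - x[i])^2 + (y[i - 1L] - y[i])^2)
  out
}

oracle_step_velocities <- function(x, y, frame, frame_interval) {
  d <- oracle_step_distances(x, y)
  out <- numeric(length(d))
  for (i in seq_along(d))
    out[i] <- d[i] / ((frame[i + 1L] - frame[i]) * frame_interval)
  out
}

oracle_segment <- function(x, y, frame, frame_interval) {
  d <- oracle_step_distances(x, y)
  d_total <- 0
  for (v in d) d_total <- d_total + v
  n <- length(x)
  disp <- sqrt((x[1L] - x[n])^2 + (y[1L] - y[n])^2)
  list(d_total = d_total, disp = disp,
       str = if (d_total > 0) disp / d_total else NA_real_,
       mean_velocity = mean(oracle_step_velocities(x, y, frame, frame_interval)))
}

# O(n * grid) double loop over points and nodes
oracle_kde <- function(px, py, gx, gy, hx, hy) {
  n <- length(px)
  out <- matrix(0, length(gx), length(gy))
  for (i in seq_along(gx)) for (j in seq_along(gy)) {
    s <- 0
    for (k in seq_len(n)) {
      s <- s + exp(-0.5 * ((gx[i] - px[k]) / hx)^2) / (hx * sqrt(2 * pi)) *
               exp(-0.5 * ((gy[j] - py[k]) / hy)^2) / (hy * sqrt(2 * pi))
    }
    out[i, j] <- s / n
  }
  out
}

# random free-form track points (not simulator output; arbitrary motion)
random_track_df <- function(id, n, scale = 20, gap_prob = 0) {
  frames <- 0L
  for (k in 2:n) {
    step <- 1L + (stats::runif(1) < gap_prob) * sample(1:3, 1L)
    frames <- c(frames, frames[k - 1L] + step)
  }
  data.frame(cell_id = id, frame = frames,
             x = cumsum(stats::rnorm(n, 0, scale)),
             y = cumsum(stats::rnorm(n, 0, scale)))
}

# track_set built from explicit radial distances along the x-axis,
# already spheroid-aligned: radial distance r -> point (r, 0)
aligned_radial_points <- function(r, cell_id = "c1") {
  pts <- data.frame(cell_id = cell_id, frame = seq_along(r) - 1L,
                    time = seq_along(r) - 1L, x = r, y = 0)
  attr(pts, "aligned") <- TRUE
  pts
}

write_track_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

split_tracks_for_test <- function(ts) {
  lapply(unique(ts$points$cell_id), function(id) get_track(ts, id))
}
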