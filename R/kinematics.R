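#' Align coordinates to the spheroid center
#'
#' Translates coordinates so the injury spheroid sits at the origin:
#' `x_new = x_cell - x_sp`, `y_new = y_cell - y_sp`. A pure translation, so
#' every distance, velocity, and straightness value is unchanged; alignment
#' only fixes the reference frame in which radial contact is evaluated.
#'
#' @param x A [track_set()] or a single track's points data.frame.
#' @param spheroid A [spheroid_geometry()]; for a `track_set`, defaults to
#'   the one stored in the set.
#' @return The same kind of object with shifted `x`, `y` and an `aligned`
#'   marker. For a `track_set`, the stored spheroid is re-centered at
#'   (0, 0) so downstream radial tests read directly off the coordinates.
#' @examples
#' sph <- spheroid_geometry(100, 50, 10)
#' pts <- data.frame(cell_id = "a", frame = 0:1, time = 0:1,
#'                   x = c(100, 120), y = c(50, 80))
#' align_to_spheroid(pts, sph)[, c("x", "y")]
#' @export
align_to_spheroid <- function(x, spheroid = NULL) UseMethod("align_to_spheroid")

#' @export
align_to_spheroid.track_set <- function(x, spheroid = NULL) {
  spheroid <- spheroid %||% x$spheroid
  if (is.null(spheroid))
    rmt_stop("usage_error",
             "align_to_spheroid: no spheroid geometry given or stored in the track_set")
  if (!is_spheroid_geometry(spheroid))
    rmt_stop("validation_error", "align_to_spheroid: 'spheroid' must be a spheroid_geometry")
  x$points$x <- x$points$x - spheroid$center_x
  x$points$y <- x$points$y - spheroid$center_y
  x$spheroid <- spheroid_geometry(0, 0, spheroid$radius)
  x$aligned <- TRUE
  x
}

#' @export
align_to_spheroid.data.frame <- function(x, spheroid = NULL) {
  if (!is_spheroid_geometry(spheroid))
    rmt_stop("validation_error", "align_to_spheroid: 'spheroid' must be a spheroid_geometry")
  if (!nrow(x))
    rmt_stop("insufficient_data", "align_to_spheroid: empty track")
  x$x <- x$x - spheroid$center_x
  x$y <- x$y - spheroid$center_y
  attr(x, "aligned") <- TRUE
  x
}

track_label <- function(points, cell_id = NULL) {
  cell_id %||% (if ("cell_id" %in% names(points) && nrow(points))
    points$cell_id[1L] else "<unnamed>")
}

#' Per-step travel distances
#'
#' Euclidean distance between consecutive recorded positions:
#' `dist_i = sqrt((x_{i-1} - x_i)^2 + (y_{i-1} - y_i)^2)`.
#'
#' @param points A track's points data.frame (>= 2 rows) with `x`, `y`.
#' @param cell_id Optional label used in error messages.
#' @return Numeric vector of length `nrow(points) - 1`, in um.
#' @examples
#' step_distances(data.frame(x = c(0, 3, 3), y = c(0, 4, 9)))  # 5 5
#' @export
step_distances <- function(points, cell_id = NULL) {
  if (nrow(points) < 2L)
    rmt_stop("insufficient_data",
             "step_distances: track '%s' has %d point(s); need >= 2",
             track_label(points, cell_id), nrow(points))
  sqrt(diff(points$x)^2 + diff(points$y)^2)
}

#' Per-step velocities
#'
#' Each step's distance divided by its elapsed time. When consecutive rows
#' are not adjacent frames (a tracking gap of g frames), the step time is
#' `g * frame_interval`: the chord distance is spread over the true elapsed
#' time rather than interpolating positions the tracker never recorded.
#'
#' @inheritParams step_distances
#' @param frame_interval Minutes per frame; must be > 0.
#' @return Numeric vector of length `nrow(points) - 1`, in um/min.
#' @examples
#' pts <- data.frame(frame = c(0L, 1L, 3L), x = c(0, 3, 6), y = c(0, 4, 8))
#' step_velocities(pts, frame_interval = 1)  # 5, then 5/2
#' @export
step_velocities <- function(points, frame_interval, cell_id = NULL) {
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    rmt_stop("validation_error", "step_velocities: 'frame_interval' must be > 0")
  d <- step_distances(points, cell_id)
  gaps <- if ("frame" %in% names(points)) diff(points$frame) else rep(1L, length(d))
  if (any(gaps <= 0))
    rmt_stop("validation_error",
             "step_velocities: track '%s' has non-increasing frames",
             track_label(points, cell_id))
  d / (gaps * frame_interval)
}

#' Kinematic summary of one track segment
#'
#' Computes, over an ordered run of points, the total path length
#' `d_total` (sum of step distances), the net displacement `disp`
#' (straight-line distance from first to last point), the straightness
#' `str = disp / d_total` (1 = perfectly straight; `NA` when the cell never
#' moved, since both 0 and 1 would be arbitrary), and the mean velocity.
#'
#' @inheritParams step_velocities
#' @param segment_label Label stored in the output row (`"approach"`,
#'   `"within"`, `"reverse"`, or `"whole"`).
#' @param velocity_method `"step_mean"` (default): mean of per-step
#'   velocities. `"segment"`: `d_total` divided by the segment's elapsed
#'   time. The two differ only when tracking gaps make step times unequal.
#' @return One-row data.frame: `cell_id`, `segment`, `n_steps`, `d_total`,
#'   `disp`, `str`, `mean_velocity`.
#' @examples
#' segment_kinematics(data.frame(frame = 0:2, x = c(0, 3, 3), y = c(0, 4, 9)),
#'                    frame_interval = 1)
#' @export
segment_kinematics <- function(points, frame_interval, cell_id = NULL,
                               segment_label = "whole",
                               velocity_method = c("step_mean", "segment")) {
  velocity_method <- match.arg(velocity_method)
  id <- track_label(points, cell_id)
  d <- step_distances(points, id)
  v <- step_velocities(points, frame_interval, id)
  n <- nrow(points)
  d_total <- sum(d)
  disp <- sqrt((points$x[n] - points$x[1L])^2 + (points$y[n] - points$y[1L])^2)
  str <- if (d_total > 0) disp / d_total else NA_real_
  mean_velocity <- switch(velocity_method,
    step_mean = mean(v),
    segment = {
      gaps <- if ("frame" %in% names(points)) diff(points$frame) else rep(1L, n - 1L)
      d_total / (sum(gaps) * frame_interval)
    })
  data.frame(cell_id = id, segment = segment_label, n_steps = length(d),
             d_total = d_total, disp = disp, str = str,
             mean_velocity = mean_velocity, stringsAsFactors = FALSE)
}
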