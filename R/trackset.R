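#' Construct a track set
#'
#' A `track_set` bundles the tracked cells of one field of view: a long-form
#' points table plus the acquisition metadata needed to work in physical
#' units (minutes, micrometers). Coordinates are expected already in um;
#' use [read_tracks()] to ingest pixel-unit tracker exports.
#'
#' @param points A data.frame with columns `cell_id`, `frame` (non-negative
#'   integer), `x`, `y` (um). A `time` column, if absent, is derived as
#'   `frame * frame_interval`. Rows are sorted by (`cell_id` first
#'   appearance, `frame`).
#' @param frame_interval Minutes per frame; must be > 0.
#' @param pixel_size um per pixel used at ingest (1 if coordinates were
#'   already physical); must be > 0.
#' @param spheroid Optional [spheroid_geometry()].
#' @param provenance Free-text note on where the tracks came from.
#'
#' @return An object of class `track_set`: a list with elements `points`
#'   (data.frame `cell_id`, `frame`, `time`, `x`, `y`), `frame_interval`,
#'   `pixel_size`, `spheroid`, `provenance`, and an `aligned` flag that
#'   [align_to_spheroid()] sets.
#' @seealso [validate_trackset()], [read_tracks()]
#' @export
track_set <- function(points, frame_interval, pixel_size = 1,
                      spheroid = NULL, provenance = "") {
  if (!is.data.frame(points))
    rmt_stop("validation_error", "track_set: 'points' must be a data.frame")
  need <- c("cell_id", "frame", "x", "y")
  missing_cols <- setdiff(need, names(points))
  if (length(missing_cols))
    rmt_stop("format_error", "track_set: missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    rmt_stop("validation_error", "track_set: 'frame_interval' must be a single number > 0")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    rmt_stop("validation_error", "track_set: 'pixel_size' must be a single number > 0")
  if (!is.null(spheroid) && !is_spheroid_geometry(spheroid))
    rmt_stop("validation_error", "track_set: 'spheroid' must be a spheroid_geometry or NULL")

  pts <- data.frame(
    cell_id = as.character(points$cell_id),
    frame   = as.integer(points$frame),
    x       = as.numeric(points$x),
    y       = as.numeric(points$y),
    stringsAsFactors = FALSE
  )
  # stable sort: cells keep file order of first appearance, frames ascend
  ord <- order(match(pts$cell_id, unique(pts$cell_id)), pts$frame)
  pts <- pts[ord, , drop = FALSE]
  pts$time <- pts$frame * frame_interval
  pts <- pts[, c("cell_id", "frame", "time", "x", "y")]
  rownames(pts) <- NULL

  structure(
    list(points = pts, frame_interval = frame_interval,
         pixel_size = pixel_size, spheroid = spheroid,
         provenance = provenance, aligned = FALSE),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  ids <- unique(x$points$cell_id)
  cat(sprintf(
    "<track_set> %d track(s), %d points; frame_interval %g min, pixel_size %g um/px%s\n",
    length(ids), nrow(x$points), x$frame_interval, x$pixel_size,
    if (isTRUE(x$aligned)) " [spheroid-aligned]" else ""))
  if (!is.null(x$spheroid))
    cat(sprintf("  spheroid: center (%g, %g), radius %g um\n",
                x$spheroid$center_x, x$spheroid$center_y, x$spheroid$radius))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Cell identifiers of a track set
#' @param ts A `track_set`.
#' @return Character vector of unique cell ids, in order of first appearance.
#' @export
track_ids <- function(ts) unique(ts$points$cell_id)

#' Extract one track's points
#' @param ts A `track_set`.
#' @param cell_id The id of the track to extract.
#' @return The track's points as a data.frame (`cell_id`, `frame`, `time`,
#'   `x`, `y`), carrying the set's `aligned` flag as an attribute.
#' @export
get_track <- function(ts, cell_id) {
  pts <- ts$points[ts$points$cell_id == cell_id, , drop = FALSE]
  if (!nrow(pts))
    rmt_stop("validation_error", "get_track: no track with cell_id '%s'", cell_id)
  rownames(pts) <- NULL
  attr(pts, "aligned") <- isTRUE(ts$aligned)
  pts
}

# split points into per-cell data.frames preserving first-appearance order
split_tracks <- function(ts) {
  ids <- track_ids(ts)
  out <- split(ts$points, factor(ts$points$cell_id, levels = ids))
  lapply(out, function(p) {
    rownames(p) <- NULL
    attr(p, "aligned") <- isTRUE(ts$aligned)
    p
  })
}

#' Check track-set invariants
#'
#' Reporting companion to the strict constructors: inspects a `track_set`
#' and returns one row per broken rule instead of raising. Rules checked:
#' positive `frame_interval` and `pixel_size`, finite coordinates, strictly
#' increasing frames within each track, positive spheroid radius if a
#' spheroid is set. Single-point tracks satisfy the storage invariants but
#' are flagged (severity `"info"`) as unusable for kinematics.
#'
#' @param ts A `track_set` (possibly hand-built and malformed).
#' @return A data.frame with columns `cell_id` (`NA` for set-level rules),
#'   `rule`, `severity` (`"error"` or `"info"`), and `detail`; zero
#'   error-severity rows if and only if all invariants hold.
#' @examples
#' ts <- track_set(data.frame(cell_id = "a", frame = 0:2, x = 0:2, y = 0),
#'                 frame_interval = 1)
#' validate_trackset(ts)  # empty
#' @export
validate_trackset <- function(ts) {
  v <- list()
  add <- function(cell_id, rule, severity, detail) {
    v[[length(v) + 1L]] <<- data.frame(
      cell_id = cell_id, rule = rule, severity = severity, detail = detail,
      stringsAsFactors = FALSE)
  }

  fi <- ts$frame_interval
  if (!is.numeric(fi) || length(fi) != 1L || !is.finite(fi) || fi <= 0)
    add(NA_character_, "frame_interval > 0", "error",
        sprintf("frame_interval is %s", paste(format(fi), collapse = ",")))
  px <- ts$pixel_size
  if (!is.numeric(px) || length(px) != 1L || !is.finite(px) || px <= 0)
    add(NA_character_, "pixel_size > 0", "error",
        sprintf("pixel_size is %s", paste(format(px), collapse = ",")))
  if (!is.null(ts$spheroid)) {
    r <- ts$spheroid$radius
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
      add(NA_character_, "spheroid radius > 0", "error",
          sprintf("radius is %s", paste(format(r), collapse = ",")))
  }

  pts <- ts$points
  for (id in unique(pts$cell_id)) {
    p <- pts[pts$cell_id == id, , drop = FALSE]
    if (any(!is.finite(p$x)) || any(!is.finite(p$y)))
      add(id, "coordinates finite", "error", "non-finite x or y")
    if (any(p$frame < 0L, na.rm = TRUE))
      add(id, "frames non-negative", "error", "negative frame index")
    d <- diff(p$frame)
    if (length(d) && any(d <= 0L))
      add(id, "strictly increasing frames", "error",
          sprintf("frame(s) %s repeated or out of order",
                  paste(unique(p$frame[c(FALSE, d <= 0L)]), collapse = ",")))
    if (is.numeric(fi) && length(fi) == 1L && is.finite(fi) && fi > 0 &&
        !isTRUE(all.equal(p$time, p$frame * fi)))
      add(id, "time = frame * frame_interval", "error", "time column inconsistent")
    if (nrow(p) < 2L)
      add(id, "at least 2 points for kinematics", "info",
          "single-point track: retained, unusable for kinematic operations")
  }

  if (!length(v))
    return(data.frame(cell_id = character(), rule = character(),
                      severity = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
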