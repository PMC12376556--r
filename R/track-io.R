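#' Column dialect for tracker exports
#'
#' Tracker exports (e.g. the ImageJ manual-tracking plugin, TrackMate spot
#' tables) name their columns differently; a dialect maps the four required
#' roles onto the file's column names.
#'
#' @param track_id,frame,x,y Column names in the file holding the track
#'   label, frame index, and pixel coordinates.
#' @return A named list of class `track_dialect`.
#' @export
track_dialect <- function(track_id = "track_id", frame = "frame",
                          x = "x", y = "y") {
  structure(list(track_id = track_id, frame = frame, x = x, y = y),
            class = "track_dialect")
}

#' Read a cell-track table
#'
#' Ingests a delimited-text track table (one row per cell per frame),
#' converts pixel coordinates to micrometers, and returns a [track_set()]
#' with per-track rows sorted by frame. Row order in the file does not
#' affect the result.
#'
#' @param path Path to a CSV or TSV file. The delimiter is chosen from the
#'   file extension (`.tsv`/`.txt` = tab, otherwise comma) unless `delim`
#'   is given.
#' @param dialect A [track_dialect()] naming the columns for track id,
#'   frame, x and y.
#' @param pixel_size um per pixel; coordinates are multiplied by this at
#'   ingest. Mandatory: acquisition metadata is never guessed.
#' @param frame_interval Minutes per frame. Mandatory.
#' @param delim Optional explicit field delimiter.
#' @param header Does the file have a header row? If `FALSE`, columns are
#'   named `V1`, `V2`, ... and the dialect should reference those.
#' @param spheroid,provenance Passed to [track_set()]; `provenance`
#'   defaults to the file path.
#'
#' @return A [track_set()] in physical units (um, minutes).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(track_id = 1, frame = 0:2,
#'                      x = c(0, 3, 3), y = c(0, 4, 9)),
#'           f, row.names = FALSE)
#' ts <- read_tracks(f, pixel_size = 2, frame_interval = 0.5)
#' ts$points
#' @export
read_tracks <- function(path, dialect = track_dialect(), pixel_size,
                        frame_interval, delim = NULL, header = TRUE,
                        spheroid = NULL, provenance = NULL) {
  if (!file.exists(path))
    rmt_stop("io_error", "read_tracks: file not found: %s", path)
  if (missing(pixel_size) || missing(frame_interval))
    rmt_stop("validation_error",
             "read_tracks: 'pixel_size' and 'frame_interval' are mandatory")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    rmt_stop("validation_error", "read_tracks: 'pixel_size' must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    rmt_stop("validation_error", "read_tracks: 'frame_interval' must be > 0")

  sep <- delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")

  roles <- unlist(dialect[c("track_id", "frame", "x", "y")])
  absent <- roles[!(roles %in% names(raw))]
  if (length(absent))
    rmt_stop("format_error",
             "read_tracks: column(s) not found in %s: %s (available: %s)",
             path, paste(absent, collapse = ", "),
             paste(names(raw), collapse = ", "))

  num <- function(role) {
    col <- raw[[roles[[role]]]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) & !is.na(col) & nzchar(trimws(col)))
    if (length(bad))
      rmt_stop("parse_error",
               "read_tracks: non-numeric '%s' value '%s' at data row %d",
               role, col[bad[1L]], bad[1L])
    val
  }
  cell_id <- as.character(raw[[roles[["track_id"]]]])
  frame <- num("frame")
  if (any(frame != floor(frame) | frame < 0))
    rmt_stop("parse_error",
             "read_tracks: 'frame' must hold non-negative integers (data row %d)",
             which(frame != floor(frame) | frame < 0)[1L])

  key <- paste(cell_id, frame, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    parts <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    rmt_stop("integrity_error",
             "read_tracks: duplicate (cell_id, frame) pair: ('%s', %s)",
             parts[1L], parts[2L])
  }

  track_set(
    data.frame(cell_id = cell_id, frame = as.integer(frame),
               x = num("x") * pixel_size, y = num("y") * pixel_size,
               stringsAsFactors = FALSE),
    frame_interval = frame_interval, pixel_size = pixel_size,
    spheroid = spheroid, provenance = provenance %||% path)
}

#' Write a track set back to delimited text
#'
#' Writes the points table as CSV (columns `cell_id`, `frame`, `time`, `x`,
#' `y`, in um and minutes) and, optionally, a JSON sidecar with the set's
#' metadata (frame interval, pixel size, spheroid geometry, provenance).
#' Numbers are printed at full double precision, so
#' `read_tracks(..., pixel_size = 1)` round-trips the coordinates.
#'
#' @param ts A [track_set()].
#' @param path Output CSV path.
#' @param meta_path Optional path for the JSON metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path, meta_path = NULL) {
  utils::write.csv(ts$points, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(frame_interval = ts$frame_interval,
                 pixel_size = ts$pixel_size,
                 spheroid = if (!is.null(ts$spheroid))
                   unclass(ts$spheroid) else NULL,
                 aligned = isTRUE(ts$aligned),
                 provenance = ts$provenance)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Write a per-segment metrics table
#'
#' One row per (cell, segment) as produced by [cohort_segment_metrics()].
#' Values are printed with 15 significant digits so the file round-trips
#' through any generic CSV reader far below 1e-9 relative error.
#'
#' @param metrics A data.frame of segment metrics.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  if (!is.data.frame(metrics))
    rmt_stop("validation_error", "write_metrics_table: 'metrics' must be a data.frame")
  out <- metrics
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
  }
  ok <- tryCatch({
    suppressWarnings(utils::write.csv(out, path, row.names = FALSE, quote = FALSE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    rmt_stop("io_error", "write_metrics_table: cannot write %s: %s",
             path, conditionMessage(ok))
  invisible(path)
}
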