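require_aligned <- function(points, what) {
  if (!isTRUE(attr(points, "aligned")))
    rmt_stop("usage_error",
             "%s: track is not spheroid-aligned; call align_to_spheroid() first",
             what)
}

#' Indices of spheroid contact
#'
#' In the spheroid-centered frame a cell is in contact at slice i when
#' `sqrt(x_i^2 + y_i^2) <= radius`; boundary equality counts as contact.
#' Contact is evaluated on recorded positions only, not on chords between
#' frames.
#'
#' @param points A spheroid-aligned track (from [align_to_spheroid()]).
#' @param radius Contact radius in um; must be > 0.
#' @return Integer vector of 1-based row indices in contact (possibly
#'   empty).
#' @export
contact_frames <- function(points, radius) {
  require_aligned(points, "contact_frames")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    rmt_stop("validation_error", "contact_frames: 'radius' must be > 0")
  which(sqrt(points$x^2 + points$y^2) <= radius)
}

#' Three-segment track partition
#'
#' Splits a track at the injury-site boundary into its approach segment
#' (all points before first contact), within segment (first through last
#' contact, inclusive — brief excursions back outside the radius between
#' those two contacts belong to the dwell, because the reverse segment is
#' defined from the final exit after which the cell never re-enters), and
#' reverse segment (all points after the last contact). A track that never
#' touches the radius is all approach.
#'
#' @inheritParams contact_frames
#' @return A list of class `segmented_track`: `cell_id`, integer index
#'   vectors `approach_idx`, `within_idx`, `reverse_idx` (1-based,
#'   contiguous, disjoint, exhaustive), and logical `contacted`.
#' @examples
#' sph <- spheroid_geometry(0, 0, 10)
#' pts <- data.frame(cell_id = "a", frame = 0:5,
#'                   x = c(15, 12, 9, 8, 11, 14), y = 0)
#' segment_track(align_to_spheroid(pts, sph), radius = 10)
#' @export
segment_track <- function(points, radius) {
  require_aligned(points, "segment_track")
  f <- contact_frames(points, radius)
  n <- nrow(points)
  idx <- seq_len(n)
  if (!length(f)) {
    seg <- list(approach_idx = idx, within_idx = integer(0),
                reverse_idx = integer(0), contacted = FALSE)
  } else {
    seg <- list(approach_idx = idx[idx < min(f)],
                within_idx = idx[idx >= min(f) & idx <= max(f)],
                reverse_idx = idx[idx > max(f)],
                contacted = TRUE)
  }
  structure(c(list(cell_id = track_label(points)), seg),
            class = "segmented_track")
}

#' @export
print.segmented_track <- function(x, ...) {
  fmt <- function(i) if (length(i)) sprintf("%d..%d (%d)", min(i), max(i), length(i)) else "-"
  cat(sprintf("<segmented_track> '%s'%s  approach %s | within %s | reverse %s\n",
              x$cell_id, if (x$contacted) "" else " [no contact]",
              fmt(x$approach_idx), fmt(x$within_idx), fmt(x$reverse_idx)))
  invisible(x)
}

#' Label reverse-migrated cells
#'
#' A cell is reverse-migrated (rM) when it contacted the injury spheroid
#' (came within one radius of its center), left it for good (its reverse
#' segment — the points after the last contact — has at least 2 points),
#' and its final position lies at least `min_reverse_displacement` beyond
#' the radius. The default threshold of 0 is the pure contact-based
#' definition; a positive value implements the "travelled away for a
#' minimum distance" reading.
#'
#' Tracks with fewer than 2 points cannot be classified; they are labeled
#' not-rM and flagged.
#'
#' @param ts A [track_set()]; aligned internally if not already.
#' @param spheroid A [spheroid_geometry()]; defaults to the one stored in
#'   `ts`.
#' @param min_reverse_displacement Minimum distance (um) of the final
#'   position beyond the spheroid radius; >= 0.
#' @return A data.frame with one row per cell: `cell_id`, `contacted`,
#'   `n_reverse_points`, `final_excess_distance` (um beyond the radius of
#'   the last point, `NA` when there is no reverse segment), `rm`
#'   (logical), `flagged` (too short to classify).
#' @export
classify_reverse_migrated <- function(ts, spheroid = NULL,
                                      min_reverse_displacement = 0) {
  if (!is.numeric(min_reverse_displacement) || min_reverse_displacement < 0)
    rmt_stop("validation_error",
             "classify_reverse_migrated: 'min_reverse_displacement' must be >= 0")
  ats <- if (isTRUE(ts$aligned) && is.null(spheroid)) ts
         else align_to_spheroid(ts, spheroid)
  radius <- ats$spheroid$radius
  rows <- lapply(split_tracks(ats), function(p) {
    id <- p$cell_id[1L]
    if (nrow(p) < 2L)
      return(data.frame(cell_id = id, contacted = FALSE,
                        n_reverse_points = 0L,
                        final_excess_distance = NA_real_,
                        rm = FALSE, flagged = TRUE,
                        stringsAsFactors = FALSE))
    seg <- segment_track(p, radius)
    nrev <- length(seg$reverse_idx)
    excess <- if (nrev) {
      last <- seg$reverse_idx[nrev]
      sqrt(p$x[last]^2 + p$y[last]^2) - radius
    } else NA_real_
    data.frame(cell_id = id, contacted = seg$contacted,
               n_reverse_points = nrev,
               final_excess_distance = excess,
               rm = seg$contacted && nrev >= 2L &&
                 isTRUE(excess >= min_reverse_displacement),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-segment kinematics for a whole cohort
#'
#' Aligns every track, partitions it at the spheroid boundary, and returns
#' one kinematic-summary row per (cell, segment) for each of the three
#' migratory segments that has at least 2 points, plus a `"whole"` row per
#' track for QC. Each row carries the cell's rM label so the table feeds
#' directly into approach/within/reverse velocity comparisons and
#' rM vs non-rM straightness comparisons.
#'
#' @inheritParams classify_reverse_migrated
#' @param frame_interval Minutes per frame; defaults to the value stored
#'   in `ts`.
#' @param velocity_method Passed to [segment_kinematics()].
#' @return A data.frame: `cell_id`, `segment`, `n_steps`, `d_total`,
#'   `disp`, `str`, `mean_velocity`, `rm`. Tracks too short for kinematics
#'   are skipped (they remain visible in [classify_reverse_migrated()]'s
#'   `flagged` column).
#' @export
cohort_segment_metrics <- function(ts, spheroid = NULL,
                                   frame_interval = NULL,
                                   min_reverse_displacement = 0,
                                   velocity_method = c("step_mean", "segment")) {
  velocity_method <- match.arg(velocity_method)
  fi <- frame_interval %||% ts$frame_interval
  ats <- if (isTRUE(ts$aligned) && is.null(spheroid)) ts
         else align_to_spheroid(ts, spheroid)
  radius <- ats$spheroid$radius
  labels <- classify_reverse_migrated(ats,
    min_reverse_displacement = min_reverse_displacement)
  rmmap <- stats::setNames(labels$rm, labels$cell_id)

  rows <- lapply(split_tracks(ats), function(p) {
    if (nrow(p) < 2L) return(NULL)
    id <- p$cell_id[1L]
    seg <- segment_track(p, radius)
    pieces <- list(approach = seg$approach_idx, within = seg$within_idx,
                   reverse = seg$reverse_idx)
    out <- lapply(names(pieces), function(lab) {
      i <- pieces[[lab]]
      if (length(i) < 2L) return(NULL)
      segment_kinematics(p[i, , drop = FALSE], fi, cell_id = id,
                         segment_label = lab,
                         velocity_method = velocity_method)
    })
    out <- c(out, list(segment_kinematics(p, fi, cell_id = id,
                                          segment_label = "whole",
                                          velocity_method = velocity_method)))
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(cell_id = character(), segment = character(),
                      n_steps = integer(), d_total = numeric(),
                      disp = numeric(), str = numeric(),
                      mean_velocity = numeric(), rm = logical(),
                      stringsAsFactors = FALSE))
  out$rm <- unname(rmmap[out$cell_id])
  rownames(out) <- NULL
  out
}
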