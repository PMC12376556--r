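#' Parameters of the synthetic neutrophil-track generator
#'
#' Bundles and validates the knobs of [simulate_trackset()]. Defaults
#' describe a plausible field of view of the sterile-injury
#' microphysiological system: cells exit an endothelial lumen 300 um from a
#' 100 um-radius injury spheroid and migrate toward it at around
#' 4 um/min (the 3-5 um/min range typical of neutrophil interstitial
#' chemotaxis in such devices), imaged every 2 minutes over 4 hours.
#'
#' @param n_cells Number of tracks.
#' @param n_frames Frames per track.
#' @param frame_interval Minutes per frame.
#' @param spheroid Injury-site [spheroid_geometry()].
#' @param lumen_offset Distance (um) of the lumen start line from the
#'   spheroid center, along -x.
#' @param lumen_jitter_sd SD (um) of the Gaussian jitter of start positions
#'   around `center_y` on the lumen line.
#' @param speed_mean,speed_sd Mean and SD (um/min) of the per-step speed,
#'   drawn from a normal distribution truncated at 0.
#' @param persistence Weight in \[0, 1\] of the previous heading against
#'   the target heading (0 = always head straight for the target).
#' @param heading_noise_sd SD (radians) of Gaussian noise added to each
#'   directed heading.
#' @param dwell_frames_mean Mean of the geometric (memoryless) number of
#'   dwell frames after first spheroid contact.
#' @param p_rm Probability in \[0, 1\] that a cell reverse-migrates after
#'   its dwell; otherwise it keeps moving without bias inside.
#' @param rm_mode `"toward_lumen"`: reverse target heading points back
#'   toward the lumen line; `"random"`: a direction drawn once at reverse
#'   onset.
#' @param within_speed_factor Multiplier in (0, 1\] applied to the step
#'   speed while the cell is inside the spheroid radius (cells crawl more
#'   slowly inside the injury site).
#' @param seed Integer seed; the generator is a pure function of the
#'   parameter set including this seed.
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_cells = 50L,
                              n_frames = 120L,
                              frame_interval = 2,
                              spheroid = spheroid_geometry(0, 0, 100),
                              lumen_offset = 300,
                              lumen_jitter_sd = 50,
                              speed_mean = 4,
                              speed_sd = 1,
                              persistence = 0.5,
                              heading_noise_sd = 0.3,
                              dwell_frames_mean = 10,
                              p_rm = 0.3,
                              rm_mode = c("toward_lumen", "random"),
                              within_speed_factor = 0.5,
                              seed = 1L) {
  rm_mode <- match.arg(rm_mode)
  chk <- function(cond, field, what) {
    if (!cond)
      rmt_stop("validation_error", "simulation_params: '%s' %s", field, what)
  }
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  chk(num1(n_cells) && n_cells >= 1 && n_cells == floor(n_cells), "n_cells", "must be a positive integer")
  chk(num1(n_frames) && n_frames >= 2 && n_frames == floor(n_frames), "n_frames", "must be an integer >= 2")
  chk(num1(frame_interval) && frame_interval > 0, "frame_interval", "must be > 0")
  chk(is_spheroid_geometry(spheroid), "spheroid", "must be a spheroid_geometry")
  chk(num1(lumen_offset) && lumen_offset > 0, "lumen_offset", "must be > 0")
  chk(num1(lumen_jitter_sd) && lumen_jitter_sd >= 0, "lumen_jitter_sd", "must be >= 0")
  chk(num1(speed_mean) && speed_mean > 0, "speed_mean", "must be > 0")
  chk(num1(speed_sd) && speed_sd >= 0, "speed_sd", "must be >= 0")
  chk(num1(persistence) && persistence >= 0 && persistence <= 1, "persistence", "must be in [0, 1]")
  chk(num1(heading_noise_sd) && heading_noise_sd >= 0, "heading_noise_sd", "must be >= 0")
  chk(num1(dwell_frames_mean) && dwell_frames_mean >= 0, "dwell_frames_mean", "must be >= 0")
  chk(num1(p_rm) && p_rm >= 0 && p_rm <= 1, "p_rm", "must be in [0, 1]")
  chk(num1(within_speed_factor) && within_speed_factor > 0 && within_speed_factor <= 1,
      "within_speed_factor", "must be in (0, 1]")
  chk(num1(seed) && seed == floor(seed), "seed", "must be an integer")
  structure(list(
    n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, spheroid = spheroid,
    lumen_offset = lumen_offset, lumen_jitter_sd = lumen_jitter_sd,
    speed_mean = speed_mean, speed_sd = speed_sd,
    persistence = persistence, heading_noise_sd = heading_noise_sd,
    dwell_frames_mean = dwell_frames_mean, p_rm = p_rm, rm_mode = rm_mode,
    within_speed_factor = within_speed_factor, seed = as.integer(seed)),
    class = "simulation_params")
}

# speed draw truncated at zero; exact zero-noise limit when sd == 0
rtrunc_speed <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    s <- stats::rnorm(1L, mean, sd)
    if (s >= 0) return(s)
  }
}

# weighted circular mean of previous and target heading
blend_heading <- function(prev, target, persistence) {
  if (persistence == 0) return(target)
  atan2(persistence * sin(prev) + (1 - persistence) * sin(target),
        persistence * cos(prev) + (1 - persistence) * cos(target))
}

# per-cell substream: Lehmer-style mix so track i is invariant to n_cells
cell_seed <- function(seed, i) {
  s0 <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s0 * 48271 + i * 9973) %% 2147483647)
}

#' Simulate a labeled cohort of neutrophil tracks
#'
#' Biased persistent random walk reproducing the three migratory behaviors
#' seen in the sterile-injury device: directed approach from the lumen to
#' the injury spheroid, a slower unbiased dwell inside it, and — for a
#' random subpopulation of probability `p_rm` — reverse migration away
#' from it (toward the lumen, or in a random direction). Each cell starts
#' on the lumen line at `x = center_x - lumen_offset` with its y position
#' jittered around `center_y`. Per step, speed is drawn from a normal
#' distribution truncated at 0 (damped by `within_speed_factor` while the
#' cell is inside the radius) and the heading is the persistence-weighted
#' circular mean of the previous heading and the current target direction,
#' plus Gaussian angular noise; dwell motion is unbiased. Dwell length is
#' geometric with mean `dwell_frames_mean`. Cells that stay at the injury
#' site (dwelling, or non-reversers after their dwell) are retained inside
#' the radius: a step that would cross the boundary is folded back by
#' radial reflection, so only cells that actually switch to reverse mode
#' leave the spheroid.
#'
#' Each track is generated from its own substream derived from
#' `(seed, cell index)`, so enlarging `n_cells` extends the cohort without
#' reshuffling existing tracks, and identical parameters give bit-identical
#' output.
#'
#' @param params A [simulation_params()].
#' @return A list with elements:
#'   \describe{
#'     \item{tracks}{A [track_set()] with `n_cells` tracks and the
#'       spheroid geometry attached (unaligned imaging frame).}
#'     \item{truth}{Ground truth, one row per cell: `cell_id`, `rm_label`
#'       (did the generator switch this cell to reverse mode), and the
#'       realized `entry_frame` (first frame in contact) and `exit_frame`
#'       (last frame in contact), `NA` when the cell never made contact.}
#'   }
#' @examples
#' sim <- simulate_trackset(simulation_params(n_cells = 5, n_frames = 40))
#' sim$tracks
#' sim$truth
#' @export
simulate_trackset <- function(params) {
  if (!inherits(params, "simulation_params"))
    rmt_stop("validation_error",
             "simulate_trackset: 'params' must come from simulation_params()")
  p <- params
  sph <- p$spheroid
  width <- max(1L, nchar(as.character(p$n_cells)))
  ids <- sprintf(paste0("cell_%0", width, "d"), seq_len(p$n_cells))

  all_pts <- vector("list", p$n_cells)
  truth <- vector("list", p$n_cells)

  for (i in seq_len(p$n_cells)) {
    set.seed(cell_seed(p$seed, i))
    x <- numeric(p$n_frames); y <- numeric(p$n_frames)
    x[1L] <- sph$center_x - p$lumen_offset
    y[1L] <- sph$center_y + stats::rnorm(1L, 0, p$lumen_jitter_sd)

    state <- "approach"        # approach -> dwell -> inside | reverse
    rm_label <- FALSE
    dwell_left <- NA_integer_
    rm_heading <- NA_real_
    heading <- atan2(sph$center_y - y[1L], sph$center_x - x[1L])

    for (t in 2:p$n_frames) {
      inside <- sqrt((x[t - 1L] - sph$center_x)^2 +
                     (y[t - 1L] - sph$center_y)^2) <= sph$radius
      speed <- rtrunc_speed(p$speed_mean, p$speed_sd)
      if (inside) speed <- speed * p$within_speed_factor

      if (state == "approach") {
        target <- atan2(sph$center_y - y[t - 1L], sph$center_x - x[t - 1L])
        heading <- blend_heading(heading, target, p$persistence) +
          (if (p$heading_noise_sd > 0) stats::rnorm(1L, 0, p$heading_noise_sd) else 0)
      } else if (state == "reverse") {
        heading <- blend_heading(heading, rm_heading, p$persistence) +
          (if (p$heading_noise_sd > 0) stats::rnorm(1L, 0, p$heading_noise_sd) else 0)
      } else {
        # dwell / unbiased inside: no directional memory or bias
        heading <- stats::runif(1L, -pi, pi)
      }

      x[t] <- x[t - 1L] + speed * p$frame_interval * cos(heading)
      y[t] <- y[t - 1L] + speed * p$frame_interval * sin(heading)

      if (state %in% c("dwell", "inside")) {
        # cells committed to the injury site stay there: fold any step
        # that would cross the boundary back inside (radial reflection)
        rr <- sqrt((x[t] - sph$center_x)^2 + (y[t] - sph$center_y)^2)
        if (rr > sph$radius) {
          refl <- max(2 * sph$radius - rr, 0) / rr
          x[t] <- sph$center_x + (x[t] - sph$center_x) * refl
          y[t] <- sph$center_y + (y[t] - sph$center_y) * refl
        }
      }

      now_inside <- sqrt((x[t] - sph$center_x)^2 +
                         (y[t] - sph$center_y)^2) <= sph$radius
      if (state == "approach" && now_inside) {
        state <- "dwell"
        dwell_left <- if (p$dwell_frames_mean > 0)
          stats::rgeom(1L, 1 / (1 + p$dwell_frames_mean)) else 0L
      } else if (state == "dwell") {
        if (dwell_left <= 0L) {
          if (stats::runif(1L) < p$p_rm) {
            state <- "reverse"
            rm_label <- TRUE
            rm_heading <- switch(p$rm_mode,
              toward_lumen = atan2(0, -1),  # straight back toward the lumen line
              random = stats::runif(1L, -pi, pi))
            heading <- rm_heading
          } else {
            state <- "inside"
          }
        } else {
          dwell_left <- dwell_left - 1L
        }
      }
    }

    rdist <- sqrt((x - sph$center_x)^2 + (y - sph$center_y)^2)
    contact <- which(rdist <= sph$radius)
    frames0 <- 0:(p$n_frames - 1L)
    all_pts[[i]] <- data.frame(cell_id = ids[i], frame = frames0,
                               x = x, y = y, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      cell_id = ids[i], rm_label = rm_label,
      entry_frame = if (length(contact)) frames0[min(contact)] else NA_integer_,
      exit_frame = if (length(contact)) frames0[max(contact)] else NA_integer_,
      stringsAsFactors = FALSE)
  }

  ts <- track_set(do.call(rbind, all_pts), frame_interval = p$frame_interval,
                  pixel_size = 1, spheroid = sph,
                  provenance = sprintf("simulate_trackset(seed=%d)", p$seed))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(tracks = ts, truth = truth)
}

#' Write ground-truth labels as JSON
#'
#' @param truth The `truth` data.frame from [simulate_trackset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- lapply(seq_len(nrow(truth)), function(i) {
    list(rm_label = truth$rm_label[i],
         entry_frame = if (is.na(truth$entry_frame[i])) NULL else truth$entry_frame[i],
         exit_frame = if (is.na(truth$exit_frame[i])) NULL else truth$exit_frame[i])
  })
  names(obj) <- truth$cell_id
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
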