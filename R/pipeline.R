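#' Pipeline configuration
#'
#' Exactly one input source must be set: a track file on disk
#' (`tracks_file`, with its acquisition metadata) or a simulation
#' (`sim`, a [simulation_params()]).
#'
#' @param out_dir Output directory (created if needed).
#' @param tracks_file Optional path to a delimited track table.
#' @param sim Optional [simulation_params()].
#' @param spheroid [spheroid_geometry()]; required for file input,
#'   defaults to the simulation's spheroid otherwise.
#' @param frame_interval,pixel_size Acquisition metadata; required for
#'   file input, taken from `sim` otherwise.
#' @param dialect [track_dialect()] for file input.
#' @param min_reverse_displacement Passed to
#'   [classify_reverse_migrated()].
#' @param density_points `"all"`: pool every track point into the KDE;
#'   `"final"`: final positions only.
#' @param density_segment Restrict the KDE to points of one segment
#'   (`"all"`, `"approach"`, `"within"`, `"reverse"`).
#' @param grid_n KDE grid nodes per axis.
#' @param seed Overrides `sim$seed` when simulating.
#' @param verbose Echo log lines to stderr as well as the run log.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            tracks_file = NULL,
                            sim = NULL,
                            spheroid = NULL,
                            frame_interval = NULL,
                            pixel_size = NULL,
                            dialect = track_dialect(),
                            min_reverse_displacement = 0,
                            density_points = c("all", "final"),
                            density_segment = c("all", "approach", "within", "reverse"),
                            grid_n = 128L,
                            seed = NULL,
                            verbose = FALSE) {
  density_points <- match.arg(density_points)
  density_segment <- match.arg(density_segment)
  if (is.null(tracks_file) == is.null(sim))
    rmt_stop("validation_error",
             "pipeline_config: exactly one of 'tracks_file' or 'sim' must be set")
  if (!is.null(tracks_file)) {
    if (is.null(spheroid) || is.null(frame_interval) || is.null(pixel_size))
      rmt_stop("validation_error",
               "pipeline_config: file input requires 'spheroid', 'frame_interval' and 'pixel_size'")
  } else if (!inherits(sim, "simulation_params")) {
    rmt_stop("validation_error", "pipeline_config: 'sim' must come from simulation_params()")
  }
  structure(list(out_dir = out_dir, tracks_file = tracks_file, sim = sim,
                 spheroid = spheroid, frame_interval = frame_interval,
                 pixel_size = pixel_size, dialect = dialect,
                 min_reverse_displacement = min_reverse_displacement,
                 density_points = density_points,
                 density_segment = density_segment,
                 grid_n = as.integer(grid_n), seed = seed,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

mean_sem <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(list(n = 0L, mean = NULL, sem = NULL))
  list(n = length(x), mean = mean(x),
       sem = if (length(x) > 1L) sem(x) else NULL)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) tracks, classifies reverse-migrated cells,
#' computes per-segment kinematics, evaluates the location KDE, and writes
#' the report bundle into `config$out_dir`:
#' `tracks.csv` + `truth.json` (simulated input only), `metrics.csv`,
#' `labels.json`, `density.csv`, `summary.json`, and `run.log`. All numeric
#' outputs are deterministic given the configuration, so re-running a
#' simulated configuration reproduces them byte-identically (only the log
#' carries timestamps).
#'
#' The summary reports cohort counts (cells, contacted, rM), per-segment
#' mean velocity and straightness with SEM, and the group comparisons that
#' reverse-migration reports typically annotate: Mann-Whitney tests of
#' approach vs within vs reverse velocity and of rM vs non-rM straightness.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the summary (as a list) and the paths of
#'   every file written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    rmt_stop("validation_error", "run_pipeline: 'config' must come from pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  log <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    writeLines(line, con)
    if (config$verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log("stage '%s' FAILED: %s", name, conditionMessage(e))
      rmt_stop("pipeline_error", "pipeline stage '%s' failed: %s",
               name, conditionMessage(e))
    })
  }

  log("rmtrack %s", as.character(utils::packageVersion("rmtrack")))
  paths <- list(log = log_path)
  truth <- NULL

  if (!is.null(config$sim)) {
    sim_params <- config$sim
    if (!is.null(config$seed)) {
      sim_params$seed <- as.integer(config$seed)
    }
    log("stage simulate: n_cells=%d n_frames=%d seed=%d p_rm=%g",
        sim_params$n_cells, sim_params$n_frames, sim_params$seed,
        sim_params$p_rm)
    sim <- stage("simulate", simulate_trackset(sim_params))
    ts <- sim$tracks
    truth <- sim$truth
    paths$tracks <- file.path(config$out_dir, "tracks.csv")
    paths$tracks_meta <- file.path(config$out_dir, "tracks_meta.json")
    write_tracks(ts, paths$tracks, paths$tracks_meta)
    paths$truth <- file.path(config$out_dir, "truth.json")
    write_ground_truth(truth, paths$truth)
  } else {
    log("stage ingest: %s", config$tracks_file)
    ts <- stage("ingest", read_tracks(
      config$tracks_file, dialect = config$dialect,
      pixel_size = config$pixel_size,
      frame_interval = config$frame_interval,
      spheroid = config$spheroid))
  }

  viol <- validate_trackset(ts)
  bad <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(bad)) {
    log("stage validate FAILED for cells: %s",
        paste(unique(bad$cell_id), collapse = ", "))
    rmt_stop("pipeline_error", "pipeline stage 'validate' failed for cell(s) %s: %s",
             paste(unique(bad$cell_id), collapse = ", "),
             paste(unique(bad$rule), collapse = "; "))
  }

  log("stage classify: min_reverse_displacement=%g um",
      config$min_reverse_displacement)
  labels <- stage("classify", classify_reverse_migrated(
    ts, min_reverse_displacement = config$min_reverse_displacement))
  paths$labels <- file.path(config$out_dir, "labels.json")
  lab_obj <- lapply(seq_len(nrow(labels)), function(i)
    list(rm = labels$rm[i], contacted = labels$contacted[i]))
  names(lab_obj) <- labels$cell_id
  jsonlite::write_json(lab_obj, paths$labels, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  log("stage metrics")
  metrics <- stage("metrics", cohort_segment_metrics(
    ts, min_reverse_displacement = config$min_reverse_displacement))
  paths$metrics <- file.path(config$out_dir, "metrics.csv")
  write_metrics_table(metrics, paths$metrics)

  log("stage density: points=%s segment=%s grid=%d",
      config$density_points, config$density_segment, config$grid_n)
  dgrid <- stage("density", {
    ats <- align_to_spheroid(ts)
    pts <- ats$points
    if (config$density_segment != "all") {
      keep <- lapply(split_tracks(ats), function(p) {
        if (nrow(p) < 1L) return(NULL)
        seg <- segment_track(p, ats$spheroid$radius)
        p[seg[[paste0(config$density_segment, "_idx")]], , drop = FALSE]
      })
      pts <- do.call(rbind, keep)
    }
    if (config$density_points == "final")
      pts <- do.call(rbind, lapply(split(pts, pts$cell_id), function(p)
        p[nrow(p), , drop = FALSE]))
    kde_heatmap(pts, n_grid = config$grid_n)
  })
  paths$density <- file.path(config$out_dir, "density.csv")
  write_density_csv(dgrid, paths$density)

  log("stage report")
  per_segment <- lapply(
    stats::setNames(nm = c("approach", "within", "reverse", "whole")),
    function(seg) {
      m <- metrics[metrics$segment == seg, , drop = FALSE]
      list(n_cells = nrow(m),
           velocity = mean_sem(m$mean_velocity),
           straightness = mean_sem(m$str))
    })
  cmp <- list()
  va <- metrics$mean_velocity[metrics$segment == "approach"]
  vw <- metrics$mean_velocity[metrics$segment == "within"]
  vr <- metrics$mean_velocity[metrics$segment == "reverse"]
  safe_cmp <- function(a, b) {
    if (length(a) >= 2L && length(b) >= 2L)
      unclass(group_comparison(a, b, "mann_whitney")) else NULL
  }
  cmp$velocity_approach_vs_within <- safe_cmp(va, vw)
  cmp$velocity_within_vs_reverse <- safe_cmp(vw, vr)
  sw <- metrics[metrics$segment == "whole", , drop = FALSE]
  cmp$straightness_rm_vs_nonrm <- safe_cmp(sw$str[sw$rm], sw$str[!sw$rm])

  summary <- list(
    n_cells = length(track_ids(ts)),
    n_contacted = sum(labels$contacted),
    n_rm = sum(labels$rm),
    min_reverse_displacement = config$min_reverse_displacement,
    spheroid = unclass(if (!is.null(ts$spheroid)) ts$spheroid else config$spheroid),
    frame_interval = ts$frame_interval,
    kde = list(bandwidth_x = dgrid$bandwidth_x,
               bandwidth_y = dgrid$bandwidth_y,
               n_points = dgrid$n_points,
               integral = density_integral(dgrid)),
    segments = per_segment,
    comparisons = cmp)
  if (!is.null(truth))
    summary$ground_truth <- list(
      n_rm_true = sum(truth$rm_label),
      classifier_accuracy = mean(labels$rm[match(truth$cell_id, labels$cell_id)] ==
                                   truth$rm_label))
  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  log("done: %d cells, %d contacted, %d rM",
      summary$n_cells, summary$n_contacted, summary$n_rm)

  invisible(list(summary = summary, paths = paths, metrics = metrics,
                 labels = labels, truth = truth, density = dgrid))
}

#' Two-group comparison for report annotation
#'
#' Thin wrapper over [stats::wilcox.test()] (Mann-Whitney) or
#' [stats::t.test()] (Welch) returning the statistic, the two-sided
#' p-value, group means with standard errors, and the conventional
#' significance label (ns, *, **, ***). The Mann-Whitney path always uses
#' the normal approximation so that heavily tied data (e.g. two identical
#' groups) is handled without method switching.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @param test `"mann_whitney"` or `"t"`.
#' @return A list of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, `n_a`, `n_b`, `mean_a`, `mean_b`, `sem_a`, `sem_b`,
#'   `significance`.
#' @examples
#' group_comparison(rnorm(10), rnorm(10, 2), "mann_whitney")
#' @export
group_comparison <- function(a, b, test = c("mann_whitney", "t")) {
  test <- match.arg(test)
  if (length(a) < 2L)
    rmt_stop("validation_error", "group_comparison: group 'a' needs >= 2 values (got %d)", length(a))
  if (length(b) < 2L)
    rmt_stop("validation_error", "group_comparison: group 'b' needs >= 2 values (got %d)", length(b))
  ht <- switch(test,
    mann_whitney = stats::wilcox.test(a, b, exact = FALSE, correct = TRUE),
    t = stats::t.test(a, b, var.equal = FALSE))
  structure(list(
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    sem_a = sem(a), sem_b = sem(b),
    significance = significance_label(ht$p.value)),
    class = "group_comparison")
}

#' Conventional significance label
#'
#' `ns` for p >= 0.05, then `*` (< 0.05), `**` (< 0.01), `***` (< 0.001).
#'
#' @param p A p-value.
#' @return A character label.
#' @export
significance_label <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: statistic %.6g, p = %.4g (%s)\n  a: n=%d mean=%.6g sem=%.3g | b: n=%d mean=%.6g sem=%.3g\n",
    x$test, x$statistic, x$p_value, x$significance,
    x$n_a, x$mean_a, x$sem_a, x$n_b, x$mean_b, x$sem_b))
  invisible(x)
}
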