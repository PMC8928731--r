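#' Run the end-to-end microbead analysis pipeline
#'
#' Orchestrates simulate -> detect -> morphometry / PFO / permeability on
#' synthetic scenes from a single JSON-style configuration, writing
#' standard-format outputs (TIFF scenes, JSON ground truth and summaries,
#' CSV tables) plus a run manifest.  Re-running with an identical
#' configuration and seed reproduces all CSV/JSON outputs bit-identically.
#'
#' The configuration is a list (or path to a JSON file) with blocks:
#' \describe{
#'   \item{seed}{Global integer seed (required).}
#'   \item{pixel_size_um}{Calibration used throughout (required).}
#'   \item{simulate}{\code{n_beads}, \code{diameter_mean_um},
#'     \code{diameter_sd_um}, optional \code{spheroid_rate},
#'     \code{noise_sd}, \code{field_width_px}, \code{field_height_px}.}
#'   \item{detect}{Optional overrides for [detection_config()] fields.}
#'   \item{morphometry}{Optional: \code{bin_width_um},
#'     \code{include_satellites}, \code{count_spheroids} (logical).}
#'   \item{pfo}{Optional: \code{groups}, a list of cohorts with
#'     \code{label}, \code{n_beads}, \code{coverage_min}, \code{coverage_max},
#'     optional \code{diameter_um}.  Each cohort is rendered one bead per
#'     scene, detected, scored and summarized.}
#'   \item{permeability}{Optional: \code{probes}, a list with \code{label}
#'     and \code{permeation_fraction}; plus optional \code{n_beads} (per
#'     probe, default 11), \code{timepoint_h}, \code{noise_sd},
#'     \code{anchor_100}, \code{anchor_0}.}
#' }
#'
#' @param config Configuration list or path to a JSON file.
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (also written to \code{manifest.json}),
#'   invisibly structured as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  px <- config$pixel_size_um
  manifest <- list(package_version = as.character(utils::packageVersion("beadmetrics")),
                   seed = seed,
                   config_hash = config_hash(config),
                   stages = list())
  log_line(seed, "run started")

  stage_paths <- list()
  detections <- NULL
  scene_set <- NULL

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    pop <- sample_bead_population(
      n = sim$n_beads, diameter_mean_um = sim$diameter_mean_um,
      diameter_sd_um = sim$diameter_sd_um,
      spheroid_rate = sim$spheroid_rate %||% 0, seed = seed,
      field_width_px = sim$field_width_px %||% 1024,
      field_height_px = sim$field_height_px %||% 1024,
      pixel_size_um = px)
    scene_set <- render_scene_set(pop, noise_sd = sim$noise_sd %||% 0.02,
                                  seed = seed)
    truth_rows <- list()
    for (f in seq_along(scene_set)) {
      base <- file.path(out_dir, sprintf("scene_%03d", f))
      write_scene(scene_set[[f]]$scene, paste0(base, ".tif"))
      write_truth(scene_set[[f]]$truth, paste0(base, ".json"))
      tr <- scene_set[[f]]$truth$beads
      tr$scene_id <- f
      truth_rows[[f]] <- tr
    }
    truth_all <- do.call(rbind, truth_rows)
    stage_paths$simulate <- "scene_*.tif"
    manifest$stages$simulate <- list(n_scenes = length(scene_set),
                                     n_beads = nrow(truth_all))
    log_line(seed, sprintf("simulate: %d scene(s), %d bead(s)",
                           length(scene_set), nrow(truth_all)))
  }

  if (!is.null(config$detect)) {
    if (is.null(scene_set)) stop("detect stage requires the simulate stage")
    dcfg <- do.call(detection_config, config$detect %||% list())
    det_rows <- list()
    for (f in seq_along(scene_set)) {
      det <- detect_beads(scene_set[[f]]$scene, dcfg)
      if (nrow(det)) det$scene_id <- f
      det_rows[[f]] <- det
    }
    detections <- do.call(rbind, det_rows)
    write.csv(detections, file.path(out_dir, "beads.csv"),
              row.names = FALSE)
    stage_paths$detect <- "beads.csv"
    manifest$stages$detect <- list(n_detections = nrow(detections),
                                   output = "beads.csv")
    log_line(seed, sprintf("detect: %d bead(s)", nrow(detections)))
  }

  if (!is.null(config$morphometry) && !is.null(detections)) {
    mo <- config$morphometry
    st <- population_stats(detections, bin_width_um = mo$bin_width_um %||% 10,
                           include_satellites = isTRUE(mo$include_satellites))
    jsonlite::write_json(unclass(st), file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (isTRUE(mo$count_spheroids)) {
      sph <- do.call(rbind, lapply(seq_along(scene_set), function(f) {
        d <- detections[detections$scene_id == f, , drop = FALSE]
        if (!nrow(d)) return(NULL)
        data.frame(scene_id = f, bead_id = d$bead_id,
                   spheroid_count = vapply(seq_len(nrow(d)), function(i)
                     as.integer(count_spheroids(scene_set[[f]]$scene,
                                                d[i, ])), integer(1)))
      }))
      write.csv(sph, file.path(out_dir, "spheroids.csv"), row.names = FALSE)
    }
    manifest$stages$morphometry <- list(n_beads = st$n_beads,
                                        mean_diameter_um = st$mean_diameter_um)
    log_line(seed, "morphometry done")
  }

  if (!is.null(config$pfo)) {
    summaries <- list()
    pfo_rows <- list()
    for (gi in seq_along(config$pfo$groups)) {
      g <- config$pfo$groups[[gi]]
      res <- simulate_pfo_cohort(
        n_beads = g$n_beads, coverage_min = g$coverage_min,
        coverage_max = g$coverage_max,
        diameter_um = g$diameter_um %||% 650, pixel_size_um = px,
        seed = seed + 1000L * gi,
        detect_config = do.call(detection_config, config$detect %||% list()))
      summaries[[g$label]] <- unclass(summarize_cohort(res$records, g$label))
      res$records$group_label <- g$label
      pfo_rows[[gi]] <- res$records
    }
    pfo_all <- do.call(rbind, pfo_rows)
    write.csv(pfo_all, file.path(out_dir, "pfo.csv"), row.names = FALSE)
    jsonlite::write_json(summaries, file.path(out_dir, "pfo_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$pfo <- list(n_groups = length(summaries),
                                output = "pfo_summary.json")
    log_line(seed, sprintf("pfo: %d cohort(s)", length(summaries)))
  }

  if (!is.null(config$permeability)) {
    pm <- config$permeability
    lad <- simulate_permeability_ladder(
      probes = pm$probes, n_beads = pm$n_beads %||% 11,
      pixel_size_um = px, seed = seed + 50000L,
      noise_sd = pm$noise_sd %||% 0.01,
      timepoint_h = pm$timepoint_h %||% NA_real_)
    write.csv(lad$records, file.path(out_dir, "permeability.csv"),
              row.names = FALSE)
    norm <- normalize_permeation(lad$mean_ratios,
                                 anchor_100 = pm$anchor_100 %||% "4 kDa",
                                 anchor_0 = pm$anchor_0 %||% "2 MDa")
    jsonlite::write_json(as.list(norm),
                         file.path(out_dir, "permeability_normalized.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$permeability <- list(n_probes = length(lad$mean_ratios),
                                         output = "permeability_normalized.json")
    log_line(seed, "permeability done")
  }

  manifest$outputs <- stage_paths
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(seed, "run finished")
  invisible(manifest)
}

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  if (is.null(config$seed) || is.null(config$pixel_size_um))
    stop("config requires 'seed' and 'pixel_size_um'")
  if (!is.null(config$simulate)) {
    need <- c("n_beads", "diameter_mean_um", "diameter_sd_um")
    miss <- setdiff(need, names(config$simulate))
    if (length(miss))
      stop("simulate block is missing: ", paste(miss, collapse = ", "))
  }
  if (!is.null(config$pfo) && is.null(config$pfo$groups))
    stop("pfo block requires 'groups'")
  invisible(TRUE)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tf))
}

log_line <- function(seed, msg) {
  message(sprintf("[%s] [INFO] [seed %d] %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), seed, msg))
}

#' Simulate, detect and score one PFO cohort
#'
#' Renders \code{n_beads} single-bead brightfield scenes whose ground-truth
#' overgrowth coverage is drawn uniformly in
#' \code{[coverage_min, coverage_max]}, runs detection and ray-based
#' coverage scoring, and returns per-bead records alongside the ground
#' truth.
#'
#' @param n_beads Number of beads (one scene each).
#' @param coverage_min,coverage_max Ground-truth coverage range in [0, 1].
#' @param diameter_um Bead diameter.
#' @param pixel_size_um Calibration, default 4 um/px.
#' @param noise_sd Scene noise, default 0.02.
#' @param seed Base seed.
#' @param detect_config A [detection_config()].
#' @param arc_contrast,band_width_um Overgrowth rendering parameters.
#' @return List with \code{records} (bead_id, coverage_fraction,
#'   coverage_category, true_coverage) and \code{n_detected}.
#' @export
simulate_pfo_cohort <- function(n_beads, coverage_min, coverage_max,
                                diameter_um = 650, pixel_size_um = 4,
                                noise_sd = 0.02, seed = 1L,
                                detect_config = detection_config(),
                                arc_contrast = 0.6, band_width_um = 40) {
  seed <- as.integer(seed)
  covs <- withr::with_seed(seed, runif(n_beads, coverage_min, coverage_max))
  side <- ceiling((diameter_um / 2 + band_width_um + 40) * 2 / pixel_size_um)
  side <- max(side, 64)
  rows <- list()
  n_det <- 0L
  for (i in seq_len(n_beads)) {
    starts <- withr::with_seed(seed + i, runif(1, 0, 360))
    arcs <- if (covs[i] > 0)
      data.frame(start_deg = starts %% 360,
                 end_deg = (starts + 360 * covs[i]) %% 360,
                 band_width_um = band_width_um, contrast = arc_contrast)
    else NULL
    if (!is.null(arcs) && covs[i] >= 1 - 1e-9)
      arcs <- data.frame(start_deg = 0, end_deg = 360,
                         band_width_um = band_width_um,
                         contrast = arc_contrast)
    spec <- scene_spec(side, side, pixel_size_um, "brightfield",
                       noise_sd = noise_sd, seed = seed + i)
    ctr <- (side - 1) / 2
    bead <- bead_spec(ctr, ctr, diameter_um, overgrowth_arcs = arcs)
    sc <- render_brightfield_scene(spec, bead)
    det <- detect_beads(sc$scene, detect_config)
    if (!nrow(det)) next
    n_det <- n_det + 1L
    rec <- pfo_records(sc$scene, det[1, , drop = FALSE])
    rec$bead_id <- i
    rec$true_coverage <- covs[i]
    rows[[length(rows) + 1L]] <- rec
  }
  records <- do.call(rbind, rows)
  list(records = records, n_detected = n_det)
}

#' Simulate a FITC-dextran permeability ladder
#'
#' Renders one fluorescence scene per probe condition (each with
#' \code{n_beads} beads at that probe's true permeation fraction), detects
#' the beads, and computes per-bead permeability records and per-probe mean
#' raw ratios.
#'
#' @param probes Either a named numeric vector of permeation fractions or a
#'   list of lists with \code{label} and \code{permeation_fraction}.
#' @param n_beads Beads per probe scene, default 11.
#' @param pixel_size_um Calibration, default 4.
#' @param noise_sd Scene noise, default 0.01.
#' @param seed Base seed.
#' @param timepoint_h Metadata carried into the records.
#' @param use_truth_positions Use ground-truth bead geometry instead of
#'   Hough detection (needed when a probe renders beads indistinguishable
#'   from the background, i.e. permeation 1).
#' @return List with \code{records} (per bead) and \code{mean_ratios}
#'   (named vector, one per probe, ready for [normalize_permeation()]).
#' @export
simulate_permeability_ladder <- function(probes, n_beads = 11,
                                         pixel_size_um = 4, noise_sd = 0.01,
                                         seed = 1L, timepoint_h = NA_real_,
                                         use_truth_positions = FALSE,
                                         field_width_px = 1024,
                                         field_height_px = 1024) {
  if (is.list(probes) && !is.null(probes[[1]]$label))
    probes <- setNames(vapply(probes, `[[`, numeric(1),
                              "permeation_fraction"),
                       vapply(probes, `[[`, character(1), "label"))
  seed <- as.integer(seed)
  pop <- sample_bead_population(n_beads, 650, 25, seed = seed,
                               field_width_px = field_width_px,
                               field_height_px = field_height_px,
                               pixel_size_um = pixel_size_um)
  rows <- list()
  for (k in seq_along(probes)) {
    beads <- lapply(pop, function(b) {
      b$permeation_fraction <- unname(probes[k]); b
    })
    fields <- vapply(beads, `[[`, integer(1), "field_index")
    recs <- list()
    for (f in seq_len(attr(pop, "n_fields"))) {
      spec <- scene_spec(field_width_px, field_height_px, pixel_size_um,
                         "fluorescence",
                         noise_sd = noise_sd, background_level = 0.9,
                         seed = seed + 100L * k + f)
      sc <- render_fluorescence_scene(spec, beads[fields == f])
      det <- if (use_truth_positions) beads_from_truth(sc$truth)
             else detect_beads(sc$scene)
      if (!nrow(det)) next
      recs[[length(recs) + 1L]] <-
        permeability_records(sc$scene, det, names(probes)[k], timepoint_h)
    }
    rows[[k]] <- do.call(rbind, recs)
  }
  records <- do.call(rbind, rows)
  mean_ratios <- vapply(split(records$raw_ratio, records$probe_label), mean,
                        numeric(1))[names(probes)]
  list(records = records, mean_ratios = mean_ratios)
}

#' Convert a ground-truth record to a detections table
#'
#' Builds a \code{"detected_beads"} data.frame from a scene's ground truth,
#' for oracle-style evaluations that bypass detection.
#'
#' @param truth A \code{"bead_truth"}.
#' @return A \code{"detected_beads"} data.frame.
#' @export
beads_from_truth <- function(truth) {
  b <- truth$beads
  px <- truth$spec$pixel_size_um
  out <- data.frame(bead_id = b$bead_id, center_x_px = b$center_x_px,
                    center_y_px = b$center_y_px,
                    radius_px = b$diameter_um / 2 / px,
                    diameter_um = b$diameter_um,
                    accumulator_score = 1,
                    malformed_flag = FALSE, satellite_flag = FALSE)
  class(out) <- c("detected_beads", class(out))
  out
}

#' Evaluate pipeline output against ground truth
#'
#' Pairs detections with ground-truth beads by greedy nearest-first
#' assignment within a matching radius and reports detection
#' precision/recall, diameter mean absolute error, and (when supplied)
#' spheroid exact-match rate, permeation MAE and coverage MAE.
#'
#' @param detections A \code{"detected_beads"} data.frame.
#' @param truth A \code{"bead_truth"} (or its \code{beads} data.frame).
#' @param spheroid_counts Optional integer vector aligned with the matched
#'   detections (by detection row).
#' @param permeability Optional data.frame with \code{bead_id} (detection)
#'   and \code{normalized_permeation_pct}.
#' @param pfo Optional data.frame with \code{bead_id} (detection) and
#'   \code{coverage_fraction}.
#' @param match_radius_px Maximum centre distance for a match, default 5 px.
#' @return List of metrics: \code{n_truth}, \code{n_detected},
#'   \code{n_matched}, \code{precision}, \code{recall},
#'   \code{diameter_mae_um}, and optional \code{spheroid_exact_match_rate},
#'   \code{permeation_mae_pct}, \code{coverage_mae}.
#' @export
evaluate_against_truth <- function(detections, truth, spheroid_counts = NULL,
                                   permeability = NULL, pfo = NULL,
                                   match_radius_px = 5) {
  tb <- if (inherits(truth, "bead_truth")) truth$beads else truth
  if (is.null(tb)) stop("ground truth is required")
  m <- match_detections(detections, tb, match_radius_px)
  matched <- m[!is.na(m$truth_row), , drop = FALSE]
  out <- list(
    n_truth = nrow(tb), n_detected = nrow(detections),
    n_matched = nrow(matched),
    precision = if (nrow(detections)) nrow(matched) / nrow(detections)
                else NA_real_,
    recall = if (nrow(tb)) nrow(matched) / nrow(tb) else NA_real_,
    diameter_mae_um = if (nrow(matched))
      mean(abs(detections$diameter_um[matched$det_row] -
                 tb$diameter_um[matched$truth_row])) else NA_real_)
  if (!is.null(spheroid_counts) && nrow(matched))
    out$spheroid_exact_match_rate <-
      mean(spheroid_counts[matched$det_row] ==
             tb$spheroid_count[matched$truth_row])
  if (!is.null(permeability) && nrow(matched)) {
    i <- match(detections$bead_id[matched$det_row], permeability$bead_id)
    out$permeation_mae_pct <-
      mean(abs(permeability$normalized_permeation_pct[i] -
                 100 * tb$permeation_fraction[matched$truth_row]),
           na.rm = TRUE)
  }
  if (!is.null(pfo) && nrow(matched)) {
    i <- match(detections$bead_id[matched$det_row], pfo$bead_id)
    out$coverage_mae <- mean(abs(pfo$coverage_fraction[i] -
                                   tb$coverage_fraction[matched$truth_row]),
                             na.rm = TRUE)
  }
  out
}

# Greedy nearest-first one-to-one assignment of detections to truths.
match_detections <- function(detections, truth_beads, match_radius_px = 5) {
  nd <- nrow(detections); nt <- nrow(truth_beads)
  res <- data.frame(det_row = seq_len(nd), truth_row = NA_integer_)
  if (!nd || !nt) return(res)
  D <- outer(detections$center_x_px, truth_beads$center_x_px, "-")^2 +
       outer(detections$center_y_px, truth_beads$center_y_px, "-")^2
  D <- sqrt(D)
  pairs <- which(D <= match_radius_px, arr.ind = TRUE)
  if (!nrow(pairs)) return(res)
  ord <- order(D[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_d[i] && !used_t[j]) {
      res$truth_row[i] <- j
      used_d[i] <- TRUE; used_t[j] <- TRUE
    }
  }
  res
}
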