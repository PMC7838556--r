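## End-to-end orchestration: synthesize -> normalize -> train -> segment ->
## PTS -> cohort statistics, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every stage's parameters plus a single root seed; per-stage seeds
#' are derived from it (`seed * 31 + stage index`, kept under 2^31) so each
#' stage is independently reproducible.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_tiles Number of synthetic training tiles.
#' @param tile_spec A [tile_spec()] for tile synthesis.
#' @param unet A [unet_config()].
#' @param n_slides Number of synthetic whole-slide label maps.
#' @param slide_size Synthetic slide side in pixels.
#' @param se_radius Structuring-element disk radius for PTS scoring.
#' @param cohort_spec A [cohort_spec()].
#' @param stain_target A [stain_model()] used as normalization reference.
#' @param normalize Apply Macenko + histogram normalization to tiles/slides.
#' @param seed Root seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            n_tiles = 210L,
                            tile_spec = ptsscore::tile_spec(tile_size = 32L,
                                                           noise_sd = 8),
                            unet = unet_config(input_size = 32L, depth = 2L,
                                               base_filters = 8L,
                                               learning_rate = 1e-2,
                                               max_epochs = 8L, patience = 4L),
                            n_slides = 5L, slide_size = 96L,
                            se_radius = 8L,
                            cohort_spec = ptsscore::cohort_spec(n = 200L),
                            stain_target = default_stain_target(),
                            normalize = FALSE,
                            seed = 1L) {
  structure(list(out_dir = out_dir, n_tiles = as.integer(n_tiles),
                 tile_spec = tile_spec, unet = unet,
                 n_slides = as.integer(n_slides),
                 slide_size = as.integer(slide_size),
                 se_radius = as.integer(se_radius),
                 cohort_spec = cohort_spec, stain_target = stain_target,
                 normalize = isTRUE(normalize), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads the scalar fields (`n_tiles`, `tile_size`, `noise_sd`, U-Net block,
#' `n_slides`, `slide_size`, `se_radius`, cohort
#' `n_patients`/`beta0`/`beta1`, `normalize`, `seed`) and builds the nested
#' spec objects with package defaults for anything unstated. (The cohort size
#' key is spelled `n_patients` because a bare `n` is a YAML 1.1 boolean.)
#'
#' @param path YAML file.
#' @param out_dir Output directory (overrides the file if given).
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  g <- function(nm, default) if (is.null(y[[nm]])) default else y[[nm]]
  u <- y$unet
  gu <- function(nm, default) if (is.null(u[[nm]])) default else u[[nm]]
  cs <- y$cohort
  gc_ <- function(nm, default) if (is.null(cs[[nm]])) default else cs[[nm]]
  pipeline_config(
    out_dir = if (is.null(out_dir)) g("out_dir", ".") else out_dir,
    n_tiles = g("n_tiles", 70L),
    tile_spec = tile_spec(tile_size = g("tile_size", 32L),
                          noise_sd = g("noise_sd", 8)),
    unet = unet_config(input_size = gu("input_size", g("tile_size", 32L)),
                       depth = gu("depth", 2L),
                       base_filters = gu("base_filters", 8L),
                       learning_rate = gu("learning_rate", 1e-3),
                       batch_size = gu("batch_size", 8L),
                       max_epochs = gu("max_epochs", 8L),
                       patience = gu("patience", 4L),
                       min_gain = gu("min_gain", 0.001)),
    n_slides = g("n_slides", 5L), slide_size = g("slide_size", 96L),
    se_radius = g("se_radius", 8L),
    cohort_spec = cohort_spec(n = gc_("n_patients", 200L),
                              beta0 = gc_("beta0", -1.69),
                              beta1 = gc_("beta1", log(29.654))),
    normalize = g("normalize", FALSE),
    seed = g("seed", 1L))
}

stage_seed <- function(config, k) (config$seed * 31L + k) %% .Machine$integer.max

preprocess_tile <- function(tile, config) {
  if (!config$normalize) return(tile)
  out <- tryCatch(
    normalize_macenko(tile, config$stain_target),
    error = function(e) tile)  # blank windows: keep as-is
  histogram_normalize(out)
}

#' Run the pipeline end to end
#'
#' Stages, in order: synthesize labeled tiles, slides and a cohort; normalize
#' tiles (optional); split and train the segmenter; segment each synthetic
#' slide and compute its PTS score; merge scores into the cohort (one
#' representative slide per patient); run the cohort statistics. Every
#' stage's outputs are written under `config$out_dir` before the next stage
#' starts; a failure stops the run naming the stage. Returns a manifest with
#' per-stage timings and MD5 checksums of all outputs; re-running with the
#' same config and seed reproduces the checksums.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Object of class `run_manifest`: list with `config_hash`, `stages`
#'   (timings), `checksums`, `outputs`.
#' @export
run_end_to_end <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  outputs <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  run_stage <- function(name, fn) {
    s <- Sys.time()
    out <- tryCatch(fn(), error = function(e)
      stop(sprintf("%s stage: %s", name, conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    say("stage %-12s %6.1fs", name, timings[[name]])
    out
  }

  synth <- run_stage("synth", function() {
    tiles <- make_labeled_tiles(config$tile_spec, config$n_tiles,
                                seed = stage_seed(config, 1L))
    slides <- lapply(seq_len(config$n_slides), function(i) {
      sz <- config$slide_size
      t4 <- as.integer(round(sz * 0.6))
      hole <- as.integer(round(sz * 0.15))
      spec <- wsi_geometry_spec(
        canvas = c(sz, sz),
        tumor = c((sz - t4) %/% 2L, (sz - t4) %/% 2L, t4, t4),
        holes = list(c((sz - hole) %/% 2L + 2L * i, (sz - hole) %/% 2L,
                       hole, hole)),
        band = max(3L, sz %/% 16L))
      w <- make_wsi_labelmap(spec)
      w$rgb <- render_labelmap_rgb(w$labels, config$tile_spec$means,
                                   noise_sd = config$tile_spec$noise_sd,
                                   seed = stage_seed(config, 10L + i))
      w
    })
    cohort <- make_cohort(config$cohort_spec, seed = stage_seed(config, 2L))
    write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
    for (i in seq_along(slides)) {
      write_labelmap(slides[[i]]$labels,
                     file.path(config$out_dir, sprintf("slide_%02d_truth.png", i)))
      write_tile(slides[[i]]$rgb,
                 file.path(config$out_dir, sprintf("slide_%02d.png", i)))
    }
    outputs <<- c(outputs, "cohort.csv",
                  sprintf("slide_%02d_truth.png", seq_along(slides)),
                  sprintf("slide_%02d.png", seq_along(slides)))
    list(tiles = tiles, slides = slides, cohort = cohort)
  })

  model <- run_stage("train", function() {
    tiles <- synth$tiles
    if (config$normalize)
      tiles <- lapply(tiles, function(p) {
        p$tile <- preprocess_tile(p$tile, config); p
      })
    sp <- split_dataset(tiles, seed = stage_seed(config, 3L))
    cfg <- config$unet
    cfg$seed <- stage_seed(config, 4L)
    train_segmenter(sp$train, sp$validation, cfg)
  })

  scored <- run_stage("segment", function() {
    lapply(seq_along(synth$slides), function(i) {
      rgb <- synth$slides[[i]]$rgb
      if (config$normalize) rgb <- preprocess_tile(rgb, config)
      pred <- predict_labelmap(model, rgb)
      write_labelmap(pred$labels,
                     file.path(config$out_dir, sprintf("slide_%02d_pred.png", i)))
      outputs <<- c(outputs, sprintf("slide_%02d_pred.png", i))
      pred$labels
    })
  })

  pts <- run_stage("pts", function() {
    res <- lapply(seq_along(scored), function(i) {
      # a slide where the segmenter found no tumor is unscorable, not fatal:
      # the patient ends up with a missing score downstream
      r <- tryCatch(compute_pts(scored[[i]], se_disk(config$se_radius)),
                    error = function(e) {
                      warning(sprintf("slide %02d unscorable: %s", i,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
      if (!is.null(r)) {
        write_pts_json(r, file.path(config$out_dir, sprintf("slide_%02d_pts.json", i)))
        outputs <<- c(outputs, sprintf("slide_%02d_pts.json", i))
      }
      r
    })
    names(res) <- sprintf("slide_%02d", seq_along(res))
    res[!vapply(res, is.null, logical(1))]
  })

  merged <- run_stage("merge", function() {
    idx <- as.integer(sub("slide_", "", names(pts)))  # slide i <-> patient i
    scores <- data.frame(
      slide_id = paste0(synth$cohort$patient_id[idx], "-S1"),
      patient_id = synth$cohort$patient_id[idx],
      pts_score = vapply(pts, function(r) r$score, numeric(1)))
    out <- merge_scores(synth$cohort, scores)
    write_cohort_csv(out, file.path(config$out_dir, "cohort_scored.csv"))
    outputs <<- c(outputs, "cohort_scored.csv")
    out
  })

  run_stage("cohort_stats", function() {
    tab1 <- table1_descriptives(merged)
    assoc <- pts_association(merged)
    sub <- subgroup_by_tstage(merged)
    roc <- roc_auc(merged$pts_score, merged$lnm)
    report <- list(
      group_sizes = as.list(tab1$group_sizes$n),
      association = assoc[, c("outcome", "or", "ci_lower", "ci_upper",
                              "p_value", "n")],
      subgroups = sub[, c("stratum", "outcome", "or", "p_value", "n")],
      auc = list(auc = roc$auc, ci_lower = roc$ci_lower,
                 ci_upper = roc$ci_upper))
    jsonlite::write_json(report, file.path(config$out_dir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows")
    outputs <<- c(outputs, "cohort_report.json")
    report
  })

  cfg_file <- file.path(config$out_dir, "config.json")
  cfg_plain <- rapply(unclass(config), function(x) x, how = "replace")
  jsonlite::write_json(cfg_plain, cfg_file, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  checks <- tools::md5sum(file.path(config$out_dir, outputs))
  names(checks) <- outputs
  manifest <- structure(list(
    config_hash = unname(tools::md5sum(cfg_file)),
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    stages = timings, checksums = checks, outputs = outputs),
    class = "run_manifest")
  jsonlite::write_json(list(config_hash = manifest$config_hash,
                            stages = timings,
                            checksums = as.list(checks)),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("pipeline run: %d outputs, %.1fs total (config %s)\n",
              length(x$outputs), x$total_seconds, substr(x$config_hash, 1, 8)))
  for (s in names(x$stages)) cat(sprintf("  %-12s %6.1fs\n", s, x$stages[[s]]))
  invisible(x)
}

#' Merge per-slide PTS scores into a cohort table
#'
#' Keeps exactly one score per patient. Patients with several scored slides
#' are resolved to the lexicographically first slide ID (the representative
#' slide), with a message; patients with no scorable slide keep their
#' existing `pts_score` if present, otherwise `NA`, with a warning.
#'
#' @param cohort Cohort data.frame with `patient_id`.
#' @param scores Data frame with columns `slide_id`, `patient_id`,
#'   `pts_score`.
#' @return The cohort with its `pts_score` column updated.
#' @export
merge_scores <- function(cohort, scores) {
  stopifnot(all(c("slide_id", "patient_id", "pts_score") %in% names(scores)))
  scores <- scores[order(scores$patient_id, scores$slide_id), , drop = FALSE]
  dup <- duplicated(scores$patient_id)
  if (any(dup)) {
    for (p in unique(scores$patient_id[dup]))
      message(sprintf("patient %s: %d slides, keeping representative slide %s",
                      p, sum(scores$patient_id == p),
                      scores$slide_id[scores$patient_id == p][1]))
    scores <- scores[!dup, , drop = FALSE]
  }
  idx <- match(cohort$patient_id, scores$patient_id)
  if (!"pts_score" %in% names(cohort)) cohort$pts_score <- NA_real_
  has <- !is.na(idx)
  cohort$pts_score[has] <- scores$pts_score[idx[has]]
  uncovered <- !has & is.na(cohort$pts_score)
  if (any(uncovered))
    warning(sprintf("%d patient(s) without a scorable slide: pts_score missing",
                    sum(uncovered)), call. = FALSE)
  cohort
}
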