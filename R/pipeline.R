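#' Default end-to-end pipeline configuration
#'
#' Configuration for the six-stage pipeline: simulate (standing in for data
#' collection) -> preprocess -> augment -> train -> evaluate -> export.
#' Any subset of fields can be overridden via a nested list or a YAML file
#' with the same structure.
#'
#' @param out_dir run directory for artifacts.
#' @param seed master seed; stage seeds derive from it.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(out_dir = tempfile("sitsense_run_"), seed = 42L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    sim = list(n_per_class = 151L, classes = posture_codes(),
               include_empty = FALSE),
    preprocess = list(drop_empty_threshold = 500, normalize = TRUE),
    augment = list(enabled = TRUE, copies_per_frame = 3L, noise_level = 0.5,
                   shift_max = 10L, rotation_max = 30,
                   erase_area_fraction = 0.10, elastic_alpha = 24,
                   elastic_sigma = 4, per_transform_probability = 0.5),
    split = list(train_fraction = 0.8, val_fraction = 0.1,
                 test_fraction = 0.1, stratified = TRUE),
    models = c("dt", "rf", "svm", "knn", "cnn"),
    resolution_study = list(enabled = FALSE,
                            resolutions = c(2, 3, 5, 10, 20, 32))
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

digest_file <- function(path) unname(tools::md5sum(path))

#' Run the six-stage pipeline
#'
#' Executes simulate -> preprocess -> augment -> train -> evaluate ->
#' export under one configuration, writing every artifact (frame
#' containers, trained models, evaluation reports, CNN learning curves,
#' optional resolution-study table) into the run directory together with a
#' reproducibility manifest recording the configuration snapshot, stage
#' seeds, artifact MD5 digests and timings. A stage failure aborts with
#' the failing stage named; artifacts of completed stages are retained.
#'
#' @param config a [pipeline_config()]-style nested list, a partial
#'   override of it, or a path to a YAML file holding one.
#' @param quiet suppress progress messages.
#' @return The run manifest (invisibly also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("sitsense")),
                   config = cfg, stages = list())
  t_all <- Sys.time()
  stage <- function(name, code) {
    t0 <- Sys.time()
    say("stage %s ...", name)
    res <- tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(
      list(seconds = round(as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")), 2)),
      res$meta)
    res$value
  }
  art <- function(name) file.path(cfg$out_dir, name)

  ds <- stage("simulate", {
    d <- generate_dataset(sim_config(n_per_class = cfg$sim$n_per_class,
                                     classes = cfg$sim$classes,
                                     seed = cfg$seed,
                                     include_empty = cfg$sim$include_empty))
    write_frames_container(d, art("frames.rds"))
    list(value = d, meta = list(frames = n_frames(d),
                                digest = digest_file(art("frames.rds"))))
  })

  ds <- stage("preprocess", {
    d <- drop_empty(ds, cfg$preprocess$drop_empty_threshold)
    removed <- attr(d, "n_removed")
    if (isTRUE(cfg$preprocess$normalize)) d <- normalize_minmax(d)
    write_frames_container(d, art("clean.rds"))
    list(value = d, meta = list(frames = n_frames(d), removed = removed,
                                digest = digest_file(art("clean.rds"))))
  })

  ds <- stage("augment", {
    if (isTRUE(cfg$augment$enabled)) {
      pol <- augment_policy(noise_level = cfg$augment$noise_level,
                            shift_max = cfg$augment$shift_max,
                            rotation_max = cfg$augment$rotation_max,
                            erase_area_fraction = cfg$augment$erase_area_fraction,
                            elastic_alpha = cfg$augment$elastic_alpha,
                            elastic_sigma = cfg$augment$elastic_sigma,
                            per_transform_probability = cfg$augment$per_transform_probability,
                            copies_per_frame = cfg$augment$copies_per_frame,
                            seed = cfg$seed + 1L)
      d <- augment_dataset(ds, pol)
    } else d <- ds
    write_frames_container(d, art("augmented.rds"))
    list(value = d, meta = list(frames = n_frames(d),
                                digest = digest_file(art("augmented.rds"))))
  })

  parts <- split_dataset(ds, split_spec(cfg$split$train_fraction,
                                        cfg$split$val_fraction,
                                        cfg$split$test_fraction,
                                        cfg$split$stratified,
                                        seed = cfg$seed + 2L))
  models <- stage("train", {
    dir.create(art("models"), showWarnings = FALSE)
    fits <- list()
    meta <- list(split = vapply(parts$indices, length, integer(1)))
    for (kind in cfg$models) {
      t0 <- Sys.time()
      fits[[kind]] <- train_model(kind, parts$train, parts$val,
                                  seed = cfg$seed + 3L)
      path <- art(file.path("models", paste0(kind, ".rds")))
      saveRDS(fits[[kind]], path, version = 2)
      if (kind == "cnn") {
        utils::write.csv(fits[[kind]]$history,
                         art(file.path("models", "cnn_history.csv")),
                         row.names = FALSE)
      }
      meta[[kind]] <- list(seconds = round(as.numeric(
        difftime(Sys.time(), t0, units = "secs")), 2),
        digest = digest_file(path))
      say("  trained %s (%.1fs)", kind, meta[[kind]]$seconds)
    }
    list(value = fits, meta = meta)
  })

  reports <- stage("evaluate", {
    reps <- lapply(models, evaluate_model, test = parts$test)
    summary_df <- data.frame(
      model = names(reps),
      accuracy = vapply(reps, `[[`, numeric(1), "accuracy"),
      f1 = vapply(reps, `[[`, numeric(1), "macro_f1"),
      precision = vapply(reps, `[[`, numeric(1), "macro_precision"),
      recall = vapply(reps, `[[`, numeric(1), "macro_recall"),
      row.names = NULL)
    utils::write.csv(summary_df, art("metrics.csv"), row.names = FALSE)
    for (kind in names(reps)) {
      utils::write.csv(as.data.frame.matrix(reps[[kind]]$confusion),
                       art(paste0("confusion_", kind, ".csv")))
    }
    jsonlite::write_json(summary_df, art("metrics.json"), digits = NA)
    list(value = reps,
         meta = list(digest = digest_file(art("metrics.csv")),
                     accuracy = setNames(summary_df$accuracy,
                                         summary_df$model)))
  })

  study <- NULL
  if (isTRUE(cfg$resolution_study$enabled)) {
    study <- stage("resolution_study", {
      st <- resolution_study(ds, model_kinds = cfg$models,
                             resolutions = cfg$resolution_study$resolutions,
                             seed = cfg$seed + 2L)
      utils::write.csv(st, art("resolution_study.csv"), row.names = FALSE)
      list(value = st,
           meta = list(digest = digest_file(art("resolution_study.csv"))))
    })
  }

  stage("export", {
    # deployment: a self-contained model bundle + class registry
    bundle <- list(classes = levels(droplevels(ds$labels)),
                   resolution = ds$resolution,
                   models = names(models))
    yaml::write_yaml(bundle, art("bundle.yaml"))
    list(value = NULL, meta = list(digest = digest_file(art("bundle.yaml"))))
  })

  manifest$total_seconds <- round(as.numeric(difftime(Sys.time(), t_all,
                                                      units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  out <- list(manifest = manifest, models = models, reports = reports,
              splits = parts, study = study, dataset = ds)
  invisible(out)
}
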