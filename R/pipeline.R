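# Pipeline driver: wires simulate -> segment/measure -> split/train ->
# predict -> evaluate -> consensus over an output directory of plain-file
# artifacts (TIFF scans, CSV tables, JSON model/report), with a run manifest
# recording the configuration hash so any artifact can be reproduced.

#' Pipeline configuration
#'
#' @param sim A [simulation_config()] (used by the `simulate` stage).
#' @param threshold Binarization method for [binarize()]: `"otsu"`,
#'   `"none"`, or a number.
#' @param min_area_mm2 Debris size filter in mm^2.
#' @param dpi_override Optional dpi override applied when reading scans.
#' @param train_fraction,split_seed,group_by_batch Split parameters (see
#'   [split_train_test()]).
#' @param forest A [forest_config()].
#' @param ci_level Confidence level for evaluation.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(), threshold = "otsu",
                            min_area_mm2 = 0.2, dpi_override = NULL,
                            train_fraction = 0.8, split_seed = 1L,
                            group_by_batch = FALSE,
                            forest = forest_config(), ci_level = 0.95) {
  if (!inherits(sim, "simulation_config")) stop("`sim` must be a simulation_config")
  if (!inherits(forest, "forest_config")) stop("`forest` must be a forest_config")
  if (!(is.numeric(threshold) || threshold %in% c("otsu", "none")))
    stop("`threshold` must be 'otsu', 'none', or a number")
  if (min_area_mm2 < 0) stop("`min_area_mm2` must be >= 0")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("`train_fraction` must be in (0, 1)")
  if (!(ci_level > 0 && ci_level < 1)) stop("`ci_level` must be in (0, 1)")
  structure(list(sim = sim, threshold = threshold,
                 min_area_mm2 = min_area_mm2, dpi_override = dpi_override,
                 train_fraction = train_fraction,
                 split_seed = as.integer(split_seed),
                 group_by_batch = isTRUE(group_by_batch),
                 forest = forest, ci_level = ci_level),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

needs <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs missing input: ", path, call. = FALSE)
  path
}

#' Run the classification pipeline
#'
#' Stages write plain-file artifacts under `out_dir`: `scans/` (synthetic
#' TIFFs + `truth.csv`), `features.csv` (one measured row per particle),
#' `model.json` + `split.csv`, `calls.csv` (per-seed predictions with vote
#' fractions), `report.json` (test-set statistics), `consensus.csv`, and
#' `manifest.json` (configuration hash and seeds). `command = "all"` runs
#' every stage in order; with fixed seeds the artifacts are byte-identical
#' across reruns.
#'
#' @param command One of `"simulate"`, `"measure"`, `"train"`, `"tune"`,
#'   `"predict"`, `"evaluate"`, `"consensus"`, `"all"`.
#' @param out_dir Artifact directory (created if absent).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the stage results that were computed.
#' @export
run_pipeline <- function(command = "all", out_dir, config = pipeline_config()) {
  commands <- c("simulate", "measure", "train", "tune", "predict",
                "evaluate", "consensus", "all")
  if (length(command) != 1L || !(command %in% commands))
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  if (!inherits(config, "pipeline_config")) stop("`config` must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  scans_dir <- file.path(out_dir, "scans")
  f_features <- file.path(out_dir, "features.csv")
  f_model <- file.path(out_dir, "model.json")
  f_split <- file.path(out_dir, "split.csv")
  f_calls <- file.path(out_dir, "calls.csv")
  f_report <- file.path(out_dir, "report.json")
  f_consensus <- file.path(out_dir, "consensus.csv")
  run <- function(cmd) command == cmd || command == "all"

  if (run("simulate")) {
    res$simulate <- generate_dataset(config$sim, out_dir = scans_dir)
  }
  if (run("measure")) {
    needs(scans_dir, "measure")
    tifs <- sort(list.files(scans_dir, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(tifs) == 0L) stop("no TIFF scans under ", scans_dir)
    feats <- do.call(rbind, lapply(tifs, function(f) {
      img <- read_scan(f, dpi_override = config$dpi_override)
      m <- measure_scan(img, method = config$threshold,
                        min_area_mm2 = config$min_area_mm2)
      if (nrow(m) > 0L) m$label_id <- seq_len(nrow(m))
      else m$label_id <- integer(0)
      m
    }))
    write.csv(feats, f_features, row.names = FALSE)
    res$measure <- feats
  }
  if (run("train")) {
    feats <- read.csv(needs(f_features, "train"), stringsAsFactors = FALSE)
    ft <- assemble_table(feats)
    split <- split_train_test(ft, train_fraction = config$train_fraction,
                              seed = config$split_seed,
                              group_by_batch = config$group_by_batch)
    model <- train_forest(split$train, config$forest)
    save_forest(model, f_model)
    split_df <- data.frame(
      tag = c(split$train$tag, split$test$tag),
      label_id = c(split$train$label_id, split$test$label_id),
      set = rep(c("train", "test"), c(nrow(split$train), nrow(split$test))))
    write.csv(split_df, f_split, row.names = FALSE)
    res$train <- list(model = model, split = split)
  }
  if (command == "tune") {
    feats <- read.csv(needs(f_features, "tune"), stringsAsFactors = FALSE)
    ft <- assemble_table(feats)
    res$tune <- tune_forest(ft, seed = config$forest$seed)
    jsonlite::write_json(res$tune$grid, file.path(out_dir, "tuning.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (run("predict")) {
    feats <- read.csv(needs(f_features, "predict"), stringsAsFactors = FALSE)
    model <- load_forest(needs(f_model, "predict"))
    ft <- assemble_table(feats)
    pred <- predict_species(model, ft)
    calls <- cbind(data.frame(tag = ft$tag, label_id = ft$label_id,
                              stringsAsFactors = FALSE), pred)
    write.csv(calls, f_calls, row.names = FALSE)
    res$predict <- calls
  }
  if (run("evaluate")) {
    calls <- read.csv(needs(f_calls, "evaluate"), stringsAsFactors = FALSE)
    split_df <- read.csv(needs(f_split, "evaluate"), stringsAsFactors = FALSE)
    meta <- parse_tags(unique(calls$tag))
    actual <- meta$species_label[match(calls$tag, meta$source_tag)]
    test_key <- paste(split_df$tag, split_df$label_id)[split_df$set == "test"]
    is_test <- paste(calls$tag, calls$label_id) %in% test_key
    report <- evaluate_classifier(actual[is_test], calls$species[is_test],
                                  level = config$ci_level)
    report_to_json(report, f_report)
    res$evaluate <- report
  }
  if (run("consensus")) {
    calls <- read.csv(needs(f_calls, "consensus"), stringsAsFactors = FALSE)
    model <- load_forest(needs(f_model, "consensus"))
    cons <- consensus_report(calls, class_labels = model$class_labels)
    write.csv(cons$table, f_consensus, row.names = FALSE)
    res$consensus <- cons
  }
  manifest <- list(config_hash = config_hash(config),
                   command = command,
                   seeds = list(simulation = config$sim$rng_seed,
                                split = config$split_seed,
                                forest = config$forest$seed),
                   package_version = as.character(utils::packageVersion("seedmorph")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
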