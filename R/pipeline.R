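#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or `paths` (named
#' list/vector with `events`, `admissions`, `vocabulary` CSV files, and
#' optionally `labels`) must be supplied. The global `seed` fans out to the
#' stages at fixed offsets (generator `+0`, split `+1`, model `+2`,
#' attention sampling `+3`) so any stage can be rerun in isolation with the
#' same result.
#'
#' @param synthetic Optional [synthetic_config()] describing generated data.
#' @param paths Optional named input files.
#' @param unit Sequence unit: `"admission"` or `"patient"`.
#' @param mode Sequence element mode: `"event"` or `"itemset"`.
#' @param bucket Time bucketing: `"none"`, `"day"`, `"admission"`.
#' @param include Optional context include-list (ids/categories/labels).
#' @param hierarchy_level Optional roll-up depth.
#' @param min_support_rate Mining minimum support rate.
#' @param max_pattern_len Mining cap on pattern items.
#' @param pathway Cohort pathway (event ids or labels); default: the
#'   highest-support mined pattern with at least two elements.
#' @param label_source `"pathway"` labels admissions by pathway containment;
#'   `"provided"` uses the label table of the input data.
#' @param model A [model_config()]; its `seed` and `split_fractions` are
#'   taken from here.
#' @param seed Global pipeline seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            unit = c("admission", "patient"),
                            mode = c("event", "itemset"),
                            bucket = c("day", "none", "admission"),
                            include = NULL, hierarchy_level = NULL,
                            min_support_rate = 0.1, max_pattern_len = Inf,
                            pathway = NULL,
                            label_source = c("pathway", "provided"),
                            model = model_config(lstm_units = 32L),
                            seed = 1L) {
  if (is.null(synthetic) == is.null(paths))
    stop("exactly one of 'synthetic' and 'paths' must be given",
         call. = FALSE)
  if (!is.null(paths)) {
    paths <- as.list(paths)
    for (nm in c("events", "admissions", "vocabulary")) {
      if (is.null(paths[[nm]]))
        stop("paths must name an '", nm, "' file", call. = FALSE)
      if (!file.exists(paths[[nm]]))
        stop("input file does not exist: ", paths[[nm]], call. = FALSE)
    }
  }
  structure(list(synthetic = synthetic, paths = paths,
                 unit = match.arg(unit), mode = match.arg(mode),
                 bucket = match.arg(bucket), include = include,
                 hierarchy_level = hierarchy_level,
                 min_support_rate = min_support_rate,
                 max_pattern_len = max_pattern_len, pathway = pathway,
                 label_source = match.arg(label_source), model = model,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `synthetic`
#' and `model` blocks are passed to [synthetic_config()] and
#' [model_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(raw[["synthetic"]])) {
    sargs <- raw[["synthetic"]]
    if (!is.null(sargs[["planted_pathways"]]))
      sargs[["planted_pathways"]] <- lapply(sargs[["planted_pathways"]],
        function(p) list(events = as.integer(unlist(p$events)),
                         rate = p$rate))
    syn <- do.call(synthetic_config, sargs)
  }
  mod <- if (!is.null(raw[["model"]])) do.call(model_config, raw[["model"]])
         else model_config(lstm_units = 32L)
  pipeline_config(
    synthetic = syn, paths = raw[["paths"]],
    unit = raw[["unit"]] %||% "admission",
    mode = raw[["mode"]] %||% "event",
    bucket = raw[["bucket"]] %||% "day", include = raw[["include"]],
    hierarchy_level = raw[["hierarchy_level"]],
    min_support_rate = raw[["min_support_rate"]] %||% 0.1,
    max_pattern_len = raw[["max_pattern_len"]] %||% Inf,
    pathway = raw[["pathway"]],
    label_source = raw[["label_source"]] %||% "pathway",
    model = mod, seed = raw[["seed"]] %||% 1L)
}

#' Run the full pathway-mining and prediction pipeline
#'
#' Executes generate/ingest, record cleaning, optional context filtering and
#' roll-up, time bucketing, sequence construction, closed-pattern mining,
#' pathway-graph merging, cohort selection, tensorization, model training
#' and evaluation, and attention export, writing every intermediate artifact
#' plus a JSON run manifest into `out_dir`. Rerunning with the same
#' configuration and seed reproduces all manifest counts and metrics.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created); `NULL` skips artifact files
#'   and returns the manifest (and objects) only.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `manifest` plus the in-memory stage
#'   objects (`cohort_data`, `db`, `mining`, `graph`, `selection`, `tensor`,
#'   `model`, `attention`).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  stage <- "ingest"
  manifest <- list(seed = config$seed, stages = list())
  result <- list()
  tryCatch({
    # -- data ---------------------------------------------------------------
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      syn$seed <- config$seed
      data <- generate_cohort(syn)
    } else {
      data <- list(
        events = read.csv(config$paths$events, stringsAsFactors = FALSE),
        admissions = read.csv(config$paths$admissions,
                              stringsAsFactors = FALSE),
        vocabulary = read.csv(config$paths$vocabulary,
                              stringsAsFactors = FALSE),
        labels = if (!is.null(config$paths$labels))
          read.csv(config$paths$labels, stringsAsFactors = FALSE))
    }
    result$cohort_data <- data
    manifest$stages$ingest <- list(
      events = nrow(data$events), admissions = nrow(data$admissions),
      vocabulary = nrow(data$vocabulary))
    say("ingest: %d events, %d admissions", nrow(data$events),
        nrow(data$admissions))
    emit("events.csv", function(f) write.csv(data$events, f,
                                             row.names = FALSE))

    # -- clean / context / granularity / bucketing --------------------------
    stage <- "clean"
    rec <- clean_records(data$events, data$admissions)
    manifest$stages$clean <- list(kept = nrow(rec),
                                  removed = nrow(data$events) - nrow(rec))
    if (!is.null(config$include)) {
      stage <- "filter_context"
      rec <- filter_context(rec, config$include, data$vocabulary)
      manifest$stages$filter_context <- list(kept = nrow(rec))
    }
    if (!is.null(config$hierarchy_level)) {
      stage <- "rollup"
      rec <- rollup_granularity(rec, data$vocabulary,
                                config$hierarchy_level)
      manifest$stages$rollup <- list(
        distinct_events = length(unique(rec$event_id)))
    }
    stage <- "bucket"
    rec <- bucket_time(rec, config$bucket)
    emit("records_clean.csv", function(f)
      write.csv(rec, f, row.names = FALSE))

    # -- sequences ----------------------------------------------------------
    stage <- "sequences"
    db <- build_sequences(rec, unit = config$unit, mode = config$mode,
                          vocabulary = data$vocabulary)
    result$db <- db
    manifest$stages$sequences <- list(n = db$n, unit = db$unit)
    say("sequences: %d (%s)", db$n, db$unit)
    emit("sequences.json", function(f) write_sequence_db(db, f))

    # -- mining -------------------------------------------------------------
    stage <- "mining"
    mining <- mine_closed_patterns(db, config$min_support_rate,
                                   config$max_pattern_len)
    result$mining <- mining
    manifest$stages$mining <- list(
      pattern_count = length(mining$patterns),
      min_support_rate = config$min_support_rate,
      min_support_count = mining$min_support_count)
    say("mining: %d closed patterns at rate %.3f",
        length(mining$patterns), config$min_support_rate)
    emit("patterns.json", function(f) write_mining_result(mining, f))
    emit("patterns.txt", function(f)
      write.table(pattern_table(mining, data$vocabulary), f, sep = "\t",
                  row.names = FALSE, quote = FALSE))

    # -- pathway graph + cohort --------------------------------------------
    stage <- "pathway_graph"
    graph <- merge_patterns(mining, data$vocabulary)
    result$graph <- graph
    manifest$stages$pathway_graph <- list(nodes = nrow(graph$nodes),
                                          links = nrow(graph$links))
    emit("sankey.json", function(f) export_sankey(graph, f))

    stage <- "cohort"
    pathway <- config$pathway %||% default_pathway(mining)
    selection <- match_pathway(db, pathway)
    result$selection <- selection
    manifest$stages$cohort <- list(
      pathway = paste(selection$pathway, collapse = "->"),
      matched = length(selection$matched_keys), total = length(selection$labels))
    say("cohort: %d / %d matched", length(selection$matched_keys),
        length(selection$labels))
    emit("cohort_labels.csv", function(f) write_cohort_labels(selection, f))

    # -- tensor + labels ----------------------------------------------------
    stage <- "tensor"
    labels <- pipeline_labels(config, data, selection)
    tensor <- build_tensor(rec, data$admissions, labels = labels,
                           max_len = config$model$max_len,
                           vocabulary = data$vocabulary)
    result$tensor <- tensor
    manifest$stages$tensor <- list(
      samples = length(tensor$keys), timesteps = tensor$T,
      features = tensor$F, positives = sum(tensor$labels))

    # -- training -----------------------------------------------------------
    stage <- "train"
    mc <- config$model
    mc$seed <- config$seed + 2L
    splits <- split_dataset(tensor, mc$split_fractions,
                            seed = config$seed + 1L)
    model <- train_model(splits$train, splits$val, mc)
    result$model <- model
    test_metrics <- evaluate_model(model, splits$test)
    manifest$stages$train <- list(
      train = length(splits$train$labels), val = length(splits$val$labels),
      test = length(splits$test$labels), epochs = mc$epochs)
    manifest$metrics <- list(auroc = test_metrics$auroc,
                             f1 = test_metrics$f1)
    say("test auroc %.4f, f1 %.4f", test_metrics$auroc, test_metrics$f1)
    emit("model.json", function(f) save_model(model, f))
    emit("metrics.json", function(f)
      jsonlite::write_json(manifest$metrics, f, auto_unbox = TRUE,
                           digits = NA))

    # -- interpretation -----------------------------------------------------
    stage <- "attention"
    amap <- extract_attention(model, tensor)
    result$attention <- amap
    mean_map <- mean_attention(amap)
    topk <- top_k_variables(mean_map, k = min(25L, tensor$F),
                            group_by_category = TRUE,
                            vocabulary = data$vocabulary)
    manifest$stages$attention <- list(
      samples = length(amap$keys),
      top_variable = topk$categories[[1]]$events[[1]]$label)
    emit("heatmap_mean.json", function(f) export_heatmap(mean_map, f))
    emit("treemap_top25.json", function(f) export_treemap(topk, f))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest$generated_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}

# highest-support mined pattern with >= 2 elements (fallback: first pattern)
default_pathway <- function(mining) {
  for (p in mining$patterns)
    if (length(p$elements) >= 2L) return(unlist(p$elements))
  unlist(mining$patterns[[1]]$elements)
}

# per-admission labels for training, per the configured label source
pipeline_labels <- function(config, data, selection) {
  if (config$label_source == "provided") {
    if (is.null(data$labels))
      stop("label_source = 'provided' but the input has no label table",
           call. = FALSE)
    return(setNames(data$labels$label, as.character(data$labels$hadm_id)))
  }
  lab <- selection$labels
  if (config$unit == "patient") {
    # admissions inherit their patient's pathway label
    subj <- as.character(data$admissions$subject_id)
    return(setNames(as.integer(unname(lab[subj])),
                    as.character(data$admissions$hadm_id)))
  }
  lab
}
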