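# End-to-end pipeline: simulate -> connect -> metrics -> compare ->
# classify, with every stage reading its predecessor's on-disk artifacts so
# subcommand runs and full runs are identical by construction.

#' Pipeline configuration
#'
#' @param input_dir Directory with an existing cohort (manifest + files), or
#'   `NULL` to simulate one.
#' @param synth Named list of [simulation_config()] arguments used when
#'   `input_dir` is `NULL` (`n_per_group`, `sampling_rate`,
#'   `segment_layout`, `noise_sd`, `effect`, ...).
#' @param bands Character vector of canonical band names to analyze.
#' @param broadband Length-2 numeric, broadband pre-filter edges in Hz.
#' @param conditions Conditions entering connectivity analysis.
#' @param fraction Binarization fraction of the off-diagonal maximum.
#' @param edge_exclusion Seconds masked at segment edges.
#' @param n_permutations Permutations per group comparison.
#' @param features Feature names for classification
#'   (see [extract_features()]).
#' @param feature_condition Condition whose features feed classification.
#' @param classifiers Classifiers to evaluate.
#' @param k_folds Cross-validation folds.
#' @param cohort_format `"csv"` or `"edf"` for simulated cohorts.
#' @param seed Master seed; every stochastic stage derives its own child
#'   seed from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            synth = list(n_per_group = 8),
                            bands = c("delta", "theta", "alpha", "beta"),
                            broadband = c(0.1, 30),
                            conditions = c("pre", "post"),
                            fraction = 0.8,
                            edge_exclusion = 1,
                            n_permutations = 999,
                            features = c("delta_mean_cc", "delta_cpl",
                                         "beta_cpl"),
                            feature_condition = "pre",
                            classifiers = c("KNN", "SVM", "DT", "RF"),
                            k_folds = 10,
                            cohort_format = "csv",
                            seed = 1L) {
  cfg <- list(input_dir = input_dir, synth = synth, bands = bands,
              broadband = as.numeric(broadband), conditions = conditions,
              fraction = fraction, edge_exclusion = edge_exclusion,
              n_permutations = n_permutations, features = features,
              feature_condition = feature_condition,
              classifiers = classifiers, k_folds = k_folds,
              cohort_format = cohort_format, seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir))
    plv_stop("config", "input_dir does not exist: %s", cfg$input_dir)
  if (cfg$fraction <= 0 || cfg$fraction > 1)
    plv_stop("config", "fraction must lie in (0, 1]")
  if (!cfg$cohort_format %in% c("csv", "edf"))
    plv_stop("config", "cohort_format must be 'csv' or 'edf'")
  canonical_bands(cfg$bands)  # validates names
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' The on-disk form is a plain mapping of the [pipeline_config()] fields;
#' serialize -> parse -> serialize is byte-stable.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    plv_stop("missing_file", "config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$synth$segment_layout))
    raw$synth$segment_layout <- unlist(raw$synth$segment_layout)
  defaults <- formals(pipeline_config)
  args <- utils::modifyList(lapply(defaults[names(defaults) != "..."], eval),
                            raw)
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$synth$segment_layout))   # keep names through JSON/YAML
    x$synth$segment_layout <- as.list(x$synth$segment_layout)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, null = "null")
  invisible(path)
}

# Build the simulation_config implied by a pipeline_config.
synth_config <- function(cfg) {
  args <- cfg$synth
  effect <- args$effect %||% "strong"
  args$effect <- NULL
  args$bands <- canonical_bands(cfg$bands)
  args$band_coupling <- default_band_coupling(effect)
  if (!is.null(args$band_amplitudes))
    args$band_amplitudes <- unlist(args$band_amplitudes)
  else
    args$band_amplitudes <- c(delta = 1, theta = 0.7, alpha = 0.8,
                              beta = 0.5)[cfg$bands]
  args$seed <- args$seed %||% derive_seed(cfg$seed, "simulate")
  do.call(simulation_config, args)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from disk and writes its artifacts under
#' `out_dir`, so stages can be run independently (the `plvnet` command-line
#' subcommands call these directly) and a full [run_pipeline()] is the
#' composition of the stages.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param cohort_dir Directory containing a cohort manifest.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(config, out_dir) {
  cohort_dir <- file.path(out_dir, "cohort")
  cohort <- generate_cohort(synth_config(config))
  write_cohort(cohort, cohort_dir, format = config$cohort_format)
  message(sprintf("simulate: wrote %d recordings to %s", length(cohort),
                  cohort_dir))
  invisible(cohort_dir)
}

#' @rdname pipeline-stages
#' @export
stage_preprocess <- function(config, cohort_dir, out_dir) {
  cohort <- read_cohort(cohort_dir)
  pp_dir <- file.path(out_dir, "preprocessed")
  dir.create(pp_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(lr) {
    rec <- preprocess_recording(lr$recording, low = config$broadband[1],
                                high = config$broadband[2])
    fname <- sprintf("%s_%s.csv", lr$subject_id, lr$condition)
    write_recording_csv(rec, file.path(pp_dir, fname))
    list(subject_id = lr$subject_id, group = lr$group,
         condition = lr$condition, file = fname,
         sampling_rate = rec$sampling_rate, seed = NA)
  })
  jsonlite::write_json(unname(entries), file.path(pp_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("preprocess: wrote %d recordings to %s", length(entries),
                  pp_dir))
  invisible(pp_dir)
}

#' @rdname pipeline-stages
#' @export
stage_connect <- function(config, cohort_dir, out_dir) {
  cohort <- read_cohort(cohort_dir)
  matrices <- cohort_connectivity(cohort, canonical_bands(config$bands),
                                  conditions = config$conditions,
                                  edge_exclusion = config$edge_exclusion,
                                  broadband = config$broadband)
  conn_dir <- file.path(out_dir, "connectivity")
  dir.create(conn_dir, recursive = TRUE, showWarnings = FALSE)
  index <- lapply(matrices, function(m) {
    fname <- sprintf("%s_%s_%s.csv", m$subject_id, m$condition, m$band$name)
    write_connectivity_csv(m, file.path(conn_dir, fname))
    list(file = fname, subject_id = m$subject_id, group = m$group,
         condition = m$condition, band = m$band$name,
         n_samples = m$n_samples)
  })
  jsonlite::write_json(unname(index), file.path(conn_dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(connectivity_long(matrices), file.path(conn_dir, "plv_long.tsv"))
  message(sprintf("connect: wrote %d matrices to %s", length(matrices),
                  conn_dir))
  invisible(conn_dir)
}

read_connectivity_index <- function(conn_dir) {
  index_file <- file.path(conn_dir, "index.json")
  if (!file.exists(index_file))
    plv_stop("missing_file", "expected connectivity index at %s", index_file)
  index <- jsonlite::read_json(index_file, simplifyVector = FALSE)
  bands <- canonical_bands()
  lapply(index, function(e) {
    V <- read_connectivity_csv(file.path(conn_dir, e$file))
    structure(list(values = V, channel_labels = rownames(V),
                   band = bands[[e$band]], condition = e$condition,
                   subject_id = e$subject_id, group = e$group,
                   n_samples = e$n_samples),
              class = "connectivity_matrix")
  })
}

#' @rdname pipeline-stages
#' @param conn_dir Directory written by [stage_connect()].
#' @export
stage_metrics <- function(config, conn_dir, out_dir) {
  matrices <- read_connectivity_index(conn_dir)
  tab <- metrics_table(matrices, fraction = config$fraction)
  graph_dir <- file.path(out_dir, "graphs")
  dir.create(graph_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in matrices) {
    g <- suppressWarnings(binarize(m, config$fraction))
    write_edge_list(g, file.path(graph_dir,
                                 sprintf("%s_%s_%s_edges.tsv", m$subject_id,
                                         m$condition, m$band$name)))
  }
  write_tsv(tab$metrics, file.path(out_dir, "metrics.tsv"))
  write_tsv(tab$degrees, file.path(out_dir, "degrees.tsv"))
  message(sprintf("metrics: %d rows -> %s", nrow(tab$metrics),
                  file.path(out_dir, "metrics.tsv")))
  invisible(file.path(out_dir, "metrics.tsv"))
}

read_metrics_tsv <- function(path) {
  if (!file.exists(path))
    plv_stop("missing_file", "expected metrics table at %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline-stages
#' @export
stage_compare <- function(config, out_dir) {
  metrics <- read_metrics_tsv(file.path(out_dir, "metrics.tsv"))
  cmp <- compare_cohort(metrics, n_permutations = config$n_permutations,
                        seed = derive_seed(config$seed, "compare"))
  write_tsv(cmp, file.path(out_dir, "comparisons.tsv"))
  message(sprintf("compare: %d contrasts -> %s", nrow(cmp),
                  file.path(out_dir, "comparisons.tsv")))
  invisible(file.path(out_dir, "comparisons.tsv"))
}

#' @rdname pipeline-stages
#' @export
stage_classify <- function(config, out_dir) {
  metrics <- read_metrics_tsv(file.path(out_dir, "metrics.tsv"))
  feats <- extract_features(metrics, features = config$features,
                            condition = config$feature_condition,
                            standardize = FALSE)
  rep_ <- crossval_classify(feats$x, feats$y, k = config$k_folds,
                            seed = derive_seed(config$seed, "classify"),
                            classifiers = config$classifiers)
  tab <- data.frame(classifier = names(rep_$report),
                    accuracy = vapply(rep_$report, `[[`, 0, "accuracy"),
                    precision = vapply(rep_$report, `[[`, 0, "precision"),
                    recall = vapply(rep_$report, `[[`, 0, "recall"))
  write_tsv(tab, file.path(out_dir, "classification.tsv"))
  jsonlite::write_json(
    list(positive = rep_$positive, k = rep_$k, seed = rep_$seed,
         folds = as.integer(rep_$folds),
         subjects = feats$subject_id, report = rep_$report),
    file.path(out_dir, "classifier_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("classify: -> %s", file.path(out_dir, "classification.tsv")))
  invisible(file.path(out_dir, "classifier_report.json"))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, computes band-resolved PLV matrices,
#' binarizes them and derives network metrics, runs the standard group and
#' condition contrasts, and evaluates the classifiers, writing all
#' artifacts plus a run manifest with stage checksums under `out_dir`.
#' Rerunning with the same configuration reproduces every output file
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path of the run manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) plv_stop("filesystem", "output directory %s is not writable",
                    out_dir)
  unlink(probe)
  cohort_dir <- if (is.null(config$input_dir))
    stage_simulate(config, out_dir) else config$input_dir
  conn_dir <- stage_connect(config, cohort_dir, out_dir)
  stage_metrics(config, conn_dir, out_dir)
  stage_compare(config, out_dir)
  stage_classify(config, out_dir)
  outputs <- c("metrics.tsv", "degrees.tsv", "comparisons.tsv",
               "classification.tsv", "classifier_report.json")
  checksums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(checksums) <- outputs
  manifest <- list(package_version = as.character(utils::packageVersion("plvnet")),
                   config = unclass(config), seed = config$seed,
                   checksums = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(file.path(out_dir, "run_manifest.json"))
}
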