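# End-to-end driver: data -> k-mer features -> partition search ->
# length search -> instance ensemble -> union + routed evaluation.

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  config
}

require_field <- function(config, section, field) {
  if (is.null(config[[section]])) {
    stop("config section '", section, "' is missing")
  }
  if (is.null(config[[section]][[field]])) {
    stop("config field '", section, "$", field, "' is missing")
  }
  config[[section]][[field]]
}

#' Default pipeline configuration
#'
#' Builds a complete pipeline config for a synthetic dataset; every field
#' can be overridden before [run_pipeline()]. Search sizes default small
#' (`Ns = 5`, `Ni = 4`) so an end-to-end run stays interactive; the
#' mutation factor and train ratio follow the method's published
#' parameter table (`Mu = 0.2`, `Tr = 0.8`).
#'
#' @param n_pos,n_neg Synthetic class sizes.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A nested config list.
#' @export
pipeline_config <- function(n_pos = 500L, n_neg = 500L, seed = 1L) {
  list(
    seed = as.integer(seed),
    data = list(type = "synthetic", n_pos = n_pos, n_neg = n_neg,
                length_range = c(15L, 30L),
                signal_kmers = data.frame(kmer = "WH", class = 1, weight = 3),
                noise = 0),
    ga_part1 = list(Ns = 5L, Ni = 4L, Mu = 0.2, Tr = 0.8),
    ga_part2 = list(Ns = 5L, Ni = 4L, Mu = 0.2),
    ensemble = list(correlation_mode = "pearson", augment_threshold = 0.999,
                    calibration_fraction = 0.5),
    metrics = list(),
    residue_policy = "skip"
  )
}

load_pipeline_data <- function(config, seed) {
  data <- config$data
  if (is.null(data)) stop("config section 'data' is missing")
  type <- data$type %||% stop("config field 'data$type' is missing")
  if (type == "synthetic") {
    sk <- data$signal_kmers
    if (!is.null(sk) && !is.data.frame(sk)) sk <- as.data.frame(sk)
    spec <- synthetic_spec(
      n_pos = data$n_pos %||% stop("config field 'data$n_pos' is missing"),
      n_neg = data$n_neg %||% stop("config field 'data$n_neg' is missing"),
      length_range = data$length_range %||% c(15L, 30L),
      signal_kmers = sk,
      background = data$background %||% rep(1 / 20, 20L),
      noise = data$noise %||% 0,
      seed = data$seed %||% derive_seed(seed, 11L))
    generate_peptides(spec)
  } else if (type %in% c("fasta", "tsv")) {
    read_labeled_sequences(
      data$path %||% stop("config field 'data$path' is missing"), type)
  } else {
    stop("unknown data$type: ", type)
  }
}

# stratified calibration/evaluation split of test-table rows
calibration_split <- function(labels, fraction, seed) {
  withr::with_seed(seed, {
    calib <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      n_cal <- max(1L, min(length(ix) - 1L, round(fraction * length(ix))))
      sample(ix, n_cal)
    }), use.names = FALSE)
  })
  sort(calib)
}

#' Run the full classification pipeline
#'
#' Executes, in order: data loading or synthesis, k-mer featurization,
#' the stage-one partition search ([run_split_ga()]), the stage-two
#' length search ([run_feature_ga()]), ensemble fitting, the
#' correct-instance union on the test table, and routed evaluation. For
#' routing, the test rows are split (stratified, seeded) into a
#' calibration part that builds the stored correct sets and an evaluation
#' part that is routed; routed metrics are computed on the evaluation
#' part. Any stage failure aborts with the stage name. Identical config
#' and seed give byte-identical summaries.
#'
#' @param config A config list (see [pipeline_config()]) or a YAML/JSON
#'   file path.
#' @param out_dir Optional artifacts directory: writes `summary.json`,
#'   the stage reports, ROC points and routed predictions.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  config <- read_pipeline_config(config)
  seed <- config$seed %||% stop("config field 'seed' is missing")
  for (f in c("Ns", "Ni", "Mu", "Tr")) require_field(config, "ga_part1", f)
  for (f in c("Ns", "Ni", "Mu")) require_field(config, "ga_part2", f)
  policy <- config$residue_policy %||% "skip"
  ens_cfg <- config$ensemble %||% list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  seqs <- stage("data", load_pipeline_data(config, seed))
  table <- stage("extract", build_feature_table(seqs, policy))

  p1 <- config$ga_part1
  split <- stage("split-ga", run_split_ga(table, ga_config(
    Ns = p1$Ns, Ni = p1$Ni, Mu = p1$Mu, Tr = p1$Tr,
    seed = derive_seed(seed, 21L))))

  subset_seqs <- function(idx) {
    out <- seqs[idx, , drop = FALSE]
    class(out) <- c("peptide_set", "data.frame")
    out
  }
  p2 <- config$ga_part2
  len <- stage("length-ga", run_feature_ga(
    subset_seqs(split$train_indices), subset_seqs(split$test_indices),
    ga_config(Ns = p2$Ns, Ni = p2$Ni, Mu = p2$Mu,
              seed = derive_seed(seed, 31L),
              inner_split = p2$inner_split),
    residue_policy = policy))

  model <- stage("train", ensemble_fit(
    len$train_table,
    base_classifier_spec(seed = derive_seed(seed, 41L)),
    correlation_mode = ens_cfg$correlation_mode %||% "pearson",
    augment_threshold = ens_cfg$augment_threshold %||% 0.999))

  union <- stage("union", correct_instance_union(model, len$test_table))

  routed <- stage("route", {
    frac <- ens_cfg$calibration_fraction %||% 0.5
    calib_idx <- calibration_split(len$test_table$labels, frac,
                                   derive_seed(seed, 51L))
    eval_idx <- setdiff(seq_along(len$test_table$labels), calib_idx)
    model <- ensemble_calibrate(model, ft_rows(len$test_table, calib_idx))
    routes <- route_and_classify(model,
                                 len$test_table$features[eval_idx, , drop = FALSE])
    truth <- len$test_table$labels[eval_idx]
    list(routes = routes, truth = truth, eval_idx = eval_idx,
         calib_idx = calib_idx,
         accuracy = mean(routes$label == truth),
         metrics = compute_metrics(truth, routes$label, routes$score))
  })

  m <- routed$metrics
  summary <- list(
    seed = seed,
    n_sequences = nrow(seqs),
    class_counts = as.list(table(factor(seqs$label, levels = 0:1))),
    split = list(fitness = split$fitness, trace = split$trace,
                 n_train = length(split$train_indices),
                 n_test = length(split$test_indices)),
    length_selection = list(SLMin = len$SLMin, SLMax = len$SLMax,
                            best_length = len$best_length,
                            best_fitness = len$best_fitness,
                            trace = len$trace),
    ensemble = list(
      base_accuracies = as.list(union$accuracies),
      union_accuracy = union$union_accuracy,
      routed_accuracy = routed$accuracy,
      n_calibration = length(routed$calib_idx),
      n_evaluation = length(routed$eval_idx)),
    metrics = list(accuracy = m$accuracy, precision = m$precision,
                   recall = m$recall, f_measure = m$f_measure, auc = m$auc,
                   tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn),
    config = config
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", pretty = TRUE)
    write_split_report(split, table, out_dir)
    write_length_report(len, out_dir)
    if (!is.null(m$roc_points)) {
      write_roc_csv(m, file.path(out_dir, "roc_points.csv"))
    }
    preds <- data.frame(id = len$test_table$ids[routed$eval_idx],
                        truth = routed$truth,
                        predicted_label = routed$routes$label,
                        chosen_classifier = routed$routes$classifier,
                        max_correlation = routed$routes$max_corr)
    utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  invisible(summary)
}

#' Sweep the pipeline over test-set sizes
#'
#' Structural counterpart of evaluating one method at several test-set
#' sizes: for each requested size, a synthetic dataset is drawn (random
#' stratified subsampling via the generator) large enough that the
#' stage-one partition leaves approximately that many test sequences, the
#' full pipeline runs, and one metrics row is recorded. Each sweep point
#' uses a seed derived from the base config's seed.
#'
#' @param test_sizes Integer vector of target test-set sizes.
#' @param config Base config (synthetic data section required); see
#'   [pipeline_config()].
#' @return Data frame with one row per size: realized `test_size`,
#'   `union_accuracy`, `routed_accuracy`, `accuracy`, `precision`,
#'   `recall`, `f_measure`, `auc`.
#' @export
run_tss_sweep <- function(test_sizes, config = pipeline_config()) {
  config <- read_pipeline_config(config)
  if ((config$data$type %||% "") != "synthetic") {
    stop("the sweep draws synthetic datasets; config$data$type must be 'synthetic'")
  }
  Tr <- require_field(config, "ga_part1", "Tr")
  rows <- lapply(seq_along(test_sizes), function(i) {
    n <- ceiling(test_sizes[i] / (1 - Tr))
    cfg <- config
    cfg$data$n_pos <- ceiling(n / 2)
    cfg$data$n_neg <- n - ceiling(n / 2)
    cfg$seed <- derive_seed(config$seed, 100L + i)
    cfg$data$seed <- NULL
    s <- run_pipeline(cfg)
    data.frame(test_size = s$split$n_test,
               union_accuracy = s$ensemble$union_accuracy,
               routed_accuracy = s$ensemble$routed_accuracy,
               accuracy = s$metrics$accuracy,
               precision = s$metrics$precision,
               recall = s$metrics$recall,
               f_measure = s$metrics$f_measure,
               auc = s$metrics$auc)
  })
  do.call(rbind, rows)
}
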