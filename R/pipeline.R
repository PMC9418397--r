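# Orchestration: configuration, cohort labeling, cross-validation and the
# end-to-end simulate -> label -> split -> balance -> train -> evaluate
# pipeline with file-based stage interfaces and provenance.

#' Default pipeline configuration
#'
#' Nested list mirroring each stage's parameters. Every random operation's
#' seed is derived from the top-level `seed` during validation, so a
#' resolved configuration never runs unseeded. Configurations are stored as
#' JSON (see [read_pipeline_config()]).
#'
#' @param outdir output directory for all artifacts.
#' @param seed master seed.
#' @param ... overrides of nested sections (`simulate`, `label`, `encode`,
#'   `folds`, `balance`, `network`, `training`), each a list merged over the
#'   defaults.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(outdir = tempfile("thermograde_run_"),
                                    seed = 1, ...) {
  cfg <- list(
    outdir = outdir, seed = seed,
    simulate = list(enabled = TRUE,
                    class_counts = c(`0` = 90, `1` = 110, `2` = 50, `3` = 30,
                                     `4` = 18, `5` = 36),
                    noise_sd = 0.2, shape = c(180, 80)),
    label = list(ambient_ceiling = 22,
                 fractions = c(calcaneal = 0.27, medial = 0.5)),
    encode = list(mode = "rectangular", window = c(18, 40)),
    folds = list(k = 5),
    balance = list(enabled = TRUE, target_per_class = NULL,
                   policy = list()),
    network = list(n_classes = 6, conv_filters = c(16, 32, 64),
                   dense_units = 128, dropout = 0.5),
    training = list(epochs = 30, batch_size = 32, lr = 1e-3,
                    use_class_weights = TRUE, online_augment = FALSE))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Values present in the file override the package defaults; everything
#' else keeps its default.
#'
#' @param path JSON file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_pipeline_config,
          c(raw[intersect(names(raw), c("outdir", "seed"))],
            raw[setdiff(names(raw), c("outdir", "seed"))]))
}

#' Validate a pipeline configuration
#'
#' Fails before any computation if a required field is missing or invalid,
#' and resolves per-stage seeds from the master seed.
#'
#' @param cfg a `pipeline_config`.
#' @return the resolved configuration.
#' @export
validate_pipeline_config <- function(cfg) {
  need <- function(cond, msg) if (!isTRUE(cond)) stop("config error: ", msg)
  need(!is.null(cfg$outdir), "missing `outdir`")
  need(is.numeric(cfg$seed) && length(cfg$seed) == 1, "missing `seed`")
  need(!is.null(cfg$folds$k) && is.numeric(cfg$folds$k) && cfg$folds$k >= 2,
       "missing or invalid `folds.k`")
  need(!is.null(cfg$training$epochs) && cfg$training$epochs >= 1,
       "missing or invalid `training.epochs`")
  need(cfg$encode$mode %in% c("rectangular", "resized", "padded"),
       "invalid `encode.mode`")
  set.seed(cfg$seed)
  stages <- c("simulate", "split", "balance", "train")
  cfg$stage_seeds <- stats::setNames(
    as.list(sample.int(.Machine$integer.max - 1L, length(stages))), stages)
  cfg
}

#' Label a cohort of thermograms (TCI + severity class)
#'
#' Accepts either an in-memory `labeled_cohort` or a manifest CSV path
#' (columns `subject_id`, `side`, `group`, `path`; `path` pointing at
#' headerless temperature-matrix CSVs). Control-group feet are class 0 from
#' their metadata. Feet that cannot be segmented or partitioned are flagged
#' (`ok = FALSE`) and the run continues.
#'
#' @param x `labeled_cohort` or manifest file path.
#' @param ambient_ceiling,fractions see [label_thermogram()].
#' @param out optional CSV path for the per-foot report; a JSON class
#'   histogram is written next to it.
#' @return data.frame with regional means, TCI, class and an `ok` flag per
#'   foot.
#' @export
label_cohort <- function(x, ambient_ceiling = 22,
                         fractions = c(calcaneal = 0.27, medial = 0.5),
                         out = NULL) {
  thermos <- if (inherits(x, "labeled_cohort")) {
    x$thermograms
  } else {
    man <- utils::read.csv(x, stringsAsFactors = FALSE)
    if (nrow(man) == 0) stop("empty manifest: ", x)
    lapply(seq_len(nrow(man)), function(i)
      read_temperature_matrix(man$path[i], subject_id = man$subject_id[i],
                              side = man$side[i], group = man$group[i]))
  }
  rows <- lapply(thermos, function(t) {
    res <- tryCatch(
      label_thermogram(t, ambient_ceiling = ambient_ceiling,
                       fractions = fractions),
      error = function(e) e, warning = function(w) w)
    if (inherits(res, "tci_result")) {
      data.frame(subject_id = t$subject_id, side = t$side, group = t$group,
                 MPA = res$regional_means[["MPA"]],
                 LPA = res$regional_means[["LPA"]],
                 MCA = res$regional_means[["MCA"]],
                 LCA = res$regional_means[["LCA"]],
                 tci = res$tci, class = res$severity_class, ok = TRUE,
                 note = "", stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = t$subject_id, side = t$side, group = t$group,
                 MPA = NA_real_, LPA = NA_real_, MCA = NA_real_,
                 LCA = NA_real_, tci = NA_real_, class = NA_integer_,
                 ok = FALSE, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    }
  })
  report <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.csv(report, out, row.names = FALSE)
    hist <- as.list(table(report$class[report$ok]))
    jsonlite::write_json(list(n = nrow(report), n_ok = sum(report$ok),
                              class_histogram = hist),
                         sub("\\.csv$", "_histogram.json", out),
                         auto_unbox = TRUE)
  }
  report
}

#' Read a cohort of temperature matrices from a manifest
#'
#' The manifest convention (CSV columns `subject_id`, `side`, `group`,
#' `path`, optional `class` and `tci_truth`) is also the adapter for
#' externally obtained matrix-format cohorts: point `path` at headerless
#' temperature CSVs and the cohort becomes usable by every stage. When
#' `class` is absent, feet are labeled through the TCI pipeline.
#'
#' @param manifest manifest CSV path.
#' @param ... arguments passed to [label_thermogram()] when labels must be
#'   computed.
#' @return a `labeled_cohort`.
#' @export
read_cohort <- function(manifest, ...) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(man) == 0) stop("empty manifest: ", manifest)
  thermos <- lapply(seq_len(nrow(man)), function(i)
    read_temperature_matrix(man$path[i], subject_id = man$subject_id[i],
                            side = man$side[i], group = man$group[i]))
  if (!"class" %in% names(man) || anyNA(man$class)) {
    res <- lapply(thermos, label_thermogram, ...)
    man$class <- vapply(res, `[[`, integer(1), "severity_class")
    if (!"tci_truth" %in% names(man))
      man$tci_truth <- vapply(res, `[[`, numeric(1), "tci")
  }
  if (!"tci_truth" %in% names(man)) man$tci_truth <- NA_real_
  structure(list(thermograms = thermos, labels = as.integer(man$class),
                 tci = man$tci_truth, truths = vector("list", nrow(man)),
                 manifest = man, seed = NA_integer_),
            class = "labeled_cohort")
}

#' Write a cohort to a directory (matrices + manifest)
#'
#' @param cohort a `labeled_cohort`.
#' @param dir output directory.
#' @param manifest_name manifest file name.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, manifest_name = "manifest.csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$path <- file.path(dir, paste0(man$subject_id, ".csv"))
  for (i in seq_along(cohort$thermograms))
    write_temperature_matrix(cohort$thermograms[[i]], man$path[i])
  out <- file.path(dir, manifest_name)
  utils::write.csv(man, out, row.names = FALSE)
  invisible(out)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint embeds the full network configuration, weights, input
#' standardization and training history.
#'
#' @param model a `thermo_cnn`.
#' @param path checkpoint file path (RDS).
#' @return `path` (invisibly) for `save_model`; the model for `load_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "thermo_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "thermo_cnn")) stop("not a thermo_cnn checkpoint: ", path)
  m
}

#' Write / read a fold split as JSON
#'
#' @param split a [stratified_folds()] result.
#' @param ids sample identifiers, parallel to the labels used for the split.
#' @param path JSON file path.
#' @return `path` invisibly; `read_folds` returns the split with an `ids`
#'   element.
#' @export
write_folds <- function(split, ids, path) {
  stopifnot(inherits(split, "fold_split"), length(ids) == length(split$assignments))
  jsonlite::write_json(list(k = split$k, seed = split$seed, ids = ids,
                            assignments = split$assignments),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(d$k), function(f)
    list(train = which(d$assignments != f), val = which(d$assignments == f)))
  structure(list(assignments = d$assignments, folds = folds, k = d$k,
                 seed = d$seed, ids = d$ids),
            class = "fold_split")
}

# Encode a cohort into a network input array.
#' @noRd
encode_cohort <- function(cohort, mode = "rectangular", window = c(18, 40),
                          ambient_ceiling = 22) {
  enc <- lapply(cohort$thermograms, function(t) {
    mask <- if (mode == "padded") segment_foot(t, ambient_ceiling) else NULL
    encode_for_network(t, mask = mask, mode = mode, window = window)
  })
  stack_encoded(enc)
}

#' Stratified cross-validation of the full training pipeline
#'
#' For each fold: offline-balance the training split (validation data is
#' never touched), train the network with inverse-frequency class weights,
#' and evaluate on the untouched validation split. Reports per-fold
#' class-wise metrics, their across-fold mean, and the pooled confusion
#' matrix over all folds.
#'
#' @param cohort a `labeled_cohort`.
#' @param k number of folds.
#' @param net_cfg a [network_config()].
#' @param tr_cfg a [train_config()] (its `class_weights` are recomputed per
#'   fold from the balanced training distribution).
#' @param policy an [augmentation_policy()] for offline balancing, or `NULL`
#'   to skip balancing.
#' @param encode_mode,window input encoding, see [encode_for_network()].
#' @param target_per_class offline balancing target; default the largest
#'   class in each fold's training split.
#' @param seed split seed.
#' @return list with `fold_reports`, `fold_macros`, `mean_macro`,
#'   `pooled_confusion`, `pooled_report`, `split`.
#' @export
cross_validate <- function(cohort, k = 5, net_cfg = network_config(),
                           tr_cfg = train_config(), policy = augmentation_policy(),
                           encode_mode = "rectangular", window = c(18, 40),
                           target_per_class = NULL, seed = 1) {
  split <- stratified_folds(cohort$labels, k = k, seed = seed)
  levels <- net_cfg$class_levels
  fold_reports <- list(); fold_macros <- list()
  all_true <- integer(); all_pred <- integer()
  models <- list()
  for (f in seq_len(k)) {
    tr <- subset_cohort(cohort, split$folds[[f]]$train)
    va <- subset_cohort(cohort, split$folds[[f]]$val)
    if (!is.null(policy))
      tr <- offline_balance(tr, policy, target_per_class = target_per_class,
                            seed = policy$seed + f)
    x_tr <- encode_cohort(tr, mode = encode_mode, window = window)
    x_va <- encode_cohort(va, mode = encode_mode, window = window)
    counts <- table(factor(tr$labels, levels = levels))
    tc <- tr_cfg
    tc$class_weights <- as.numeric(inverse_frequency_weights(as.numeric(counts)))
    tc$seed <- tr_cfg$seed + f
    model <- build_network(net_cfg, seed = tr_cfg$seed + f)
    model <- train_network(model, x_tr, tr$labels, x_va, va$labels, tc)
    pred <- predict(model, x_va)
    ev <- evaluate_predictions(va$labels, pred$labels, levels = levels)
    fold_reports[[f]] <- ev
    fold_macros[[f]] <- ev$macro
    all_true <- c(all_true, va$labels)
    all_pred <- c(all_pred, pred$labels)
    models[[f]] <- model
  }
  pooled_cm <- confusion(all_true, all_pred, levels = levels)
  pooled_rep <- classwise_metrics(pooled_cm)
  mean_macro <- colMeans(do.call(rbind, fold_macros))
  list(fold_reports = fold_reports, fold_macros = fold_macros,
       mean_macro = mean_macro, pooled_confusion = pooled_cm,
       pooled_report = pooled_rep, split = split, models = models)
}

#' Run the full pipeline
#'
#' Executes simulate -> label -> split -> balance -> train -> evaluate ->
#' report, writing every artifact (manifests, labeling report, fold
#' metrics, pooled confusion matrix, JSON summary, plain-text log) under
#' `cfg$outdir`. Rerunning the same configuration reproduces identical
#' manifests and metrics.
#'
#' @param cfg a `pipeline_config` (list or JSON path).
#' @return invisibly, a list with the output directory, the labeling
#'   report and the cross-validation summary.
#' @export
run_pipeline <- function(cfg = default_pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg <- validate_pipeline_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$outdir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat("", file = logf)

  if (!isTRUE(cfg$simulate$enabled))
    stop("missing stage input: no input cohort and `simulate` disabled")
  cohort <- generate_cohort(class_counts = unlist(cfg$simulate$class_counts),
                            noise_sd = cfg$simulate$noise_sd,
                            shape = cfg$simulate$shape,
                            seed = cfg$stage_seeds$simulate,
                            dir = file.path(cfg$outdir, "data"))
  log_line("simulate: generated %d thermograms", length(cohort$thermograms))

  labels_csv <- file.path(cfg$outdir, "labels.csv")
  report <- label_cohort(cohort, ambient_ceiling = cfg$label$ambient_ceiling,
                         fractions = unlist(cfg$label$fractions),
                         out = labels_csv)
  log_line("label: %d of %d feet labeled", sum(report$ok), nrow(report))

  policy <- if (isTRUE(cfg$balance$enabled))
    do.call(augmentation_policy,
            c(cfg$balance$policy, list(seed = cfg$stage_seeds$balance)))
  else NULL
  net_cfg <- network_config(
    input_shape = switch(cfg$encode$mode, rectangular = c(180, 80),
                         c(227, 227)),
    n_classes = cfg$network$n_classes,
    conv_filters = unlist(cfg$network$conv_filters),
    dense_units = cfg$network$dense_units, dropout = cfg$network$dropout)
  tr_cfg <- train_config(epochs = cfg$training$epochs,
                         batch_size = cfg$training$batch_size,
                         lr = cfg$training$lr,
                         augment_policy = if (isTRUE(cfg$training$online_augment))
                           policy else NULL,
                         seed = cfg$stage_seeds$train)
  cv <- cross_validate(cohort, k = cfg$folds$k, net_cfg = net_cfg,
                       tr_cfg = tr_cfg, policy = policy,
                       encode_mode = cfg$encode$mode,
                       window = unlist(cfg$encode$window),
                       target_per_class = cfg$balance$target_per_class,
                       seed = cfg$stage_seeds$split)
  log_line("split: k = %d stratified folds", cfg$folds$k)
  log_line("train/evaluate: %d folds trained (%d epochs each)", cfg$folds$k,
           cfg$training$epochs)

  for (f in seq_len(cfg$folds$k)) {
    fdir <- file.path(cfg$outdir, sprintf("fold_%d", f))
    dir.create(fdir, showWarnings = FALSE)
    utils::write.csv(as.data.frame(cv$fold_reports[[f]]$classwise),
                     file.path(fdir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(cv$fold_reports[[f]]$confusion)),
                     file.path(fdir, "confusion.csv"))
    utils::write.csv(cv$models[[f]]$history,
                     file.path(fdir, "history.csv"), row.names = FALSE)
    save_model(cv$models[[f]], file.path(fdir, "model.rds"))
  }
  write_folds(cv$split, cohort$manifest$subject_id,
              file.path(cfg$outdir, "folds.json"))
  utils::write.csv(as.data.frame(cv$pooled_report),
                   file.path(cfg$outdir, "pooled_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(cv$pooled_confusion)),
                   file.path(cfg$outdir, "pooled_confusion.csv"))
  summary <- list(
    seed = cfg$seed, k = cfg$folds$k,
    n_thermograms = length(cohort$thermograms),
    class_histogram = as.list(table(cohort$labels)),
    mean_macro = as.list(cv$mean_macro),
    pooled_macro = as.list(macro_average(cv$pooled_report)))
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("report: summary written to %s", file.path(cfg$outdir, "summary.json"))
  invisible(list(outdir = cfg$outdir, labeling = report, cv = cv,
                 summary = summary))
}
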