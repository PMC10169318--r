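# End-to-end experimental protocol.
#
# The corpus is split into three disjoint cohorts: a base-training cohort
# (trains the conventional softmax model and the skip-feature + SVM
# model), a stacking cohort (scored by both base models; those score pairs
# train the ANN combiner), and a held-out validation cohort on which all
# three models are compared. The reference corpus geometry is 910 images
# split 374 / 352 / 184; the desk-scale default uses 140 synthetic images
# split 60 / 40 / 40 at tiny backbone scale.

#' Split a dataset into three disjoint stratified cohorts
#'
#' Shuffles each class separately under the seed, interleaves the classes,
#' and cuts sequentially into the requested sizes, so every cohort is
#' class-balanced to within one sample. Disjointness and two-class
#' presence are verified on every call.
#'
#' @param n_samples dataset size, or a list of `ImageSample`s.
#' @param sizes integer triple `c(train, stack, validation)` summing to
#'   the dataset size, all >= 2.
#' @param seed integer seed.
#' @param labels optional 0/1 vector (required when `n_samples` is a
#'   count; derived from the samples otherwise).
#' @return a `gn_cohort_split`: list of index vectors `train`, `stack`,
#'   `validation`.
#' @export
split_cohorts <- function(n_samples, sizes, seed = 0L, labels = NULL) {
  if (is.list(n_samples)) {
    labels <- sample_labels(n_samples)
    n <- length(n_samples)
  } else {
    n <- as.integer(n_samples)
    if (is.null(labels)) stopf("labels are required when passing a count")
  }
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L) stopf("sizes must be a triple (train, stack, validation)")
  if (any(sizes < 2L))
    stopf("every cohort needs >= 2 samples so both classes can be present")
  if (sum(sizes) != n)
    stopf("cohort sizes (%d) must sum to the dataset size (%d)", sum(sizes), n)
  idx <- with_seed(seed, {
    pos <- sample(which(labels == 1L))
    neg <- sample(which(labels == 0L))
    m <- max(length(pos), length(neg))
    inter <- as.vector(rbind(c(pos, rep(NA, m - length(pos))),
                             c(neg, rep(NA, m - length(neg)))))
    inter[!is.na(inter)]
  })
  bounds <- cumsum(c(0L, sizes))
  split <- structure(list(train = idx[(bounds[1] + 1L):bounds[2]],
                          stack = idx[(bounds[2] + 1L):bounds[3]],
                          validation = idx[(bounds[3] + 1L):bounds[4]],
                          seed = as.integer(seed)),
                     class = "gn_cohort_split")
  check_cohorts(split, labels)
  split
}

check_cohorts <- function(split, labels) {
  ids <- c(split$train, split$stack, split$validation)
  if (anyDuplicated(ids))
    stopf("cohort leakage: a sample id appears in more than one cohort")
  for (nm in c("train", "stack", "validation"))
    if (length(unique(labels[split[[nm]]])) < 2L)
      stopf("cohort '%s' does not contain both classes", nm)
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' @param synth a [synth_params()] for the synthetic corpus (ignored when
#'   `samples` are passed to [run_pipeline()]).
#' @param backbone a [backbone_spec()].
#' @param cohort_sizes triple `c(train, stack, validation)`.
#' @param train a [train_config()] for the conventional head.
#' @param svm_C,svm_kernel SVM penalty and [kernel_spec()].
#' @param combiner_hidden,combiner_lr,combiner_epochs combiner settings.
#' @param seed global seed; every stochastic stage derives its stream from
#'   it.
#' @param out_dir report directory, or `NULL` to skip writing files.
#' @return a `gn_pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_params(image_size = 64L,
                                                 n_granules = c(2L, 4L),
                                                 granule_radius = c(4, 8),
                                                 background_texture_scale = 12,
                                                 noise_sd = 0.03,
                                                 membrane_curves = 2L),
                            backbone = backbone_spec("tiny"),
                            cohort_sizes = c(60L, 40L, 40L),
                            train = train_config(learning_rate = 0.05),
                            svm_C = 1, svm_kernel = kernel_spec("radial"),
                            combiner_hidden = 4L, combiner_lr = 2,
                            combiner_epochs = 2000L,
                            seed = 0L, out_dir = NULL) {
  cohort_sizes <- as.integer(cohort_sizes)
  if (sum(cohort_sizes) %% 2L != 0L)
    stopf("cohort sizes must sum to an even number (balanced corpus)")
  structure(list(synth = synth, backbone = backbone,
                 cohort_sizes = cohort_sizes, train = train,
                 svm_C = svm_C, svm_kernel = svm_kernel,
                 combiner_hidden = as.integer(combiner_hidden),
                 combiner_lr = combiner_lr,
                 combiner_epochs = as.integer(combiner_epochs),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "gn_pipeline_config")
}

# One forward pass per image serving both models: full skip features for
# the SVM and pooled stage-5 channels for the softmax head.
extract_both <- function(extractor, samples) {
  flat <- vector("list", length(samples))
  pooled <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    fm <- extract_features(extractor, samples[[i]])
    flat[[i]] <- fm$flat; pooled[[i]] <- fm$pooled5
  }
  list(flat = do.call(rbind, flat), pooled = do.call(rbind, pooled))
}

#' Run the full protocol
#'
#' Generates (or accepts) the corpus, splits it, trains the conventional
#' and improved (skip + SVM) base models on the training cohort, fits the
#' ANN combiner on the stacking cohort's score pairs, evaluates all three
#' models on the validation cohort, audits the report for
#' self-consistency, and (optionally) writes JSON/CSV reports and the ROC
#' plot.
#'
#' @param config a [pipeline_config()].
#' @param samples optional pre-made list of `ImageSample`s; generated from
#'   `config$synth` when omitted.
#' @return a `gn_report`: per-model evaluation (`conventional`,
#'   `improved`, `multimodel`), the cohort split, trained models, a stage
#'   log, and the config hash.
#' @export
run_pipeline <- function(config = pipeline_config(), samples = NULL) {
  stages <- list(); t_all <- proc.time()[3]
  tick <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    stages[[name]] <<- round(proc.time()[3] - t0, 3)
    val
  }
  cfg_hash <- params_hash(config[setdiff(names(config), "out_dir")])

  samples <- tick("simulate", {
    if (is.null(samples))
      generate_dataset(sum(config$cohort_sizes) %/% 2L, config$synth,
                       seed = derive_seed(config$seed, 1L, 100L))
    else samples
  })
  split <- tick("split", split_cohorts(samples, config$cohort_sizes,
                                       seed = derive_seed(config$seed, 2L, 100L)))
  extractor <- tick("backbone",
                    build_backbone(config$backbone,
                                   seed = derive_seed(config$seed, 3L, 100L)))
  feats <- list()
  for (nm in c("train", "stack", "validation"))
    feats[[nm]] <- tick(paste0("features_", nm),
                        extract_both(extractor, samples[split[[nm]]]))
  y <- lapply(split[c("train", "stack", "validation")],
              function(ix) sample_labels(samples[ix]))

  cfg_train <- config$train
  cfg_train$seed <- derive_seed(config$seed, 4L, 100L)
  conventional <- tick("train_conventional",
    train_conventional(samples[split$train], spec = config$backbone,
                       cfg = cfg_train, extractor = extractor,
                       features = feats$train$pooled))
  improved <- tick("train_improved",
    fit_svm(feats$train$flat, y$train, C = config$svm_C,
            kernel = config$svm_kernel))
  combiner <- tick("train_combiner", {
    s_imp <- svm_score(improved, feats$stack$flat)
    s_conv <- predict_proba_matrix(conventional, feats$stack$pooled)
    fit_combiner(s_imp, s_conv, y$stack,
                 seed = derive_seed(config$seed, 5L, 100L),
                 hidden = config$combiner_hidden,
                 learning_rate = config$combiner_lr,
                 epochs = config$combiner_epochs)
  })
  evals <- tick("evaluate", {
    s_imp <- svm_score(improved, feats$validation$flat)
    s_conv <- predict_proba_matrix(conventional, feats$validation$pooled)
    s_multi <- combiner_score(combiner, s_imp, s_conv)
    list(conventional = evaluate_model(y$validation, s_conv),
         improved = evaluate_model(y$validation, s_imp),
         multimodel = evaluate_model(y$validation, s_multi))
  })
  audit_report(evals)

  report <- structure(list(
    evaluations = evals, split = split, config_hash = cfg_hash,
    models = list(conventional = conventional, improved = improved,
                  stacked = stacked_model(improved, conventional, combiner,
                                          extractor)),
    stage_seconds = stages,
    total_seconds = round(proc.time()[3] - t_all, 3)
  ), class = "gn_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Every number in the metric table must be recomputable from the emitted
# confusion matrix through the metrics module.
audit_report <- function(evals) {
  for (nm in names(evals)) {
    ev <- evals[[nm]]; cm <- ev$confusion
    redo <- c(precision = precision(cm), recall = recall(cm),
              f1 = f1_score(cm), accuracy = accuracy(cm),
              auroc = ev$roc$auroc)
    if (max(abs(redo - ev$metrics)) > 1e-12)
      stopf("self-consistency audit failed for model '%s'", nm)
  }
  invisible(TRUE)
}

#' Write pipeline reports to disk
#'
#' Emits `metrics.json` (per-model raw and 2-dp metrics plus counts),
#' per-model `confusion_*.csv` and `roc_*.csv`, a combined `roc.png`, and
#' `stages.json` with wall-clock timings and the config hash.
#'
#' @param report a `gn_report`.
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stopf("cannot create output directory '%s'", out_dir)
  ev <- report$evaluations
  metrics <- lapply(ev, function(e)
    list(confusion = e$confusion[c("TP", "FN", "FP", "TN")],
         metrics = as.list(e$metrics),
         metrics_2dp = as.list(e$metrics_2dp)))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(ev)) {
    cm <- ev[[nm]]$confusion
    utils::write.csv(data.frame(TP = cm$TP, FN = cm$FN, FP = cm$FP,
                                TN = cm$TN),
                     file.path(out_dir, paste0("confusion_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(ev[[nm]]$roc$points,
                     file.path(out_dir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
  }
  plot_roc(lapply(ev, `[[`, "roc"), file.path(out_dir, "roc.png"))
  jsonlite::write_json(list(config_hash = report$config_hash,
                            stage_seconds = report$stage_seconds,
                            total_seconds = report$total_seconds),
                       file.path(out_dir, "stages.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.gn_report <- function(x, ...) {
  cat(sprintf("<gn_report> config %s, %.1fs total\n", x$config_hash,
              x$total_seconds))
  tab <- t(vapply(x$evaluations, function(e) e$metrics_2dp, numeric(5)))
  print(tab)
  invisible(x)
}
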