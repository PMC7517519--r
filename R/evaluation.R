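#' Leave-one-site-out folds
#'
#' One fold per acquisition site: the fold's test set is exactly that
#' site's subjects and its training set is everything else, so every
#' fold partitions the cohort and no site ever contributes to both
#' sides. Cross-site generalization — the clinically relevant regime —
#' is what this design measures.
#'
#' @param cohort a `cohort` with at least two sites.
#' @return list of folds, each `list(test_site, train_idx, test_idx,
#'   train_subjects, test_subjects)` (indices into the cohort; id
#'   vectors for bookkeeping).
#' @export
loso_folds <- function(cohort) {
  ph <- phenotype(cohort)
  sites <- unique(ph$site_id)
  if (length(sites) < 2L) {
    stop("leave-one-site-out needs at least two sites")
  }
  lapply(sites, function(s) {
    test_idx <- which(ph$site_id == s)
    train_idx <- which(ph$site_id != s)
    list(test_site = s, train_idx = train_idx, test_idx = test_idx,
         train_subjects = ph$subject_id[train_idx],
         test_subjects = ph$subject_id[test_idx])
  })
}

#' Classification accuracy
#'
#' @param labels 0/1 vector of true labels.
#' @param predictions 0/1 vector of predicted labels, same length.
#' @return fraction of exact matches, in `[0, 1]`.
#' @export
accuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have the same length")
  }
  if (length(labels) < 1L) stop("need at least one prediction")
  mean(labels == predictions)
}

#' Area under the ROC curve (rank-sum formulation)
#'
#' The probability that a uniformly chosen positive is scored above a
#' uniformly chosen negative, with ties counted one half — the
#' Mann-Whitney statistic normalized by the number of pairs.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have the same length")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Overall accuracy across sites
#'
#' @param per_site_accuracy numeric vector of per-site accuracies.
#' @param weights optional site sizes; `NULL` gives the unweighted site
#'   mean, sizes give the subject-weighted mean.
#' @return weighted or unweighted mean accuracy.
#' @export
overall_accuracy <- function(per_site_accuracy, weights = NULL) {
  if (is.null(weights)) mean(per_site_accuracy)
  else stats::weighted.mean(per_site_accuracy, weights)
}

#' Run leave-one-site-out cross-validation for one fusion head
#'
#' For every fold a fresh model is built (Xavier init from a
#' fold-specific seed derived from `seed`) and trained on the training
#' sites only; nothing from the test site — subjects, statistics, batch
#' pools — is touched before prediction (per-subject z-scoring uses no
#' cross-subject statistics, so it cannot leak).
#'
#' @param cohort a `cohort` with >= 2 sites and both classes.
#' @param head fusion head name (see [build_model()]).
#' @param encoder_cfg an [encoder_config()].
#' @param config a [train_config()].
#' @param seed integer seed; fold f trains from seed
#'   `derive(seed, f)` so heads compared at the same `seed` are matched.
#' @param keep_models keep each fold's trained model (memory permitting).
#' @param verbose print per-fold progress.
#' @return object of class `loso_result`: list with `folds` (per-fold
#'   predictions, accuracy, AUC), `summary` data.frame, and overall
#'   accuracies (site-mean and subject-weighted).
#' @export
run_loso <- function(cohort, head = "attention",
                     encoder_cfg = encoder_config(),
                     config = train_config(), seed = config$seed,
                     keep_models = FALSE, verbose = FALSE) {
  folds <- loso_folds(cohort)
  ph <- phenotype(cohort)
  fold_results <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    fold_seed <- derive_seed(seed, f)
    model <- build_model(encoder_cfg, head = head,
                         n_regions = nrow(cohort$subjects[[1]]$values),
                         seed = fold_seed)
    cfg <- config
    cfg$seed <- fold_seed
    train_pool <- subset_cohort(cohort, fold$train_idx)
    model <- train(model, train_pool, cfg)
    scores <- predict_proba(model, cohort$subjects[fold$test_idx],
                            standardize = config$standardize)
    labels <- ph$label[fold$test_idx]
    acc <- accuracy(labels, as.integer(scores > 0.5))
    fold_auc <- if (length(unique(labels)) == 2L) auc(labels, scores)
                else NA_real_
    fold_results[[f]] <- list(
      test_site = fold$test_site,
      predictions = data.frame(subject_id = ph$subject_id[fold$test_idx],
                               site_id = fold$test_site, label = labels,
                               score = scores, stringsAsFactors = FALSE),
      accuracy = acc, auc = fold_auc, n_test = length(labels),
      model = if (keep_models) model else NULL)
    if (verbose) {
      message(sprintf("[loso] head=%s site=%s acc=%.3f auc=%.3f",
                      head, fold$test_site, acc, fold_auc))
    }
  }
  summary_df <- data.frame(
    site = vapply(fold_results, `[[`, character(1), "test_site"),
    n = vapply(fold_results, `[[`, integer(1), "n_test"),
    accuracy = vapply(fold_results, `[[`, numeric(1), "accuracy"),
    auc = vapply(fold_results, `[[`, numeric(1), "auc"),
    stringsAsFactors = FALSE)
  structure(list(head = head, folds = fold_results, summary = summary_df,
                 overall_site_mean = overall_accuracy(summary_df$accuracy),
                 overall_weighted = overall_accuracy(summary_df$accuracy,
                                                     summary_df$n)),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> head=%s\n", x$head))
  print(x$summary, row.names = FALSE)
  cat(sprintf("overall accuracy: site mean %.3f | subject-weighted %.3f\n",
              x$overall_site_mean, x$overall_weighted))
  invisible(x)
}

head_display_name <- function(head) {
  switch(head,
         none = "SC-CNN",
         dense = "SC-CNN-Dense",
         lstm = "SC-CNN-LSTM",
         attention = "SC-CNN-Attention",
         head)
}

#' Leave-one-site-out benchmark over several fusion heads
#'
#' Runs [run_loso()] for each requested head with matched seeds (fold f
#' of every head starts from the same derived seed and draws the same
#' batch stream), and tabulates per-site accuracy and AUC per model plus
#' two overall columns: the unweighted site mean and the
#' subject-weighted mean. Both are reported because the two summaries
#' genuinely differ on imbalanced site sizes.
#'
#' @inheritParams run_loso
#' @param heads character vector from
#'   `c("none", "dense", "lstm", "attention")`.
#' @return object of class `sccnn_benchmark`: list with `results` (one
#'   `loso_result` per head), `accuracy_table` and `auc_table` (wide,
#'   rows = models, columns = sites + overall).
#' @export
run_benchmark <- function(cohort, heads = c("none", "dense", "lstm",
                                            "attention"),
                          encoder_cfg = encoder_config(),
                          config = train_config(), seed = config$seed,
                          verbose = FALSE) {
  heads <- match.arg(heads, c("none", "dense", "lstm", "attention"),
                     several.ok = TRUE)
  results <- lapply(heads, function(h) {
    run_loso(cohort, head = h, encoder_cfg = encoder_cfg, config = config,
             seed = seed, verbose = verbose)
  })
  names(results) <- heads
  sites <- results[[1]]$summary$site
  make_table <- function(metric) {
    rows <- lapply(results, function(r) r$summary[[metric]])
    tab <- do.call(rbind, rows)
    colnames(tab) <- sites
    df <- data.frame(model = vapply(heads, head_display_name, character(1)),
                     tab,
                     overall_site_mean = vapply(results, function(r) {
                       overall_accuracy(r$summary[[metric]])
                     }, numeric(1)),
                     overall_weighted = vapply(results, function(r) {
                       overall_accuracy(r$summary[[metric]],
                                        r$summary$n)
                     }, numeric(1)),
                     row.names = NULL, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df
  }
  structure(list(results = results,
                 accuracy_table = make_table("accuracy"),
                 auc_table = make_table("auc")),
            class = "sccnn_benchmark")
}

#' @export
print.sccnn_benchmark <- function(x, ...) {
  cat("<sccnn_benchmark> accuracy (rows = models, columns = sites):\n")
  print(x$accuracy_table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Emits tab-delimited accuracy and AUC tables plus one predictions file
#' per model/fold (`subject_id`, `site_id`, `label`, `score`).
#'
#' @param benchmark an object from [run_benchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "sccnn_benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(benchmark$accuracy_table,
                     file.path(dir, "accuracy.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(benchmark$auc_table, file.path(dir, "auc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (h in names(benchmark$results)) {
    preds <- do.call(rbind, lapply(benchmark$results[[h]]$folds,
                                   `[[`, "predictions"))
    utils::write.table(preds,
                       file.path(dir, sprintf("predictions_%s.tsv", h)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
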