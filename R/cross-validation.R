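METRIC_NAMES <- c("roc_auc", "aupr", "accuracy", "precision", "recall", "f_score")

# features + labels for one fold: known evidence = training positives only
fold_datasets <- function(kb, matrices, fold, neg_ratio, cfg) {
  drugs <- names(kb$drugs); diseases <- names(kb$diseases)
  gold <- as_assoc(kb$gold)
  train_pos <- fold$train_pos
  test_pos <- fold$test_pos

  if (fold$strategy == "drug_wise") {
    # negatives drawn from the respective drug sets: test negatives among
    # test-drug pairs, train negatives among train-drug pairs
    train_drugs <- setdiff(unique(c(train_pos$drug_id, drugs)), fold$test_drugs)
    test_neg <- sample_negatives(fold$test_drugs, diseases, gold,
                                 round(neg_ratio * nrow(test_pos)))
    train_neg <- sample_negatives(train_drugs, diseases, gold,
                                  round(neg_ratio * nrow(train_pos)))
  } else {
    n_test <- round(neg_ratio * nrow(test_pos))
    n_train <- round(neg_ratio * nrow(train_pos))
    neg <- sample_negatives(drugs, diseases, gold, n_test + n_train)
    test_neg <- neg[seq_len(n_test), , drop = FALSE]
    train_neg <- neg[n_test + seq_len(n_train), , drop = FALSE]
  }

  train_pairs <- rbind(
    cbind(train_pos, label = 1L),
    cbind(train_neg, label = 0L)
  )
  test_pairs <- rbind(
    cbind(test_pos, label = 1L),
    cbind(test_neg, label = 0L)
  )
  # evidence: training positives only; exclude_self guards the features of
  # the training positives themselves
  known <- train_pos
  list(
    train = build_feature_table(matrices, train_pairs, known, cfg),
    test = build_feature_table(matrices, test_pairs, known,
                               fusion_config(w = cfg$w, aggregation = cfg$aggregation,
                                             exclude_self = FALSE))
  )
}

#' Run repeated k-fold cross-validation of the fused classifier
#'
#' For every repetition and fold: split the gold standard (drug-wise or
#' pair-wise), sample negatives at `neg_ratio` per positive, fuse the 10
#' features using the training positives as the only evidence (test
#' associations never contribute), fit the L2 logistic classifier, score
#' the held-out pairs and compute the six metrics. Fully reproducible from
#' `seed`.
#'
#' @param kb a `knowledge_base`.
#' @param matrices output of [build_similarity_matrices()].
#' @param strategy `"drug_wise"` (hide 10\% of drugs with all their
#'   indications) or `"pair_wise"` (hide 10\% of associations).
#' @param k folds per repetition (default 10).
#' @param repetitions number of repetitions (default 10).
#' @param neg_ratio negatives sampled per positive (default 1).
#' @param seed integer seed driving all randomness of the run.
#' @param cfg a [fusion_config()].
#' @param C regularisation strength for [train_logistic()].
#' @param threshold classification cutoff for the threshold metrics.
#' @param permute_labels permute train and test labels within each fold —
#'   the permutation null; recovered AUC should be ~0.5.
#' @return object of class `evaluation_report`: per-fold metric rows plus
#'   means/standard deviations; `print` and `summary` methods.
#' @export
run_cross_validation <- function(kb, matrices, strategy = c("drug_wise", "pair_wise"),
                                 k = 10, repetitions = 10, neg_ratio = 1,
                                 seed = 1L, cfg = fusion_config(), C = 1,
                                 threshold = 0.5, permute_labels = FALSE) {
  strategy <- match.arg(strategy)
  validate_knowledge_base(kb)
  rows <- vector("list", repetitions * k)
  with_seed(seed, {
    for (rep_i in seq_len(repetitions)) {
      folds <- if (strategy == "drug_wise") {
        split_drug_wise(kb$gold, k)
      } else {
        split_pair_wise(kb$gold, k)
      }
      for (f in seq_along(folds)) {
        fold <- folds[[f]]
        if (fold$strategy == "drug_wise") {
          stopifnot(length(intersect(fold$test_pos$drug_id,
                                     fold$train_pos$drug_id)) == 0)
        }
        ds <- fold_datasets(kb, matrices, fold, neg_ratio, cfg)
        if (permute_labels) {
          ds$train$label <- sample(ds$train$label)
          ds$test$label <- sample(ds$test$label)
          # permutation can produce a single-class training fold at tiny n;
          # resample until both classes present (bounded retries)
          tries <- 0
          while (length(unique(ds$train$label)) < 2 && tries < 100) {
            ds$train$label <- sample(ds$train$label); tries <- tries + 1
          }
        }
        model <- train_logistic(ds$train, C = C)
        scores <- predict(model, ds$test)
        m <- evaluate_predictions(scores, ds$test$label, threshold)
        rows[[(rep_i - 1) * k + f]] <- data.frame(
          repetition = rep_i, fold = f, as.data.frame(m))
      }
    }
  })
  metrics <- do.call(rbind, rows)
  report <- list(
    strategy = strategy, k = k, repetitions = repetitions,
    neg_ratio = neg_ratio, seed = seed, permuted = permute_labels,
    metrics = metrics,
    mean = colMeans(metrics[, METRIC_NAMES]),
    sd = vapply(metrics[, METRIC_NAMES], stats::sd, 0)
  )
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$strategy, " CV, ", x$repetitions, " x ",
      x$k, "-fold, neg_ratio ", x$neg_ratio,
      if (x$permuted) ", permuted labels" else "", "\n", sep = "")
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.evaluation_report <- function(object, ...) {
  out <- data.frame(metric = METRIC_NAMES,
                    mean = as.numeric(object$mean[METRIC_NAMES]),
                    sd = as.numeric(object$sd[METRIC_NAMES]))
  attr(out, "strategy") <- object$strategy
  out
}

#' Write an evaluation report as CSV (per-fold metrics) + JSON summary
#'
#' @param report an `evaluation_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "cv_metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(strategy = report$strategy, k = report$k,
         repetitions = report$repetitions, neg_ratio = report$neg_ratio,
         seed = report$seed, permuted = report$permuted,
         mean = as.list(report$mean), sd = as.list(report$sd)),
    file.path(dir, "cv_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
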