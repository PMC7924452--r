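as_assoc <- function(df) {
  df <- unique(df[, c("drug_id", "disease_id"), drop = FALSE])
  rownames(df) <- NULL
  df
}

assoc_key <- function(df) paste(df$drug_id, df$disease_id)

#' Drug-wise cross-validation folds
#'
#' Partitions the *drugs* of the gold standard into `k` folds; fold f's test
#' positives are all associations of fold-f drugs (the drugs and every one
#' of their indications are hidden together), train positives are the rest.
#' No drug appears on both sides of a fold.
#'
#' @param gold data frame of gold associations (`drug_id`, `disease_id`).
#' @param k number of folds (default 10, hiding 10\% of drugs per fold).
#' @param seed optional seed for the drug shuffle.
#' @return list of `cv_fold` objects with elements `strategy`, `train_pos`,
#'   `test_pos`.
#' @export
split_drug_wise <- function(gold, k = 10, seed = NULL) {
  gold <- as_assoc(gold)
  if (!nrow(gold)) stop_input("split_drug_wise: empty gold standard")
  if (k < 2) stop_input("split_drug_wise: k must be at least 2")
  drugs <- unique(gold$drug_id)
  if (length(drugs) < k) stop_input("split_drug_wise: fewer drugs than folds")
  with_seed(seed, {
    shuffled <- sample(drugs)
    fold_of <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
    lapply(seq_len(k), function(f) {
      test_drugs <- names(fold_of)[fold_of == f]
      test <- gold[gold$drug_id %in% test_drugs, , drop = FALSE]
      train <- gold[!gold$drug_id %in% test_drugs, , drop = FALSE]
      structure(list(strategy = "drug_wise", fold = f,
                     train_pos = as_assoc(train), test_pos = as_assoc(test),
                     test_drugs = test_drugs),
                class = "cv_fold")
    })
  })
}

#' Pair-wise cross-validation folds
#'
#' Partitions the gold *associations* into `k` folds: 90\% positive training
#' and 10\% positive test per fold at `k = 10`.
#'
#' @inheritParams split_drug_wise
#' @return list of `cv_fold` objects.
#' @export
split_pair_wise <- function(gold, k = 10, seed = NULL) {
  gold <- as_assoc(gold)
  if (!nrow(gold)) stop_input("split_pair_wise: empty gold standard")
  if (k < 2) stop_input("split_pair_wise: k must be at least 2")
  if (nrow(gold) < k) stop_input("split_pair_wise: fewer associations than folds")
  with_seed(seed, {
    fold_of <- rep_len(seq_len(k), nrow(gold))[sample.int(nrow(gold))]
    lapply(seq_len(k), function(f) {
      structure(list(strategy = "pair_wise", fold = f,
                     train_pos = as_assoc(gold[fold_of != f, , drop = FALSE]),
                     test_pos = as_assoc(gold[fold_of == f, , drop = FALSE])),
                class = "cv_fold")
    })
  })
}

#' Sample negative drug-disease pairs
#'
#' Draws exactly `n` pairs uniformly without replacement from the
#' `drugs x diseases` lattice minus the forbidden set.
#'
#' @param drugs,diseases identifier vectors spanning the candidate lattice.
#' @param forbidden data frame of pairs that must not be drawn (the gold
#'   standard, plus any negatives already taken).
#' @param n number of pairs to draw.
#' @param seed optional seed.
#' @return data frame (`drug_id`, `disease_id`) of `n` sampled negatives.
#' @export
sample_negatives <- function(drugs, diseases, forbidden, n, seed = NULL) {
  drugs <- unique(drugs); diseases <- unique(diseases)
  total <- length(drugs) * length(diseases)
  forbidden <- as_assoc(forbidden)
  forbidden <- forbidden[forbidden$drug_id %in% drugs &
                           forbidden$disease_id %in% diseases, , drop = FALSE]
  avail <- total - nrow(forbidden)
  if (n > avail) {
    stop_input("sample_negatives: requested ", n, " pairs but only ",
               avail, " non-forbidden pairs exist")
  }
  with_seed(seed, {
    forb_idx <- (match(forbidden$drug_id, drugs) - 1L) * length(diseases) +
      match(forbidden$disease_id, diseases)
    ok <- setdiff(seq_len(total), forb_idx)
    take <- ok[sample.int(length(ok), n)]
    data.frame(
      drug_id = drugs[(take - 1L) %/% length(diseases) + 1L],
      disease_id = diseases[(take - 1L) %% length(diseases) + 1L],
      stringsAsFactors = FALSE
    )
  })
}

#' Fit the L2-regularised logistic classifier on a labelled feature table
#'
#' Ridge-penalised maximum-likelihood logistic regression on the 10 fused
#' features (no standardisation: the features share the `[0,1]` scale).
#' The objective is the mean negative log-likelihood plus
#' `lambda/2 * ||beta||^2` with the intercept unpenalised — the per-
#' observation convention, so duplicating the data set leaves the decision
#' function unchanged. `C` scales the strength inversely
#' (`lambda = lambda0 / C`); the default `lambda0 = 1e-3` is a light ridge
#' that stabilises the fit without visibly biasing the coefficients.
#'
#' @param features a labelled `feature_table` (or data frame with the 10
#'   feature columns and a 0/1 `label`).
#' @param C inverse regularisation strength multiplier (default 1).
#' @param lambda0 base penalty weight at `C = 1`.
#' @return object of class `fused_logit` with coefficients, intercept and a
#'   regularisation descriptor; has `print`, `coef` and `predict` methods.
#' @export
train_logistic <- function(features, C = 1, lambda0 = 1e-3) {
  cols <- feature_column_names()
  stopifnot(all(cols %in% names(features)), "label" %in% names(features))
  y <- features$label
  if (length(unique(y)) < 2) {
    stop_input("train_logistic: both classes must be present")
  }
  X <- as.matrix(features[, cols, drop = FALSE])
  lambda <- lambda0 / C
  fit <- ridge_logit_irls(X, y, lambda)
  structure(list(coefficients = stats::setNames(fit$beta, cols),
                 intercept = fit$intercept,
                 regularization = list(type = "L2", C = C, lambda = lambda),
                 n = nrow(X), converged = fit$converged),
            class = "fused_logit")
}

# Newton / iteratively reweighted least squares for the ridge-penalised
# logistic objective f(b) = -mean(loglik) + lambda/2 * ||beta||^2 (intercept
# unpenalised). The 11x11 Hessian solve is exact, so the optimum is reached
# to machine precision in a handful of iterations.
ridge_logit_irls <- function(X, y, lambda, max_iter = 100, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  Z <- cbind(1, X)
  theta <- numeric(p + 1)
  pen <- c(0, rep(lambda, p))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% theta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Z, mu - y)) / n + pen * theta
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z * w, Z) / n + diag(pen, p + 1)
    step <- solve(H, grad)
    # damped Newton: halve until the objective does not increase
    obj <- function(th) {
      e <- drop(Z %*% th)
      mean(log1p(exp(-abs(e))) + pmax(e, 0) - y * e) +
        sum(pen * th^2) / 2
    }
    f0 <- obj(theta)
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      if (obj(cand) <= f0 + 1e-14 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta_new <- theta - alpha * step
    if (max(abs(theta_new - theta)) < tol) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
  }
  list(intercept = unname(theta[1]), beta = unname(theta[-1]),
       converged = converged)
}

#' @export
coef.fused_logit <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
print.fused_logit <- function(x, ...) {
  cat("<fused_logit> L2 logistic regression (C = ", x$regularization$C,
      ", n = ", x$n, ")\n", sep = "")
  print(round(coef(x), 4))
  invisible(x)
}

#' Predict association probabilities from a fitted classifier
#'
#' @param object a `fused_logit`.
#' @param newdata a `feature_table` (or data frame with the feature columns).
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.fused_logit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
  stats::plogis(object$intercept + drop(X %*% object$coefficients))
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive outranks a random negative, with the
#' midrank convention for ties.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop_input("roc_auc: both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise average precision: the mean of the precision values at the
#' ranks of the positives, descending by score.
#'
#' @inheritParams roc_auc
#' @return AUPR in `(0,1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1)) stop_input("average_precision: no positives")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  cum_tp <- cumsum(y)
  prec <- cum_tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Classification metrics for scored pairs
#'
#' Computes `roc_auc` (rank statistic), `aupr` (average precision), and
#' threshold metrics `accuracy`, `precision`, `recall`, `f_score` at the
#' given probability cutoff.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels (both classes present).
#' @param threshold classification cutoff (default 0.5).
#' @return named list of the six metrics.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop_input("evaluate_predictions: both classes must be present")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_score <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(
    roc_auc = roc_auc(scores, labels),
    aupr = average_precision(scores, labels),
    accuracy = (tp + tn) / length(labels),
    precision = precision,
    recall = recall,
    f_score = f_score
  )
}
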