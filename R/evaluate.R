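#' Matthews correlation coefficient
#'
#' Balanced classification quality from the four confusion-matrix counts,
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},}
#' in \[-1, 1\]: +1 perfect prediction, 0 random, -1 inverse. Preferred over
#' accuracy on imbalanced active/inactive sets. When any factor of the
#' denominator is zero (e.g. the classifier predicts a single class) the
#' conventional value 0 is returned.
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return MCC in \[-1, 1\].
#' @examples
#' matthews_cc(tp = 50, tn = 50, fp = 0, fn = 0)  # +1
#' matthews_cc(tp = 0, tn = 0, fp = 50, fn = 50)  # -1
#' @export
matthews_cc <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (anyNA(counts) || any(counts < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all confusion counts are zero", call. = FALSE)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Confusion counts from truth and prediction vectors
#'
#' @param truth,predicted Binary 0/1 vectors of equal length.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted))
  if (!all(c(truth, predicted) %in% c(0L, 1L))) {
    stop("truth and predicted must be binary", call. = FALSE)
  }
  tibble::tibble(
    tp = sum(truth == 1L & predicted == 1L),
    tn = sum(truth == 0L & predicted == 0L),
    fp = sum(truth == 0L & predicted == 1L),
    fn = sum(truth == 1L & predicted == 0L)
  )
}

#' k-fold partition of one target's compounds
#'
#' Randomly partitions a target's compound set into k folds of equal size
#' (within 1). With `stratified = TRUE` (the default, recommended for the
#' typical 9:1 inactive:active imbalance) actives and inactives are dealt into
#' folds separately so every fold mirrors the class ratio; this avoids
#' degenerate single-class folds at small sample sizes.
#'
#' @param activity An [activity_set()].
#' @param k Number of folds (>= 2, at most the compound count).
#' @param seed Integer seed; the same seed reproduces the assignment exactly.
#' @param stratified Stratify folds by activity label (default `TRUE`).
#' @return An integer vector of fold indices in 1..k, one per compound, with
#'   attributes `k`, `seed`, `stratified`.
#' @export
kfold_partition <- function(activity, k, seed, stratified = TRUE) {
  stopifnot(inherits(activity, "activity_set"))
  n <- length(activity$labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds compound count (", n, ")", call. = FALSE)
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      for (cls in c(0L, 1L)) {
        idx <- which(activity$labels == cls)
        if (length(idx) < k) {
          stop("class ", cls, " has fewer than k = ", k,
               " members; use stratified = FALSE", call. = FALSE)
        }
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
  })
  structure(fold, k = k, seed = as.integer(seed), stratified = stratified)
}

#' Random-forest classifier plug-in
#'
#' Default classifier for [evaluate_reduced_representation()], backed by the
#' randomForest package. Any classifier can be substituted as a list with a
#' `fit(x, y)` element returning a model and a `predict(model, x)` element
#' returning 0/1 labels, where `x` is a 0/1 matrix.
#'
#' @param ntree Number of trees (default 200).
#' @return A classifier contract list with elements `fit` and `predict`.
#' @export
classifier_random_forest <- function(ntree = 200) {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    stop("the randomForest package is required for the default classifier",
         call. = FALSE)
  }
  list(
    fit = function(x, y) {
      randomForest::randomForest(x, factor(y, levels = c(0L, 1L)),
                                 ntree = ntree)
    },
    predict = function(model, x) {
      as.integer(as.character(predict(model, x)))
    }
  )
}

# Shared CV engine: per fold, run selection on the pooled training compounds
# of all targets, then score each target's test fold. Scoring is by held-out
# normalized MI always, and by classifier MCC when a classifier is given.
cv_engine <- function(collection, n_select, k, seed, classifier = NULL,
                      subsample_size = NULL, stratified = TRUE) {
  stopifnot(inherits(collection, "target_collection"))
  sets <- collection$activity_sets
  seed <- as.integer(seed)
  folds <- lapply(seq_along(sets), function(i) {
    kfold_partition(sets[[i]], k = k, seed = seed + i, stratified = stratified)
  })
  rows <- list()
  selections <- list()
  for (j in seq_len(k)) {
    train_sets <- lapply(seq_along(sets), function(i) {
      tr <- folds[[i]] != j
      activity_set(
        bit_matrix(sets[[i]]$matrix$values[tr, , drop = FALSE]),
        sets[[i]]$labels[tr],
        sets[[i]]$target_id
      )
    })
    train_coll <- target_collection(train_sets)
    sel <- aic_max_select(train_coll, n_select = n_select,
                          subsample_size = subsample_size, seed = seed + j)
    selections[[j]] <- sel$selected
    for (i in seq_along(sets)) {
      a <- sets[[i]]
      tr <- folds[[i]] != j
      te <- !tr
      xtr <- a$matrix$values[tr, sel$selected, drop = FALSE]
      xte <- a$matrix$values[te, sel$selected, drop = FALSE]
      ytr <- a$labels[tr]
      yte <- a$labels[te]
      test_set <- activity_set(bit_matrix(xte), yte, a$target_id)
      nmi <- normalized_mi(test_set, sel$selected)
      mcc <- NA_real_
      if (!is.null(classifier)) {
        if (length(unique(ytr)) < 2L) {
          stop("degenerate training fold ", j, " for target ", a$target_id,
               ": a single activity class", call. = FALSE)
        }
        model <- classifier$fit(xtr, ytr)
        pred <- as.integer(classifier$predict(model, xte))
        if (length(pred) != length(yte) ||
            anyNA(pred) || !all(pred %in% c(0L, 1L))) {
          stop("classifier contract violation: predictions must be a 0/1 ",
               "vector of test-fold length", call. = FALSE)
        }
        cc <- confusion_counts(yte, pred)
        mcc <- matthews_cc(cc$tp, cc$tn, cc$fp, cc$fn)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target_id = a$target_id, fold = j, n_bits = n_select,
        mcc = mcc, norm_mi = nmi
      )
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  structure(
    list(
      folds = folds_tbl,
      summary = folds_tbl |>
        dplyr::group_by(.data$target_id) |>
        dplyr::summarise(mean_mcc = mean(.data$mcc),
                         mean_norm_mi = mean(.data$norm_mi),
                         .groups = "drop"),
      selections = tibble::tibble(fold = seq_len(k), selected = selections),
      config = list(n_select = n_select, k = k, seed = seed,
                    subsample_size = subsample_size, stratified = stratified)
    ),
    class = "aic_cv"
  )
}

#' Cross-validated classification of a reduced representation
#'
#' The validation protocol for a reduced fingerprint: the compound set of each
#' target is split into k folds; in each fold the greedy selector is run on
#' the pooled training compounds of all targets (so the representation is
#' general, never seeing test compounds), then for every target a classifier
#' is trained on that target's training fold restricted to the selected bits
#' and scored on the held-out fold by Matthews correlation coefficient.
#' Held-out normalized MI of the selected bits is reported alongside.
#'
#' @inheritParams aic_max_select
#' @param classifier A classifier contract (see [classifier_random_forest()]),
#'   the default.
#' @param k Number of folds (default 10).
#' @param stratified Stratify folds by activity label (default `TRUE`).
#' @return An `aic_cv` object: `folds` (tibble with `target_id`, `fold`,
#'   `n_bits`, `mcc`, `norm_mi`), `summary` (per-target means), `selections`
#'   (per-fold selected bits) and `config`. The grand mean MCC is available
#'   via [generics::glance()].
#' @export
evaluate_reduced_representation <- function(collection, n_select,
                                            classifier =
                                              classifier_random_forest(),
                                            k = 10, seed = 1L,
                                            subsample_size = NULL,
                                            stratified = TRUE) {
  if (is.null(classifier) || !is.list(classifier) ||
      !is.function(classifier$fit) || !is.function(classifier$predict)) {
    stop("classifier contract violation: need list(fit = , predict = )",
         call. = FALSE)
  }
  cv_engine(collection, n_select = n_select, k = k, seed = seed,
            classifier = classifier, subsample_size = subsample_size,
            stratified = stratified)
}

#' Cross-validated held-out information score
#'
#' As [evaluate_reduced_representation()] but classifier-free: in each fold
#' the bits selected on the training compounds are scored by the plug-in
#' normalized mutual information with the true activity labels of the held-out
#' test compounds, per target. This measures how much activity information the
#' reduced representation carries on unseen compounds.
#'
#' @inheritParams evaluate_reduced_representation
#' @return An `aic_cv` object whose `folds$norm_mi` holds the held-out scores
#'   (`mcc` is `NA`).
#' @export
information_score_cv <- function(collection, n_select, k = 10, seed = 1L,
                                 subsample_size = NULL, stratified = TRUE) {
  cv_engine(collection, n_select = n_select, k = k, seed = seed,
            classifier = NULL, subsample_size = subsample_size,
            stratified = stratified)
}

#' @export
print.aic_cv <- function(x, ...) {
  cat(sprintf("<aic_cv: %d-fold, %d bits>\n", x$config$k, x$config$n_select))
  print(x$summary, ...)
  invisible(x)
}
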