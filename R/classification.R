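#' Balanced subsampling of the majority class
#'
#' Down-samples the majority class uniformly at random, without
#' replacement, to the minority class size; deterministic given the seed.
#'
#' @param labels Factor or character labels, named by subject id (or a
#'   plain vector, in which case positional ids are used).
#' @param seed Integer RNG seed.
#' @return Character vector of retained subject ids.
#' @export
balanced_subsample <- function(labels, seed = 1L) {
  ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need two classes to balance")
  if (length(classes) > 2L) stop("balanced_subsample supports two classes")
  n <- table(labels)
  n_min <- min(n)
  keep <- character(0)
  set.seed(seed)
  for (cl in classes) {
    cl_ids <- ids[labels == cl]
    keep <- c(keep, if (length(cl_ids) > n_min)
      sample(cl_ids, n_min) else cl_ids)
  }
  keep[order(match(keep, ids))]
}

#' ROC area under the curve via the rank statistic
#'
#' AUC computed as the normalized Mann-Whitney statistic of the scores:
#' the probability that a random positive outscores a random negative,
#' with ties contributing 1/2.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Labels, two classes.
#' @param positive The label counted as positive; default the second level
#'   (factors) or the lexicographically larger unique value.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("roc_auc needs exactly two classes present")
  if (is.null(positive)) positive <- classes[2]
  if (!positive %in% classes) stop("positive class not present")
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Metrics from a confusion matrix
#'
#' @param cm List or vector with `tp`, `fn`, `fp`, `tn` counts (positive
#'   class = untreated OSA by convention).
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.list(cm)
  need <- c("tp", "fn", "fp", "tn")
  if (!all(need %in% names(cm))) stop("cm needs tp, fn, fp, tn")
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative")
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion matrix")
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# stratified fold assignment: within each class, shuffle and deal folds
# round-robin. Deterministic given the seed.
assign_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Cross-validated marker-panel classification
#'
#' Stratified k-fold (default 10-fold) cross-validation of a linear
#' maximum-margin classifier (support vector machine, linear kernel, unit
#' cost) predicting group membership from the detected marker intensities.
#' Per fold, the model is fitted on the training subjects and scored on the
#' held-out subjects; the AUC is averaged over folds while the confusion
#' matrix is pooled over folds at the classifier's default decision
#' threshold (the margin sign — no threshold tuning).
#'
#' Auto-scaling moments (per-feature mean/SD) are cohort statistics; by
#' default they are recomputed inside each training fold and applied to the
#' fold's test subjects, so no information leaks from test to train.
#' `scale = "global"` instead scales once on the full cohort before
#' splitting (the simpler, leakage-prone variant some studies use).
#'
#' @param x Numeric matrix, subjects x features (e.g. the TIC-normalized
#'   intensities of the detected markers), with subject ids as rownames.
#' @param labels Two-class labels, one per row of `x`.
#' @param positive Label treated as positive (conventionally
#'   `"osa_untreated"`).
#' @param k Number of folds (>= 2; at most the smaller class size).
#' @param seed Integer seed controlling fold assignment.
#' @param cost SVM cost parameter.
#' @param kernel SVM kernel (default `"linear"`).
#' @param scale `"fold"` (leakage-free, default) or `"global"`.
#' @return A `performance_report`: list with `auc` (fold-averaged),
#'   `fold_auc`, `accuracy`, `sensitivity`, `specificity`, `confusion`
#'   (pooled tp/fn/fp/tn), `k`, `seed`, `positive`.
#' @export
crossvalidate <- function(x, labels, positive = NULL, k = 10L, seed = 1L,
                          cost = 1, kernel = "linear",
                          scale = c("fold", "global")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("labels must match rows of x")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("need exactly two classes")
  if (is.null(positive))
    positive <- if ("osa_untreated" %in% classes) "osa_untreated" else classes[2]
  if (k < 2L) stop("k must be at least 2")
  if (min(table(labels)) < k)
    stop("fewer subjects in the smaller class (", min(table(labels)),
         ") than folds (", k, ")")
  scale_cols <- function(train, apply_to) {
    mu <- colMeans(train)
    sdv <- apply(train, 2, stats::sd)
    sdv[sdv == 0] <- 1  # constant feature in fold: centre only
    list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
         test = sweep(sweep(apply_to, 2, mu), 2, sdv, "/"))
  }
  if (scale == "global") {
    sc <- scale_cols(x, x)
    x <- sc$train
  }
  fold <- assign_folds(labels, k, seed)
  y <- factor(labels, levels = classes)
  fold_auc <- numeric(k)
  pred_all <- character(nrow(x))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (scale == "fold") {
      sc <- scale_cols(x[tr, , drop = FALSE], x[te, , drop = FALSE])
      xtr <- sc$train; xte <- sc$test
    } else {
      xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    }
    fit <- e1071::svm(xtr, y[tr], kernel = kernel, cost = cost, scale = FALSE)
    pr <- stats::predict(fit, xte, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # decision values are oriented toward the first class in the colname
    first <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
    score <- if (first == positive) dv else -dv
    fold_auc[f] <- roc_auc(score, labels[te], positive = positive)
    pred_all[te] <- as.character(pr)
  }
  is_pos <- labels == positive
  pred_pos <- pred_all == positive
  cm <- list(tp = sum(is_pos & pred_pos), fn = sum(is_pos & !pred_pos),
             fp = sum(!is_pos & pred_pos), tn = sum(!is_pos & !pred_pos))
  met <- confusion_metrics(cm)
  structure(list(auc = mean(fold_auc), fold_auc = fold_auc,
                 accuracy = met$accuracy, sensitivity = met$sensitivity,
                 specificity = met$specificity, confusion = cm,
                 k = k, seed = seed, positive = positive,
                 scale = scale, cost = cost, kernel = kernel),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(paste0("<performance_report> %d-fold CV (seed %d)\n",
                     "  AUC (fold-averaged): %.3f\n",
                     "  accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
                     "  pooled confusion: tp=%d fn=%d fp=%d tn=%d (positive: %s)\n"),
              x$k, x$seed, x$auc, x$accuracy, x$sensitivity, x$specificity,
              x$confusion$tp, x$confusion$fn, x$confusion$fp, x$confusion$tn,
              x$positive))
  invisible(x)
}
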