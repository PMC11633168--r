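#' Sex-differentiated taxa by LDA effect size
#'
#' Two-class LEfSe-style screen (see [lda_effect_scores()]) with the
#' conventional LDA threshold 2.0 and Kruskal-Wallis cutoff 0.05;
#' markers are labeled by the sex they are enriched in. Genus- and
#' species-level tables should be screened as separate feature sets.
#'
#' @param table a [taxon_profile_table()] or samples x taxa matrix.
#' @param sex_labels per-sample `"female"`/`"male"`.
#' @param alpha,lda_threshold,n_boot,seed see [lda_effect_scores()].
#' @return data.frame of markers with an `enriched_in` column.
#' @export
sex_differential <- function(table, sex_labels, alpha = 0.05,
                             lda_threshold = 2.0, n_boot = 30, seed = 1) {
  sx <- as.character(sex_labels)
  if (length(unique(sx)) < 2) stop("need both sexes")
  res <- lda_effect_scores(table, sx, alpha = alpha,
                           lda_threshold = lda_threshold,
                           n_boot = n_boot, seed = seed)
  names(res)[names(res) == "class"] <- "enriched_in"
  res
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = (U / (n1 * n0))` with `U` the rank-sum statistic of the
#' positive-class scores; ties get half-credit. Equals trapezoidal
#' integration of the empirical ROC curve.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (positive = the larger-scoring class
#'   label given in `positive`).
#' @param positive which label counts as positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels, positive = labels[1]) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("need both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#' @inheritParams auc_mann_whitney
#' @return data.frame of (fpr, tpr) at every score threshold.
#' @export
roc_points <- function(scores, labels, positive = labels[1]) {
  o <- order(scores, decreasing = TRUE)
  pos <- labels[o] == positive
  tpr <- cumsum(pos) / sum(pos)
  fpr <- cumsum(!pos) / sum(!pos)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Train and evaluate a random-forest sex classifier
#'
#' Stratified 70/30 train/test split (balanced representation of the
#' classes), a 500-tree classification forest (mtry = sqrt(p), unlimited
#' depth), held-out AUC by the Mann-Whitney formulation, and normalized
#' Gini (mean decrease in impurity) feature importances.
#'
#' @param features samples x features numeric matrix (typically the
#'   differential-marker abundances).
#' @param labels binary class labels.
#' @param train_fraction fraction used for training (stratified).
#' @param n_trees number of trees.
#' @param seed integer seed (fixes split and forest).
#' @param positive label treated as the positive class (default
#'   `"female"` when present, else the first label).
#' @param n_repeats number of independent split/forest repeats for
#'   stability reporting; `auc` and `importances` are averaged over
#'   repeats (the single-split AUC at a 70/30 split of a few hundred
#'   samples carries a null sd of about 0.06; averaging repeats
#'   estimates the same quantity with less noise). ROC points and test
#'   scores come from the first repeat.
#' @return a `classifier_report`: `auc`, `auc_repeats`, `roc`,
#'   `importances` (ranked), `split`, `n_trees`, `seed`, `test_scores`,
#'   `test_labels`.
#' @export
train_sex_classifier <- function(features, labels, train_fraction = 0.7,
                                 n_trees = 500, seed = 1,
                                 positive = NULL, n_repeats = 1) {
  X <- as.matrix(features)
  y <- as.character(labels)
  stopifnot(nrow(X) == length(y), n_repeats >= 1)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("labels must be binary")
  if (is.null(positive))
    positive <- if ("female" %in% classes) "female" else classes[1]
  ybin <- as.integer(y == positive)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  aucs <- numeric(n_repeats)
  imp_sum <- stats::setNames(numeric(ncol(X)), colnames(X))
  first <- NULL
  for (rep_i in seq_len(n_repeats)) {
    train_idx <- unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      sample(idx, floor(train_fraction * length(idx)))
    }))
    test_idx <- setdiff(seq_along(y), train_idx)
    if (!all(classes %in% y[train_idx]) || !all(classes %in% y[test_idx]))
      stop("a class is absent from the train or test split")
    fit <- .rf_cpp(X[train_idx, , drop = FALSE], ybin[train_idx],
                   X[test_idx, , drop = FALSE], as.integer(n_trees),
                   mtry, 1L)
    scores <- as.numeric(fit$prob)
    aucs[rep_i] <- auc_mann_whitney(scores, y[test_idx],
                                    positive = positive)
    imp_sum <- imp_sum + as.numeric(fit$importance)
    if (rep_i == 1)
      first <- list(scores = scores, labels = y[test_idx])
  }
  imp <- sort(imp_sum / n_repeats, decreasing = TRUE)
  structure(list(auc = mean(aucs),
                 auc_repeats = aucs,
                 roc = roc_points(first$scores, first$labels, positive),
                 importances = imp,
                 split = c(train_fraction = train_fraction,
                           stratified = 1),
                 n_trees = n_trees, mtry = mtry, seed = seed,
                 n_repeats = n_repeats, positive = positive,
                 test_scores = first$scores,
                 test_labels = first$labels),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "classifier_report: AUC %.3f (%d trees, mtry %d, %d%% train)\n",
    x$auc, x$n_trees, x$mtry, round(100 * x$split["train_fraction"])))
  top <- utils::head(x$importances, 5)
  cat("  top importances:",
      paste(sprintf("%s=%.3f", display_name(names(top)), top),
            collapse = ", "), "\n")
  invisible(x)
}
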