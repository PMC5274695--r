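# SVM top layer and grouped stratified cross-validation.
#
# The SVM maximizes the standard soft-margin dual
#   nu(lambda) = sum_i lambda_i
#              - 1/2 sum_ij lambda_i lambda_j y_i y_j K(x_i, x_j)
# subject to 0 <= lambda_i <= C and sum_i lambda_i y_i = 0, solved by
# libsvm (via e1071). The multi-class wrapper is one-vs-rest: one
# binary machine per class, decision by maximal decision-function
# value, matching the per-class one-vs-rest metric definitions.

#' Fit a one-vs-rest SVM
#'
#' @param features numeric matrix N x d (finite values).
#' @param labels integer labels in `0..n_classes-1`; at least 2 classes.
#' @param kernel `"linear"` or `"radial"`.
#' @param C soft-margin regularization constant (default 1).
#' @return an `svm_ovr` model: one binary machine per class, each with
#'   its support-vector coefficients `lambda_y` (= lambda_i * y_i) and
#'   intercept.
#' @export
svm_fit <- function(features, labels, kernel = c("linear", "radial"),
                    C = 1) {
  kernel <- match.arg(kernel)
  stopifnot(is.matrix(features), all(is.finite(features)),
            nrow(features) == length(labels))
  classes <- sort(unique(as.integer(labels)))
  if (length(classes) < 2) stop("svm_fit() needs at least 2 classes")
  machines <- lapply(classes, function(cl) {
    yb <- factor(ifelse(labels == cl, "pos", "rest"),
                 levels = c("pos", "rest"))
    e1071::svm(features, yb, kernel = kernel, cost = C, scale = FALSE)
  })
  structure(list(machines = machines, classes = classes,
                 kernel = kernel, C = C),
            class = "svm_ovr")
}

#' Decision values of a one-vs-rest SVM
#'
#' @param model an `svm_ovr` from [svm_fit()].
#' @param features numeric matrix N x d.
#' @return N x n_classes matrix of decision-function values, one column
#'   per class (positive = that class).
#' @export
svm_decision <- function(model, features) {
  stopifnot(inherits(model, "svm_ovr"))
  vals <- vapply(model$machines, function(m) {
    dv <- attr(stats::predict(m, features, decision.values = TRUE),
               "decision.values")
    # orient so that larger = more "pos"
    if (colnames(dv)[1] == "pos/rest") dv[, 1] else -dv[, 1]
  }, numeric(nrow(features)))
  matrix(vals, nrow(features), length(model$machines))
}

#' Predict labels with a one-vs-rest SVM
#'
#' @inheritParams svm_decision
#' @return integer labels (maximal decision value wins).
#' @export
svm_predict <- function(model, features) {
  dv <- svm_decision(model, features)
  model$classes[max.col(dv, ties.method = "first")]
}

#' Dual-constraint residuals of a fitted SVM
#'
#' Returns `sum_i lambda_i y_i` for each binary subproblem; a correctly
#' solved dual makes these zero.
#'
#' @param model an `svm_ovr`.
#' @return numeric vector, one residual per class machine.
#' @export
svm_dual_residuals <- function(model) {
  vapply(model$machines, function(m) sum(m$coefs), numeric(1))
}

#' Grouped stratified k-fold plan
#'
#' Partitions sample indices into `k` disjoint folds, stratified by
#' class and grouped: all rows sharing a group id (e.g. the 8 augmented
#' variants of one source patch) are assigned to the same fold, so no
#' augmentation leakage can occur. Groups are dealt round-robin per
#' class after a seeded shuffle; fold sizes differ by at most one group
#' per class. Deterministic given `seed`.
#'
#' @param labels integer labels, one per sample.
#' @param k fold count (default 10).
#' @param groups group id per sample (default: each sample its own
#'   group); a group must not mix labels.
#' @param seed integer seed.
#' @return a `fold_plan`: list with `k`, `fold` (fold id per sample,
#'   1..k), `groups`, `seed`.
#' @export
make_folds <- function(labels, k = 10L, groups = seq_along(labels),
                       seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  stopifnot(length(groups) == n, k >= 2)
  if (length(unique(groups)) < k)
    stop("need at least k groups (", k, "), got ",
         length(unique(groups)))
  glab <- tapply(labels, groups, function(v) {
    u <- unique(v)
    if (length(u) > 1) stop("a group mixes labels")
    u
  })
  gids <- names(glab)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  gfold <- integer(length(gids)); names(gfold) <- gids
  offset <- 0L
  for (cl in sort(unique(as.vector(glab)))) {
    idx <- which(glab == cl)
    idx <- idx[sample.int(length(idx))]
    gfold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)        # continue the deal across classes
  }
  fold <- gfold[as.character(groups)]
  names(fold) <- NULL
  structure(list(k = as.integer(k), fold = fold, groups = groups,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Cross-validate the CNN + head pipeline on a data matrix
#'
#' For each fold: train the CNN on the remaining folds, extract
#' penultimate features, fit the head (one-vs-rest SVM or the CNN's own
#' softmax), and evaluate on the held-out fold.
#'
#' @param data N x 785 data matrix from [build_data_matrix()] (last
#'   column = label).
#' @param plan a `fold_plan` over the rows of `data`; augmented
#'   variants of one source patch must share a fold.
#' @param cnn_cfg a [cnn_config()].
#' @param head `"svm"` or `"softmax"`.
#' @param kernel,C SVM head settings.
#' @param retrain_cnn if `FALSE`, the CNN is trained once on all rows
#'   and only the head is refit per fold (faster, slightly optimistic
#'   for the CNN representation).
#' @return list with `per_fold` (list of `metrics_report`), `mean_report`
#'   (fields averaged over folds) and `accuracy` (mean overall accuracy).
#' @export
cross_validate <- function(data, plan, cnn_cfg = cnn_config(),
                           head = c("svm", "softmax"),
                           kernel = "linear", C = 1,
                           retrain_cnn = TRUE) {
  head <- match.arg(head)
  stopifnot(inherits(plan, "fold_plan"), length(plan$fold) == nrow(data))
  grp <- plan$groups
  for (g in unique(grp)) {
    f <- unique(plan$fold[grp == g])
    if (length(f) > 1)
      stop("fold leakage: group ", g, " spans folds ",
           paste(f, collapse = ", "))
  }
  x <- data[, 1:784, drop = FALSE]
  y <- as.integer(data[, 785])
  shared_model <- if (!retrain_cnn) cnn_train(cnn_cfg, x, y) else NULL
  reports <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    tr <- plan$fold != f; te <- !tr
    model <- if (retrain_cnn) cnn_train(cnn_cfg, x[tr, , drop = FALSE],
                                        y[tr])
    else shared_model
    if (head == "svm") {
      ftr <- penultimate_features(model, x[tr, , drop = FALSE])
      fte <- penultimate_features(model, x[te, , drop = FALSE])
      sv <- svm_fit(ftr, y[tr], kernel = kernel, C = C)
      pred <- svm_predict(sv, fte)
      scores <- svm_decision(sv, fte)
    } else {
      scores <- cnn_forward(model, x[te, , drop = FALSE])
      pred <- max.col(scores, ties.method = "first") - 1L
    }
    reports[[f]] <- metrics_report(y[te], pred, scores)
  }
  accs <- vapply(reports, function(r) r$overall_accuracy, numeric(1))
  list(per_fold = reports,
       mean_report = mean_metrics(reports),
       accuracy = mean(accs))
}

# average numeric fields of a list of metrics reports
mean_metrics <- function(reports) {
  cols <- c("accuracy", "ppv", "npv", "sensitivity", "specificity",
            "mcc", "auc")
  per_class <- Reduce(`+`, lapply(reports, function(r)
    as.matrix(r$per_class[, cols]))) / length(reports)
  out <- data.frame(class = reports[[1]]$per_class$class, per_class)
  list(overall_accuracy = mean(vapply(reports, `[[`, numeric(1),
                                      "overall_accuracy")),
       per_class = out,
       macro = colMeans(per_class))
}
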