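# Stratified fold assignment: class proportions per fold within one sample
# of the global proportions.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Inner cross-validated grid search for the SVM cost parameter on the
# training folds only; ties resolved toward the smallest cost.
.tune_cost <- function(xtr, ytr, kernel, cost_grid, inner_folds, gamma) {
  fold <- .stratified_folds(ytr, inner_folds)
  acc <- vapply(cost_grid, function(cost) {
    hits <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      if (length(unique(ytr[tr])) < 2) return(NA_real_)
      m <- e1071::svm(xtr[tr, , drop = FALSE], droplevels(ytr[tr]),
                      kernel = kernel, cost = cost, gamma = gamma,
                      scale = FALSE)
      mean(as.character(predict(m, xtr[!tr, , drop = FALSE])) ==
             as.character(ytr[!tr]))
    }, numeric(1))
    mean(hits, na.rm = TRUE)
  }, numeric(1))
  cost_grid[which.max(acc)]
}

# Fit + predict for one outer fold. Returns predicted labels and (binary)
# a decision score oriented toward the positive class (second level).
.fit_predict <- function(algorithm, xtr, ytr, xte, cost_grid, inner_folds,
                         gamma, binary) {
  pos <- levels(ytr)[2]
  if (algorithm %in% c("radial", "linear")) {
    cost <- .tune_cost(xtr, ytr, algorithm, cost_grid, inner_folds, gamma)
    m <- e1071::svm(xtr, ytr, kernel = algorithm, cost = cost, gamma = gamma,
                    scale = FALSE, decision.values = binary)
    pr <- predict(m, xte, decision.values = binary)
    score <- NULL
    if (binary) {
      dv <- attr(pr, "decision.values")
      score <- if (startsWith(colnames(dv)[1], paste0(pos, "/"))) dv[, 1] else -dv[, 1]
    }
    list(pred = as.character(pr), score = score, cost = cost)
  } else if (algorithm == "rf") {
    m <- randomForest::randomForest(xtr, ytr)
    pr <- predict(m, xte)
    score <- NULL
    if (binary) score <- predict(m, xte, type = "prob")[, pos]
    list(pred = as.character(pr), score = score, cost = NA_real_)
  } else stop("unknown algorithm: ", algorithm)
}

#' Iterated stratified cross-validation of the diagnostic classifier
#'
#' The paper-style harness: `n_iterations` repetitions of stratified
#' `outer_folds`-fold cross-validation; on each training split an inner
#' `inner_folds`-fold grid search tunes the SVM cost over `cost_grid`; the
#' best-tuned radial-kernel model is evaluated on the held-out fold.
#' Multiclass problems use libsvm's one-vs-one voting. Predictions are
#' pooled over all iterations into a confusion matrix; for binary tasks the
#' ROC AUC is computed per iteration from the held-out decision scores and
#' summarized as mean with a 2.5/97.5 percentile interval.
#'
#' @param x numeric feature matrix (samples x features), no missing values.
#' @param y labels; for `task = "binary"` a 2-level factor whose second
#'   level is the positive class (character input: alphabetical levels).
#' @param task `"binary"` or `"multiclass"`.
#' @param n_iterations,outer_folds,inner_folds,cost_grid harness settings.
#' @param seed integer seed; same seed reproduces the report exactly.
#' @param algorithm `"radial"` (default), `"linear"` or `"rf"`.
#' @return a `cv_report`: pooled confusion matrix (predicted x actual),
#'   pooled accuracy, per-class sensitivity, per-iteration accuracies,
#'   binary AUC summary, precision/recall/F1, tuned costs, fold
#'   assignments.
#' @export
run_cv <- function(x, y, task = c("binary", "multiclass"),
                   n_iterations = 100, outer_folds = 4, inner_folds = 3,
                   cost_grid = 1:10, seed = 1, algorithm = "radial") {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values")
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (task == "binary" && nlevels(y) != 2)
    stop("binary task needs exactly 2 classes")
  small <- table(y) < outer_folds
  if (any(small))
    stop("class(es) smaller than the fold count: ",
         paste(names(which(small)), collapse = ", "))
  binary <- task == "binary"
  gamma <- 1 / (ncol(x) * var(as.vector(x)))
  n <- nrow(x)
  lev <- levels(y)

  set.seed(as.integer(seed))
  conf <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  acc_iter <- numeric(n_iterations)
  aucs <- if (binary) numeric(n_iterations) else NULL
  costs <- matrix(NA_real_, n_iterations, outer_folds)
  folds <- matrix(0L, n, n_iterations)
  for (it in seq_len(n_iterations)) {
    fold <- .stratified_folds(y, outer_folds)
    folds[, it] <- fold
    preds <- character(n)
    scores <- numeric(n)
    for (f in seq_len(outer_folds)) {
      tr <- fold != f
      fp <- .fit_predict(algorithm, x[tr, , drop = FALSE], droplevels(y[tr]),
                         x[!tr, , drop = FALSE], cost_grid, inner_folds,
                         gamma, binary)
      preds[!tr] <- fp$pred
      if (binary) scores[!tr] <- fp$score
      costs[it, f] <- fp$cost
    }
    conf <- conf + unclass(table(factor(preds, lev), y))
    acc_iter[it] <- mean(preds == as.character(y))
    if (binary)
      aucs[it] <- as.numeric(pROC::auc(y, scores, levels = lev,
                                       direction = "<", quiet = TRUE))
  }

  report <- list(
    task = task, algorithm = algorithm, levels = lev,
    confusion = conf,
    accuracy = sum(diag(conf)) / sum(conf),
    per_class_sensitivity = diag(conf) / colSums(conf),
    accuracy_per_iteration = acc_iter,
    mean_iteration_accuracy = mean(acc_iter),
    tuned_costs = costs, folds = folds,
    n_iterations = n_iterations, outer_folds = outer_folds, seed = seed
  )
  if (binary) {
    pos <- lev[2]; neg <- lev[1]
    tp <- conf[pos, pos]; fp <- conf[pos, neg]
    fn <- conf[neg, pos]
    report$auc <- list(mean = mean(aucs),
                       ci = quantile(aucs, c(0.025, 0.975), names = FALSE),
                       per_iteration = aucs)
    report$recall <- tp / (tp + fn)
    report$precision <- tp / (tp + fp)
    report$f1 <- 2 * report$precision * report$recall /
      (report$precision + report$recall)
  }
  structure(report, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation (%s, %s): %d iterations x %d folds\n",
              x$task, x$algorithm, x$n_iterations, x$outer_folds))
  cat(sprintf("Pooled accuracy: %.1f%%\n", 100 * x$accuracy))
  if (!is.null(x$auc))
    cat(sprintf("Mean AUC: %.3f (95%% CI %.3f-%.3f)\n",
                x$auc$mean, x$auc$ci[1], x$auc$ci[2]))
  cat("Confusion matrix (rows = predicted, cols = actual):\n")
  print(x$confusion)
  invisible(x)
}

#' Compare classification algorithms under the identical CV harness
#'
#' @inheritParams run_cv
#' @param algorithms subset of `"radial"`, `"linear"`, `"rf"`.
#' @return data frame with one row per algorithm (mean pooled accuracy,
#'   and binary AUC when applicable), plus the full reports in
#'   `attr(, "reports")`.
#' @export
compare_algorithms <- function(x, y, task = c("binary", "multiclass"),
                               algorithms = c("radial", "linear", "rf"),
                               n_iterations = 20, outer_folds = 4,
                               inner_folds = 3, cost_grid = 1:10, seed = 1) {
  task <- match.arg(task)
  bad <- setdiff(algorithms, c("radial", "linear", "rf"))
  if (length(bad)) stop("unknown algorithm(s): ", paste(bad, collapse = ", "))
  reports <- lapply(algorithms, function(alg)
    run_cv(x, y, task, n_iterations, outer_folds, inner_folds, cost_grid,
           seed = seed, algorithm = alg))
  names(reports) <- algorithms
  out <- data.frame(
    algorithm = algorithms,
    accuracy = vapply(reports, function(r) r$accuracy, numeric(1)),
    auc = vapply(reports, function(r)
      if (is.null(r$auc)) NA_real_ else r$auc$mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Rank features by cross-validated t-statistic strength
#'
#' Features are ranked by the mean absolute equal-variance t-statistic
#' computed on training folds only (binary: positive-vs-negative contrast;
#' multiclass: the maximum over one-vs-rest contrasts), averaged over
#' `n_iterations` stratified fold splits. The tissue-site indicator is
#' ranked by the same statistic on its 0/1 values.
#'
#' @inheritParams run_cv
#' @param n_iterations fold-split repetitions for ranking stability.
#' @return character vector: feature names, strongest first.
#' @export
rank_features <- function(x, y, task = c("binary", "multiclass"),
                          n_iterations = 10, outer_folds = 4, seed = 1) {
  task <- match.arg(task)
  x <- as.matrix(x)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  set.seed(as.integer(seed))
  total <- numeric(ncol(x)); nfold <- 0L
  for (it in seq_len(n_iterations)) {
    fold <- .stratified_folds(y, outer_folds)
    for (f in seq_len(outer_folds)) {
      tr <- fold != f
      xt <- x[tr, , drop = FALSE]; yt <- y[tr]
      tstat <- if (task == "binary") {
        abs(col_ttests(xt[yt == levels(y)[2], , drop = FALSE],
                       xt[yt != levels(y)[2], , drop = FALSE])$t)
      } else {
        do.call(pmax, lapply(levels(y), function(cl)
          abs(col_ttests(xt[yt == cl, , drop = FALSE],
                         xt[yt != cl, , drop = FALSE])$t)))
      }
      total <- total + tstat
      nfold <- nfold + 1L
    }
  }
  colnames(x)[order(-(total / nfold))]
}

#' Classification accuracy versus number of top-ranked features
#'
#' Re-runs the full CV harness restricted to the top-k ranked features for
#' each requested k.
#'
#' @inheritParams run_cv
#' @param ranking ordered feature names from [rank_features()]; must cover
#'   every requested k.
#' @param k_values feature counts to evaluate.
#' @return a `feature_curve` data frame (`k`, `accuracy`), with the
#'   ranking in `attr(, "ranking")`.
#' @export
accuracy_vs_k <- function(x, y, task = c("binary", "multiclass"), ranking,
                          k_values, n_iterations = 20, outer_folds = 4,
                          inner_folds = 3, cost_grid = 1:10, seed = 1) {
  task <- match.arg(task)
  if (any(k_values > length(ranking)))
    stop("k exceeds the number of ranked features")
  if (!all(ranking %in% colnames(x)))
    stop("ranking names features absent from the matrix")
  acc <- vapply(k_values, function(k) {
    run_cv(x[, ranking[seq_len(k)], drop = FALSE], y, task,
           n_iterations, outer_folds, inner_folds, cost_grid,
           seed = seed)$accuracy
  }, numeric(1))
  out <- data.frame(k = k_values, accuracy = acc)
  attr(out, "ranking") <- ranking
  class(out) <- c("feature_curve", "data.frame")
  out
}
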