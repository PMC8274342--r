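# Repeated stratified hold-out nested cross-validation of a linear SVM on
# parcel-mean features.

#' Cross-validation scheme
#'
#' Repeated hold-out with class-size stratification: in every iteration,
#' 80% of the smaller class count is drawn for training from *each* class
#' (a class-balanced training set, minimizing class imbalance), the
#' remainder is the test set, an inner stratified CV on the training split
#' selects the SVM cost from a log-spaced grid, the model is refitted on
#' the full training split, and balanced accuracy is measured on the
#' held-out split.
#'
#' @param iterations number of hold-out repetitions (default 250)
#' @param train_fraction fraction of the smallest class reserved for
#'   training (default 0.8), in (0, 1)
#' @param inner_folds folds of the inner selection loop
#' @param cost_grid candidate SVM cost parameters
#' @param seed seed governing all splits (so different feature sets
#'   evaluated under the same scheme share identical splits)
#' @return a `cv_scheme`
#' @export
cv_scheme <- function(iterations = 250, train_fraction = 0.8,
                      inner_folds = 5, cost_grid = 10^seq(-3, 2),
                      seed = 1) {
  stopifnot(iterations >= 1, train_fraction > 0, train_fraction < 1,
            inner_folds >= 2, all(cost_grid > 0))
  structure(list(iterations = as.integer(iterations),
                 train_fraction = train_fraction,
                 inner_folds = as.integer(inner_folds),
                 cost_grid = cost_grid, seed = as.integer(seed)),
            class = "cv_scheme")
}

# Fit the linear SVM (bias via constant column) and return a predict closure.
fit_linear_svm <- function(x, y01, cost) {
  Xa <- cbind(x, 1)
  w <- .svm_linear_cpp(Xa, ifelse(y01 == 1, 1, -1), cost, 1000L, 1e-4)
  function(newx) as.numeric(cbind(newx, 1) %*% w > 0)
}

balanced_accuracy <- function(truth, pred) {
  sens <- mean(pred[truth == 1] == 1)
  spec <- mean(pred[truth == 0] == 0)
  mean(c(sens, spec))
}

# z-score columns using training statistics only; constant columns dropped.
fit_scaler <- function(xtr) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  keep <- sdv > 0
  list(mu = mu, sd = sdv, keep = keep,
       apply = function(x) sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]),
                                 2, sdv[keep], "/"))
}

#' Nested cross-validated linear SVM classification
#'
#' @param features subjects x features numeric matrix (e.g. parcel means;
#'   concatenate columns to combine modalities)
#' @param labels two-level factor or character vector; the second level (in
#'   sorted order) is coded as the positive class
#' @param scheme a [cv_scheme()]
#' @return numeric vector of balanced accuracies (one per iteration), with
#'   attributes `chosen_cost` (per iteration) and `dropped_features`
#' @export
nested_cv_classify <- function(features, labels, scheme = cv_scheme()) {
  stopifnot(inherits(scheme, "cv_scheme"))
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes")
  cls <- levels(labels)
  i0 <- which(labels == cls[1]); i1 <- which(labels == cls[2])
  if (length(i0) < 3 || length(i1) < 3)
    stop("each class needs at least 3 members")
  if (any(!is.finite(features))) stop("features must be finite")
  const_cols <- apply(features, 2, sd) == 0
  if (any(const_cols)) {
    message(sum(const_cols), " constant feature column(s) dropped")
    features <- features[, !const_cols, drop = FALSE]
  }
  y01 <- as.integer(labels == cls[2])
  n_train <- max(2L, floor(scheme$train_fraction * min(length(i0), length(i1))))

  # draw all splits up front: they depend only on labels and the seed, so
  # different feature sets are evaluated on identical splits
  set.seed(scheme$seed)
  splits <- lapply(seq_len(scheme$iterations), function(i) {
    tr <- c(sample(i0, n_train), sample(i1, n_train))
    list(train = tr, test = setdiff(seq_along(labels), tr))
  })

  bacc <- numeric(scheme$iterations)
  chosen <- numeric(scheme$iterations)
  for (it in seq_len(scheme$iterations)) {
    tr <- splits[[it]]$train; te <- splits[[it]]$test
    xtr <- features[tr, , drop = FALSE]; ytr <- y01[tr]
    # inner stratified folds on the training split
    fold_of <- integer(length(tr))
    for (cl in 0:1) {
      m <- which(ytr == cl)
      fold_of[m] <- rep_len(seq_len(scheme$inner_folds), length(m))
    }
    inner <- vapply(scheme$cost_grid, function(cost) {
      acc <- vapply(seq_len(scheme$inner_folds), function(f) {
        itr <- fold_of != f; ite <- !itr
        if (length(unique(ytr[itr])) < 2 || !any(ite)) return(NA_real_)
        sc <- fit_scaler(xtr[itr, , drop = FALSE])
        mdl <- fit_linear_svm(sc$apply(xtr[itr, , drop = FALSE]), ytr[itr], cost)
        balanced_accuracy(ytr[ite], mdl(sc$apply(xtr[ite, , drop = FALSE])))
      }, numeric(1))
      mean(acc, na.rm = TRUE)
    }, numeric(1))
    best <- scheme$cost_grid[which.max(inner)]  # ties -> smallest cost
    sc <- fit_scaler(xtr)
    mdl <- fit_linear_svm(sc$apply(xtr), ytr, best)
    bacc[it] <- balanced_accuracy(y01[te],
                                  mdl(sc$apply(features[te, , drop = FALSE])))
    chosen[it] <- best
  }
  attr(bacc, "chosen_cost") <- chosen
  attr(bacc, "dropped_features") <- which(const_cols)
  bacc
}

#' Compare classifier configurations by Friedman ranking over iterations
#'
#' Configurations must have been evaluated with identical schemes (same
#' seed and labels), so that iteration i used the same train/test split in
#' every configuration; the Friedman test then treats iterations as
#' blocks.
#'
#' @param bacc_list named list of equal-length BACC vectors from
#'   [nested_cv_classify()]
#' @return a `ranking_result` (higher BACC better)
#' @export
compare_configurations <- function(bacc_list) {
  lens <- lengths(bacc_list)
  if (length(unique(lens)) != 1)
    stop("unpaired BACC vectors: iteration counts differ")
  friedman_rank(do.call(cbind, bacc_list), direction = "higher")
}
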