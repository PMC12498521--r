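#' Root mean square error of a model's predicted probabilities
#'
#' `sqrt(mean((SPP - y01)^2))` with the labels recoded to 0/1. Bounded in
#' [0, 1], so the default grid cutoff of 100 retains every model.
#'
#' @param model An `esl_model`.
#' @param X Encoded rows.
#' @param y Labels in -1/+1.
#' @return Nonnegative scalar.
#' @export
model_rmse <- function(model, X, y) {
  spp <- stats::plogis(predict_sps(model, X))
  y01 <- (y + 1) / 2
  sqrt(mean((spp - y01)^2))
}

#' Training classification accuracy
#'
#' Fraction of rows whose predicted class (+1 iff SPS >= 0) matches the
#' label.
#'
#' @inheritParams model_rmse
#' @return Value in [0, 1].
#' @export
model_accuracy <- function(model, X, y) {
  sps <- predict_sps(model, X)
  mean(ifelse(sps >= 0, 1, -1) == y)
}

# stratified fold ids: seeded shuffle within class, then round-robin
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Taxa are split into k folds preserving class proportions (per-class
#' round-robin after a seeded shuffle, so per-fold class counts differ by
#' at most 1 from perfect stratification). For each fold a model is fitted
#' on the remaining k-1 folds and classification accuracy is measured on
#' the held-out taxa.
#'
#' @inheritParams fit_sgl_logistic
#' @param k Number of folds (>= 2); each class must have at least k members.
#' @param seed Seed for the fold shuffle.
#' @return List with `fold_accuracy` (length k), `mean_accuracy`, `folds`
#'   (fold id per row) and `models`.
#' @export
kfold_cv <- function(X, y, w = rep(1, length(y)), groups, k = 5L,
                     lambda1 = 0.1, lambda2 = 0.1, seed = 42L,
                     opts = fit_options()) {
  stopifnot(k >= 2L)
  if (min(sum(y == 1), sum(y == -1)) < k) {
    stop("a class has fewer than k = ", k,
         " members; use a smaller k", call. = FALSE)
  }
  fold <- .stratified_folds(y, k, seed)
  acc <- numeric(k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- fit_sgl_logistic(X[tr, , drop = FALSE], y[tr], w[tr], groups,
                          lambda1, lambda2, opts)
    models[[f]] <- m
    acc[f] <- model_accuracy(m, X[!tr, , drop = FALSE], y[!tr])
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc), folds = fold,
       models = models)
}

# inclusive lattice min..max by step (max included when it is an integer
# number of steps away, within 1e-9)
.lambda_lattice <- function(grid) {
  stopifnot(length(grid) == 3L)
  lo <- grid[1]; hi <- grid[2]; step <- grid[3]
  if (step <= 0) stop("grid step must be > 0", call. = FALSE)
  if (lo < 0 || hi > 1 || lo > hi) {
    stop("grid bounds must satisfy 0 <= min <= max <= 1", call. = FALSE)
  }
  n <- floor((hi - lo) / step + 1e-9)
  lo + step * (0:n)
}

#' Grid search over the (lambda1, lambda2) regularization space
#'
#' Fits a model at every pair of the inclusive lattices defined by
#' `(min, max, step)` for each lambda, then marks each model as retained
#' when its RMSE is at most `rmse_cutoff`, its training accuracy at least
#' `acc_cutoff`, and it selects at least `min_groups` groups. The default
#' RMSE cutoff of 100 excludes nothing (RMSE is bounded by 1); the default
#' accuracy cutoff is 0.95.
#'
#' @inheritParams fit_sgl_logistic
#' @param lambda1_grid,lambda2_grid Numeric `c(min, max, step)`.
#' @param rmse_cutoff,acc_cutoff,min_groups Retention thresholds.
#' @return An `esl_grid`: list with `results` (data.frame: lambda1, lambda2,
#'   rmse, train_accuracy, n_groups_selected, retained) and `models`.
#' @export
grid_search <- function(X, y, w = rep(1, length(y)), groups,
                        lambda1_grid = c(0.1, 0.3, 0.1),
                        lambda2_grid = c(0.1, 0.3, 0.1),
                        rmse_cutoff = 100, acc_cutoff = 0.95,
                        min_groups = 1L, opts = fit_options(),
                        feature_map = NULL,
                        hypothesis_name = "hypothesis") {
  l1s <- .lambda_lattice(lambda1_grid)
  l2s <- .lambda_lattice(lambda2_grid)
  cells <- expand.grid(lambda1 = l1s, lambda2 = l2s,
                       KEEP.OUT.ATTRS = FALSE)
  if (!nrow(cells)) stop("empty lambda lattice", call. = FALSE)
  models <- vector("list", nrow(cells))
  res <- cells
  res$rmse <- res$train_accuracy <- NA_real_
  res$n_groups_selected <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    m <- fit_sgl_logistic(X, y, w, groups, cells$lambda1[i],
                          cells$lambda2[i], opts, feature_map,
                          hypothesis_name)
    models[[i]] <- m
    res$rmse[i] <- model_rmse(m, X, y)
    res$train_accuracy[i] <- model_accuracy(m, X, y)
    res$n_groups_selected[i] <- n_groups_selected(m)
  }
  res$retained <- res$rmse <= rmse_cutoff &
    res$train_accuracy >= acc_cutoff &
    res$n_groups_selected >= min_groups
  structure(list(results = res, models = models), class = "esl_grid")
}

#' @export
print.esl_grid <- function(x, ...) {
  cat("Lambda grid search:", nrow(x$results), "models,",
      sum(x$results$retained), "retained\n")
  print(x$results, ...)
  invisible(x)
}
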