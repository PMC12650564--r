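# Machine-learning regressors with leakage-safe grid-search tuning.
#
# Learners are implemented natively (no suitable R packages are assumed):
#   SVR - epsilon-insensitive support vector regression via its dual QP
#         (solved with quadprog);
#   RF  - random forest of compiled exact-greedy regression trees;
#   KRR - kernel ridge regression in closed form;
#   XGB - gradient-boosted regression trees (squared loss, shrinkage,
#         row/feature subsampling).

#' Machine-learning method configuration
#'
#' @param method one of `"SVR"`, `"RF"`, `"KRR"`, `"XGB"`.
#' @param grid named list of candidate parameter values; defaults from
#'   [default_grids()], with any supplied entries overriding the defaults
#'   key by key.
#' @param inner_cv_folds folds for tuning on the training data (default 5).
#' @param metric tuning criterion: `"pearson"` (default) or `"mse"`.
#' @param seed RNG seed (fold assignment, bootstraps, subsampling).
#' @return an `ml_config`.
#' @export
ml_config <- function(method = c("SVR", "RF", "KRR", "XGB"), grid = list(),
                      inner_cv_folds = 5, metric = c("pearson", "mse"),
                      seed = 1) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  stopifnot(inner_cv_folds >= 2)
  full <- default_grids()[[method]]
  for (nm in names(grid)) full[[nm]] <- grid[[nm]]
  if (length(full) == 0 || any(lengths(full) == 0))
    stop("parameter grid must be non-empty", call. = FALSE)
  structure(list(method = method, grid = full,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 metric = metric, seed = as.integer(seed)),
            class = "ml_config")
}

#' Default hyperparameter grids
#'
#' @return named list of per-method grids (SVR: `cost`, `gamma`,
#'   `epsilon`; RF: `n_trees`, `max_depth`, `feature_fraction`; KRR:
#'   `alpha`, `kernel`, `gamma`; XGB: `eta`, `max_depth`, `n_rounds`,
#'   `subsample`).
#' @export
default_grids <- function() {
  list(
    SVR = list(cost = c(1, 10), gamma = c(0.01, 0.1),
               epsilon = c(0.01, 0.1)),
    RF = list(n_trees = c(100, 200), max_depth = c(6, 12),
              feature_fraction = c(0.33, 1)),
    KRR = list(alpha = c(0.1, 1, 10), kernel = c("linear", "rbf"),
               gamma = c(0.01, 0.1)),
    XGB = list(eta = c(0.1, 0.3), max_depth = c(2, 4),
               n_rounds = c(50, 100), subsample = 0.8))
}

# ---- kernels ----------------------------------------------------------

ml_kernel <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(A, B))
  # rbf
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# ---- KRR --------------------------------------------------------------

krr_fit <- function(X, y, alpha, kernel = "rbf", gamma = 0.1) {
  xc <- colMeans(X)
  Xc <- sweep(X, 2L, xc)
  ym <- mean(y)
  K <- ml_kernel(Xc, Xc, kernel, gamma)
  dual <- solve(K + diag(alpha, nrow(K)), y - ym)
  list(X = Xc, xc = xc, ym = ym, dual = dual, kernel = kernel,
       gamma = gamma)
}

krr_predict <- function(fit, Xnew) {
  Kn <- ml_kernel(sweep(Xnew, 2L, fit$xc), fit$X, fit$kernel, fit$gamma)
  drop(Kn %*% fit$dual) + fit$ym
}

# ---- SVR (dual QP) ----------------------------------------------------

svr_fit <- function(X, y, cost = 1, gamma = 0.1, epsilon = 0.1,
                    kernel = "rbf") {
  n <- nrow(X)
  xc <- colMeans(X); Xc <- sweep(X, 2L, xc)
  ym <- mean(y); yc <- y - ym
  K <- ml_kernel(Xc, Xc, kernel, gamma)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  dvec <- c(yc - epsilon, -yc - epsilon)
  Amat <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  bvec <- c(0, rep(0, 2 * n), rep(-cost, 2 * n))
  sol <- quadprog::solve.QP(D, dvec, Amat, bvec, meq = 1)
  coef <- sol$solution[1:n] - sol$solution[(n + 1):(2 * n)]
  f0 <- drop(K %*% coef)
  # intercept from margin support vectors, else median residual
  tol <- 1e-6 * cost
  a <- sol$solution[1:n]; as <- sol$solution[(n + 1):(2 * n)]
  on_margin_up <- a > tol & a < cost - tol
  on_margin_lo <- as > tol & as < cost - tol
  b_vals <- c((yc - f0 - epsilon)[on_margin_up],
              (yc - f0 + epsilon)[on_margin_lo])
  b <- if (length(b_vals)) mean(b_vals) else
    stats::median(yc - f0)
  list(X = Xc, xc = xc, ym = ym, coef = coef, b = b, kernel = kernel,
       gamma = gamma)
}

svr_predict <- function(fit, Xnew) {
  Kn <- ml_kernel(sweep(Xnew, 2L, fit$xc), fit$X, fit$kernel, fit$gamma)
  drop(Kn %*% fit$coef) + fit$b + fit$ym
}

# ---- random forest ----------------------------------------------------

rf_fit <- function(X, y, n_trees = 200, max_depth = 12,
                   feature_fraction = 0.33, min_node = 5) {
  n <- nrow(X)
  mtry <- max(1L, floor(feature_fraction * ncol(X)))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    rows <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- tree_fit_cpp(X, y, as.integer(rows - 1L),
                               as.integer(max_depth),
                               as.integer(min_node), as.integer(mtry))
  }
  list(trees = trees)
}

rf_predict <- function(fit, Xnew) {
  preds <- vapply(fit$trees, function(tr) drop(tree_predict_cpp(tr, Xnew)),
                  numeric(nrow(Xnew)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

# ---- gradient boosting ------------------------------------------------

gbt_fit <- function(X, y, eta = 0.1, max_depth = 3, n_rounds = 100,
                    subsample = 0.8, min_node = 5) {
  n <- nrow(X)
  base <- mean(y)
  pred <- rep(base, n)
  trees <- vector("list", n_rounds)
  for (t in seq_len(n_rounds)) {
    rows <- sample.int(n, max(2L, floor(subsample * n)))
    resid <- y - pred
    tr <- tree_fit_cpp(X, resid, as.integer(rows - 1L),
                       as.integer(max_depth), as.integer(min_node),
                       as.integer(ncol(X)))
    trees[[t]] <- tr
    pred <- pred + eta * drop(tree_predict_cpp(tr, X))
  }
  list(base = base, eta = eta, trees = trees)
}

gbt_predict <- function(fit, Xnew) {
  out <- rep(fit$base, nrow(Xnew))
  for (tr in fit$trees)
    out <- out + fit$eta * drop(tree_predict_cpp(tr, Xnew))
  out
}

# ---- harness ----------------------------------------------------------

ml_fit_one <- function(method, X, y, params) {
  switch(method,
    SVR = svr_fit(X, y, cost = params$cost, gamma = params$gamma,
                  epsilon = params$epsilon),
    RF = rf_fit(X, y, n_trees = params$n_trees,
                max_depth = params$max_depth,
                feature_fraction = params$feature_fraction),
    KRR = krr_fit(X, y, alpha = params$alpha, kernel = params$kernel,
                  gamma = params$gamma),
    XGB = gbt_fit(X, y, eta = params$eta, max_depth = params$max_depth,
                  n_rounds = params$n_rounds,
                  subsample = params$subsample))
}

ml_predict_one <- function(method, fit, Xnew) {
  switch(method,
    SVR = svr_predict(fit, Xnew),
    RF = rf_predict(fit, Xnew),
    KRR = krr_predict(fit, Xnew),
    XGB = gbt_predict(fit, Xnew))
}

ml_score <- function(y, pred, metric) {
  if (metric == "mse") return(-mean((y - pred)^2))
  if (sd(pred) == 0 || sd(y) == 0) return(-Inf)
  cor(y, pred)
}

#' Fit a tuned machine-learning regressor and predict
#'
#' Every grid point is scored by inner k-fold cross-validation on the
#' training data only (Pearson correlation by default); the best point is
#' refit on the full training data and used to predict `predict_features`.
#' Grid points that fail are logged and skipped.
#'
#' @param method_cfg an [ml_config()].
#' @param train_features,train_y training data (no missing values).
#' @param predict_features features to predict (columns aligned with
#'   training).
#' @return list with `predictions`, `best_params`, `tuning` (per-grid-point
#'   scores data.frame).
#' @export
fit_predict <- function(method_cfg, train_features, train_y,
                        predict_features) {
  stopifnot(inherits(method_cfg, "ml_config"))
  X <- as.matrix(train_features)
  y <- as.numeric(train_y)
  Xp <- as.matrix(predict_features)
  if (anyNA(X) || anyNA(y) || anyNA(Xp))
    stop("missing values are not allowed", call. = FALSE)
  if (ncol(Xp) != ncol(X))
    stop("train and predict features are not column-aligned", call. = FALSE)
  if (sd(y) == 0)
    stop("training phenotype has zero variance", call. = FALSE)
  grid <- expand.grid(method_cfg$grid, stringsAsFactors = FALSE)
  k <- method_cfg$inner_cv_folds
  n <- nrow(X)
  if (n < 2 * k) k <- max(2L, n %/% 3L)
  set.seed(method_cfg$seed)
  folds <- sample(rep_len(seq_len(k), n))
  scores <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- as.list(grid[i, , drop = FALSE])
    fold_scores <- rep(NA_real_, k)
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- folds != f
      res <- tryCatch({
        set.seed(method_cfg$seed + 131 * i + f)
        fit <- ml_fit_one(method_cfg$method, X[tr, , drop = FALSE], y[tr],
                          params)
        pred <- ml_predict_one(method_cfg$method, fit,
                               X[!tr, , drop = FALSE])
        ml_score(y[!tr], pred, method_cfg$metric)
      }, error = function(e) NA_real_)
      if (is.na(res)) { ok <- FALSE; break }
      fold_scores[f] <- res
    }
    if (ok) scores[i] <- mean(fold_scores)
  }
  if (all(is.na(scores) | scores == -Inf))
    scores[is.na(scores)] <- -Inf
  if (all(scores == -Inf, na.rm = TRUE) && anyNA(scores))
    stop("every grid point failed", call. = FALSE)
  scores[is.na(scores)] <- -Inf
  best_i <- which.max(scores)
  best <- as.list(grid[best_i, , drop = FALSE])
  set.seed(method_cfg$seed + 997)
  fit <- ml_fit_one(method_cfg$method, X, y, best)
  predictions <- ml_predict_one(method_cfg$method, fit, Xp)
  names(predictions) <- rownames(Xp)
  list(predictions = predictions, best_params = best,
       tuning = cbind(grid, score = scores))
}
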