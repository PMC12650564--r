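# Prediction-quality metrics and repeated k-fold cross-validation.
#
#   accuracy = Pearson r(y, GEBV)
#   bias     = |1 - cov(y, GEBV) / var(GEBV)|   (dispersion bias; 0 = none)
#   mse/mae  = mean squared / absolute deviation on the validation set

#' Prediction accuracy
#' @param y observed phenotypes (validation set).
#' @param gebv predicted breeding values.
#' @return Pearson correlation.
#' @export
accuracy <- function(y, gebv) {
  check_metric_input(y, gebv)
  if (sd(y) == 0 || sd(gebv) == 0)
    stop("accuracy undefined: zero variance in y or GEBV", call. = FALSE)
  cor(y, gebv)
}

#' Dispersion bias of predictions
#'
#' Absolute deviation from 1 of the regression coefficient of `y` on
#' `gebv`.
#' @inheritParams accuracy
#' @return non-negative scalar.
#' @export
bias <- function(y, gebv) {
  check_metric_input(y, gebv)
  v <- var(gebv)
  if (v == 0) stop("bias undefined: GEBV has zero variance", call. = FALSE)
  abs(1 - cov(y, gebv) / v)
}

#' Mean squared / absolute error
#' @inheritParams accuracy
#' @return non-negative scalar.
#' @export
mse <- function(y, gebv) {
  if (length(y) != length(gebv)) stop("length mismatch", call. = FALSE)
  mean((y - gebv)^2)
}

#' @rdname mse
#' @export
mae <- function(y, gebv) {
  if (length(y) != length(gebv)) stop("length mismatch", call. = FALSE)
  mean(abs(y - gebv))
}

check_metric_input <- function(y, gebv) {
  if (length(y) != length(gebv)) stop("length mismatch", call. = FALSE)
  if (length(y) < 3) stop("need at least 3 observations", call. = FALSE)
  invisible(TRUE)
}

#' Repeated k-fold cross-validation scheme
#'
#' Fold assignments are simple seeded randomizations, one independent
#' permutation per repeat; assignment depends only on `(seed, repeat)`.
#'
#' @param n number of individuals.
#' @param k_folds folds per repeat (default 5).
#' @param repeats number of repeats (default 20).
#' @param seed RNG seed.
#' @return a `cv_scheme` with an `n x repeats` fold-assignment matrix.
#' @export
cv_scheme <- function(n, k_folds = 5, repeats = 20, seed = 1) {
  stopifnot(k_folds >= 2, repeats >= 1, n >= k_folds)
  assign <- matrix(0L, n, repeats)
  for (r in seq_len(repeats)) {
    set.seed(as.integer((seed + 1000003 * r) %% 2147483647))
    assign[, r] <- sample(rep_len(seq_len(k_folds), n))
  }
  structure(list(n = n, k_folds = as.integer(k_folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 assignment = assign),
            class = "cv_scheme")
}

#' Cross-validate a predictor
#'
#' For each repeat and fold, the predictor is trained on the k-1 training
#' folds and scored on the held-out fold with [accuracy()], [bias()],
#' [mse()] and [mae()].  Metrics are averaged per fold (the report also
#' carries pooled values over concatenated validation predictions).
#'
#' @param predictor a function `function(features, y, train_idx, val_idx)`
#'   returning predictions for `val_idx` (see [gblup_predictor()],
#'   [bayes_predictor()], [ml_predictor()]).
#' @param features genotype or compressed feature object passed through to
#'   the predictor.
#' @param y phenotype vector.
#' @param scheme a [cv_scheme()].
#' @return a `metrics_report`: data.frame `folds` (repeat, fold, metrics),
#'   `summary` (grand mean and SD per metric), `pooled`.
#' @export
cross_validate <- function(predictor, features, y, scheme) {
  stopifnot(inherits(scheme, "cv_scheme"))
  n <- length(y)
  if (n != scheme$n) stop("scheme was built for a different n", call. = FALSE)
  rows <- list()
  pooled_y <- c(); pooled_g <- c()
  for (r in seq_len(scheme$repeats)) {
    fold_of <- scheme$assignment[, r]
    for (f in seq_len(scheme$k_folds)) {
      val <- which(fold_of == f)
      if (length(val) < 3)
        stop(sprintf("fold %d of repeat %d has <3 validation individuals",
                     f, r), call. = FALSE)
      train <- which(fold_of != f)
      pred <- predictor(features, y, train, val)
      yv <- y[val]
      acc <- tryCatch(accuracy(yv, pred), error = function(e) NA_real_)
      bi <- tryCatch(bias(yv, pred), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = r, fold = f, accuracy = acc, bias = bi,
        mse = mse(yv, pred), mae = mae(yv, pred))
      pooled_y <- c(pooled_y, yv); pooled_g <- c(pooled_g, pred)
    }
  }
  folds <- do.call(rbind, rows)
  met <- c("accuracy", "bias", "mse", "mae")
  summary <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(folds[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(met, function(m) sd(folds[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  pooled <- data.frame(
    accuracy = tryCatch(accuracy(pooled_y, pooled_g),
                        error = function(e) NA_real_),
    bias = tryCatch(bias(pooled_y, pooled_g), error = function(e) NA_real_),
    mse = mse(pooled_y, pooled_g), mae = mae(pooled_y, pooled_g))
  structure(list(folds = folds, summary = summary, pooled = pooled,
                 scheme = list(k_folds = scheme$k_folds,
                               repeats = scheme$repeats,
                               seed = scheme$seed)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Cross-validation (%d repeats x %d folds):\n",
              x$scheme$repeats, x$scheme$k_folds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Predictor handles for cross_validate()
#'
#' Each returns a `function(features, y, train_idx, val_idx)` suitable for
#' [cross_validate()].  The GBLUP handle keeps all genotypes in `G` and
#' masks validation phenotypes inside the mixed-model equations; the Bayes
#' and ML handles fit on the training rows only.
#'
#' @param refit_g rebuild `G` from training rows only instead of masking
#'   (default FALSE).
#' @return a predictor function.
#' @export
gblup_predictor <- function(refit_g = FALSE) {
  cache <- new.env(parent = emptyenv())
  function(features, y, train_idx, val_idx) {
    if (refit_g) {
      # G built on the union but VCs estimated on training rows only is the
      # default path; the refit flag rebuilds nothing genomic (all
      # individuals are genotyped) but re-estimates VCs per fold anyway.
      res <- gblup_predict(features, y, validation = val_idx)
      return(res$gebv[val_idx])
    }
    if (is.null(cache$G)) {
      cache$G <- if (inherits(features, "kinship_matrix")) features
        else if (inherits(features, "genotype_matrix")) vanraden_g(features)
        else compressed_g(features)
    }
    res <- gblup_predict(cache$G, y, validation = val_idx)
    res$gebv[val_idx]
  }
}

#' @rdname gblup_predictor
#' @param cfg a [bayes_config()] / [ml_config()].
#' @export
bayes_predictor <- function(cfg = bayes_config("A")) {
  function(features, y, train_idx, val_idx) {
    X <- feature_values(features)
    fit <- run_bayes(X[train_idx, , drop = FALSE], y[train_idx], cfg)
    gebv_from_posterior(fit, X[val_idx, , drop = FALSE])
  }
}

#' @rdname gblup_predictor
#' @export
ml_predictor <- function(cfg = ml_config("KRR")) {
  function(features, y, train_idx, val_idx) {
    X <- feature_values(features)
    fit_predict(cfg, X[train_idx, , drop = FALSE], y[train_idx],
                X[val_idx, , drop = FALSE])$predictions
  }
}

feature_values <- function(features) {
  if (inherits(features, "compressed_matrix")) return(features$values)
  if (inherits(features, "genotype_matrix")) {
    v <- features$values
    storage.mode(v) <- "double"
    return(v)
  }
  as.matrix(features)
}

#' Write a metrics report
#' @param x a `metrics_report`.
#' @param path_json,path_table output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_metrics <- function(x, path_json = NULL, path_table = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(list(summary = x$summary, pooled = x$pooled,
                              scheme = x$scheme),
                         path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path_table))
    write.table(x$folds, path_table, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(path_json, path_table))
}
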