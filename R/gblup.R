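# REML variance components (single genomic random effect, eigendecomposition
# form) and GBLUP via the equivalent variance-model solve of Henderson's
# mixed-model equations.
#
# Model: y = X b + a + e,  a ~ N(0, G sigma_a^2),  e ~ N(0, I sigma_e^2);
# fixed effects default to the overall mean only.

#' REML variance components for a single genomic random effect
#'
#' Profiles the restricted likelihood over the variance ratio
#' `lambda = sigma_a^2 / sigma_e^2` on the eigenbasis of `G`, which makes
#' each evaluation O(n) after one eigendecomposition.
#'
#' @param y numeric phenotype vector (no missing values; subset to
#'   phenotyped individuals first).
#' @param X fixed-effect design matrix (default: intercept only).
#' @param G a `kinship_matrix` (or plain symmetric matrix) for the same
#'   individuals as `y`.
#' @return a `variance_components` list: `sigma_a2`, `sigma_e2`, `h2`,
#'   `loglik` (restricted), `convergence`.
#' @export
reml_variance_components <- function(y, X = NULL, G) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("need at least 10 phenotyped individuals", call. = FALSE)
  if (anyNA(y)) stop("y must not contain missing values", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  Gm <- if (inherits(G, "kinship_matrix")) G$values else as.matrix(G)
  if (nrow(Gm) != n)
    stop("G dimension does not match phenotype length", call. = FALSE)
  p <- ncol(X)
  eg <- eigen(Gm, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  neg2_restricted <- function(log_lambda) {
    lambda <- exp(log_lambda)
    v <- lambda * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xt, Xt * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    b <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, yt * w)))
    r <- yt - Xt %*% b
    sse <- sum(w * r^2)
    sigma_e2 <- sse / (n - p)
    (n - p) * log(sigma_e2) + sum(log(v)) + 2 * sum(log(diag(ch))) +
      (n - p)
  }

  lo <- -20; hi <- 20
  grid <- seq(lo, hi, length.out = 9)
  gvals <- vapply(grid, neg2_restricted, numeric(1))
  flat <- (max(gvals) - min(gvals)) < 1e-6
  if (flat)
    warning("restricted likelihood is flat in the variance ratio; ",
            "variance components are not separately identifiable ",
            "(is G proportional to the identity?)")
  opt <- optimize(neg2_restricted, c(lo, hi), tol = 1e-8)
  lambda <- exp(opt$minimum)
  # recover sigma_e2 at the optimum
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xt, Xt * w)
  b <- solve(XtWX, crossprod(Xt, yt * w))
  r <- yt - Xt %*% b
  sigma_e2 <- sum(w * r^2) / (n - p)
  sigma_a2 <- lambda * sigma_e2
  boundary <- opt$minimum <= lo + 1e-6
  if (boundary)
    warning("sigma_a^2 estimate pinned at the zero boundary")
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 h2 = sigma_a2 / (sigma_a2 + sigma_e2),
                 loglik = -0.5 * opt$objective,
                 convergence = !flat && !boundary),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components: sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
    x$sigma_a2, x$sigma_e2, x$h2))
  invisible(x)
}

#' Solve the GBLUP mixed-model equations
#'
#' Uses the variance-model form: with `V = sigma_a^2 G_oo + sigma_e^2 I` on
#' the observed individuals, `b = (X'V^-1 X)^-1 X'V^-1 y` and
#' `a = sigma_a^2 G[, obs] V^-1 (y - X b)`, which equals the Henderson MME
#' solution and yields GEBVs for masked (unphenotyped) individuals through
#' their genomic relationships.
#'
#' @param y full-length phenotype vector (values for masked individuals are
#'   ignored and may be `NA`).
#' @param X fixed design for all individuals (default intercept).
#' @param G `kinship_matrix` (or matrix) covering all individuals.
#' @param vc a `variance_components` (or list with `sigma_a2`, `sigma_e2`).
#' @param observed_mask logical vector; `TRUE` where the phenotype is used.
#' @return a `gblup_result`: `b` (fixed effects), `gebv` (all
#'   individuals), `fitted` (observed rows).
#' @export
solve_mme <- function(y, X = NULL, G, vc, observed_mask = NULL) {
  Gm <- if (inherits(G, "kinship_matrix")) G$values else as.matrix(G)
  n_all <- nrow(Gm)
  if (is.null(observed_mask)) observed_mask <- !is.na(y)
  obs <- which(observed_mask)
  if (length(obs) < 2) stop("need at least 2 observed phenotypes",
                            call. = FALSE)
  if (is.null(X)) X <- matrix(1, n_all, 1L)
  X <- as.matrix(X)
  yo <- as.numeric(y[obs])
  Xo <- X[obs, , drop = FALSE]
  V <- vc$sigma_a2 * Gm[obs, obs, drop = FALSE] +
    diag(vc$sigma_e2, length(obs))
  Vi_y_X <- tryCatch(solve(V, cbind(yo, Xo)), error = function(e)
    stop("singular GBLUP system; consider diagonal stabilization of G",
         call. = FALSE))
  Vi_y <- Vi_y_X[, 1L]
  Vi_X <- Vi_y_X[, -1L, drop = FALSE]
  b <- solve(crossprod(Xo, Vi_X), crossprod(Xo, Vi_y))
  resid <- yo - drop(Xo %*% b)
  Vi_resid <- solve(V, resid)
  gebv <- vc$sigma_a2 * drop(Gm[, obs, drop = FALSE] %*% Vi_resid)
  names(gebv) <- rownames(Gm)
  structure(list(b = drop(b), gebv = gebv,
                 fitted = drop(Xo %*% b) + gebv[obs],
                 observed = obs),
            class = "gblup_result")
}

#' GBLUP prediction from raw or compressed genotypes
#'
#' Builds the appropriate relationship matrix (VanRaden for dosage input,
#' standardized cross-product for compressed features), estimates variance
#' components by REML on the training individuals, and solves the
#' mixed-model equations with validation phenotypes masked.
#'
#' @param g_or_x a [genotype_matrix()], `compressed_matrix`,
#'   `kinship_matrix`, or plain feature matrix.
#' @param y phenotype vector for all individuals (`NA` allowed for masked
#'   rows in addition to `validation`).
#' @param validation optional indices to mask (treated as prediction
#'   candidates).
#' @param vc optional precomputed `variance_components` (skips REML).
#' @return list with `gebv`, `vc`, `fit` (`gblup_result`) and `G`.
#' @export
gblup_predict <- function(g_or_x, y, validation = NULL, vc = NULL) {
  G <- if (inherits(g_or_x, "kinship_matrix")) {
    g_or_x
  } else if (inherits(g_or_x, "genotype_matrix")) {
    vanraden_g(g_or_x)
  } else {
    compressed_g(g_or_x)
  }
  observed <- !is.na(y)
  if (!is.null(validation)) observed[validation] <- FALSE
  obs <- which(observed)
  if (is.null(vc))
    vc <- reml_variance_components(y[obs],
                                   G = G$values[obs, obs, drop = FALSE])
  fit <- solve_mme(y, G = G, vc = vc, observed_mask = observed)
  list(gebv = fit$gebv, vc = vc, fit = fit, G = G)
}
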