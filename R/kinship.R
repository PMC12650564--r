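# Genomic relationship matrices from raw dosages (VanRaden) or from
# compressed autoencoder features (standardized cross-product).

#' VanRaden genomic relationship matrix
#'
#' `G = W W' / sum(2 p_j q_j)` where `W` is the dosage matrix centered by
#' twice the alt-allele frequency `p_j` (estimated from the full genotyped
#' set) and `q_j = 1 - p_j`.
#'
#' @param g a [genotype_matrix()] or a complete dosage matrix.
#' @param stabilize add 1e-6 to the diagonal if the smallest eigenvalue is
#'   below -1e-8 (default TRUE).
#' @return a `kinship_matrix` (list with `values`, `flavor`, `source`).
#' @export
vanraden_g <- function(g, stabilize = TRUE) {
  M <- if (inherits(g, "genotype_matrix")) g$values else as.matrix(g)
  if (anyNA(M))
    stop("VanRaden G requires a complete dosage matrix", call. = FALSE)
  storage.mode(M) <- "double"
  p <- colMeans(M) / 2
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic; VanRaden denominator is zero",
         call. = FALSE)
  W <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(W) / denom
  new_kinship(G, flavor = "vanraden", source = ncol(M),
              stabilize = stabilize)
}

#' Relationship matrix from compressed features
#'
#' Columns are standardized to mean 0, variance 1 (sample variance
#' denominator `n - 1` by default) and `G = X X' / n_columns`.
#' Zero-variance columns are dropped with a message.
#'
#' @param x a `compressed_matrix` (from [compress_all()]) or a plain
#'   numeric matrix of features.
#' @param population_variance use the `1/n` variance denominator instead of
#'   `1/(n-1)` (default FALSE).
#' @param stabilize as in [vanraden_g()].
#' @return a `kinship_matrix` with flavor `"compressed"`.
#' @export
compressed_g <- function(x, population_variance = FALSE, stabilize = TRUE) {
  X <- if (inherits(x, "compressed_matrix")) x$values else as.matrix(x)
  if (ncol(X) < 2) stop("need at least 2 feature columns", call. = FALSE)
  mu <- colMeans(X)
  v <- apply(X, 2L, var)
  if (population_variance) v <- v * (nrow(X) - 1) / nrow(X)
  keep <- v > 0
  if (!any(keep))
    stop("all feature columns have zero variance", call. = FALSE)
  if (!all(keep))
    message(sprintf("dropping %d zero-variance feature column(s)",
                    sum(!keep)))
  Xs <- sweep(X[, keep, drop = FALSE], 2L, mu[keep])
  Xs <- sweep(Xs, 2L, sqrt(v[keep]), "/")
  G <- tcrossprod(Xs) / ncol(Xs)
  new_kinship(G, flavor = "compressed", source = ncol(Xs),
              stabilize = stabilize)
}

new_kinship <- function(G, flavor, source, stabilize = TRUE) {
  G <- (G + t(G)) / 2           # enforce exact symmetry
  stabilized <- FALSE
  if (stabilize) {
    ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8) {
      diag(G) <- diag(G) + 1e-6
      stabilized <- TRUE
      message("kinship stabilized: added 1e-6 to the diagonal")
    }
  }
  structure(list(values = G, flavor = flavor, source = source,
                 stabilized = stabilized),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("KinshipMatrix (%s): %d x %d, mean diagonal %.3f\n",
              x$flavor, nrow(x$values), ncol(x$values),
              mean(diag(x$values))))
  invisible(x)
}

#' Correlation between two relationship matrices
#'
#' Pearson correlation of the strictly upper-triangular elements (the
#' diagonal is excluded by default since self-relationships would inflate
#' the agreement).
#'
#' @param g1,g2 `kinship_matrix` objects (or plain symmetric matrices) of
#'   identical dimension and individual order.
#' @param include_diagonal include the diagonal in the correlation
#'   (default FALSE).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
compare_g <- function(g1, g2, include_diagonal = FALSE) {
  a <- if (inherits(g1, "kinship_matrix")) g1$values else as.matrix(g1)
  b <- if (inherits(g2, "kinship_matrix")) g2$values else as.matrix(g2)
  if (!identical(dim(a), dim(b)))
    stop("relationship matrices have different dimensions", call. = FALSE)
  sel <- upper.tri(a, diag = include_diagonal)
  cor(a[sel], b[sel])
}

#' Write / read a kinship matrix as delimited text with an id header
#' @param k a `kinship_matrix`.
#' @param path file path.
#' @return `path` invisibly (`write`) or a `kinship_matrix` (`read`).
#' @export
write_kinship <- function(k, path) {
  write.table(format(as.data.frame(k$values), digits = 17, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  invisible(path)
}

#' @rdname write_kinship
#' @param flavor flavor label for the re-read matrix.
#' @export
read_kinship <- function(path, flavor = "vanraden") {
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                    check.names = FALSE)
  new_kinship(as.matrix(tab), flavor = flavor, source = NA_integer_,
              stabilize = FALSE)
}
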