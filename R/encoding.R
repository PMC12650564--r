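# One-hot encoding of dosages and chunked column partitioning.
#
# Dosage 0 -> [1,0,0], 1 -> [0,1,0], 2 -> [0,0,1]; each marker occupies a
# consecutive column triple [is0, is1, is2] in marker order.

#' One-hot encode a genotype matrix
#'
#' @param g a [genotype_matrix()] or an integer dosage matrix; must be
#'   complete (no missing entries) with values in `{0,1,2}`.
#' @return an `n x 3m` numeric 0/1 matrix; column names are
#'   `<marker>_0/_1/_2`.
#' @export
one_hot_encode <- function(g) {
  v <- if (inherits(g, "genotype_matrix")) g$values else as.matrix(g)
  if (anyNA(v)) {
    idx <- which(is.na(v), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "missing genotype at individual '%s', marker '%s'; complete the matrix (e.g. impute_mean()) before encoding",
      rownames(v)[idx[1L]] %||% idx[1L],
      colnames(v)[idx[2L]] %||% idx[2L]), call. = FALSE)
  }
  if (!all(v %in% 0:2)) stop("dosages must be 0, 1 or 2", call. = FALSE)
  n <- nrow(v); m <- ncol(v)
  enc <- matrix(0, n, 3L * m)
  for (d in 0:2) {
    cols <- seq_len(m) * 3L - (2L - d)
    enc[, cols] <- (v == d) + 0
  }
  snp <- colnames(v) %||% paste0("snp", seq_len(m))
  colnames(enc) <- paste0(rep(snp, each = 3L), "_", rep(0:2, m))
  rownames(enc) <- rownames(v)
  enc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decode one-hot (or reconstructed) triples back to dosages
#'
#' Each consecutive column triple is decoded by argmax, so real-valued
#' autoencoder reconstructions decode directly.  An exact tie within a
#' triple breaks deterministically to the lower dosage, with a warning.
#'
#' @param enc an `n x 3m` numeric matrix.
#' @return an `n x m` integer dosage matrix.
#' @export
decode_one_hot <- function(enc) {
  enc <- as.matrix(enc)
  if (ncol(enc) %% 3L != 0L)
    stop("encoded matrix must have a multiple of 3 columns", call. = FALSE)
  m <- ncol(enc) %/% 3L
  n <- nrow(enc)
  out <- matrix(0L, n, m)
  tied <- FALSE
  for (j in seq_len(m)) {
    triple <- enc[, (3L * j - 2L):(3L * j), drop = FALSE]
    mx <- pmax(triple[, 1L], triple[, 2L], triple[, 3L])
    # which.max semantics: first (= lowest dosage) wins a tie
    tied <- tied || any(rowSums(triple == mx) > 1L)
    out[, j] <- max.col(triple, ties.method = "first") - 1L
  }
  if (tied)
    warning("tie(s) within one-hot triple broken to the lower dosage")
  rownames(out) <- rownames(enc)
  if (!is.null(colnames(enc)))
    colnames(out) <- unique(sub("_[012]$", "", colnames(enc)))
  out
}

#' Divide markers into approximately equal chunks
#'
#' Contiguous column blocks in input order; every chunk holds
#' `floor(m / n_chunks)` markers except the last, which absorbs the
#' remainder.
#'
#' @param g a [genotype_matrix()], an encoded one-hot matrix, or a plain
#'   dosage matrix.
#' @param n_chunks number of chunks (1..m).
#' @return a `chunk_set`: list with `chunks` (each a `one_hot_chunk` with
#'   `chunk_index`, `snp_ids`, `data`), `total_snps`, `n_chunks`.
#' @export
divide_chunks <- function(g, n_chunks) {
  if (inherits(g, "genotype_matrix")) {
    enc <- one_hot_encode(g)
    snp_ids <- g$markers$id
  } else {
    enc <- as.matrix(g)
    if (ncol(enc) %% 3L != 0L)
      stop("encoded matrix must have a multiple of 3 columns", call. = FALSE)
    snp_ids <- unique(sub("_[012]$", "", colnames(enc))) %||%
      paste0("snp", seq_len(ncol(enc) %/% 3L))
    if (length(snp_ids) != ncol(enc) %/% 3L)
      snp_ids <- paste0("snp", seq_len(ncol(enc) %/% 3L))
  }
  m <- ncol(enc) %/% 3L
  n_chunks <- as.integer(n_chunks)
  if (n_chunks < 1L || n_chunks > m)
    stop(sprintf("n_chunks must be in 1..%d (got %d)", m, n_chunks),
         call. = FALSE)
  base <- m %/% n_chunks
  sizes <- rep(base, n_chunks)
  sizes[n_chunks] <- base + m %% n_chunks
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  chunks <- lapply(seq_len(n_chunks), function(k) {
    cols <- (3L * starts[k] - 2L):(3L * stops[k])
    structure(list(chunk_index = k - 1L,
                   snp_ids = snp_ids[starts[k]:stops[k]],
                   data = enc[, cols, drop = FALSE]),
              class = "one_hot_chunk")
  })
  structure(list(chunks = chunks, total_snps = m, n_chunks = n_chunks),
            class = "chunk_set")
}

#' @export
print.chunk_set <- function(x, ...) {
  cat(sprintf("ChunkSet: %d SNPs in %d chunk(s), sizes %s\n",
              x$total_snps, x$n_chunks,
              paste(vapply(x$chunks, function(c) length(c$snp_ids), 1L),
                    collapse = ",")))
  invisible(x)
}

#' Reassemble a chunk set into the full encoded matrix
#'
#' Column-wise concatenation in chunk order; verifies that chunks agree on
#' individual ordering and are in their original order.
#'
#' @param cs a `chunk_set`.
#' @return the `n x 3m` encoded matrix.
#' @export
reassemble <- function(cs) {
  stopifnot(inherits(cs, "chunk_set"))
  rows <- vapply(cs$chunks, function(c) nrow(c$data), 1L)
  if (length(unique(rows)) != 1L)
    stop("chunks disagree on individual count", call. = FALSE)
  idx <- vapply(cs$chunks, function(c) c$chunk_index, 1L)
  if (!identical(idx, sort(idx)))
    stop("chunks are out of order; refusing to reassemble", call. = FALSE)
  rn <- lapply(cs$chunks, function(c) rownames(c$data))
  if (length(unique(rn)) != 1L)
    stop("chunks disagree on individual ordering", call. = FALSE)
  do.call(cbind, lapply(cs$chunks, function(c) c$data))
}

#' Write / read chunk files
#'
#' One delimited text file per chunk (rows = individuals, header = one-hot
#' column labels) plus a JSON manifest recording chunk order, SNP
#' boundaries and md5 checksums.
#'
#' @param cs a `chunk_set`.
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_chunks <- function(cs, dir) {
  stopifnot(inherits(cs, "chunk_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(cs$n_chunks)
  for (k in seq_len(cs$n_chunks)) {
    ch <- cs$chunks[[k]]
    files[k] <- file.path(dir, sprintf("chunk_%05d.tsv", ch$chunk_index))
    write.table(as.data.frame(ch$data), files[k], sep = "\t", quote = FALSE,
                row.names = TRUE, col.names = NA)
  }
  manifest <- list(
    total_snps = cs$total_snps,
    n_chunks = cs$n_chunks,
    chunks = lapply(cs$chunks, function(ch) list(
      chunk_index = ch$chunk_index,
      file = basename(files[ch$chunk_index + 1L]),
      snp_ids = ch$snp_ids,
      md5 = unname(tools::md5sum(files[ch$chunk_index + 1L])))))
  mpath <- file.path(dir, "chunks_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' @rdname write_chunks
#' @param verify check md5 checksums against the manifest (default TRUE).
#' @export
read_chunks <- function(dir, verify = TRUE) {
  mpath <- file.path(dir, "chunks_manifest.json")
  if (!file.exists(mpath))
    stop(sprintf("no chunk manifest at '%s'", mpath), call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  chunks <- lapply(manifest$chunks, function(entry) {
    f <- file.path(dir, entry$file)
    if (verify && !identical(unname(tools::md5sum(f)), entry$md5))
      stop(sprintf("checksum mismatch for chunk file '%s'", entry$file),
           call. = FALSE)
    tab <- read.table(f, header = TRUE, sep = "\t", row.names = 1L,
                      check.names = FALSE)
    structure(list(chunk_index = entry$chunk_index,
                   snp_ids = unlist(entry$snp_ids),
                   data = as.matrix(tab)),
              class = "one_hot_chunk")
  })
  structure(list(chunks = chunks,
                 total_snps = manifest$total_snps,
                 n_chunks = manifest$n_chunks),
            class = "chunk_set")
}
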