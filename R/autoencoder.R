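# Per-chunk symmetric autoencoders and the compressed genotype matrix.
#
# Architecture: input -> encoder widths (ReLU) -> bottleneck (sigmoid)
# -> mirrored decoder (sigmoid throughout) -> input reconstruction.
# Training minimizes elementwise reconstruction MSE with Adam.

#' Autoencoder hyperparameter specification
#'
#' @param neurons encoder layer widths, last entry = bottleneck width per
#'   chunk (default `c(20, 16, 12, 5)`).
#' @param batch_size minibatch size (default 32).
#' @param epochs training epochs (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed governing the 60/20/20 row split and, combined
#'   with the chunk index, weight initialization and shuffling.
#' @return an `ae_spec` object.
#' @export
ae_spec <- function(neurons = c(20, 16, 12, 5), batch_size = 32,
                    epochs = 200, learning_rate = 1e-3, seed = 1) {
  neurons <- as.integer(neurons)
  stopifnot(length(neurons) >= 1, all(neurons >= 1),
            batch_size >= 1, epochs >= 1, learning_rate > 0)
  structure(list(neurons = neurons, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ae_spec")
}

#' @export
print.ae_spec <- function(x, ...) {
  cat(sprintf(
    "Autoencoder spec: neurons %s (bottleneck %d), batch %d, epochs %d, lr %g, seed %d\n",
    paste(x$neurons, collapse = "-"), bottleneck_width(x), x$batch_size,
    x$epochs, x$learning_rate, x$seed))
  invisible(x)
}

bottleneck_width <- function(spec) spec$neurons[length(spec$neurons)]

# deterministic per-chunk seed below 2^31
chunk_seed <- function(seed, chunk_index) {
  as.integer((as.numeric(seed) + 7919 * (as.numeric(chunk_index) + 1)) %%
               2147483647)
}

#' Build an untrained symmetric autoencoder
#'
#' Layer widths mirror the encoder in reverse, ending at the input
#' dimension.  Encoder layers are ReLU except the bottleneck; the
#' bottleneck and all decoder layers are sigmoid, so bottleneck
#' activations (the compressed features) live in (0, 1).
#'
#' @param input_dim input width (3 x SNPs in the chunk).
#' @param spec an [ae_spec()].
#' @return an `ae_model` describing widths and activations (weights are
#'   initialized at training time).
#' @export
build_model <- function(input_dim, spec) {
  stopifnot(inherits(spec, "ae_spec"))
  k <- length(spec$neurons)
  if (bottleneck_width(spec) > input_dim)
    stop(sprintf("bottleneck width %d exceeds input dimension %d",
                 bottleneck_width(spec), input_dim), call. = FALSE)
  widths <- c(input_dim, spec$neurons,
              rev(spec$neurons)[-1L], input_dim)
  # acts per weight layer: 0 = ReLU, 1 = sigmoid
  acts <- c(if (k > 1) rep(0L, k - 1L), 1L,        # encoder; bottleneck sigmoid
            rep(1L, k))                            # decoder all sigmoid
  structure(list(widths = as.integer(widths), acts = as.integer(acts),
                 n_encoder_layers = k, spec = spec),
            class = "ae_model")
}

# seeded 60/20/20 row split shared by all chunks
ae_split <- function(n, seed) {
  if (n < 5) stop("need at least 5 individuals for a 60/20/20 split",
                  call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- max(1L, floor(0.6 * n))
  n_test <- max(1L, floor(0.2 * n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[n_train + seq_len(n_test)]),
       validation = sort(perm[(n_train + n_test + 1L):n]))
}

#' Train the autoencoder for one chunk
#'
#' Rows are split 60/20/20 into training/testing/validation partitions by a
#' seeded shuffle (the same split for every chunk of a run); weights are
#' initialized from a per-(seed, chunk) RNG stream so results do not depend
#' on chunk training order.
#'
#' @param chunk a `one_hot_chunk` (from [divide_chunks()]).
#' @param spec an [ae_spec()].
#' @param split optional list with `train`/`test`/`validation` row indices;
#'   computed from `spec$seed` when `NULL`.
#' @return a `trained_chunk_model` with fitted weights and per-partition
#'   reconstruction MSE.
#' @export
train_chunk <- function(chunk, spec, split = NULL) {
  stopifnot(inherits(chunk, "one_hot_chunk"), inherits(spec, "ae_spec"))
  X <- chunk$data
  n <- nrow(X)
  if (is.null(split)) split <- ae_split(n, spec$seed)
  model <- build_model(ncol(X), spec)
  set.seed(chunk_seed(spec$seed, chunk$chunk_index))
  fit <- ae_train_cpp(X, model$widths, model$acts,
                      as.integer(split$train - 1L),
                      spec$epochs, spec$batch_size, spec$learning_rate)
  out <- structure(list(chunk_index = chunk$chunk_index,
                        weights = fit$weights, biases = fit$biases,
                        widths = model$widths, acts = model$acts,
                        n_encoder_layers = model$n_encoder_layers,
                        spec = spec, input_dim = ncol(X),
                        snp_ids = chunk$snp_ids),
                   class = "trained_chunk_model")
  out$mse <- list(
    train = reconstruction_mse(X[split$train, , drop = FALSE],
                               reconstruct_chunk(out, X[split$train, , drop = FALSE])),
    test = reconstruction_mse(X[split$test, , drop = FALSE],
                              reconstruct_chunk(out, X[split$test, , drop = FALSE])),
    validation = reconstruction_mse(X[split$validation, , drop = FALSE],
                                    reconstruct_chunk(out, X[split$validation, , drop = FALSE])))
  out
}

#' Bottleneck activations for a chunk
#'
#' @param model a `trained_chunk_model`.
#' @param chunk a `one_hot_chunk` (or a plain matrix with matching width).
#' @return `n x bottleneck` matrix of sigmoid activations in (0, 1).
#' @export
compress_chunk <- function(model, chunk) {
  X <- if (inherits(chunk, "one_hot_chunk")) chunk$data else as.matrix(chunk)
  if (ncol(X) != model$input_dim)
    stop(sprintf("chunk width %d does not match model input %d",
                 ncol(X), model$input_dim), call. = FALSE)
  out <- ae_forward_cpp(X, model$weights, model$biases, model$acts,
                        model$n_encoder_layers)
  rownames(out) <- rownames(X)
  out
}

# full encoder+decoder forward pass
reconstruct_chunk <- function(model, X) {
  ae_forward_cpp(as.matrix(X), model$weights, model$biases, model$acts, -1L)
}

#' Compress all chunks into the compressed genotype representation
#'
#' Trains one autoencoder per chunk (independently seeded) and
#' concatenates bottleneck blocks in chunk order, giving an
#' `n x d` matrix with `d = bottleneck x n_chunks`.
#'
#' @param cs a `chunk_set`.
#' @param spec an [ae_spec()].
#' @param keep_models return the trained models too (default FALSE).
#' @return a `compressed_matrix`: list with `values`, `d`, `spec`,
#'   per-chunk `mse`.
#' @export
compress_all <- function(cs, spec, keep_models = FALSE) {
  stopifnot(inherits(cs, "chunk_set"))
  n <- nrow(cs$chunks[[1L]]$data)
  split <- ae_split(n, spec$seed)
  blocks <- vector("list", cs$n_chunks)
  mses <- vector("list", cs$n_chunks)
  models <- if (keep_models) vector("list", cs$n_chunks) else NULL
  for (k in seq_len(cs$n_chunks)) {
    model <- tryCatch(train_chunk(cs$chunks[[k]], spec, split = split),
                      error = function(e) stop(sprintf(
                        "chunk %d failed: %s", k - 1L, conditionMessage(e)),
                        call. = FALSE))
    blocks[[k]] <- compress_chunk(model, cs$chunks[[k]])
    mses[[k]] <- model$mse
    if (keep_models) models[[k]] <- model
  }
  values <- do.call(cbind, blocks)
  colnames(values) <- paste0("f", seq_len(ncol(values)))
  structure(list(values = values, d = ncol(values),
                 bottleneck = bottleneck_width(spec),
                 n_chunks = cs$n_chunks, spec = spec, mse = mses,
                 models = models),
            class = "compressed_matrix")
}

#' @export
print.compressed_matrix <- function(x, ...) {
  cat(sprintf(
    "CompressedMatrix: %d individuals x %d features (bottleneck %d x %d chunks)\n",
    nrow(x$values), x$d, x$bottleneck, x$n_chunks))
  invisible(x)
}

#' Mean squared reconstruction error
#'
#' Mean of squared elementwise differences over all matrix entries.
#'
#' @param x,x_prime matrices of identical shape.
#' @return non-negative scalar.
#' @export
reconstruction_mse <- function(x, x_prime) {
  x <- as.matrix(x); x_prime <- as.matrix(x_prime)
  if (!identical(dim(x), dim(x_prime)))
    stop("shapes differ", call. = FALSE)
  mean((x - x_prime)^2)
}

#' Compression ratio
#'
#' `(1 - d/p) * 100`, rounded to two decimals.
#'
#' @param p original dimension.
#' @param d compressed dimension (`0 < d <= p`).
#' @return percentage reduction.
#' @export
compression_ratio <- function(p, d) {
  stopifnot(p > 0, d > 0)
  if (d > p) stop("compressed dimension exceeds original", call. = FALSE)
  round((1 - d / p) * 100, 2)
}

#' Seeded random hyperparameter search
#'
#' Samples `n_trials` specifications from the given search space, trains
#' each on a subsample of chunks, and returns the spec minimizing mean
#' validation-partition reconstruction MSE.
#'
#' @param cs a `chunk_set`.
#' @param search_space list with candidate values: `neurons` (list of
#'   integer vectors), `batch_size`, `epochs`, `learning_rate` (vectors).
#' @param n_trials number of sampled candidates.
#' @param seed RNG seed for sampling (training seeds derive from it).
#' @param n_eval_chunks how many chunks to evaluate per trial (default 1).
#' @return list with `best` (`ae_spec`) and a `trials` data.frame log.
#' @export
random_search <- function(cs, search_space, n_trials, seed = 1,
                          n_eval_chunks = 1) {
  stopifnot(n_trials >= 1)
  defaults <- list(neurons = list(c(20, 16, 12, 5)), batch_size = 32,
                   epochs = 200, learning_rate = 1e-3)
  for (nm in names(defaults))
    if (is.null(search_space[[nm]])) search_space[[nm]] <- defaults[[nm]]
  if (any(lengths(search_space) == 0))
    stop("empty search space", call. = FALSE)
  set.seed(seed)
  eval_chunks <- sample(seq_len(cs$n_chunks),
                        min(n_eval_chunks, cs$n_chunks))
  picks <- lapply(seq_len(n_trials), function(i) list(
    neurons = search_space$neurons[[sample.int(length(search_space$neurons), 1)]],
    batch_size = sample(search_space$batch_size, 1),
    epochs = sample(search_space$epochs, 1),
    learning_rate = sample(search_space$learning_rate, 1)))
  scores <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    sp <- ae_spec(picks[[i]]$neurons, picks[[i]]$batch_size,
                  picks[[i]]$epochs, picks[[i]]$learning_rate,
                  seed = chunk_seed(seed, i))
    mses <- vapply(eval_chunks, function(k)
      train_chunk(cs$chunks[[k]], sp)$mse$validation, numeric(1))
    scores[i] <- mean(mses)
  }
  best_i <- which.min(scores)
  best <- ae_spec(picks[[best_i]]$neurons, picks[[best_i]]$batch_size,
                  picks[[best_i]]$epochs, picks[[best_i]]$learning_rate,
                  seed = seed)
  trials <- data.frame(
    trial = seq_len(n_trials),
    neurons = vapply(picks, function(p) paste(p$neurons, collapse = "-"), ""),
    batch_size = vapply(picks, function(p) p$batch_size, numeric(1)),
    epochs = vapply(picks, function(p) p$epochs, numeric(1)),
    learning_rate = vapply(picks, function(p) p$learning_rate, numeric(1)),
    validation_mse = scores)
  list(best = best, trials = trials)
}

#' Write / read a compressed matrix as delimited text
#' @param x a `compressed_matrix` (or plain matrix).
#' @param path output path.
#' @return `path` invisibly (`write`), or a numeric matrix (`read`).
#' @export
write_compressed <- function(x, path) {
  v <- if (inherits(x, "compressed_matrix")) x$values else as.matrix(x)
  write.table(format(as.data.frame(v), digits = 17, trim = TRUE,
                     scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  invisible(path)
}

#' @rdname write_compressed
#' @export
read_compressed <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                    check.names = FALSE)
  as.matrix(tab)
}
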