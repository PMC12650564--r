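# Bayesian whole-genome regression front end over the compiled Gibbs
# samplers.  Features are column-centered (not variance-standardized by
# default); the intercept has a flat prior; all other hyperpriors follow
# the conventional heuristics documented in bayes_config().

#' Bayesian sampler configuration
#'
#' Defaults follow common whole-genome-regression practice: 18,000 Gibbs
#' cycles with the first 3,000 discarded as burn-in, and a null proportion
#' `pi = 0.99` for BayesB.  The effect-variance prior is scaled-inverse
#' chi-square with `nu = 4.2` and scale chosen so the prior mean effect
#' variance equals `var(y) * R2 / (MSx * d * (1 - pi))` with `R2 = 0.5`
#' and `MSx` the mean column sum of squares.
#'
#' @param method one of `"A"`, `"B"`, `"Cpi"`, `"Lasso"`.
#' @param n_iterations total Gibbs cycles (default 18000).
#' @param burn_in cycles discarded (default 3000).
#' @param thinning keep every `thinning`-th post-burn-in draw (default 1).
#' @param pi null-marker proportion: fixed for BayesB (default 0.99),
#'   initial value for BayesCpi (default 0.5).
#' @param nu effect-variance prior degrees of freedom (default 4.2).
#' @param r2 heuristic proportion of variance attributed to markers when
#'   setting prior scales (default 0.5).
#' @param nu_e residual-variance prior df (default 4.2).
#' @param beta_a,beta_b Beta prior for `pi` in BayesCpi (default 1, 1).
#' @param lasso_r,lasso_delta Gamma(shape, rate) prior for `lambda^2` in
#'   the Bayesian Lasso (default 1, 0.1).
#' @param lambda2 fixed value for `lambda^2` (Lasso); `NULL` = sampled.
#' @param scale,scale_e explicit scaled-inverse-chi-square prior scales for
#'   the effect and residual variances; `NULL` (default) derives them from
#'   the `r2` heuristic.  Combined with large `nu`/`nu_e` these pin the
#'   variances, which is how the conjugate-oracle tests fix known values.
#' @param standardize variance-standardize feature columns (default FALSE;
#'   compressed features already live in a common scale).
#' @param seed RNG seed.
#' @return a `bayes_config`.
#' @export
bayes_config <- function(method = c("A", "B", "Cpi", "Lasso"),
                         n_iterations = 18000, burn_in = 3000,
                         thinning = 1, pi = NULL, nu = 4.2, r2 = 0.5,
                         nu_e = 4.2, beta_a = 1, beta_b = 1,
                         lasso_r = 1, lasso_delta = 0.1, lambda2 = NULL,
                         scale = NULL, scale_e = NULL,
                         standardize = FALSE, seed = 1) {
  method <- match.arg(method)
  if (is.null(pi)) pi <- switch(method, B = 0.99, Cpi = 0.5, 0)
  stopifnot(burn_in < n_iterations, thinning >= 1, pi >= 0, pi <= 1)
  structure(list(method = method, n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), pi = pi, nu = nu,
                 r2 = r2, nu_e = nu_e, beta_a = beta_a, beta_b = beta_b,
                 lasso_r = lasso_r, lasso_delta = lasso_delta,
                 lambda2 = lambda2, scale = scale, scale_e = scale_e,
                 standardize = standardize,
                 seed = as.integer(seed)),
            class = "bayes_config")
}

run_bayes <- function(features, y, cfg) {
  stopifnot(inherits(cfg, "bayes_config"))
  W <- as.matrix(features)
  y <- as.numeric(y)
  if (anyNA(y)) stop("training phenotypes must not be missing",
                     call. = FALSE)
  if (nrow(W) != length(y))
    stop("feature rows and phenotype length differ", call. = FALSE)
  centers <- colMeans(W)
  W <- sweep(W, 2L, centers)
  scales <- rep(1, ncol(W))
  if (cfg$standardize) {
    s <- apply(W, 2L, sd)
    scales[s > 0] <- s[s > 0]
    W <- sweep(W, 2L, scales, "/")
  }
  d <- ncol(W)
  vy <- var(y)
  if (vy <= 0) warning("phenotype has zero variance; ",
                       "effects will concentrate at zero")
  msx <- mean(colSums(W^2)) / nrow(W)
  if (!is.finite(msx) || msx <= 0) msx <- 1
  pi_eff <- if (cfg$method %in% c("B", "Cpi")) cfg$pi else 0
  target_var <- max(vy, 1e-8) * cfg$r2 /
    (msx * d * max(1 - pi_eff, 1 / d))
  S <- cfg$scale %||% (target_var * max(cfg$nu - 2, 0.1) / cfg$nu)
  S_e <- cfg$scale_e %||%
    (max(vy, 1e-8) * (1 - cfg$r2) * max(cfg$nu_e - 2, 0.1) / cfg$nu_e)
  method_code <- match(cfg$method, c("A", "B", "Cpi", "Lasso")) - 1L
  fix_lambda <- !is.null(cfg$lambda2)
  lambda2_init <- if (fix_lambda) cfg$lambda2 else
    max(2 * d / max(sum(apply(W, 2, var)) * cfg$r2 / max(vy, 1e-8), 1e-6), 1)
  set.seed(cfg$seed)
  res <- bayes_gibbs_cpp(W, y, method_code, cfg$n_iterations, cfg$burn_in,
                         cfg$thinning, cfg$pi, cfg$nu, S, cfg$nu_e, S_e,
                         cfg$beta_a, cfg$beta_b, cfg$lasso_r,
                         cfg$lasso_delta, lambda2_init, fix_lambda)
  trace <- res$trace
  colnames(trace) <- c("sigma_e2", "var_g", "pi", "lambda2", "k_included")
  structure(list(method = cfg$method,
                 effects = drop(res$beta_mean),
                 intercept = res$mu_mean,
                 inclusion_prob = drop(res$incl_prob),
                 sigma_e2 = res$sigma_e2_mean,
                 sigma_b2 = res$sigma_b2_mean,
                 pi = res$pi_mean,
                 lambda2 = res$lambda2_mean,
                 centers = centers, scales = scales,
                 standardize = cfg$standardize,
                 n_saved = res$n_saved,
                 trace = trace,
                 config = cfg),
            class = "posterior_summary")
}

#' BayesA / BayesB / BayesCpi / Bayesian Lasso Gibbs samplers
#'
#' From-scratch single-site Gibbs samplers.  `bayes_a()` gives every
#' marker its own scaled-inverse-chi-square effect variance; `bayes_b()`
#' adds a spike at zero with fixed null proportion `pi` (indicator drawn
#' from the marginalized conditional with the effect integrated out);
#' `bayes_cpi()` uses a common slab variance and samples `pi` from a Beta
#' posterior; `bayes_lasso()` places the Park-Casella double-exponential
#' hierarchy on effects.
#'
#' @param features numeric matrix (individuals x features), training rows.
#' @param y numeric training phenotypes.
#' @param cfg a [bayes_config()]; its `method` field is overridden to match
#'   the called sampler.
#' @return a `posterior_summary`: posterior-mean effects, intercept,
#'   inclusion probabilities, hyperparameter means, monitored-scalar trace.
#' @export
bayes_a <- function(features, y, cfg = bayes_config("A")) {
  cfg$method <- "A"; cfg$pi <- 0
  run_bayes(features, y, cfg)
}

#' @rdname bayes_a
#' @export
bayes_b <- function(features, y, cfg = bayes_config("B")) {
  if (cfg$method != "B") { cfg$method <- "B"; if (cfg$pi == 0) cfg$pi <- 0.99 }
  run_bayes(features, y, cfg)
}

#' @rdname bayes_a
#' @export
bayes_cpi <- function(features, y, cfg = bayes_config("Cpi")) {
  if (cfg$method != "Cpi") { cfg$method <- "Cpi"; cfg$pi <- 0.5 }
  run_bayes(features, y, cfg)
}

#' @rdname bayes_a
#' @export
bayes_lasso <- function(features, y, cfg = bayes_config("Lasso")) {
  cfg$method <- "Lasso"
  run_bayes(features, y, cfg)
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "Bayes%s posterior: %d effects, intercept %.4g, sigma_e2 %.4g, %d saved draws\n",
    x$method, length(x$effects), x$intercept, x$sigma_e2, x$n_saved))
  invisible(x)
}

#' GEBVs from a posterior summary
#'
#' Linear predictor `intercept + features %*% posterior-mean effects`,
#' applying the training centering (and scaling, if used) constants.
#'
#' @param summary a `posterior_summary`.
#' @param features_all feature matrix for the individuals to predict
#'   (columns aligned with the training features).
#' @return named numeric GEBV vector.
#' @export
gebv_from_posterior <- function(summary, features_all) {
  X <- as.matrix(features_all)
  if (ncol(X) != length(summary$effects))
    stop("feature columns do not match the fitted effects", call. = FALSE)
  Xc <- sweep(X, 2L, summary$centers)
  if (summary$standardize) Xc <- sweep(Xc, 2L, summary$scales, "/")
  out <- drop(summary$intercept + Xc %*% summary$effects)
  names(out) <- rownames(X)
  out
}

#' Effective sample sizes of monitored scalars
#'
#' @param summary a `posterior_summary`.
#' @return named numeric vector of ESS values (requires the coda package).
#' @export
posterior_ess <- function(summary) {
  if (!requireNamespace("coda", quietly = TRUE))
    stop("posterior_ess() requires the coda package", call. = FALSE)
  apply(summary$trace, 2L, function(v) {
    if (sd(v) == 0) return(NA_real_)
    unname(coda::effectiveSize(coda::mcmc(v)))
  })
}
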