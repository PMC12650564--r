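# Synthetic diploid genotypes and additive phenotypes.
#
# Genotypes come from a first-order haplotype copying chain: the allele at
# marker j is copied from marker j-1 on the same haplotype with probability
# ld_rho, else drawn fresh at the marker's allele frequency.  LD therefore
# decays geometrically with distance, which is enough to exercise
# compression and kinship behavior without a coalescent simulator.

#' Simulation configuration
#'
#' @param n_individuals number of individuals.
#' @param m_snps number of biallelic markers.
#' @param n_qtl number of causal markers (default `max(10, m/100)`).
#' @param h2 target narrow-sense heritability in `[0, 1]` (default 0.5);
#'   the residual is scaled so the realized sample heritability matches
#'   exactly.
#' @param ld_rho adjacent-marker haplotype copying probability in
#'   `[0, 1)` (default 0.5).
#' @param maf_range allele-frequency sampling range (default
#'   `c(0.05, 0.5)`).
#' @param n_families number of full-sib families; 0 = unrelated (default).
#' @param qtl_effect_dist `"normal"` (default) or `"gamma"` (heavy-tailed,
#'   random sign) marker effect distribution.
#' @param seed RNG seed.
#' @return a `sim_config`.
#' @export
sim_config <- function(n_individuals, m_snps,
                       n_qtl = min(m_snps, max(10L, m_snps %/% 100L)),
                       h2 = 0.5,
                       ld_rho = 0.5, maf_range = c(0.05, 0.5),
                       n_families = 0,
                       qtl_effect_dist = c("normal", "gamma"), seed = 1) {
  qtl_effect_dist <- match.arg(qtl_effect_dist)
  stopifnot(n_individuals >= 2, m_snps >= 1, n_qtl <= m_snps,
            h2 >= 0, h2 <= 1, ld_rho >= 0, ld_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], n_families >= 0)
  structure(list(n_individuals = as.integer(n_individuals),
                 m_snps = as.integer(m_snps), n_qtl = as.integer(n_qtl),
                 h2 = h2, ld_rho = ld_rho, maf_range = maf_range,
                 n_families = as.integer(n_families),
                 qtl_effect_dist = qtl_effect_dist,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# haplotype copying chain: k haplotypes x m markers of 0/1 alleles
sim_haplotypes <- function(k, freqs, ld_rho) {
  m <- length(freqs)
  H <- matrix(0L, k, m)
  H[, 1L] <- rbinom(k, 1L, freqs[1L])
  if (m > 1L) for (j in 2:m) {
    copy <- runif(k) < ld_rho
    fresh <- rbinom(k, 1L, freqs[j])
    H[, j] <- ifelse(copy, H[, j - 1L], fresh)
  }
  H
}

#' Simulate unrelated genotypes
#'
#' @param cfg a [sim_config()] (with `n_families = 0`); configurations with
#'   families dispatch to [simulate_families()].
#' @return a [genotype_matrix()] with attribute `"freqs"` (the generating
#'   allele frequencies).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_families > 0) return(simulate_families(cfg))
  set.seed(cfg$seed)
  freqs <- runif(cfg$m_snps, cfg$maf_range[1], cfg$maf_range[2])
  H1 <- sim_haplotypes(cfg$n_individuals, freqs, cfg$ld_rho)
  H2 <- sim_haplotypes(cfg$n_individuals, freqs, cfg$ld_rho)
  g <- genotype_matrix(H1 + H2)
  attr(g, "freqs") <- freqs
  g
}

#' Simulate full-sib family genotypes
#'
#' Two parents per family are drawn from the copying-chain population;
#' offspring haplotypes are produced by Mendelian gamete sampling with a
#' per-adjacent-marker recombination probability `(1 - ld_rho) / 2`, so
#' tighter LD in the founders also means fewer crossovers.  Family sizes
#' are `n / n_families`, remainder to the last family.
#'
#' @param cfg a [sim_config()] with `n_families >= 1`.
#' @return a [genotype_matrix()] with attribute `"family"` (family index
#'   per individual).
#' @export
simulate_families <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_families >= 1)
  set.seed(cfg$seed)
  freqs <- runif(cfg$m_snps, cfg$maf_range[1], cfg$maf_range[2])
  m <- cfg$m_snps
  nf <- cfg$n_families
  recomb <- (1 - cfg$ld_rho) / 2
  base <- cfg$n_individuals %/% nf
  sizes <- rep(base, nf)
  sizes[nf] <- sizes[nf] + cfg$n_individuals %% nf
  gamete <- function(h1, h2) {
    # switch between parental haplotypes with prob recomb per interval
    state <- numeric(m)
    state[1L] <- rbinom(1L, 1L, 0.5)
    if (m > 1L) {
      switches <- runif(m - 1L) < recomb
      state[-1L] <- cumsum(c(state[1L], switches))[-1L] %% 2
    }
    ifelse(state == 0, h1, h2)
  }
  rows <- vector("list", cfg$n_individuals)
  fam <- integer(cfg$n_individuals)
  idx <- 0L
  for (f in seq_len(nf)) {
    sire <- list(sim_haplotypes(1L, freqs, cfg$ld_rho)[1L, ],
                 sim_haplotypes(1L, freqs, cfg$ld_rho)[1L, ])
    dam <- list(sim_haplotypes(1L, freqs, cfg$ld_rho)[1L, ],
                sim_haplotypes(1L, freqs, cfg$ld_rho)[1L, ])
    for (o in seq_len(sizes[f])) {
      idx <- idx + 1L
      rows[[idx]] <- gamete(sire[[1L]], sire[[2L]]) +
        gamete(dam[[1L]], dam[[2L]])
      fam[idx] <- f
    }
  }
  g <- genotype_matrix(do.call(rbind, rows))
  attr(g, "freqs") <- freqs
  attr(g, "family") <- fam
  g
}

#' Simulate additive phenotypes on a genotype matrix
#'
#' QTL positions are sampled without replacement; effects are standard
#' normal (or gamma with random sign); the true breeding value (TBV) is
#' the centered QTL dosage score, and the residual standard deviation is
#' set so the realized sample heritability equals `cfg$h2` exactly.
#'
#' @param g a [genotype_matrix()], typically from [simulate_genotypes()].
#' @param cfg the [sim_config()].
#' @return a `sim_result`: `genotype`, `phenotypes` (data.frame id/trait),
#'   `tbv`, `qtl_idx`, `qtl_effects`, `h2_realized`.
#' @export
simulate_phenotypes <- function(g, cfg) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "sim_config"))
  if (cfg$n_qtl < 1 && cfg$h2 > 0)
    stop("h2 > 0 requires at least one QTL", call. = FALSE)
  set.seed(cfg$seed + 104729L)
  n <- n_individuals(g)
  qtl_idx <- sort(sample.int(n_markers(g), cfg$n_qtl))
  effects <- switch(cfg$qtl_effect_dist,
    normal = rnorm(cfg$n_qtl),
    gamma = rgamma(cfg$n_qtl, shape = 0.4, rate = 1.66) *
      sample(c(-1, 1), cfg$n_qtl, replace = TRUE))
  Q <- g$values[, qtl_idx, drop = FALSE]
  storage.mode(Q) <- "double"
  Q <- sweep(Q, 2L, colMeans(Q))
  tbv <- drop(Q %*% effects)
  var_tbv <- var(tbv)
  if (cfg$h2 == 1 && var_tbv == 0)
    stop("h2 = 1 with zero TBV variance; increase n_qtl or MAF",
         call. = FALSE)
  e <- rnorm(n)
  e <- e - mean(e)
  # orthogonalize the residual against the TBV so the realized sample
  # heritability is exact, not just exact in expectation
  if (var_tbv > 0) e <- e - tbv * cov(e, tbv) / var_tbv
  if (cfg$h2 == 0) {
    pheno <- e / sd(e)
  } else if (cfg$h2 == 1) {
    pheno <- tbv
  } else {
    target_ve <- var_tbv * (1 - cfg$h2) / cfg$h2
    e <- e * sqrt(target_ve / var(e))
    pheno <- tbv + e
  }
  h2_realized <- if (cfg$h2 == 0) 0 else
    if (var(pheno) > 0) var_tbv / var(pheno) else NA_real_
  structure(list(genotype = g,
                 phenotypes = data.frame(id = g$individual_ids,
                                         trait = pheno,
                                         stringsAsFactors = FALSE),
                 tbv = tbv, qtl_idx = qtl_idx, qtl_effects = effects,
                 h2_realized = h2_realized, config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "SimResult: %d individuals, %d SNPs, %d QTL, realized h2 = %.3f\n",
    n_individuals(x$genotype), n_markers(x$genotype),
    length(x$qtl_idx), x$h2_realized))
  invisible(x)
}
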