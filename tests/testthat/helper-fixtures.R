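# Shared fixtures, all generated in code under fixed seeds.

# small complete genotype matrix
toy_genotypes <- function(n = 20, m = 30, seed = 42, ld_rho = 0.3,
                          n_families = 0) {
  simulate_genotypes(sim_config(n, m, ld_rho = ld_rho,
                                n_families = n_families, seed = seed))
}

# simulated panel with phenotypes
toy_panel <- function(n = 100, m = 200, n_qtl = 20, h2 = 0.5, seed = 42,
                      ld_rho = 0.3) {
  sc <- sim_config(n, m, n_qtl = n_qtl, h2 = h2, ld_rho = ld_rho,
                   seed = seed)
  simulate_phenotypes(simulate_genotypes(sc), sc)
}

# handcrafted matrix with known dosages
hand_genotypes <- function() {
  genotype_matrix(matrix(c(0L, 2L,
                           1L, 1L,
                           2L, 0L), nrow = 3, byrow = TRUE,
                         dimnames = list(c("a", "b", "c"),
                                         c("m1", "m2"))))
}

# write a genotype matrix to a temp file, return the path
write_temp_matrix <- function(g, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  write_matrix(g, path, sep = sep)
  path
}
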