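test_that("genotype_matrix validates dosage range, ids and metadata", {
  expect_error(genotype_matrix(matrix(c(0L, 3L), 1)), "out of range")
  expect_error(genotype_matrix(matrix(0L, 2, 2),
                               individual_ids = c("a", "a")), "unique")
  g <- hand_genotypes()
  expect_identical(dim(g), c(3L, 2L))
  expect_identical(g$markers$id, c("m1", "m2"))
  # NA is the missing sentinel and is accepted
  expect_silent(genotype_matrix(matrix(c(0L, NA, 2L, 1L), 2)))
})

test_that("read_vcf maps GT to alt dosage, skips multi-allelics", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- system.file("extdata", "toy.vcf", package = "gsae")
  expect_warning(g <- read_vcf(vcf), "multi-allelic")
  # rs3 (A -> G,T) dropped; 3 samples x 2 sites remain
  expect_identical(dim(g), c(3L, 2L))
  expect_identical(unname(g$values[, "rs1"]), c(0L, 1L, 2L))
  # "./." -> NA; phased "1|1" -> 2
  expect_identical(unname(g$values[, "rs2"]), c(NA, 2L, 1L))
  expect_identical(g$markers$ref, c("A", "C"))
  expect_error(read_vcf(tempfile()), "does not exist")
})

test_that("read_matrix round-trips, honors orientation, flags bad tokens", {
  g <- toy_genotypes(n = 8, m = 5)
  path <- write_temp_matrix(g)
  g2 <- read_matrix(path)
  expect_identical(g2$values, g$values)

  # transposed file with the snps-in-rows flag reads identically
  tp <- tempfile(fileext = ".tsv")
  write.table(as.data.frame(t(g$values)), tp, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  g3 <- read_matrix(tp, orientation = "snps-in-rows")
  expect_identical(g3$values, g$values)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("\tm1\tm2", "a\t0\t3", "b\t1\t2"), bad)
  expect_error(read_matrix(bad), "'3'.*row 'a'.*column 'm2'")
})

test_that("compute_call_rate counts non-missing fractions", {
  v <- matrix(1L, 10, 3)
  v[1, 2] <- NA
  v[, 3] <- NA
  g <- genotype_matrix(v)
  expect_equal(unname(compute_call_rate(g)), c(1, 0.9, 0))
})

test_that("compute_maf folds the alt frequency at 0.5", {
  g <- genotype_matrix(cbind(het = rep(1L, 4), ref = rep(0L, 4),
                             mix = c(0L, 0L, 1L, 1L)))
  expect_equal(unname(compute_maf(g)), c(0.5, 0, 0.25))
})

test_that("hwe_test matches a brute-force expected-count oracle", {
  # oracle: chi-square from explicitly computed HWE expected counts
  hwe_oracle <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    p <- (2 * n2 + n1) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    sum((c(n0, n1, n2) - e)^2 / e)
  }
  expect_equal(hwe_test(25, 50, 25)$chisq, 0)
  expect_equal(hwe_test(25, 50, 25)$p, 1)
  # all-homozygote extreme at p = 0.5: statistic equals n
  expect_equal(hwe_test(50, 0, 50)$chisq, 100)
  expect_equal(hwe_test(50, 0, 50)$chisq, hwe_oracle(50, 0, 50))
  expect_equal(hwe_test(100, 0, 0)$p, 1)   # monomorphic
  set.seed(7)
  for (i in 1:20) {
    cnt <- as.vector(rmultinom(1, 200, c(0.3, 0.5, 0.2)))
    res <- hwe_test(cnt[1], cnt[2], cnt[3])
    expect_equal(res$chisq, hwe_oracle(cnt[1], cnt[2], cnt[3]))
    expect_equal(res$p, pchisq(res$chisq, 1, lower.tail = FALSE))
    # ref/alt relabeling leaves the statistic unchanged
    expect_equal(res$chisq, hwe_test(cnt[3], cnt[2], cnt[1])$chisq)
  }
})

test_that("apply_qc removes by threshold with first-filter attribution", {
  set.seed(11)
  n <- 100
  ok <- matrix(rbinom(n * 3, 2, 0.4), n)        # clean markers
  low_cr <- c(rep(NA_integer_, 11), rbinom(n - 11, 2, 0.4))  # call rate 0.89
  low_maf <- c(rep(1L, 2), rep(0L, n - 2))      # maf 0.01
  hwe_bad <- rep(c(0L, 2L), n / 2)              # no hets at p=0.5
  # marker failing both call-rate and MAF attributes to call rate
  both <- c(rep(NA_integer_, 11), rep(0L, n - 11))
  g <- genotype_matrix(cbind(ok, low_cr, low_maf, hwe_bad, both))
  res <- apply_qc(g)
  expect_identical(res$report$removed_call_rate, 2L)
  expect_identical(res$report$removed_maf, 1L)
  expect_identical(res$report$removed_hwe, 1L)
  expect_identical(res$report$retained, 3L)
  expect_identical(res$report$retained + res$report$removed_call_rate +
                     res$report$removed_maf + res$report$removed_hwe,
                   res$report$input_markers)
  # boundary is strict: call rate exactly 0.90 and MAF exactly 0.05 stay
  cr90 <- c(rep(NA_integer_, 10), rbinom(n - 10, 2, 0.4))
  maf05 <- c(rep(1L, 10), rep(0L, 90))          # p = 0.05 exactly
  g2 <- genotype_matrix(cbind(cr90, maf05))
  res2 <- apply_qc(g2)
  expect_identical(res2$report$retained, 2L)
  # idempotence and column-order preservation
  res3 <- apply_qc(res$genotype)
  expect_identical(res3$report$retained, res$report$retained)
  expect_identical(res3$genotype$markers$id, res$genotype$markers$id)
  expect_error(apply_qc(genotype_matrix(matrix(0L, 10, 2))),
               "every marker")
})

test_that("qc report serializes to JSON with consistent counts", {
  res <- apply_qc(toy_genotypes(50, 20))
  js <- jsonlite::fromJSON(qc_report_json(res$report))
  expect_equal(js$input_markers,
               js$retained + js$removed_call_rate + js$removed_maf +
                 js$removed_hwe)
})

test_that("impute_mean completes a matrix with rounded column means", {
  v <- matrix(c(0L, 0L, NA, 2L, 2L, 2L), 3)
  g <- impute_mean(genotype_matrix(v))
  expect_false(anyNA(g$values))
  expect_identical(g$values[3, 1], 0L)
})
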