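test_that("signed fold follows the mutant-positive sign convention", {
  f <- signed_fold(c(100, 100, 100), c(50, 50, 50))
  expect_equal(f$signed_fold, -2)
  expect_equal(signed_fold(c(80, 100, 120), c(80, 100, 120))$signed_fold, 1)
  expect_error(signed_fold(c(-1, 1, 1), c(1, 1, 1)), "positive")

  # involution: swapping genotype labels flips the sign (and fixes +1)
  set.seed(2)
  for (i in 1:25) {
    wt <- rlnorm(3, 5, 0.2); mut <- rlnorm(3, 5, 0.2)
    a <- signed_fold(wt, mut)$signed_fold
    b <- signed_fold(mut, wt)$signed_fold
    if (abs(a) > 1) expect_equal(b, -a) else expect_equal(b, a)
    # invariant under common rescaling of all arrays
    expect_equal(signed_fold(wt * 7, mut * 7)$signed_fold, a)
  }
})

test_that("probe sets collapse to the highest-intensity probe per gene", {
  mat <- rbind(pA1 = c(500, 500), pA2 = c(800, 800), pB1 = c(10, 10),
               pC1 = c(7, 7), pC2 = c(7, 7))
  map <- data.frame(probe_id = c("pA1", "pA2", "pB1", "pC1", "pC2"),
                    gene = c("A", "A", "B", "C", "C"))
  out <- collapse_probe_sets(mat, map)
  expect_equal(out["A", ], c(800, 800))
  expect_equal(out["B", ], c(10, 10))          # single probe unchanged
  expect_equal(unname(out["C", ]), c(7, 7))    # tie: lexicographically first
  expect_equal(rownames(out), c("A", "B", "C"))

  # unmapped probes pass through under their own id
  out2 <- collapse_probe_sets(mat, map[map$gene != "B", ])
  expect_true("pB1" %in% rownames(out2))
})

test_that("fold-scan counts match an independent enumeration", {
  # hand-built 10-gene matrix: 3 WT then 3 MUT arrays
  set.seed(8)
  mat <- matrix(rlnorm(60, 5, 0.1), 10, 6,
                dimnames = list(paste0("g", 1:10),
                                c(paste0("WT", 1:3), paste0("MUT", 1:3))))
  mat[1, 4:6] <- mat[1, 4:6] * 3       # planted up in mutants
  mat[2, 4:6] <- mat[2, 4:6] / 2.5     # planted down in mutants
  genotypes <- rep(c("WT", "MUT"), each = 3)
  cutoffs <- c(1.2, 1.4, 2.0)
  got <- fold_scan_fdr(mat, genotypes, cutoffs)

  # oracle: direct per-gene ratios and explicit subset enumeration
  count <- function(g1, g2) {
    r <- apply(mat, 1, function(x) mean(x[g2]) / mean(x[g1]))
    sf <- ifelse(r >= 1, r, -1 / r)
    vapply(cutoffs, function(cc) sum(abs(sf) > cc), numeric(1))
  }
  expect_equal(got$n_observed, count(1:3, 4:6))
  combos <- combn(6, 3, simplify = FALSE)
  mixed <- Filter(function(s) length(intersect(s, 1:3)) %in% 1:2, combos)
  mixed <- Filter(function(s) 1 %in% s, mixed)
  expect_length(mixed, 9L)            # 3v3 has 9 mixed balanced relabelings
  nulls <- sapply(mixed, function(s) count(s, setdiff(1:6, s)))
  expect_equal(got$n_null, rowMeans(nulls))
  expect_equal(got$fdr, rowMeans(nulls) / got$n_observed)

  # no probe beyond an extreme cutoff: FDR undefined
  expect_true(is.na(fold_scan_fdr(mat, genotypes, 50)$fdr))
  expect_error(fold_scan_fdr(mat, genotypes, 0.5), "cutoffs")
  expect_error(fold_scan_fdr(mat, rep("WT", 6)), "equal group sizes")
})

test_that("planted regulation lowers the fold-scan FDR below the null", {
  null_sim <- simulate_expression(expr_sim_config(
    n_genes = 400, regulated_fraction = 0, seed = 41))
  reg_sim <- simulate_expression(expr_sim_config(
    n_genes = 400, regulated_fraction = 0.05, fold_meanlog = log(2.5),
    seed = 41))
  # compare at a cutoff low enough that the pure-null contrast has
  # observed calls (at 10% CV almost nothing clears 1.4 under the null)
  f_null <- fold_scan_fdr(null_sim$matrix, null_sim$genotypes, 1.2)
  f_reg <- fold_scan_fdr(reg_sim$matrix, reg_sim$genotypes, 1.2)
  expect_lt(f_reg$fdr, f_null$fdr)
})

test_that("regulated-percent arithmetic rounds half-up", {
  expect_equal(fraction_regulated(18, 53), 34L)
  expect_equal(fraction_regulated(450, 45101), 1L)
  expect_equal(fraction_regulated(0, 53), 0L)
  expect_equal(fraction_regulated(1, 8), 13L)   # 12.5 rounds up
  expect_error(fraction_regulated(5, 0), "positive")
  expect_error(fraction_regulated(6, 5), "<=")
})

test_that("reference-normalized relative abundance is efficiency-corrected", {
  ct <- c(22, 22, 22)
  expect_equal(qpcr_relative_abundance(ct, ct, ct, ct)$fold, 1)
  # one cycle earlier for the target in mutants = 2-fold at E = 2
  expect_equal(qpcr_relative_abundance(ct, ct - 1, ct, ct)$fold, 2)
  # invariant to a shift applied equally to every Ct (prefactor cancels)
  r1 <- qpcr_relative_abundance(c(20, 21, 20), c(19, 19, 20),
                                c(18, 18, 18), c(18, 19, 18))
  r2 <- qpcr_relative_abundance(c(20, 21, 20) + 5, c(19, 19, 20) + 5,
                                c(18, 18, 18) + 5, c(18, 19, 18) + 5)
  expect_equal(r1$fold, r2$fold)
  expect_true(qpcr_relative_abundance(c(22, NA, NA), ct, ct, ct)$nd)

  # planted 2.2-fold upregulation recovered within +/- 0.3
  set.seed(12)
  folds <- replicate(100, {
    d <- log(2.2) / log(2)
    qpcr_relative_abundance(22 + rnorm(3, 0, 0.1),
                            22 - d + rnorm(3, 0, 0.1),
                            18 + rnorm(3, 0, 0.1),
                            18 + rnorm(3, 0, 0.1))$fold
  })
  expect_lt(abs(mean(folds) - 2.2), 0.3)
})

test_that("expression matrix TSV round-trips through the reader", {
  sim <- simulate_expression(expr_sim_config(n_genes = 20, seed = 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(probe_id = rownames(sim$matrix), sim$matrix,
                   check.names = FALSE)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_expression_matrix(f)
  expect_equal(back, sim$matrix)
})
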