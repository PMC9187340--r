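# Contact maps, residue-pair LD, the distance-matched permutation test,
# per-gene contingency tests and BH correction.

# Residue-pair table with given physical distances and r2 values.
pairs_df <- function(res_i, res_j, phys, r2, class_pair = "nonsyn-nonsyn") {
  data.frame(protein_id = "p", res_i = res_i, res_j = res_j,
             aa_distance = res_j - res_i, physical_distance = phys,
             r2 = r2, class_pair = class_pair, n_snp_pairs = 1L,
             stringsAsFactors = FALSE)
}

test_that("contact maps load symmetrically, honoring the cutoff and missing
           data, and reject conflicting entries", {
  df <- data.frame(res_i = c(1, 2), res_j = c(2, 3), dist = c(8, 12))
  cm <- load_contact_map(df)
  expect_equal(cm$distances[1, 2], 8)
  expect_equal(cm$distances[2, 1], 8)
  expect_equal(cm$distances[3, 2], 12)
  expect_true(is.na(cm$distances[1, 3]))  # unknown pair stays missing
  expect_true(all(diag(cm$distances) == 0))
  bad <- data.frame(res_i = c(1, 2), res_j = c(2, 1), dist = c(8, 9))
  expect_error(load_contact_map(bad), "conflicting.*\\(2, 1\\)|\\(1, 2\\)")
})

test_that("PDB ingestion distinguishes min-heavy-atom from C-alpha distances", {
  skip_if_not_installed("bio3d")
  # two residues: CA atoms 11 apart, but side-chain atoms 9.9 apart
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   2      11.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CB  ALA A   2      10.900   0.000   0.000  1.00  0.00           C",
    "END")
  tmp <- tempfile(fileext = ".pdb")
  writeLines(pdb, tmp)
  cm_heavy <- contact_map_from_pdb(tmp, mode = "min_heavy_atom")
  cm_ca <- contact_map_from_pdb(tmp, mode = "ca")
  expect_equal(cm_heavy$distances[1, 2], 9.9, tolerance = 1e-6)
  expect_equal(cm_ca$distances[1, 2], 11, tolerance = 1e-6)
  expect_true(cm_heavy$distances[1, 2] <= 10 && cm_ca$distances[1, 2] > 10)
})

test_that("residue_pair_ld joins SNPs to residues and pools codon SNP pairs", {
  n <- 10
  plants <- list(list(pos = 1, allele = "T", carriers = 1:4),     # codon 0
                 list(pos = 31, allele = "T", carriers = 1:4),    # codon 10
                 list(pos = 61, allele = "T", carriers = 5:8))    # codon 20
  aln <- planted_column_aln(n, 90, plants, contig = "ctg1")
  snps <- extract_snps(aln)
  snps$snps$class <- "nonsynonymous"
  snps$snps$gene_id <- "geneA"
  snps$snps$codon_id <- c(0L, 10L, 20L)
  rmap <- data.frame(gene_id = "geneA", codon_id = c(0L, 10L, 20L),
                     residue = c(1L, 11L, 21L))
  cm <- load_contact_map(data.frame(res_i = c(1, 1, 11), res_j = c(11, 21, 21),
                                    dist = c(6, 30, 25)))
  pr <- residue_pair_ld(snps, rmap, cm)
  expect_equal(nrow(pr), 3L)
  close <- pr[pr$res_i == 1 & pr$res_j == 11, ]
  expect_equal(close$r2, 1)
  expect_equal(close$aa_distance, 10L)
  expect_equal(close$physical_distance, 6)
})

test_that("permutation test: planted maximal signal gives the smallest
           possible p, absent close pairs are not testable", {
  set.seed(1)
  # close pairs r2 = 1, far pairs r2 = 0, matched aa distances
  pr <- rbind(pairs_df(1:10, (1:10) + 20, phys = 5, r2 = 1),
              pairs_df(101:140, (101:140) + 20, phys = 30, r2 = 0))
  res <- contact_ld_permutation_test(pr, n_perm = 199, seed = 4)
  ns <- res[res$class_pair == "nonsyn-nonsyn", ]
  expect_true(ns$testable)
  expect_equal(ns$observed, 1)
  expect_equal(ns$p, 1 / 200)
  # syn class has no pairs at all
  expect_false(res$testable[res$class_pair == "syn-syn"])
  # close pairs below the aa separation threshold are excluded
  pr2 <- pairs_df(1:10, (1:10) + 3, phys = 5, r2 = 1)
  res2 <- contact_ld_permutation_test(pr2, n_perm = 99)
  expect_false(res2$testable[1])
})

test_that("permutation p-values are calibrated under an exchangeable null", {
  set.seed(99)
  rejections <- 0L
  n_data <- 120L
  for (d in seq_len(n_data)) {
    # close pairs are a small minority, as in real structures, so the
    # matched far pools stay rich
    m <- 300L
    pr <- pairs_df(seq_len(m), seq_len(m) + sample(6:10, m, replace = TRUE),
                   phys = ifelse(runif(m) < 0.05, 5, 30), r2 = runif(m))
    res <- contact_ld_permutation_test(pr, n_perm = 99,
                                       seed = 1000 + d)
    p <- res$p[res$class_pair == "nonsyn-nonsyn"]
    if (!is.na(p) && p <= 0.05) rejections <- rejections + 1L
  }
  # binomial(120, 0.05) central range
  expect_gte(rejections, qbinom(0.005, n_data, 0.05))
  expect_lte(rejections, qbinom(0.995, n_data, 0.05))
})

test_that("gene contingency test reproduces the worked odds ratio and
           applies the exclusion rules", {
  # 75 banded pairs engineered to give table (10, 5, 20, 40)
  mk <- function(m, phys, r2) pairs_df(seq_len(m) + 300,
                                       seq_len(m) + 300 + 50,
                                       phys = phys, r2 = r2)
  pr <- rbind(mk(10, 5, 0.95), mk(5, 5, 0.1), mk(20, 30, 0.95),
              mk(40, 30, 0.1))
  res <- gene_contact_association(pr, high_ld_quantile = 0.6, min_close = 5)
  expect_true(res$eligible)
  expect_equal(c(res$close_high, res$close_low, res$far_high, res$far_low),
               c(10L, 5L, 20L, 40L))
  expect_equal(res$odds_ratio, 4)
  # matches the direct chi-square on the same table
  expect_equal(res$chi2_p,
               chisq.test(matrix(c(10, 5, 20, 40), 2, byrow = TRUE),
                          correct = FALSE)$p.value)
  # a zero cell triggers the Haldane correction but keeps chi2 on raw counts
  pr0 <- rbind(mk(8, 5, 0.95), mk(20, 30, 0.95), mk(40, 30, 0.1))
  res0 <- gene_contact_association(pr0, high_ld_quantile = 0.6)
  expect_equal(res0$close_low, 0L)
  expect_equal(res0$odds_ratio, (8.5 * 40.5) / (0.5 * 20.5))
  # fewer than five close pairs: gene excluded
  pr4 <- rbind(mk(4, 5, 0.95), mk(40, 30, 0.1))
  expect_false(gene_contact_association(pr4)$eligible)
  # pairs outside the 30-100 aa band are ignored
  near <- pairs_df(1:50, (1:50) + 5, phys = 5, r2 = 1)
  expect_false(gene_contact_association(rbind(near, pr4))$eligible)
})

test_that("odds ratio and chi-square agree with a contingency oracle on
           random tables", {
  set.seed(8)
  for (rep in 1:200) {
    cells <- rmultinom(1, size = sample(60:200, 1),
                       prob = runif(4, 0.05, 1))[, 1]
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    if (a + b < 5) next
    # build a pair table realizing exactly this 2x2 table
    pr <- rbind(
      if (a) pairs_df(seq_len(a), seq_len(a) + 40, 5, 0.9) else NULL,
      if (b) pairs_df(seq_len(b) + 500, seq_len(b) + 540, 5, 0.1) else NULL,
      if (c_) pairs_df(seq_len(c_) + 1000, seq_len(c_) + 1040, 30, 0.9) else NULL,
      if (d) pairs_df(seq_len(d) + 1500, seq_len(d) + 1540, 30, 0.1) else NULL)
    res <- gene_contact_association(pr, high_ld_quantile = 0.5, min_close = 5)
    if (!res$eligible || is.na(res$chi2_p)) next
    # oracle on the realized table (threshold placement is tested elsewhere)
    tab <- c(res$close_high, res$close_low, res$far_high, res$far_low)
    cc <- if (any(tab == 0)) tab + 0.5 else tab
    expect_equal(res$odds_ratio, (cc[1] * cc[4]) / (cc[2] * cc[3]))
    n <- sum(tab)
    e <- outer(c(tab[1] + tab[2], tab[3] + tab[4]),
               c(tab[1] + tab[3], tab[2] + tab[4])) / n
    chi2 <- sum((matrix(tab, 2, byrow = TRUE) - e)^2 / e)
    expect_equal(res$chi2_p, pchisq(chi2, df = 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("BH adjustment follows the step-up rule", {
  mk_tests <- function(ps) {
    data.frame(protein_id = paste0("p", seq_along(ps)), close_high = 10L,
               close_low = 5L, far_high = 5L, far_low = 10L,
               odds_ratio = 4, chi2_p = ps, eligible = TRUE,
               stringsAsFactors = FALSE)
  }
  one <- fdr_adjust(mk_tests(0.01))
  expect_equal(one$bh_q, 0.01)
  four <- fdr_adjust(mk_tests(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(four$bh_q, rep(0.04, 4))
  expect_true(all(four$significant))
  none <- fdr_adjust(mk_tests(rep(1, 5)))
  expect_false(any(none$significant))
})
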