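# r-squared / minor-allele D, pair tables, profiles, contrasts, gene stats.

test_that("r_squared reproduces worked haplotype-count examples", {
  expect_equal(r_squared(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # four genotypes AB, Ab, aB, ab one each: exact independence
  expect_equal(r_squared(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  # counts AB=4, Ab=1, aB=1, ab=4 (n=10)
  x <- c(rep(1, 5), rep(0, 5))
  y <- c(rep(1, 4), 0, 1, rep(0, 4))
  expect_equal(r_squared(x, y), 0.36)
  expect_error(r_squared(c(1, 1, 1, 1), c(1, 0, 1, 0)),
               class = "hyperLD_undefined")
})

test_that("d_minor signs attraction vs repulsion and normalizes to r2", {
  expect_equal(d_minor(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0.25)
  expect_equal(d_minor(c(1, 1, 0, 0), c(0, 0, 1, 1)), -0.25)
  expect_equal(d_minor(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    d <- d_minor(x, y)
    r2 <- r_squared(x, y)
    p <- min(mean(x), 1 - mean(x)); q <- min(mean(y), 1 - mean(y))
    expect_equal(d^2 / (p * (1 - p) * q * (1 - q)), r2, tolerance = 1e-12)
    # r2 symmetric and relabel-invariant; d_minor canonical under relabeling
    expect_equal(r_squared(y, x), r2)
    expect_equal(r_squared(1 - x, y), r2)
    if (mean(x) != 0.5) expect_equal(d_minor(1 - x, y), d)
  }
})

test_that("r_squared equals the brute-force oracle on exhaustive small inputs", {
  for (n in 3:6) {
    combos <- expand.grid(rep(list(0:1), n))
    for (i in seq_len(nrow(combos))) {
      x <- as.integer(combos[i, ])
      if (length(unique(x)) < 2) next
      for (j in seq_len(nrow(combos))) {
        y <- as.integer(combos[j, ])
        if (length(unique(y)) < 2) next
        expect_equal(r_squared(x, y), r2_oracle(x, y), tolerance = 1e-12)
      }
    }
  }
})

test_that("ld_pairs stratifies by distance, class and gene relation", {
  states <- rbind(c(1, 1, 0, 0, 0, 0),
                  c(1, 1, 0, 0, 0, 0),
                  c(0, 0, 1, 1, 1, 0),
                  c(1, 0, 1, 0, 1, 0))
  snps <- snp_table_from_states(
    states, pos = c(10, 60, 150, 2500),
    class = c("nonsynonymous", "nonsynonymous", "synonymous", "synonymous"),
    gene_id = c("g1", "g1", "g2", NA))
  pairs <- ld_pairs(snps, max_distance = 2000)
  expect_equal(nrow(pairs), 3L)  # the distant SNP pairs with nothing
  p12 <- pairs[pairs$i == 1 & pairs$j == 2, ]
  expect_equal(p12$r2, 1)
  expect_equal(p12$distance, 50L)
  expect_equal(p12$class_pair, "nonsyn-nonsyn")
  expect_equal(p12$relation, "same_gene")
  p13 <- pairs[pairs$i == 1 & pairs$j == 3, ]
  expect_equal(p13$class_pair, "mixed")
  expect_equal(p13$relation, "adjacent_genes")
  # conservation: totals match qualifying pairs
  prof <- ld_profile(snps, maf_min = 0, max_distance = 2000)
  expect_equal(sum(prof$n_pairs), nrow(pairs))
})

test_that("ld_profile applies the MAF filter and aggregates single pairs", {
  states <- rbind(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                  c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                  c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  snps <- snp_table_from_states(states, pos = c(100, 200, 300),
                                class = "synonymous", gene_id = "g1")
  # SNP 3 has maf 0.05: excluded by the strict MAF > 0.05 filter
  prof <- ld_profile(snps, maf_min = 0.05, max_distance = 500,
                     bin_edges = seq(0, 500, 250))
  populated <- prof[prof$n_pairs > 0, ]
  expect_equal(nrow(populated), 1L)
  expect_equal(populated$mean_r2, 1)
  expect_equal(populated$n_pairs, 1L)
  expect_equal(populated$bin_start, 0)
  # with maf_min 0 all three pairs qualify
  prof0 <- ld_profile(snps, maf_min = 0, max_distance = 500,
                      bin_edges = seq(0, 500, 250))
  expect_equal(sum(prof0$n_pairs), 3L)
})

test_that("planted class contrast appears in every populated profile bin", {
  set.seed(11)
  n <- 20
  carriers <- sample.int(n, 6)
  plants <- list()
  pos <- 0L
  classes <- character(0)
  for (k in 1:8) {
    pos <- pos + 40L
    plants[[length(plants) + 1]] <- list(pos = pos, allele = "T",
                                         carriers = carriers)
  }
  for (k in 1:8) {
    pos <- pos + 40L
    plants[[length(plants) + 1]] <- list(pos = pos, allele = "T",
                                         carriers = sample.int(n, 6))
  }
  aln <- planted_column_aln(n, 800, plants)
  snps <- extract_snps(aln)
  # first 8 SNPs perfectly coupled nonsyn; last 8 independent syn
  snps$snps$class <- rep(c("nonsynonymous", "synonymous"), each = 8)
  snps$snps$gene_id <- "g1"
  prof <- ld_profile(snps, maf_min = 0.05, max_distance = 800,
                     bin_edges = seq(0, 800, 200))
  ns <- prof[prof$class_pair == "nonsyn-nonsyn" & prof$n_pairs > 0, ]
  sy <- prof[prof$class_pair == "syn-syn" & prof$n_pairs > 0, ]
  expect_true(all(abs(ns$mean_r2 - 1) < 1e-9))
  expect_true(all(sy$mean_r2 < 0.5))
})

test_that("MAF matching is a no-op for identical MAF compositions and
           recovers the stratified mean otherwise", {
  # nonsyn pairs all in one MAF cell; syn pairs half in that cell (r2 = 0)
  # and half in another cell (r2 = 1): matched syn mean -> cell mean 0
  n <- 20
  mk <- function(k, coupled, m) {
    t(vapply(seq_len(m), function(i) {
      v <- integer(n); v[sample.int(n, k)] <- 1L; v
    }, integer(n)))
  }
  set.seed(5)
  states <- rbind(
    do.call(rbind, replicate(6, {v <- integer(n); v[1:5] <- 1L; rbind(v)},
                             simplify = FALSE)),   # nonsyn maf 0.25 coupled
    mk(5, FALSE, 6),                               # syn maf 0.25 independent
    do.call(rbind, replicate(6, {v <- integer(n); v[1:2] <- 1L; rbind(v)},
                             simplify = FALSE)))   # syn maf 0.1 coupled
  snps <- snp_table_from_states(states, pos = seq_len(nrow(states)) * 10,
                                class = rep(c("nonsynonymous", "synonymous",
                                              "synonymous"), each = 6),
                                gene_id = "g1")
  res <- maf_matched_contrast(snps, maf_min = 0, max_distance = 10000,
                              dist_bin_width = 10000, maf_bin_width = 0.05,
                              n_resamples = 400, seed = 9)
  expect_equal(res$nonsyn_mean, 1)
  # matched syn mean must reflect only the maf-0.25 syn cell (low LD), far
  # below the raw syn mean that includes the coupled maf-0.1 pairs
  expect_lt(res$syn_matched_mean, 0.35)
  expect_gt(res$syn_raw_mean, res$syn_matched_mean)
  # determinism under a fixed seed
  res2 <- maf_matched_contrast(snps, maf_min = 0, max_distance = 10000,
                               dist_bin_width = 10000, maf_bin_width = 0.05,
                               n_resamples = 400, seed = 9)
  expect_identical(res, res2)
})

test_that("gene_ld_stats enforces the pair-count threshold and computes excess", {
  set.seed(13)
  n <- 12
  carriers <- 1:4
  # geneA: 20 coupled nonsyn SNPs + 20 independent syn SNPs within 300 nt
  plants <- c(
    lapply(1:20, function(k) list(pos = 5L * k, allele = "T",
                                  carriers = carriers)),
    lapply(1:20, function(k) list(pos = 150L + 5L * k, allele = "C",
                                  carriers = sample.int(n, 4))))
  aln <- planted_column_aln(n, 600, plants)
  snps <- extract_snps(aln)
  snps$snps$class <- ifelse(snps$snps$minor == "T", "nonsynonymous",
                            "synonymous")
  snps$snps$gene_id <- "geneA"
  gs <- gene_ld_stats(snps, max_pair_distance = 300, min_pairs = 100,
                      maf_min = 0)
  expect_equal(gs$gene_id, "geneA")
  expect_equal(gs$ld_nonsyn, 1)
  expect_lt(gs$ld_syn, 0.5)
  expect_equal(gs$excess, gs$ld_nonsyn - gs$ld_syn)
  # raising min_pairs above the availables excludes the gene
  gs2 <- gene_ld_stats(snps, max_pair_distance = 300, min_pairs = 1e5)
  expect_equal(nrow(gs2), 0L)
})

test_that("correlate_gene_stats recovers monotone, null and confounded cases", {
  set.seed(3)
  stats <- data.frame(gene_id = paste0("g", 1:10), x = 1:10, y = 2 * (1:10))
  res <- correlate_gene_stats(stats, "x", "y")
  expect_equal(res$rho, 1)
  expect_lt(res$p, 0.01)
  # independent x and y over many genes: small rho, typically ns
  big <- data.frame(x = rnorm(1000), y = rnorm(1000))
  res2 <- correlate_gene_stats(big, "x", "y")
  expect_lt(abs(res2$rho), 0.1)
  expect_gt(res2$p, 0.01)
  # y driven solely by a well-separated confounder: stratifying on it
  # removes the signal (each quantile stratum holds one confounder level)
  conf <- rep(c(0, 10, 20, 30, 40), each = 100)
  df <- data.frame(x = conf + rnorm(500), y = conf + rnorm(500), z = conf)
  raw <- correlate_gene_stats(df, "x", "y")
  ctl <- correlate_gene_stats(df, "x", "y", control = "z", n_strata = 5)
  expect_gt(raw$rho, 0.9)
  expect_lt(abs(ctl$rho_pooled), 0.15)
  expect_true(all(abs(ctl$strata$rho) < 0.3, na.rm = TRUE))
})
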