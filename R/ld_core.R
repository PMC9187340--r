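# r-squared / signed minor-allele D, pairwise LD tables, distance profiles,
# MAF-matched contrasts, and gene-level LD statistics.

#' Linkage disequilibrium r-squared between two biallelic sites
#'
#' `r2 = (p(AB) - p(A)p(B))^2 / (p(A)(1-p(A)) p(B)(1-p(B)))` where `p(A)`
#' and `p(B)` are the minor-allele frequencies and `p(AB)` the frequency of
#' genotypes carrying the minor allele at both sites.  The value is
#' invariant under 0/1 relabeling of either site.
#'
#' @param x,y Binary vectors (1 = minor allele) of equal length over the
#'   same genotypes.
#' @return r-squared in `[0, 1]`.  A monomorphic input raises a classed
#'   error (`hyperLD_undefined`), never a silent 0.
#' @examples
#' r_squared(c(1, 1, 0, 0), c(1, 1, 0, 0))  # 1
#' @export
r_squared <- function(x, y) {
  check_pair(x, y)
  p <- mean(x); q <- mean(y)
  pab <- mean(x * y)
  (pab - p * q)^2 / (p * (1 - p) * q * (1 - q))
}

#' Signed minor-allele linkage disequilibrium D
#'
#' `D = p(AB) - p(A)p(B)` with both sites polarized to their minor alleles
#' (inputs with allele frequency > 0.5 are flipped to the canonical minor
#' orientation; an exact 0.5 tie keeps the given orientation).  Positive D
#' is attraction (coupling) of minor alleles, negative is repulsion.
#'
#' @inheritParams r_squared
#' @return Signed D.  `d_minor(x, y)^2` equals `r_squared(x, y)` times the
#'   allele-frequency normalizer.
#' @export
d_minor <- function(x, y) {
  check_pair(x, y)
  if (mean(x) > 0.5) x <- 1 - x
  if (mean(y) > 0.5) y <- 1 - y
  mean(x * y) - mean(x) * mean(y)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("state vectors differ in length")
  if (length(x) < 2L) stop("need at least 2 genotypes")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    undefined_result("LD undefined: monomorphic site")
  }
  invisible(TRUE)
}

# Vectorized r2 / D over index vectors into a 0/1 state matrix (rows = SNPs,
# columns = genotypes, 1 = minor allele).
pair_ld_values <- function(states, i, j) {
  n <- ncol(states)
  si <- states[i, , drop = FALSE]
  sj <- states[j, , drop = FALSE]
  p <- rowMeans(si); q <- rowMeans(sj)
  pab <- rowMeans(si * sj)
  d <- pab - p * q
  list(r2 = d^2 / (p * (1 - p) * q * (1 - q)), d = d)
}

#' All qualifying SNP pairs with LD values and stratification labels
#'
#' Enumerates unordered same-contig SNP pairs within `max_distance`
#' nucleotides whose MAFs both exceed `maf_min`, and computes r-squared and
#' signed minor-allele D for each, plus the class pair
#' (nonsyn-nonsyn / syn-syn / mixed), the gene relation
#' (same_gene / adjacent_genes / intergenic) and, within genes, the exon
#' relation.
#'
#' @param snps A classified [snp_table()].
#' @param max_distance Maximum pair distance in nucleotides (absolute
#'   difference of 0-based positions).
#' @param maf_min Strict lower bound on both MAFs (e.g. 0.05); 0 keeps all.
#' @return data.frame with one row per pair: `contig`, `i`, `j` (row indices
#'   into `snps`), `distance`, `r2`, `d_minor`, `class_pair`, `relation`,
#'   `exon_relation`, `gene_i`, `gene_j`, `maf_i`, `maf_j`.
#' @export
ld_pairs <- function(snps, max_distance = 2000L, maf_min = 0) {
  df <- snps$snps
  keep <- which(df$maf > maf_min)
  parts <- split(keep, df$contig[keep])
  res <- lapply(parts, function(idx) {
    pos <- df$pos[idx]
    o <- order(pos)
    idx <- idx[o]; pos <- pos[o]
    m <- length(idx)
    if (m < 2L) return(NULL)
    hi <- findInterval(pos + max_distance, pos)
    counts <- pmax(hi - seq_len(m), 0L)
    if (sum(counts) == 0L) return(NULL)
    a <- rep(seq_len(m), counts)
    b <- sequence(counts, from = seq_len(m) + 1L)
    i <- idx[a]; j <- idx[b]
    ld <- pair_ld_values(snps$states, i, j)
    ci <- df$class[i]; cj <- df$class[j]
    class_pair <- ifelse(ci == "nonsynonymous" & cj == "nonsynonymous",
                         "nonsyn-nonsyn",
                         ifelse(ci == "synonymous" & cj == "synonymous",
                                "syn-syn", "mixed"))
    gi <- df$gene_id[i]; gj <- df$gene_id[j]
    relation <- ifelse(!is.na(gi) & !is.na(gj),
                       ifelse(gi == gj, "same_gene", "adjacent_genes"),
                       "intergenic")
    ei <- df$exon_index[i]; ej <- df$exon_index[j]
    exon_relation <- ifelse(relation == "same_gene" & !is.na(ei) & !is.na(ej),
                            ifelse(ei == ej, "same_exon", "different_exons"),
                            "na")
    data.frame(contig = df$contig[i], i = i, j = j,
               distance = abs(df$pos[j] - df$pos[i]),
               r2 = ld$r2, d_minor = ld$d,
               class_pair = class_pair, relation = relation,
               exon_relation = exon_relation,
               gene_i = gi, gene_j = gj,
               maf_i = df$maf[i], maf_j = df$maf[j],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) res <- ld_pairs_empty()
  rownames(res) <- NULL
  res
}

ld_pairs_empty <- function() {
  data.frame(contig = character(0), i = integer(0), j = integer(0),
             distance = integer(0), r2 = numeric(0), d_minor = numeric(0),
             class_pair = character(0), relation = character(0),
             exon_relation = character(0), gene_i = character(0),
             gene_j = character(0), maf_i = numeric(0), maf_j = numeric(0),
             stringsAsFactors = FALSE)
}

#' Distance-stratified LD profile
#'
#' Mean r-squared per distance bin, class pair and gene relation, with a
#' standard error computed across contigs (population SD of per-contig
#' means / sqrt(number of contigs); contigs contributing fewer than
#' `min_contig_pairs` pairs to a cell are skipped for the SE, and the SE is
#' `NA` with fewer than 2 contributing contigs).
#'
#' @inheritParams ld_pairs
#' @param maf_min Strict MAF filter applied to both SNPs (default 0.05).
#' @param bin_edges Distance bin edges in nucleotides; default 50-nt bins up
#'   to `max_distance`.
#' @param min_contig_pairs Minimum per-contig pair count for the SE.
#' @return data.frame of class `ld_profile`: `bin_start`, `bin_end`,
#'   `class_pair`, `relation`, `mean_r2`, `n_pairs`, `se_r2`, `n_contigs`.
#'   Empty cells carry `n_pairs = 0` and `NA` means.
#' @export
ld_profile <- function(snps, maf_min = 0.05, max_distance = 2000L,
                       bin_edges = NULL, min_contig_pairs = 10L) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  if (is.null(bin_edges)) bin_edges <- seq(0L, max_distance, by = 50L)
  pairs <- ld_pairs(snps, max_distance = max_distance, maf_min = maf_min)
  pairs <- pairs[pairs$distance < max(bin_edges), , drop = FALSE]
  bin <- cut(pairs$distance, breaks = bin_edges, right = FALSE,
             include.lowest = FALSE)
  lv_bin <- levels(cut(numeric(0), breaks = bin_edges, right = FALSE))
  grid <- expand.grid(bin = lv_bin,
                      class_pair = c("nonsyn-nonsyn", "syn-syn", "mixed"),
                      relation = c("same_gene", "adjacent_genes", "intergenic"),
                      stringsAsFactors = FALSE)
  key <- function(b, cp, rel) paste(b, cp, rel, sep = "|")
  pk <- key(as.character(bin), pairs$class_pair, pairs$relation)
  mean_by <- tapply(pairs$r2, pk, mean)
  n_by <- tapply(pairs$r2, pk, length)
  gk <- key(grid$bin, grid$class_pair, grid$relation)
  grid$mean_r2 <- as.numeric(mean_by[gk])
  grid$n_pairs <- as.integer(n_by[gk])
  grid$n_pairs[is.na(grid$n_pairs)] <- 0L
  # across-contig SE
  ck <- paste(pk, pairs$contig, sep = "|")
  cmean <- tapply(pairs$r2, ck, mean)
  cn <- tapply(pairs$r2, ck, length)
  cell_of <- sub("\\|[^|]*$", "", names(cmean))
  ok <- cn >= min_contig_pairs
  se <- vapply(gk, function(k) {
    v <- cmean[ok & cell_of == k]
    if (length(v) < 2L) return(NA_real_)
    sqrt(mean((v - mean(v))^2)) / sqrt(length(v))
  }, numeric(1))
  nctg <- vapply(gk, function(k) sum(ok & cell_of == k), integer(1))
  grid$se_r2 <- unname(se)
  grid$n_contigs <- unname(nctg)
  edges <- t(vapply(strsplit(gsub("\\[|\\)", "", grid$bin), ","), as.numeric,
                    numeric(2)))
  out <- data.frame(bin_start = edges[, 1], bin_end = edges[, 2],
                    grid[, c("class_pair", "relation", "mean_r2", "n_pairs",
                             "se_r2", "n_contigs")],
                    stringsAsFactors = FALSE)
  class(out) <- c("ld_profile", "data.frame")
  out
}

#' MAF-matched contrast of nonsynonymous vs synonymous pair LD
#'
#' Within each distance bin, syn-syn pairs are resampled with replacement to
#' match the joint two-dimensional MAF histogram (unordered MAF pair, bin
#' width `maf_bin_width`) of the nonsyn-nonsyn pairs, removing MAF
#' composition as a confounder of the LD contrast.  MAF cells with no
#' syn-syn pair are excluded from both classes (and counted in
#' `n_unmatchable`).
#'
#' @inheritParams ld_profile
#' @param dist_bin_width Distance bin width in nucleotides.
#' @param maf_bin_width MAF histogram bin width (default 0.05).
#' @param n_resamples Number of resampling replicates.
#' @param seed RNG seed; fixed seed gives identical output.
#' @return data.frame per distance bin: `bin_start`, `bin_end`, `n_nonsyn`,
#'   `n_unmatchable`, `nonsyn_mean`, `syn_matched_mean`, `syn_matched_lo`,
#'   `syn_matched_hi` (2.5/97.5% resampling quantiles), `syn_raw_mean`,
#'   `n_syn`.
#' @export
maf_matched_contrast <- function(snps, maf_min = 0.05, max_distance = 2000L,
                                 dist_bin_width = 250L, maf_bin_width = 0.05,
                                 n_resamples = 1000L, seed = 1L) {
  pairs <- ld_pairs(snps, max_distance = max_distance, maf_min = maf_min)
  pairs <- pairs[pairs$class_pair %in% c("nonsyn-nonsyn", "syn-syn"), ,
                 drop = FALSE]
  if (!any(pairs$class_pair == "nonsyn-nonsyn") ||
      !any(pairs$class_pair == "syn-syn")) {
    undefined_result("both class pairs must be populated for a MAF-matched contrast")
  }
  set.seed(seed)
  cell_lo <- floor(pmin(pairs$maf_i, pairs$maf_j) / maf_bin_width)
  cell_hi <- floor(pmax(pairs$maf_i, pairs$maf_j) / maf_bin_width)
  pairs$maf_cell <- paste(cell_lo, cell_hi, sep = ":")
  pairs$dbin <- pairs$distance %/% dist_bin_width
  out <- lapply(sort(unique(pairs$dbin)), function(b) {
    sub <- pairs[pairs$dbin == b, , drop = FALSE]
    ns <- sub[sub$class_pair == "nonsyn-nonsyn", , drop = FALSE]
    sy <- sub[sub$class_pair == "syn-syn", , drop = FALSE]
    row <- data.frame(bin_start = b * dist_bin_width,
                      bin_end = (b + 1) * dist_bin_width,
                      n_nonsyn = nrow(ns), n_unmatchable = 0L,
                      nonsyn_mean = NA_real_, syn_matched_mean = NA_real_,
                      syn_matched_lo = NA_real_, syn_matched_hi = NA_real_,
                      syn_raw_mean = if (nrow(sy)) mean(sy$r2) else NA_real_,
                      n_syn = nrow(sy))
    if (nrow(ns) == 0L || nrow(sy) == 0L) return(row)
    syn_cells <- split(sy$r2, sy$maf_cell)
    matchable <- ns$maf_cell %in% names(syn_cells)
    row$n_unmatchable <- sum(!matchable)
    ns <- ns[matchable, , drop = FALSE]
    row$n_nonsyn <- nrow(ns)
    if (nrow(ns) == 0L) return(row)
    row$nonsyn_mean <- mean(ns$r2)
    cells <- table(ns$maf_cell)
    draws <- vapply(seq_len(n_resamples), function(rep) {
      tot <- 0
      for (cl in names(cells)) {
        pool <- syn_cells[[cl]]
        tot <- tot + sum(pool[sample.int(length(pool), cells[[cl]],
                                         replace = TRUE)])
      }
      tot / nrow(ns)
    }, numeric(1))
    row$syn_matched_mean <- mean(draws)
    qs <- quantile(draws, c(0.025, 0.975), names = FALSE)
    row$syn_matched_lo <- qs[1]; row$syn_matched_hi <- qs[2]
    row
  })
  do.call(rbind, out)
}

#' Gene-level LD statistics
#'
#' Mean r-squared over within-gene SNP pairs closer than
#' `max_pair_distance` nucleotides (a gene-length control), split by class
#' pair.  Genes with fewer than `min_pairs` qualifying pairs are dropped.
#' Optionally appends pn/ps when the alignment and annotation are supplied.
#'
#' @inheritParams ld_pairs
#' @param max_pair_distance Maximum within-gene pair distance (default 300).
#' @param min_pairs Minimum qualifying pair count per gene (default 100).
#' @param maf_min Strict MAF filter (default 0: all non-singleton SNPs).
#' @param aln,ann Optional [haploid_alignment()] and [gene_annotation()]; if
#'   both are given, pn/ps columns are merged in via [gene_pn_ps()].
#' @return data.frame of class `gene_ld_stats`: `gene_id`, `n_pairs`,
#'   `n_syn_pairs`, `n_nonsyn_pairs`, `ld_all`, `ld_syn`, `ld_nonsyn`,
#'   `excess` (= ld_nonsyn - ld_syn), plus pn/ps columns when requested.
#'   Class means are `NA` when a gene has no pair of that class.
#' @export
gene_ld_stats <- function(snps, max_pair_distance = 300L, min_pairs = 100L,
                          maf_min = 0, aln = NULL, ann = NULL) {
  pairs <- ld_pairs(snps, max_distance = max_pair_distance, maf_min = maf_min)
  pairs <- pairs[pairs$relation == "same_gene", , drop = FALSE]
  genes <- unique(pairs$gene_i)
  out <- lapply(genes, function(g) {
    sub <- pairs[pairs$gene_i == g, , drop = FALSE]
    if (nrow(sub) < min_pairs) return(NULL)
    syn <- sub$r2[sub$class_pair == "syn-syn"]
    ns <- sub$r2[sub$class_pair == "nonsyn-nonsyn"]
    ld_syn <- if (length(syn)) mean(syn) else NA_real_
    ld_nonsyn <- if (length(ns)) mean(ns) else NA_real_
    data.frame(gene_id = g, n_pairs = nrow(sub),
               n_syn_pairs = length(syn), n_nonsyn_pairs = length(ns),
               ld_all = mean(sub$r2), ld_syn = ld_syn, ld_nonsyn = ld_nonsyn,
               excess = ld_nonsyn - ld_syn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_pairs = integer(0),
                      n_syn_pairs = integer(0), n_nonsyn_pairs = integer(0),
                      ld_all = numeric(0), ld_syn = numeric(0),
                      ld_nonsyn = numeric(0), excess = numeric(0),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(aln) && !is.null(ann) && nrow(out) > 0L) {
    pp <- gene_pn_ps(aln, ann, snps, genes = out$gene_id)
    out <- merge(out, pp[, c("gene_id", "pn", "ps", "pn_ps")],
                 by = "gene_id", sort = FALSE)
  }
  class(out) <- c("gene_ld_stats", "data.frame")
  out
}

#' Spearman correlation between gene-level statistics
#'
#' Spearman rho and p-value between two columns of a gene statistics table.
#' With fewer than 30 complete observations the p-value comes from a seeded
#' permutation test (two-sided, B = 10000); otherwise from the large-sample
#' approximation.  When a control variable is given, the correlation is
#' additionally computed within quantile strata of the control and combined
#' by pooling within-stratum ranks (rank, center per stratum, Pearson on the
#' pooled centered ranks).
#'
#' @param stats A data.frame (e.g. from [gene_ld_stats()]).
#' @param x,y Column names to correlate.
#' @param control Optional column name to stratify on.
#' @param n_strata Number of control quantile strata (default 5).
#' @param seed Seed for the small-sample permutation p-value.
#' @return A list with `rho`, `p`, `n`, `method`; with a control, also
#'   `strata` (per-stratum data.frame) and `rho_pooled`, `p_pooled`.
#'   All-tied ranks give `rho = NA`.
#' @export
correlate_gene_stats <- function(stats, x, y, control = NULL, n_strata = 5L,
                                 seed = 1L) {
  keep <- stats[, c(x, y, control), drop = FALSE]
  keep <- keep[stats_complete(keep), , drop = FALSE]
  if (nrow(keep) < 3L) stop("need at least 3 genes with both fields defined")
  res <- spearman_test(keep[[x]], keep[[y]], seed = seed)
  res$n <- nrow(keep)
  if (!is.null(control)) {
    ctl <- keep[[control]]
    qs <- unique(quantile(ctl, probs = seq(0, 1, length.out = n_strata + 1)))
    stratum <- cut(ctl, breaks = qs, include.lowest = TRUE)
    per <- lapply(levels(stratum), function(s) {
      sub <- keep[stratum == s, , drop = FALSE]
      if (nrow(sub) < 3L) {
        return(data.frame(stratum = s, n = nrow(sub), rho = NA_real_,
                          p = NA_real_))
      }
      st <- spearman_test(sub[[x]], sub[[y]], seed = seed)
      data.frame(stratum = s, n = nrow(sub), rho = st$rho, p = st$p)
    })
    res$strata <- do.call(rbind, per)
    rx <- ry <- numeric(nrow(keep))
    for (s in levels(stratum)) {
      m <- stratum == s
      rx[m] <- rank(keep[[x]][m]) - mean(rank(keep[[x]][m]))
      ry[m] <- rank(keep[[y]][m]) - mean(rank(keep[[y]][m]))
    }
    if (sd(rx) == 0 || sd(ry) == 0) {
      res$rho_pooled <- NA_real_; res$p_pooled <- NA_real_
    } else {
      r <- cor(rx, ry)
      n <- nrow(keep)
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      res$rho_pooled <- r
      res$p_pooled <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  res
}

stats_complete <- function(df) {
  Reduce(`&`, lapply(df, function(v) !is.na(v) & is.finite(v)))
}

spearman_test <- function(x, y, seed = 1L, n_perm = 10000L) {
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    return(list(rho = NA_real_, p = NA_real_, method = "undefined (tied ranks)"))
  }
  rho <- cor(x, y, method = "spearman")
  n <- length(x)
  if (n >= 30L) {
    p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
    method <- "spearman (asymptotic)"
  } else {
    set.seed(seed)
    perm <- vapply(seq_len(n_perm),
                   function(b) cor(x, sample(y), method = "spearman"),
                   numeric(1))
    p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    method <- "spearman (permutation)"
  }
  list(rho = rho, p = p, method = method)
}
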