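# Shared SNPs between two populations on a common coordinate system, and
# the correlation of per-pair LD across populations.

#' Match SNPs shared between two populations
#'
#' A position is shared when it is biallelic and polymorphic in both
#' populations.  The allele match is `identical_nucleotides` when the two
#' allele sets coincide (regardless of which allele is minor, unless
#' `require_same_minor`), `same_aa_different_nucleotides` when both
#' populations' coding variants encode the same amino-acid pair through
#' different nucleotide pairs, and `different` otherwise.
#'
#' @param snps_a,snps_b Classified [snp_table()]s on the same coordinates.
#' @param require_same_minor Also require the same minor allele for
#'   `identical_nucleotides` (default `FALSE`: same allele set suffices).
#' @return data.frame: `contig`, `pos`, `idx_a`, `idx_b`, `allele_match`.
#' @export
match_shared_snps <- function(snps_a, snps_b, require_same_minor = FALSE) {
  da <- snps_a$snps; db <- snps_b$snps
  ka <- paste(da$contig, da$pos); kb <- paste(db$contig, db$pos)
  hit <- match(ka, kb)
  ia <- which(!is.na(hit)); ib <- hit[ia]
  if (length(ia) == 0L) {
    return(data.frame(contig = character(0), pos = integer(0),
                      idx_a = integer(0), idx_b = integer(0),
                      allele_match = character(0), stringsAsFactors = FALSE))
  }
  set_a <- paste(pmin(da$major[ia], da$minor[ia]),
                 pmax(da$major[ia], da$minor[ia]))
  set_b <- paste(pmin(db$major[ib], db$minor[ib]),
                 pmax(db$major[ib], db$minor[ib]))
  same_nt <- if (require_same_minor) {
    da$major[ia] == db$major[ib] & da$minor[ia] == db$minor[ib]
  } else set_a == set_b
  aa_a <- paste(pmin(da$aa_major[ia], da$aa_minor[ia]),
                pmax(da$aa_major[ia], da$aa_minor[ia]))
  aa_b <- paste(pmin(db$aa_major[ib], db$aa_minor[ib]),
                pmax(db$aa_major[ib], db$aa_minor[ib]))
  coding <- !is.na(da$aa_major[ia]) & !is.na(db$aa_major[ib]) &
    !is.na(da$aa_minor[ia]) & !is.na(db$aa_minor[ib])
  allele_match <- ifelse(same_nt, "identical_nucleotides",
                         ifelse(coding & aa_a == aa_b,
                                "same_aa_different_nucleotides", "different"))
  data.frame(contig = da$contig[ia], pos = da$pos[ia],
             idx_a = ia, idx_b = ib, allele_match = allele_match,
             stringsAsFactors = FALSE)
}

#' LD of shared SNP pairs in two populations
#'
#' Pairs of shared SNPs within `max_distance` nucleotides, with r-squared
#' computed independently in each population.  SNPs falling inside a
#' haploblock of either population are excluded, as are SNPs in genes whose
#' overall LD (`ld_all` from [gene_ld_stats()]) exceeds that population's
#' `gene_ld_quantile` quantile -- both exclusions remove within-population
#' linkage that would inflate the cross-population correlation.
#'
#' @param shared A [match_shared_snps()] table.
#' @param snps_a,snps_b The population [snp_table()]s.
#' @param blocks_a,blocks_b Optional haploblock sets (`haploblock_set` or
#'   data.frame with `contig`, `start`, `end`).
#' @param gene_stats_a,gene_stats_b Optional [gene_ld_stats()] tables.
#' @param max_distance Maximum pair distance (default 2000).
#' @param gene_ld_quantile Gene-LD exclusion quantile (default 0.8).
#' @return data.frame of class `shared_pair_ld`: `contig`, `pos_i`, `pos_j`,
#'   `distance`, `r2_pop_a`, `r2_pop_b`, `class_pair`, `relation`
#'   (`same_gene`/`different_genes`), `allele_match` (pair level:
#'   `identical` if both SNPs match nucleotides, `same_aa` if both match at
#'   least at the amino-acid level, else `different`).
#' @export
shared_pair_ld <- function(shared, snps_a, snps_b,
                           blocks_a = NULL, blocks_b = NULL,
                           gene_stats_a = NULL, gene_stats_b = NULL,
                           max_distance = 2000L, gene_ld_quantile = 0.8) {
  da <- snps_a$snps
  keep <- rep(TRUE, nrow(shared))
  in_blocks <- function(contig, pos, blocks) {
    bl <- if (inherits(blocks, "haploblock_set")) blocks$blocks else blocks
    inside <- rep(FALSE, length(pos))
    for (b in seq_len(nrow(bl))) {
      inside <- inside | (contig == bl$contig[b] & pos >= bl$start[b] &
                            pos < bl$end[b])
    }
    inside
  }
  if (!is.null(blocks_a)) keep <- keep & !in_blocks(shared$contig, shared$pos, blocks_a)
  if (!is.null(blocks_b)) keep <- keep & !in_blocks(shared$contig, shared$pos, blocks_b)
  high_ld_genes <- function(gs, q) {
    if (is.null(gs) || nrow(gs) == 0L) return(character(0))
    gs$gene_id[gs$ld_all > quantile(gs$ld_all, q, names = FALSE)]
  }
  bad_a <- high_ld_genes(gene_stats_a, gene_ld_quantile)
  bad_b <- high_ld_genes(gene_stats_b, gene_ld_quantile)
  gene_a <- da$gene_id[shared$idx_a]
  gene_b <- snps_b$snps$gene_id[shared$idx_b]
  if (length(bad_a)) keep <- keep & !(gene_a %in% bad_a)
  if (length(bad_b)) keep <- keep & !(gene_b %in% bad_b)
  sh <- shared[keep, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(sh)), sh$contig), function(rows) {
    pos <- sh$pos[rows]
    o <- order(pos); rows <- rows[o]; pos <- pos[o]
    m <- length(rows)
    if (m < 2L) return(NULL)
    hi <- findInterval(pos + max_distance, pos)
    counts <- pmax(hi - seq_len(m), 0L)
    if (sum(counts) == 0L) return(NULL)
    a <- rep(seq_len(m), counts)
    b <- sequence(counts, from = seq_len(m) + 1L)
    ri <- rows[a]; rj <- rows[b]
    lda <- pair_ld_values(snps_a$states, sh$idx_a[ri], sh$idx_a[rj])
    ldb <- pair_ld_values(snps_b$states, sh$idx_b[ri], sh$idx_b[rj])
    ci <- da$class[sh$idx_a[ri]]; cj <- da$class[sh$idx_a[rj]]
    class_pair <- ifelse(ci == "nonsynonymous" & cj == "nonsynonymous",
                         "nonsyn-nonsyn",
                         ifelse(ci == "synonymous" & cj == "synonymous",
                                "syn-syn", "mixed"))
    gi <- da$gene_id[sh$idx_a[ri]]; gj <- da$gene_id[sh$idx_a[rj]]
    relation <- ifelse(!is.na(gi) & !is.na(gj) & gi == gj,
                       "same_gene", "different_genes")
    mi <- sh$allele_match[ri]; mj <- sh$allele_match[rj]
    allele_match <- ifelse(
      mi == "identical_nucleotides" & mj == "identical_nucleotides",
      "identical",
      ifelse(mi %in% c("identical_nucleotides", "same_aa_different_nucleotides") &
               mj %in% c("identical_nucleotides", "same_aa_different_nucleotides"),
             "same_aa", "different"))
    data.frame(contig = sh$contig[ri], pos_i = sh$pos[ri], pos_j = sh$pos[rj],
               distance = sh$pos[rj] - sh$pos[ri],
               r2_pop_a = lda$r2, r2_pop_b = ldb$r2,
               class_pair = class_pair, relation = relation,
               allele_match = allele_match, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(0), pos_i = integer(0),
                      pos_j = integer(0), distance = integer(0),
                      r2_pop_a = numeric(0), r2_pop_b = numeric(0),
                      class_pair = character(0), relation = character(0),
                      allele_match = character(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  class(res) <- c("shared_pair_ld", "data.frame")
  res
}

#' Cross-population LD correlation by stratum
#'
#' Spearman correlation of (r2 in population A, r2 in population B) within
#' strata of allele match x class pair x gene relation.  Strata with fewer
#' than `min_n` pairs, or with constant r2 in either population, are
#' reported as not testable.
#'
#' @param pair_table A [shared_pair_ld()] table.
#' @param by Stratification columns.
#' @param min_n Minimum pairs per stratum (default 3).
#' @return data.frame: the stratum labels plus `n`, `rho`, `p`, `testable`.
#' @export
ld_correlation <- function(pair_table,
                           by = c("allele_match", "class_pair", "relation"),
                           min_n = 3L) {
  key <- interaction(pair_table[by], drop = TRUE, sep = "|")
  out <- lapply(levels(key), function(k) {
    sub <- pair_table[key == k, , drop = FALSE]
    labels <- as.data.frame(sub[1, by, drop = FALSE], stringsAsFactors = FALSE)
    row <- cbind(labels, data.frame(n = nrow(sub), rho = NA_real_,
                                    p = NA_real_, testable = FALSE))
    if (nrow(sub) < min_n) return(row)
    if (sd(sub$r2_pop_a) == 0 || sd(sub$r2_pop_b) == 0) return(row)
    ct <- suppressWarnings(cor.test(sub$r2_pop_a, sub$r2_pop_b,
                                    method = "spearman", exact = FALSE))
    row$rho <- unname(ct$estimate); row$p <- ct$p.value; row$testable <- TRUE
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
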