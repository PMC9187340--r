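# Small in-code fixtures shared across test files.

# Alignment from a character vector of equal-length sequences.
aln_from <- function(..., contig = "ctg1") {
  haploid_alignment(c(...), contig_id = contig)
}

# Alignment whose column `pos` (0-based) is a biallelic site with `minor`
# carried by genotypes `carriers`, on an otherwise constant background.
planted_column_aln <- function(n, L, plants, background = "A",
                               contig = "ctg1") {
  mat <- matrix(background, nrow = n, ncol = L)
  for (p in plants) mat[p$carriers, p$pos + 1L] <- p$allele
  rownames(mat) <- sprintf("g%02d", seq_len(n))
  haploid_alignment(mat, contig_id = contig)
}

# snp_table directly from a 0/1 state matrix (rows = SNPs).
snp_table_from_states <- function(states, pos, contig = "ctg1",
                                  class = "noncoding", gene_id = NA_character_,
                                  exon_index = NA_integer_) {
  n <- ncol(states)
  maf <- rowMeans(states)
  stopifnot(all(maf <= 0.5 + 1e-9))
  df <- data.frame(contig = contig, pos = as.integer(pos),
                   major = "A", minor = "T", maf = maf,
                   mac = as.integer(rowSums(states)),
                   singleton = rowSums(states) == 1,
                   class = class, gene_id = gene_id,
                   exon_index = exon_index, stringsAsFactors = FALSE)
  snp_table(df, states, sprintf("g%02d", seq_len(n)))
}

# Brute-force r2 via explicit 2x2 haplotype counting.
r2_oracle <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  pa <- mean(x); pb <- mean(y); pab <- n11 / n
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# One-gene annotation covering [start, end) on the given strand.
one_gene_ann <- function(start, end, strand = "+", gene = "geneA",
                         contig = "ctg1") {
  gene_annotation(gene, contig, strand, start, end)
}
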