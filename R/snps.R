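# SNP tables: biallelic polymorphic sites with per-genotype minor-allele
# states, MAF, and synonymous/nonsynonymous classification.

#' Construct a SNP table
#'
#' Usually produced by [extract_snps()].  A `snp_table` couples a per-SNP
#' data.frame (`$snps`) to an integer matrix of minor-allele indicators
#' (`$states`, SNPs x genotypes, 1 = genotype carries the minor allele).
#'
#' @param snps data.frame with columns `contig`, `pos` (0-based), `major`,
#'   `minor`, `maf`, `mac`, `singleton`, `class`, `gene_id`, `exon_index`,
#'   `codon_id`, `codon_pos`, `aa_major`, `aa_minor`.
#' @param states Integer matrix (0/1), one row per SNP, one column per
#'   genotype.
#' @param genotype_ids Genotype identifiers (column names of `states`).
#' @return An object of class `snp_table`.
#' @export
snp_table <- function(snps, states, genotype_ids = colnames(states)) {
  stopifnot(nrow(snps) == nrow(states))
  defaults <- list(class = "noncoding", gene_id = NA_character_,
                   exon_index = NA_integer_, codon_id = NA_integer_,
                   codon_pos = NA_integer_, aa_major = NA_character_,
                   aa_minor = NA_character_)
  for (nm in names(defaults)) {
    if (is.null(snps[[nm]])) snps[[nm]] <- defaults[[nm]]
  }
  states <- matrix(as.integer(states), nrow = nrow(states),
                   dimnames = list(NULL, genotype_ids))
  structure(list(snps = snps, states = states, genotype_ids = genotype_ids),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs x %d genotypes (%s)\n",
              nrow(x$snps), ncol(x$states),
              paste(names(table(x$snps$class)), table(x$snps$class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Number of SNPs in a snp_table
#' @param snps A `snp_table`.
#' @return Integer count.
#' @export
n_snps <- function(snps) nrow(snps$snps)

#' Subset a snp_table by SNP index
#' @param snps A `snp_table`.
#' @param idx Logical or integer row index.
#' @return The subset `snp_table`.
#' @export
subset_snps <- function(snps, idx) {
  snp_table(snps$snps[idx, , drop = FALSE],
            snps$states[idx, , drop = FALSE],
            snps$genotype_ids)
}

#' Combine snp_tables over the same genotypes
#' @param ... `snp_table` objects sharing identical genotype ids.
#' @return A single `snp_table`.
#' @export
rbind_snps <- function(...) {
  parts <- list(...)
  ids <- parts[[1]]$genotype_ids
  stopifnot(all(vapply(parts, function(p) identical(p$genotype_ids, ids),
                       logical(1))))
  snp_table(do.call(rbind, lapply(parts, `[[`, "snps")),
            do.call(rbind, lapply(parts, `[[`, "states")), ids)
}

#' Extract biallelic SNPs from a haploid alignment
#'
#' Columns containing any gap or N are excluded entirely; columns with
#' exactly two distinct nucleotides become SNPs (3+ alleles are dropped).
#' Major/minor alleles are assigned by count; an exact tie at MAF = 0.5 is
#' broken deterministically so that the alphabetically first allele is major.
#'
#' @param aln A [haploid_alignment()].
#' @param drop_singletons Drop SNPs whose minor allele occurs in exactly one
#'   genotype (the default, matching the analysis convention for dense
#'   polymorphism data).
#' @return A [snp_table()] with `class` set to `"noncoding"` throughout; run
#'   [classify_coding_sites()] to classify coding SNPs.
#' @export
extract_snps <- function(aln, drop_singletons = TRUE) {
  mat <- aln$seq
  n <- nrow(mat)
  counts <- vapply(NUCLEOTIDES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  gapfree <- rowSums(counts) == n
  nalleles <- rowSums(counts > 0)
  keep <- which(gapfree & nalleles == 2L)
  if (length(keep) == 0L) {
    return(snp_table(empty_snp_df(aln$contig_id),
                     matrix(integer(0), 0, n,
                            dimnames = list(NULL, aln$genotype_ids))))
  }
  cnt <- counts[keep, , drop = FALSE]
  # max.col(ties.method = "first") makes the alphabetically first allele
  # major on an exact tie, since columns are ordered A,C,G,T.
  major_idx <- max.col(cnt, ties.method = "first")
  major <- NUCLEOTIDES[major_idx]
  cnt_minor <- cnt
  cnt_minor[cbind(seq_along(keep), major_idx)] <- 0L
  minor_idx <- max.col(cnt_minor > 0, ties.method = "first")
  minor <- NUCLEOTIDES[minor_idx]
  mac <- cnt_minor[cbind(seq_along(keep), minor_idx)]
  states <- t(mat[, keep, drop = FALSE] == rep(minor, each = n))
  df <- data.frame(contig = aln$contig_id, pos = keep - 1L,
                   major = major, minor = minor,
                   maf = mac / n, mac = as.integer(mac),
                   singleton = mac == 1L, stringsAsFactors = FALSE)
  st <- snp_table(df, states, aln$genotype_ids)
  if (drop_singletons) st <- subset_snps(st, !st$snps$singleton)
  st
}

empty_snp_df <- function(contig) {
  data.frame(contig = character(0), pos = integer(0), major = character(0),
             minor = character(0), maf = numeric(0), mac = integer(0),
             singleton = logical(0), stringsAsFactors = FALSE)
}

# Majority base (A/C/G/T) of an alignment column; ties alphabetical; NA if
# no called base.
consensus_base <- function(aln, pos) {
  col <- aln$seq[, pos + 1L]
  cnt <- vapply(NUCLEOTIDES, function(b) sum(col == b), numeric(1))
  if (all(cnt == 0)) return(NA_character_)
  NUCLEOTIDES[which.max(cnt)]
}

#' Classify coding SNPs as synonymous or nonsynonymous
#'
#' For each SNP inside an annotated exon, the two codon variants are built by
#' substituting each allele into the major-allele background codon (the other
#' codon positions are held at their per-column major alleles, so a SNP is
#' classified independently even when its codon contains another segregating
#' site).  Minus-strand genes are reverse-complemented onto the coding
#' strand.  Identical encoded amino acids mean synonymous; different
#' (including stop gain/loss) mean nonsynonymous.  Codons truncated by a
#' contig edge leave the SNP `"noncoding"` with a warning.
#'
#' @param snps A [snp_table()] from [extract_snps()].
#' @param aln The source [haploid_alignment()].
#' @param ann A [gene_annotation()] table.
#' @return The `snp_table` with `class`, `gene_id`, `exon_index`, `codon_id`,
#'   `codon_pos`, `aa_major`, `aa_minor` filled for coding SNPs.
#' @export
classify_coding_sites <- function(snps, aln, ann) {
  df <- snps$snps
  ann <- ann[ann$contig == aln$contig_id, , drop = FALSE]
  truncated <- 0L
  for (gene in unique(ann$gene_id)) {
    cds <- gene_cds_positions(ann, gene)
    hit <- which(df$pos %in% cds$positions & df$contig == cds$contig)
    if (length(hit) == 0L) next
    cds_index <- match(df$pos[hit], cds$positions) - 1L  # 0-based CDS offset
    codon_id <- cds_index %/% 3L
    codon_pos <- cds_index %% 3L
    exon_rows <- ann[ann$gene_id == gene, , drop = FALSE]
    for (k in seq_along(hit)) {
      i <- hit[k]
      cpos <- cds$positions[codon_id[k] * 3L + 1:3]  # genomic, coding order
      if (anyNA(cpos)) { truncated <- truncated + 1L; next }
      bg <- vapply(cpos, function(p) consensus_base(aln, p), character(1))
      if (anyNA(bg)) { truncated <- truncated + 1L; next }
      if (cds$strand == "-") bg <- complement_base(bg)
      maj <- df$major[i]; mnr <- df$minor[i]
      if (cds$strand == "-") { maj <- complement_base(maj); mnr <- complement_base(mnr) }
      cod_major <- bg; cod_major[codon_pos[k] + 1L] <- maj
      cod_minor <- bg; cod_minor[codon_pos[k] + 1L] <- mnr
      aa_major <- translate_codon(paste(cod_major, collapse = ""))
      aa_minor <- translate_codon(paste(cod_minor, collapse = ""))
      ex <- exon_rows$exon_index[exon_rows$start <= df$pos[i] &
                                   df$pos[i] < exon_rows$end]
      df$gene_id[i] <- gene
      df$exon_index[i] <- if (length(ex)) ex[1] else NA_integer_
      df$codon_id[i] <- codon_id[k]
      df$codon_pos[i] <- codon_pos[k]
      df$aa_major[i] <- aa_major
      df$aa_minor[i] <- aa_minor
      df$class[i] <- if (identical(aa_major, aa_minor)) "synonymous" else "nonsynonymous"
    }
  }
  if (truncated > 0L) {
    warning(truncated, " coding SNP(s) in codons truncated by a contig edge ",
            "left unclassified (noncoding)")
  }
  snp_table(df, snps$states, snps$genotype_ids)
}

#' Per-gene pn/ps ratio
#'
#' pn = nonsynonymous SNP count / nonsynonymous site count, ps likewise for
#' synonymous; site counts are computed from the major-allele coding
#' sequence per codon by enumerating all nine single-nucleotide changes
#' (NG86-style fractional weights, see [codon_site_weights()]).
#'
#' @param aln A [haploid_alignment()].
#' @param ann A [gene_annotation()] table.
#' @param snps A classified [snp_table()].
#' @param genes Genes to evaluate (default: all in `ann`).
#' @return data.frame with `gene_id`, `n_syn_snps`, `n_nonsyn_snps`,
#'   `syn_sites`, `nonsyn_sites`, `pn`, `ps`, `pn_ps`.  `pn_ps` is `NA`
#'   (undefined, not infinite) when ps = 0.
#' @export
gene_pn_ps <- function(aln, ann, snps, genes = unique(ann$gene_id)) {
  df <- snps$snps
  out <- lapply(genes, function(gene) {
    cds <- gene_cds_positions(ann, gene)
    bg <- vapply(cds$positions, function(p) consensus_base(aln, p), character(1))
    if (cds$strand == "-") bg <- complement_base(bg)
    codons <- vapply(seq_len(length(bg) %/% 3L), function(k) {
      paste(bg[(3L * (k - 1L) + 1L):(3L * k)], collapse = "")
    }, character(1))
    w <- codon_site_weights(codons)
    syn_sites <- sum(w[, "syn"], na.rm = TRUE)
    nonsyn_sites <- sum(w[, "nonsyn"], na.rm = TRUE)
    in_gene <- !is.na(df$gene_id) & df$gene_id == gene
    n_syn <- sum(in_gene & df$class == "synonymous")
    n_nonsyn <- sum(in_gene & df$class == "nonsynonymous")
    pn <- if (nonsyn_sites > 0) n_nonsyn / nonsyn_sites else NA_real_
    ps <- if (syn_sites > 0) n_syn / syn_sites else NA_real_
    data.frame(gene_id = gene, n_syn_snps = n_syn, n_nonsyn_snps = n_nonsyn,
               syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
               pn = pn, ps = ps,
               pn_ps = if (!is.na(ps) && ps > 0) pn / ps else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read a SNP table as TSV
#'
#' Genotype states are serialized as a 0/1 string per SNP (column `states`),
#' with genotype ids recorded in a header comment line.
#'
#' @param snps A `snp_table`.
#' @param path File path.
#' @return `write_snp_table()` returns `path` invisibly; `read_snp_table()`
#'   returns a `snp_table`.
#' @export
write_snp_table <- function(snps, path) {
  df <- snps$snps
  df$states <- apply(snps$states, 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# genotypes=", paste(snps$genotype_ids, collapse = ",")),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  header <- readLines(path, n = 1L)
  ids <- strsplit(sub("^# genotypes=", "", header), ",")[[1]]
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = list(states = "character"))
  states <- do.call(rbind, lapply(strsplit(df$states, ""), as.integer))
  if (is.null(states)) states <- matrix(integer(0), 0, length(ids))
  df$states <- NULL
  colnames(states) <- ids
  snp_table(df, states, ids)
}
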