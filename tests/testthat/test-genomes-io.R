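# Alignment I/O, SNP extraction, coding-site classification, diversity.

test_that("FASTA round trip preserves the alignment and uppercases symbols", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">g1", "acgtacgtna", ">g2", "ACGTACGTTA", ">g3", "acgzacgtta"),
             tmp)
  aln <- read_haploid_alignment(tmp, contig_id = "c1")
  expect_equal(n_genotypes(aln), 3L)
  expect_equal(alignment_length(aln), 10L)
  expect_equal(paste(aln$seq[1, ], collapse = ""), "ACGTACGTNA")
  # unknown symbol z mapped to N
  expect_equal(unname(aln$seq[3, 4]), "N")
  out <- tempfile(fileext = ".fasta")
  write_haploid_alignment(aln, out)
  back <- read_haploid_alignment(out, contig_id = "c1")
  expect_identical(back$seq, aln$seq)
  expect_identical(back$genotype_ids, aln$genotype_ids)
})

test_that("unequal record lengths raise an error naming the record", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGTACGTAC", ">g2", "ACGTACGTA"), tmp)
  expect_error(read_haploid_alignment(tmp), "record 2.*g2")
  expect_error(haploid_alignment(c(a = "AAAA")), "at least 2")
})

test_that("extract_snps applies the biallelic, gap and singleton rules", {
  # columns: 0 singleton A/T; 1 tie AAATTT; 2 triallelic; 3 gap; 4 clean 2:4
  mat <- rbind(c("A", "A", "A", "A", "T"),
               c("A", "A", "A", "A", "T"),
               c("A", "A", "C", "A", "A"),
               c("A", "T", "T", "-", "A"),
               c("A", "T", "A", "A", "A"),
               c("T", "T", "A", "A", "A"))
  aln <- haploid_alignment(mat, contig_id = "c")
  snps <- extract_snps(aln, drop_singletons = TRUE)
  expect_equal(snps$snps$pos, c(1L, 4L))
  # tie at MAF 0.5: alphabetically first (A) is major
  expect_equal(snps$snps$major[1], "A")
  expect_equal(snps$snps$minor[1], "T")
  expect_equal(snps$snps$maf[1], 0.5)
  expect_equal(snps$snps$maf[2], 2 / 6)
  # with singletons kept, column 0 appears too
  all_snps <- extract_snps(aln, drop_singletons = FALSE)
  expect_equal(all_snps$snps$pos, c(0L, 1L, 4L))
  expect_true(all_snps$snps$singleton[1])
})

test_that("extract_snps is invariant under genotype row permutation", {
  set.seed(42)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C", "G", "T"), 8 * 40, replace = TRUE,
                         prob = c(0.7, 0.1, 0.1, 0.1)), nrow = 8)
    rownames(mat) <- paste0("g", 1:8)
    aln <- haploid_alignment(mat, contig_id = "c")
    perm <- sample(8)
    aln_p <- haploid_alignment(mat[perm, ], contig_id = "c")
    a <- extract_snps(aln); b <- extract_snps(aln_p)
    expect_identical(a$snps, b$snps)
    expect_identical(a$states[, perm, drop = FALSE], b$states)
  }
})

test_that("nucleotide diversity matches brute force and the 2k(n-k) identity", {
  a1 <- aln_from("AAAAAAAAAA", "AAAAAAAAAA")
  expect_equal(nucleotide_diversity(a1), 0)
  a2 <- aln_from("AAAAAAAAAA", "TTAAAAAAAA")
  expect_equal(nucleotide_diversity(a2), 0.2)
  # 3 genotypes engineered so pairwise differences are 1/10, 2/10, 3/10
  a3 <- aln_from("AAAAAAAAAA", "TAAAAAAAAA", "ATTAAAAAAA")
  expect_equal(nucleotide_diversity(a3), mean(c(0.1, 0.3, 0.2)))
  # single biallelic column, minor count k of n: pi = 2k(n-k)/(n(n-1))
  for (n in c(4, 7, 10)) {
    for (k in 1:(n %/% 2)) {
      mat <- matrix("A", n, 1)
      mat[seq_len(k), 1] <- "T"
      aln <- haploid_alignment(mat, contig_id = "c")
      expect_equal(nucleotide_diversity(aln), 2 * k * (n - k) / (n * (n - 1)))
    }
  }
  # gap columns excluded from numerator and denominator
  a4 <- aln_from("TA-AAAAAAA", "AAAA-AAAAA")
  expect_equal(nucleotide_diversity(a4), 1 / 8)
  a5 <- aln_from("--", "AA")
  expect_error(nucleotide_diversity(a5), class = "hyperLD_undefined")
})

test_that("coding classification matches the genetic code on worked codons", {
  # gene at [0,6): codons GGA|GGA background; SNPs alter specific positions
  mat <- rbind(c("G", "G", "A", "G", "G", "A"),
               c("G", "G", "A", "G", "G", "A"),
               c("G", "G", "C", "A", "G", "A"),
               c("G", "G", "C", "A", "G", "A"))
  aln <- haploid_alignment(mat, contig_id = "ctg1")
  ann <- one_gene_ann(0, 6)
  snps <- classify_coding_sites(extract_snps(aln), aln, ann)
  # GGA->GGC at codon position 3: Gly/Gly synonymous
  i <- which(snps$snps$pos == 2)
  expect_equal(snps$snps$class[i], "synonymous")
  expect_equal(snps$snps$aa_major[i], "G")
  # GGA->AGA at codon position 1: Gly/Arg nonsynonymous
  j <- which(snps$snps$pos == 3)
  expect_equal(snps$snps$class[j], "nonsynonymous")
  expect_equal(snps$snps$codon_id[j], 1L)
  expect_equal(snps$snps$codon_pos[j], 0L)
})

test_that("minus-strand classification reverse-complements onto the coding strand", {
  # coding strand codon GAA/GAG (Glu/Glu): plus-strand alignment is its
  # reverse complement TTC with a T/C SNP at plus position 0
  mat <- rbind(c("T", "T", "C"),
               c("T", "T", "C"),
               c("C", "T", "C"),
               c("C", "T", "C"))
  aln <- haploid_alignment(mat, contig_id = "ctg1")
  ann <- one_gene_ann(0, 3, strand = "-")
  snps <- classify_coding_sites(extract_snps(aln), aln, ann)
  expect_equal(snps$snps$class[1], "synonymous")
  expect_setequal(c(snps$snps$aa_major[1], snps$snps$aa_minor[1]), "E")
})

test_that("classification agrees with an exhaustive 64-codon oracle", {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  nts <- c("A", "C", "G", "T")
  n_checked <- 0L
  for (cd in codons) {
    base <- strsplit(cd, "")[[1]]
    for (p in 1:3) {
      for (alt in setdiff(nts, base[p])) {
        mut <- base; mut[p] <- alt
        expected <- if (code[[cd]] == code[[paste(mut, collapse = "")]])
          "synonymous" else "nonsynonymous"
        # 4 genotypes: 2 major codon, 2 with the substitution
        mat <- rbind(base, base, mut, mut)
        dimnames(mat) <- list(paste0("g", 1:4), NULL)
        aln <- haploid_alignment(mat, contig_id = "ctg1")
        snps <- classify_coding_sites(extract_snps(aln), aln,
                                      one_gene_ann(0, 3))
        i <- which(snps$snps$pos == p - 1L)
        expect_equal(snps$snps$class[i], expected,
                     label = paste(cd, "->", paste(mut, collapse = "")))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_equal(n_checked, 64L * 9L)
})

test_that("codon site weights match hand enumeration for TTT", {
  w <- codon_site_weights("TTT")
  expect_equal(unname(w[1, "syn"]), 1 / 3)
  expect_equal(unname(w[1, "nonsyn"]), 8 / 3)
  all64 <- codon_site_weights(names(Biostrings::GENETIC_CODE))
  expect_true(all(abs(rowSums(all64) - 3) < 1e-12))
})

test_that("gene_pn_ps counts sites NG86-style and handles degenerate cases", {
  # gene of GGA codons (syn sites: position 3 fully degenerate -> 1 of 9
  # changes*? GGA: GGC,GGG,GGT all Gly -> 3 syn changes = 1 site per codon)
  mat <- do.call(rbind, replicate(6, rep(c("G", "G", "A"), 4), simplify = FALSE))
  # one synonymous SNP (third position GGA->GGC) and no nonsyn SNPs
  mat[1:2, 3] <- "C"
  aln <- haploid_alignment(mat, contig_id = "ctg1")
  ann <- one_gene_ann(0, 12, gene = "geneA")
  snps <- classify_coding_sites(extract_snps(aln), aln, ann)
  pp <- gene_pn_ps(aln, ann, snps)
  expect_equal(pp$syn_sites, 4 * 1)
  expect_equal(pp$nonsyn_sites, 4 * 2)
  expect_equal(pp$n_syn_snps, 1L)
  expect_equal(pp$pn_ps, 0)
  # ps = 0 -> undefined, not infinity
  mat2 <- mat
  mat2[1:2, 3] <- "A"      # remove the syn SNP
  mat2[1:2, 4] <- "A"      # add nonsyn GGA->AGA
  aln2 <- haploid_alignment(mat2, contig_id = "ctg1")
  snps2 <- classify_coding_sites(extract_snps(aln2), aln2, ann)
  pp2 <- gene_pn_ps(aln2, ann, snps2)
  expect_true(is.na(pp2$pn_ps))
})

test_that("snp_table TSV round trip preserves SNPs and states", {
  aln <- planted_column_aln(6, 30, list(
    list(pos = 3, allele = "T", carriers = 1:3),
    list(pos = 17, allele = "C", carriers = c(2, 5))))
  snps <- extract_snps(aln)
  tmp <- tempfile(fileext = ".tsv")
  write_snp_table(snps, tmp)
  back <- read_snp_table(tmp)
  expect_equal(back$snps$pos, snps$snps$pos)
  expect_equal(back$snps$maf, snps$snps$maf)
  expect_identical(unname(back$states), unname(snps$states))
  expect_identical(back$genotype_ids, snps$genotype_ids)
})

test_that("GFF3 round trip preserves gene structure and coordinates", {
  ann <- rbind(gene_annotation("geneA", "ctg1", "+", c(10, 100), c(40, 130)),
               gene_annotation("geneB", "ctg1", "-", 200, 260))
  tmp <- tempfile(fileext = ".gff3")
  write_gff3(ann, tmp, contig_lengths = c(ctg1 = 1000))
  back <- read_gff3(tmp)
  back <- back[order(back$gene_id, back$start), ]
  expect_setequal(unique(back$gene_id), c("geneA", "geneB"))
  a <- back[back$gene_id == "geneA", ]
  expect_equal(a$start, c(10, 100))
  expect_equal(a$end, c(40, 130))
  b <- back[back$gene_id == "geneB", ]
  expect_equal(b$strand[1], "-")
  expect_equal(b$start, 200)
})
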