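# Ground-truth synthetic data: haploid alignments with background SNPs
# drawn from a neutral-like site-frequency spectrum, planted two-haplotype
# haploblocks, planted coupled nonsynonymous pairs, and contact maps whose
# segment structure can mirror planted LD segments.

#' Synthetic population specification
#'
#' Defaults describe a population of 30 haploid genotypes over a 30 kb
#' contig carrying 10 single-exon genes of 300 codons, with ~10% of
#' gap-free sites polymorphic and minor-allele counts drawn from a neutral
#' site-frequency spectrum `P(k) proportional to 1/k + 1/(n-k)` truncated
#' at singletons -- a desk-scale caricature of a hyperpolymorphic haploid
#' population.
#'
#' @param n_genotypes Number of haploid genotypes.
#' @param contig_length Contig length in nucleotides.
#' @param n_genes Number of single-exon genes.
#' @param gene_length_codons Gene length in codons.
#' @param gene_spacing Distance between gene starts in nucleotides.
#' @param first_gene_start Start of the first gene (0-based).
#' @param p_poly Per-site background polymorphism probability.
#' @param haploblocks List of planted blocks, each
#'   `list(start=, end=, freq=, n_snps=, noise=0)`: a two-haplotype segment
#'   with the minor haplotype at frequency `freq`, `n_snps` fully coupled
#'   SNPs, and per-genotype state-flip noise `noise`.
#' @param coupled_pairs List of planted nonsynonymous pairs, each
#'   `list(gene=, n_pairs=, maf=, r2=1)`: pairs of second-codon-position
#'   SNPs (always nonsynonymous) with equal MAF and target r-squared.
#' @param seed RNG seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_genotypes = 30L, contig_length = 30000L,
                       n_genes = 10L, gene_length_codons = 300L,
                       gene_spacing = 2500L, first_gene_start = 1000L,
                       p_poly = 0.1, haploblocks = list(),
                       coupled_pairs = list(), seed = 1L) {
  gene_len <- 3L * gene_length_codons
  stopifnot(first_gene_start + (n_genes - 1L) * gene_spacing + gene_len <=
              contig_length,
            n_genotypes >= 4L)
  structure(list(n_genotypes = as.integer(n_genotypes),
                 contig_length = as.integer(contig_length),
                 n_genes = as.integer(n_genes),
                 gene_length_codons = as.integer(gene_length_codons),
                 gene_spacing = as.integer(gene_spacing),
                 first_gene_start = as.integer(first_gene_start),
                 p_poly = p_poly, haploblocks = haploblocks,
                 coupled_pairs = coupled_pairs, seed = as.integer(seed)),
            class = "synth_spec")
}

# Neutral-like minor-allele-count sampler, truncated at singletons.
sample_mac <- function(n_sites, n) {
  ks <- 2:(n %/% 2)
  w <- 1 / ks + 1 / (n - ks)
  ks[sample.int(length(ks), n_sites, replace = TRUE, prob = w / sum(w))]
}

#' Generate a synthetic haploid population with known ground truth
#'
#' Background SNPs are placed independently per site; within each planted
#' haploblock genotypes are assigned to two haplotypes at the stated
#' frequency and all block SNPs are fully coupled to haplotype identity
#' (minus optional noise); planted nonsynonymous pairs are realized as
#' coupled minor alleles hitting a target r-squared.  An infeasible
#' r-squared target for the given MAF raises an error stating the feasible
#' bound.
#'
#' @param spec A [synth_spec()].
#' @return List with `alignment` (a [haploid_alignment()]), `annotation`
#'   (a [gene_annotation()] table), and `truth` (list recording every
#'   planted feature: `background` positions, `haploblocks`,
#'   `coupled_pairs` with realized carrier sets, `contig_length`, `spec`).
#' @export
generate_population <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_genotypes
  L <- spec$contig_length
  ref <- sample(NUCLEOTIDES, L, replace = TRUE)
  aln <- matrix(rep(ref, each = n), nrow = n)
  gene_starts <- spec$first_gene_start +
    (seq_len(spec$n_genes) - 1L) * spec$gene_spacing
  gene_len <- 3L * spec$gene_length_codons
  ann <- do.call(rbind, lapply(seq_len(spec$n_genes), function(i) {
    gene_annotation(sprintf("gene%02d", i), "synth1", "+",
                    gene_starts[i], gene_starts[i] + gene_len)
  }))
  class(ann) <- c("gene_annotation", "data.frame")

  blocked <- rep(FALSE, L)
  blocks_truth <- list()
  for (hb in spec$haploblocks) {
    noise <- hb$noise %||% 0
    span <- seq(hb$start, hb$end - 1L)
    blocked[span + 1L] <- TRUE
    carriers <- sample.int(n, max(1L, round(hb$freq * n)))
    sites <- sort(sample(span, hb$n_snps))
    for (p in sites) {
      alt <- sample(setdiff(NUCLEOTIDES, ref[p + 1L]), 1L)
      who <- carriers
      if (noise > 0) {
        flip <- runif(n) < noise
        who <- union(setdiff(carriers, which(flip)),
                     setdiff(which(flip), carriers))
      }
      aln[who, p + 1L] <- alt
    }
    blocks_truth[[length(blocks_truth) + 1L]] <- data.frame(
      start = hb$start, end = hb$end, freq = length(carriers) / n,
      n_snps = hb$n_snps, stringsAsFactors = FALSE)
  }

  pairs_truth <- list()
  reserved <- rep(FALSE, L)
  for (cp in spec$coupled_pairs) {
    gi <- cp$gene
    r2 <- cp$r2 %||% 1
    k <- max(2L, round(cp$maf * n))
    p <- k / n
    p11_max <- p  # full coupling
    p11_target <- p^2 + sqrt(r2) * p * (1 - p)
    if (p11_target > p11_max + 1e-9) {
      stop(sprintf(
        "infeasible r2 target %.3f at MAF %.3f: feasible r2 <= %.3f",
        r2, p, ((p11_max - p^2) / (p * (1 - p)))^2))
    }
    k11 <- round(n * p11_target)
    # second codon positions of non-stop codons are always nonsynonymous
    # substitutions (TAA <-> TGA is the lone synonymous second-position pair)
    codon_starts <- gene_starts[gi] + 3L * (0:(spec$gene_length_codons - 1L))
    ref_codons <- vapply(codon_starts, function(s) {
      paste(ref[s + 1:3], collapse = "")
    }, character(1))
    not_stop <- translate_codon(ref_codons) != "*"
    codon2 <- codon_starts[not_stop] + 1L
    avail <- codon2[!reserved[codon2 + 1L] & !blocked[codon2 + 1L]]
    pos <- sort(sample(avail, 2L * cp$n_pairs))
    reserved[pos + 1L] <- TRUE
    for (q in seq_len(cp$n_pairs)) {
      pa <- pos[2L * q - 1L]; pb <- pos[2L * q]
      ca <- sample.int(n, k)
      cb <- c(sample(ca, k11), sample(setdiff(seq_len(n), ca), k - k11))
      for (set in list(list(pos = pa, who = ca), list(pos = pb, who = cb))) {
        alt <- sample(setdiff(NUCLEOTIDES, ref[set$pos + 1L]), 1L)
        aln[set$who, set$pos + 1L] <- alt
      }
      pairs_truth[[length(pairs_truth) + 1L]] <- data.frame(
        gene_id = sprintf("gene%02d", gi), pos_i = pa, pos_j = pb,
        target_r2 = r2, maf = k / n, stringsAsFactors = FALSE)
    }
  }

  free <- which(!blocked & !reserved) - 1L
  is_poly <- free[runif(length(free)) < spec$p_poly]
  if (length(is_poly)) {
    macs <- sample_mac(length(is_poly), n)
    for (idx in seq_along(is_poly)) {
      p <- is_poly[idx]
      alt <- sample(setdiff(NUCLEOTIDES, ref[p + 1L]), 1L)
      aln[sample.int(n, macs[idx]), p + 1L] <- alt
    }
  }

  rownames(aln) <- sprintf("synth_g%03d", seq_len(n))
  truth <- list(
    background = data.frame(pos = is_poly,
                            mac = if (length(is_poly)) macs else integer(0)),
    haploblocks = if (length(blocks_truth)) do.call(rbind, blocks_truth) else
      data.frame(start = integer(0), end = integer(0), freq = numeric(0),
                 n_snps = integer(0)),
    coupled_pairs = if (length(pairs_truth)) do.call(rbind, pairs_truth) else
      data.frame(gene_id = character(0), pos_i = integer(0),
                 pos_j = integer(0), target_r2 = numeric(0), maf = numeric(0)),
    contig_length = L, spec = spec)
  list(alignment = haploid_alignment(aln, contig_id = "synth1"),
       annotation = ann, truth = truth)
}

#' Generate a two-population synthetic pair with shared SNPs
#'
#' Two populations on the same reference, sharing a fraction of background
#' SNP positions (same major/minor alleles, independent carrier sets), with
#' optional coupled nonsynonymous pairs planted at the same positions in
#' both populations to emulate shared epistatic selection.
#'
#' @param spec A [synth_spec()] used for both populations.
#' @param share_fraction Fraction of population-A background SNP positions
#'   reused in population B (default 0.25).
#' @param shared_coupled Optional list as `coupled_pairs` in [synth_spec()];
#'   these pairs are planted at identical positions and alleles in both
#'   populations (carrier sets independent, coupling preserved).
#' @param seed RNG seed.
#' @return List with `pop_a`, `pop_b` (each as [generate_population()]) and
#'   `shared_positions`.
#' @export
generate_population_pair <- function(spec, share_fraction = 0.25,
                                     shared_coupled = list(), seed = 1L) {
  spec_a <- spec; spec_a$seed <- seed
  spec_a$coupled_pairs <- c(spec$coupled_pairs, shared_coupled)
  pop_a <- generate_population(spec_a)
  set.seed(seed + 1L)
  n <- spec$n_genotypes
  L <- spec$contig_length
  ref <- vapply(seq_len(L), function(p) {
    consensus_base(pop_a$alignment, p - 1L)
  }, character(1))
  aln_b <- matrix(rep(ref, each = n), nrow = n)
  shared_pos <- sort(sample(pop_a$truth$background$pos,
                            round(share_fraction *
                                    nrow(pop_a$truth$background))))
  # shared positions: same alleles, independent carriers
  snps_a <- extract_snps(pop_a$alignment, drop_singletons = FALSE)
  for (p in shared_pos) {
    row <- which(snps_a$snps$pos == p)
    if (!length(row)) next
    alt <- snps_a$snps$minor[row[1]]
    if (alt == ref[p + 1L]) alt <- snps_a$snps$major[row[1]]
    mac <- sample_mac(1L, n)
    aln_b[sample.int(n, mac), p + 1L] <- alt
  }
  # population-B private background; planted pair positions are protected
  taken <- rep(FALSE, L)
  taken[shared_pos + 1L] <- TRUE
  tp_all <- pop_a$truth$coupled_pairs
  if (nrow(tp_all)) taken[c(tp_all$pos_i, tp_all$pos_j) + 1L] <- TRUE
  priv <- which(!taken) - 1L
  priv <- priv[runif(length(priv)) < spec$p_poly * 0.5]
  for (p in priv) {
    alt <- sample(setdiff(NUCLEOTIDES, ref[p + 1L]), 1L)
    aln_b[sample.int(n, sample_mac(1L, n)), p + 1L] <- alt
  }
  # shared coupled pairs: replant at identical positions/alleles in B
  tp <- pop_a$truth$coupled_pairs
  if (length(shared_coupled) && nrow(tp)) {
    shared_genes <- vapply(shared_coupled, function(cp)
      sprintf("gene%02d", cp$gene), character(1))
    tp <- tp[tp$gene_id %in% shared_genes, , drop = FALSE]
    for (q in seq_len(nrow(tp))) {
      k <- max(2L, round(tp$maf[q] * n))
      ca <- sample.int(n, k)
      for (p in c(tp$pos_i[q], tp$pos_j[q])) {
        row <- which(snps_a$snps$pos == p)
        alt <- snps_a$snps$minor[row[1]]
        if (alt == ref[p + 1L]) alt <- snps_a$snps$major[row[1]]
        aln_b[ca, p + 1L] <- alt
      }
    }
  }
  rownames(aln_b) <- sprintf("synthB_g%03d", seq_len(n))
  pop_b <- list(alignment = haploid_alignment(aln_b, contig_id = "synth1"),
                annotation = pop_a$annotation,
                truth = list(shared_positions = shared_pos,
                             shared_coupled = tp,
                             contig_length = L))
  list(pop_a = pop_a, pop_b = pop_b, shared_positions = shared_pos)
}

#' Generate a segmented contact map with a matching residue map
#'
#' Residues are partitioned into consecutive segments; within-segment
#' distances are drawn below the contact cutoff margin and between-segment
#' distances above it, emulating compact structural units.  Aligning
#' planted LD segments (e.g. haploblocks spanning the same codon ranges)
#' with these segments produces genes whose LD patterns mirror their
#' structure.
#'
#' @param n_residues Number of residues.
#' @param segments List of residue index vectors (1-based) partitioning
#'   `1:n_residues`; default two equal halves.
#' @param gene_id Gene the residue map points at.
#' @param within_range,between_range Uniform sampling ranges (Angstroms) for
#'   within- and between-segment distances (defaults keep them strictly
#'   below / above 10 Angstroms).
#' @param protein_id Protein identifier.
#' @param seed RNG seed.
#' @return List with `contact_map` (a `contact_map`), `residue_map`
#'   (data.frame `gene_id`, `codon_id`, `residue`; codon i maps to residue
#'   i+1), and `segments`.
#' @export
generate_contact_map <- function(n_residues, segments = NULL,
                                 gene_id = "gene01",
                                 within_range = c(4, 9),
                                 between_range = c(15, 40),
                                 protein_id = "synth_protein", seed = 1L) {
  set.seed(seed)
  if (is.null(segments)) {
    half <- n_residues %/% 2L
    segments <- list(seq_len(half), seq(half + 1L, n_residues))
  }
  seg_of <- integer(n_residues)
  for (s in seq_along(segments)) seg_of[segments[[s]]] <- s
  m <- matrix(NA_real_, n_residues, n_residues)
  for (i in seq_len(n_residues - 1L)) {
    for (j in seq(i + 1L, n_residues)) {
      rng <- if (seg_of[i] == seg_of[j]) within_range else between_range
      m[i, j] <- m[j, i] <- runif(1, rng[1], rng[2])
    }
  }
  diag(m) <- 0
  list(contact_map = structure(list(protein_id = protein_id,
                                    n_residues = n_residues, distances = m),
                               class = "contact_map"),
       residue_map = data.frame(gene_id = gene_id,
                                codon_id = seq_len(n_residues) - 1L,
                                residue = seq_len(n_residues),
                                stringsAsFactors = FALSE),
       segments = segments)
}

#' Write a contact map as TSV
#' @param cm A `contact_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contact_map <- function(cm, path) {
  idx <- which(upper.tri(cm$distances) & !is.na(cm$distances), arr.ind = TRUE)
  df <- data.frame(protein_id = cm$protein_id, res_i = idx[, 1],
                   res_j = idx[, 2],
                   dist = cm$distances[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
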