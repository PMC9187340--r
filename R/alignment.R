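# Haploid multi-genotype alignments: construction, FASTA I/O, diversity.
# Coordinates are 0-based half-open throughout the package; GFF3 input is
# converted from 1-based closed at the boundary.

#' Construct a haploid alignment
#'
#' @param seqs Character vector of equal-length aligned sequences (one per
#'   haploid genotype), or a character matrix of single symbols with one row
#'   per genotype.
#' @param genotype_ids Unique genotype identifiers; defaults to the names of
#'   `seqs`.
#' @param contig_id Contig/scaffold name the alignment projects onto.
#' @return An object of class `haploid_alignment`: a list with `contig_id`,
#'   `genotype_ids`, and `seq`, an `n x L` character matrix over
#'   A, C, G, T, `-`, N.  Lowercase input is uppercased; any other symbol is
#'   mapped to N.
#' @export
haploid_alignment <- function(seqs, genotype_ids = NULL, contig_id = "contig") {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(genotype_ids)) genotype_ids <- rownames(mat)
  } else {
    if (is.null(genotype_ids)) genotype_ids <- names(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != lens[1])[1]
      stop(sprintf(
        "alignment records have unequal lengths: record %d ('%s') has %d, expected %d",
        bad, genotype_ids[bad] %||% as.character(bad), lens[bad], lens[1]))
    }
    mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  }
  if (nrow(mat) < 2L) stop("a haploid alignment needs at least 2 genotypes")
  if (is.null(genotype_ids)) genotype_ids <- paste0("g", seq_len(nrow(mat)))
  if (anyDuplicated(genotype_ids)) stop("genotype_ids must be unique")
  mat <- toupper(mat)
  mat[!(mat %in% c("A", "C", "G", "T", "-", "N"))] <- "N"
  dimnames(mat) <- list(genotype_ids, NULL)
  structure(list(contig_id = contig_id,
                 genotype_ids = genotype_ids,
                 seq = mat),
            class = "haploid_alignment")
}

#' @export
print.haploid_alignment <- function(x, ...) {
  cat(sprintf("haploid_alignment: %d genotypes x %d positions on '%s'\n",
              nrow(x$seq), ncol(x$seq), x$contig_id))
  invisible(x)
}

#' Number of genotypes / alignment length
#' @param aln A `haploid_alignment`.
#' @return Integer.
#' @export
n_genotypes <- function(aln) nrow(aln$seq)

#' @rdname n_genotypes
#' @export
alignment_length <- function(aln) ncol(aln$seq)

#' Read a haploid multi-FASTA alignment
#'
#' All records must have equal length; rows are kept in file order, symbols
#' are uppercased and anything outside A/C/G/T/-/N becomes N.
#'
#' @param path Path to an aligned multi-FASTA file.
#' @param contig_id Contig name; defaults to the file name without extension.
#' @return A [haploid_alignment()].
#' @export
read_haploid_alignment <- function(path, contig_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("alignment must contain at least 2 records")
  w <- Biostrings::width(set)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1])[1]
    stop(sprintf(
      "unequal record lengths in '%s': record %d ('%s') has length %d, expected %d",
      path, bad, names(set)[bad], w[bad], w[1]))
  }
  if (is.null(contig_id)) {
    contig_id <- sub("\\.[^.]*$", "", basename(path))
  }
  haploid_alignment(as.character(set), genotype_ids = names(set),
                    contig_id = contig_id)
}

#' Write a haploid alignment as multi-FASTA
#' @param aln A `haploid_alignment`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_haploid_alignment <- function(aln, path) {
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- aln$genotype_ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Nucleotide diversity of a haploid alignment
#'
#' Mean over all unordered genotype pairs of the fraction of differing
#' positions among compared positions.  Columns containing a gap or N in any
#' genotype are excluded from both numerator and denominator, mirroring a
#' gap-free-column analysis convention.
#'
#' @param aln A `haploid_alignment`.
#' @param positions Optional 0-based positions to restrict to (e.g. a site
#'   class); applied before the gap-free filter.
#' @return Mean pairwise difference frequency (a fraction).
#' @export
nucleotide_diversity <- function(aln, positions = NULL) {
  mat <- aln$seq
  if (!is.null(positions)) mat <- mat[, positions + 1L, drop = FALSE]
  ok <- colSums(mat == "-" | mat == "N") == 0L
  mat <- mat[, ok, drop = FALSE]
  if (ncol(mat) == 0L) {
    undefined_result("nucleotide diversity undefined: no comparable (gap-free) columns")
  }
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      tot <- tot + mean(mat[i, ] != mat[j, ])
    }
  }
  tot / (n * (n - 1L) / 2L)
}
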