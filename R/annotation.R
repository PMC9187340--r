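# Gene annotations as an exon-level table (one row per exon), 0-based
# half-open internally.  GFF3 is read/written via rtracklayer.

#' Build a gene annotation table
#'
#' @param gene_id Gene identifier.
#' @param contig_id Contig the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends 0-based half-open exon intervals, in genomic order.
#' @param phase Codon frame of the first coding exon (bases to skip at the 5'
#'   end of the coding sequence), default 0.
#' @return A data.frame of class `gene_annotation` with one row per exon and
#'   columns `gene_id`, `contig`, `strand`, `start`, `end`, `exon_index`,
#'   `phase`.  Exon indices run in transcription order.  Multiple genes are
#'   combined with `rbind()`.
#' @export
gene_annotation <- function(gene_id, contig_id, strand, starts, ends,
                            phase = 0L) {
  stopifnot(length(starts) == length(ends), strand %in% c("+", "-"))
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  if (any(ends <= starts)) stop("exon end must exceed start (0-based half-open)")
  if (length(starts) > 1L && any(starts[-1] < ends[-length(ends)])) {
    stop("exons of gene '", gene_id, "' overlap")
  }
  exon_index <- if (strand == "+") seq_along(starts) else rev(seq_along(starts))
  cds_len <- sum(ends - starts) - phase
  if (cds_len %% 3L != 0L) {
    warning("coding length of gene '", gene_id,
            "' is not a multiple of 3 after phase adjustment")
  }
  structure(data.frame(gene_id = gene_id, contig = contig_id, strand = strand,
                       start = starts, end = ends, exon_index = exon_index,
                       phase = as.integer(phase), stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

#' Read gene annotations from GFF3
#'
#' CDS features (falling back to exon features when no CDS is present) are
#' grouped by their `Parent` (or `ID`/`gene_id`) attribute.  1-based closed
#' GFF coordinates are converted to 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_annotation` data.frame (see [gene_annotation()]).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  keep <- type == "CDS"
  if (!any(keep)) keep <- type == "exon"
  if (!any(keep)) stop("no CDS or exon features in ", path)
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  gid <- NULL
  for (field in c("gene_id", "Parent", "ID")) {
    if (field %in% names(md)) {
      v <- md[[field]]
      if (methods::is(v, "CharacterList")) {
        v <- vapply(v, function(x) if (length(x)) x[[1]] else NA_character_,
                    character(1))
      }
      v <- as.character(v)
      if (!all(is.na(v))) { gid <- v; break }
    }
  }
  if (is.null(gid)) stop("cannot determine gene ids in ", path)
  parts <- split(seq_along(gr), gid)
  out <- lapply(names(parts), function(g) {
    idx <- parts[[g]]
    sub <- gr[idx]
    ph <- if ("phase" %in% names(md)) suppressWarnings(as.integer(md$phase[idx])) else NA_integer_
    strand <- as.character(BiocGenerics::strand(sub))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    o <- order(BiocGenerics::start(sub))
    first <- if (strand == "+") o[1] else o[length(o)]
    phase <- ph[first]
    if (is.na(phase)) phase <- 0L
    gene_annotation(g, as.character(GenomeInfoDb::seqnames(sub))[1], strand,
                    starts = BiocGenerics::start(sub) - 1L,
                    ends = BiocGenerics::end(sub), phase = phase)
  })
  ann <- do.call(rbind, out)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write gene annotations as GFF3
#' @param ann A `gene_annotation` data.frame.
#' @param path Output path.
#' @param contig_lengths Optional named vector for the sequence-region header.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(ann, path, contig_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  gr$type <- "CDS"
  gr$ID <- paste0(ann$gene_id, ".cds", ann$exon_index)
  gr$Parent <- ann$gene_id
  # per-exon phase: bases to skip so translation lands on a codon boundary
  phase <- integer(nrow(ann))
  for (g in unique(ann$gene_id)) {
    rows <- which(ann$gene_id == g)
    rows <- rows[order(ann$exon_index[rows])]
    lens <- (ann$end - ann$start)[rows]
    before <- cumsum(c(0L, lens[-length(lens)]))
    p1 <- ann$phase[rows[1]]
    phase[rows] <- (3L - ((before - p1) %% 3L)) %% 3L
    phase[rows[1]] <- p1
  }
  gr$phase <- phase
  if (!is.null(contig_lengths)) {
    GenomeInfoDb::seqlengths(gr) <- contig_lengths[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Coding-order genomic positions (0-based) of a gene's CDS after phase
# trimming, plus the strand.  For "-" genes positions run 3'->5' genomically,
# i.e. in translation order.
gene_cds_positions <- function(ann, gene) {
  rows <- ann[ann$gene_id == gene, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown gene: ", gene)
  rows <- rows[order(rows$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(rows)),
                       function(i) seq(rows$start[i], rows$end[i] - 1L)),
                use.names = FALSE)
  strand <- rows$strand[1]
  if (strand == "-") pos <- rev(pos)
  phase <- rows$phase[1]
  if (phase > 0L) pos <- pos[-seq_len(phase)]
  pos <- pos[seq_len(3L * (length(pos) %/% 3L))]
  list(positions = pos, strand = strand, contig = rows$contig[1])
}
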