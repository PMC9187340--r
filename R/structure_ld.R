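# LD vs protein structure: contact maps, residue-pair LD tables, the
# distance-matched permutation test, and per-gene contingency tests.

#' Load a residue-residue contact map from TSV
#'
#' The TSV has columns `res_i`, `res_j`, `dist` (Angstroms; an optional
#' `protein_id` column is honored) with 1-based residue indices.  Entries
#' are symmetrized; conflicting duplicate entries raise an error naming the
#' pair.  Missing pairs stay `NA` (unknown distance).
#'
#' @param source File path or data.frame.
#' @param protein_id Protein identifier (default from the table or
#'   `"protein"`).
#' @param n_residues Matrix dimension; default the largest index seen.
#' @return Object of class `contact_map`: list with `protein_id`,
#'   `n_residues`, and `distances`, a symmetric matrix in Angstroms with 0
#'   diagonal.
#' @export
load_contact_map <- function(source, protein_id = NULL, n_residues = NULL) {
  df <- if (is.character(source)) read.delim(source, stringsAsFactors = FALSE)
        else as.data.frame(source)
  stopifnot(all(c("res_i", "res_j", "dist") %in% names(df)))
  if (is.null(protein_id)) {
    protein_id <- if ("protein_id" %in% names(df)) df$protein_id[1] else "protein"
  }
  if (is.null(n_residues)) n_residues <- max(df$res_i, df$res_j)
  m <- matrix(NA_real_, n_residues, n_residues)
  for (k in seq_len(nrow(df))) {
    i <- df$res_i[k]; j <- df$res_j[k]; d <- df$dist[k]
    for (cell in list(c(i, j), c(j, i))) {
      cur <- m[cell[1], cell[2]]
      if (!is.na(cur) && abs(cur - d) > 1e-6) {
        stop(sprintf("conflicting distances for residue pair (%d, %d): %g vs %g",
                     i, j, cur, d))
      }
      m[cell[1], cell[2]] <- d
    }
  }
  diag(m) <- 0
  structure(list(protein_id = protein_id, n_residues = n_residues,
                 distances = m),
            class = "contact_map")
}

#' Contact map from atomic coordinates (PDB)
#'
#' Inter-residue distance is the minimum over heavy-atom pairs by default,
#' or the C-alpha/C-alpha distance.  Requires the bio3d package.
#'
#' @param path Path to a PDB file.
#' @param mode `"min_heavy_atom"` (default) or `"ca"`.
#' @param chain Optional chain identifier to restrict to.
#' @param protein_id Protein identifier (default: file name).
#' @return A `contact_map` (residues renumbered 1..n in sequence order).
#' @export
contact_map_from_pdb <- function(path, mode = c("min_heavy_atom", "ca"),
                                 chain = NULL, protein_id = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("contact_map_from_pdb() requires the bio3d package")
  }
  mode <- match.arg(mode)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (mode == "ca") {
    at <- at[at$elety == "CA", , drop = FALSE]
  } else {
    at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  }
  resnos <- sort(unique(at$resno))
  n <- length(resnos)
  m <- matrix(NA_real_, n, n)
  coords <- lapply(resnos, function(r) {
    as.matrix(at[at$resno == r, c("x", "y", "z")])
  })
  for (i in seq_len(n)) {
    m[i, i] <- 0
    for (j in seq_len(n)[-seq_len(i)]) {
      dd <- sqrt(outer(rowSums(coords[[i]]^2), rowSums(coords[[j]]^2), "+") -
                   2 * coords[[i]] %*% t(coords[[j]]))
      m[i, j] <- m[j, i] <- min(dd)
    }
  }
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(protein_id = protein_id, n_residues = n, distances = m),
            class = "contact_map")
}

#' Residue-pair LD table for one protein
#'
#' Joins coding SNPs to structure residues through a residue map
#' (`gene_id`, `codon_id` 0-based, `residue` 1-based) and emits, separately
#' for nonsynonymous and synonymous SNPs, every unordered residue pair with
#' at least one mapped SNP on each side.  The pair's r-squared is the mean
#' over the SNP cross-pairs of the two codons (usually a single pair).
#'
#' @param snps A classified [snp_table()].
#' @param residue_map data.frame with `gene_id`, `codon_id`, `residue`.
#' @param contact_map A [load_contact_map()] result.
#' @param gene_id Gene to analyse (default: the single gene in the map).
#' @return data.frame of class `residue_pair_ld`: `protein_id`, `res_i`,
#'   `res_j`, `aa_distance`, `physical_distance` (`NA` when unknown), `r2`,
#'   `class_pair`, `n_snp_pairs`.
#' @export
residue_pair_ld <- function(snps, residue_map, contact_map, gene_id = NULL) {
  if (is.null(gene_id)) {
    gene_id <- unique(residue_map$gene_id)
    stopifnot(length(gene_id) == 1L)
  }
  rm <- residue_map[residue_map$gene_id == gene_id, , drop = FALSE]
  df <- snps$snps
  out <- list()
  for (cls in c("nonsynonymous", "synonymous")) {
    sel <- which(!is.na(df$gene_id) & df$gene_id == gene_id &
                   df$class == cls & !df$singleton)
    if (length(sel) < 2L) next
    res <- rm$residue[match(df$codon_id[sel], rm$codon_id)]
    ok <- !is.na(res)
    sel <- sel[ok]; res <- res[ok]
    residues <- sort(unique(res))
    if (length(residues) < 2L) next
    by_res <- split(sel, res)
    cp <- if (cls == "nonsynonymous") "nonsyn-nonsyn" else "syn-syn"
    for (ii in seq_len(length(residues) - 1L)) {
      for (jj in seq(ii + 1L, length(residues))) {
        ri <- residues[ii]; rj <- residues[jj]
        si <- by_res[[as.character(ri)]]
        sj <- by_res[[as.character(rj)]]
        grid <- expand.grid(a = si, b = sj)
        vals <- pair_ld_values(snps$states, grid$a, grid$b)
        phys <- if (ri <= contact_map$n_residues && rj <= contact_map$n_residues)
          contact_map$distances[ri, rj] else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          protein_id = contact_map$protein_id, res_i = ri, res_j = rj,
          aa_distance = rj - ri, physical_distance = phys,
          r2 = mean(vals$r2), class_pair = cp, n_snp_pairs = nrow(grid),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(0), res_i = integer(0),
               res_j = integer(0), aa_distance = integer(0),
               physical_distance = numeric(0), r2 = numeric(0),
               class_pair = character(0), n_snp_pairs = integer(0),
               stringsAsFactors = FALSE)
  class(res) <- c("residue_pair_ld", "data.frame")
  res
}

#' Distance-matched permutation test for contact-associated LD
#'
#' Tests whether mean r-squared over physically close residue pairs (within
#' `contact_cutoff` Angstroms) exceeds that over distant pairs, controlling
#' for sequence distance: each close pair is replaced, in every permutation
#' replicate, by a uniformly drawn distant pair (`physical_distance >
#' cutoff`; unknown distances are excluded from both sets) at the same
#' amino-acid distance, falling back to the nearest available aa distance
#' within +/-2 when the exact stratum is empty.  Close pairs with no
#' matchable distant pair are dropped from both the observed statistic and
#' the null.  Pairs closer than `min_aa_separation` residues are excluded
#' up front.  The test runs separately for nonsyn-nonsyn and syn-syn pairs.
#'
#' @param pairs A [residue_pair_ld()] table (may pool several proteins).
#' @param contact_cutoff Contact distance in Angstroms (default 10).
#' @param min_aa_separation Minimum residue separation (default 5).
#' @param n_perm Number of permutation replicates (default 1000).
#' @param seed RNG seed.
#' @return data.frame with one row per class: `class_pair`, `n_close`,
#'   `n_dropped`, `observed` (mean r2 over close pairs), `null_mean`, `p`
#'   (`(1 + #{null >= observed}) / (n_perm + 1)`), `testable`.
#' @export
contact_ld_permutation_test <- function(pairs, contact_cutoff = 10,
                                        min_aa_separation = 5L,
                                        n_perm = 1000L, seed = 1L) {
  set.seed(seed)
  out <- lapply(c("nonsyn-nonsyn", "syn-syn"), function(cp) {
    sub <- pairs[pairs$class_pair == cp &
                   pairs$aa_distance >= min_aa_separation &
                   !is.na(pairs$r2), , drop = FALSE]
    row <- data.frame(class_pair = cp, n_close = 0L, n_dropped = 0L,
                      observed = NA_real_, null_mean = NA_real_,
                      p = NA_real_, testable = FALSE,
                      stringsAsFactors = FALSE)
    known <- !is.na(sub$physical_distance)
    close <- sub[known & sub$physical_distance <= contact_cutoff, , drop = FALSE]
    far <- sub[known & sub$physical_distance > contact_cutoff, , drop = FALSE]
    if (nrow(close) == 0L || nrow(far) == 0L) return(row)
    far_by_aa <- split(seq_len(nrow(far)), far$aa_distance)
    cand <- lapply(close$aa_distance, function(d) {
      for (tol in 0:2) {
        hits <- unlist(far_by_aa[as.character(seq(d - tol, d + tol))],
                       use.names = FALSE)
        if (length(hits)) return(hits)
      }
      integer(0)
    })
    keep <- lengths(cand) > 0L
    row$n_dropped <- sum(!keep)
    close <- close[keep, , drop = FALSE]
    cand <- cand[keep]
    if (nrow(close) == 0L) return(row)
    obs <- mean(close$r2)
    null_means <- vapply(seq_len(n_perm), function(b) {
      mean(vapply(cand, function(cs) {
        far$r2[cs[sample.int(length(cs), 1L)]]
      }, numeric(1)))
    }, numeric(1))
    row$n_close <- nrow(close)
    row$observed <- obs
    row$null_mean <- mean(null_means)
    row$p <- (1 + sum(null_means >= obs - 1e-12)) / (n_perm + 1)
    row$testable <- TRUE
    row
  })
  do.call(rbind, out)
}

#' Per-gene contact/LD contingency test
#'
#' Within the amino-acid distance band `aa_band`, residue pairs are cross
#' classified as physically close (within `contact_cutoff`) vs far and high
#' vs low LD (high: r2 at or above the per-gene `high_ld_quantile` of
#' banded pairs).  Reports the odds ratio (Haldane 0.5 correction when any
#' cell is empty) and the chi-square p-value on the raw counts.  Genes with
#' fewer than `min_close` close pairs, or without two distinct r2 values,
#' are flagged ineligible.
#'
#' @param pairs A [residue_pair_ld()] table for one protein.
#' @param contact_cutoff Contact distance in Angstroms (default 10).
#' @param aa_band Inclusive amino-acid distance band (default `c(30, 100)`).
#' @param high_ld_quantile Per-gene LD quantile defining "high" (default 0.9).
#' @param min_close Minimum close-pair count (default 5).
#' @param class_pair Which class to test (default `"nonsyn-nonsyn"`; use
#'   `NULL` to pool all classes).
#' @return One-row data.frame of class `gene_contact_test`: `protein_id`,
#'   the four cell counts (`close_high`, `close_low`, `far_high`,
#'   `far_low`), `odds_ratio`, `chi2_p`, `eligible`.
#' @export
gene_contact_association <- function(pairs, contact_cutoff = 10,
                                     aa_band = c(30L, 100L),
                                     high_ld_quantile = 0.9, min_close = 5L,
                                     class_pair = "nonsyn-nonsyn") {
  if (!is.null(class_pair)) {
    pairs <- pairs[pairs$class_pair %in% class_pair, , drop = FALSE]
  }
  sub <- pairs[pairs$aa_distance >= aa_band[1] &
                 pairs$aa_distance <= aa_band[2] &
                 !is.na(pairs$physical_distance) & !is.na(pairs$r2), ,
               drop = FALSE]
  pid <- if (nrow(pairs)) pairs$protein_id[1] else NA_character_
  row <- data.frame(protein_id = pid, close_high = NA_integer_,
                    close_low = NA_integer_, far_high = NA_integer_,
                    far_low = NA_integer_, odds_ratio = NA_real_,
                    chi2_p = NA_real_, eligible = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(sub) == 0L || length(unique(sub$r2)) < 2L) return(row)
  thr <- quantile(sub$r2, high_ld_quantile, names = FALSE)
  close <- sub$physical_distance <= contact_cutoff
  high <- sub$r2 >= thr
  a <- sum(close & high); b <- sum(close & !high)
  c_ <- sum(!close & high); d <- sum(!close & !high)
  row$close_high <- a; row$close_low <- b
  row$far_high <- c_; row$far_low <- d
  if (a + b < min_close) return(row)
  cells <- c(a, b, c_, d)
  if (any(cells == 0L)) cells <- cells + 0.5
  row$odds_ratio <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    row$chi2_p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  row$eligible <- TRUE
  row
}

#' Benjamini-Hochberg adjustment over per-gene contact tests
#'
#' Step-up BH correction over all eligible genes of one population.
#'
#' @param tests data.frame of [gene_contact_association()] rows.
#' @param alpha FDR level (default 0.05).
#' @return The input with `bh_q` and `significant` (`bh_q <= alpha`) added;
#'   ineligible rows keep `NA`.
#' @export
fdr_adjust <- function(tests, alpha = 0.05) {
  stopifnot(nrow(tests) >= 1L)
  tests$bh_q <- NA_real_
  ok <- tests$eligible & !is.na(tests$chi2_p)
  tests$bh_q[ok] <- p.adjust(tests$chi2_p[ok], method = "BH")
  tests$significant <- !is.na(tests$bh_q) & tests$bh_q <= alpha
  tests
}
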