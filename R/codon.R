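# Genetic-code utilities shared by SNP classification and pn/ps counting.
# The code table itself comes from Biostrings; everything here is bookkeeping
# around single-nucleotide substitutions within codons.

NUCLEOTIDES <- c("A", "C", "G", "T")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(ifelse(is.na(aa), NA_character_, aa))
}

complement_base <- function(x) chartr("ACGTN-", "TGCAN-", x)

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN-", "TGCAN-", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Synonymous/nonsynonymous site weights of a codon
#'
#' Enumerates all nine single-nucleotide changes of a codon and apportions
#' fractional synonymous and nonsynonymous site counts (NG86-style: each
#' codon position contributes 1/3 site per possible change).  Changes to or
#' from a stop codon count as nonsynonymous.
#'
#' @param codon Character vector of 3-letter DNA codons.
#' @return A two-column matrix with columns `syn` and `nonsyn`; each row sums
#'   to 3.  Rows are `NA` for codons containing non-ACGT symbols.
#' @examples
#' codon_site_weights("TTT")  # 1/3 synonymous, 8/3 nonsynonymous
#' @export
codon_site_weights <- function(codon) {
  codon <- toupper(codon)
  out <- matrix(NA_real_, nrow = length(codon), ncol = 2,
                dimnames = list(codon, c("syn", "nonsyn")))
  tab <- codon_weight_table()
  hit <- match(codon, rownames(tab))
  ok <- !is.na(hit)
  out[ok, ] <- tab[hit[ok], ]
  out
}

# Precomputed 64-codon weight table, built once per session.
codon_weight_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- names(Biostrings::GENETIC_CODE)
    tab <- t(vapply(codons, function(cd) {
      aa <- translate_codon(cd)
      nt <- strsplit(cd, "")[[1]]
      syn <- 0
      for (p in 1:3) {
        for (alt in setdiff(NUCLEOTIDES, nt[p])) {
          mut <- nt
          mut[p] <- alt
          if (identical(translate_codon(paste(mut, collapse = "")), aa)) {
            syn <- syn + 1 / 3
          }
        }
      }
      c(syn = syn, nonsyn = 3 - syn)
    }, numeric(2)))
    cache <<- tab
    tab
  }
})
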