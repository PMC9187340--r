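# Haploblock detection: sliding-window LD scan, lognormal heavy-tail
# threshold, block calling, per-block haplotype statistics, and
# cross-population overlap.

#' Sliding-window LD scan
#'
#' Windows of `window_len` nucleotides on a fixed grid with step `step`;
#' each valid window's `mean_r2` is the mean r-squared over all unordered
#' pairs of non-singleton SNPs lying fully inside the window.  Windows with
#' fewer than `min_snps` SNPs are invalid and carry no mean.
#'
#' @param snps A [snp_table()]; singleton SNPs are ignored.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param window_len Window length in nucleotides (default 250).
#' @param step Grid step in nucleotides (default 20).
#' @param min_snps Minimum SNPs per valid window (default 10).
#' @return data.frame of class `window_track` with `contig`, `start`, `end`,
#'   `n_snps`, `n_pairs`, `mean_r2`, `valid`; attributes record the scan
#'   parameters and contig lengths.  Contigs shorter than `window_len`
#'   contribute no windows.
#' @export
window_ld_scan <- function(snps, contig_lengths, window_len = 250L,
                           step = 20L, min_snps = 10L) {
  stopifnot(!is.null(names(contig_lengths)))
  df <- snps$snps
  keep <- which(!df$singleton)
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    if (len < window_len) return(NULL)
    starts <- seq(0L, len - window_len, by = step)
    k_max <- length(starts) - 1L
    idx <- keep[df$contig[keep] == ctg]
    pos <- sort(df$pos[idx])
    ord <- idx[order(df$pos[idx])]
    n_snps <- findInterval(starts + window_len - 1L, pos) -
      findInterval(starts - 1L, pos)
    sum_r2 <- numeric(length(starts))
    n_pairs <- integer(length(starts))
    m <- length(pos)
    if (m >= 2L) {
      hi <- findInterval(pos + window_len - 1L, pos)
      counts <- pmax(hi - seq_len(m), 0L)
      if (sum(counts) > 0L) {
        a <- rep(seq_len(m), counts)
        b <- sequence(counts, from = seq_len(m) + 1L)
        ld <- pair_ld_values(snps$states, ord[a], ord[b])
        lo <- pos[a]; hp <- pos[b]
        k_min_p <- ceiling(pmax(0L, hp - window_len + 1L) / step)
        k_max_p <- pmin(lo %/% step, k_max)
        nk <- pmax(k_max_p - k_min_p + 1L, 0L)
        ok <- nk > 0L
        ks <- sequence(nk[ok], from = k_min_p[ok] + 1L)  # 1-based window idx
        r2rep <- rep(ld$r2[ok], nk[ok])
        tab_sum <- rowsum(r2rep, ks)
        tab_n <- rowsum(rep(1L, length(ks)), ks)
        wi <- as.integer(rownames(tab_sum))
        sum_r2[wi] <- tab_sum[, 1]
        n_pairs[wi] <- tab_n[, 1]
      }
    }
    valid <- n_snps >= min_snps & n_pairs > 0L
    data.frame(contig = ctg, start = starts, end = starts + window_len,
               n_snps = as.integer(n_snps), n_pairs = n_pairs,
               mean_r2 = ifelse(valid, sum_r2 / pmax(n_pairs, 1L), NA_real_),
               valid = valid, stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, out)
  if (is.null(track)) {
    track <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), n_snps = integer(0),
                        n_pairs = integer(0), mean_r2 = numeric(0),
                        valid = logical(0), stringsAsFactors = FALSE)
  }
  structure(track,
            class = c("window_track", "data.frame"),
            window_len = window_len, step = step, min_snps = min_snps,
            contig_lengths = contig_lengths)
}

#' Heavy-tail LD threshold against a moment-matched lognormal
#'
#' Fits a lognormal to the valid window means by matching the raw-scale mean
#' and variance (method of moments), then scans a grid of empirical
#' quantiles (0.50-0.999 in steps of 0.001 by default) for the smallest
#' value `t` above the empirical median at which the empirical survival is
#' at least `tail_ratio` times the lognormal survival.  For a sample that
#' actually is lognormal the moment-matched fit tracks the empirical
#' survival closely throughout the scanned range, so no grid value crosses
#' the ratio and no haploblocks are callable (`threshold = NA`); a planted
#' high-LD component lifts the empirical survival far above the fitted tail
#' well before the component's own range.
#'
#' @param track A [window_ld_scan()] result with at least 100 valid windows.
#' @param tail_ratio Required survival ratio (default 2); larger values can
#'   only raise the threshold.
#' @param grid Optional explicit threshold grid; defaults to the empirical
#'   quantiles described above.
#' @return An object of class `ld_threshold`: list with `threshold` (`NA` if
#'   none), `meanlog`, `sdlog`, `tail_ratio`, `n_windows`, and `grid`, a
#'   data.frame of the scanned values with both survivals.
#' @export
fit_tail_threshold <- function(track, tail_ratio = 2, grid = NULL) {
  x <- track$mean_r2[track$valid]
  if (length(x) < 100L) stop("need at least 100 valid windows")
  m <- mean(x); v <- var(x)
  if (v <= 0 || m <= 0) {
    message("degenerate window LD distribution; no threshold")
    return(structure(list(threshold = NA_real_, meanlog = NA_real_,
                          sdlog = NA_real_, tail_ratio = tail_ratio,
                          n_windows = length(x), grid = NULL),
                     class = "ld_threshold"))
  }
  sdlog2 <- log(1 + v / m^2)
  meanlog <- log(m) - sdlog2 / 2
  sdlog <- sqrt(sdlog2)
  if (is.null(grid)) {
    grid <- unique(quantile(x, probs = seq(0.5, 0.999, by = 0.001),
                            names = FALSE))
  }
  grid <- sort(grid)
  s_emp <- vapply(grid, function(t) mean(x > t), numeric(1))
  s_ln <- plnorm(grid, meanlog, sdlog, lower.tail = FALSE)
  med <- median(x)
  eligible <- s_emp >= tail_ratio * s_ln & grid > med & s_emp > 0
  thr <- if (any(eligible)) grid[which(eligible)[1]] else NA_real_
  structure(list(threshold = thr, meanlog = meanlog, sdlog = sdlog,
                 tail_ratio = tail_ratio, n_windows = length(x),
                 grid = data.frame(t = grid, s_emp = s_emp, s_lognormal = s_ln)),
            class = "ld_threshold")
}

#' @export
print.ld_threshold <- function(x, ...) {
  cat(sprintf(
    "ld_threshold: %s (lognormal meanlog=%.3f sdlog=%.3f, tail_ratio=%g, %d windows)\n",
    if (is.na(x$threshold)) "none (no heavy tail)" else sprintf("%.4f", x$threshold),
    x$meanlog, x$sdlog, x$tail_ratio, x$n_windows))
  invisible(x)
}

#' Call haploblocks from a window track
#'
#' Maximal runs of consecutive grid windows that are valid and exceed the
#' threshold are merged; the block span is the union of its member windows.
#' Any non-qualifying grid window (invalid or at/below threshold) separates
#' blocks.  The genome summary partitions assayed positions into
#' in-block / background (scorable but outside blocks) / unscorable
#' (not covered by any valid window); the three fractions sum to 1.
#'
#' @param track A [window_ld_scan()] result.
#' @param threshold A numeric threshold or an [fit_tail_threshold()] result.
#' @return An object of class `haploblock_set`: list with `blocks` (data
#'   frame `contig`, `start`, `end`, `n_windows`, `mean_r2`), `summary`
#'   (fractions and block count), plus the scan parameters.  An `NA`
#'   threshold yields zero blocks.
#' @export
call_haploblocks <- function(track, threshold) {
  if (inherits(threshold, "ld_threshold")) threshold <- threshold$threshold
  step <- attr(track, "step"); wl <- attr(track, "window_len")
  contig_lengths <- attr(track, "contig_lengths")
  blocks <- list()
  if (!is.na(threshold)) {
    for (ctg in unique(track$contig)) {
      w <- track[track$contig == ctg, , drop = FALSE]
      w <- w[order(w$start), , drop = FALSE]
      qual <- which(w$valid & w$mean_r2 > threshold)
      if (length(qual) == 0L) next
      run <- cumsum(c(1L, diff(w$start[qual]) != step))
      for (r in unique(run)) {
        members <- qual[run == r]
        blocks[[length(blocks) + 1L]] <- data.frame(
          contig = ctg, start = w$start[members[1]],
          end = w$start[members[length(members)]] + wl,
          n_windows = length(members),
          mean_r2 = mean(w$mean_r2[members]), stringsAsFactors = FALSE)
      }
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               n_windows = integer(0), mean_r2 = numeric(0),
               stringsAsFactors = FALSE)
  total <- sum(contig_lengths)
  scorable_w <- 0L; block_w <- 0L
  for (ctg in names(contig_lengths)) {
    wv <- track[track$contig == ctg & track$valid, , drop = FALSE]
    if (nrow(wv)) {
      scorable_w <- scorable_w +
        sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(wv$start + 1L, wv$end))))
    }
    bl <- blocks[blocks$contig == ctg, , drop = FALSE]
    if (nrow(bl)) block_w <- block_w + sum(bl$end - bl$start)
  }
  summary <- list(n_blocks = nrow(blocks),
                  assayed_length = total,
                  fraction_in_blocks = block_w / total,
                  fraction_background = (scorable_w - block_w) / total,
                  fraction_unscorable = 1 - scorable_w / total,
                  threshold = threshold)
  structure(list(blocks = blocks, summary = summary,
                 contig_lengths = contig_lengths,
                 window_len = wl, step = step),
            class = "haploblock_set")
}

#' @export
print.haploblock_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "haploblock_set: %d blocks, %.1f%% of genome in blocks, %.1f%% background, %.1f%% unscorable\n",
    s$n_blocks, 100 * s$fraction_in_blocks, 100 * s$fraction_background,
    100 * s$fraction_unscorable))
  invisible(x)
}

#' Per-block haplotype statistics
#'
#' For each haploblock: the mean MAF of contained SNPs, each genotype's
#' fraction of contained SNPs at which it carries the minor allele, and a
#' two-way haplotype assignment (minor haplotype when that fraction is at
#' least 0.5).  In a clean two-haplotype block the minor fractions are
#' bimodal at 0 and 1.  Blocks with fewer than 2 SNPs carry `NA` statistics.
#'
#' @param hb A [call_haploblocks()] result.
#' @param snps The [snp_table()] the scan was computed from.
#' @return The `haploblock_set` with `blocks` gaining `n_snps`, `mean_maf`,
#'   `minor_haplotype_freq`; plus `minor_fractions` (blocks x genotypes
#'   matrix), `assignment` (character matrix, "major"/"minor"), and summary
#'   entries `fraction_short` (blocks < 1000 nt) and `block_lengths`.
#' @export
haploblock_stats <- function(hb, snps) {
  bl <- hb$blocks
  df <- snps$snps
  ng <- ncol(snps$states)
  mf <- matrix(NA_real_, nrow = nrow(bl), ncol = ng,
               dimnames = list(NULL, snps$genotype_ids))
  bl$n_snps <- 0L; bl$mean_maf <- NA_real_; bl$minor_haplotype_freq <- NA_real_
  for (b in seq_len(nrow(bl))) {
    inb <- which(df$contig == bl$contig[b] & df$pos >= bl$start[b] &
                   df$pos < bl$end[b] & !df$singleton)
    bl$n_snps[b] <- length(inb)
    if (length(inb) < 2L) next
    bl$mean_maf[b] <- mean(df$maf[inb])
    mf[b, ] <- colMeans(snps$states[inb, , drop = FALSE])
    bl$minor_haplotype_freq[b] <- mean(mf[b, ] >= 0.5)
  }
  assignment <- ifelse(is.na(mf), "unassigned",
                       ifelse(mf >= 0.5, "minor", "major"))
  hb$blocks <- bl
  hb$minor_fractions <- mf
  hb$assignment <- assignment
  hb$summary$block_lengths <- bl$end - bl$start
  hb$summary$fraction_short <-
    if (nrow(bl)) mean(bl$end - bl$start < 1000L) else NA_real_
  hb
}

#' Per-genotype minor-allele fraction over a region set
#'
#' Fraction of (non-singleton) SNPs at which each genotype carries the minor
#' allele, restricted to positions inside (`complement = FALSE`) or outside
#' (`complement = TRUE`) the given intervals.  Useful for comparing the
#' bimodal within-haploblock distribution to the unimodal background.
#'
#' @param snps A [snp_table()].
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open), e.g. a `haploblock_set$blocks`.
#' @param complement Use positions outside the intervals instead.
#' @return Named numeric vector (one fraction per genotype).
#' @export
minor_fraction_by_genotype <- function(snps, intervals, complement = FALSE) {
  df <- snps$snps
  inside <- rep(FALSE, nrow(df))
  for (b in seq_len(nrow(intervals))) {
    inside <- inside | (df$contig == intervals$contig[b] &
                          df$pos >= intervals$start[b] &
                          df$pos < intervals$end[b])
  }
  sel <- which(!df$singleton & (if (complement) !inside else inside))
  if (length(sel) == 0L) {
    return(setNames(rep(NA_real_, ncol(snps$states)), snps$genotype_ids))
  }
  colMeans(snps$states[sel, , drop = FALSE])
}

#' Cross-population haploblock overlap
#'
#' Observed fraction of positions falling inside haploblocks in both
#' populations, against the fraction expected under independent placement
#' (the product of the two marginal fractions), over a common denominator.
#'
#' @param blocks_a,blocks_b Haploblock interval sets: either
#'   `haploblock_set` objects or data.frames with `contig`, `start`, `end`.
#' @param total_length Denominator in positions; required when plain data
#'   frames are given, otherwise taken from the block sets' contig lengths.
#' @return List with `observed`, `expected`, `fraction_a`, `fraction_b`,
#'   `denominator`.
#' @export
cross_population_overlap <- function(blocks_a, blocks_b, total_length = NULL) {
  get_blocks <- function(x) if (inherits(x, "haploblock_set")) x$blocks else x
  ba <- get_blocks(blocks_a); bb <- get_blocks(blocks_b)
  if (is.null(total_length)) {
    if (!inherits(blocks_a, "haploblock_set")) {
      stop("total_length is required with plain block data frames")
    }
    total_length <- sum(blocks_a$contig_lengths)
  }
  width_of <- function(bl) {
    if (nrow(bl) == 0L) return(0)
    sum(vapply(split(bl, bl$contig), function(s) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(s$start + 1L, s$end))))
    }, numeric(1)))
  }
  inter_width <- 0
  for (ctg in intersect(unique(ba$contig), unique(bb$contig))) {
    ra <- IRanges::reduce(IRanges::IRanges(
      ba$start[ba$contig == ctg] + 1L, ba$end[ba$contig == ctg]))
    rb <- IRanges::reduce(IRanges::IRanges(
      bb$start[bb$contig == ctg] + 1L, bb$end[bb$contig == ctg]))
    inter_width <- inter_width +
      sum(IRanges::width(IRanges::intersect(ra, rb)))
  }
  fa <- width_of(ba) / total_length
  fb <- width_of(bb) / total_length
  list(observed = inter_width / total_length, expected = fa * fb,
       fraction_a = fa, fraction_b = fb, denominator = total_length)
}

#' Write haploblocks as BED / window track as bedGraph
#'
#' BED uses 0-based half-open coordinates with the block mean r-squared
#' scaled to 0-1000 in the score column.
#'
#' @param hb A `haploblock_set`.
#' @param track A `window_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_haploblocks_bed <- function(hb, path) {
  bl <- hb$blocks
  bed <- data.frame(bl$contig, bl$start, bl$end,
                    paste0("haploblock_", seq_len(nrow(bl))),
                    as.integer(round(1000 * pmin(bl$mean_r2, 1)))
                    )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_haploblocks_bed
#' @export
write_window_bedgraph <- function(track, path) {
  w <- track[track$valid, , drop = FALSE]
  write.table(data.frame(w$contig, w$start, w$end, signif(w$mean_r2, 6)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
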