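# Forward Wright-Fisher simulation of a short sequence under additive,
# compensatory-epistatic and balancing (NFDS / AOD) fitness models, with the
# LD summary protocol used for the natural-population analysis (sample of
# haploid genotypes, MAF > 5%, mean r2 per site class).

#' Fitness model specification
#'
#' Selection acts additively across loci on the fitness scale: each carried
#' deleterious nonsynonymous allele contributes `s_nonsyn` (haploid carrier
#' or homozygote) or `h * s_nonsyn` (heterozygote); synonymous sites are
#' neutral.  Nonsynonymous sites are split into disjoint consecutive pairs
#' and each pair can carry a positive-epistasis increment for the double
#' mutant on the same haplotype:
#'
#' * `"none"`: no epistasis (the additive, non-epistatic model).
#' * `"full"`: increment `-2 * s_nonsyn`, so the double mutant is fully
#'   compensated back to fitness 1 (two equal fitness peaks).
#' * `"partial"`: increment `-2 * s_nonsyn * alpha`, `alpha` in `[0, 1]`.
#' * `"ridge"`: one pair member is individually neutral, the other
#'   deleterious, the double mutant neutral (three of the four allele
#'   combinations confer high fitness -- a flat curved ridge).
#'
#' Balancing selection is optional: `"nfds"` places one site under negative
#' frequency-dependent selection with coefficient `s(p) = nfds_smax *
#' (1 - 2p)` (favored while rare, disfavored while common, neutral at
#' p = 0.5); `"aod"` makes `n_aod` sites fully recessive (`h = 0`) and
#' weakly deleterious (`s_aod`), generating associative overdominance.
#'
#' @param s_nonsyn Selection coefficient of a nonsynonymous allele
#'   (default -0.01; must be <= 0).
#' @param h Dominance coefficient for diploid simulations (default 0.5).
#' @param epistasis One of `"none"`, `"full"`, `"partial"`, `"ridge"`.
#' @param alpha Compensation fraction for `"partial"` (default 0.5).
#' @param balancing One of `"none"`, `"nfds"`, `"aod"`.
#' @param nfds_smax Maximum NFDS coefficient (default 0.01).
#' @param n_aod,s_aod Number and coefficient of recessive AOD sites
#'   (defaults 10 and -0.0025).
#' @return An object of class `fitness_model`.
#' @export
fitness_model <- function(s_nonsyn = -0.01, h = 0.5,
                          epistasis = c("none", "full", "partial", "ridge"),
                          alpha = 0.5,
                          balancing = c("none", "nfds", "aod"),
                          nfds_smax = 0.01, n_aod = 10L, s_aod = -0.0025) {
  epistasis <- match.arg(epistasis)
  balancing <- match.arg(balancing)
  stopifnot(s_nonsyn <= 0, alpha >= 0, alpha <= 1)
  structure(list(s_nonsyn = s_nonsyn, h = h, epistasis = epistasis,
                 alpha = alpha, balancing = balancing,
                 nfds_smax = nfds_smax, n_aod = as.integer(n_aod),
                 s_aod = s_aod),
            class = "fitness_model")
}

#' Wright-Fisher run specification
#'
#' @param n Population size in individuals (default 200).
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param L Sequence length in sites (default 99; site classes follow a
#'   codon-like pattern with twice as many nonsynonymous as synonymous
#'   sites: positions 1 and 2 of each triplet nonsynonymous, position 3
#'   synonymous).
#' @param mu Per-site per-generation mutation probability (reversible
#'   0 <-> 1 flips); see [mutation_rate_for_pi()] for the diversity scaling.
#' @param recomb Per-offspring recombination probability (single uniform
#'   crossover); 0 reproduces a fully linked sequence.
#' @param generations Number of generations (default `100 * n`).
#' @param model A [fitness_model()].
#' @param sample_n Haploid genotypes sampled at the end (default 100,
#'   capped at the number of chromosomes).
#' @param seed RNG seed; the whole run is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 200L, ploidy = c("haploid", "diploid"), L = 99L,
                       mu = 2.5e-4, recomb = 0, generations = 100L * n,
                       model = fitness_model(), sample_n = 100L, seed = 1L) {
  ploidy <- match.arg(ploidy)
  stopifnot(n >= 2L, L >= 1L, mu >= 0, mu < 1, generations >= 1L)
  structure(list(n = as.integer(n), ploidy = ploidy, L = as.integer(L),
                 mu = mu, recomb = recomb,
                 generations = as.integer(generations), model = model,
                 sample_n = as.integer(sample_n), seed = as.integer(seed)),
            class = "sim_config")
}

#' Mutation rate targeting a diversity level
#'
#' The scaling `mu = pi / (2 N)` used to reach a target nucleotide
#' diversity at population size `N` (e.g. pi = 0.1 at N = 1000 gives
#' mu = 5e-5).
#'
#' @param pi_target Target nucleotide diversity.
#' @param n Population size in individuals.
#' @return Per-site per-generation mutation rate.
#' @export
mutation_rate_for_pi <- function(pi_target, n) pi_target / (2 * n)

# Site layout and selection vectors for a config.  Special balancing sites
# get their own class and are excluded from pairing and from the syn/nonsyn
# LD summaries.
build_sim_sites <- function(config) {
  L <- config$L
  model <- config$model
  cls <- rep(c("nonsynonymous", "nonsynonymous", "synonymous"),
             length.out = L)
  s <- ifelse(cls == "nonsynonymous", model$s_nonsyn, 0)
  h <- rep(model$h, L)
  nfds_site <- -1L
  if (model$balancing == "nfds") {
    nfds_site <- sample(which(cls == "nonsynonymous"), 1L)
    cls[nfds_site] <- "balanced"
    s[nfds_site] <- 0  # handled frequency-dependently
  }
  if (model$balancing == "aod") {
    aod <- sample(L, min(model$n_aod, L))
    cls[aod] <- "aod"
    s[aod] <- model$s_aod
    h[aod] <- 0
  }
  epi_pairs <- matrix(integer(0), 0, 2)
  epi_eps <- numeric(0)
  if (model$epistasis != "none") {
    ns <- which(cls == "nonsynonymous")
    n_pairs <- length(ns) %/% 2L
    if (n_pairs > 0L) {
      epi_pairs <- cbind(ns[2 * seq_len(n_pairs) - 1L], ns[2 * seq_len(n_pairs)])
      eps_full <- -2 * model$s_nonsyn
      epi_eps <- rep(switch(config$model$epistasis,
                            full = eps_full,
                            partial = eps_full * model$alpha,
                            ridge = -model$s_nonsyn), n_pairs)
      if (model$epistasis == "ridge") {
        # member A individually neutral, B deleterious, AB neutral
        s[epi_pairs[, 1]] <- 0
      }
    }
  }
  list(class = cls, s = s, h = h, epi_pairs = epi_pairs, epi_eps = epi_eps,
       nfds_site = nfds_site, nfds_smax = model$nfds_smax)
}

#' Fitness of a genotype under a fitness model
#'
#' Reference implementation of the fitness function the simulator applies:
#' additive across loci with a positivity floor.  For diploids, a site
#' contributes `s` when homozygous and `h * s` when heterozygous; an
#' epistatic pair contributes half its increment per haplotype carrying
#' both members; the NFDS site contributes `nfds_smax * (1 - 2 p)` at
#' current population frequency `p`.
#'
#' @param geno Haploid 0/1 vector, or a 2 x L matrix of the two haplotypes
#'   of a diploid individual.
#' @param sites A site layout: list with `s` (per-site selection
#'   coefficients, recycled), `h` (dominance, recycled), `epi_pairs`
#'   (two-column site-index matrix), `epi_eps`, `nfds_site` (-1 for none)
#'   and `nfds_smax`; [run_wright_fisher()] builds this from a
#'   [fitness_model()].
#' @param nfds_freq Current population frequency of the NFDS allele.
#' @param fitness_floor Positivity floor (default 1e-6).
#' @return A positive fitness value.
#' @examples
#' # diploid heterozygote at one deleterious site, s = -0.01, h = 0.5
#' sites <- list(s = -0.01, h = 0.5,
#'               epi_pairs = matrix(integer(0), 0, 2),
#'               epi_eps = numeric(0), nfds_site = -1L, nfds_smax = 0.01)
#' genotype_fitness(rbind(1, 0), sites)  # 0.995
#' @export
genotype_fitness <- function(geno, sites, nfds_freq = 0.5,
                             fitness_floor = 1e-6) {
  hap <- if (is.matrix(geno)) geno else matrix(geno, nrow = 1)
  L <- ncol(hap)
  s <- rep(sites$s, length.out = L)
  h <- rep(sites$h %||% 0.5, length.out = L)
  acc <- 0
  if (nrow(hap) == 1L) {
    acc <- acc + sum(s[hap[1, ] == 1])
  } else {
    g <- colSums(hap)
    acc <- acc + sum(s[g == 2]) + sum(h[g == 1] * s[g == 1])
  }
  if (sites$nfds_site > 0) {
    s_nfds <- (sites$nfds_smax %||% 0.01) * (1 - 2 * nfds_freq)
    if (nrow(hap) == 1L) {
      if (hap[1, sites$nfds_site] == 1) acc <- acc + s_nfds
    } else {
      g <- sum(hap[, sites$nfds_site])
      if (g == 2) acc <- acc + s_nfds
      else if (g == 1) acc <- acc + h[sites$nfds_site] * s_nfds
    }
  }
  if (nrow(sites$epi_pairs) > 0L) {
    for (k in seq_len(nrow(sites$epi_pairs))) {
      a <- sites$epi_pairs[k, 1]; b <- sites$epi_pairs[k, 2]
      if (nrow(hap) == 1L) {
        if (hap[1, a] == 1 && hap[1, b] == 1) acc <- acc + sites$epi_eps[k]
      } else {
        for (r in 1:2) {
          if (hap[r, a] == 1 && hap[r, b] == 1) {
            acc <- acc + 0.5 * sites$epi_eps[k]
          }
        }
      }
    }
  }
  max(1 + acc, fitness_floor)
}

#' Run a Wright-Fisher simulation
#'
#' Starts from a monomorphic population and evolves it for
#' `config$generations` generations: parents are sampled with probability
#' proportional to fitness, every site mutates (0 <-> 1) with probability
#' `mu` per generation, and recombination follows `config$recomb`.  At the
#' end a random sample of haploid genotypes is drawn.  Fully reproducible
#' from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_result`: list with `sample` (0/1 matrix,
#'   sampled haplotypes x sites), `site_class`, `sites` (the realized
#'   selection layout), `pi` (sample nucleotide diversity), `sfs` (sample
#'   minor-allele count spectrum), and `config`.
#' @export
run_wright_fisher <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sites <- build_sim_sites(config)
  ploidy <- if (config$ploidy == "diploid") 2L else 1L
  n_hap <- config$n * ploidy
  epi_pairs0 <- if (nrow(sites$epi_pairs)) sites$epi_pairs - 1L else
    matrix(integer(0), 0, 2)
  pop <- wf_simulate_cpp(n_hap, config$L, ploidy, config$mu,
                         config$generations, sites$s, sites$h,
                         epi_pairs0, sites$epi_eps,
                         sites$nfds_site - 1L,
                         config$model$nfds_smax, config$recomb, 1e-6)
  take <- min(config$sample_n, n_hap)
  samp <- pop[sample.int(n_hap, take), , drop = FALSE]
  f <- colMeans(samp)
  mac <- pmin(colSums(samp), take - colSums(samp))
  pi <- mean(2 * f * (1 - f)) * take / (take - 1)
  structure(list(sample = samp, site_class = sites$class, sites = sites,
                 pi = pi, sfs = tabulate(mac[mac > 0], nbins = take %/% 2),
                 config = config),
            class = "sim_result")
}

#' LD summary of a simulated sample
#'
#' Mean r-squared over all pairs of same-class SNPs with sample minor
#' allele frequency above `maf_min`, separately for synonymous and
#' nonsynonymous sites (special balancing sites are excluded), plus the
#' sample nucleotide diversity.
#'
#' @param result A [run_wright_fisher()] result.
#' @param maf_min Strict MAF cutoff in the sample (default 0.05).
#' @return List with `pi`, `ld_syn`, `ld_nonsyn`, `excess`
#'   (= ld_nonsyn - ld_syn, `NA` if either side is undefined), `n_syn`,
#'   `n_nonsyn` (qualifying SNP counts).  A class with fewer than 2
#'   qualifying SNPs has an `NA` mean.
#' @export
summarize_ld <- function(result, maf_min = 0.05) {
  samp <- result$sample
  f <- colMeans(samp)
  maf <- pmin(f, 1 - f)
  class_mean <- function(cls) {
    idx <- which(result$site_class == cls & maf > maf_min)
    if (length(idx) < 2L) return(list(mean = NA_real_, n = length(idx)))
    states <- t(samp[, idx, drop = FALSE])
    pr <- t(combn(length(idx), 2))
    vals <- pair_ld_values(states, pr[, 1], pr[, 2])
    list(mean = mean(vals$r2), n = length(idx))
  }
  syn <- class_mean("synonymous")
  nonsyn <- class_mean("nonsynonymous")
  list(pi = result$pi, ld_syn = syn$mean, ld_nonsyn = nonsyn$mean,
       excess = nonsyn$mean - syn$mean, n_syn = syn$n, n_nonsyn = nonsyn$n)
}

#' Replicate simulations over a condition grid
#'
#' Runs `n_replicates` seeded replicates of each named condition and
#' collects the per-replicate LD summaries.
#'
#' @param conditions Named list of [sim_config()] objects (their `seed`
#'   fields are overridden per replicate).
#' @param n_replicates Replicates per condition.
#' @param seed Base seed; replicate seeds are derived deterministically and
#'   stay below 2^31.
#' @return data.frame: `condition`, `replicate`, `seed`, `pi`, `ld_syn`,
#'   `ld_nonsyn`, `excess`, `n_syn`, `n_nonsyn`.
#' @export
replicate_experiment <- function(conditions, n_replicates = 20L, seed = 1L) {
  stopifnot(length(conditions) >= 1L, !is.null(names(conditions)))
  out <- list()
  for (ci in seq_along(conditions)) {
    for (r in seq_len(n_replicates)) {
      cfg <- conditions[[ci]]
      cfg$seed <- as.integer((seed * 97L + ci * 1013L + r * 7L) %% 2147483647L)
      res <- run_wright_fisher(cfg)
      s <- summarize_ld(res)
      out[[length(out) + 1L]] <- data.frame(
        condition = names(conditions)[ci], replicate = r, seed = cfg$seed,
        pi = s$pi, ld_syn = s$ld_syn, ld_nonsyn = s$ld_nonsyn,
        excess = s$excess, n_syn = s$n_syn, n_nonsyn = s$n_nonsyn,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Export a simulated sample as a haploid alignment
#'
#' Encodes ancestral/derived states as A/T so simulated samples can flow
#' through the alignment-based pipeline; the per-site class goes to a
#' sidecar table.
#'
#' @param result A [run_wright_fisher()] result.
#' @return List with `alignment` (a [haploid_alignment()]) and
#'   `site_classes` (data.frame `pos`, `class`).
#' @export
sim_to_alignment <- function(result) {
  mat <- ifelse(result$sample == 1L, "T", "A")
  rownames(mat) <- sprintf("sim_g%03d", seq_len(nrow(mat)))
  list(alignment = haploid_alignment(mat, contig_id = "sim"),
       site_classes = data.frame(pos = seq_len(ncol(mat)) - 1L,
                                 class = result$site_class,
                                 stringsAsFactors = FALSE))
}
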