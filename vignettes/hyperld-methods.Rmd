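---
title: "Detecting epistatic selection from linkage disequilibrium in hyperpolymorphic haploid populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epistatic selection from linkage disequilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperLD)
```

## The scientific problem

In most species nucleotide diversity is a small parameter (π ≈ 0.001–0.01),
which leaves little room for selection to act on *combinations* of
segregating alleles.  In a hyperpolymorphic species — π of order 0.1, as in
the wood-decaying fungus *Schizophyllum commune* — standing variation can
span a sizeable portion of the fitness landscape, and epistatic selection
between polymorphisms becomes detectable within a single population.
hyperLD implements the LD-based toolkit for that detection in haploid
samples:

1. **Class-contrasted LD.** For biallelic sites the package uses
   \(r^2 = \frac{(p_{AB} - p_A p_B)^2}{p_A(1-p_A)\,p_B(1-p_B)}\), where
   \(p_A, p_B\) are minor-allele frequencies and \(p_{AB}\) the frequency of
   genotypes carrying both minor alleles.  The signed statistic
   \(D = p_{AB} - p_A p_B\), polarized to minor alleles, separates attraction
   (coupling) from repulsion.  Excess mean \(r^2\) between nonsynonymous
   SNPs over synonymous SNPs at the same distance — particularly within
   genes — is the footprint of compensatory (positive) epistasis, because
   only coadapted combinations of individually deleterious alleles persist.
2. **Haploblocks.** Short genomic segments in which the gene pool collapses
   onto two deeply diverged haplotypes produce locally extreme LD and a
   bimodal per-genotype minor-allele fraction; they indicate balancing
   selection.  A sliding-window scan with a heavy-tail threshold against a
   moment-matched lognormal null calls these segments.
3. **Structure-contact LD.** If compensation acts through physical
   interactions within the folded protein, LD should be elevated between
   codons whose residues are close in the structure.  A distance-matched
   permutation test (genome-wide) and per-gene 2×2 contingency tests with
   BH correction (per protein) quantify this.
4. **Cross-population LD correlation.** Shared epistatic constraints
   correlate the LD of the same SNP pairs across diverged populations even
   outside haploblocks, most strongly for same-gene nonsynonymous pairs
   carrying the same alleles.
5. **Forward simulation.** A Wright–Fisher simulator with compensatory
   fitness models establishes which combinations of epistasis and balancing
   selection can generate the observed LD contrasts.

## Conventions and data model

Coordinates are 0-based half-open internally; GFF3 input is converted from
1-based closed on read, and BED output is 0-based half-open.  A
`haploid_alignment` stores an n × L character matrix over A, C, G, T, `-`,
N; columns containing a gap or N in any genotype are excluded from all
analyses (a gap-free-column convention, appropriate for projected
whole-genome alignments of de novo assemblies).  Only biallelic columns
become SNPs; singletons (minor allele in exactly one genotype) are dropped
by default because with dozens of genotypes they are dominated by sequencing
and assembly error and carry no LD information.  An exact 50/50 allele split
is resolved deterministically: the alphabetically first allele is called
major.

SNP classification substitutes each allele into the major-allele background
codon (other codon positions held at their column-wise major alleles),
reverse-complemented for minus-strand genes.  Each SNP is classified
independently even when its codon contains another segregating site; this
matches an analysis in which per-site classes are fixed annotations, and
avoids making a SNP's class depend on phased haplotypes.  Stop-gain and
stop-loss changes count as nonsynonymous.  Per-gene \(p_n/p_s\) uses
NG86-style fractional site counting: each codon's nine single-nucleotide
changes contribute syn/nonsyn site weights of 1/3 each, summed over the
major-allele coding sequence.  \(p_s = 0\) yields an undefined (NA) ratio,
never infinity.

## Tunable parameters

| Parameter | Default | Role |
|---|---|---|
| `maf_min` | 0.05 | strict minor-allele-frequency filter for LD profiles; common alleles carry the epistatic signal |
| `max_distance` | 2000 nt | pair window for LD profiles and shared-SNP pairs |
| window `window_len`/`step`/`min_snps` | 250 / 20 / 10 | haploblock scan geometry; windows with fewer than 10 non-singleton SNPs are unscorable |
| `tail_ratio` | 2.0 | empirical survival must exceed the fitted lognormal survival by this factor |
| `contact_cutoff` | 10 Å | residues closer than this are "in contact" |
| `min_aa_separation` | 5 aa | removes trivially close sequence neighbours from the permutation test |
| `aa_band` | 30–100 aa | sequence-distance band for per-gene contingency tests |
| `high_ld_quantile` | 0.9 | per-gene threshold defining "high LD" pairs |
| `gene_ld_quantile` | 0.8 | genes above this overall-LD quantile are excluded from cross-population pairs |
| gene stats `max_pair_distance`/`min_pairs` | 300 nt / 100 | gene-length control and minimum information per gene |

All stochastic operations (resampling, permutations, simulation) take an
explicit seed and are reproducible byte-for-byte.

## Numerical and procedural choices

**Heavy-tail threshold.**  The window-LD distribution is compared with a
lognormal whose raw-scale mean and variance match the data (method of
moments: \(\sigma^2 = \log(1 + v/m^2)\), \(\mu = \log m - \sigma^2/2\)).
The threshold is the smallest value on a grid of empirical quantiles
(0.50–0.999 in steps of 0.001) above the empirical median at which the
empirical survival is at least `tail_ratio` times the lognormal survival.
For a genuinely lognormal sample the moment-matched fit tracks the
empirical survival closely over this whole range, so no grid point crosses
a ratio of 2 and no haploblocks are called; a high-LD subpopulation of
windows inflates the fitted variance but lifts the empirical survival much
faster, producing a crossing well below the planted component.  Requiring
the crossing to persist into the extreme tail was considered and rejected:
the inflated fitted variance makes the fitted tail overtake the empirical
one again beyond the planted mass, which would veto exactly the cases the
scan exists to find.

**Window means.**  A window's LD is the mean \(r^2\) over all unordered
pairs of non-singleton SNPs lying entirely inside the window, which keeps
each window's value independent of context outside it.  Blocks are maximal
runs of consecutive qualifying grid windows; any invalid or sub-threshold
grid window separates blocks; the block span is the union of its windows.
The genome partition (in blocks / background / unscorable) is exact by
construction: positions covered by at least one valid window are scorable.

**Haplotype assignment.**  Within a called block each genotype's fraction
of minor alleles is computed over the block's SNPs; genotypes at ≥ 0.5 are
assigned to the minor haplotype.  The assignment is always made; bimodality
of the fractions is reported separately rather than gating the assignment.

**Distance-matched permutation test.**  Close residue pairs (≤ 10 Å,
sequence separation ≥ 5 aa) are compared with distant pairs (> 10 Å; pairs
with unknown distance are excluded from both sides — a conservative null).
Each permutation replicate replaces every close pair with a uniformly drawn
distant pair at the same amino-acid separation (± 2 aa fallback when the
exact stratum is empty; close pairs with no match are dropped from both the
observed statistic and the null).  The p-value is
\((1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)\).  This matched
resampling scheme is approximately valid; its calibration requires distant
pairs to greatly outnumber close pairs within each separation stratum, which
holds in real protein structures (most residue pairs are far apart) and in
the calibration experiments shipped with the package.  The Spearman p-value
for gene-statistic correlations uses the large-sample approximation at
n ≥ 30 and a seeded permutation test below that.

**Contingency tests.**  Within the 30–100 aa band, pairs are cross
classified as close/far × high/low LD (high: at or above the per-gene 0.9
quantile).  The odds ratio applies a Haldane 0.5 correction only when a
cell is empty; the chi-square statistic is computed on the raw counts
without continuity correction; genes with fewer than five close pairs, or
without two distinct \(r^2\) values, are ineligible.  BH correction runs
over all eligible genes of one population.

## The Wright–Fisher simulator

`run_wright_fisher()` evolves a monomorphic population of `n` individuals
(haploid, or diploid with two haplotypes each) over a short sequence with
reversible per-site 0↔1 mutation at rate μ, fitness-proportional parent
sampling, and optional single-crossover recombination.  Site classes follow
a codon-like layout with twice as many nonsynonymous as synonymous sites.
Fitness is additive across loci on the fitness scale with a positivity
floor: a carried nonsynonymous allele contributes \(s\) (haploid carrier or
homozygote) or \(hs\) (heterozygote); synonymous sites are neutral.
Nonsynonymous sites are split into disjoint pairs; a double mutant on one
haplotype gains an epistatic increment ε — full compensation sets
ε = −2s so both fitness peaks are exactly equal, partial compensation
scales it by α < 1, and a "ridge" variant makes one member individually
neutral so three of the four allele combinations are fit.  In diploids each
haplotype carrying both members contributes ε/2, making the cis double-mutant
heterozygote (2hs + ε/2 with h = 0.5) and the double homozygote (2s + ε)
both exactly compensated; a trans double heterozygote is not compensated,
as befits interactions within a physical protein molecule.  Balancing
selection is available as negative frequency-dependent selection
(one site with \(s(p) = s_{max}(1 - 2p)\): favored while rare, disfavored
while common) or associative overdominance (recessive weakly deleterious
sites).  The balancing driver sites carry their own class and are excluded
from the LD_syn/LD_nonsyn summaries, so the reported contrast reflects the
ordinary sites.  The LD summary follows the sampling protocol used for the
natural-population analysis: a random sample of 100 haploid genotypes, SNPs
at sample MAF > 0.05, mean \(r^2\) within each class.

### Study conditions for the shipped experiments

The replicate experiments run at desk scale — haploid N = 200, L = 99,
100·N generations — chosen so a full battery completes in minutes.  Raw
selection coefficients do not transfer across population sizes, so the
desk-scale conditions preserve *population-scaled* intensities instead:

* **Neutral calibration:** μ = 2.5×10⁻⁴ (θ = 2Nμ = 0.1).  Mean sample π is
  compared with the infinite-alleles expectation θ/(1+θ); for the
  reversible two-allele mutation model the exact stationary value is
  θ/(1+2θ), about 2% lower at this θ — far inside the between-replicate
  noise of non-recombining sequences.
* **Additive (Hill–Robertson) direction:** s = −0.05, μ = 10⁻³; the
  nonsynonymous class stays populated in essentially every replicate and
  interference among deleterious alleles drives LD_nonsyn at or below
  LD_syn.
* **Compensatory epistasis with NFDS:** s = −0.2 and s_max = 0.2
  (N·s = N·s_max = 40), μ = 10⁻³ (θ = 0.4; π ≈ 0.10, the hyperpolymorphic
  regime).  The selection strength is set by the requirement that the
  mutation–selection-balance frequency of uncompensated single mutants,
  μ/s = 0.005, stay far below the 0.05 MAF filter: qualifying nonsynonymous
  SNPs are then almost exclusively established compensated pairs riding
  the two balanced clades (r² ≈ 1), while the synonymous class mixes clade
  markers with low-LD within-clade transients — the mechanism that makes
  the excess positive.  With weak scaled selection the structure collapses:
  deleterious singles drift through the MAF filter and even to fixation,
  and the class contrast inverts.
* **μ grid (hyperpolymorphism effect):** μ ∈ {6.25×10⁻⁵, 2.5×10⁻⁴, 10⁻³}
  under the epistasis+NFDS model.  The grid statistic is the unconditional
  mean excess, with replicates lacking two qualifying SNPs in a class
  counted as zero excess — no standing polymorphism means no excess, and
  conditioning on polymorphism would bias the low-μ points upward.

Replicates without measurable LD in a class are reported as NA by
`summarize_ld()`; `replicate_experiment()` leaves aggregation to the
caller.  AOD is implemented (diploid, h = 0, 10 sites at s = −0.0025 by
default) but the shipped directional experiments use NFDS, which maintains
the balanced clades far more reliably at desk scale.

## What the synthetic-data generator emulates — and what it does not

`generate_population()` draws background SNPs independently per site with
minor-allele counts from a neutral-like folded spectrum
\(P(k) \propto 1/k + 1/(n-k)\) truncated at singletons, plants two-haplotype
haploblocks (all block SNPs fully coupled to a haplotype assignment at a
stated frequency, optional flip noise), and plants coupled nonsynonymous
pairs at second codon positions of non-stop codons (the single synonymous
second-position exchange, TAA↔TGA, is avoided by construction) with an
exact carrier-overlap construction hitting a target r².  The two-population
mode shares a fraction of SNP positions (default 0.25) with independent
carrier sets, plus optionally pairs coupled in both populations.

The generator controls *structure*, not *genealogy*: background sites are
independent, so background LD sits at the sampling floor E[r²] ≈ 1/n with
no distance decay, there is no recombination map, no indel variation, no
missing data beyond what the caller introduces, and no shared ancestry
between the two populations beyond the planted features.  Passing the
planted-recovery tests therefore demonstrates that the detection machinery
recovers known structure through the full I/O path, not that real genomes
meet the method's assumptions.  Within planted blocks the SNP density
default used in the recovery experiments is 100 SNPs/kb — conservative for
a species where a quarter of alignable sites are polymorphic, and
comfortably above the 40 SNPs/kb floor the 250/20/10 window geometry needs
to score a block at all.

## Degenerate inputs and undefined results

Monomorphic state vectors make \(r^2\) undefined and raise a classed error
(`hyperLD_undefined`) rather than returning 0; empty profile cells carry
`n_pairs = 0` and NA means; a gene without synonymous pairs has NA
`ld_syn` and NA excess; \(p_s = 0\) gives NA \(p_n/p_s\); a degenerate
(zero-variance) window distribution yields no threshold; strata below the
minimum size are flagged not-testable.  Across-contig standard errors use
the population SD of per-contig means divided by √(number of contigs),
skipping contigs contributing fewer than 10 pairs to the cell, and are NA
with fewer than two contributing contigs.

## Known limitations

* Haploblock assignment is strictly two-way; blocks containing three
  haplotypes are reported with their bimodality diagnostics but not split.
* The permutation test's validity is approximate (matched resampling, not
  an exact randomization test); it is anti-conservative when close pairs
  are a large fraction of their separation stratum.
* Classification against the major-allele background can differ from a
  haplotype-aware classification when two segregating sites share a codon.
* The simulator's reversible two-allele mutation model lets high-μ runs
  revisit states; it is the natural finite-sites choice for 100-nt
  sequences but differs from infinite-sites expectations at large θ.
* Cross-population analyses require both populations projected onto a
  shared coordinate system; the package performs no projection itself.
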