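---
title: "Methods: topology weighting, window admixture statistics and recombination scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology weighting, window admixture statistics and recombination scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`introscan` implements a window-based analysis of introgression between
hybridising species, built around the *Heliconius* study system: two pairs
of sympatric, hybridising taxa (*cydno*-like and *timareta*-like
populations alongside western and eastern *melpomene*, labelled `cyd`,
`tim`, `melW`, `melE`) with *numata* (`num`) as outgroup.  The pipeline
has four layers:

1. **Genotype I/O and filtering** (`load_genotypes`, `apply_site_filters`,
   `window_iter`): VCF input, the SNP acceptance rules, and window
   iteration.
2. **Window genealogies and topology weighting** (`distance_matrix`,
   `neighbour_joining`, `enumerate_topologies`, `weight_exact`,
   `weight_sampled`): how much of each possible rooted taxon topology is
   contained in the genealogy of each 50-SNP window.
3. **Window admixture statistics** (`polarize`, `f_d`, `d_stat`, `fst`,
   `dxy`, `admixture_scan`): site-pattern admixture estimation in physical
   windows.
4. **Recombination and the genome scan** (`crossover_rate`, `rescale_rho`,
   `build_scan_table`, `spearman_thinned`, `fused_vs_unfused`,
   `chromosome_summary`): linking admixture to recombination rate, gene
   density, chromosome length and fusion status.

A fifth component, the coalescent generator (`simulate_genealogies`,
`simulate_sequence_windows`, `make_scan_fixture`), produces the synthetic
data on which every layer is validated.

# SNP filtering

Sites are accepted when the record QUAL is at least 30 and (optionally)
biallelic.  Individual genotype calls with read depth below 8 are masked
*before* any site-level test, because the per-call acceptance rule is
stated at the call level; site-level completeness is then evaluated on the
masked matrix.  Sites where more than 75% of genotypes are heterozygous
(computed over called genotypes only — the denominator choice is exposed
via `het_denominator`) or where the minor allele occurs in fewer than two
haploid copies are removed; a site left monomorphic by masking has zero
minor copies and is likewise removed, since it is no longer a SNP.  Two
stock completeness rulesets are provided: `filter_rules_set1` (at least
9 of 10 samples called in every ingroup population, 1 outgroup) and
`filter_rules_set2` (at least 4 ingroup samples, 1 outgroup).

Windows come in two flavours.  Fixed-SNP windows (default 50 SNPs) hold
the information content per tree constant, which matters because
neighbour-joining topologies from too few SNPs are noisy while physically
long windows mix multiple genealogies; the trailing partial block is
dropped for the same reason.  Fixed-physical windows (e.g. 100 kb sliding
by 20 kb) are used for the site-frequency statistics, which benefit from
intra-window recombination.

# Topology weighting

For `k` ingroup taxa there are `(2k-3)!!` possible rooted topologies — 15
for four taxa.  `enumerate_topologies` generates them in a deterministic
canonical order (topologies written with lexicographically sorted
children, then sorted as strings).  The published figure numbering of the
15 topologies cannot be reconstructed fully from text, so identifiers are
bound by structure: callers resolve a topology by its parenthesised form
via `match_topology`, and may attach aliases (`species`, `geography`).

The weighting of a genealogy is the fraction of combinations of one tip
per taxon whose induced rooted subtree matches each candidate topology.
Rather than pruning the tree once per combination, `weight_exact` roots
the genealogy on the outgroup tip, precomputes the pairwise-MRCA table and
the topological depth of every node, and reads off the induced topology of
a combination from depth comparisons alone: the deepest pairwise MRCA
among the chosen tips identifies a cherry, and the relative depths of the
remaining MRCAs resolve the rest.  For four (and three) ingroup taxa this
classification vectorises over thousands of combinations; other `k` fall
back to a generic per-combination merge.  The identity of this fast path
with physical pruning is asserted against an independent brute-force
enumerator (prune, relabel, canonicalise) in the test suite.

Genealogies are first *simplified*: any clade whose tips all belong to one
taxon collapses to a single representative tip with a multiplicity, which
changes no weighting but shrinks the combination count (the product over
taxa of remaining tip counts).  Exact weighting is used when that count is
at most 2,000 (the published threshold); otherwise `weight_sampled` draws
combinations uniformly with replacement in batches of 100 and stops when
the Wilson score interval (95% by default) of every topology's weighting
is narrower than 0.05.  We read the published stopping rule "95% binomial
confidence interval of < 0.05" as *total interval width* below 0.05 — the
stricter of the two plausible readings — and expose it as
`sampling_config(max_ci_width=)`.  Sampling is seeded and deterministic;
hitting `max_draws` (default 20,000) without convergence flags the vector.

`monophyly_summary` reports, per topology, the mean weighting and the
percentage of windows with weighting 1 (complete monophyly of the implied
taxon pairs).  Exact vectors are compared to 1 within 1e-9; sampled
vectors within half the target CI width, since a sampled estimate cannot
be distinguished from 1 more finely than its own resolution.

# Window admixture statistics

All site-pattern statistics use derived-allele frequencies polarised
against the outgroup, which must be present and fixed at a site
(`polarize` drops sites where the outgroup is polymorphic or missing).
With populations arranged `((P1, P2), P3, O)` — P1 the allopatric control,
P2 and P3 the hybridising pair — the per-site discordant pattern
contributions are `abba = (1-p1) p2 p3` and `baba = p1 (1-p2) p3`.
Patterson's D is the normalised window sum.  The admixture proportion fd
divides the same numerator by its value under complete admixture,
substituting the donor frequency `pD = max(p2, p3)` for both `p2` and
`p3` per site.  Because the donor-substituted per-site difference is at
least the raw difference whenever the latter is non-negative, fd lies in
[0, 1] once non-positive numerators are truncated to 0; truncation is the
default because a negative admixture proportion is uninterpretable, and
the raw ratio is emitted alongside (`fd_raw`) for diagnostics.

Fst is a Hudson-type ratio-of-sums estimator (`1 - sum(Hw)/sum(Hb)` with
unbiased within-population heterozygosities), the standard recommendation
for window statistics; the source analysis does not name its estimator, so
this choice is ours.  dXY divides the summed between-population
heterozygosity by the *full* window length in bp, counting monomorphic
positions as zero differences, because both simulated and genomic windows
include invariant sites.  Window sufficiency follows the rule that at
least 50% of samples per population must be genotyped, evaluated as the
mean haplotype call rate per population over the window
(`min_prop_called`); the published phrase is per-window rather than
per-site, and the threshold is configurable.

# Recombination rates

The crossover rate at a position is the slope of a local linear regression
of map position (cM) on physical position (bp).  The published "loess
span = 2 Mb" is a *distance*, not a point fraction, so the implementation
uses a fixed 2 Mb bandwidth with tricube weights (degree 1, no robustness
iterations) rather than any particular loess binding; slopes are floored
at zero because linkage maps are monotone and negative fitted slopes are
numerical noise.  Queries outside the mapped interval are evaluated at the
nearest boundary and flagged.  Because recombination is male-limited in
Lepidoptera, all rates derived from these maps are male-specific; no
sex-averaging is applied.

Externally estimated population recombination rates (rho, consumed from
TSV — their likelihood computation is out of scope) are rescaled to cM/Mb
with one multiplicative constant per chromosome chosen so that the
length-weighted integral equals the chromosome's linkage-map length
(averaged across replicate maps with `average_map_length`).  Rescaling is
exact by construction and preserves the rank order of windows.

# Genome-scan layer

Chromosomes are treated as single arms folded about the physical midpoint
(holocentric Lepidoptera chromosomes lack localised centromeres), giving a
relative position in [0, 1] binned at 5% of the arm.  Gene density is the
unioned CDS coverage of each window via `GenomicRanges`.  Correlations
between fd and recombination use Spearman's rank correlation with average
ranks and the large-sample p-value, after systematic thinning (every k-th
window, default `thin_step = 5`) to reduce serial correlation between
overlapping windows — the published analyses thin but do not state the
scheme, so systematic retention was chosen for determinism — and
optionally restricted to the intermediate 2-8 cM/Mb band.  The
fused-vs-unfused comparison bins windows by crossover rate in 1 cM/Mb
steps up to 7 cM/Mb (beyond which fused chromosomes have too few windows)
and applies a two-sided Mann-Whitney U test per bin; `wilcox.test`
provides the exact distribution for small tie-free samples and the
tie-corrected normal approximation otherwise.  Per-bin p-values are not
multiplicity-corrected, matching the per-bin reporting convention of the
source analysis.

# The synthetic-data generator

Coalescent simulation runs in msprime through a bundled Python worker;
the R layer owns the model description, all stochastic model-level draws
(per-locus migration rates, pulse fractions, worker seeds) and parsing, so
a single R seed reproduces every output byte-for-byte.

**Five-taxon genealogies** (`demography_five_taxon`): species tree
`(((cyd,tim),(melW,melE)),num)`, constant diploid Ne 2,000,000, between-
pair split 6,000,000 generations.  The within-pair split times are shown
only graphically in the source and default here to 4,000,000 generations;
the outgroup split defaults to 16,000,000 generations (about 4 Mya at the
4 generations/year implied by "6 million generations is roughly 1.5
million years").  Both are exposed as parameters.  Continuous migration
connects the sympatric non-sister pairs cyd–melW and tim–melE from the
within-pair splits to the present (the species hybridise where they
co-occur today); each locus draws its own rate from Gamma(shape 1,
scale 3) in migrants per generation (expectation 3), four-fold higher from
cyd into melW and from melE into tim than in reverse — the predominant
directions inferred in the study system.  A drawn value `m` migrants per
generation is interpreted as `Ne x (per-lineage migration fraction)`,
i.e. `4m` on the conventional `4Nm` coalescent scale; the source does not
define its simulator's unit, so the interpretation is documented and the
conversion isolated in one place.  Genealogy tips are haploid samples on
the diploid-scaled model, so pair coalescence occurs at rate `1/(2N)` and
the three-taxon discordance probability `(1/3) exp(-T/(2Ne))` is exactly
the quantity the calibration tests check.

**Four-taxon sequence windows** (`demography_four_taxon`): `((P1,P2),P3)`
plus outgroup, splits at 4, 6 and 16 million generations, admixture as an
instantaneous pulse from P3 into P2 of fraction `f` at 10% of the P2–P3
split time before present (the pulse time is unstated in the source;
recent-relative-to-split is the natural choice and it is a parameter).
Mutation is binary infinite-sites-style at 2.9e-9 per bp per generation
(the accepted *Heliconius* rate); "population recombination at rate of
1%" is ambiguous in the source and is implemented as rho per bp
(`rho_per_bp = 0.01`, i.e. 4Ner per bp), which makes linkage decay well
within a 50 kb window.  Expansion/contraction variants are available via
`size_changes` (10-fold change at the pulse time by default, magnitude
unstated in the source).

**Genome-scan fixtures** (`make_scan_fixture`): at least two chromosomes
with fused/unfused labels; a smooth within-chromosome recombination
profile (`0.4 + 1.2 sin(pi x/L)`, low at the ends) scaled so every
chromosome integrates to the same 55 cM map length — hence shorter
chromosomes recombine faster per bp, as in the study system; a linkage map
integrating that profile at 200 kb marker spacing; CDS intervals drawn
uniformly to a 15% coverage target; and per-window four-taxon sequence
simulations whose pulse fraction is either a monotone increasing function
of the local recombination rate (`coupling = "coupled"`, planting a
recoverable admixture–recombination correlation) or constant
(`"independent"`, the null).  Pulse fractions are deterministic given the
rate so that all between-window variance is genealogical.

## What the generator does and does not emulate

The simulations capture lineage sorting, directional gene flow,
recombination within windows and the admixture–recombination coupling,
which is what the statistics are sensitive to.  They do not emulate
selection (barrier loci arise only through the imposed coupling),
sequencing error, missing data patterns, phasing error, or linkage
*between* windows — fixture windows are unlinked, which is why the scan
tests run without thinning.  Passing tests therefore demonstrate that the
estimators recover truth under the stated demographic conditions, not that
real-data confounders are absent.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero denominators in D/fd/Fst
return NA rather than infinities; empty windows yield zero sites and NA
statistics with dXY/pi 0; NJ refuses incomplete distance matrices; exact
weighting refuses combination counts above threshold with a typed
condition so callers can fall back to sampling.  Ties in the MRCA-depth
classifier cannot produce ambiguity on binary trees (any tie at the
maximum implies the balanced topology, which the second comparison stage
resolves); NJ tie behaviour is ape's deterministic rule.

Test and validation problem sizes are scaled-down versions of the source
designs, chosen so the whole suite runs on a laptop-class machine: 2,000
rather than 20,000 genealogies for the five-taxon gene-flow comparison
(the compared weighting gaps are an order of magnitude larger than their
standard errors at that size), 5,000 loci for the triplet calibration,
25 windows of 20 kb per cell for the admixture-recovery grid, and
2 chromosomes x 12-15 windows for the end-to-end scans.  The Ne-robustness
comparison of fd against Fst and dXY uses ranges *normalised by each
statistic's grand mean across Ne*: the three statistics live on different
scales (dXY is per-bp divergence, an order of magnitude smaller than the
proportions fd and Fst), so absolute ranges would compare units rather
than sensitivity; on the relative scale fd's range is several-fold smaller
than either comparison statistic, which is the robustness claim the
simulations support.

# Known limitations

- The weighting layer assumes one outgroup tip per combination and binary
  genealogies (NJ and msprime both produce them).
- fd underestimates the admixture proportion when Ne is large relative to
  split times (loss of lineage sorting) and when introgression runs
  predominantly from P2 into P3; both behaviours are inherited from the
  estimator, not corrected.
- Crossover rates are only as good as the linkage map locally; the 2 Mb
  bandwidth cannot resolve fine-scale rate variation, which is why rho is
  consumed as a complementary high-resolution track.
- The scan layer treats windows as exchangeable observations after
  thinning; it does not model residual autocorrelation.
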