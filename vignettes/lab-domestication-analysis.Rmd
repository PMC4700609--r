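---
title: "Detecting domestication signatures in laboratory fly strains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domestication signatures in laboratory fly strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labSweeps)
```

# The scientific problem

Laboratory strains of *Drosophila melanogaster* have spent roughly a
century in bottles: a handful of founder flies, tiny effective population
sizes, relaxed natural selection on most traits, and sustained selection
on a few (docility, fecundity in vials). labSweeps asks, given the genomes
of a few inbred lab strains, a large wild population sample and an
outgroup species: which variants are private to the lab, which are
unusually differentiated, whether coding variants show relaxed or ongoing
selective constraint, and where extended haplotypes betray recent
sweeps.

The pipeline has six analysis stages, each usable on its own:

1. **Site filtering and polarisation** (`filterSites`). A site enters the
   analysis only if at least 75% of lab strains and 75% of wild samples
   carry a called base (ceilings: with five strains that means at least
   four), at most two alleles segregate among called ingroup bases, and
   the outgroup base matches one of them. The non-outgroup allele is the
   derived state. Derived alleles seen exactly once in the wild and never
   in the lab are dropped as likely sequencing error. Sites where both
   ingroup alleles differ from the outgroup are unpolarizable and
   excluded; the eligible-site denominator is reported alongside the SNP
   table.
2. **Classification** (`classifyLabSpecific`, `zClassifyFst`). A SNP is
   *lab-specific* when its derived allele is absent from every wild
   sample. Differentiation is measured with Hudson's FST in the
   single-site ratio form
   $F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
   {p_1(1-p_2)+p_2(1-p_1)}$, Z-transformed over all SNPs with defined FST
   (population-form SD, negative values retained so the transform is not
   distorted); SNPs with $Z_{F_{ST}} > 2.5$ are highly differentiated,
   split by which group carries the derived allele at higher frequency.
   Lab frequency classes are fifths of the five-strain site frequency
   spectrum, with 4/4 under one missing strain counting as fixed.
3. **Functional annotation** (`annotateSnps`). Region (5'UTR, CDS,
   intron, 3'UTR, intergenic; one longest transcript per gene), codon
   position, replacement vs silent status, Grantham distance for
   replacements, and the preferred-codon shift class (P2P/P2N/N2P/N2N)
   for silent changes.
4. **Selective-constraint statistics** (`summarizeBins`,
   `simulateNeutral`, `compareBins`). Four parameters per frequency bin —
   mean Grantham score per replacement SNP, replacement/silent ratio per
   individual, the C1/(C2+C3) codon-position ratio, and per-individual
   N2P and P2N proportions — compared by Wilcoxon rank-sum tests against
   a wild reference and against a neutral envelope: $n$ mutations dropped
   uniformly on the coding sequence, each position mutated to one of the
   other three bases with probability 1/3, 1000 replicates, envelope =
   mean ± 1 SD.
5. **Diversity and haplotypes** (`wattersonWindows`, `dxyWindows`,
   `extendHaplotypes`, `haplotypeOutliers`, `randomSiteBaseline`).
   Watterson's $\theta_S = S/(a_n L_{eff})$ in 50 kb windows, Dxy in
   100 kb windows, and the extended-haplotype statistic: from each
   classified SNP, extend left and right while all derived-allele
   carriers agree at called bases and at most one carrier is missing per
   site. Blocks with $Z_{hap} > 2.5$ against the pooled block-length
   distribution are sweep candidates; a random-site baseline gives the
   null block length at matched site counts.
6. **Enrichment and trees** (`categoryEnrichment`, `geneSetEnrichment`,
   `njTree`). Chi-squared category enrichment with BH correction,
   gene-set enrichment with optional gene-length normalisation of the
   background, and neighbor-joining trees on p-distances with
   site-resampling bootstrap.

`runPipeline` chains all stages; `expectedDeNovoSnps` reproduces the
mutation-supply arithmetic that bounds how many lab-private SNPs de novo
mutation alone can explain.

# The synthetic-data generator

Real inputs at study scale (hundreds of genomes, 120 Mb each) are neither
shippable nor needed to validate the statistics. `simulateDataset` builds
a complete miniature study with known truth:

```{r simulate}
cfg <- simulationConfig(genome_length = 20000L, arm_names = c("2L", "X"),
                        n_wild = 20L, pool_size = 60L, seed = 1L)
ds <- simulateDataset(cfg)
ds
```

The generator is forward-in-time. An ancestral pool of haplotypes
receives segregating sites under the neutral site-frequency spectrum
(derived-allele count $i$ with probability $\propto 1/i$), which makes
expected pairwise diversity exactly `ancestral_theta` — the property the
Watterson-recovery checks lean on. The wild panel is drawn from the pool
without replacement. The lab side mimics isofemale-line history: a
founding stock sampled from the pool, an optional shared drift
("domestication") phase, then five strains founded from disjoint founder
sets and inbred as tiny Wright–Fisher populations (with crossover
recombination) until one haplotype fixes — so each strain's consensus has
zero heterozygosity by construction. Strain-private de novo mutations
accrue at the configured per-generation rate. The outgroup is the
ancestral sequence plus divergence.

## Scaling choices, and what they mean

Arms are compressed to tens–hundreds of kb, but every *per-bp* rate keeps
its realistic value: diversity 0.005/bp, outgroup divergence 0.05/bp,
recombination 1e-8/bp/generation, de novo mutation 3.5e-9/bp/generation.
This keeps bp-scale phenomena — haplotype block lengths, sweep flank
spans — on their natural scale. (A per-arm genetic-map rescaling was
considered and rejected: it shreds kb-scale sweep flanks that are real at
these rates.) Missing data is i.i.d. per site per sample, 2% in the wild
and 0.1% in the lab: real missingness is clustered in coverage gaps, and
the i.i.d. rate is chosen to match the *block-truncation hazard* (the
chance that two of five strains are uncalled at the same site) of
realistically clustered missingness, which is what the haplotype
statistics actually feel.

Shared lab drift defaults to zero generations. A shared Wright–Fisher
phase collapses lineages startlingly fast (a 20-haplotype stock keeps
only ~3 lineages after 10 generations), which makes strains clones of one
another and turns whole arms into "shared haplotypes". Configurations
with a drift phase are still available — they are exactly how the
two-fold lab/wild diversity reduction and the monophyletic lab clade are
produced — but the neutral default keeps strains distinct so block-length
statistics behave like a panel of distinct strains.

## Selection

Selected loci are planted as standing variants: the derived allele at
pool frequency `selected_init_freq` (default 0.25), carried on a clean
ancestral-background span of about `sweep_span` (uniform 0.8–1.2×,
default 15 kb) on each side — a young allele on a single shared
background. Each strain's founder set is conditioned to include carrier
founders (at least 40% of founder haplotypes): the loci worth scanning
are, by construction, the ones whose alleles the founders captured.
Selection then acts mechanistically during inbreeding as fitness-biased
transmission (weight $1+s$ per carried selected allele), so fixation
still has to beat drift. One caveat discovered during design: with four
founding individuals per strain there is no room for several selected
loci on the *same* arm to be captured at workable frequencies
simultaneously (classic interference), so multi-locus study designs place
one selected locus per arm.

# Numerical and statistical choices

* **Thresholds.** $Z_{F_{ST}}$ and $Z_{hap}$ cutoffs are 2.5; both Z
  transforms use the population (n) form of the SD over the pooled set.
  Degenerate distributions (zero SD) are errors, not silent zeros.
* **Frequency fifths.** `lab_der/lab_called` mapped by ceiling to
  {0.2, ..., 1.0}; fixed-with-missing (4/4) maps to 1.0.
* **Haplotype congruence** is evaluated over derived-allele carriers
  (non-carriers vary freely); `congruence = "all"` requires agreement
  across all five strains. Single-carrier SNPs get a consensus-run
  measure flagged experimental — it is a different statistic, so
  cross-class comparisons in the tests are restricted to multi-carrier
  classes.
* **Window estimators** use per-window effective n (rounded mean called
  samples at eligible sites) and eligible-bp denominators; windows with
  no eligible sites report missing, not zero.
* **Ratio-statistic bias.** The constraint parameters are ratios, whose
  per-replicate values carry O(1/n) bias relative to the
  infinite-replicate (enumeration) limit. Validation against exhaustive
  enumeration therefore uses many mutations per replicate relative to the
  replicate count, keeping the bias well below the Monte-Carlo SE band.
* **Sweep scans need a background.** The $Z_{hap}$ threshold is
  $\mu + 2.5\sigma$ of the pooled block set, and sweep blocks themselves
  inflate $\sigma$: with $w$ the sweep fraction of blocks, outliers are
  detectable only when $\sqrt{(1-w)/w} \gg 2.5$, i.e. sweeps must be a
  small minority (a few percent) of the block set. Validation runs
  therefore use genomes large enough that the ~200-strong neutral block
  set dominates the five planted sweeps.
* **Baseline contrast is one-sided.** Sweeps elongate haplotypes, so the
  neutral expectation is that the fixed class is not *elevated* above the
  random-site baseline (within 2 SE); shorter-than-baseline fixed classes
  are consistent with neutrality.
* **Subsampling test filters.** The wild-singleton exclusion is lifted
  inside `subsampleSpecificityTest`: subset-private alleles are wild
  singletons by construction, and keeping the guard filter would zero the
  replicate counts.

# What passing tests do and do not show

The generator validates the statistics under its own assumptions:
free-recombining unrelated pool haplotypes, i.i.d. missingness, a single
panmictic wild panel, selection only at planted loci. Real data add
population structure, linkage disequilibrium at fine scales, clustered
coverage gaps, reference bias and alignment error; none of these are
emulated, so green tests certify the implementation and its statistical
behaviour at study-like parameter values — not robustness to every
real-data pathology. The packaged preferred-codon table is likewise a
synthetic default (one preferred codon per amino acid, C/G-ending bias);
analyses of real data should substitute an empirically derived table.

Problem sizes used by the validation suite were chosen to make each
property measurable with comfortable statistical margins: 150 kb arms and
~40-genome wild panels for sweep recovery and clade support, 100 kb and
50 genomes for diversity recovery, 60 kb for the null haplotype
properties, 1000 replicates for the neutral envelope.

# Known limitations

* The wild panel is a single population; the "global populations vs focal
  panel" distinction collapses to one panel.
* The simulator's lab-specific SNPs arise almost entirely from ancestral
  variation missed by the wild sample (plus rare de novo events) — which
  is also the interpretation the mutation-supply arithmetic supports.
* Gene-length normalisation uses the linear (sparse-hit) expectation;
  saturated gene sets (nearly every gene hit) would need an explicit
  per-gene hit-probability model.
* The Sign test in `subsampleSpecificityTest` compares one observed count
  against the replicate distribution; as with the original design, it is
  sharp against upward shifts but its null distribution is not uniform —
  interpret borderline p-values through the replicate quantiles it
  returns.
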