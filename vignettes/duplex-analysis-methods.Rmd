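---
title: "Methods: duplex consensus simulation and ultra-rare variant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex consensus simulation and ultra-rare variant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Duplex sequencing detects substitutions at variant allele frequencies
(VAFs) of 1e-4 to 1e-5 by requiring concordant evidence from both
strands of a single source molecule. Reads carry random double-stranded
molecular tags; the reads from one strand of one molecule are collapsed
into a single-strand consensus sequence (SSCS), and the two
complementary SSCS are joined into a duplex consensus sequence (DCS) in
which any disagreement becomes N. Because polymerase errors,
single-strand DNA lesions (8-oxo-G, cytosine deamination) and
sequencing errors affect one strand only, they survive at the SSCS
level but are erased at the DCS level; only true variants, present on
both strands, persist. This package implements that analysis chain for
a targeted coding region — here a synthetic stand-in for a receptor
tyrosine kinase gene sequenced in sperm DNA pools to quantify ultra-rare
de novo mutations, their spectra, and selection (dN/dS) signatures of
clonal expansion in the male germline.

`duplexr` is tidyverse-shaped: every analysis function takes a data
frame and returns a tibble, so stages chain with the pipe; fitted
result objects carry `tidy()`/`glance()` methods and `plot_*()` /
`autoplot()` visualisations.

## The synthetic-data generator

`simulate_library()` emulates the statistical structure the analysis
relies on, per source molecule:

* **Tags and families.** Each molecule gets two random 12-mers (the
  double barcode). Each strand founds a read family whose size is drawn
  iid from `1 + Geometric(mean - 1)` with mean 6 read pairs per strand
  (the family-size law of the real libraries is not published; a
  geometric law with a mean of a few reads is what under-amplified
  duplex libraries typically show, and the value is configurable).
  Pairs whose first mate carries the lexicographically smaller tag are
  the "ab" orientation, the mirror pairs "ba" — exactly the information
  the consensus caller uses to separate strands.
* **True variants** are carried by each molecule independently with the
  configured molecular fraction, on both strands, so the expected VAF
  equals the fraction.
* **Strand-asymmetric damage.** 8-oxo-G lesions convert a G on one
  strand (read as G>T on that strand, C>A in transcript coordinates
  when the lesion sits on the bottom strand) at 5e-6 per base;
  cytosine deamination converts a C on one strand (C>T / G>A) at
  2e-5 per base. The defaults put deamination above oxidation, the
  usual ordering in enzymatically fragmented libraries, at rates that
  reproduce a clear SSCS-level artifact excess while remaining
  realistic for fresh genomic DNA.
* **PCR jackpot errors** are placed on the branching duplication tree:
  every read pair draws a random leaf path through `pcr_cycles = 20`
  duplications; each distinct tree edge spanned by the family can
  mutate any base at 1e-6 per base per duplication (a high-fidelity
  polymerase), and the error propagates to every descendant read.
  Early-cycle errors can therefore dominate a whole strand family —
  the jackpot — but never both strands.
* **Sequencing errors** hit every mate independently at 1e-3 per base
  (Illumina-like). Base qualities are emitted constant (Q37), so
  quality trimming is a no-op unless the generator is configured to
  degrade read ends.

Reads are materialised as standard paired FASTQ (or kept in memory as a
tibble); each ~440 bp subregion is fully covered by the two 300-base
mates, whose 288-base inserts overlap in the fragment middle. With
23,000 molecules per subregion and the default family-size law, about
48% of molecules yield an SSCS pair with at least 3 reads per strand,
giving a per-position DCS coverage close to 11,000 — the working depth
of the study conditions this generator models.

What the generator does **not** emulate: restriction-fragment end
heterogeneity, capture-efficiency differences between subregions,
per-cycle quality decay, tag errors/collisions, and indels. Passing
tests therefore demonstrate the correctness of the statistical
machinery under the modelled error structure, not performance on real
reads with alignment artifacts.

## Consensus calling

`build_sscs()` implements the per-position rule: the consensus base is
the unique base supported by at least `majority = 0.7` of non-N
observations; no winner, or two bases tying at the threshold, gives N.
Families below `min_family_size = 3` reads per strand are rejected.
`build_dcs()` keeps positions where both strand consensuses agree on a
non-N base and masks everything else. The external pipeline the study
used does not print its thresholds, so both values are package
defaults, exposed in the configuration and recorded in every run log.
The batch engine (`call_consensus()`) computes identical results from
sparse read-versus-reference deviations so that a ~275,000-pair library
is processed in seconds; a property test checks it against the literal
per-family implementation.

Coverage bookkeeping: a DCS exists only when both strands reach the
minimum family size; pileup coverage at a position counts non-N DCS
bases, so allele counts always sum to coverage.

## Variant calling and filtering

`call_variants()` emits one call per (position, alternate) with at
least one supporting DCS; VAF = alternate DCS count / DCS coverage.
Tiers summarise the evidence quality: tier 1 requires every supporting
family to have at least 3 reads on both strands with at least 75%
alternate support on both; tier 2 requires at least one read per
strand in full agreement; anything weaker is "lower". A variant seen at
a VAF of at least 0.05 in **all** libraries sharing a donor pool and
target panel is masked as a SNP (the underlying germline rule is
"about 10%"; 0.05 is a deliberately permissive implementation of that
approximation and is configurable). The final table keeps exonic and
splice-region, non-SNP calls with coverage at least 1000 that are
tier 1, or tier 2 and detected more than once across the analysis set
(identical substitution, position and alleles; counting is invariant
to library order). "Detected more than once" is counted across
libraries, matching how recurrent substitutions are counted once per
library in the frequency numerator.

## Mutation frequencies

The overall mutation frequency is

$$\mathrm{freq} = \frac{\sum_i \mathrm{variant\_count}_i}
{\sum_i \overline{\mathrm{cov}}_i \times \mathrm{region\_size}_i}$$

summed over libraries, with identical substitutions collapsed within a
library and counted once per library across libraries. The default
analysis scope restricts both the numerator (exonic calls) and the
denominator (exonic positions, mean DCS coverage over them) to the
coding footprint; `scope = "all"` switches to every sequenced position
since published descriptions leave the denominator convention open —
reports name the mode. Confidence intervals are exact Garwood (Poisson
chi-square quantile) intervals, chosen over normal approximations
because the counts are tiny. Stratified frequencies reuse the formula
with stratum-restricted numerators and stratum-appropriate
denominators (a protein domain's footprint for domain strata); group
comparisons use pairwise chi-square tests on count-versus-exposure
tables with Bonferroni–Holm correction, plus Fisher's exact test for
small tables.

## Mutational spectra

Spectra are pyrimidine-centred (classes C>A, C>G, C>T, T>A, T>C, T>G in
fixed order; purine-reference variants folded by reverse complement),
optionally within the trinucleotide context (96 categories, contexts
ordered alphabetically within class). Each category carries its
opportunity — the number of reference alleles (or contexts) in the
region — and the per-type normalised frequency divides the count by
(opportunity / region size) × total sequenced nucleotides. The
bootstrap cosine reference draws `n` mutations from the reference
spectrum's category distribution 1000 times and computes the cosine of
each resample against the original reference, where `n` is the query's
mutation count; resampling both sides is available as a switch because
the verbal description of the procedure is ambiguous, and resampling
only the query-sized sample is the stricter, documented default.

## Selection analysis

Synonymous and nonsynonymous site counts follow Nei–Gojobori: each
codon position contributes (synonymous single-base changes)/3
synonymous sites, so every codon contributes exactly 3 sites. Changes
creating a stop codon count as nonsynonymous (stop-gained variants are
nonsynonymous observations); splice-region variants are excluded from
dN/dS; the analysed regions are assumed sense-codon only. dN is the
nonsynonymous count per nonsynonymous site, dS the synonymous count
per synonymous site; dS = 0 leaves the ratio undefined rather than
infinite.

The randomization null asks what dN/dS would look like if the observed
mutational spectrum fell at random with respect to synonymous and
nonsynonymous sites: each of 1000 iterations places n mutations by
drawing a 6-class substitution from the observed spectrum and then a
uniformly random compatible site (with replacement — n is far below the
number of sites, so collisions are negligible and the contract stays
simple). The null range is reported as the 2.5th/97.5th percentiles by
default, with min/max available, because the source material reports
only a "lower/upper range" without defining it. The 6-class spectrum is
preserved by default (a 96-context-preserving null would need context-
conditional site pools and adds little at these mutation counts). Under
a spectrum uniform over all possible single-base changes the null
median is 1 by construction — the defining property of the
normalisation, covered by a test at n = 200 on a 300-codon region.

Per-stratum reports (domain × age group) use the domain's own codon
footprint for site counts and the pooled coding spectrum for the null,
a deliberately stable choice when strata contain few mutations.

## The synthetic reference

`synthetic_reference()` builds a random 4415 bp gene model — 13 exons
(806 sense codons), ten ~440 bp subregions covering 4405 targeted
positions, three protein domains — with three codons pinned (373 TAC,
380 GGG, 540 AAC) so that the well-known receptor substitutions
c.1118A>G (p.Y373C), c.1138G>A (p.G380R) and c.1620C>A/G (p.N540K) are
reproduced by the annotation code. It is explicitly synthetic: a
stand-in with the study's target architecture, not the real gene
sequence. Domain residue boundaries (IgI-III 23–369, TM inter-domain
370–471, TK 472–755) are documented assumptions chosen to place those
residues in their described domains.

## Numerical choices and degenerate inputs

* Ties at exactly the consensus majority threshold are called N
  (conservative).
* Zero-coverage VAFs, zero-exposure rates and zero-vector cosines are
  errors, not NaNs; dS = 0 gives an NA ratio; empty strata produce
  frequency 0 with a one-sided Poisson interval.
* All internal coordinates are 0-based half-open; every written report
  and the VCF-style output are 1-based.
* Every stochastic step takes an explicit seed; identical configuration
  and seed reproduce byte-identical reports.

## Problem sizes used in the shipped experiments

The validation experiments run three independent spike-in series of
four libraries (fractions 0.1 to 1e-4, four variants each, one
subregion per library at 23,000 molecules, duplex coverage ~11,000) and
average detection and log-log R² across series; the error-suppression
experiment uses a 3,000-molecule null library; VAF-recovery checks use
2,600-molecule libraries over three seeds; unit tests run miniature
libraries of 40–400 molecules. These sizes give stable statistics at
interactive runtimes on a single CPU.

## Known limitations

Real-data alignment is out of scope (simulated reads are
coordinate-anchored by construction); indels and structural variants
are not called; tag error correction and duplex clustering are not
modelled; signature refitting against published catalogues is not
performed — the spectrum module only compares against externally
supplied reference spectra.
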