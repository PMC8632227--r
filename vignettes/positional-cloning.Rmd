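---
title: "From a variant catalogue to a cloned recessive locus: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a variant catalogue to a cloned recessive locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `indelmapr`, the
parameters that matter, and the decisions taken where the design was
genuinely open. The package addresses a common forward-genetics workflow
in selfing crops: two inbred accessions are resequenced against one
reference, their polymorphisms are catalogued and annotated, a subset of
InDels becomes cheap agarose-gel markers, and those markers — together
with pooled-sequencing allele frequencies — positionally clone a
recessive mutant locus segregating 3:1 in an F2 population.

## The synthetic-data generator

Every stage is testable without external data because the generator
produces all inputs from one seed. Its defaults encode the study
conditions the package is built around:

* SNP rate 2719.65 per Mb and InDel rate 485.61 per Mb (one SNP every
  ~368 bp, one InDel every ~2,059 bp);
* transition bias 0.732, the fraction implied by a Ts/Tv ratio of 2.73;
* InDel length mixture (1 bp, 2–20 bp, 21–200 bp) of 48.07 % / 44.34 % /
  6.70 % (normalised — the three printed shares sum to 99.11 %);
* 21.44 % of variant calls emitted heterozygous;
* an F2 of 982 individuals with one recessive causal mutation, expected
  to segregate 3:1.

Genes are placed non-overlapping with 2–5 exons, 5′/3′ UTRs, a CDS that
starts with ATG, ends with a stop, contains no internal stop, has length
divisible by 3, and canonical GT..AG intron dinucleotides. Minus-strand
genes are laid out by mirroring a transcript-forward layout, so both
strands are exercised equally.

**The cross.** The mutant parent is modelled as the reference background
carrying a single planted G→A substitution on the coding strand of a
gene near the requested position; the site is chosen so the change is
missense (EMS-type mutageneses overwhelmingly produce G:C→A:T
transitions, and a phenotype-causing allele must alter the protein). The
mapping parent is the reference plus all homozygous accession variants.
Heterozygous calls in the truth set are deliberate artifacts that
exercise downstream zygosity filters: two inbred cultivars carry no
segregating sites, so such calls are excluded from the alternate genome
and from pool allele frequencies.

**Recombination.** Each F2 gamete receives one obligate crossover per
chromosome plus a Poisson(1) number of extras at uniform positions. No
genetic map is assumed; this is a deliberately simple stand-in that is
sufficient for marker-based recovery experiments, not an inference about
any real map. On the short synthetic chromosomes used in tests this
makes per-bp recombination much denser than in a real genome, which
shrinks mapping intervals; conclusions about *rates* of recovery
transfer, absolute interval sizes do not.

**Markers for the F2.** `pick_genomewide_markers()` selects homozygous
20–200 bp InDels at quantile positions per chromosome (emulating an
evenly spaced genome-wide set), and the recovery experiment adds a
ladder of fine markers at fixed offsets around the causal site
(±30 kb, ±10 kb, ±3 kb, ±0.5 kb by default). F2 genotypes are taken from
local ancestry, i.e. every marker is treated as perfectly informative
and co-dominant — the behaviour of a good agarose InDel assay.

**What the generator does not emulate:** sequencing reads and their
errors, alignment and variant-calling artifacts,
linkage-disequilibrium-structured accession panels (panel genotypes are
drawn independently per locus from a per-locus allele-frequency prior,
Beta(1.2, 1.2) by default), band intensities on gels, segregation
distortion, and polygenic or incompletely penetrant phenotypes. Passing
tests therefore demonstrate correctness of the analysis logic under
idealised inputs, not robustness to upstream calling noise.

## Variant catalogue

Definitions follow the VCF convention: positions are 1-based; InDels are
left-aligned with an anchor base, and `indel_len` excludes the anchor.
A record is an SV when it is a symbolic inversion or an
insertion/deletion of ≥100 bp (configurable); SVs are excluded from the
InDel length classes (1 / 2–20 / >20 bp). The Ts/Tv ratio is reported as
undefined (`NA`) when there are no transversions, never as infinity.
Window densities use half-open, BED-like windows `[k·w, (k+1)·w)`, the
last window truncated and scaled by its true width; density denominators
use the full declared chromosome length with no gap exclusion, matching
how per-Mb figures are usually quoted. Mean spacing is
`covered length / count`, equivalently `1e6 / density-per-Mb`.

## Effect annotation

Each homozygous variant receives exactly one region by fixed precedence:
CDS > splice region > 5′/3′ UTR > intron > 5-kb upstream > 5-kb
downstream > intergenic. Choices behind that rule:

* **Splice region** = first/last 2 bp of each intron (the canonical
  donor/acceptor dinucleotides). The width is a parameter
  (`splice_width`) because conventions differ.
* **Mutually exclusive categories** make proportions sum to 100 %. When
  a variant sits in the flanking zones of two genes the nearer gene
  wins; at an exact distance tie upstream beats downstream.
* **One transcript per gene.** Proportions are reported at gene level;
  multi-transcript aggregation is out of scope.
* **InDels are located by their first changed base** (anchor + 1), so an
  InDel overlapping a CDS boundary is classified by where it starts to
  differ.

Inside a CDS, the affected codon is rebuilt on the coding strand and
both alleles are translated with the standard nuclear code: synonymous,
missense (with amino-acid change, e.g. `G245E`), stop gain/loss, or
start loss when the initiator ATG is disrupted. InDels are frameshift
when `indel_len mod 3 ≠ 0`, otherwise in-frame. Large-effect classes are
frameshift, splice change, start loss and stop gain/loss. Two invariants
are enforced by tests: agreement with a brute-force translate-both-codons
oracle over random codons and substitutions, and exact invariance of all
calls under reverse-complementing the genome and flipping every gene.

## Marker design

**Screening.** Homozygous insertions/deletions of 20–200 bp are
candidate markers; 20 bp is the smallest length difference reliably
resolved on a 3 % agarose gel, and 200 bp keeps both parental products
inside the amplicon-size envelope. A candidate is discarded when another
InDel of ≥5 bp lies within 350 bp — an invented but conservative
"clean flank" rule so the assay measures only the target polymorphism.
Both thresholds are parameters; tests that verify exact predicted
product sizes on the alternate genome tighten the rule to exclude *all*
flanking InDels, since any untyped InDel inside the amplicon shifts the
product size.

**PIC.** Marker informativeness across an accession panel uses the
heterozygosity-corrected form standard in marker literature,
`PIC = 1 − Σpᵢ² − Σ_{i<j} 2pᵢ²pⱼ²`; a plain expected-heterozygosity
variant (`1 − Σp²`) is available via `method = "expected_het"`. The
screening threshold is strict (`PIC > 0.5`): a locus at exactly the
threshold is rejected. For a biallelic locus PIC is maximised at
allele frequency 0.5 (PIC = 0.375), which tests verify by grid search.

**Primers.** The design envelope is: product 200–350 bp on the reference
allele, primer 18–29 nt, Tm 55–64 °C, GC 35–65 %, homopolymers ≤4, and
no 3′ G/C run longer than 3. Melting temperatures use unified
nearest-neighbor thermodynamics with the entropic salt correction
(`ΔS + 0.368·N·ln[Na⁺]`) at 50 mM monovalent cation and 50 nM total
oligo — common primer-design defaults. All primer windows in ±400 bp
flanks are enumerated; among constraint-satisfying pairs the one
minimising `|Tm_f − 59.5| + |Tm_r − 59.5|` wins, ties broken by leftmost
forward then leftmost reverse primer, making designs fully
deterministic. Infeasible candidates return an explicit design-failure
record rather than being silently dropped (real marker sets also contain
non-amplifying assays). `insilico_pcr()` validates an assay by locating
both primer sites on each parental genome (optionally tolerating a
couple of substitutions per site, as annealing does) and checking that
exactly one product appears per genome with sizes differing by the InDel
length. Dimer/secondary-structure thermodynamics beyond the 3′-clamp
screen are out of scope.

## BSA mapping

**Pooling.** The recessive bulk is sampled once (one DNA pool) and its
mutant-parent allele fraction per marker is computed from member
genotypes, `(2·#A + #H) / (2·n)`; band intensities are not modelled.
Pool calls use 0.9/0.1 thresholds (A-like / B-like / H-like).

**Coarse mapping.** Markers unlinked to the locus sit near 0.5 in a
recessive bulk; the causal region is skewed toward 1. Each marker gets a
one-sided binomial test against 0.5, Bonferroni-corrected across
markers — with a few dozen tests a conservative correction costs little
power and avoids false peaks. The maximal-fraction marker is reported
only when significant; permuted phenotypes therefore rarely yield any
call.

**Fine mapping.** Among phenotypically recessive individuals, any
non-`A` genotype at a marker is a recombinant between that marker and
the locus. The interval is delimited by the nearest flanking markers
showing ≥1 recombinant on each side of the zero-recombinant core; when
no marker is recombinant-free (dense recombination, as on the short
synthetic chromosomes), the markers with the minimal recombinant count
are bracketed instead, with a warning. Genes overlapping the interval
become the candidate list.

**Candidate nomination.** The filter for a recessive EMS-induced causal
SNP inside the interval: alternate-allele frequency ≥0.9 in the mutant
pool, within [0.20, 0.45] in the wild pool (the expectation for a
recessive allele among phenotypically wild F2 plants is 1/3), G→A or
C→T substitution, and a protein-altering annotation (missense or any
large-effect class). Every threshold is an argument; the EMS restriction
can be disabled for non-EMS mutants. The wild-pool window already uses
the second bulk's information, so no separate Δ(SNP-index) statistic is
computed.

## Problem sizes and numerical choices

Tests and the acceptance script run the recovery experiment on a genome
of 3 × 400 kb chromosomes with 45 genes, 982 F2 individuals, a
30-recessive bulk over 6 markers per chromosome, and an 8-marker fine
ladder — population sizes at study scale, genome scaled to keep a full
seeded replicate in a few seconds. Replicated runs (50 seeds in the
acceptance suite) measure how often the fine interval contains the
planted mutation and how often the scan ranks it first. All random draws
flow from a single integer seed per run; generators record their seed in
output headers, and reruns of the pipeline are byte-identical.

Degenerate inputs are handled explicitly rather than numerically: no
transversions → undefined Ts/Tv; no synonymous calls → undefined NS/S
ratio; empty mapping interval → empty candidate list with a warning;
infeasible primer constraints → failure record; PIC input frequencies
must sum to 1 within 1e-9.

## Known limitations

* The simulator's idealisations listed above; in particular, marker
  genotypes are error-free, so genotyping-error robustness is untested.
* Region precedence is one defensible convention among several; tools
  differ, and percentages shift slightly under other precedence rules.
* The nearest-neighbor Tm model ignores divalent cations and dNTP
  corrections; designed primers should still be sanity-checked by any
  full-featured design tool before ordering.
* Fine-mapping assumes fully penetrant, phenotype-verified recessives;
  misphenotyped individuals would inflate recombinant counts at all
  markers.
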