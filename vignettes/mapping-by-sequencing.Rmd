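---
title: "Mapping a recessive splice-site mutant from pooled F2 sequencing"
author: "poolscan"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

# The experimental design this package models

A recessive mutant is isolated from an EMS-mutagenized population of a
diploid, selfing plant. Crossing the mutant to a wild-type accession and
selfing the F1 yields an F2 population in which the mutant phenotype
segregates 3:1 (wild type : mutant) if a single recessive locus is causal.
Two bulks are formed — one of mutant-phenotype plants, one of wild-type
plants — and sequenced together with both parents. Near the causal locus the
mutant pool is fixed for the mutant haplotype while the wild-type pool
carries it at an expected allele frequency of 1/3; far from the locus both
pools drift around 1/2. The package turns that allele-frequency contrast
into a mapped interval, a shortlist of candidate variants, and a mechanistic
prediction for splice-site candidates.

# The ED statistic and the scan

For each biallelic variant, each pool contributes a nucleotide-frequency
vector over A, C, G, T (for InDels, over two ref/alt pseudo-alleles: read
support is mapped onto two slots so the identical machinery applies). The
association statistic is the Euclidean distance

$$\mathrm{ED} = \sqrt{\sum_{b \in \{A,C,G,T\}} \left(f^{\text{mut}}_b -
f^{\text{wt}}_b\right)^2},$$

which is 0 when the pools agree and $\sqrt{2}$ when they are fixed for
different alleles. Sites with pool depth below `min_depth` (default 4) are
excluded rather than divided by zero.

The raw ED track is noisy, so the scan works on a smoothed profile: at each
variant, a tricube-weighted mean of $\mathrm{ED}^k$ over variants within
half a window (`window_bp` default 2 Mb, `k` default 1) on the same
chromosome. The smoother was chosen to be deterministic, window-local, and
loess-like in shape; the variant itself always contributes, so isolated
variants keep their own value, and no smoothing crosses a chromosome
boundary. Powered-ED variants of the scan are widespread, which is why the
exponent is exposed; the default follows the plain distance.

The significance threshold is `median(fitted) + 3 * sd(fitted)` computed
genome-wide over the fitted values, with the sample (n−1) standard
deviation. Candidate regions are maximal runs of consecutive variants at or
above the threshold (ties inclusive, so the rule is deterministic); runs on
one chromosome closer than `merge_gap_bp` (default 100 kb) merge; merged
runs with fewer than `min_variants` (default 10) above-threshold variants
are dropped, which suppresses isolated false positives at 20–60x depths.
Region bounds are the outermost above-threshold variant positions snapped
outward to the 10-kb grid, and sizes are reported in Mb rounded half-up to
two decimals — the conventions of published region tables.

# From region to candidate: the homozygous-differential filter

Within a candidate region, a variant is a plausible recessive cause only if
its genotype pattern matches the cross: mutant parent and mutant pool
homozygous for the alternate allele, wild-type parent homozygous reference,
and the wild-type pool **either heterozygous-looking or reference** — the
dominant-phenotype pool is expected to carry the mutant allele at fraction
1/3, so excluding heterozygous wild pools would discard exactly the true
signal. Genotypes are called from allele-depth fractions with `hom_frac`
(default 0.90, which tolerates one stray read at ~20x) and `min_depth`
(default 4). A site below `min_depth` in any of the four roles is called
LOW_DEPTH and dropped with the reason recorded; LOW_DEPTH takes precedence
over the fraction thresholds because a two-read site should never be called
homozygous, even though a fraction-first reading of the rule is conceivable.

Survivors are classified against gene models by strand-aware positional
windows that follow mainstream annotator conventions: splice donor and
acceptor are the first/last 2 intronic bases, the splice region covers
exonic bases 1–3 at a junction and intronic bases 3–8, upstream/downstream
extend 5 kb from the gene span, CODING is inside the CDS, INTRON elsewhere
in an intron, INTRAGENIC inside the gene but in no transcript feature, and
INTERGENIC otherwise. Exonic non-coding (UTR-like) bases away from
junctions also map to INTRAGENIC: the category set deliberately has no UTR
label, and inventing one would change the report format. One category per
(variant, gene) pair; the reported effect is the highest-priority one over
all nearby genes, with priority
donor > acceptor > splice region > coding > intron > upstream > downstream >
intragenic > intergenic. The shortlist is ordered by that priority, then ED
descending, then position — splice-site variants with strong pool contrast
surface first.

# The splice engine

For a donor-site mutation the engine enumerates what the spliceosome can do
once U1 snRNP no longer recognizes the authentic 5' splice site:

* **Intron retention** — the intron stays in the mature transcript;
  translation reads into it and usually meets a premature stop.
* **Cryptic donor** — U1 recognizes a canonical GT inside the upstream
  exon; splicing there deletes the exon's 3' tail. One transcript is
  emitted per GT found within `scan_bp` (default 200 bp) of the broken
  junction, nearest first. No splice-strength scoring is attempted: the
  design goal is to enumerate candidate products, not rank their
  efficiencies, and a single observed product motivated the nearest-first
  order.

All splice logic runs in transcript orientation (minus-strand genes are
reverse-complemented once, then treated identically), which makes the
engine strand-invariant by construction — a property the tests verify by
mirroring whole genes. CDSs are rebuilt from the variant transcript,
translated with the standard genetic code, and cut at the first in-frame
stop; a missing stop raises a flag instead of failing. Protein diffs are
classified as TRUNCATION (variant is a proper prefix), INTERNAL_DELETION
(prefix + suffix match, one contiguous block removed), IDENTICAL, or OTHER.
Acceptor mutations and exon skipping are out of scope. Ambiguity codes in a
CDS are an error, not silently translated.

The packaged five-exon demonstration gene (`causal_gene_fixture()`) is
engineered so the three outcomes carry distinct, hand-checkable
arithmetic: a 1338-nt CDS (445 aa), intron retention that terminates after
two intronic codons (456-nt CDS, 151 aa), and a single cryptic GT 54 bp
upstream of the junction giving an in-frame 1284-nt CDS (427 aa, 18
residues deleted). Its filler sequence uses A/C-only codons, so no stray GT
donors or stop codons can arise by accident.

# The simulator

`sim_config()` encodes the study conditions: pools of 37 + 37 plants from a
400-plant F2, per-sample mean depths of 22x/57x (parents) and 49x/58x
(pools), 2000 homozygous background SNVs in the mutant parent with 95%
G:C→A:T transitions (the EMS signature), a symmetric per-read error rate of
0.002, 4 cM/Mb recombination, and one fully penetrant recessive causal SNV
placed on the donor of the demonstration gene's second intron. Gametes
recombine under a Haldane (no-interference) model: crossover counts are
Poisson with the chromosome's genetic length, breakpoints uniform on the
genetic map, chromosomes assorting independently. Depths are Poisson,
alternate-read counts binomial at the pool allele frequency perturbed by the
error rate. One seed drives everything; a fixed seed reproduces every output
byte-for-byte.

The default genome is **seven 30-Mb chromosomes** with the signal on
chromosome 1. This is a deliberate design point: the genome-wide
median + 3 SD threshold only makes sense when most of the genome is
genetically unlinked to the causal locus. On a single 30-Mb chromosome
(~120 cM) every variant is linked — the selected pools skew allele
frequencies everywhere, the median fitted ED rises to ~0.4, and the
threshold exceeds the theoretical ED ceiling at the causal locus itself, so
no region can ever be called. A multi-chromosome genome restores the
near-zero background that real experiments have; single-chromosome
configurations remain available for studying exactly that failure mode.

Two null modes exist. `all_reference = TRUE` sequences reference material
in all four roles, so alternate reads arise only from sequencing error;
this is the null used to check that the region caller stays quiet. Note
that even this null is not perfectly silent: error reads cluster by chance,
the error-regime threshold is tiny, and neighboring smoothed values share
windows, so an occasional run produces one small false region — the
acceptance script reports the observed rate rather than hiding it. The
second mode, `causal = FALSE` with the EMS background still segregating,
is deliberately harsher: pools of 37 random individuals undergo
chromosome-scale haplotype drift that produces smooth multi-Mb ED bumps,
and a genome-wide median + 3 SD threshold will flag one or two of them in
most runs. That behavior is a real property of small-pool BSA designs (and
a reason practitioners inspect profiles rather than trust thresholds
blindly), not an implementation artifact.

What the simulator does **not** emulate: read-level artifacts (no FASTQ, no
mapping bias, no base-quality structure), InDel length spectra (InDel
support enters through hand-built VCF fixtures exercising the pseudo-allele
path), crossover interference, segregation distortion, and incomplete
penetrance. Passing tests therefore demonstrate the statistical machinery
under idealized sampling, not robustness to alignment pathology.

# Numerical and interface choices

* Coordinates are 1-based closed at every file boundary (VCF/GFF
  convention) and 0-based half-open internally; the converters are inverse
  bijections and property-tested.
* Sample roles (mutant/wild-type parent and pool) are always given
  explicitly by a role map, never inferred from VCF column order: a silent
  pool swap would invert every filter.
* Multi-allelic VCF records are skipped with a message by default (EMS
  bulks are overwhelmingly biallelic) or split on request.
* Region sizes round half-up (not banker's rounding) to match printed
  tables; bounds snap outward to 10-kb multiples.
* The VCF and GFF3 emitters are deterministic and timestamp-free, so
  read → write → read is a fixed point and fixed-seed runs are
  byte-identical.
* The segregation chi-square applies the Yates continuity correction by
  default for the 1-df test (configurable); the 5% critical value is
  computed from the chi-square distribution, not hard-coded.
* CAPS/dCAPS digest logic finds overlapping recognition-site occurrences
  left to right and cuts at `site_start + cut_offset`; fragment multisets
  decide allele distinguishability, mirroring gel logic. Only exact-match
  recognition sequences are supported.

# Problem sizes used by the test suite

The unit and property tests run the simulator at a reduced scale chosen to
keep the suite quick while preserving the scan's geometry: the same seven
30-Mb chromosomes but half the variant density (1000 background SNVs), 300
F2 plants, and 200 background gene models; depths, pool sizes and the
causal position stay at study defaults. The end-to-end acceptance checks
run the full default configuration (2000 variants, 400 F2) over 20 fixed
seeds for both the recovery and the null experiment. Randomized property
tests (ED invariants, smoothing oracles, translation length laws) use fixed
seeds throughout, so every run of the suite is reproducible.

# Known limitations

* The effect classifier handles one transcript per gene (the first mRNA of
  a gene is used; alternatives are logged and ignored).
* The cryptic-donor search considers only canonical GT dinucleotides in the
  upstream exon; non-canonical donors (GC-AG introns) and downstream-exon
  (acceptor-side) events are not modeled.
* The ED scan assumes biallelic variants; multi-allelic records must be
  split upstream.
* The threshold rule is global; organisms with very long chromosomes
  relative to total genome size weaken it, as the single-chromosome analysis
  above shows.
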