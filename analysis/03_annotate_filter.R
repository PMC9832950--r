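#!/usr/bin/env Rscript
# Stage 3: candidate shortlist.
#
# Restricts the variant table to the candidate regions from stage 2, applies
# the homozygous-differential filter (mutant parent and mutant pool
# homozygous alternate, wild-type parent homozygous reference, wild-type
# pool heterozygous or reference — the expected pattern of the causal locus
# in a recessive F2 design), classifies each survivor's effect against the
# gene models, and ranks by effect priority, then ED.

suppressMessages(library(poolscan))

roles <- setNames(sample_roles(), sample_roles())
variants <- read_vcf("results/sim/pools.vcf", roles)
genes <- read_gff3("results/sim/genes.gff3")
regions <- utils::read.delim("results/regions.tsv")
points <- utils::read.delim("results/points.tsv")

in_region <- rep(FALSE, nrow(variants))
for (i in seq_len(nrow(regions))) {
  in_region <- in_region | (variants$chrom == regions$chrom[i] &
                              variants$pos >= regions$start[i] &
                              variants$pos <= regions$end[i])
}
cat(sum(in_region), "variants fall in candidate regions\n")

surviving <- homozygous_differential_filter(variants[in_region, ],
                                            min_depth = 4, hom_frac = 0.9)
cat(nrow(surviving), "survive the homozygous-differential filter\n")

eff <- classify_effects(surviving, genes)
shortlist <- cbind(surviving, eff)
key <- paste(points$chrom, points$pos)
shortlist$ed <- points$ed[match(paste(shortlist$chrom, shortlist$pos), key)]
shortlist <- rank_candidates(shortlist)

cat("effect categories:\n")
print(table(shortlist$effect))
cat("top candidate:\n")
print(shortlist[1, c("chrom", "pos", "ref", "alt", "effect", "gene_id", "ed")])

write_shortlist_tsv(shortlist, "results/shortlist.tsv")
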