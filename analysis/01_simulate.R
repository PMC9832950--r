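#!/usr/bin/env Rscript
# Stage 1: generate the synthetic pooled-sequencing experiment.
#
# Simulates an EMS-mutagenized F2 mapping population: a recessive causal
# donor-site SNV on chromosome 1 of a seven-chromosome genome, 2000
# G:C->A:T-biased background SNVs, two phenotype-selected pools of 37 plants,
# and parent/pool short-read depths of 22-58x. Writes the VCF, gene models
# and ground truth that the later stages consume.

suppressMessages(library(poolscan))

seed <- 1L
out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg, dir = out_dir)

cat("simulated", nrow(sim$variants), "variants on",
    length(cfg$chrom), "chromosomes\n")
cat("F2 phenotypes:", sim$truth$n_wildtype, "wild-type vs",
    sim$truth$n_mutant, "mutant\n")
cat("causal SNV:", sim$truth$causal_chrom, sim$truth$causal_pos,
    "in", sim$truth$causal_gene_id, "\n")
cat("wrote pools.vcf, genes.gff3, truth.tsv under", out_dir, "\n")
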