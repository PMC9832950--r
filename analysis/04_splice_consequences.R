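#!/usr/bin/env Rscript
# Stage 4: splice consequences of the top candidate.
#
# The top-ranked candidate is a donor-site SNV (G>A at the first base of the
# causal gene's second intron). The splice engine enumerates the outcomes a
# broken donor leaves to the spliceosome: retain the intron (premature stop)
# or use a cryptic GT in the upstream exon (in-frame partial exon deletion),
# reconstructs each CDS, translates, and diffs the proteins.

suppressMessages(library(poolscan))

shortlist <- utils::read.delim("results/shortlist.tsv")
top <- shortlist[1, ]
cat("top candidate:", top$chrom, top$pos, paste0(top$ref, ">", top$alt),
    top$effect, "in", top$gene_id, "\n")

# the simulation's causal gene, with its local reference and mutant sequence
fx <- causal_gene_fixture(chrom = top$chrom, causal_pos = top$pos,
                          gene_id = top$gene_id)
cons <- predict_donor_mutation_consequences(fx$gene, fx$genome_mut,
                                            intron_index = fx$intron_index,
                                            scan_bp = 200)
ref_protein <- cons[[1]]$protein
for (tv in cons) {
  d <- diff_proteins(ref_protein, tv$protein)
  cat(sprintf("%-17s CDS %4d nt  protein %3d aa  premature_stop %-5s  %s",
              tv$kind, nchar(tv$spliced_cds), nchar(tv$protein),
              tv$premature_stop, d$type))
  if (d$aa_removed > 0) cat("  (", d$aa_removed, "aa removed )")
  cat("\n")
}

write_transcripts_tsv(cons, "results/transcripts.tsv")
cat("wrote results/transcripts.tsv\n")
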