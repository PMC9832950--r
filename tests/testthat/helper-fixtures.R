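# Shared fixtures: toy gene models, small simulator configurations, and a
# builder for variant tables with explicit per-role counts.

# Plus-strand two-exon toy gene on a 700-bp sequence: exons 101-200 and
# 301-400, fully coding. Intron = 201-300.
toy_two_exon_gene <- function(strand = "+") {
  gene_model("toyg", "toychr", strand,
             exons = data.frame(start = c(101, 301), end = c(200, 400)),
             cds_start = 101, cds_end = 400)
}

# Variant table row with the four roles' ref/alt counts given as a list,
# e.g. counts = list(mutant_parent = c(0, 19), ...).
make_variant_row <- function(chrom = "toychr", pos = 100L, ref = "C",
                             alt = "T", counts) {
  rec <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    class = if (nchar(ref) == 1 && nchar(alt) == 1) "SNP" else "INDEL",
                    stringsAsFactors = FALSE)
  for (role in sample_roles()) {
    rec[[paste0(role, "_ref")]] <- counts[[role]][1]
    rec[[paste0(role, "_alt")]] <- counts[[role]][2]
  }
  rec
}

# The depth quartet of the reported causal donor-site SNV:
# mutant parent 0,19 / wild-type pool 32,12 / mutant pool 0,37 / wild-type
# parent 53,0.
causal_row_counts <- list(mutant_parent = c(0, 19),
                          wildtype_parent = c(53, 0),
                          mutant_pool = c(0, 37),
                          wildtype_pool = c(32, 12))

# Reduced-scale simulator configuration for fast stochastic tests: the
# default 7 x 30-Mb genome geometry (the ED-versus-distance profile depends
# on it), but half the variant density, 300 F2 plants and fewer gene models.
# Depths, pool size and the causal position stay at study defaults.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             n_background_variants = 1000L,
             n_f2 = 300L,
             n_genes = 200L,
             ...)
}

# Draw a random point on the 4-simplex (a nucleotide-frequency vector).
random_freq_vector <- function() {
  x <- stats::rexp(4)
  f <- x / sum(x)
  structure(list(freq = stats::setNames(f, c("A", "C", "G", "T")),
                 depth = 100, usable = TRUE), class = "freq_vector")
}
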