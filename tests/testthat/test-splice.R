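# Local builder: two-exon gene with an in-frame cryptic GT planted in exon 1
# and a GT..AG intron; used for randomized splice properties.
random_splice_gene <- function(k1, k2, k3, intron_body = NULL, chrom = "rchr") {
  # exon1: ATG + k1 filler codons + GTC + k2 filler codons (cryptic tail)
  # intron: GT <body> AG ; exon2: ATC + k3 filler codons + TGA
  filler <- function(n) poolscan:::.ac_filler(3 * n)
  exon1 <- paste0("ATG", filler(k1), "GTC", filler(k2))
  if (is.null(intron_body)) intron_body <- filler(32)
  intron <- paste0("GT", intron_body, "AG")
  exon2 <- paste0("ATC", filler(k3), "TGA")
  flank <- filler(10)
  seqs <- paste0(flank, exon1, intron, exon2, flank)
  e1s <- nchar(flank) + 1L
  e1e <- e1s + nchar(exon1) - 1L
  e2s <- e1e + nchar(intron) + 1L
  e2e <- e2s + nchar(exon2) - 1L
  gene <- gene_model("rg", chrom, "+",
                     exons = data.frame(start = c(e1s, e2s), end = c(e1e, e2e)),
                     cds_start = e1s, cds_end = e2e)
  genome <- stats::setNames(seqs, chrom)
  # mutant genome: donor G -> A
  mut <- genome
  substr(mut[[chrom]], e1e + 1L, e1e + 1L) <- "A"
  names(mut) <- chrom
  list(gene = gene, genome_ref = genome, genome_mut = mut)
}

test_that("reference CDS assembly concatenates exons and honors strand", {
  chrom <- "t"
  # exon pieces ATGGCC + TGA with a GT..AG intron between
  seqs <- stats::setNames(paste0("ATGGCC", "GTAAAG", "TGA"), chrom)
  g <- gene_model("mini", chrom, "+",
                  exons = data.frame(start = c(1, 13), end = c(6, 15)),
                  cds_start = 1, cds_end = 15)
  expect_equal(build_reference_cds(g, seqs), "ATGGCCTGA")

  # single-exon gene: genomic substring unchanged
  g1 <- gene_model("one", chrom, "+",
                   exons = data.frame(start = 1, end = 15),
                   cds_start = 1, cds_end = 15)
  expect_equal(build_reference_cds(g1, seqs),
               get_seq(seqs, chrom, 1, 15))

  # the same model on the minus strand gives the reverse complement
  g_minus <- gene_model("minim", chrom, "-",
                        exons = data.frame(start = c(1, 13), end = c(6, 15)),
                        cds_start = 1, cds_end = 15)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(build_reference_cds(g_minus, seqs), rc("ATGGCCTGA"))
})

test_that("translation follows the standard code with stop-search semantics", {
  expect_equal(translate_cds("ATGTAA"),
               list(protein = "M", premature_stop = FALSE, no_stop = FALSE))
  early <- translate_cds("ATGTAAGGG")
  expect_equal(early$protein, "M")
  expect_true(early$premature_stop)
  open_ended <- translate_cds("ATGGCCGCA")
  expect_equal(open_ended$protein, "MAA")
  expect_true(open_ended$no_stop)
  expect_error(translate_cds("AT"), "codon")
  expect_error(translate_cds("ATGNNNTAA"), "non-ACGT")

  # length law against a brute-force oracle on random sequences with a
  # planted stop
  set.seed(9)
  for (i in 1:50) {
    n_codons <- sample(5:60, 1)
    stop_at <- sample(2:n_codons, 1)
    safe <- c("GCA", "GCC", "CTC", "AAC", "CAC", "ATC")
    codons <- sample(safe, n_codons, replace = TRUE)
    codons[stop_at] <- sample(c("TAA", "TAG", "TGA"), 1)
    cds <- paste(codons, collapse = "")
    got <- translate_cds(cds)
    # oracle: position of the first stop codon scanned frame-by-frame
    first_stop <- NA
    for (j in seq_len(n_codons)) {
      if (substr(cds, 3 * j - 2, 3 * j) %in% c("TAA", "TAG", "TGA")) {
        first_stop <- j
        break
      }
    }
    expect_equal(nchar(got$protein), first_stop - 1L)
    expect_equal(got$premature_stop, first_stop < n_codons)
  }
})

test_that("the engineered donor mutation yields IR truncation and in-frame PED", {
  fx <- causal_gene_fixture()
  ref_cds <- build_reference_cds(fx$gene, fx$genome_ref)
  expect_equal(nchar(ref_cds), 1338)
  ref_tr <- translate_cds(ref_cds)
  expect_equal(nchar(ref_tr$protein), 445)
  expect_false(ref_tr$premature_stop)

  cons <- predict_donor_mutation_consequences(fx$gene, fx$genome_mut,
                                              fx$intron_index)
  kinds <- vapply(cons, `[[`, "", "kind")
  expect_equal(kinds, c("REFERENCE", "INTRON_RETENTION", "CRYPTIC_DONOR"))

  ref_v <- cons[[1]]
  ir <- cons[[2]]
  ped <- cons[[3]]
  expect_equal(ref_v$spliced_cds, ref_cds)
  expect_true(startsWith(ir$spliced_cds, "ATG"))

  expect_equal(nchar(ir$spliced_cds), 456)
  expect_equal(nchar(ir$protein), 151)
  expect_true(ir$premature_stop)
  d_ir <- diff_proteins(ref_v$protein, ir$protein)
  expect_equal(d_ir$type, "TRUNCATION")
  expect_equal(d_ir$shared_prefix_aa, 151)

  expect_equal(ped$deletion_bp, 54L)
  expect_equal(nchar(ped$spliced_cds), 1338 - 54)
  expect_equal(nchar(ped$protein), 427)
  expect_false(ped$premature_stop)
  expect_equal(ped$deletion_bp,
               nchar(ref_v$spliced_cds) - nchar(ped$spliced_cds))
  d_ped <- diff_proteins(ref_v$protein, ped$protein)
  expect_equal(d_ped$type, "INTERNAL_DELETION")
  expect_equal(d_ped$aa_removed, 18L)

  # with a scan window shorter than 54 bp no cryptic donor is reachable
  near_only <- predict_donor_mutation_consequences(fx$gene, fx$genome_mut,
                                                   fx$intron_index,
                                                   scan_bp = 50)
  expect_equal(vapply(near_only, `[[`, "", "kind"),
               c("REFERENCE", "INTRON_RETENTION"))
})

test_that("IR prefix and cryptic-donor frame preservation hold on random genes", {
  set.seed(21)
  for (i in 1:15) {
    k1 <- sample(5:40, 1)
    k2 <- sample(2:30, 1)
    k3 <- sample(5:40, 1)
    rs <- random_splice_gene(k1, k2, k3)
    cons <- predict_donor_mutation_consequences(rs$gene, rs$genome_mut, 1)
    kinds <- vapply(cons, `[[`, "", "kind")
    expect_equal(kinds[1:2], c("REFERENCE", "INTRON_RETENTION"))
    ref_p <- cons[[1]]$protein
    ir_p <- cons[[2]]$protein
    # IR protein equals the reference for the residues encoded upstream of
    # the retained intron
    L <- 3 * (1 + k1 + 1 + k2) # CDS nt upstream of the junction
    n_shared <- min(floor(L / 3), nchar(ir_p), nchar(ref_p))
    expect_equal(substr(ir_p, 1, n_shared), substr(ref_p, 1, n_shared))
    # nearest cryptic GT deletes the k2-codon tail + GTC in frame
    cd <- cons[kinds == "CRYPTIC_DONOR"]
    expect_gte(length(cd), 1)
    nearest <- cd[[1]]
    expect_equal(nearest$deletion_bp %% 3, 0)
    if (!nearest$premature_stop && !nearest$no_stop) {
      d <- diff_proteins(ref_p, nearest$protein)
      expect_equal(d$type, "INTERNAL_DELETION")
      expect_equal(d$aa_removed, nearest$deletion_bp / 3)
      expect_equal(nearest$deletion_bp,
                   nchar(cons[[1]]$spliced_cds) - nchar(nearest$spliced_cds))
    }
  }
})

test_that("the engine is strand-invariant", {
  rs <- random_splice_gene(8, 4, 10)
  chrom <- rs$gene$chrom
  L <- nchar(rs$genome_mut[[chrom]])
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  mirror_genome <- stats::setNames(rc(rs$genome_mut[[chrom]]), chrom)
  ex <- rs$gene$exons
  mirror_exons <- data.frame(start = rev(L - ex$end + 1L),
                             end = rev(L - ex$start + 1L))
  mirror <- gene_model("rg_rc", chrom, "-", exons = mirror_exons,
                       cds_start = L - rs$gene$cds_end + 1L,
                       cds_end = L - rs$gene$cds_start + 1L)
  a <- predict_donor_mutation_consequences(rs$gene, rs$genome_mut, 1)
  b <- predict_donor_mutation_consequences(mirror, mirror_genome, 1)
  expect_equal(vapply(a, `[[`, "", "kind"), vapply(b, `[[`, "", "kind"))
  expect_equal(vapply(a, `[[`, "", "protein"), vapply(b, `[[`, "", "protein"))
  expect_equal(vapply(a, `[[`, "", "spliced_cds"),
               vapply(b, `[[`, "", "spliced_cds"))
})

test_that("protein diffs classify truncation, internal deletion and other", {
  ref <- "MSTELLARKQWLNDPEACME"
  expect_equal(diff_proteins(ref, ref)$type, "IDENTICAL")
  tr <- diff_proteins(ref, substr(ref, 1, 8))
  expect_equal(tr$type, "TRUNCATION")
  expect_equal(tr$shared_prefix_aa, 8)
  expect_equal(tr$aa_removed, nchar(ref) - 8)
  del <- diff_proteins(ref, paste0(substr(ref, 1, 5), substr(ref, 11, nchar(ref))))
  expect_equal(del$type, "INTERNAL_DELETION")
  expect_equal(del$aa_removed, 5)
  expect_equal(diff_proteins(ref, "MXXXXXXXXXXXXXXXXXXP")$type, "OTHER")
  expect_error(diff_proteins("", ref))
})

test_that("degenerate inputs are rejected", {
  fx <- causal_gene_fixture()
  expect_error(predict_donor_mutation_consequences(fx$gene, fx$genome_mut, 9),
               "intron_index")
  tiny <- gene_model("tiny", "t", "+",
                     exons = data.frame(start = c(1, 10), end = c(5, 18)),
                     cds_start = 1, cds_end = 18)
  # intron is 4 bp here, the minimum; the constructor refuses anything shorter
  expect_error(gene_model("bad", "t", "+",
                          exons = data.frame(start = c(1, 8), end = c(5, 18)),
                          cds_start = 1, cds_end = 18),
               "intron")
})
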