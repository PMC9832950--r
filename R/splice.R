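# Transcript-oriented view of a gene: exon and intron sequences in transcript
# order (reverse-complemented for minus-strand genes) plus the CDS bounds in
# transcript coordinates. Working in transcript orientation makes the splice
# logic strand-free.
.tx_structure <- function(gene, genome) {
  ex <- gene$exons
  n <- nrow(ex)
  exon_seqs <- character(n)
  for (i in seq_len(n)) {
    exon_seqs[i] <- get_seq(genome, gene$chrom, ex$start[i], ex$end[i])
  }
  ins <- introns(gene)
  intron_seqs <- character(nrow(ins))
  for (i in seq_len(nrow(ins))) {
    intron_seqs[i] <- get_seq(genome, gene$chrom, ins$start[i], ins$end[i])
  }
  lens <- nchar(exon_seqs)
  cum <- cumsum(lens)
  total <- cum[n]
  # plus-strand (genomic-order concatenation) coordinate of a genomic position
  plus_coord <- function(g) {
    for (i in seq_len(n)) {
      if (g >= ex$start[i] && g <= ex$end[i]) {
        return((if (i > 1) cum[i - 1] else 0L) + (g - ex$start[i] + 1L))
      }
    }
    stop("position ", g, " is not exonic in gene ", gene$gene_id)
  }
  if (gene$strand == "+") {
    cds_t1 <- plus_coord(gene$cds_start)
    cds_t2 <- plus_coord(gene$cds_end)
  } else {
    exon_seqs <- rev(vapply(exon_seqs, .rev_comp, ""))
    intron_seqs <- rev(vapply(intron_seqs, .rev_comp, ""))
    cds_t1 <- total - plus_coord(gene$cds_end) + 1L
    cds_t2 <- total - plus_coord(gene$cds_start) + 1L
  }
  list(exons = unname(exon_seqs), introns = unname(intron_seqs),
       cds_t1 = cds_t1, cds_t2 = cds_t2)
}

#' Reference coding sequence of a gene model
#'
#' Concatenates the exonic CDS segments 5' to 3' in transcript orientation
#' (minus-strand genes are reverse-complemented).
#'
#' @param gene A [gene_model()].
#' @param genome Genome sequences covering the gene span (see [read_fasta()]).
#' @return CDS nucleotide string.
#' @export
build_reference_cds <- function(gene, genome) {
  ts <- .tx_structure(gene, genome)
  mrna <- paste(ts$exons, collapse = "")
  cds <- substr(mrna, ts$cds_t1, ts$cds_t2)
  if (nchar(cds) < 3) stop("CDS shorter than one codon in gene ", gene$gene_id)
  cds
}

#' Translate a coding sequence (standard genetic code)
#'
#' Translation stops at the first in-frame stop codon; the protein excludes
#' the stop. `premature_stop` is TRUE iff the first stop occurs before the
#' final complete codon. If no stop codon occurs, the full-length protein is
#' returned with `no_stop = TRUE`. Trailing bases short of a codon are
#' ignored. Ambiguity codes are not accepted.
#'
#' @param cds Nucleotide string, length >= 3, A/C/G/T only.
#' @return List with `protein`, `premature_stop`, `no_stop`.
#' @examples
#' translate_cds("ATGTAA") # protein "M", no premature stop
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) < 3) stop("CDS must be at least one codon")
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  n_codons <- nchar(cds) %/% 3L
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_i <- which(aa == "*")
  if (length(stop_i) == 0) {
    return(list(protein = paste(aa, collapse = ""), premature_stop = FALSE,
                no_stop = TRUE))
  }
  first <- stop_i[1]
  list(protein = paste(aa[seq_len(first - 1L)], collapse = ""),
       premature_stop = first < n_codons, no_stop = FALSE)
}

# Build one transcript-variant record from a mature mRNA and the transcript
# coordinate of the CDS start within it.
.transcript_variant <- function(kind, mature, cds_t1, deletion_bp = 0L) {
  coding <- substr(mature, cds_t1, nchar(mature))
  tr <- translate_cds(coding)
  cds_len <- if (tr$no_stop) 3L * (nchar(coding) %/% 3L) else
    3L * (nchar(tr$protein) + 1L)
  list(kind = kind,
       spliced_cds = substr(coding, 1, cds_len),
       protein = tr$protein,
       premature_stop = tr$premature_stop,
       no_stop = tr$no_stop,
       deletion_bp = as.integer(deletion_bp))
}

#' Mis-splicing outcomes of a broken splice donor site
#'
#' Models the two outcomes available to the spliceosome when the donor
#' (5'-GT) of intron `intron_index` is mutated: intron retention (U1 fails to
#' recognize any donor; the intron stays in the mature transcript and
#' translation reads into it, usually hitting a premature stop) and cryptic
#' donor use (U1 recognizes a canonical GT inside the upstream exon; splicing
#' there deletes the exon's 3' tail). One CRYPTIC_DONOR variant is emitted per
#' canonical GT found in the upstream exon within `scan_bp` of the broken
#' junction, nearest first. The reference transcript is always included for
#' diffing. No splice-strength scoring is attempted.
#'
#' Pass the mutant genome if the retained intron's own sequence matters for
#' the stop search (the donor base change can create or destroy a stop).
#'
#' @param gene A [gene_model()].
#' @param genome Genome sequences covering the gene span.
#' @param intron_index Intron whose donor is broken (1-based, transcript
#'   order).
#' @param scan_bp How far into the upstream exon to search for a cryptic GT.
#' @return List of transcript variants, each with `kind` (REFERENCE,
#'   INTRON_RETENTION or CRYPTIC_DONOR), `spliced_cds`, `protein`,
#'   `premature_stop`, `no_stop`, `deletion_bp`.
#' @export
predict_donor_mutation_consequences <- function(gene, genome, intron_index,
                                                scan_bp = 200L) {
  ts <- .tx_structure(gene, genome)
  n_introns <- length(ts$introns)
  stopifnot(intron_index >= 1, intron_index <= n_introns, scan_bp > 0)
  if (nchar(ts$introns[intron_index]) < 4) {
    stop("intron ", intron_index, " shorter than 4 bp")
  }
  exl <- nchar(ts$exons)
  cum <- cumsum(exl)
  i <- intron_index

  out <- list(.transcript_variant("REFERENCE",
                                  paste(ts$exons, collapse = ""), ts$cds_t1))

  # intron retention: intron i stays in the mature transcript
  mature_ir <- paste(c(ts$exons[seq_len(i)], ts$introns[i],
                       ts$exons[seq(i + 1L, length(ts$exons))]), collapse = "")
  t1_ir <- if (ts$cds_t1 > cum[i]) ts$cds_t1 + nchar(ts$introns[i]) else ts$cds_t1
  out[[length(out) + 1L]] <- .transcript_variant("INTRON_RETENTION",
                                                 mature_ir, t1_ir)

  # cryptic donor: canonical GT in the upstream exon within scan_bp of the
  # junction; splicing there removes the exon's 3' tail
  up <- ts$exons[i]
  L <- exl[i]
  tails <- integer(0)
  for (p in seq_len(L - 1L)) {
    tail_len <- L - p + 1L
    if (tail_len > scan_bp) next
    if (substr(up, p, p + 1L) == "GT") tails <- c(tails, tail_len)
  }
  for (tail_len in sort(tails)) {
    p <- L - tail_len + 1L
    new_exons <- ts$exons
    new_exons[i] <- substr(up, 1, p - 1L)
    del_start_tx <- (if (i > 1) cum[i - 1L] else 0L) + p
    if (ts$cds_t1 >= del_start_tx && ts$cds_t1 <= cum[i]) next # start codon lost
    t1_cd <- if (ts$cds_t1 > cum[i]) ts$cds_t1 - tail_len else ts$cds_t1
    out[[length(out) + 1L]] <- .transcript_variant(
      "CRYPTIC_DONOR", paste(new_exons, collapse = ""), t1_cd,
      deletion_bp = tail_len)
  }
  out
}

.common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0) n else neq[1] - 1L
}

.common_suffix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  neq <- which(av != bv)
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Classify the difference between a reference and a variant protein
#'
#' TRUNCATION: the variant is a proper prefix of the reference.
#' INTERNAL_DELETION: the variant equals the reference with one contiguous
#' block removed (checked by prefix + suffix match). For those two types
#' `aa_removed` is the length difference; otherwise OTHER (or IDENTICAL).
#'
#' @param reference_protein,variant_protein Non-empty amino-acid strings.
#' @return List with `shared_prefix_aa`, `type`, `aa_removed`.
#' @export
diff_proteins <- function(reference_protein, variant_protein) {
  stopifnot(nchar(reference_protein) > 0, nchar(variant_protein) > 0)
  lcp <- .common_prefix_len(reference_protein, variant_protein)
  nr <- nchar(reference_protein)
  nv <- nchar(variant_protein)
  if (reference_protein == variant_protein) {
    return(list(shared_prefix_aa = lcp, type = "IDENTICAL", aa_removed = 0L))
  }
  if (nv < nr && lcp == nv) {
    return(list(shared_prefix_aa = lcp, type = "TRUNCATION",
                aa_removed = nr - nv))
  }
  if (nv < nr) {
    lcs <- .common_suffix_len(reference_protein, variant_protein)
    if (lcp + lcs >= nv) {
      return(list(shared_prefix_aa = lcp, type = "INTERNAL_DELETION",
                  aa_removed = nr - nv))
    }
  }
  list(shared_prefix_aa = lcp, type = "OTHER", aa_removed = 0L)
}
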