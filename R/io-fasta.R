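#' Read a genome FASTA as a named character vector
#'
#' Sequences are uppercased and restricted to A/C/G/T/N. Sequence names are
#' the first whitespace-delimited token of each header. A genome may carry an
#' `offsets` attribute (named integer per chromosome) meaning the stored
#' string starts at genomic position `offset + 1`; [get_seq()] honors it, so a
#' gene's neighborhood can stand in for a full chromosome.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence id in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  if (any(grepl("[^ACGTN]", seqs))) stop("FASTA contains non-ACGTN characters")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Extract a genomic subsequence (1-based closed), honoring offsets
#'
#' @param genome Named character vector from [read_fasta()] or the simulator,
#'   optionally with an `offsets` attribute.
#' @param chrom Chromosome id.
#' @param start,end 1-based closed genomic bounds.
#' @return Character scalar.
#' @export
get_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  off <- 0L
  offs <- attr(genome, "offsets")
  if (!is.null(offs) && chrom %in% names(offs)) off <- offs[[chrom]]
  s <- start - off
  e <- end - off
  n <- nchar(genome[[chrom]])
  if (s < 1 || e > n) {
    stop("requested ", chrom, ":", start, "-", end,
         " outside the stored sequence")
  }
  substr(genome[[chrom]], s, e)
}

.rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
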