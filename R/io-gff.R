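#' Construct a strand-aware gene model
#'
#' A gene model is the exon/intron/CDS skeleton the annotator and the splice
#' engine operate on: ordered non-overlapping exons in genomic coordinates,
#' genomic CDS bounds inside the exon union, and a strand flag. Intron i is
#' the gap between exon i and exon i+1 and must leave room for the canonical
#' GT...AG dinucleotides (length >= 4).
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based closed),
#'   sorted by genomic position, non-overlapping.
#' @param cds_start,cds_end Genomic CDS bounds (1-based closed).
#' @param gene_start,gene_end Genomic gene-span bounds; default to the exon
#'   span. A span wider than the mRNA leaves intragenic territory.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_start, cds_end,
                       gene_start = min(exons$start), gene_end = max(exons$end)) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)), nrow(exons) >= 1)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) stop("gene ", gene_id, ": exon end < start")
  if (nrow(exons) > 1) {
    gaps <- exons$start[-1] - exons$end[-nrow(exons)] - 1L
    if (any(gaps < 0)) stop("gene ", gene_id, ": overlapping exons")
    if (any(gaps < 4)) stop("gene ", gene_id, ": intron shorter than 4 bp")
  }
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  if (cds_start > cds_end) stop("gene ", gene_id, ": cds_start > cds_end")
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    stop("gene ", gene_id, ": CDS bounds outside exons")
  }
  if (gene_start > min(exons$start) || gene_end < max(exons$end)) {
    stop("gene ", gene_id, ": gene span does not cover exons")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds_start = cds_start, cds_end = cds_end,
                 gene_start = gene_start, gene_end = gene_end),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s) %d exon(s), CDS %d-%d\n",
              x$gene_id, x$chrom, x$gene_start, x$gene_end, x$strand,
              nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

#' Intron intervals of a gene model
#'
#' @param gene A [gene_model()].
#' @return data.frame with genomic `start`, `end` per intron (0 rows for
#'   single-exon genes). Intron order is genomic; use the strand flag for
#'   transcript order.
#' @export
introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

#' Read gene models from a GFF3 file
#'
#' Accepts gene/mRNA/exon/CDS features. One mRNA per gene is used (the first
#' by position if several, with a message). Genes whose structure violates the
#' gene-model invariants (overlapping exons, CDS outside the exon union) are
#' rejected with a warning.
#'
#' @param path GFF3 file path.
#' @return List of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, "")
  } else rep(NA_character_, length(gr))
  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)
  strands <- as.character(BiocGenerics::strand(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))

  gene_idx <- which(type == "gene")
  models <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    mrna_idx <- which(type == "mRNA" & parents == gid)
    if (length(mrna_idx) == 0) {
      warning("gene ", gid, ": no mRNA feature; skipped")
      next
    }
    if (length(mrna_idx) > 1) {
      mrna_idx <- mrna_idx[order(starts[mrna_idx])]
      message("read_gff3: gene ", gid, " has ", length(mrna_idx),
              " mRNAs; using the first (", ids[mrna_idx[1]], ")")
    }
    mid <- ids[mrna_idx[1]]
    exon_idx <- which(type == "exon" & parents == mid)
    cds_idx <- which(type == "CDS" & parents == mid)
    if (length(exon_idx) == 0 || length(cds_idx) == 0) {
      warning("gene ", gid, ": missing exon or CDS features; skipped")
      next
    }
    gm <- tryCatch(
      gene_model(gene_id = gid, chrom = chroms[gi], strand = strands[gi],
                 exons = data.frame(start = starts[exon_idx], end = ends[exon_idx]),
                 cds_start = min(starts[cds_idx]), cds_end = max(ends[cds_idx]),
                 gene_start = starts[gi], gene_end = ends[gi]),
      error = function(e) {
        warning("gene ", gid, " rejected: ", conditionMessage(e))
        NULL
      })
    if (!is.null(gm)) models[[length(models) + 1L]] <- gm
  }
  models
}

#' Write gene models as GFF3
#'
#' Deterministic minimal emitter (gene, mRNA, exon, CDS rows); a fixed point
#' under [read_gff3()] for models produced in this package.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, start, end, strand, attrs) {
    paste(chrom, "poolscan", type,
          format(start, scientific = FALSE, trim = TRUE),
          format(end, scientific = FALSE, trim = TRUE),
          ".", strand, ".", attrs, sep = "\t")
  }
  for (g in genes) {
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
               fmt(g$chrom, "gene", g$gene_start, g$gene_end, g$strand,
                   paste0("ID=", g$gene_id)),
               fmt(g$chrom, "mRNA", min(g$exons$start), max(g$exons$end), g$strand,
                   paste0("ID=", mid, ";Parent=", g$gene_id)))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines, fmt(g$chrom, "exon", g$exons$start[i], g$exons$end[i],
                            g$strand, paste0("Parent=", mid)))
    }
    for (i in seq_len(nrow(g$exons))) {
      s <- max(g$exons$start[i], g$cds_start)
      e <- min(g$exons$end[i], g$cds_end)
      if (s <= e) {
        lines <- c(lines, fmt(g$chrom, "CDS", s, e, g$strand,
                              paste0("Parent=", mid)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
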