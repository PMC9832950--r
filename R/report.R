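#' Write candidate regions as a TSV
#'
#' Column layout mirrors the standard region-summary table of a
#' mapping-by-sequencing report: variant class, chromosome, 1-based bounds,
#' size in Mb (2 decimals) and the number of overlapping gene models. Zero
#' regions yield a header-only file.
#'
#' @param regions Region table from [call_regions()] (may have 0 rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  cols <- c("variant_class", "chrom", "start", "end", "size_mb", "n_variants", "n_genes")
  out <- regions[, intersect(cols, names(regions)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the candidate-variant shortlist as a TSV
#'
#' Mirrors the per-variant table of a mapping report: position, alleles,
#' per-role ref,alt read counts, and effect category, one row per surviving
#' variant in ranked order.
#'
#' @param shortlist Ranked variant table from [rank_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shortlist_tsv <- function(shortlist, path) {
  utils::write.table(shortlist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write splice-consequence transcript variants as a TSV
#'
#' @param consequences List of transcript variants from
#'   [predict_donor_mutation_consequences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_tsv <- function(consequences, path) {
  rows <- lapply(consequences, function(tv) {
    data.frame(kind = tv$kind,
               cds_bp = nchar(tv$spliced_cds),
               protein_aa = nchar(tv$protein),
               premature_stop = tv$premature_stop,
               deletion_bp = tv$deletion_bp,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), cds_bp = integer(), protein_aa = integer(),
               premature_stop = logical(), deletion_bp = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
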