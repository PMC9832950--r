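# Effect categories in priority order (highest first). The reported category
# for a variant is the highest-priority one over all overlapping/nearby genes.
.EFFECT_PRIORITY <- c("SPLICE_SITE_DONOR", "SPLICE_SITE_ACCEPTOR",
                      "SPLICE_SITE_REGION", "CODING", "INTRON", "UPSTREAM",
                      "DOWNSTREAM", "INTRAGENIC", "INTERGENIC")

#' Effect-classification window parameters
#'
#' Window sizes follow the conventions of standard variant annotators:
#' donor/acceptor = first/last 2 intronic bases, splice region = exonic bases
#' 1-3 adjacent to a junction or intronic bases 3-8, upstream/downstream =
#' within 5 kb of the gene span (strand-aware).
#'
#' @param splice_site_bp Donor/acceptor window (intronic bases from each end).
#' @param region_exonic_bp Exonic splice-region window at a junction.
#' @param region_intronic_bp Intronic splice-region window (outer bound).
#' @param updownstream_bp Upstream/downstream window.
#' @return Parameter list for [classify_effect()].
#' @export
effect_params <- function(splice_site_bp = 2L, region_exonic_bp = 3L,
                          region_intronic_bp = 8L, updownstream_bp = 5000L) {
  list(splice_site_bp = splice_site_bp, region_exonic_bp = region_exonic_bp,
       region_intronic_bp = region_intronic_bp, updownstream_bp = updownstream_bp)
}

#' Effect priority rank (1 = highest)
#' @param category Effect category string(s).
#' @return Integer rank(s).
#' @export
effect_priority <- function(category) match(category, .EFFECT_PRIORITY)

# Category of `pos` relative to one gene, or NA if unrelated to it.
.classify_one <- function(pos, gene, params) {
  ex <- gene$exons
  ins <- introns(gene)
  plus <- gene$strand == "+"
  if (pos >= gene$gene_start && pos <= gene$gene_end) {
    # intronic windows, measured from the transcript 5' (donor) and 3'
    # (acceptor) ends of the intron
    if (nrow(ins) > 0) {
      for (i in seq_len(nrow(ins))) {
        if (pos < ins$start[i] || pos > ins$end[i]) next
        d5 <- if (plus) pos - ins$start[i] + 1L else ins$end[i] - pos + 1L
        d3 <- if (plus) ins$end[i] - pos + 1L else pos - ins$start[i] + 1L
        if (d5 <= params$splice_site_bp) return("SPLICE_SITE_DONOR")
        if (d3 <= params$splice_site_bp) return("SPLICE_SITE_ACCEPTOR")
        if (d5 <= params$region_intronic_bp || d3 <= params$region_intronic_bp) {
          return("SPLICE_SITE_REGION")
        }
        return("INTRON")
      }
    }
    for (i in seq_len(nrow(ex))) {
      if (pos < ex$start[i] || pos > ex$end[i]) next
      # exonic bases 1..region_exonic_bp adjacent to an intron junction
      d_into <- Inf
      if (i > 1) d_into <- min(d_into, pos - ex$start[i] + 1L)
      if (i < nrow(ex)) d_into <- min(d_into, ex$end[i] - pos + 1L)
      if (d_into <= params$region_exonic_bp) return("SPLICE_SITE_REGION")
      if (pos >= gene$cds_start && pos <= gene$cds_end) return("CODING")
      return("INTRAGENIC") # exonic non-coding (UTR-like)
    }
    return("INTRAGENIC") # inside the gene span but in no mRNA feature
  }
  w <- params$updownstream_bp
  before <- pos < gene$gene_start && pos >= gene$gene_start - w
  after <- pos > gene$gene_end && pos <= gene$gene_end + w
  if (before) return(if (plus) "UPSTREAM" else "DOWNSTREAM")
  if (after) return(if (plus) "DOWNSTREAM" else "UPSTREAM")
  NA_character_
}

#' Classify a variant's positional effect against gene models
#'
#' Assigns one category per (variant, gene) pair by strand-aware windows and
#' reports the highest-priority category over all genes near the variant:
#' SPLICE_SITE_DONOR > SPLICE_SITE_ACCEPTOR > SPLICE_SITE_REGION > CODING >
#' INTRON > UPSTREAM > DOWNSTREAM > INTRAGENIC > INTERGENIC.
#'
#' @param variant A list or one-row data.frame with `chrom` and `pos`.
#' @param gene_models List of [gene_model()] objects.
#' @param params See [effect_params()].
#' @return List with `category` and `gene_id` (NA for INTERGENIC).
#' @export
classify_effect <- function(variant, gene_models, params = effect_params()) {
  chrom <- variant$chrom[1]
  pos <- variant$pos[1]
  best <- "INTERGENIC"
  best_gene <- NA_character_
  for (g in gene_models) {
    if (g$chrom != chrom) next
    if (pos < g$gene_start - params$updownstream_bp ||
        pos > g$gene_end + params$updownstream_bp) next
    cat_g <- .classify_one(pos, g, params)
    if (is.na(cat_g)) next
    if (effect_priority(cat_g) < effect_priority(best)) {
      best <- cat_g
      best_gene <- g$gene_id
    }
  }
  list(category = best, gene_id = best_gene)
}

#' Classify many variants at once
#'
#' @param variants Variant table with `chrom`, `pos`.
#' @param gene_models List of [gene_model()]s.
#' @param params See [effect_params()].
#' @return data.frame with `effect` and `gene_id` per variant row.
#' @export
classify_effects <- function(variants, gene_models, params = effect_params()) {
  res <- lapply(seq_len(nrow(variants)), function(i) {
    classify_effect(list(chrom = variants$chrom[i], pos = variants$pos[i]),
                    gene_models, params)
  })
  data.frame(effect = vapply(res, `[[`, "", "category"),
             gene_id = vapply(res, `[[`, "", "gene_id"),
             stringsAsFactors = FALSE)
}

#' Genotype call from ref/alt read counts
#'
#' `alt_fraction = alt / (ref + alt)`. A site with depth below `min_depth` is
#' LOW_DEPTH (takes precedence: a 2-read site is never called homozygous);
#' otherwise HOM_ALT if the alt fraction is at least `hom_frac`, HOM_REF if at
#' most `1 - hom_frac`, else HET.
#'
#' @param ref_count,alt_count Read counts (vectors allowed).
#' @param min_depth Minimum depth for a confident call.
#' @param hom_frac Homozygosity threshold in (0.5, 1].
#' @return data.frame with `call` and `alt_fraction` per site.
#' @export
genotype_from_counts <- function(ref_count, alt_count, min_depth = 4L,
                                 hom_frac = 0.9) {
  stopifnot(hom_frac > 0.5, hom_frac <= 1)
  depth <- ref_count + alt_count
  af <- ifelse(depth > 0, alt_count / depth, NA_real_)
  call <- ifelse(depth < min_depth, "LOW_DEPTH",
                 ifelse(af >= hom_frac, "HOM_ALT",
                        ifelse(af <= 1 - hom_frac, "HOM_REF", "HET")))
  data.frame(call = call, alt_fraction = af, stringsAsFactors = FALSE)
}

#' Homozygous-differential filter for causal candidates
#'
#' Keeps a variant iff the mutant parent and the mutant pool are homozygous
#' for the alternate allele, the wild-type parent is homozygous reference,
#' and the wild-type pool is HET or HOM_REF. The wild-type (dominant
#' phenotype) pool of an F2 carries the mutant allele at an expected fraction
#' of 1/3, so a heterozygous-looking wild pool is the signature of the true
#' locus, not a disqualifier. Variants with LOW_DEPTH in any role are dropped
#' with the reason recorded.
#'
#' @param variants Variant table with the eight per-role count columns.
#' @param min_depth,hom_frac Passed to [genotype_from_counts()].
#' @return The surviving rows, with `<role>_gt` call columns appended. The
#'   `dropped` attribute holds a data.frame of dropped row indices + reasons.
#' @export
homozygous_differential_filter <- function(variants, min_depth = 4L,
                                           hom_frac = 0.9) {
  gt <- lapply(sample_roles(), function(role) {
    genotype_from_counts(variants[[paste0(role, "_ref")]],
                         variants[[paste0(role, "_alt")]],
                         min_depth = min_depth, hom_frac = hom_frac)$call
  })
  names(gt) <- sample_roles()
  low <- Reduce(`|`, lapply(gt, function(g) g == "LOW_DEPTH"))
  ok <- gt$mutant_parent == "HOM_ALT" &
    gt$mutant_pool == "HOM_ALT" &
    gt$wildtype_parent == "HOM_REF" &
    gt$wildtype_pool %in% c("HET", "HOM_REF")
  keep <- ok & !low
  reason <- ifelse(low, "LOW_DEPTH", "genotype_pattern")
  out <- variants[keep, , drop = FALSE]
  for (role in sample_roles()) out[[paste0(role, "_gt")]] <- gt[[role]][keep]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(row = which(!keep),
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Rank shortlisted candidate variants
#'
#' Sort key: effect priority (splice-site categories first), then ED
#' descending, then position ascending.
#'
#' @param shortlist data.frame with columns `effect`, `pos` and optionally
#'   `ed` (missing ED treated as 0).
#' @return The reordered shortlist.
#' @export
rank_candidates <- function(shortlist) {
  if (nrow(shortlist) == 0) return(shortlist)
  ed <- if (!is.null(shortlist$ed)) shortlist$ed else numeric(nrow(shortlist))
  ed[is.na(ed)] <- 0
  o <- order(effect_priority(shortlist$effect), -ed, shortlist$pos)
  out <- shortlist[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
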