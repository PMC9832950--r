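#' Pipeline configuration
#'
#' A single configuration object drives the whole run: either a simulation
#' block or real input files, plus per-stage parameters (module defaults
#' unless overridden).
#'
#' @param simulate A [sim_config()], or NULL when reading files.
#' @param vcf,gff,sample_role_map Input files + role mapping when not
#'   simulating.
#' @param min_depth Per-pool depth floor for the scan and genotyping.
#' @param window_bp,k Smoother window (bp) and ED exponent.
#' @param min_variants,merge_gap_bp Region-calling parameters.
#' @param hom_frac Homozygosity threshold of the candidate filter.
#' @param splice_scan_bp Cryptic-donor search window.
#' @param out_dir Optional output directory (regions.tsv, shortlist.tsv,
#'   transcripts.tsv, report.json, resolved config).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(), vcf = NULL, gff = NULL,
                            sample_role_map = NULL, min_depth = 4L,
                            window_bp = 2e6, k = 1L, min_variants = 10L,
                            merge_gap_bp = 1e5, hom_frac = 0.9,
                            splice_scan_bp = 200L, out_dir = NULL) {
  structure(list(simulate = simulate, vcf = vcf, gff = gff,
                 sample_role_map = sample_role_map, min_depth = min_depth,
                 window_bp = window_bp, k = k, min_variants = min_variants,
                 merge_gap_bp = merge_gap_bp, hom_frac = hom_frac,
                 splice_scan_bp = splice_scan_bp, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the mapping-by-sequencing pipeline
#'
#' Executes simulate (or load) -> ED scan -> smoothing -> threshold -> region
#' calling -> homozygous-differential filter -> effect annotation -> ranking
#' -> splice-consequence prediction for the top candidate (when the causal
#' gene's sequence is available, i.e. in simulation mode), and writes the
#' report files when `out_dir` is set. One message per stage reports the
#' in/out counts of the analysis funnel.
#'
#' @param config A [pipeline_config()].
#' @return A run report list: `params`, `threshold` (per variant class),
#'   `points`, `regions`, `shortlist`, `top_candidate`, `splice`, `truth`
#'   (simulation only), `counts`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  splice_fixture <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    variants <- sim$variants
    gene_models <- sim$gene_models
    splice_fixture <- sim$splice_fixture
    truth <- sim$truth
  } else {
    stopifnot(!is.null(config$vcf), !is.null(config$gff),
              !is.null(config$sample_role_map))
    variants <- read_vcf(config$vcf, config$sample_role_map)
    gene_models <- read_gff3(config$gff)
  }
  message("pipeline: ", nrow(variants), " variants in")

  # scan per variant class (SNVs and InDels get their own thresholds)
  points_all <- ed_profile(variants, min_depth = config$min_depth)
  thresholds <- list()
  regions_list <- list()
  points_out <- list()
  for (cl in unique(points_all$class)) {
    pts <- points_all[points_all$class == cl, , drop = FALSE]
    if (nrow(pts) < 2) next
    pts <- fit_profile(pts, window_bp = config$window_bp, k = config$k)
    thr <- compute_threshold(pts)
    thresholds[[cl]] <- thr
    regions_list[[cl]] <- call_regions(pts, thr,
                                       min_variants = config$min_variants,
                                       merge_gap_bp = config$merge_gap_bp,
                                       gene_models = gene_models)
    points_out[[cl]] <- pts
  }
  points <- do.call(rbind, points_out)
  if (is.null(points)) {
    points <- points_all[0, , drop = FALSE]
    points$ed_fitted <- numeric(0)
  }
  regions <- if (length(regions_list)) do.call(rbind, regions_list) else
    call_regions(points_all[0, ], Inf)
  rownames(regions) <- NULL
  message("pipeline: ", nrow(points), " usable scan points, ",
          nrow(regions), " candidate region(s)")

  # shortlist: variants inside a region, homozygous-differential filtered,
  # annotated and ranked
  in_region <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(regions))) {
    in_region <- in_region | (variants$chrom == regions$chrom[i] &
                                variants$pos >= regions$start[i] &
                                variants$pos <= regions$end[i])
  }
  region_variants <- variants[in_region, , drop = FALSE]
  surviving <- homozygous_differential_filter(region_variants,
                                              min_depth = config$min_depth,
                                              hom_frac = config$hom_frac)
  message("pipeline: ", nrow(region_variants), " variants in regions, ",
          nrow(surviving), " survive the homozygous-differential filter")
  shortlist <- surviving
  if (nrow(surviving) > 0) {
    eff <- classify_effects(surviving, gene_models)
    shortlist <- cbind(surviving, eff)
    key <- paste(points$chrom, points$pos)
    shortlist$ed <- points$ed[match(paste(shortlist$chrom, shortlist$pos), key)]
    shortlist <- rank_candidates(shortlist)
  } else {
    shortlist$effect <- character(0)
    shortlist$gene_id <- character(0)
    shortlist$ed <- numeric(0)
  }
  top <- if (nrow(shortlist) > 0) shortlist[1, , drop = FALSE] else NULL

  splice <- NULL
  if (!is.null(top) && !is.null(splice_fixture) &&
      identical(top$gene_id, splice_fixture$gene$gene_id) &&
      top$effect == "SPLICE_SITE_DONOR") {
    splice <- predict_donor_mutation_consequences(
      splice_fixture$gene, splice_fixture$genome_mut,
      intron_index = splice_fixture$intron_index,
      scan_bp = config$splice_scan_bp)
    message("pipeline: splice engine emitted ",
            paste(vapply(splice, `[[`, "", "kind"), collapse = ", "))
  }

  report <- list(
    params = config[setdiff(names(config), "out_dir")],
    threshold = thresholds,
    points = points,
    regions = regions,
    shortlist = shortlist,
    top_candidate = top,
    splice = splice,
    truth = truth,
    counts = list(variants_in = nrow(variants),
                  scan_points = nrow(points),
                  regions = nrow(regions),
                  region_variants = nrow(region_variants),
                  shortlist = nrow(shortlist))
  )
  if (!is.null(config$out_dir)) .write_run_report(report, config$out_dir)
  report
}

# Serialize the run outputs; report.json is deterministic for a fixed
# (config, seed): no timestamps, full numeric precision.
.write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_regions_tsv(report$regions, file.path(dir, "regions.tsv"))
  write_shortlist_tsv(report$shortlist, file.path(dir, "shortlist.tsv"))
  write_transcripts_tsv(if (is.null(report$splice)) list() else report$splice,
                        file.path(dir, "transcripts.tsv"))
  params <- report$params
  params$simulate <- if (!is.null(params$simulate)) unclass(params$simulate)
  json <- list(
    params = params,
    threshold = report$threshold,
    regions = report$regions,
    shortlist = report$shortlist,
    top_candidate = report$top_candidate,
    splice = lapply(report$splice, function(tv)
      tv[c("kind", "protein", "premature_stop", "deletion_bp")]),
    truth = report$truth,
    counts = report$counts
  )
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}
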