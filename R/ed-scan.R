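#' Per-variant Euclidean-distance track from a variant table
#'
#' Computes, for every variant with sufficient depth in both pools, the
#' Euclidean distance between the mutant-pool and wild-type-pool
#' allele-frequency vectors. For biallelic sites only the reference- and
#' alternate-allele slots of the frequency vector are non-zero, so the ED
#' over the full allele space reduces to the two-component form used here;
#' [ed_statistic()] on full vectors gives identical values.
#'
#' @param variants Variant table (see [read_vcf()]).
#' @param min_depth Minimum per-pool depth for a site to enter the scan.
#' @return data.frame of scan points: `vid` (row index into `variants`),
#'   `chrom`, `pos`, `class`, `ed`, sorted by (chrom, pos).
#' @export
ed_profile <- function(variants, min_depth = 4L) {
  md <- variants$mutant_pool_ref + variants$mutant_pool_alt
  wd <- variants$wildtype_pool_ref + variants$wildtype_pool_alt
  usable <- md >= min_depth & wd >= min_depth
  fm <- variants$mutant_pool_alt / md
  fw <- variants$wildtype_pool_alt / wd
  ed <- sqrt((fm - fw)^2 + ((1 - fm) - (1 - fw))^2)
  out <- data.frame(vid = seq_len(nrow(variants)), chrom = variants$chrom,
                    pos = variants$pos, class = variants$class, ed = ed,
                    stringsAsFactors = FALSE)[usable, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Smooth the ED profile along each chromosome
#'
#' The fitted value at a variant is the tricube-distance-weighted mean of
#' `ed^k` over all variants of the same chromosome within `window_bp / 2`
#' base pairs. The variant itself always contributes (weight 1 at distance
#' 0), so an isolated variant's fitted value is its own `ed^k`. No smoothing
#' bleeds across chromosomes.
#'
#' @param points Scan points from [ed_profile()], sorted by (chrom, pos).
#' @param window_bp Full window width in bp (default 2 Mb).
#' @param k Exponent applied to ED before averaging (default 1; powered-ED
#'   variants of the scan are common, hence configurable).
#' @return `points` with an `ed_fitted` column added.
#' @export
fit_profile <- function(points, window_bp = 2e6, k = 1L) {
  stopifnot(window_bp > 0, k >= 1)
  if (is.unsorted(order(points$chrom, points$pos))) {
    points <- points[order(points$chrom, points$pos), , drop = FALSE]
  }
  h <- window_bp / 2
  edk <- points$ed^k
  fitted <- numeric(nrow(points))
  for (chrom in unique(points$chrom)) {
    idx <- which(points$chrom == chrom)
    pos <- points$pos[idx]
    v <- edk[idx]
    lo <- findInterval(pos - h, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + h, pos)
    for (j in seq_along(idx)) {
      sel <- lo[j]:hi[j]
      d <- abs(pos[sel] - pos[j])
      w <- (1 - (d / h)^3)^3
      fitted[idx[j]] <- sum(w * v[sel]) / sum(w)
    }
  }
  points$ed_fitted <- fitted
  points
}

#' Genome-wide significance threshold for the fitted ED profile
#'
#' `median(ed_fitted) + 3 * sd(ed_fitted)`, with the sample standard
#' deviation (n - 1 denominator), over all fitted values genome-wide.
#'
#' @param points Scan points with `ed_fitted` (see [fit_profile()]).
#' @return Threshold scalar.
#' @export
compute_threshold <- function(points) {
  x <- points$ed_fitted
  stopifnot(!is.null(x), length(x) >= 2)
  stats::median(x) + 3 * stats::sd(x)
}

#' Round half-up to 2 decimals (region sizes in Mb)
#' @noRd
.round2_half_up <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100

#' Size of a candidate region in Mb
#'
#' `(end - start) / 1e6`, rounded half-up to 2 decimals.
#'
#' @param start,end 1-based region bounds.
#' @return Size in Mb.
#' @examples
#' region_size_mb(11620000, 24230000) # 12.61
#' region_size_mb(16300000, 18240000) # 1.94
#' @export
region_size_mb <- function(start, end) {
  stopifnot(all(end >= start))
  .round2_half_up((end - start) / 1e6)
}

#' Call candidate regions from the fitted ED profile
#'
#' Finds maximal runs of consecutive variants with `ed_fitted >= threshold`
#' (ties inclusive). Runs on the same chromosome separated by less than
#' `merge_gap_bp` are merged; merged runs carrying fewer than `min_variants`
#' above-threshold variants are dropped. Region bounds are the first/last
#' above-threshold variant positions, rounded outward to the 10-kb grid.
#'
#' @param points Scan points with `ed_fitted`.
#' @param threshold Threshold from [compute_threshold()].
#' @param min_variants Minimum above-threshold variants per surviving region.
#' @param merge_gap_bp Runs closer than this (bp, last-to-first variant
#'   distance) are merged.
#' @param gene_models Optional list of [gene_model()]s used to count genes
#'   overlapping each region (`n_genes`, else `NA`).
#' @return data.frame of regions: `variant_class`, `chrom`, `start`, `end`,
#'   `size_mb`, `n_variants`, `n_genes`; sorted, non-overlapping. Zero rows
#'   when nothing exceeds the threshold.
#' @export
call_regions <- function(points, threshold, min_variants = 10L,
                         merge_gap_bp = 1e5, gene_models = NULL) {
  empty <- data.frame(variant_class = character(), chrom = character(),
                      start = numeric(), end = numeric(), size_mb = numeric(),
                      n_variants = integer(), n_genes = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(points) == 0) return(empty)
  stopifnot(!is.null(points$ed_fitted))
  vclass <- if (length(unique(points$class)) == 1) points$class[1] else "ALL"
  out <- list()
  for (chrom in unique(points$chrom)) {
    cp <- points[points$chrom == chrom, , drop = FALSE]
    cp <- cp[order(cp$pos), , drop = FALSE]
    above <- cp$ed_fitted >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- data.frame(i0 = starts_i[r$values], i1 = ends_i[r$values])
    # merge runs separated by < merge_gap_bp (last variant to first variant)
    merged <- runs[1, , drop = FALSE]
    nvar <- runs$i1[1] - runs$i0[1] + 1L
    if (nrow(runs) > 1) {
      for (j in 2:nrow(runs)) {
        gap <- cp$pos[runs$i0[j]] - cp$pos[merged$i1[nrow(merged)]]
        if (gap < merge_gap_bp) {
          merged$i1[nrow(merged)] <- runs$i1[j]
          nvar[length(nvar)] <- nvar[length(nvar)] + (runs$i1[j] - runs$i0[j] + 1L)
        } else {
          merged <- rbind(merged, runs[j, ])
          nvar <- c(nvar, runs$i1[j] - runs$i0[j] + 1L)
        }
      }
    }
    keep <- nvar >= min_variants
    merged <- merged[keep, , drop = FALSE]
    nvar <- nvar[keep]
    if (nrow(merged) == 0) next
    start <- floor(cp$pos[merged$i0] / 1e4) * 1e4
    end <- ceiling(cp$pos[merged$i1] / 1e4) * 1e4
    out[[chrom]] <- data.frame(variant_class = vclass, chrom = chrom,
                               start = start, end = end,
                               size_mb = region_size_mb(start, end),
                               n_variants = nvar, n_genes = NA_integer_,
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  regions <- do.call(rbind, out)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  if (!is.null(gene_models)) {
    g_chrom <- vapply(gene_models, function(g) g$chrom, "")
    g_start <- vapply(gene_models, function(g) g$gene_start, numeric(1))
    g_end <- vapply(gene_models, function(g) g$gene_end, numeric(1))
    regions$n_genes <- vapply(seq_len(nrow(regions)), function(i) {
      sum(g_chrom == regions$chrom[i] &
            g_start <= regions$end[i] & g_end >= regions$start[i])
    }, integer(1))
  }
  regions
}
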