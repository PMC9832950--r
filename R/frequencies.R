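#' Per-sample nucleotide read counts at one site
#'
#' A `pool_counts` object holds the read support observed in one sample at one
#' variant site. For SNVs the counts live on the four nucleotide slots
#' A, C, G, T; for InDels the reference- and alternate-supporting reads are
#' mapped onto two pseudo-allele slots `ref` and `alt`, so that the same
#' distance machinery applies to both variant classes.
#'
#' @param counts Named non-negative numeric vector. Names must be either a
#'   subset of `c("A","C","G","T")` (missing nucleotides are filled with 0)
#'   or exactly `c("ref","alt")`.
#' @return An object of class `pool_counts`: a named numeric vector over the
#'   full allele space.
#' @examples
#' pool_counts(c(C = 32, T = 12))
#' pool_counts(c(ref = 10, alt = 3)) # InDel pseudo-alleles
#' @export
pool_counts <- function(counts) {
  nm <- names(counts)
  if (is.null(nm) || any(!nzchar(nm))) stop("counts must be named")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (all(nm %in% c("A", "C", "G", "T"))) {
    full <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
  } else if (setequal(nm, c("ref", "alt"))) {
    full <- stats::setNames(numeric(2), c("ref", "alt"))
  } else {
    stop("counts names must be nucleotides A/C/G/T or ref/alt pseudo-alleles")
  }
  full[nm] <- counts
  structure(full, class = "pool_counts")
}

#' Allele-frequency vector of one sample at one site
#'
#' Divides each allele's read count by the total depth. Sites with depth below
#' `min_depth` (including depth 0) are flagged unusable rather than producing
#' divisions by zero; unusable sites are excluded from the distance scan.
#'
#' @param counts A [pool_counts()] object (or named vector accepted by it).
#' @param min_depth Minimum total depth for the site to be usable (>= 1).
#' @return A `freq_vector`: list with `freq` (named frequencies summing to 1
#'   when usable), `depth`, and `usable`.
#' @examples
#' allele_frequencies(pool_counts(c(C = 32, T = 12)))
#' @export
allele_frequencies <- function(counts, min_depth = 4L) {
  stopifnot(min_depth >= 1L)
  if (!inherits(counts, "pool_counts")) counts <- pool_counts(counts)
  depth <- sum(counts)
  usable <- depth >= min_depth
  freq <- if (depth > 0) unclass(counts) / depth else unclass(counts) * 0
  structure(list(freq = freq, depth = depth, usable = usable),
            class = "freq_vector")
}

#' Euclidean distance between two pools' allele-frequency vectors
#'
#' The association statistic of the scan:
#' `ED = sqrt( sum_b (f_mut[b] - f_wt[b])^2 )` over the allele space `b`
#' (A, G, C, T for SNVs; ref/alt pseudo-alleles for InDels). ED tends to 0 at
#' sites unlinked to the selected locus and approaches `sqrt(2)` where the two
#' pools are fixed for different alleles.
#'
#' @param f_mut,f_wt `freq_vector` objects on the same allele space.
#' @return Non-negative scalar in `[0, sqrt(2)]`.
#' @examples
#' f1 <- allele_frequencies(pool_counts(c(C = 0, T = 37)))
#' f2 <- allele_frequencies(pool_counts(c(C = 32, T = 12)))
#' ed_statistic(f1, f2) # 1.02853
#' @export
ed_statistic <- function(f_mut, f_wt) {
  stopifnot(inherits(f_mut, "freq_vector"), inherits(f_wt, "freq_vector"))
  if (!identical(names(f_mut$freq), names(f_wt$freq))) {
    stop("mismatched allele space: SNV and InDel frequency vectors cannot be compared")
  }
  if (!f_mut$usable || !f_wt$usable) {
    stop("ed_statistic requires two usable frequency vectors")
  }
  sqrt(sum((f_mut$freq - f_wt$freq)^2))
}
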