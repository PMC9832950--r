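#' Chi-square test of a Mendelian segregation ratio
#'
#' Tests observed dominant/recessive phenotype counts against an expected
#' ratio (3:1 for a monogenic recessive trait in an F2). With one degree of
#' freedom the Yates continuity correction is applied by default:
#' `chi2 = sum( (max(|O - E| - 0.5, 0))^2 / E )`.
#'
#' @param n_dominant,n_recessive Observed phenotype counts.
#' @param ratio Expected dominant:recessive ratio as a length-2 numeric
#'   (default `c(3, 1)`).
#' @param yates Apply the continuity correction (default TRUE).
#' @param alpha Significance level for the 1-df critical value.
#' @return List with `n_dominant`, `n_recessive`, `expected`, `chi_square`,
#'   `critical_value`, `consistent` (`chi_square < critical_value`).
#' @examples
#' segregation_chi_square(277, 97) # chi2 = 0.128, consistent with 3:1
#' @export
segregation_chi_square <- function(n_dominant, n_recessive, ratio = c(3, 1),
                                   yates = TRUE, alpha = 0.05) {
  stopifnot(n_dominant >= 0, n_recessive >= 0, all(ratio > 0),
            length(ratio) == 2)
  total <- n_dominant + n_recessive
  if (total <= 0) stop("total count must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0)) stop("zero expected count")
  obs <- c(n_dominant, n_recessive)
  dev <- abs(obs - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  crit <- stats::qchisq(1 - alpha, df = 1)
  list(n_dominant = n_dominant, n_recessive = n_recessive,
       expected = expected, chi_square = chi2, critical_value = crit,
       consistent = chi2 < crit)
}

#' Restriction-digest fragment lengths of an amplicon
#'
#' Every occurrence of the recognition sequence (overlapping occurrences
#' allowed, scanned left to right) contributes a cut at
#' `site_start + cut_offset`; fragments are the inter-cut lengths. An
#' amplicon without the site yields a single full-length fragment.
#'
#' @param amplicon Nucleotide string.
#' @param recognition Enzyme recognition sequence (exact match, no
#'   degenerate bases).
#' @param cut_offset Bases from the site start to the cut (0 to
#'   `nchar(recognition)`); 3 for a blunt cutter like SmaI (CCC^GGG).
#' @return Integer vector of fragment lengths summing to `nchar(amplicon)`.
#' @examples
#' digest_fragments(strrep("A", 300), "CCCGGG", 3) # no site: 300
#' @export
digest_fragments <- function(amplicon, recognition, cut_offset) {
  stopifnot(nchar(recognition) > 0, cut_offset >= 0,
            cut_offset <= nchar(recognition))
  n <- nchar(amplicon)
  # overlapping matches: lookahead keeps the scan position advancing by 1
  hits <- gregexpr(paste0("(?=", recognition, ")"), amplicon, perl = TRUE)[[1]]
  if (hits[1] == -1) return(n)
  cuts <- as.integer(hits) - 1L + cut_offset
  cuts <- cuts[cuts > 0 & cuts < n]
  diff(c(0L, sort(unique(cuts)), n))
}

#' CAPS/dCAPS distinguishability of two alleles
#'
#' Digests the reference-allele and alternate-allele amplicons with the same
#' enzyme and compares the fragment-length multisets: the marker
#' distinguishes the alleles iff the patterns differ (homozygotes show one
#' pattern each on a gel; heterozygotes show the union).
#'
#' @param amplicon_ref,amplicon_alt Same-length amplicon sequences for the
#'   two alleles of an SNV.
#' @param recognition,cut_offset See [digest_fragments()].
#' @return List with `fragments_ref`, `fragments_alt`, `distinguishable`.
#' @export
caps_distinguishes <- function(amplicon_ref, amplicon_alt, recognition,
                               cut_offset) {
  stopifnot(nchar(amplicon_ref) == nchar(amplicon_alt))
  fr <- digest_fragments(amplicon_ref, recognition, cut_offset)
  fa <- digest_fragments(amplicon_alt, recognition, cut_offset)
  list(fragments_ref = fr, fragments_alt = fa,
       distinguishable = !identical(sort(fr), sort(fa)))
}
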