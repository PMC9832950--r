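#' Convert 1-based closed intervals to 0-based half-open
#'
#' File formats consumed here (VCF, GFF3) use 1-based closed coordinates;
#' internal slice arithmetic uses 0-based half-open intervals. These two
#' converters are exact inverses.
#'
#' @param start,end Integer vectors, 1-based closed bounds (`start <= end`).
#' @return A list with elements `start` and `end` in the other convention.
#' @examples
#' coord_1to0(101, 200) # list(start = 100, end = 200), width 100
#' @export
coord_1to0 <- function(start, end) {
  stopifnot(all(start >= 1L), all(end >= start))
  list(start = start - 1L, end = end)
}

#' @rdname coord_1to0
#' @export
coord_0to1 <- function(start, end) {
  stopifnot(all(start >= 0L), all(end > start))
  list(start = start + 1L, end = end)
}
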