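#' Length of 1-based inclusive intervals
#'
#' Under the 1-based inclusive convention used throughout the package the
#' length of an interval is `end - start + 1`; e.g. the span
#' 1,719,571..1,732,013 is 12,443 bp.
#'
#' @param x a `GRanges`/`IRanges`, or a numeric start vector.
#' @param end numeric end vector when `x` is numeric.
#' @return integer vector of lengths in bp.
#' @export
intervalLength <- function(x, end = NULL) {
  if (is.numeric(x)) {
    stopifnot(!is.null(end), all(end >= x), all(x >= 1))
    return(as.integer(end - x + 1))
  }
  BiocGenerics::width(x)
}

#' Gap between two intervals
#'
#' Number of bases strictly between two intervals on the same chromosome:
#' `start(b) - end(a) - 1` when `a` precedes `b`, and 0 when the intervals
#' overlap or abut. The gap is symmetric in its arguments.
#'
#' @param a,b length-1 `GRanges` (or `IRanges`, in which case no chromosome
#'   check is performed).
#' @return gap in bp (>= 0).
#' @export
intervalGap <- function(a, b) {
  if (methods::is(a, "GRanges") && methods::is(b, "GRanges")) {
    if (as.character(GenomicRanges::seqnames(a))[1L] !=
        as.character(GenomicRanges::seqnames(b))[1L])
      stop("domain error: intervals on different chromosomes")
  }
  gap <- max(BiocGenerics::start(a)[1L], BiocGenerics::start(b)[1L]) -
    min(BiocGenerics::end(a)[1L], BiocGenerics::end(b)[1L]) - 1L
  max(0L, gap)
}
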