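#' GenomeAssembly: named chromosome sequences with a soft-mask track
#'
#' Container for an assembled genome: a [Biostrings::DNAStringSet] of
#' uppercase chromosome sequences (alphabet restricted to A, C, G, T, N)
#' plus a per-chromosome [IRanges::IRangesList] recording which positions
#' were soft-masked (lowercase) in the source FASTA. Composition scans treat
#' soft-masked bases as ordinary bases; the mask is carried so writers can
#' restore case.
#'
#' @slot seqs [Biostrings::DNAStringSet] of chromosome sequences; names are
#'   the chromosome identifiers and must be unique and non-empty.
#' @slot softMask [IRanges::IRangesList], parallel to `seqs`, of lowercase
#'   (soft-masked) runs in 1-based inclusive coordinates.
#'
#' @seealso [GenomeAssembly()], [readGenome()], [writeGenome()]
#' @exportClass GenomeAssembly
setClass("GenomeAssembly",
  slots = c(seqs = "DNAStringSet", softMask = "IRangesList")
)

setValidity("GenomeAssembly", function(object) {
  msg <- character(0)
  nms <- names(object@seqs)
  if (is.null(nms) || any(!nzchar(nms)))
    msg <- c(msg, "all sequences must be named")
  if (anyDuplicated(nms))
    msg <- c(msg, sprintf("duplicate chromosome id: %s",
                          nms[duplicated(nms)][1L]))
  if (length(object@seqs) > 0L) {
    af <- Biostrings::alphabetFrequency(object@seqs)
    allowed <- c("A", "C", "G", "T", "N")
    other <- rowSums(af[, setdiff(colnames(af), allowed), drop = FALSE])
    if (any(other > 0))
      msg <- c(msg, sprintf("sequence %s contains non-{A,C,G,T,N} letters",
                            nms[which(other > 0)[1L]]))
  }
  if (!identical(names(object@softMask), nms))
    msg <- c(msg, "softMask must be parallel to seqs (same names, same order)")
  lens <- BiocGenerics::width(object@seqs)
  for (i in seq_along(object@softMask)) {
    m <- object@softMask[[i]]
    if (length(m) && (min(BiocGenerics::start(m)) < 1L ||
                      max(BiocGenerics::end(m)) > lens[i]))
      msg <- c(msg, sprintf("softMask out of bounds on %s", nms[i]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAssembly
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector
#'   of chromosome sequences (uppercase A/C/G/T/N).
#' @param softMask optional [IRanges::IRangesList] of soft-masked runs,
#'   parallel to `seqs`; defaults to an empty mask.
#' @return a [GenomeAssembly-class] object.
#' @examples
#' ga <- GenomeAssembly(c(chrI = "ACGTACGT", chrII = "TTTTAAAA"))
#' chromLengths(ga)
#' @export
GenomeAssembly <- function(seqs, softMask = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(softMask)) {
    softMask <- IRanges::IRangesList(lapply(seq_along(seqs),
                                            function(i) IRanges::IRanges()))
    names(softMask) <- names(seqs)
  }
  methods::new("GenomeAssembly", seqs = seqs, softMask = softMask)
}

#' ContiguityReport: assembly contiguity and composition metrics
#'
#' Holds the standard contiguity statistics of an assembly (total length,
#' number of sequences, largest sequence, N50/N90, L50/L90, auN) together
#' with composition metrics (GC percent over unambiguous bases, N count per
#' 100 kb). Composition slots are `NA` when the report was computed from
#' sequence lengths alone.
#'
#' @slot totalLength total assembly length in bp.
#' @slot nSequences number of sequences.
#' @slot largest largest sequence length in bp.
#' @slot n50,n90 Nx statistics in bp.
#' @slot l50,l90 Lx statistics (sequence counts).
#' @slot auN area-under-the-Nx-curve statistic, \eqn{\sum L_i^2 / \sum L_i}.
#' @slot gcPercent GC content in percent (NA if unknown).
#' @slot nsPer100kb N bases per 100 kb (NA if unknown).
#' @seealso [contiguityStats()], [assemblyReport()]
#' @exportClass ContiguityReport
setClass("ContiguityReport",
  slots = c(totalLength = "numeric", nSequences = "numeric",
            largest = "numeric", n50 = "numeric", n90 = "numeric",
            l50 = "numeric", l90 = "numeric", auN = "numeric",
            gcPercent = "numeric", nsPer100kb = "numeric")
)

setValidity("ContiguityReport", function(object) {
  msg <- character(0)
  if (object@n90 > object@n50 || object@n50 > object@largest)
    msg <- c(msg, "must satisfy N90 <= N50 <= largest")
  if (object@l50 > object@l90 || object@l90 > object@nSequences)
    msg <- c(msg, "must satisfy L50 <= L90 <= number of sequences")
  if (object@auN > object@largest + 1e-9)
    msg <- c(msg, "auN cannot exceed the largest sequence")
  if (length(msg)) msg else TRUE
})
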