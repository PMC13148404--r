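#' @rdname GenomeAssembly-class
#' @param x a `GenomeAssembly`.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("genomeSeqs", function(x) standardGeneric("genomeSeqs"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("softMask", function(x) standardGeneric("softMask"))
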