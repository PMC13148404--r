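#' @describeIn GenomeAssembly-class chromosome identifiers.
#' @export
setMethod("chromNames", "GenomeAssembly", function(x) names(x@seqs))

#' @describeIn GenomeAssembly-class named vector of chromosome lengths (bp).
#' @export
setMethod("chromLengths", "GenomeAssembly",
          function(x) stats::setNames(BiocGenerics::width(x@seqs),
                                      names(x@seqs)))

#' @describeIn GenomeAssembly-class the underlying
#'   [Biostrings::DNAStringSet].
#' @export
setMethod("genomeSeqs", "GenomeAssembly", function(x) x@seqs)

#' @describeIn GenomeAssembly-class the soft-mask
#'   [IRanges::IRangesList].
#' @export
setMethod("softMask", "GenomeAssembly", function(x) x@softMask)

#' @describeIn GenomeAssembly-class number of chromosomes.
#' @export
setMethod("length", "GenomeAssembly", function(x) length(x@seqs))

#' @describeIn GenomeAssembly-class extract one chromosome as a
#'   [Biostrings::DNAString].
#' @param i chromosome id or index.
#' @export
setMethod("[[", "GenomeAssembly", function(x, i) x@seqs[[i]])

setMethod("show", "GenomeAssembly", function(object) {
  lens <- chromLengths(object)
  cat(sprintf("GenomeAssembly with %d sequence(s), %s bp total\n",
              length(lens), format(sum(lens), big.mark = ",")))
  n <- min(length(lens), 8L)
  for (i in seq_len(n)) {
    nm <- sum(BiocGenerics::width(object@softMask[[i]]))
    cat(sprintf("  %-12s %12s bp%s\n", names(lens)[i],
                format(lens[i], big.mark = ","),
                if (nm > 0) sprintf("  (%s bp soft-masked)",
                                    format(nm, big.mark = ",")) else ""))
  }
  if (length(lens) > n) cat(sprintf("  ... and %d more\n", length(lens) - n))
})

#' Read a genome FASTA into a GenomeAssembly
#'
#' Sequences are uppercased; lowercase (soft-masked) runs are preserved as a
#' parallel mask track. Record ids are the first whitespace-delimited token
#' of each header. Duplicate ids or non-IUPAC characters (anything outside
#' A/C/G/T/N in either case) are format errors; the error message names the
#' offending sequence and position.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return a [GenomeAssembly-class].
#' @seealso [writeGenome()]
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("format error: duplicate FASTA header '",
         ids[duplicated(ids)][1L], "'")
  chr <- as.character(raw)
  names(chr) <- ids
  bad <- regexpr("[^ACGTNacgtn]", chr)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("format error: non-IUPAC character '%s' in %s at position %d",
                 substr(chr[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  mask <- IRanges::IRangesList(lapply(chr, function(s) {
    m <- gregexpr("[acgtn]+", s)[[1L]]
    if (m[1L] == -1L) IRanges::IRanges()
    else IRanges::IRanges(start = as.integer(m),
                          width = attr(m, "match.length"))
  }))
  seqs <- Biostrings::DNAStringSet(toupper(chr))
  GenomeAssembly(seqs, mask)
}

#' Write a GenomeAssembly to FASTA
#'
#' Restores soft-masked runs to lowercase and wraps lines at `width`
#' characters. Writing then re-reading an assembly reproduces the sequences
#' and mask exactly.
#'
#' @param assembly a [GenomeAssembly-class].
#' @param path output path.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
writeGenome <- function(assembly, path, width = 70L) {
  chr <- as.character(genomeSeqs(assembly))
  mask <- softMask(assembly)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(chr)) {
    s <- chr[i]
    m <- mask[[i]]
    if (length(m)) {
      v <- strsplit(s, "", fixed = TRUE)[[1L]]
      idx <- unlist(lapply(seq_along(m), function(j)
        seq.int(BiocGenerics::start(m)[j], BiocGenerics::end(m)[j])))
      v[idx] <- tolower(v[idx])
      s <- paste(v, collapse = "")
    }
    writeLines(paste0(">", names(chr)[i]), con)
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
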