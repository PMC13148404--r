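#' Assembly contiguity statistics
#'
#' Computes total length, number of sequences, largest sequence, N50/N90,
#' L50/L90 and auN from a vector of sequence lengths. Nx is the length of
#' the sequence at which the cumulative sorted-descending length first
#' reaches x% of the total ("at least x%", the QUAST convention, so an
#' exact tie counts); Lx is the number of sequences needed to reach it;
#' auN = \eqn{\sum L_i^2 / \sum L_i}, the expected length of the sequence
#' containing a randomly chosen base.
#'
#' @param lengths positive sequence lengths in bp (need not be sorted).
#' @param gcPercent,nsPer100kb optional composition metrics to carry in the
#'   report.
#' @return a [ContiguityReport-class].
#' @examples
#' contiguityStats(c(3, 2, 2, 1))  # N50 = 2, L50 = 2, auN = 2.25
#' @export
contiguityStats <- function(lengths, gcPercent = NA_real_,
                            nsPer100kb = NA_real_) {
  if (length(lengths) == 0L)
    stop("domain error: empty length list")
  if (any(lengths <= 0))
    stop("domain error: lengths must be positive")
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(l)
  cum <- cumsum(l)
  nx <- function(x) {
    i <- which(cum >= x / 100 * total)[1L]
    c(n = l[i], l = i)
  }
  s50 <- nx(50); s90 <- nx(90)
  methods::new("ContiguityReport",
    totalLength = total, nSequences = length(l), largest = l[1L],
    n50 = s50[["n"]], n90 = s90[["n"]],
    l50 = s50[["l"]], l90 = s90[["l"]],
    auN = sum(l^2) / total,
    gcPercent = gcPercent, nsPer100kb = nsPer100kb)
}

#' Assembly composition statistics
#'
#' GC percent is computed over unambiguous bases only,
#' \eqn{(G+C)/(A+C+G+T) \times 100}; N density is N count per 100 kb of
#' total length (N bases included in that denominator). Soft-masked bases
#' count as ordinary bases.
#'
#' @param assembly a [GenomeAssembly-class].
#' @return named list with `gcPercent` and `nsPer100kb`.
#' @export
compositionStats <- function(assembly) {
  af <- Biostrings::alphabetFrequency(genomeSeqs(assembly))
  tot <- colSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  acgt <- sum(tot[c("A", "C", "G", "T")])
  if (acgt == 0)
    stop("domain error: assembly contains no unambiguous bases")
  list(gcPercent = unname(sum(tot[c("G", "C")]) / acgt * 100),
       nsPer100kb = unname(tot[["N"]] / sum(tot) * 1e5))
}

#' Full assembly report (contiguity + composition)
#'
#' @param assembly a [GenomeAssembly-class].
#' @return a [ContiguityReport-class] with composition slots filled.
#' @export
assemblyReport <- function(assembly) {
  comp <- compositionStats(assembly)
  contiguityStats(chromLengths(assembly),
                  gcPercent = comp$gcPercent,
                  nsPer100kb = comp$nsPer100kb)
}

setMethod("show", "ContiguityReport", function(object) {
  cat("ContiguityReport\n")
  fmt <- function(x) format(x, big.mark = ",")
  cat(sprintf("  Total length  %s bp in %d sequence(s)\n",
              fmt(object@totalLength), object@nSequences))
  cat(sprintf("  Largest       %s bp\n", fmt(object@largest)))
  cat(sprintf("  N50 / N90     %s / %s bp\n", fmt(object@n50),
              fmt(object@n90)))
  cat(sprintf("  L50 / L90     %d / %d\n", object@l50, object@l90))
  cat(sprintf("  auN           %s\n", format(round(object@auN, 2),
                                             big.mark = ",")))
  if (!is.na(object@gcPercent))
    cat(sprintf("  GC content    %.1f%%\n", object@gcPercent))
  if (!is.na(object@nsPer100kb))
    cat(sprintf("  N's per 100kb %.1f\n", object@nsPer100kb))
})

#' Convert a ContiguityReport to a one-row data.frame
#' @param report a [ContiguityReport-class].
#' @return data.frame with one column per metric.
#' @export
reportAsDataFrame <- function(report) {
  data.frame(totalLength = report@totalLength,
             nSequences = report@nSequences,
             largest = report@largest,
             n50 = report@n50, n90 = report@n90,
             l50 = report@l50, l90 = report@l90,
             auN = report@auN,
             gcPercent = report@gcPercent,
             nsPer100kb = report@nsPer100kb)
}

# round to `digits` significant figures with halves away from zero
.signifHalfUp <- function(x, digits = 2L) {
  if (x == 0) return(0)
  e <- ceiling(log10(abs(x)))
  if (abs(x) == 10^(e)) e <- e + 1L
  m <- x / 10^(e - digits)
  floor(abs(m) + 0.5) * sign(x) * 10^(e - digits)
}

#' Fold change between two assembly metrics
#'
#' Ratio of new to old (`direction = "increase"`) or old to new
#' (`"reduction"`), rounded to 2 significant figures with halves rounded
#' away from zero; this rounding reproduces mixed-precision published fold
#' values such as 2.9, 11, 6.7 and 2.3 from a single rule.
#'
#' @param old,new positive metric values.
#' @param direction `"increase"` or `"reduction"`.
#' @return list with `value` (rounded), `raw` (unrounded ratio) and `label`
#'   (e.g. `"2.9-fold increase"`).
#' @examples
#' foldChange(793.5, 2335.6, "increase")$value  # 2.9
#' @export
foldChange <- function(old, new, direction = c("increase", "reduction")) {
  direction <- match.arg(direction)
  if (old <= 0 || new <= 0)
    stop("domain error: fold change requires positive values")
  raw <- if (direction == "increase") new / old else old / new
  value <- .signifHalfUp(raw, 2L)
  list(value = value, raw = raw,
       label = sprintf("%s-fold %s",
                       trimws(formatC(value, digits = 2, format = "fg")),
                       direction))
}
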