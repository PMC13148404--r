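#' Global pairwise identity between two LTR sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1 and
#' gap -2 per gapped position; identity is the number of identical aligned
#' columns over all alignment columns (gap columns count in the
#' denominator), reported in percent to 2 decimals. Since paired LTRs are
#' identical at insertion and diverge neutrally, this identity acts as the
#' molecular clock used to rank element ages.
#'
#' @param a,b DNA sequences ([Biostrings::DNAString] or character).
#' @param match,mismatch,gap alignment scores (defaults +1/-1/-2).
#' @return identity percent in \[0, 100\], rounded to 2 decimals.
#' @examples
#' ltrPairIdentity("ACGTACGT", "ACGTACGT")  # 100
#' @export
ltrPairIdentity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (is.character(a)) a <- Biostrings::DNAString(a)
  if (is.character(b)) b <- Biostrings::DNAString(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("domain error: empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0,
                                       gapExtension = abs(gap))
  s1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  round(sum(s1 == s2 & s1 != "-") / length(s1) * 100, 2)
}

#' Find LTR retrotransposon candidates by seed-and-extend
#'
#' A transparent analogue of suffix-array LTR candidate finders: exact
#' k-mer seeds anchor same-strand direct-repeat pairs, seeds sharing a
#' diagonal are clustered and extended with an X-drop heuristic, and the
#' resulting 5'/3' LTR pairs are kept when the extended LTR lengths lie in
#' `[minLtr, maxLtr]`, the LTR start-to-start distance lies in
#' `[minDist, maxDist]`, and the global alignment identity between the two
#' LTRs reaches `minSimilarity`. Overlapping candidates are resolved
#' greedily by identity then length. k-mers occurring more than
#' `maxKmerOcc` times are skipped as low-complexity/satellite seeds.
#'
#' @param seq a [Biostrings::DNAString] or character scalar (one
#'   chromosome).
#' @param minLtr,maxLtr allowed LTR lengths in bp (defaults 100/1000).
#' @param minDist,maxDist allowed 5'-to-3' LTR start-to-start distance in
#'   bp (defaults 1000/15000).
#' @param minSimilarity minimum LTR pair identity in percent (default 85).
#' @param k seed length (default 20).
#' @param maxKmerOcc skip seeds from k-mers occurring more often than this
#'   (default 10).
#' @param requireTGCA if TRUE, require each LTR to start with TG and end
#'   with CA with at most 1 mismatch over the four bases (default FALSE).
#' @param chrom chromosome id used for the output `GRanges` (default
#'   `"seq"`).
#' @return a [GenomicRanges::GRanges] of element spans (5' LTR start to 3'
#'   LTR end) with metadata columns `ltr5Start`, `ltr5End`, `ltr3Start`,
#'   `ltr3End`, `ltrLength`, `identity`, `structuralClass`, `note`.
#' @export
findLTRCandidates <- function(seq, minLtr = 100L, maxLtr = 1000L,
                              minDist = 1000L, maxDist = 15000L,
                              minSimilarity = 85, k = 20L,
                              maxKmerOcc = 10L, requireTGCA = FALSE,
                              chrom = "seq") {
  if (minLtr > maxLtr || minDist > maxDist)
    stop("config error: min parameter exceeds max")
  s <- if (is.character(seq)) seq else as.character(seq)
  emptyRes <- GenomicRanges::GRanges()
  h <- .kmerHash(s, k)
  if (length(h) == 0L) return(emptyRes)
  dt <- data.table::data.table(h = h, pos = seq_along(h))
  dt <- dt[!is.na(h)]
  cnt <- dt[, list(n = .N), by = "h"]
  keepH <- cnt[cnt$n >= 2L & cnt$n <= maxKmerOcc]$h
  dt <- dt[dt$h %in% keepH]
  if (nrow(dt) == 0L) return(emptyRes)
  pairs <- dt[, {
    p <- sort(pos)
    if (length(p) < 2L) NULL else {
      cmb <- utils::combn(p, 2L)
      d <- cmb[2L, ] - cmb[1L, ]
      ok <- d >= minDist & d <= maxDist
      list(p1 = cmb[1L, ok], d = d[ok])
    }
  }, by = "h"]
  if (nrow(pairs) == 0L) return(emptyRes)
  data.table::setorder(pairs, d, p1)
  raw <- charToRaw(s)
  cand <- list()
  for (dv in unique(pairs$d)) {
    p1s <- pairs[pairs$d == dv]$p1
    breaks <- c(0L, which(diff(p1s) > maxLtr), length(p1s))
    for (b in seq_len(length(breaks) - 1L)) {
      grp <- p1s[(breaks[b] + 1L):breaks[b + 1L]]
      seedS <- min(grp); seedE <- max(grp) + k - 1L
      ext <- .extendDiagonal(raw, seedS, seedE, dv)
      L <- ext[2L] - ext[1L] + 1L
      if (L < minLtr || L > maxLtr) next
      cand[[length(cand) + 1L]] <- c(ext[1L], ext[2L], dv)
    }
  }
  if (length(cand) == 0L) return(emptyRes)
  cm <- unique(do.call(rbind, cand))
  res <- list()
  for (i in seq_len(nrow(cm))) {
    s1 <- cm[i, 1L]; e1 <- cm[i, 2L]; dv <- cm[i, 3L]
    s2 <- s1 + dv; e2 <- e1 + dv
    if (e1 >= s2) next
    ltr5 <- substr(s, s1, e1); ltr3 <- substr(s, s2, e2)
    if (requireTGCA) {
      mm <- sum(substr(ltr5, 1, 2) != "TG",
                substr(ltr5, nchar(ltr5) - 1, nchar(ltr5)) != "CA") +
            sum(substr(ltr3, 1, 2) != "TG",
                substr(ltr3, nchar(ltr3) - 1, nchar(ltr3)) != "CA")
      if (mm > 1L) next
    }
    id <- ltrPairIdentity(ltr5, ltr3)
    if (id < minSimilarity) next
    res[[length(res) + 1L]] <- data.frame(
      start = s1, end = e2, ltr5Start = s1, ltr5End = e1,
      ltr3Start = s2, ltr3End = e2, ltrLength = e1 - s1 + 1L,
      identity = id)
  }
  if (length(res) == 0L) return(emptyRes)
  df <- do.call(rbind, res)
  # greedy resolution of overlapping element spans: identity, then length
  df <- df[order(-df$identity, -(df$end - df$start)), , drop = FALSE]
  kept <- logical(nrow(df))
  occ <- IRanges::IRanges()
  for (i in seq_len(nrow(df))) {
    iv <- IRanges::IRanges(df$start[i], df$end[i])
    if (length(IRanges::findOverlaps(iv, occ)) == 0L) {
      kept[i] <- TRUE
      occ <- c(occ, iv)
    }
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  cls <- lapply(df$end - df$start + 1L, flagStructuralClass)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ltr5Start = df$ltr5Start, ltr5End = df$ltr5End,
    ltr3Start = df$ltr3Start, ltr3End = df$ltr3End,
    ltrLength = df$ltrLength, identity = df$identity,
    structuralClass = vapply(cls, `[[`, character(1), "class"),
    note = vapply(cls, `[[`, character(1), "note"))
  gr
}

#' Summarize paired-LTR identities (insertion-age proxy)
#'
#' @param identities numeric identity percents, or a `GRanges` from
#'   [findLTRCandidates()] (its `identity` column is used).
#' @param superfamily optional character vector of superfamily labels
#'   (e.g. Copia/Gypsy), parallel to the identities; grouped medians are
#'   reported when present.
#' @return list with `n`, `medianIdentity`, `nAt100` and `pctAt100` (a
#'   count of elements whose identity is exactly 100.00 after 2-decimal
#'   rounding, as a percent to 1 decimal), `nLTRSequences` (two per
#'   element) and `perSuperfamilyMedian`.
#' @examples
#' summarizeLTRAges(c(100, 99, 98))  # median 99, 33.3% at 100
#' @export
summarizeLTRAges <- function(identities, superfamily = NULL) {
  if (methods::is(identities, "GRanges"))
    identities <- S4Vectors::mcols(identities)$identity
  if (length(identities) == 0L)
    stop("domain error: no elements")
  id <- round(identities, 2)
  n100 <- sum(id == 100)
  perSf <- NULL
  if (!is.null(superfamily)) {
    stopifnot(length(superfamily) == length(id))
    perSf <- vapply(split(id, superfamily), stats::median, numeric(1))
  }
  list(n = length(id),
       medianIdentity = stats::median(id),
       nAt100 = n100,
       pctAt100 = round(n100 / length(id) * 100, 1),
       nLTRSequences = 2L * length(id),
       perSuperfamilyMedian = perSf)
}

#' Structural class of an LTR element from length and protein domains
#'
#' Elements up to 8 kb are canonical; 8-10 kb are canonical with a "long"
#' note; elements over 10 kb are "oversized" (putative nested insertion)
#' when at least one retrotransposon protein domain is detected and
#' "nested_disrupted" when none is.
#'
#' @param lengthBp element length in bp.
#' @param domains character vector of detected protein domains (e.g. RT,
#'   INT, RNaseH, AP); empty when none.
#' @return list with `class` and `note`.
#' @examples
#' flagStructuralClass(12443, c("RT", "RNaseH"))$class  # "oversized"
#' @export
flagStructuralClass <- function(lengthBp, domains = character(0)) {
  if (lengthBp <= 8000) list(class = "canonical", note = "")
  else if (lengthBp <= 10000) list(class = "canonical", note = "long")
  else if (length(domains) > 0L)
    list(class = "oversized", note = "putative nested insertion")
  else list(class = "nested_disrupted", note = "")
}
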