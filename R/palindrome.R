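#' Find inverted repeats (palindromes) by seed-and-extend
#'
#' Exact k-mer seeds between the sequence and its reverse complement anchor
#' arm pairs on a shared anti-diagonal; seeds are clustered, extended with
#' an X-drop heuristic, and each candidate's arm identity is measured by
#' global alignment of arm1 against the reverse complement of arm2
#' ([ltrPairIdentity()] scoring). Pairs are reported when the arm lengths
#' lie in `[minArm, maxArm]`, the spacer does not exceed `maxSpacer`, and
#' the identity reaches `minIdentity`; contained or duplicated pairs are
#' collapsed to the highest-identity maximal pair.
#'
#' @param seq a [Biostrings::DNAString] or character scalar (one
#'   chromosome).
#' @param minArm,maxArm allowed arm lengths in bp (defaults 100/10000).
#' @param maxSpacer maximum spacer between the arms in bp (default 50000).
#' @param minIdentity minimum arm identity in percent (default 90).
#' @param k seed length (default 15; `minArm` must be >= `k`).
#' @param maxKmerOcc skip seeds from k-mers occurring more often than this
#'   in either orientation (default 20).
#' @param chrom chromosome id for the output (default `"seq"`).
#' @return a [S4Vectors::DataFrame] with columns `chrom`, `arm1Start`,
#'   `arm1End`, `arm2Start`, `arm2End`, `armLength` (of arm1), `spacer`
#'   and `identity`, sorted by `arm1Start`.
#' @export
findInvertedRepeats <- function(seq, minArm = 100L, maxArm = 10000L,
                                maxSpacer = 50000L, minIdentity = 90,
                                k = 15L, maxKmerOcc = 20L, chrom = "seq") {
  if (minArm > maxArm) stop("config error: minArm exceeds maxArm")
  if (minArm < k) stop("config error: minArm must be >= seed length k")
  s <- if (is.character(seq)) seq else as.character(seq)
  n <- nchar(s)
  empty <- S4Vectors::DataFrame(chrom = character(0),
                                arm1Start = integer(0),
                                arm1End = integer(0),
                                arm2Start = integer(0),
                                arm2End = integer(0),
                                armLength = integer(0),
                                spacer = integer(0),
                                identity = numeric(0))
  if (n < 2L * k) return(empty)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- .kmerHash(s, k)
  h2 <- .kmerHash(rc, k)
  d1 <- data.table::data.table(h = h1, i = seq_along(h1))[!is.na(h)]
  d2 <- data.table::data.table(h = h2, j = seq_along(h2))[!is.na(h)]
  c1 <- d1[, list(n1 = .N), by = "h"]
  c2 <- d2[, list(n2 = .N), by = "h"]
  okH <- intersect(c1[c1$n1 <= maxKmerOcc]$h, c2[c2$n2 <= maxKmerOcc]$h)
  d1 <- d1[d1$h %in% okH]; d2 <- d2[d2$h %in% okH]
  if (nrow(d1) == 0L || nrow(d2) == 0L) return(empty)
  m <- merge(d1, d2, by = "h", allow.cartesian = TRUE)
  # rc k-mer j corresponds to forward segment [n-j-k+2, n-j+1]
  m$fwdEnd <- n - m$j + 1L
  m$cdiag <- m$i + m$fwdEnd         # anti-diagonal: arm1 pos + arm2 pos
  # arm1 seed must lie left of its partner segment
  m <- m[(m$fwdEnd - k + 1L) > (m$i + k - 1L)]
  if (nrow(m) == 0L) return(empty)
  data.table::setorder(m, cdiag, i)
  raw <- charToRaw(s)
  cand <- list()
  for (cv in unique(m$cdiag)) {
    iv <- unique(m[m$cdiag == cv]$i)
    breaks <- c(0L, which(diff(iv) > maxArm), length(iv))
    for (b in seq_len(length(breaks) - 1L)) {
      grp <- iv[(breaks[b] + 1L):breaks[b + 1L]]
      seedS <- min(grp); seedE <- max(grp) + k - 1L
      ext <- .extendAntiDiagonal(raw, seedS, seedE, cv)
      a1s <- ext[1L]; a1e <- ext[2L]
      a2s <- cv - a1e; a2e <- cv - a1s
      L <- a1e - a1s + 1L
      if (L < minArm || L > maxArm) next
      sp <- a2s - a1e - 1L
      if (sp < 0L || sp > maxSpacer) next
      cand[[length(cand) + 1L]] <- c(a1s, a1e, a2s, a2e)
    }
  }
  if (length(cand) == 0L) return(empty)
  cm <- unique(do.call(rbind, cand))
  rows <- list()
  for (i in seq_len(nrow(cm))) {
    a1 <- substr(s, cm[i, 1L], cm[i, 2L])
    a2 <- substr(s, cm[i, 3L], cm[i, 4L])
    a2rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(a2)))
    id <- ltrPairIdentity(a1, a2rc)
    if (id < minIdentity) next
    rows[[length(rows) + 1L]] <- data.frame(
      arm1Start = cm[i, 1L], arm1End = cm[i, 2L],
      arm2Start = cm[i, 3L], arm2End = cm[i, 4L],
      armLength = cm[i, 2L] - cm[i, 1L] + 1L,
      spacer = cm[i, 3L] - cm[i, 2L] - 1L,
      identity = id)
  }
  if (length(rows) == 0L) return(empty)
  df <- do.call(rbind, rows)
  # collapse overlapping/contained pairs: best identity, then longest arm
  df <- df[order(-df$identity, -df$armLength), , drop = FALSE]
  kept <- logical(nrow(df))
  occ1 <- IRanges::IRanges(); occ2 <- IRanges::IRanges()
  for (i in seq_len(nrow(df))) {
    iv1 <- IRanges::IRanges(df$arm1Start[i], df$arm1End[i])
    iv2 <- IRanges::IRanges(df$arm2Start[i], df$arm2End[i])
    dup <- length(IRanges::findOverlaps(iv1, occ1)) > 0L &&
           length(IRanges::findOverlaps(iv2, occ2)) > 0L
    if (!dup) {
      kept[i] <- TRUE
      occ1 <- c(occ1, iv1); occ2 <- c(occ2, iv2)
    }
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$arm1Start), , drop = FALSE]
  rownames(df) <- NULL
  S4Vectors::DataFrame(cbind(data.frame(chrom = chrom,
                                        stringsAsFactors = FALSE), df))
}

#' Cassette encapsulation relative to inverted repeats
#'
#' Labels each cassette interval relative to each inverted repeat on the
#' same chromosome: `inside-spacer` (contained in the gap between the
#' arms), `inside-arm` (contained in either arm), `spanning` (overlapping
#' an arm and the spacer, or both arms) or `free`. Overlap with centromere
#' cores is reported in bp.
#'
#' @param cassettes a [GenomicRanges::GRanges] of cassette intervals
#'   (names or `$name` used as labels).
#' @param irs inverted repeats as returned by [findInvertedRepeats()].
#' @param cores optional `GRanges` of centromere cores.
#' @return a data.frame with one row per cassette x same-chromosome IR
#'   (cassettes with no IR on their chromosome get a single `free` row):
#'   columns `cassette`, `chrom`, `irIndex`, `relation`, `coreOverlap`.
#' @export
encapsulationReport <- function(cassettes, irs, cores = NULL) {
  labs <- if (!is.null(cassettes$name)) cassettes$name
          else if (!is.null(names(cassettes))) names(cassettes)
          else paste0("cassette", seq_along(cassettes))
  rows <- list()
  for (i in seq_along(cassettes)) {
    chrom <- as.character(GenomicRanges::seqnames(cassettes))[i]
    cs <- BiocGenerics::start(cassettes)[i]
    ce <- BiocGenerics::end(cassettes)[i]
    coreBp <- 0L
    if (!is.null(cores) && length(cores)) {
      cc <- cores[as.character(GenomicRanges::seqnames(cores)) == chrom]
      if (length(cc))
        coreBp <- sum(BiocGenerics::width(IRanges::intersect(
          IRanges::IRanges(cs, ce),
          IRanges::reduce(IRanges::IRanges(BiocGenerics::start(cc),
                                           BiocGenerics::end(cc))))))
    }
    irc <- which(irs$chrom == chrom)
    if (length(irc) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        cassette = labs[i], chrom = chrom, irIndex = NA_integer_,
        relation = "free", coreOverlap = coreBp)
      next
    }
    for (j in irc) {
      a1s <- irs$arm1Start[j]; a1e <- irs$arm1End[j]
      a2s <- irs$arm2Start[j]; a2e <- irs$arm2End[j]
      sps <- a1e + 1L; spe <- a2s - 1L
      inArm <- (cs >= a1s && ce <= a1e) || (cs >= a2s && ce <= a2e)
      inSpacer <- sps <= spe && cs >= sps && ce <= spe
      ovArm <- (cs <= a1e && ce >= a1s) || (cs <= a2e && ce >= a2s)
      ovSpacer <- sps <= spe && cs <= spe && ce >= sps
      relation <- if (inSpacer) "inside-spacer"
        else if (inArm) "inside-arm"
        else if (ovArm && (ovSpacer || (cs <= a1e && ce >= a2s)))
          "spanning"
        else if (ovArm || ovSpacer) "spanning"
        else "free"
      rows[[length(rows) + 1L]] <- data.frame(
        cassette = labs[i], chrom = chrom, irIndex = j,
        relation = relation, coreOverlap = coreBp)
    }
  }
  do.call(rbind, rows)
}
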