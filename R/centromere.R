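#' Sliding-window AT fraction profile
#'
#' Computes the AT fraction (A+T over unambiguous bases) in sliding windows
#' of `window` bp advanced by `step` bp. A final truncated window is added
#' when the full windows do not reach the sequence end; windows containing
#' only N have undefined AT fraction and are flagged.
#'
#' @param seq a [Biostrings::DNAString], character scalar, or
#'   [GenomeAssembly-class] with `chrom` given.
#' @param window window size in bp (>= 1).
#' @param step step size in bp (1 <= step <= window).
#' @param chrom chromosome id when `seq` is a `GenomeAssembly`.
#' @return a [S4Vectors::DataFrame] with columns `start`, `end`, `at`
#'   (fraction in \[0,1\], NA for all-N windows) and `allN`; window, step
#'   and sequence length are stored in `metadata()`.
#' @examples
#' atProfile("ATGC", window = 2, step = 1)$at  # 1.0 0.5 0.0
#' @export
atProfile <- function(seq, window = 1000L, step = 100L, chrom = NULL) {
  if (methods::is(seq, "GenomeAssembly")) {
    stopifnot(!is.null(chrom))
    seq <- seq[[chrom]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  stopifnot(window >= 1L, step >= 1L, step <= window)
  n <- length(seq)
  stopifnot(n >= 1L)
  if (window > n) {
    warning("window larger than sequence; using a single truncated window")
    starts <- 1L
  } else {
    starts <- seq.int(1L, n - window + 1L, by = step)
    lastEnd <- starts[length(starts)] + window - 1L
    if (lastEnd < n) starts <- c(starts, starts[length(starts)] + step)
  }
  ends <- pmin(starts + window - 1L, n)
  v <- Biostrings::Views(seq, start = starts, end = ends)
  lf <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
  denom <- rowSums(lf)
  at <- ifelse(denom > 0, (lf[, "A"] + lf[, "T"]) / denom, NA_real_)
  out <- S4Vectors::DataFrame(start = starts, end = ends, at = at,
                              allN = denom == 0)
  S4Vectors::metadata(out) <- list(window = as.integer(window),
                                   step = as.integer(step),
                                   seqlength = n, chrom = chrom)
  out
}

#' Call AT-rich islands from a window profile
#'
#' Identifies maximal runs of windows whose AT fraction meets `atThreshold`,
#' merges runs separated by at most `mergeGap` bp, discards merged islands
#' shorter than `minIsland` bp, and marks the island with the highest mean
#' window AT (ties broken leftmost) as retained — the single AT island kept
#' per chromosome. Island boundaries are the first window start to the last
#' window end of the run, clipped to the sequence.
#'
#' @param profile output of [atProfile()].
#' @param atThreshold minimum window AT fraction (default 0.70).
#' @param mergeGap maximum gap in bp between runs that are merged
#'   (default 2000).
#' @param minIsland minimum island size in bp (default 5000).
#' @return a [S4Vectors::DataFrame] with columns `start`, `end`, `width`,
#'   `meanAT` and `retained`, sorted by start; zero rows when no window
#'   passes the threshold.
#' @export
callATIslands <- function(profile, atThreshold = 0.70, mergeGap = 2000L,
                          minIsland = 5000L) {
  stopifnot(nrow(profile) > 0L)
  pass <- !is.na(profile$at) & profile$at >= atThreshold
  empty <- S4Vectors::DataFrame(start = integer(0), end = integer(0),
                                width = integer(0), meanAT = numeric(0),
                                retained = logical(0))
  if (!any(pass)) return(empty)
  r <- rle(pass)
  idxEnd <- cumsum(r$lengths)
  idxStart <- idxEnd - r$lengths + 1L
  runs <- which(r$values)
  ir <- IRanges::IRanges(start = profile$start[idxStart[runs]],
                         end = profile$end[idxEnd[runs]])
  merged <- IRanges::reduce(ir, min.gapwidth = mergeGap + 1L)
  keep <- BiocGenerics::width(merged) >= minIsland
  merged <- merged[keep]
  if (length(merged) == 0L) return(empty)
  meanAT <- vapply(seq_along(merged), function(i) {
    inWin <- profile$start >= BiocGenerics::start(merged)[i] &
      profile$end <= BiocGenerics::end(merged)[i] & !is.na(profile$at)
    mean(profile$at[inWin])
  }, numeric(1))
  retained <- rep(FALSE, length(merged))
  retained[order(-meanAT, BiocGenerics::start(merged))[1L]] <- TRUE
  S4Vectors::DataFrame(start = BiocGenerics::start(merged),
                       end = BiocGenerics::end(merged),
                       width = BiocGenerics::width(merged),
                       meanAT = meanAT, retained = retained)
}

# Base-resolution refinement of one island edge by a two-proportion
# Bernoulli changepoint MLE. `atv` is a logical vector (base is A or T),
# `edge` the coarse edge position, `side` which flank is background.
# Rates p0 (background) and p1 (island) are estimated from the data.
.refineEdge <- function(atv, edge, side = c("left", "right"),
                        halfwidth = 2500L, p0, p1) {
  side <- match.arg(side)
  n <- length(atv)
  lo <- max(1L, edge - halfwidth)
  hi <- min(n, edge + halfwidth)
  x <- as.numeric(atv[lo:hi])
  m <- length(x)
  if (m < 10L || p0 >= p1) return(edge)
  ll0 <- x * log(p0) + (1 - x) * log(1 - p0)
  ll1 <- x * log(p1) + (1 - x) * log(1 - p1)
  # left edge: background then island; right edge: island then background
  if (side == "left") {
    score <- cumsum(ll0 - ll1)     # boundary after position t
    t <- which.max(c(0, score))    # t-1 background positions
    lo + t - 1L                    # first island base
  } else {
    score <- cumsum(ll1 - ll0)
    t <- which.max(c(0, score))    # t-1 island positions in the region
    max(lo, lo + t - 2L)           # last island base
  }
}

#' Call regional centromeres across an assembly
#'
#' Runs the AT-bias sliding-window scan on every chromosome, keeps the
#' highest non-overlapping AT island per chromosome, optionally refines the
#' island edges to base resolution with a two-proportion changepoint
#' estimator (background and core AT rates estimated from the chromosome),
#' and classifies chromosome morphology from the arm ratio
#' ([classifyMorphology()]).
#'
#' @param assembly a [GenomeAssembly-class].
#' @param window,step sliding-window parameters (defaults 1000/100 bp).
#' @param atThreshold,mergeGap,minIsland island-calling parameters, see
#'   [callATIslands()].
#' @param refine logical; refine island edges to base resolution
#'   (default TRUE).
#' @return a [GenomicRanges::GRanges] of centromere cores with metadata
#'   columns `coreATpct`, `coreSize`, `pArm`, `qArm`, `armRatio` (2
#'   decimals; `Inf` when p = 0) and `morphology`. Chromosomes without a
#'   qualifying island are omitted (with a message).
#' @export
callCentromeres <- function(assembly, window = 1000L, step = 100L,
                            atThreshold = 0.70, mergeGap = 2000L,
                            minIsland = 5000L, refine = TRUE) {
  out <- list()
  for (chrom in chromNames(assembly)) {
    seq <- assembly[[chrom]]
    n <- length(seq)
    prof <- atProfile(seq, window = window, step = step)
    isl <- callATIslands(prof, atThreshold = atThreshold,
                         mergeGap = mergeGap, minIsland = minIsland)
    if (nrow(isl) == 0L) {
      message("no AT island called on ", chrom)
      next
    }
    top <- isl[isl$retained, , drop = FALSE]
    s <- top$start[1L]; e <- min(top$end[1L], n)
    if (refine) {
      atv <- as.integer(Biostrings::letterFrequencyInSlidingView(
        seq, view.width = 1L, letters = "AT")) > 0L
      lo2 <- min(s + window, e); hi2 <- max(e - window, s)
      if (hi2 - lo2 < 500L) { lo2 <- s; hi2 <- e }
      p1 <- mean(atv[lo2:hi2])
      outer <- atv[-seq.int(max(1L, s - window), min(n, e + window))]
      p0 <- if (length(outer) > 1000L) mean(outer) else 0.5
      p0 <- min(max(p0, 1e-3), 0.999); p1 <- min(max(p1, 1e-3), 0.999)
      if (p1 > p0) {
        hw <- as.integer(2L * window + mergeGap)
        s <- .refineEdge(atv, s, "left", halfwidth = hw, p0 = p0, p1 = p1)
        e <- .refineEdge(atv, e, "right", halfwidth = hw, p0 = p0, p1 = p1)
        if (e <= s) { s <- top$start[1L]; e <- min(top$end[1L], n) }
      }
    }
    coreSeq <- Biostrings::subseq(seq, s, e)
    lf <- Biostrings::letterFrequency(coreSeq, c("A", "C", "G", "T"))
    atPct <- (lf[["A"]] + lf[["T"]]) / sum(lf) * 100
    morph <- classifyMorphology(n, c(s, e))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      coreATpct = round(atPct, 2), coreSize = e - s + 1L,
      pArm = morph$pArm, qArm = morph$qArm,
      armRatio = morph$ratio, morphology = morph$class)
    out[[chrom]] <- gr
  }
  if (length(out) == 0L) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  res <- unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
  res
}

#' Screen for the budding-yeast point-centromere motif
#'
#' Scans both strands for CDEI and CDEIII consensus elements (IUPAC
#' degenerate alphabet, mismatches allowed) and reports full
#' CDEI-spacer-CDEIII hits in which both elements lie on the same strand
#' with a spacer length inside `spacerRange`. Partial (element-only) hits
#' are reported alongside.
#'
#' @param seq a [Biostrings::DNAString] or character scalar.
#' @param cdei CDEI consensus (default `"RTCACRTG"`).
#' @param cdeiii CDEIII core consensus variants (default with and without
#'   the optional extra T: `c("TGTTTGNNTTCCGAA", "TGTTTTGNNTTCCGAA")`).
#' @param spacerRange allowed spacer lengths in bp (default `c(70, 90)`).
#' @param maxMismatch maximum mismatches per element (default 1).
#' @return a [S4Vectors::DataFrame] with columns `start`, `end`, `strand`,
#'   `element` (`"CDEI"`, `"CDEIII"` or `"full"`) and `mismatches`; full
#'   hits span CDEI start to CDEIII end.
#' @export
scanPointCentromereMotif <- function(seq,
                                     cdei = "RTCACRTG",
                                     cdeiii = c("TGTTTGNNTTCCGAA",
                                                "TGTTTTGNNTTCCGAA"),
                                     spacerRange = c(70L, 90L),
                                     maxMismatch = 1L) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  for (p in c(cdei, cdeiii)) {
    bad <- setdiff(strsplit(p, "")[[1L]], names(Biostrings::IUPAC_CODE_MAP))
    if (length(bad))
      stop("config error: non-IUPAC letter '", bad[1L],
           "' in consensus ", p)
  }
  n <- length(seq)
  scanOne <- function(subject, pattern) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                  max.mismatch = maxMismatch,
                                  fixed = FALSE)
    if (length(m) == 0L)
      return(data.frame(start = integer(0), end = integer(0),
                        mm = integer(0)))
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pattern),
                                      subject,
                                      starting.at = BiocGenerics::start(m),
                                      fixed = FALSE)
    data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
               mm = mm)
  }
  collect <- function(subject, strandChar) {
    h1 <- scanOne(subject, cdei)
    h3 <- do.call(rbind, lapply(cdeiii, function(p) scanOne(subject, p)))
    full <- list()
    if (nrow(h1) && nrow(h3)) {
      for (i in seq_len(nrow(h1))) {
        sp <- h3$start - h1$end[i] - 1L
        ok <- which(sp >= spacerRange[1L] & sp <= spacerRange[2L])
        for (j in ok)
          full[[length(full) + 1L]] <- data.frame(
            start = h1$start[i], end = h3$end[j],
            mm = h1$mm[i] + h3$mm[j])
      }
    }
    mk <- function(df, el) if (nrow(df) == 0L) NULL else
      data.frame(start = df$start, end = df$end, strand = strandChar,
                 element = el, mismatches = df$mm)
    rbind(mk(h1, "CDEI"), mk(h3, "CDEIII"),
          if (length(full)) mk(do.call(rbind, full), "full") else NULL)
  }
  fwd <- collect(seq, "+")
  rcHits <- collect(Biostrings::reverseComplement(seq), "-")
  if (!is.null(rcHits) && nrow(rcHits)) {
    s <- n - rcHits$end + 1L
    e <- n - rcHits$start + 1L
    rcHits$start <- s; rcHits$end <- e
  }
  res <- rbind(fwd, rcHits)
  if (is.null(res))
    res <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), element = character(0),
                      mismatches = integer(0))
  res <- res[order(res$start, res$element), , drop = FALSE]
  rownames(res) <- NULL
  S4Vectors::DataFrame(res)
}

#' Classify chromosome morphology from the centromere position
#'
#' Arm lengths exclude the centromere core: the left arm is
#' `core start - 1`, the right arm `chromosome length - core end`; p is the
#' shorter and q the longer arm. Classes follow the standard arm-ratio
#' (q/p) thresholds: metacentric (<= 1.7), submetacentric (<= 3.0),
#' acrocentric (<= 7.0), telocentric (> 7.0; a zero-length p arm gives an
#' infinite ratio and is telocentric).
#'
#' @param chromLength chromosome length in bp.
#' @param core centromere core as `c(start, end)` or a length-1 `GRanges`/
#'   `IRanges`.
#' @param thresholds class boundaries for q/p (default `c(1.7, 3.0, 7.0)`).
#' @return list with `pArm`, `qArm`, `ratio` (rounded to 2 decimals) and
#'   `class`.
#' @export
classifyMorphology <- function(chromLength, core,
                               thresholds = c(1.7, 3.0, 7.0)) {
  if (!is.numeric(core)) core <- c(BiocGenerics::start(core)[1L],
                                   BiocGenerics::end(core)[1L])
  s <- core[1L]; e <- core[2L]
  if (s < 1 || e > chromLength || s > e)
    stop("domain error: core outside chromosome")
  left <- s - 1
  right <- chromLength - e
  p <- min(left, right); q <- max(left, right)
  ratio <- if (p == 0) Inf else round(q / p, 2)
  cls <- if (ratio <= thresholds[1L]) "metacentric"
    else if (ratio <= thresholds[2L]) "submetacentric"
    else if (ratio <= thresholds[3L]) "acrocentric"
    else "telocentric"
  list(pArm = p, qArm = q, ratio = ratio, class = cls)
}

#' Per-column conservation of a DNA multiple alignment
#'
#' For each alignment column the Shannon entropy
#' \eqn{H = -\sum p \log_2 p} is computed over the non-gap A/C/G/T symbols
#' and converted to information content \eqn{2 - H} bits; 2.0 bits means
#' absolute identity across rows, 0 bits a uniform column. All-gap columns
#' have undefined entropy and are flagged.
#'
#' @param alignment equal-length gapped DNA strings: a character vector,
#'   [Biostrings::DNAMultipleAlignment] or `DNAStringSet` (gap `"-"`).
#' @return a [S4Vectors::DataFrame] with columns `position`, `entropy`,
#'   `information`, `gapFraction` and `allGap`.
#' @export
columnConservation <- function(alignment) {
  if (methods::is(alignment, "DNAMultipleAlignment"))
    alignment <- as.character(Biostrings::DNAStringSet(alignment))
  if (methods::is(alignment, "DNAStringSet") ||
      methods::is(alignment, "BStringSet"))
    alignment <- as.character(alignment)
  stopifnot(is.character(alignment))
  if (length(alignment) < 2L)
    stop("alignment must have at least 2 rows")
  if (length(unique(nchar(alignment))) != 1L)
    stop("format error: ragged alignment (rows differ in length)")
  m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  ncolA <- ncol(m)
  ent <- info <- gapf <- numeric(ncolA)
  allGap <- logical(ncolA)
  for (j in seq_len(ncolA)) {
    col <- m[, j]
    gapf[j] <- mean(col == "-")
    obs <- col[col %in% c("A", "C", "G", "T")]
    if (length(obs) == 0L) {
      allGap[j] <- TRUE
      ent[j] <- NA_real_; info[j] <- NA_real_
    } else {
      p <- table(obs) / length(obs)
      ent[j] <- -sum(p * log2(p))
      info[j] <- 2 - ent[j]
    }
  }
  S4Vectors::DataFrame(position = seq_len(ncolA), entropy = ent,
                       information = info, gapFraction = gapf,
                       allGap = allGap)
}
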