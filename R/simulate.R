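#' Configuration for the synthetic genome generator
#'
#' Returns a validated configuration list whose defaults describe a small
#' predatory-yeast-like genome: six nuclear chromosomes of 1.2-3.5 Mb at
#' 33.9% GC; one 26-34 kb AT-rich (~75.5% AT) regional centromere core per
#' chromosome containing a chromosome-specific satellite array; 74 paired-
#' LTR retrotransposons peaked at ~5.5 kb (19 with identical LTR pairs,
#' a few oversized nested elements >10 kb); 708 intron-bearing genes with
#' GT-AG introns whose lengths are right-skewed around a 113 bp median
#' (plus single-exon genes to a 5,428-gene universe); co-transcribed gene
#' pairs bridged by 189-247 bp intergenic splice junctions; and palindromic
#' cassettes including an 8,575 bp-arm / 2,019 bp-spacer / 0.02%-divergence
#' structure. Any component can be scaled or disabled.
#'
#' @param chromLengths named chromosome lengths in bp.
#' @param gc background GC fraction.
#' @param centromeres list: `size` (bp per chromosome, recycled), `at`
#'   (core AT fraction), `satelliteUnit` (unit length per chromosome),
#'   `satelliteFraction` (fraction of the core occupied by the array),
#'   `armRatio` (q/p placement target per chromosome). `NULL` disables.
#' @param ltr list: `countsPerChrom`, `ltrLengthRange`,
#'   `elementLengthMean`/`elementLengthSD`, `nOversized`,
#'   `oversizedLength`, `nIdentical` (elements with divergence 0),
#'   `divergenceMean`/`divergenceMax` (percent). `NULL` disables.
#' @param genes list: `nIntronGenes`, `nSingleExonGenes`,
#'   `intronsPerGeneExtra` (Poisson mean of introns beyond the first),
#'   `intronMeanLog`/`intronSdLog`/`intronRange` (lognormal intron
#'   lengths, bp), `exonMeanLog`/`exonSdLog`/`exonRange`,
#'   `canonicalFraction`, `sjFraction` (fraction of introns emitted as
#'   observed splice junctions). `NULL` disables.
#' @param bridges list: `n` (co-transcribed gene pairs), `geneLength`,
#'   `spacerRange` (bp; also the excised junction length). `NULL`
#'   disables.
#' @param cassettes list of palindromic cassette specs, each a list with
#'   `chrom` (index), `armLength`, `spacer`, `armDivergence` (percent),
#'   `nMembers`. `NULL` disables.
#' @param seed integer seed governing all randomness; per-feature
#'   substreams are derived from it deterministically.
#' @return a list of class `"sim_config"`.
#' @export
simConfig <- function(
    chromLengths = c(chrI = 3497966, chrII = 2933000, chrIII = 2335549,
                     chrIV = 2052000, chrV = 1831595, chrVI = 1215549),
    gc = 0.339,
    centromeres = list(size = c(26781, 34016, 31850, 33021, 25953, 30499),
                       at = 0.755,
                       satelliteUnit = c(147, 22, 61, 32, 109, 61),
                       satelliteFraction = 0.0124,
                       armRatio = c(2.36, 4.50, 5.20, 6.16, 98.66, 2.94)),
    ltr = list(countsPerChrom = c(8, 18, 15, 13, 10, 10),
               ltrLengthRange = c(200, 400),
               elementLengthMean = 5500, elementLengthSD = 700,
               nOversized = 3, oversizedLength = 12000,
               nIdentical = 19, divergenceMean = 2.5, divergenceMax = 15),
    genes = list(nIntronGenes = 708, nSingleExonGenes = 4708,
                 intronsPerGeneExtra = 0.25,
                 intronMeanLog = log(113), intronSdLog = 0.65,
                 intronRange = c(37, 2318),
                 exonMeanLog = log(400), exonSdLog = 0.5,
                 exonRange = c(50, 3000),
                 canonicalFraction = 1.0, sjFraction = 0.8),
    bridges = list(n = 6, geneLength = 1000, spacerRange = c(189, 247)),
    cassettes = list(
      list(chrom = 4, armLength = 8575, spacer = 2019,
           armDivergence = 0.02, nMembers = 2),
      list(chrom = 3, armLength = 124, spacer = 7200,
           armDivergence = 0, nMembers = 1),
      list(chrom = 5, armLength = 139, spacer = 7400,
           armDivergence = 0, nMembers = 1)),
    seed = 1L) {
  stopifnot(all(chromLengths > 0), gc > 0, gc < 1)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  cfg <- list(chromLengths = chromLengths, gc = gc,
              centromeres = centromeres, ltr = ltr, genes = genes,
              bridges = bridges, cassettes = cassettes,
              seed = as.integer(seed))
  if (!is.null(centromeres)) {
    nc <- length(chromLengths)
    for (f in c("size", "satelliteUnit", "armRatio"))
      cfg$centromeres[[f]] <- rep_len(centromeres[[f]], nc)
    if (any(cfg$centromeres$size >= chromLengths))
      stop("config error: centromere core exceeds chromosome length")
  }
  class(cfg) <- "sim_config"
  cfg
}

# uniform placement of one feature avoiding occupied ranges
.placeFeature <- function(occ, L, len, pad = 50L, maxTry = 500L) {
  if (len + 2L * pad >= L)
    stop("config error: infeasible placement (feature exceeds chromosome)")
  for (t in seq_len(maxTry)) {
    s <- sample.int(L - len - pad, 1L) + pad
    iv <- IRanges::IRanges(max(1L, s - pad), min(L, s + len - 1L + pad))
    if (length(IRanges::findOverlaps(iv, occ)) == 0L)
      return(list(start = s, occ = c(occ, iv)))
  }
  stop("config error: infeasible placement (no free interval found)")
}

# place many small features into the free gaps left by the macro features
.fillGaps <- function(occ, L, lens, pad = 50L) {
  free <- IRanges::gaps(IRanges::reduce(occ), start = 1L, end = L)
  free <- free[BiocGenerics::width(free) > 2L * pad]
  if (length(free) == 0L)
    stop("config error: infeasible placement (no free space)")
  starts <- integer(length(lens))
  totalFree <- sum(BiocGenerics::width(free))
  need <- sum(lens + pad)
  if (need > totalFree)
    stop("config error: infeasible placement (features exceed free space)")
  slack <- totalFree - need
  u <- stats::runif(length(lens))
  gapPlan <- floor(0.7 * slack * u / sum(u))
  gi <- 1L
  cursor <- BiocGenerics::start(free)[1L] + pad
  for (i in seq_along(lens)) {
    g <- gapPlan[i]
    placed <- FALSE
    while (!placed) {
      cursor <- cursor + g
      g <- 0L
      if (gi <= length(free) &&
          cursor + lens[i] - 1L + pad <= BiocGenerics::end(free)[gi]) {
        starts[i] <- cursor
        cursor <- cursor + lens[i] + pad
        placed <- TRUE
      } else {
        gi <- gi + 1L
        if (gi > length(free))
          stop("config error: infeasible placement (ran out of space)")
        cursor <- BiocGenerics::start(free)[gi] + pad
      }
    }
  }
  starts
}

#' Introduce point substitutions at a fixed divergence
#'
#' Exactly `round(divergence/100 * length)` distinct, uniformly chosen
#' positions are substituted; each substituted base differs from the
#' original. No indels are introduced.
#'
#' @param seq character scalar or [Biostrings::DNAString].
#' @param divergence percent divergence in `[0, 100)`.
#' @param seed optional integer; when given, seeds the RNG so the mutation
#'   is reproducible in isolation.
#' @return mutated sequence as a character scalar.
#' @examples
#' mutateSequence("ACGTACGT", 0)  # unchanged
#' @export
mutateSequence <- function(seq, divergence, seed = NULL) {
  if (divergence < 0 || divergence >= 100)
    stop("domain error: divergence must be in [0, 100)")
  if (!is.null(seed)) set.seed(seed)
  s <- if (is.character(seq)) seq else as.character(seq)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  nmut <- round(divergence / 100 * length(v))
  if (nmut == 0L) return(s)
  pos <- sample.int(length(v), nmut)
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, nmut, replace = TRUE)
  v[pos] <- vapply(seq_len(nmut), function(i) {
    a <- alts[[v[pos[i]]]]
    if (is.null(a)) "A" else a[pick[i]]
  }, character(1))
  paste(v, collapse = "")
}

#' Plant a palindromic cassette into a sequence
#'
#' Writes `arm1 | spacer | arm2` at `position`, where `arm2` is the
#' reverse complement of `arm1` mutated at `armDivergence` percent, and
#' records member gene intervals inside the structure (members are placed
#' in the arms when the arms can hold them, otherwise in the spacer).
#'
#' @param seq character scalar or [Biostrings::DNAString].
#' @param position 1-based start of the cassette.
#' @param armLength,spacerLength arm and spacer sizes in bp.
#' @param armDivergence percent divergence between the arms (default 0).
#' @param nMembers number of member gene intervals to record (default 0).
#' @param chrom chromosome label for the truth rows (default `"seq"`).
#' @return list with `seq` (modified character scalar) and `truth` (a
#'   data.frame of `cassette_ir` and `cassette_member` rows; the IR row
#'   carries `identity` = 100 - `armDivergence`).
#' @export
plantPalindromicCassette <- function(seq, position, armLength,
                                     spacerLength, armDivergence = 0,
                                     nMembers = 0L, chrom = "seq") {
  stopifnot(armLength >= 1, spacerLength >= 0, position >= 1)
  s <- if (is.character(seq)) seq else as.character(seq)
  total <- 2L * armLength + spacerLength
  if (position + total - 1L > nchar(s))
    stop("config error: cassette exceeds sequence")
  gcArm <- 0.40
  arm1 <- paste(.randBases(armLength, gcArm), collapse = "")
  spacer <- if (spacerLength > 0)
    paste(.randBases(spacerLength, 0.25), collapse = "") else ""
  if (spacerLength > 0) {
    # non-self-complementary A-tracts at the spacer termini pin the
    # arm/spacer boundaries (A pairs with T under inversion, so the two
    # tracts cannot extend the palindrome into the spacer)
    g <- min(12L, spacerLength %/% 2L + spacerLength %% 2L)
    substr(spacer, 1L, g) <- strrep("A", g)
    substr(spacer, spacerLength - g + 1L, spacerLength) <- strrep("A", g)
  }
  arm2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mutateSequence(arm1, armDivergence))))
  block <- paste0(arm1, spacer, arm2)
  substr(s, position, position + total - 1L) <- block
  a1s <- position; a1e <- position + armLength - 1L
  a2s <- a1e + spacerLength + 1L; a2e <- a2s + armLength - 1L
  truth <- data.frame(type = "cassette_ir", chrom = chrom,
                      start = a1s, end = a2e, strand = "+",
                      arm1Start = a1s, arm1End = a1e,
                      arm2Start = a2s, arm2End = a2e,
                      spacer = spacerLength,
                      divergence = armDivergence,
                      identity = 100 - armDivergence,
                      stringsAsFactors = FALSE)
  if (nMembers > 0L) {
    memberLen <- min(1000L, max(50L, armLength - 200L),
                     if (spacerLength > 300L) spacerLength - 200L
                     else .Machine$integer.max)
    mem <- list()
    for (m in seq_len(nMembers)) {
      if (armLength >= memberLen + 200L) {
        # alternate members between the two arms
        if (m %% 2L == 1L) { ms <- a1s + 100L }
        else { ms <- a2s + 100L }
      } else {
        ms <- a1e + 1L + 100L + (m - 1L) * (memberLen + 50L)
        if (ms + memberLen - 1L > a2s - 1L)
          stop("config error: members exceed cassette span")
      }
      mem[[m]] <- data.frame(type = "cassette_member", chrom = chrom,
                             start = ms, end = ms + memberLen - 1L,
                             strand = "+", arm1Start = NA, arm1End = NA,
                             arm2Start = NA, arm2End = NA, spacer = NA,
                             divergence = NA, identity = NA,
                             stringsAsFactors = FALSE)
    }
    truth <- rbind(truth, do.call(rbind, mem))
  }
  list(seq = s, truth = truth)
}

#' Generate a synthetic genome with planted architecture
#'
#' Draws i.i.d. background bases at the configured GC and plants, in fixed
#' stage order, centromere cores with satellite arrays, paired-LTR
#' elements, palindromic cassettes, co-transcribed bridge gene pairs and
#' intron-bearing genes, recording every feature in a truth table. The
#' same seed yields byte-identical output; per-stage random substreams are
#' derived from the seed so that disabling one feature type does not
#' perturb the others.
#'
#' @param config a [simConfig()] list.
#' @return a list of class `"simulated_genome"` with elements `assembly`
#'   ([GenomeAssembly-class]), `models` (gene models, see [geneModels()]),
#'   `junctions` (`GRanges` in SJ.out.tab semantics), `truth` (data.frame,
#'   one row per planted feature, sorted by type/chrom/start) and
#'   `config`.
#' @export
generateGenome <- function(config = simConfig()) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$chromLengths
  nms <- names(L)
  nChrom <- length(L)
  seed <- config$seed
  truth <- list()
  exonRows <- list()
  sjRows <- list()
  chromVecs <- vector("list", nChrom)
  occ <- lapply(seq_len(nChrom), function(i) IRanges::IRanges())

  # stage 1: background
  for (c in seq_len(nChrom)) {
    set.seed(.substream(seed, 100L + c))
    chromVecs[[c]] <- .randBases(L[c], config$gc)
  }

  writeBlock <- function(c, start, block) {
    v <- strsplit(block, "", fixed = TRUE)[[1L]]
    chromVecs[[c]][start:(start + length(v) - 1L)] <<- v
  }

  # stage 2: centromere cores with satellite arrays
  if (!is.null(config$centromeres)) {
    cen <- config$centromeres
    for (c in seq_len(nChrom)) {
      set.seed(.substream(seed, 200L + c))
      m <- cen$size[c]
      r <- cen$armRatio[c]
      p <- max(1L, floor((L[c] - m) / (1 + r)))
      s <- p + 1L
      core <- .randBases(m, 1 - cen$at)
      unit <- paste(.randBases(cen$satelliteUnit[c], 0.15), collapse = "")
      copies <- max(2L, round(cen$satelliteFraction * m /
                                cen$satelliteUnit[c]))
      array <- strrep(unit, copies)
      aoff <- sample.int(m - nchar(array), 1L)
      core[aoff:(aoff + nchar(array) - 1L)] <-
        strsplit(array, "", fixed = TRUE)[[1L]]
      chromVecs[[c]][s:(s + m - 1L)] <- core
      occ[[c]] <- c(occ[[c]], IRanges::IRanges(s - 100L, s + m - 1L + 100L))
      truth[[length(truth) + 1L]] <- data.frame(
        type = "centromere", chrom = nms[c], start = s, end = s + m - 1L,
        strand = "+", at = cen$at, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "satellite", chrom = nms[c], start = s + aoff - 1L,
        end = s + aoff - 1L + nchar(array) - 1L, strand = "+",
        unit = cen$satelliteUnit[c], copies = copies,
        stringsAsFactors = FALSE)
    }
  }

  # stage 3: LTR retrotransposons
  if (!is.null(config$ltr)) {
    lt <- config$ltr
    counts <- rep_len(lt$countsPerChrom, nChrom)
    total <- sum(counts)
    set.seed(.substream(seed, 300L))
    div <- c(rep(0, min(lt$nIdentical, total)),
             pmin(lt$divergenceMax,
                  stats::rexp(max(0L, total - lt$nIdentical),
                              rate = 1 / lt$divergenceMean)))
    div <- sample(div)          # shuffle across chromosomes
    nOver <- min(lt$nOversized, total)
    oversized <- sample.int(total, nOver)
    k <- 0L
    for (c in seq_len(nChrom)) {
      set.seed(.substream(seed, 300L + c))
      for (i in seq_len(counts[c])) {
        k <- k + 1L
        ltrLen <- sample(seq(lt$ltrLengthRange[1L], lt$ltrLengthRange[2L]),
                         1L)
        elemLen <- if (k %in% oversized) lt$oversizedLength else
          max(2L * ltrLen + 1000L,
              round(stats::rnorm(1L, lt$elementLengthMean,
                                 lt$elementLengthSD)))
        ltr5 <- paste(.randBases(ltrLen, config$gc), collapse = "")
        substr(ltr5, 1L, 2L) <- "TG"
        substr(ltr5, ltrLen - 1L, ltrLen) <- "CA"
        ltr3 <- mutateSequence(ltr5, div[k])
        internal <- paste(.randBases(elemLen - 2L * ltrLen, config$gc),
                          collapse = "")
        block <- paste0(ltr5, internal, ltr3)
        pl <- .placeFeature(occ[[c]], L[c], nchar(block))
        occ[[c]] <- pl$occ
        writeBlock(c, pl$start, block)
        s <- pl$start
        truth[[length(truth) + 1L]] <- data.frame(
          type = "ltr_element", chrom = nms[c], start = s,
          end = s + elemLen - 1L, strand = "+",
          ltr5Start = s, ltr5End = s + ltrLen - 1L,
          ltr3Start = s + elemLen - ltrLen, ltr3End = s + elemLen - 1L,
          ltrLength = ltrLen, divergence = div[k],
          identity = 100 - div[k],
          oversized = k %in% oversized, stringsAsFactors = FALSE)
      }
    }
  }

  # stage 4: palindromic cassettes
  if (!is.null(config$cassettes)) {
    for (ci in seq_along(config$cassettes)) {
      cs <- config$cassettes[[ci]]
      c <- ((cs$chrom - 1L) %% nChrom) + 1L
      set.seed(.substream(seed, 400L + ci))
      total <- 2L * cs$armLength + cs$spacer
      pl <- .placeFeature(occ[[c]], L[c], total)
      occ[[c]] <- pl$occ
      tmp <- plantPalindromicCassette(
        paste(rep("A", total), collapse = ""), 1L, cs$armLength,
        cs$spacer, cs$armDivergence, nMembers = cs$nMembers,
        chrom = nms[c])
      writeBlock(c, pl$start, tmp$seq)
      tr <- tmp$truth
      shift <- pl$start - 1L
      for (f in c("start", "end", "arm1Start", "arm1End", "arm2Start",
                  "arm2End"))
        if (f %in% names(tr)) tr[[f]] <- tr[[f]] + shift
      truth[[length(truth) + 1L]] <- tr
    }
  }

  # stage 5: bridge gene pairs with intergenic splice junctions
  if (!is.null(config$bridges) && config$bridges$n > 0L) {
    br <- config$bridges
    set.seed(.substream(seed, 500L))
    chroms <- rep_len(seq_len(nChrom), br$n)
    for (i in seq_len(br$n)) {
      c <- chroms[i]
      set.seed(.substream(seed, 500L + i))
      spacer <- sample(seq(br$spacerRange[1L], br$spacerRange[2L]), 1L)
      blockLen <- 2L * br$geneLength + spacer
      pl <- .placeFeature(occ[[c]], L[c], blockLen)
      occ[[c]] <- pl$occ
      s <- pl$start
      aEnd <- s + br$geneLength - 1L
      bStart <- aEnd + spacer + 1L
      gA <- sprintf("brgA_%02d", i); gB <- sprintf("brgB_%02d", i)
      exonRows[[length(exonRows) + 1L]] <- data.frame(
        chrom = nms[c], start = s, end = aEnd, strand = "+",
        tx = paste0(gA, ".t1"), gene = gA, stringsAsFactors = FALSE)
      exonRows[[length(exonRows) + 1L]] <- data.frame(
        chrom = nms[c], start = bStart, end = bStart + br$geneLength - 1L,
        strand = "+", tx = paste0(gB, ".t1"), gene = gB,
        stringsAsFactors = FALSE)
      sjRows[[length(sjRows) + 1L]] <- data.frame(
        chrom = nms[c], start = aEnd + 1L, end = bStart - 1L,
        strand = "+", motif = 1L, annotated = 0L,
        unique = stats::rpois(1L, 25L) + 5L, multi = 0L, overhang = 40L,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "bridge_junction", chrom = nms[c], start = aEnd + 1L,
        end = bStart - 1L, strand = "+", upstreamGene = gA,
        downstreamGene = gB, spacer = spacer, stringsAsFactors = FALSE)
    }
  }

  # stage 6: genes (multi-exon intron-bearing + single-exon)
  if (!is.null(config$genes) &&
      (config$genes$nIntronGenes > 0L ||
       config$genes$nSingleExonGenes > 0L)) {
    gn <- config$genes
    set.seed(.substream(seed, 600L))
    nTot <- gn$nIntronGenes + gn$nSingleExonGenes
    isIntronGene <- sample(rep(c(TRUE, FALSE),
                               c(gn$nIntronGenes, gn$nSingleExonGenes)))
    geneChrom <- sample(seq_len(nChrom), nTot, replace = TRUE,
                        prob = L / sum(L))
    rlen <- function(n, meanLog, sdLog, range) {
      pmin(range[2L], pmax(range[1L],
                           round(stats::rlnorm(n, meanLog, sdLog))))
    }
    gid <- 0L
    for (c in seq_len(nChrom)) {
      idx <- which(geneChrom == c)
      if (length(idx) == 0L) next
      set.seed(.substream(seed, 600L + c))
      specs <- lapply(idx, function(i) {
        nIntrons <- if (isIntronGene[i])
          1L + stats::rpois(1L, gn$intronsPerGeneExtra) else 0L
        exLens <- rlen(nIntrons + 1L, gn$exonMeanLog, gn$exonSdLog,
                       gn$exonRange)
        inLens <- if (nIntrons > 0L)
          rlen(nIntrons, gn$intronMeanLog, gn$intronSdLog,
               gn$intronRange) else integer(0)
        list(exLens = exLens, inLens = inLens,
             strand = sample(c("+", "-"), 1L),
             canonical = if (nIntrons > 0L)
               stats::runif(nIntrons) < gn$canonicalFraction
             else logical(0))
      })
      lens <- vapply(specs, function(sp)
        sum(sp$exLens) + sum(sp$inLens), numeric(1))
      starts <- .fillGaps(occ[[c]], L[c], as.integer(lens))
      for (q in seq_along(idx)) {
        gid <- gid + 1L
        sp <- specs[[q]]
        gs <- starts[q]
        glen <- as.integer(lens[q])
        # build the gene in transcript orientation
        pieces <- character(0)
        exIv <- matrix(0L, nrow = length(sp$exLens), ncol = 2L)
        cursor <- 1L
        for (e in seq_along(sp$exLens)) {
          exIv[e, ] <- c(cursor, cursor + sp$exLens[e] - 1L)
          pieces <- c(pieces, paste(.randBases(sp$exLens[e], config$gc),
                                    collapse = ""))
          cursor <- cursor + sp$exLens[e]
          if (e <= length(sp$inLens)) {
            il <- sp$inLens[e]
            inner <- paste(.randBases(il - 4L, config$gc), collapse = "")
            ends <- if (sp$canonical[e]) c("GT", "AG") else c("GC", "AG")
            pieces <- c(pieces, paste0(ends[1L], inner, ends[2L]))
            cursor <- cursor + il
          }
        }
        block <- paste(pieces, collapse = "")
        strand <- sp$strand
        if (strand == "-") {
          block <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(block)))
          exIv <- cbind(glen - exIv[, 2L] + 1L, glen - exIv[, 1L] + 1L)
          exIv <- exIv[rev(seq_len(nrow(exIv))), , drop = FALSE]
        }
        writeBlock(c, gs, block)
        gname <- sprintf("g%05d", gid)
        txname <- paste0(gname, ".t1")
        exonRows[[length(exonRows) + 1L]] <- data.frame(
          chrom = nms[c], start = gs + exIv[, 1L] - 1L,
          end = gs + exIv[, 2L] - 1L, strand = strand, tx = txname,
          gene = gname, stringsAsFactors = FALSE)
        if (length(sp$inLens) > 0L) {
          # intron genomic intervals from consecutive exons
          exSorted <- exIv[order(exIv[, 1L]), , drop = FALSE]
          is0 <- gs + exSorted[-nrow(exSorted), 2L]
          ie0 <- gs + exSorted[-1L, 1L] - 2L
          canon <- sp$canonical
          if (strand == "-") canon <- rev(canon)
          for (j in seq_along(is0)) {
            truth[[length(truth) + 1L]] <- data.frame(
              type = "intron", chrom = nms[c], start = is0[j],
              end = ie0[j], strand = strand, gene = gname,
              canonical = canon[j],
              donor = if (canon[j]) "GT" else "GC",
              acceptor = "AG", stringsAsFactors = FALSE)
            if (stats::runif(1L) < gn$sjFraction) {
              sjRows[[length(sjRows) + 1L]] <- data.frame(
                chrom = nms[c], start = is0[j], end = ie0[j],
                strand = strand, motif = if (canon[j]) 1L else 0L,
                annotated = 1L, unique = stats::rpois(1L, 20L) + 1L,
                multi = 0L, overhang = 35L, stringsAsFactors = FALSE)
            }
          }
        }
        truth[[length(truth) + 1L]] <- data.frame(
          type = "gene", chrom = nms[c], start = gs,
          end = gs + glen - 1L, strand = strand, gene = gname,
          nExons = nrow(exIv), stringsAsFactors = FALSE)
      }
    }
  }

  # assemble outputs
  seqs <- Biostrings::DNAStringSet(vapply(chromVecs, paste,
                                          character(1), collapse = ""))
  names(seqs) <- nms
  assembly <- GenomeAssembly(seqs)

  models <- GenomicRanges::GRangesList()
  if (length(exonRows) > 0L) {
    ed <- data.table::rbindlist(exonRows)
    gr <- GenomicRanges::GRanges(ed$chrom,
                                 IRanges::IRanges(ed$start, ed$end),
                                 strand = ed$strand)
    grl <- S4Vectors::split(gr, ed$tx)
    geneOfTx <- vapply(split(ed$gene, ed$tx), `[`, character(1), 1L)
    models <- geneModels(grl, geneOfTx[names(grl)])
  }

  junctions <- GenomicRanges::GRanges()
  if (length(sjRows) > 0L) {
    sj <- data.table::rbindlist(sjRows)
    o <- order(sj$chrom, sj$start)
    sj <- sj[o, ]
    junctions <- GenomicRanges::GRanges(
      sj$chrom, IRanges::IRanges(sj$start, sj$end), strand = sj$strand,
      motifCode = sj$motif, annotated = sj$annotated > 0L,
      uniqueReads = sj$unique, multiReads = sj$multi,
      maxOverhang = sj$overhang)
    junctions$supported <- junctions$uniqueReads +
      junctions$multiReads > 0L
  }

  truthDf <- if (length(truth) > 0L)
    as.data.frame(data.table::rbindlist(truth, fill = TRUE))
  else data.frame(type = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0))
  if (nrow(truthDf) > 0L)
    truthDf <- truthDf[order(truthDf$type, truthDf$chrom, truthDf$start),
                       , drop = FALSE]
  rownames(truthDf) <- NULL

  structure(list(assembly = assembly, models = models,
                 junctions = junctions, truth = truthDf,
                 config = config),
            class = "simulated_genome")
}

#' Write a simulated genome to disk
#'
#' Emits FASTA, GFF3, SJ.out.tab and a truth TSV into `dir`; all writers
#' are deterministic, so the same seed yields byte-identical files.
#'
#' @param sim output of [generateGenome()].
#' @param dir output directory (created if missing).
#' @return named character vector of the four paths, invisibly.
#' @export
writeSimulatedGenome <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "annotation.gff3"),
             sj = file.path(dir, "SJ.out.tab"),
             truth = file.path(dir, "truth.tsv"))
  writeGenome(sim$assembly, paths[["fasta"]])
  if (length(sim$models) > 0L)
    writeAnnotation(sim$models, paths[["gff3"]], dialect = "gff3")
  else writeLines("##gff-version 3", paths[["gff3"]])
  writeSpliceJunctions(sim$junctions, paths[["sj"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
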