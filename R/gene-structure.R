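#' Extract introns from gene models
#'
#' Introns are the gaps between consecutive exons of each transcript.
#' Donor and acceptor dinucleotides are read from the genome strand-aware:
#' on the minus strand the genomic slice is reverse-complemented before the
#' terminal dinucleotides are taken, so a canonical intron reads GT...AG in
#' transcription orientation on either strand. Introns with identical
#' coordinates across transcripts of the same gene are deduplicated.
#'
#' @param models gene models as documented in [geneModels()].
#' @param assembly a [GenomeAssembly-class].
#' @return a [GenomicRanges::GRanges] of introns with metadata columns
#'   `gene_id`, `transcript_id`, `donor`, `acceptor`, `length` and
#'   `canonical` (donor "GT" and acceptor "AG").
#' @export
extractIntrons <- function(models, assembly) {
  geneIds <- S4Vectors::mcols(models)$gene_id
  lens <- chromLengths(assembly)
  u <- BiocGenerics::unlist(models, use.names = FALSE)
  grp <- rep(seq_along(models), lengths(models))
  o <- order(grp, BiocGenerics::start(u))
  u <- u[o]; grp <- grp[o]
  chromU <- as.character(GenomicRanges::seqnames(u))
  st <- BiocGenerics::start(u); en <- BiocGenerics::end(u)
  oob <- st < 1L | en > lens[chromU]
  if (any(oob))
    stop("annotation error: exon outside chromosome bounds in ",
         names(models)[grp[which(oob)[1L]]])
  idx <- which(diff(grp) == 0L)
  if (length(idx)) {
    bad <- idx[st[idx + 1L] <= en[idx]]
    if (length(bad))
      stop("annotation error: overlapping exons in transcript ",
           names(models)[grp[bad[1L]]])
  }
  if (length(idx) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = character(0), transcript_id = character(0),
      donor = character(0), acceptor = character(0),
      length = integer(0), canonical = logical(0))
    return(gr)
  }
  ti <- grp[idx]
  df <- data.frame(chrom = chromU[idx], start = en[idx] + 1L,
                   end = st[idx + 1L] - 1L,
                   strand = as.character(BiocGenerics::strand(u))[idx],
                   gene_id = geneIds[ti],
                   transcript_id = names(models)[ti],
                   stringsAsFactors = FALSE)
  df <- df[df$end >= df$start, , drop = FALSE]
  # deduplicate identical intron coordinates within a gene
  key <- paste(df$gene_id, df$chrom, df$start, df$end)
  df <- df[!duplicated(key), , drop = FALSE]
  donor <- acceptor <- character(nrow(df))
  for (j in seq_len(nrow(df))) {
    sl <- Biostrings::subseq(assembly[[df$chrom[j]]], df$start[j],
                             df$end[j])
    if (df$strand[j] == "-") sl <- Biostrings::reverseComplement(sl)
    sc <- as.character(sl)
    donor[j] <- substr(sc, 1L, 2L)
    acceptor[j] <- substr(sc, nchar(sc) - 1L, nchar(sc))
  }
  o <- order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = df$gene_id, transcript_id = df$transcript_id,
    donor = donor[o], acceptor = acceptor[o],
    length = df$end[o] - df$start[o] + 1L,
    canonical = donor[o] == "GT" & acceptor[o] == "AG")
  gr
}

#' Validate splice sites against the canonical GT-AG consensus
#'
#' @param introns output of [extractIntrons()].
#' @return list with `percentCanonical` (1 decimal) and `motifTally`, a
#'   table of donor-acceptor motif pairs.
#' @export
validateSpliceSites <- function(introns) {
  if (length(introns) == 0L)
    stop("domain error: no introns to validate")
  canon <- S4Vectors::mcols(introns)$canonical
  motifs <- paste(S4Vectors::mcols(introns)$donor,
                  S4Vectors::mcols(introns)$acceptor, sep = "-")
  list(percentCanonical = round(mean(canon) * 100, 1),
       motifTally = sort(table(motifs), decreasing = TRUE))
}

#' Intron summary statistics
#'
#' @param introns output of [extractIntrons()].
#' @param nGenes total number of genes in the annotation, used as the
#'   denominator of the intron-containing-gene percentage.
#' @return list with `count`, `meanLength`, `medianLength`, `minLength`,
#'   `maxLength`, `intronsPerGene`, `nIntronGenes` and
#'   `percentIntronGenes` (1 decimal). With zero introns the moments are
#'   `NA`.
#' @export
intronStats <- function(introns, nGenes) {
  stopifnot(nGenes >= 1)
  n <- length(introns)
  if (n == 0L)
    return(list(count = 0L, meanLength = NA_real_,
                medianLength = NA_real_, minLength = NA_integer_,
                maxLength = NA_integer_, intronsPerGene = 0,
                nIntronGenes = 0L, percentIntronGenes = 0))
  len <- S4Vectors::mcols(introns)$length
  ng <- length(unique(S4Vectors::mcols(introns)$gene_id))
  list(count = n,
       meanLength = round(mean(len), 1),
       medianLength = stats::median(len),
       minLength = min(len),
       maxLength = max(len),
       intronsPerGene = round(n / nGenes, 2),
       nIntronGenes = ng,
       percentIntronGenes = round(ng / nGenes * 100, 1))
}

#' Classify splice junctions as intragenic or intergenic bridges
#'
#' A junction fully inside a single gene span is `intragenic`. A junction
#' whose start lies within `tolerance` bp after one gene's 3' genomic
#' boundary and whose end lies within `tolerance` bp before the next
#' gene's 5' genomic boundary — two distinct genes on the same strand — is
#' an `intergenic_bridge`, the signature of co-transcription with the
#' intergenic spacer excised as an intron. Everything else (including
#' junctions below the read-support cutoff and junctions on chromosomes
#' absent from the annotation) is `unassigned`.
#'
#' @param junctions a `GRanges` as from [readSpliceJunctions()].
#' @param models gene models as documented in [geneModels()].
#' @param tolerance anchor tolerance in bp (default 50).
#' @param minUniqueReads minimum unique-read support for bridge calling
#'   (default 1).
#' @return a data.frame with one row per junction: `chrom`, `start`,
#'   `end`, `class`, `upstreamGene`, `downstreamGene`, `offset5`,
#'   `offset3`. Classes partition the input.
#' @export
classifyJunctions <- function(junctions, models, tolerance = 50L,
                              minUniqueReads = 1L) {
  geneIds <- S4Vectors::mcols(models)$gene_id
  u <- BiocGenerics::unlist(models, use.names = FALSE)
  grp <- rep(seq_along(models), lengths(models))
  ed <- data.table::data.table(
    gene = geneIds[grp],
    chrom = as.character(GenomicRanges::seqnames(u)),
    start = BiocGenerics::start(u),
    end = BiocGenerics::end(u),
    strand = as.character(BiocGenerics::strand(u)))
  # collapse exons (and multiple transcripts) to one span per gene
  spans <- as.data.frame(ed[, list(chrom = chrom[1L],
                                   start = min(start), end = max(end),
                                   strand = strand[1L]), by = "gene"])
  out <- lapply(seq_along(junctions), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(junctions))[i]
    js <- BiocGenerics::start(junctions)[i]
    je <- BiocGenerics::end(junctions)[i]
    row <- data.frame(chrom = chrom, start = js, end = je,
                      class = "unassigned",
                      upstreamGene = NA_character_,
                      downstreamGene = NA_character_,
                      offset5 = NA_real_, offset3 = NA_real_)
    ur <- junctions$uniqueReads[i]
    if (!is.null(ur) && !is.na(ur) && ur < minUniqueReads) return(row)
    g <- spans[spans$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0L) {
      warning("junction chromosome ", chrom, " absent from annotation")
      return(row)
    }
    inside <- which(js >= g$start & je <= g$end)
    if (length(inside) > 0L) {
      row$class <- "intragenic"
      row$upstreamGene <- row$downstreamGene <- g$gene[inside[1L]]
      return(row)
    }
    up <- g[g$end < js, , drop = FALSE]
    dn <- g[g$start > je, , drop = FALSE]
    if (nrow(up) && nrow(dn)) {
      a <- up[which.max(up$end), ]
      b <- dn[which.min(dn$start), ]
      o5 <- js - a$end - 1L
      o3 <- b$start - je - 1L
      if (a$gene != b$gene && a$strand == b$strand &&
          o5 <= tolerance && o3 <= tolerance) {
        row$class <- "intergenic_bridge"
        row$upstreamGene <- a$gene
        row$downstreamGene <- b$gene
        row$offset5 <- o5
        row$offset3 <- o3
      }
    }
    row
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Spatial context of a cassette relative to centromeres and telomeres
#'
#' Distance to the nearest centromere core is 0 when the cassette overlaps
#' a core; telomere distance is the smaller of the distances to either
#' chromosome end. Zones: `centromere_embedded` (core distance 0),
#' `pericentromeric` (0 < distance <= `periThreshold`), `euchromatic`
#' otherwise.
#'
#' @param cassette a length-1 `GRanges` (or `c(start, end)` with `chrom`).
#' @param cores `GRanges` of centromere cores.
#' @param chromLength chromosome length in bp.
#' @param periThreshold pericentromeric buffer in bp (default 16000).
#' @param chrom chromosome id when `cassette` is numeric.
#' @return list with `coreDistance`, `telomereDistance`, `zone`, `note`.
#' @export
spatialContext <- function(cassette, cores, chromLength,
                           periThreshold = 16000L, chrom = NULL) {
  if (is.numeric(cassette)) {
    stopifnot(!is.null(chrom))
    cassette <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(cassette[1L], cassette[2L]))
  }
  chrom <- as.character(GenomicRanges::seqnames(cassette))[1L]
  cs <- BiocGenerics::start(cassette)[1L]
  ce <- BiocGenerics::end(cassette)[1L]
  stopifnot(cs >= 1, ce <= chromLength)
  telo <- min(cs - 1L, chromLength - ce)
  cc <- cores
  if (length(cc))
    cc <- cc[as.character(GenomicRanges::seqnames(cc)) == chrom]
  if (length(cc) == 0L)
    return(list(coreDistance = NA_real_, telomereDistance = telo,
                zone = "euchromatic",
                note = "no centromere core on chromosome"))
  gaps <- vapply(seq_along(cc), function(i) {
    intervalGap(cassette, cc[i])
  }, numeric(1))
  overlap <- vapply(seq_along(cc), function(i) {
    cs <= BiocGenerics::end(cc)[i] && ce >= BiocGenerics::start(cc)[i]
  }, logical(1))
  d <- if (any(overlap)) 0 else min(gaps)
  zone <- if (d == 0) "centromere_embedded"
    else if (d <= periThreshold) "pericentromeric"
    else "euchromatic"
  list(coreDistance = d, telomereDistance = telo, zone = zone, note = "")
}
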