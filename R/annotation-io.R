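#' Gene models as a GRangesList of exons per transcript
#'
#' The package represents gene models as a [GenomicRanges::GRangesList]
#' whose elements are the ordered exons of one transcript (1-based inclusive
#' coordinates, sorted by start, non-overlapping) and whose names are the
#' transcript ids; `mcols(models)$gene_id` carries the parent gene of each
#' transcript.
#'
#' @param exons a [GenomicRanges::GRangesList] of exons per transcript
#'   (names = transcript ids).
#' @param geneIds character vector of gene ids, parallel to `exons`.
#' @return the validated `GRangesList` with `gene_id` metadata column.
#' @export
geneModels <- function(exons, geneIds) {
  stopifnot(methods::is(exons, "GRangesList"),
            length(geneIds) == length(exons),
            !is.null(names(exons)))
  if (any(lengths(exons) < 1L))
    stop("transcript ", names(exons)[lengths(exons) < 1L][1L],
         " has no exons")
  u <- BiocGenerics::unlist(exons, use.names = FALSE)
  grp <- rep(seq_along(exons), lengths(exons))
  o <- order(grp, BiocGenerics::start(u))
  u <- u[o]
  exons <- methods::as(BiocGenerics::relist(u, exons), "GRangesList")
  idx <- which(diff(grp) == 0L)
  if (length(idx)) {
    bad <- idx[BiocGenerics::start(u)[idx + 1L] <=
                 BiocGenerics::end(u)[idx]]
    if (length(bad))
      stop("annotation error: overlapping exons in transcript ",
           names(exons)[grp[bad[1L]]])
  }
  S4Vectors::mcols(exons)$gene_id <- as.character(geneIds)
  exons
}

#' Read gene models from GFF3 or GTF
#'
#' Parses exon features and groups them by transcript. Both attribute
#' dialects are supported; GFF3 exons must carry a `Parent` attribute and
#' GTF exons a `transcript_id`. Coordinates are kept 1-based inclusive.
#' Exons lacking transcript attribution, or rows with end < start, are
#' format errors.
#'
#' @param path path to the annotation file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return gene models as documented in [geneModels()], transcripts ordered
#'   by (chromosome, start).
#' @export
readAnnotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", comment.char = "#", quote = "",
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (!is.null(raw)) {
    if (ncol(raw) != 9L)
      stop("format error: expected 9 tab-separated columns, found ",
           ncol(raw))
    if (any(raw[[5]] < raw[[4]]))
      stop("format error: end < start at line ",
           which(raw[[5]] < raw[[4]])[1L])
  }
  gr <- tryCatch(rtracklayer::import(path, format = dialect),
                 error = function(e)
                   stop("format error reading ", path, ": ",
                        conditionMessage(e)))
  type <- tolower(as.character(gr$type))
  ex <- gr[type == "exon"]
  if (length(ex) == 0L)
    return(geneModels(GenomicRanges::GRangesList(), character(0)))
  if (dialect == "gff3") {
    parents <- ex$Parent
    if (is.null(parents) || any(lengths(parents) == 0L))
      stop("format error: exon without Parent (transcript) attribute")
    tx <- vapply(parents, function(p) as.character(p)[1L], character(1))
    txrows <- gr[type %in% c("mrna", "transcript")]
    geneOf <- character(0)
    if (length(txrows)) {
      gp <- vapply(txrows$Parent, function(p)
        if (length(p)) as.character(p)[1L] else NA_character_, character(1))
      geneOf <- stats::setNames(gp, as.character(txrows$ID))
    }
    gene <- geneOf[tx]
    gene[is.na(gene)] <- tx[is.na(gene)]
  } else {
    tx <- ex$transcript_id
    if (is.null(tx) || any(is.na(tx) | !nzchar(tx)))
      stop("format error: exon without transcript_id attribute")
    gene <- ex$gene_id
    if (is.null(gene)) gene <- tx
    gene[is.na(gene)] <- tx[is.na(gene)]
  }
  S4Vectors::mcols(ex) <- NULL
  grl <- S4Vectors::split(ex, tx)
  geneIds <- vapply(S4Vectors::split(gene, tx), `[`, character(1), 1L)
  # deterministic transcript order: (chromosome, start of first exon)
  firstChrom <- vapply(grl, function(g)
    as.character(GenomicRanges::seqnames(g))[1L], character(1))
  firstStart <- vapply(grl, function(g)
    min(BiocGenerics::start(g)), numeric(1))
  o <- order(firstChrom, firstStart, names(grl))
  geneModels(grl[o], geneIds[names(grl)[o]])
}

#' Write gene models to GFF3 or GTF
#'
#' Emits gene, transcript and exon features sorted by (chromosome, start).
#' Writing then re-reading with [readAnnotation()] reproduces the input
#' coordinates in either dialect.
#'
#' @param models gene models as documented in [geneModels()].
#' @param path output path.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(models, path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  geneIds <- S4Vectors::mcols(models)$gene_id
  txIds <- names(models)
  firstChrom <- vapply(models, function(g)
    as.character(GenomicRanges::seqnames(g))[1L], character(1))
  firstStart <- vapply(models, function(g)
    min(BiocGenerics::start(g)), numeric(1))
  o <- order(firstChrom, firstStart, txIds)
  rows <- list()
  for (i in o) {
    ex <- models[[i]]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
    str <- as.character(BiocGenerics::strand(ex))[1L]
    s <- min(BiocGenerics::start(ex)); e <- max(BiocGenerics::end(ex))
    if (dialect == "gff3") {
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\tchromArch\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
        chrom, s, e, str, geneIds[i])
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\tchromArch\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        chrom, s, e, str, txIds[i], geneIds[i])
      rows[[length(rows) + 1L]] <- paste(sprintf(
        "%s\tchromArch\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        chrom, BiocGenerics::start(ex), BiocGenerics::end(ex), str,
        txIds[i]), collapse = "\n")
    } else {
      attr0 <- sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                       geneIds[i], txIds[i])
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\tchromArch\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        chrom, s, e, str, attr0)
      rows[[length(rows) + 1L]] <- paste(sprintf(
        "%s\tchromArch\texon\t%d\t%d\t.\t%s\t.\t%s",
        chrom, BiocGenerics::start(ex), BiocGenerics::end(ex), str,
        attr0), collapse = "\n")
    }
  }
  header <- if (dialect == "gff3") "##gff-version 3" else
    "#!dialect gtf"
  writeLines(c(header, unlist(rows)), path)
  invisible(path)
}

#' Read STAR splice junctions (SJ.out.tab)
#'
#' Parses the 9-column tab format emitted by the STAR aligner: chromosome,
#' intron start (1-based), intron end (inclusive), strand code (0 =
#' undefined, 1 = +, 2 = -), intron motif code, annotated flag, unique
#' reads, multi-mapping reads, maximum overhang. Rows with zero unique and
#' zero multi reads are retained but flagged `supported = FALSE`.
#'
#' @param path path to an SJ.out.tab file.
#' @return a [GenomicRanges::GRanges] of excised introns with metadata
#'   columns `motifCode`, `annotated`, `uniqueReads`, `multiReads`,
#'   `maxOverhang`, `supported`. An empty file yields an empty `GRanges`.
#' @export
readSpliceJunctions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      motifCode = integer(0), annotated = logical(0),
      uniqueReads = integer(0), multiReads = integer(0),
      maxOverhang = integer(0), supported = logical(0))
    return(gr)
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) != 9L)
    stop("format error: SJ.out.tab requires 9 columns, found ", ncol(df))
  strand <- c(`0` = "*", `1` = "+", `2` = "-")[as.character(df[[4]])]
  if (any(is.na(strand)))
    stop("format error: invalid strand code ",
         df[[4]][is.na(strand)][1L])
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]], end = df[[3]]),
    strand = strand,
    motifCode = as.integer(df[[5]]),
    annotated = as.integer(df[[6]]) > 0L,
    uniqueReads = as.integer(df[[7]]),
    multiReads = as.integer(df[[8]]),
    maxOverhang = as.integer(df[[9]]))
  gr$supported <- gr$uniqueReads + gr$multiReads > 0L
  gr
}

#' Write splice junctions in STAR SJ.out.tab format
#'
#' @param junctions a `GRanges` as returned by [readSpliceJunctions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpliceJunctions <- function(junctions, path) {
  code <- c(`*` = 0L, `+` = 1L, `-` = 2L)
  o <- order(as.character(GenomicRanges::seqnames(junctions)),
             BiocGenerics::start(junctions))
  junctions <- junctions[o]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(junctions)),
    start = BiocGenerics::start(junctions),
    end = BiocGenerics::end(junctions),
    strand = code[as.character(BiocGenerics::strand(junctions))],
    motif = junctions$motifCode,
    annotated = as.integer(junctions$annotated),
    unique = junctions$uniqueReads,
    multi = junctions$multiReads,
    overhang = junctions$maxOverhang)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export intervals as BED6
#'
#' Converts 1-based inclusive `GRanges` to the 0-based half-open BED
#' convention at the boundary; rows are sorted by (chromosome, start).
#'
#' @param gr a `GRanges`; names (or `gr$name`) populate the BED name field.
#' @param path output path.
#' @param scores optional numeric scores (default 0).
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, scores = NULL) {
  nm <- if (!is.null(gr$name)) gr$name
        else if (!is.null(names(gr))) names(gr)
        else rep(".", length(gr))
  sc <- if (is.null(scores)) rep(0, length(gr)) else scores
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = nm, score = sc,
    strand = as.character(BiocGenerics::strand(gr)))[o, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
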