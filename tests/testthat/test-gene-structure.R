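# build a one-chromosome assembly + models with fully specified introns
intronFixture <- function(motifs, intronLens = NULL, seed = 71) {
  set.seed(seed)
  nIntrons <- length(motifs)
  if (is.null(intronLens)) intronLens <- rep(100L, nIntrons)
  exonLen <- 80L
  v <- character(0)
  exStarts <- exEnds <- integer(0)
  cursor <- 101L
  v <- strsplit(randomDNA(100), "")[[1]]
  for (i in seq_len(nIntrons + 1L)) {
    exStarts <- c(exStarts, cursor)
    exEnds <- c(exEnds, cursor + exonLen - 1L)
    v <- c(v, strsplit(randomDNA(exonLen), "")[[1]])
    cursor <- cursor + exonLen
    if (i <= nIntrons) {
      donor <- substr(motifs[i], 1, 2)
      acceptor <- substr(motifs[i], 4, 5)
      mid <- randomDNA(intronLens[i] - 4L)
      v <- c(v, strsplit(paste0(donor, mid, acceptor), "")[[1]])
      cursor <- cursor + intronLens[i]
    }
  }
  v <- c(v, strsplit(randomDNA(100), "")[[1]])
  asm <- GenomeAssembly(c(c1 = paste(v, collapse = "")))
  models <- geneModels(
    GenomicRanges::GRangesList(
      tx1 = GenomicRanges::GRanges("c1",
        IRanges::IRanges(exStarts, exEnds), strand = "+")),
    "gene1")
  list(assembly = asm, models = models)
}

test_that("introns are extracted with strand-aware terminal dinucleotides", {
  fx <- intronFixture(c("GT-AG", "GT-AG"))
  introns <- extractIntrons(fx$models, fx$assembly)
  expect_equal(length(introns), 2L)
  expect_equal(BiocGenerics::start(introns), c(181L, 361L))
  expect_equal(introns$donor, c("GT", "GT"))
  expect_equal(introns$acceptor, c("AG", "AG"))
  expect_true(all(introns$canonical))
  expect_equal(introns$length, c(100L, 100L))

  # minus-strand mirror of the same gene: reverse-complement the
  # chromosome and flip the exon coordinates
  n <- chromLengths(fx$assembly)[["c1"]]
  rcAsm <- GenomeAssembly(c(c1 = as.character(
    Biostrings::reverseComplement(genomeSeqs(fx$assembly)[["c1"]]))))
  ex <- fx$models[["tx1"]]
  flipped <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(n - BiocGenerics::end(ex) + 1L,
                     n - BiocGenerics::start(ex) + 1L), strand = "-")
  mm <- geneModels(GenomicRanges::GRangesList(tx1 = flipped), "gene1")
  intronsRC <- extractIntrons(mm, rcAsm)
  expect_equal(length(intronsRC), 2L)
  expect_true(all(intronsRC$canonical))
  expect_equal(sort(intronsRC$length), sort(introns$length))

  # single-exon gene: no introns
  single <- geneModels(GenomicRanges::GRangesList(
    s1 = GenomicRanges::GRanges("c1", IRanges::IRanges(1, 50),
                                strand = "+")), "gS")
  expect_length(extractIntrons(single, fx$assembly), 0L)

  # overlapping exons are an annotation error naming the transcript
  expect_error(geneModels(GenomicRanges::GRangesList(
    bad = GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 50),
                                                        c(100, 150)),
                                 strand = "+")), "gB"),
    "overlapping exons in transcript bad")
})

test_that("splice-site validation tallies canonical and deviant motifs", {
  fx <- intronFixture(c(rep("GT-AG", 9), "GC-AG"))
  introns <- extractIntrons(fx$models, fx$assembly)
  v <- validateSpliceSites(introns)
  expect_equal(v$percentCanonical, 90)
  expect_equal(unname(v$motifTally[["GC-AG"]]), 1L)
  expect_equal(unname(v$motifTally[["GT-AG"]]), 9L)

  fx0 <- intronFixture(c("CT-AC", "GC-TG"))
  expect_equal(
    validateSpliceSites(extractIntrons(fx0$models,
                                       fx0$assembly))$percentCanonical, 0)
  expect_error(validateSpliceSites(GenomicRanges::GRanges()),
               "domain error")
})

test_that("intron statistics match hand computations", {
  fx <- intronFixture(rep("GT-AG", 3), intronLens = c(40L, 100L, 160L))
  introns <- extractIntrons(fx$models, fx$assembly)
  st <- intronStats(introns, nGenes = 10)
  expect_equal(st$count, 3L)
  expect_equal(st$meanLength, 100)
  expect_equal(st$medianLength, 100)
  expect_equal(st$minLength, 40L)
  expect_equal(st$maxLength, 160L)
  expect_equal(st$percentIntronGenes, 10)  # 1 of 10 genes

  # the published gene-level fraction: 708 intron-bearing of 5,428 genes
  mock <- GenomicRanges::GRanges("c1", IRanges::IRanges(1:708 * 1000,
                                                        1:708 * 1000 + 99))
  S4Vectors::mcols(mock) <- S4Vectors::DataFrame(
    gene_id = sprintf("g%d", 1:708), transcript_id = sprintf("t%d", 1:708),
    donor = "GT", acceptor = "AG", length = 100L, canonical = TRUE)
  expect_equal(intronStats(mock, nGenes = 5428)$percentIntronGenes, 13)

  one <- intronFixture("GT-AG", intronLens = 113L)
  st1 <- intronStats(extractIntrons(one$models, one$assembly), nGenes = 1)
  expect_equal(st1$meanLength, 113)
  expect_equal(st1$medianLength, 113)
  expect_equal(st1$minLength, 113L)
})

test_that("junction classification separates bridges from intragenic splicing", {
  models <- geneModels(GenomicRanges::GRangesList(
    tA = GenomicRanges::GRanges("c1", IRanges::IRanges(c(1000, 1500),
                                                       c(1200, 2000)),
                                strand = "+"),
    tB = GenomicRanges::GRanges("c1", IRanges::IRanges(2221, 3000),
                                strand = "+"),
    tC = GenomicRanges::GRanges("c1", IRanges::IRanges(9000, 9500),
                                strand = "+")), c("gA", "gB", "gC"))
  jx <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(1201, 2001, 4000, 2001),
                     c(1499, 2220, 4200, 2220)),
    strand = "+",
    uniqueReads = c(15L, 22L, 8L, 0L))
  calls <- classifyJunctions(jx, models)
  expect_equal(calls$class,
               c("intragenic", "intergenic_bridge", "unassigned",
                 "unassigned"))
  # exact anchors: offsets (0, 0)
  expect_equal(calls$offset5[2], 0)
  expect_equal(calls$offset3[2], 0)
  expect_equal(calls$upstreamGene[2], "gA")
  expect_equal(calls$downstreamGene[2], "gB")
  # classification partitions the input
  expect_equal(nrow(calls), length(jx))

  # anchors beyond tolerance are not bridges
  far <- GenomicRanges::GRanges("c1", IRanges::IRanges(2151, 2300),
                                strand = "+", uniqueReads = 9L)
  expect_equal(classifyJunctions(far, models, tolerance = 100)$class,
               "unassigned")
  expect_equal(classifyJunctions(far, models, tolerance = 200)$class,
               "unassigned")  # still overlaps gB, not between the genes

  # unknown chromosome: unassigned with a warning
  alien <- GenomicRanges::GRanges("c9", IRanges::IRanges(10, 20),
                                  strand = "+", uniqueReads = 4L)
  expect_warning(cal <- classifyJunctions(alien, models), "absent")
  expect_equal(cal$class, "unassigned")
})

test_that("bridge recovery on the simulated genome is exact", {
  sim <- smallSim()
  calls <- classifyJunctions(sim$junctions, sim$models)
  expect_equal(nrow(calls), length(sim$junctions))
  tr <- sim$truth[sim$truth$type == "bridge_junction", ]
  bridges <- calls[calls$class == "intergenic_bridge", ]
  expect_equal(nrow(bridges), nrow(tr))   # no false bridges
  expect_setequal(paste(bridges$chrom, bridges$start, bridges$end),
                  paste(tr$chrom, tr$start, tr$end))
  expect_true(all(bridges$offset5 == 0 & bridges$offset3 == 0))
})

test_that("spatial context zones follow the distance thresholds", {
  cores <- GenomicRanges::GRanges("c1", IRanges::IRanges(100000, 130000))
  ctx <- function(s, e) spatialContext(c(s, e), cores,
                                       chromLength = 1e6, chrom = "c1")
  expect_equal(ctx(125000, 126000)$zone, "centromere_embedded")
  expect_equal(ctx(125000, 126000)$coreDistance, 0)
  over <- ctx(133201, 134000)           # 3,200 bp from the core
  expect_equal(over$coreDistance, 3200)
  expect_equal(over$zone, "pericentromeric")
  farCtx <- ctx(150001, 151000)         # 20,000 bp away
  expect_equal(farCtx$coreDistance, 20000)
  expect_equal(farCtx$zone, "euchromatic")
  expect_equal(farCtx$telomereDistance, 150000)
  none <- spatialContext(c(10, 20), GenomicRanges::GRanges(),
                         chromLength = 1e6, chrom = "c1")
  expect_true(is.na(none$coreDistance))
  expect_match(none$note, "no centromere")
})

test_that("intron statistics are invariant under strand mirroring", {
  sim <- smallSim()
  introns <- extractIntrons(sim$models, sim$assembly)
  v1 <- validateSpliceSites(introns)
  s1 <- intronStats(introns, nGenes = 140)

  lens <- chromLengths(sim$assembly)
  rcAsm <- GenomeAssembly(vapply(chromNames(sim$assembly), function(ch)
    as.character(Biostrings::reverseComplement(
      genomeSeqs(sim$assembly)[[ch]])), character(1)))
  u <- BiocGenerics::unlist(sim$models, use.names = FALSE)
  grp <- rep(seq_along(sim$models), lengths(sim$models))
  chromU <- as.character(GenomicRanges::seqnames(u))
  flipped <- GenomicRanges::GRanges(chromU,
    IRanges::IRanges(lens[chromU] - BiocGenerics::end(u) + 1L,
                     lens[chromU] - BiocGenerics::start(u) + 1L),
    strand = ifelse(as.character(BiocGenerics::strand(u)) == "+",
                    "-", "+"))
  mm <- geneModels(S4Vectors::split(flipped, names(sim$models)[grp]),
                   S4Vectors::mcols(sim$models)$gene_id[
                     match(sort(names(sim$models)), names(sim$models))])
  intronsRC <- extractIntrons(mm, rcAsm)
  expect_equal(validateSpliceSites(intronsRC)$percentCanonical,
               v1$percentCanonical)
  s2 <- intronStats(intronsRC, nGenes = 140)
  expect_equal(s2$count, s1$count)
  expect_equal(s2$meanLength, s1$meanLength)
  expect_equal(s2$medianLength, s1$medianLength)
  expect_equal(s2$minLength, s1$minLength)
  expect_equal(s2$maxLength, s1$maxLength)
})
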