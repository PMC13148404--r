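# shared fixtures, all built in code at test time

randomDNA <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a five-gene annotation fixture spanning both strands and 1-3 exons,
# used for dialect round-trips and intron extraction
fiveGeneFixture <- function() {
  gr <- function(chrom, starts, ends, strand)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                           strand = strand)
  exons <- GenomicRanges::GRangesList(
    t1.1 = gr("c1", c(101, 301), c(200, 400), "+"),
    t2.1 = gr("c1", 1001, 1500, "+"),
    t3.1 = gr("c1", c(2001, 2301, 2601), c(2100, 2400, 2700), "-"),
    t4.1 = gr("c2", c(501, 801), c(600, 900), "-"),
    t5.1 = gr("c2", 1501, 1600, "+"))
  geneModels(exons, c("g1", "g2", "g3", "g4", "g5"))
}

# an assembly hosting fiveGeneFixture with canonical GT-AG termini planted
# at every implied intron
fiveGeneAssembly <- function(seed = 11) {
  set.seed(seed)
  v1 <- strsplit(randomDNA(3000), "")[[1]]
  v2 <- strsplit(randomDNA(2000), "")[[1]]
  plantIntron <- function(v, s, e, strand) {
    if (strand == "+") {
      v[s:(s + 1)] <- c("G", "T"); v[(e - 1):e] <- c("A", "G")
    } else {
      v[s:(s + 1)] <- c("C", "T"); v[(e - 1):e] <- c("A", "C")
    }
    v
  }
  v1 <- plantIntron(v1, 201, 300, "+")
  v1 <- plantIntron(v1, 2101, 2300, "-")
  v1 <- plantIntron(v1, 2401, 2600, "-")
  v2 <- plantIntron(v2, 601, 800, "-")
  GenomeAssembly(c(c1 = paste(v1, collapse = ""),
                   c2 = paste(v2, collapse = "")))
}

# small simulated genome shared across tests (cached per session)
.fixtureCache <- new.env(parent = emptyenv())

smallSimConfig <- function(seed = 101L) {
  simConfig(
    chromLengths = c(cA = 450000, cB = 350000),
    centromeres = list(size = c(25000, 28000), at = 0.755,
                       satelliteUnit = c(61, 109),
                       satelliteFraction = 0.0124,
                       armRatio = c(2.4, 5.0)),
    ltr = list(countsPerChrom = c(4, 4), ltrLengthRange = c(200, 400),
               elementLengthMean = 5500, elementLengthSD = 700,
               nOversized = 1, oversizedLength = 11000,
               nIdentical = 2, divergenceMean = 2.5, divergenceMax = 15),
    genes = list(nIntronGenes = 60, nSingleExonGenes = 80,
                 intronsPerGeneExtra = 0.25,
                 intronMeanLog = log(113), intronSdLog = 0.65,
                 intronRange = c(37, 2318),
                 exonMeanLog = log(400), exonSdLog = 0.5,
                 exonRange = c(50, 3000),
                 canonicalFraction = 1.0, sjFraction = 0.8),
    bridges = list(n = 2, geneLength = 1000, spacerRange = c(189, 247)),
    cassettes = list(list(chrom = 1, armLength = 600, spacer = 300,
                          armDivergence = 0, nMembers = 2)),
    seed = seed)
}

smallSim <- function() {
  if (is.null(.fixtureCache$smallSim))
    .fixtureCache$smallSim <- generateGenome(smallSimConfig())
  .fixtureCache$smallSim
}

# full study-scale simulated genome for the acceptance checks
fullSim <- function() {
  if (is.null(.fixtureCache$fullSim))
    .fixtureCache$fullSim <- generateGenome(simConfig(seed = 1L))
  .fixtureCache$fullSim
}
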