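test_that("an empty configuration yields a bare background genome", {
  cfg <- simConfig(chromLengths = c(c1 = 50000), centromeres = NULL,
                   ltr = NULL, genes = NULL, bridges = NULL,
                   cassettes = NULL, seed = 81L)
  sim <- generateGenome(cfg)
  expect_equal(chromLengths(sim$assembly), c(c1 = 50000L))
  expect_equal(nrow(sim$truth), 0L)
  expect_length(sim$models, 0L)
  expect_length(sim$junctions, 0L)
  d <- withr::local_tempdir()
  paths <- writeSimulatedGenome(sim, d)
  expect_identical(readLines(paths[["gff3"]]), "##gff-version 3")
})

test_that("truth-table bookkeeping matches the configuration", {
  cfg <- smallSimConfig()
  sim <- smallSim()
  tab <- table(sim$truth$type)
  expect_equal(unname(tab[["centromere"]]), length(cfg$chromLengths))
  expect_equal(unname(tab[["satellite"]]), length(cfg$chromLengths))
  expect_equal(unname(tab[["ltr_element"]]),
               sum(cfg$ltr$countsPerChrom))
  expect_equal(unname(tab[["gene"]]),
               cfg$genes$nIntronGenes + cfg$genes$nSingleExonGenes)
  expect_equal(unname(tab[["bridge_junction"]]), cfg$bridges$n)
  expect_equal(unname(tab[["cassette_ir"]]), length(cfg$cassettes))
  # every truth interval lies inside its chromosome
  lens <- chromLengths(sim$assembly)
  expect_true(all(sim$truth$start >= 1))
  expect_true(all(sim$truth$end <= lens[sim$truth$chrom]))
  # the gene universe carries the configured number of intron genes
  nIntronGenes <- length(unique(
    sim$truth$gene[sim$truth$type == "intron"]))
  expect_equal(nIntronGenes, cfg$genes$nIntronGenes)
})

test_that("identical seeds give byte-identical outputs, new seeds differ", {
  cfg <- simConfig(chromLengths = c(c1 = 80000, c2 = 60000),
                   centromeres = list(size = 8000, at = 0.755,
                                      satelliteUnit = 61,
                                      satelliteFraction = 0.0124,
                                      armRatio = 3),
                   ltr = list(countsPerChrom = 1,
                              ltrLengthRange = c(200, 400),
                              elementLengthMean = 5000,
                              elementLengthSD = 300, nOversized = 0,
                              oversizedLength = 11000, nIdentical = 1,
                              divergenceMean = 2, divergenceMax = 10),
                   genes = list(nIntronGenes = 5, nSingleExonGenes = 5,
                                intronsPerGeneExtra = 0.25,
                                intronMeanLog = log(113),
                                intronSdLog = 0.65,
                                intronRange = c(37, 2318),
                                exonMeanLog = log(400), exonSdLog = 0.5,
                                exonRange = c(50, 3000),
                                canonicalFraction = 1, sjFraction = 1),
                   bridges = list(n = 1, geneLength = 800,
                                  spacerRange = c(189, 247)),
                   cassettes = list(list(chrom = 2, armLength = 300,
                                         spacer = 150, armDivergence = 0,
                                         nMembers = 0)),
                   seed = 91L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- writeSimulatedGenome(generateGenome(cfg), d1)
  p2 <- writeSimulatedGenome(generateGenome(cfg), d2)
  for (f in names(p1))
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])))
  cfg2 <- cfg; cfg2$seed <- 92L
  d3 <- withr::local_tempdir()
  p3 <- writeSimulatedGenome(generateGenome(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(p1[["fasta"]])),
                         unname(tools::md5sum(p3[["fasta"]]))))
})

test_that("mutateSequence places the exact substitution count", {
  expect_identical(mutateSequence("ACGTACGT", 0), "ACGTACGT")
  set.seed(93)
  x <- randomDNA(200)
  y <- mutateSequence(x, 0.5)    # exactly 1 substitution
  vx <- strsplit(x, "")[[1]]; vy <- strsplit(y, "")[[1]]
  expect_equal(sum(vx != vy), 1L)
  expect_equal(ltrPairIdentity(x, y), 99.5)
  # sampling check: mean identity at 2% divergence
  ids <- vapply(1:200, function(i) {
    z <- randomDNA(300)
    ltrPairIdentity(z, mutateSequence(z, 2))
  }, numeric(1))
  expect_gte(mean(ids), 97.9)
  expect_lte(mean(ids), 98.1)
  expect_error(mutateSequence("ACGT", 100), "domain error")
})

test_that("divergence-0 truth intervals slice back to planted sequences", {
  sim <- smallSim()
  tr <- sim$truth
  # identical LTR pairs: the 5' and 3' LTR slices are equal
  ltr0 <- tr[tr$type == "ltr_element" & tr$divergence == 0, ]
  expect_gte(nrow(ltr0), 1L)
  for (i in seq_len(nrow(ltr0))) {
    chromSeq <- sim$assembly[[ltr0$chrom[i]]]
    l5 <- as.character(Biostrings::subseq(chromSeq, ltr0$ltr5Start[i],
                                          ltr0$ltr5End[i]))
    l3 <- as.character(Biostrings::subseq(chromSeq, ltr0$ltr3Start[i],
                                          ltr0$ltr3End[i]))
    expect_identical(l5, l3)
  }
  # divergence-0 cassette: arm2 is exactly the reverse complement of arm1
  ir0 <- tr[tr$type == "cassette_ir" & tr$divergence == 0, ]
  for (i in seq_len(nrow(ir0))) {
    chromSeq <- sim$assembly[[ir0$chrom[i]]]
    a1 <- Biostrings::subseq(chromSeq, ir0$arm1Start[i], ir0$arm1End[i])
    a2 <- Biostrings::subseq(chromSeq, ir0$arm2Start[i], ir0$arm2End[i])
    expect_identical(as.character(Biostrings::reverseComplement(a1)),
                     as.character(a2))
  }
  # bridge spacer length equals the recorded junction span
  br <- tr[tr$type == "bridge_junction", ]
  expect_true(all(br$end - br$start + 1L == br$spacer))
  # planted intron termini match their recorded motifs
  introns <- extractIntrons(sim$models, sim$assembly)
  tin <- tr[tr$type == "intron", ]
  key <- paste(tin$chrom, tin$start, tin$end)
  found <- match(paste(as.character(GenomicRanges::seqnames(introns)),
                       BiocGenerics::start(introns),
                       BiocGenerics::end(introns)), key)
  expect_false(anyNA(found))
  expect_identical(introns$donor, tin$donor[found])
})

test_that("background composition is conserved outside planted islands", {
  sim <- smallSim()
  tr <- sim$truth[sim$truth$type == "centromere", ]
  gcs <- vapply(chromNames(sim$assembly), function(ch) {
    seq <- sim$assembly[[ch]]
    core <- tr[tr$chrom == ch, ]
    left <- Biostrings::subseq(seq, 1, core$start - 1)
    lf <- Biostrings::letterFrequency(left, c("A", "C", "G", "T"))
    unname((lf[["G"]] + lf[["C"]]) / sum(lf) * 100)
  }, numeric(1))
  # arms contain genes/LTRs drawn at the same GC, so the background holds
  expect_true(all(abs(gcs - 33.9) < 0.5))
})

test_that("infeasible configurations fail before any output is produced", {
  expect_error(simConfig(chromLengths = c(c1 = 10000),
                         centromeres = list(size = 20000, at = 0.75,
                                            satelliteUnit = 61,
                                            satelliteFraction = 0.01,
                                            armRatio = 3)),
               "config error")
  cfg <- simConfig(chromLengths = c(c1 = 30000), centromeres = NULL,
                   ltr = NULL, bridges = NULL, cassettes = NULL,
                   genes = list(nIntronGenes = 100,
                                nSingleExonGenes = 100,
                                intronsPerGeneExtra = 0.25,
                                intronMeanLog = log(113),
                                intronSdLog = 0.65,
                                intronRange = c(37, 2318),
                                exonMeanLog = log(400), exonSdLog = 0.5,
                                exonRange = c(50, 3000),
                                canonicalFraction = 1, sjFraction = 1),
                   seed = 94L)
  expect_error(generateGenome(cfg), "infeasible")
})
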