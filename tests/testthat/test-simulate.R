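# Generator contracts: determinism, structural guarantees, ground-truth
# ledgers and parameter recovery at small scale.

test_that("omega = 0 forbids nonsynonymous change", {
  sim <- simulateOrthologPairs(3, omega = 0, kappa = 2, t = 0.5,
                               nCodons = 80, seed = 1)
  aaA <- unname(as.character(Biostrings::translate(seqA(sim))))
  aaB <- unname(as.character(Biostrings::translate(seqB(sim))))
  expect_equal(aaA, aaB)
  # but synonymous change did occur at this divergence
  expect_false(all(as.character(seqA(sim)) == as.character(seqB(sim))))
})

test_that("zero branch length leaves the sequences identical", {
  sim <- simulateCodonPair(omega = 1, kappa = 2, t = 0, nCodons = 50,
                           seed = 2)
  expect_equal(as.character(seqA(sim)), as.character(seqB(sim)),
               ignore_attr = TRUE)
})

test_that("codon simulation is deterministic under a fixed seed", {
  a <- simulateOrthologPairs(3, 0.5, 2, 0.2, 100, seed = 7)
  b <- simulateOrthologPairs(3, 0.5, 2, 0.2, 100, seed = 7)
  c <- simulateOrthologPairs(3, 0.5, 2, 0.2, 100, seed = 8)
  expect_identical(as.character(seqA(a)), as.character(seqA(b)))
  expect_identical(as.character(seqB(a)), as.character(seqB(b)))
  expect_false(identical(as.character(seqA(a)), as.character(seqA(c))))
})

test_that("mean NG86 omega-hat is near 1 for neutral simulation", {
  sim <- simulateOrthologPairs(40, omega = 1, kappa = 1, t = 0.4,
                               nCodons = 300, seed = 10)
  est <- kaksNG86(sim)
  expect_lt(abs(mean(est$omega) - 1), 0.15)
})

test_that("uniform gene assignment places one gene per chromosome", {
  g <- simulateGenomeAnnotation(10, 10, teRate = 0, seed = 3)
  tx <- transcripts(g$models)
  expect_equal(as.vector(table(as.character(GenomicRanges::seqnames(tx)))),
               rep(1L, 10))
  expect_length(g$te, 0)
  expect_false(any(g$teLedger$te_overlap))
})

test_that("gene regions tile the transcript span exactly", {
  g <- simulateGenomeAnnotation(30, 5, teRate = 0.3, seed = 4)
  regions <- partitionGeneRegions(g$models)
  tx <- transcripts(g$models)
  for (k in seq_along(tx)) {
    gid <- tx$gene_id[k]
    inside <- regions[regions$gene_id == gid &
                        regions$region != "promoter"]
    expect_equal(sum(GenomicRanges::width(inside)),
                 GenomicRanges::width(tx[k]), info = gid)
    expect_equal(sum(GenomicRanges::width(IRanges::reduce(inside))),
                 sum(GenomicRanges::width(inside)), info = gid)
    prom <- regions[regions$gene_id == gid & regions$region == "promoter"]
    expect_length(GenomicRanges::intersect(prom, inside), 0)
  }
})

test_that("planted TEs overlap exactly the ledgered gene regions", {
  g <- simulateGenomeAnnotation(40, 5, teRate = 0.25, seed = 5)
  regions <- partitionGeneRegions(g$models)
  hit <- IRanges::overlapsAny(regions, g$te, ignore.strand = TRUE)
  observed <- unique(paste(regions$gene_id[hit], regions$region[hit]))
  planted <- paste(g$teLedger$gene_id, g$teLedger$region)[g$teLedger$te_overlap]
  expect_setequal(observed, planted)
})

test_that("expression generator plants recoverable classes", {
  e <- simulateExpression(sprintf("g%03d", 1:100),
                          fractions = c(specific = 0.2,
                                        constitutive = 0.3, silent = 0.1),
                          seed = 6)
  cls <- classifyTissuePattern(e$matrix)
  expect_equal(cls$class, e$classes$class)
  expect_equal(sum(cls$class == "specific"), 20)
  expect_equal(sum(cls$class == "constitutive"), 30)
  expect_equal(cls$specific_tissue[cls$class == "specific"],
               e$classes$specific_tissue[e$classes$class == "specific"])
})

test_that("zero expression scale silences every gene", {
  e <- simulateExpression(sprintf("g%02d", 1:20), scale = 0, seed = 7)
  expect_true(all(e$matrix == 0))
  expect_true(all(e$classes$class == "silent"))
})

test_that("expression output is byte-identical under a fixed seed", {
  e1 <- simulateExpression(sprintf("g%02d", 1:15), seed = 8)
  e2 <- simulateExpression(sprintf("g%02d", 1:15), seed = 8)
  f1 <- tempfile()
  f2 <- tempfile()
  writeExpressionMatrix(e1$matrix, f1)
  writeExpressionMatrix(e2$matrix, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("methylation generator recovers the planted region rate", {
  g <- simulateGenomeAnnotation(200, 5, teRate = 0, seed = 9)
  m <- simulateMethylation(g$models, g$teLedger, teEffect = 0,
                           siteDensity = 0.5, coverage = 50,
                           contextProbs = c(0.6, 0.2, 0.2),
                           promoterLength = 0, seed = 10)
  regions <- partitionGeneRegions(g$models, promoterLength = 0)
  prof <- profileGenes(m$calls, regions)
  intronCG <- prof[prof$region == "intron" & prof$context == "CG", ]
  nSites <- sum(intronCG$n_sites)
  expect_gt(nSites, 1e4)
  level <- sum(intronCG$methylated_reads) / sum(intronCG$total_reads)
  expect_lt(abs(level - 0.35), 0.02)  # generator default for intron CG
})

test_that("zero coverage leaves every call uncovered", {
  g <- simulateGenomeAnnotation(5, 5, teRate = 0, seed = 11)
  m <- simulateMethylation(g$models, coverage = 0, seed = 12)
  expect_true(all(!m$calls$covered))
  expect_true(all(m$calls$total == 0))
})

test_that("a clustered chromosome is detected by the permutation test", {
  # 5x gene-assignment weight on one chromosome; PSG labels follow genes on
  # that chromosome, so the PSG distribution departs from uniformity
  rejections <- 0
  nRep <- 20
  for (r in seq_len(nRep)) {
    g <- simulateGenomeAnnotation(100, 5, chromWeights = c(5, 1, 1, 1, 1),
                                  teRate = 0, seed = 100 + r)
    map <- data.frame(
      gene_id = geneIds(g$models),
      chrom = as.character(GenomicRanges::seqnames(transcripts(g$models))))
    psg <- map$gene_id[map$chrom == "Chr01"][1:15]
    pt <- permutationDistributionTest(psg, map, B = 199, seed = r)
    if (pt$empirical_p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / nRep, 0.8)
})

test_that("the full study bundle is internally consistent", {
  s <- simulateStudy(simulationConfig(seed = 3, nGenes = 30, nCodons = 60))
  expect_length(s$pairs, 30)
  expect_equal(pairIds(s$pairs), geneIds(s$genome$models))
  expect_equal(nrow(s$estimatesTruth), 30)
  expect_equal(rownames(s$expression$matrix), geneIds(s$genome$models))
  expect_true(all(s$retention$retention_class %in% 1:3))
})
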