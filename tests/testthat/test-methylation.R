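# Region partition arithmetic, read-weighted levels, conservation, TE
# stratification and the methylation-expression correlation.

test_that("plus-strand promoter arithmetic is exact", {
  m <- makeGeneModel(exonStarts = 5001, exonEnds = 6000,
                     cdsStart = 5101, cdsEnd = 5900)
  regions <- partitionGeneRegions(m, promoterLength = 2000)
  prom <- regions[regions$region == "promoter"]
  expect_equal(GenomicRanges::start(prom), 3001)
  expect_equal(GenomicRanges::end(prom), 5000)
})

test_that("minus-strand promoter sits 5' of the high-coordinate end", {
  m <- makeGeneModel(strand = "-", exonStarts = 7001, exonEnds = 8000,
                     cdsStart = 7101, cdsEnd = 7900)
  regions <- partitionGeneRegions(m, promoterLength = 2000)
  prom <- regions[regions$region == "promoter"]
  expect_equal(GenomicRanges::start(prom), 8001)
  expect_equal(GenomicRanges::end(prom), 10000)
  utr5 <- regions[regions$region == "UTR5"]
  expect_equal(GenomicRanges::start(utr5), 7901)
})

test_that("a CDS-spanning single exon leaves UTRs and introns empty", {
  m <- makeGeneModel(exonStarts = 1001, exonEnds = 2000,
                     cdsStart = 1001, cdsEnd = 2000)
  regions <- partitionGeneRegions(m, promoterLength = 100)
  expect_setequal(as.character(unique(regions$region)),
                  c("promoter", "exon"))
})

test_that("promoters are truncated at the chromosome start with a warning", {
  m <- makeGeneModel(exonStarts = 501, exonEnds = 1500,
                     cdsStart = 601, cdsEnd = 1400)
  expect_warning(regions <- partitionGeneRegions(m, promoterLength = 2000),
                 "truncated")
  prom <- regions[regions$region == "promoter"]
  expect_equal(GenomicRanges::start(prom), 1)
  expect_equal(GenomicRanges::end(prom), 500)
})

test_that("weighted level is read-weighted, not site-averaged", {
  calls <- makeCalls(data.frame(pos = c(10, 20), ctx = "CG",
                                meth = c(3, 0), total = c(10, 90)))
  iv <- GenomicRanges::GRanges("Chr01", IRanges::IRanges(1, 100))
  got <- weightedMethylation(calls, iv, "CG")
  expect_equal(got$level, 0.03)   # 3/100, not mean(0.3, 0)
  expect_equal(got$n_sites, 2)
  one <- weightedMethylation(
    makeCalls(data.frame(pos = 5, ctx = "CG", meth = 30, total = 100)),
    iv, "CG")
  expect_equal(one$level, 0.30)
  none <- weightedMethylation(calls, iv, "CHH")
  expect_true(is.na(none$level))
})

test_that("read counts are conserved across the four transcript regions", {
  g <- simulateGenomeAnnotation(20, 4, teRate = 0.2, seed = 1)
  m <- simulateMethylation(g$models, g$teLedger, teEffect = 0.1, seed = 2)
  regions <- partitionGeneRegions(g$models)
  prof <- profileGenes(m$calls, regions)
  tx <- transcripts(g$models)
  for (k in seq_len(5)) {
    gid <- tx$gene_id[k]
    for (cx in METH_CONTEXTS) {
      sub <- prof[prof$gene_id == gid & prof$context == cx &
                    prof$region != "promoter", ]
      span <- weightedMethylation(m$calls, tx[k], cx)
      expect_equal(sum(sub$total_reads), span$total_reads,
                   info = paste(gid, cx))
      expect_equal(sum(sub$methylated_reads), span$methylated_reads,
                   info = paste(gid, cx))
    }
  }
  # levels bounded wherever defined
  expect_true(all(prof$level >= 0 & prof$level <= 1, na.rm = TRUE))
})

test_that("profiles cover the full region x context grid per gene", {
  g <- simulateGenomeAnnotation(8, 2, teRate = 0, seed = 3)
  m <- simulateMethylation(g$models, seed = 4)
  prof <- profileGenes(m$calls, partitionGeneRegions(g$models))
  expect_equal(nrow(prof), 8 * 5 * 3)
})

test_that("interval overlap matches a naive all-pairs oracle", {
  set.seed(5)
  for (rep in 1:10) {
    a <- IRanges::IRanges(sample(1:100, 12), width = sample(1:20, 12,
                                                            replace = TRUE))
    b <- IRanges::IRanges(sample(1:100, 8), width = sample(1:20, 8,
                                                           replace = TRUE))
    got <- IRanges::overlapsAny(a, b)
    naive <- vapply(seq_along(a), function(i) {
      any(IRanges::start(a)[i] <= IRanges::end(b) &
            IRanges::end(a)[i] >= IRanges::start(b))
    }, logical(1))
    expect_equal(got, naive)
  }
})

test_that("an abutting TE does not count as overlap (half-open BED input)", {
  m <- makeGeneModel(exonStarts = 5001, exonEnds = 6000,
                     cdsStart = 5001, cdsEnd = 6000)
  regions <- partitionGeneRegions(m, promoterLength = 1000)
  # BED 0-based half-open [3000, 4000) abuts the promoter 4001..5000
  bed <- tempfile(fileext = ".bed")
  writeLines("Chr01\t3000\t4000", bed)
  te <- readTEIntervals(bed)
  calls <- makeCalls(data.frame(pos = c(4500, 5500), ctx = "CG",
                                meth = c(5, 5), total = c(10, 10)))
  prof <- profileGenes(calls, regions)
  strat <- teOverlapStratification(prof, regions, te)
  expect_true(all(strat$n_with_te == 0))
  expect_true(all(strat$flag == "insufficient_group"))
})

test_that("a planted promoter TE methylation effect is recovered", {
  g <- simulateGenomeAnnotation(150, 5, teRate = 0.3, seed = 6)
  m <- simulateMethylation(g$models, g$teLedger, teEffect = 0.2,
                           siteDensity = 0.05, coverage = 30, seed = 7)
  regions <- partitionGeneRegions(g$models)
  prof <- profileGenes(m$calls, regions)
  strat <- teOverlapStratification(prof, regions, g$te)
  promCG <- strat[strat$region == "promoter" & strat$context == "CG", ]
  expect_gt(promCG$n_with_te, 10)
  expect_lt(abs(promCG$difference - 0.2), 0.05)
  expect_lt(promCG$p, 0.01)
})

test_that("group comparisons run per region and context", {
  g <- simulateGenomeAnnotation(40, 4, teRate = 0, seed = 8)
  m <- simulateMethylation(g$models, seed = 9)
  prof <- profileGenes(m$calls, partitionGeneRegions(g$models))
  ids <- geneIds(g$models)
  out <- compareMethylationGroups(prof, ids[1:20], ids[21:40],
                                  test = "kruskal_wallis")
  expect_equal(nrow(out), 15)
  expect_true(all(out$p[!is.na(out$p)] >= 0))
})

test_that("monotone-decreasing methylation gives Spearman rho of -1", {
  ids <- sprintf("g%02d", 1:10)
  prof <- data.frame(gene_id = ids, region = "exon", context = "CG",
                     methylated_reads = 100 - (1:10) * 9,
                     total_reads = 100, n_sites = 10,
                     level = (100 - (1:10) * 9) / 100)
  mat <- matrix(rep(1:10, 6), 10, 6, dimnames = list(ids, TISSUES))
  out <- methylationExpressionCorrelation(prof, mat, context = "CG",
                                          regions = "exon")
  expect_equal(out$rho, -1)
  expect_lt(out$p, 0.01)
  expect_error(methylationExpressionCorrelation(prof[1:2, ], mat),
               "fewer than 3")
})

test_that("independent methylation and expression layers give null rho", {
  set.seed(10)
  rhos <- replicate(50, {
    ids <- sprintf("g%03d", 1:100)
    prof <- data.frame(gene_id = ids, region = "exon", context = "CG",
                       methylated_reads = rbinom(100, 100, 0.3),
                       total_reads = 100, n_sites = 10)
    prof$level <- prof$methylated_reads / 100
    mat <- matrix(rlnorm(600), 100, 6, dimnames = list(ids, TISSUES))
    methylationExpressionCorrelation(prof, mat, regions = "exon")$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)
  expect_lt(stats::quantile(abs(rhos), 0.95), 0.3)
})
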