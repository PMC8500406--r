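# NG86 site and difference counting against independent enumeration, plus
# the closed-form Jukes-Cantor correction on a hand-worked alignment.

# independent brute-force oracle: classify the nine mutations of a codon
# directly against the genetic code, by string manipulation
bruteForceSites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  nS <- 0
  for (p in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- nt
      if (gc[[mut]] != "*" && gc[[mut]] == aa) nS <- nS + 1
    }
  }
  c(S = nS / 3, N = 3 - nS / 3)
}

test_that("site counts match brute-force enumeration for all 61 sense codons", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  expect_length(sense, 61)
  for (codon in sense) {
    expect_equal(codonSitesNG86(codon), bruteForceSites(codon),
                 info = codon)
  }
  expect_error(codonSitesNG86("TAA"), "sense")
  expect_error(codonSitesNG86("NNT"), "sense")
})

test_that("spot site counts: TTT, GGG and the no-synonymous-change codon TGG", {
  expect_equal(codonSitesNG86("TTT"), c(S = 1 / 3, N = 8 / 3))
  expect_equal(codonSitesNG86("GGG"), c(S = 1, N = 2))
  expect_equal(codonSitesNG86("TGG"), c(S = 0, N = 3))
})

test_that("pathway averaging over mutational orders", {
  # single synonymous change
  expect_equal(countDifferencesNG86("TTT", "TTC"), c(Sd = 1, Nd = 0))
  # identity
  expect_equal(countDifferencesNG86("AAA", "AAA"), c(Sd = 0, Nd = 0))
  # two differing positions: average of TTT->GTT->GTA and TTT->TTA->GTA
  expect_equal(countDifferencesNG86("TTT", "GTA"), c(Sd = 0.5, Nd = 1.5))
  # Sd + Nd equals the number of differing positions on random codon pairs
  set.seed(11)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (i in 1:50) {
    a <- sample(sense, 1)
    b <- sample(sense, 1)
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    d <- countDifferencesNG86(a, b)
    expect_equal(unname(d["Sd"] + d["Nd"]), k, info = paste(a, b))
  }
})

test_that("hand-worked three-codon alignment reproduces closed-form Ks", {
  ops <- OrthologPairSet(geneA = "a", geneB = "b",
                         seqA = "TTTGGGGGG", seqB = "TTCGGGGGG")
  est <- kaksNG86(ops)
  expect_equal(est$S, 7 / 3)
  expect_equal(est$N, 20 / 3)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$pS, 3 / 7)
  expect_equal(est$Ks, -0.75 * log(1 - 4 / 3 * 3 / 7))
  expect_equal(est$Ks, 0.6355, tolerance = 1e-4)
  expect_equal(est$Ka, 0)
  expect_equal(est$omega, 0)
})

test_that("identical sequences give zero distances and undefined omega", {
  ops <- OrthologPairSet(geneA = "a", geneB = "b",
                         seqA = "ATGGCTAAA", seqB = "ATGGCTAAA")
  est <- kaksNG86(ops)
  expect_equal(est$Ks, 0)
  expect_equal(est$Ka, 0)
  expect_true(is.na(est$omega))
  expect_match(est$flags, "omega_undefined")
})

test_that("estimates are symmetric in the two sequences and conserve sites", {
  sim <- simulateOrthologPairs(5, omega = 0.8, kappa = 2, t = 0.3,
                               nCodons = 150, seed = 21)
  swapped <- OrthologPairSet(pairIds(sim), geneIdsB(sim), geneIdsA(sim),
                             as.character(seqB(sim)),
                             as.character(seqA(sim)))
  a <- kaksNG86(sim)
  b <- kaksNG86(swapped)
  for (col in c("S", "N", "Sd", "Nd", "Ks", "Ka", "omega")) {
    expect_equal(a[[col]], b[[col]], info = col)
  }
  # S + N = 3 x analyzable codons
  expect_equal(a$S + a$N, 3 * a$n_codons_used)
})

test_that("ambiguous codon columns are dropped pairwise", {
  ops <- OrthologPairSet(geneA = "a", geneB = "b",
                         seqA = "TTTNNNGGG", seqB = "TTCAAAGGG")
  est <- kaksNG86(ops)
  expect_equal(est$n_codons_used, 2L)
  expect_equal(est$Sd, 1)
})

test_that("saturated synonymous proportion is flagged, not corrected", {
  ops <- OrthologPairSet(geneA = "a", geneB = "b",
                         seqA = strrep("GGA", 20), seqB = strrep("GGG", 20))
  est <- kaksNG86(ops)
  expect_true(is.na(est$Ks))
  expect_match(est$flags, "saturated")
})

test_that("a pair simulated without nonsynonymous change has Ka near 0", {
  # under omega = 0 the protein is invariant; pathway averaging can still
  # assign small fractional Nd to codons hit more than once, so Ka is
  # bounded well below Ks rather than exactly zero
  sim <- simulateOrthologPairs(3, omega = 0, kappa = 2, t = 0.1,
                               nCodons = 100, seed = 5)
  aaA <- unname(as.character(Biostrings::translate(seqA(sim))))
  aaB <- unname(as.character(Biostrings::translate(seqB(sim))))
  expect_equal(aaA, aaB)
  est <- kaksNG86(sim)
  expect_true(all(est$Ks > 0))
  expect_true(all(est$Ka < 0.1 * est$Ks))
  # codon columns differing at a single position contribute no Nd at all
  expect_true(all(est$Nd < est$Sd))
})

test_that("NG86 omega-hat tracks true omega in rank across a small grid", {
  omegas <- c(0.2, 0.5, 1, 2)
  means <- vapply(seq_along(omegas), function(i) {
    sim <- simulateOrthologPairs(20, omegas[i], kappa = 2, t = 0.3,
                                 nCodons = 200, seed = 100 + i)
    mean(kaksNG86(sim)$omega, na.rm = TRUE)
  }, numeric(1))
  expect_equal(order(means), seq_along(omegas))
})
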