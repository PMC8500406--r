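## Whole-study simulation: one config object fixes every stream, and each
## generator emits a ground-truth ledger so downstream stages can be tested
## for parameter recovery without any external data.

#' Simulation configuration with study-condition defaults
#'
#' Collects every simulator parameter into one validated list. Defaults
#' emulate the study conditions of a two-Brassica ortholog screen at desk
#' scale: ten chromosomes, a small fraction of genes evolving with omega
#' above the screening threshold, moderate transition bias, synonymous
#' divergence well below the Ks saturation filter, and plant-typical
#' methylation rates.
#'
#' @param seed Master seed; every stream is derived from it.
#' @param nGenes,nChroms,chromWeights Genome layout.
#' @param nCodons Codons per simulated coding sequence.
#' @param psgFraction Fraction of genes simulated with `omegaPsg`.
#' @param omegaPsg,omegaBackground True omega of the selected and the
#'   background class.
#' @param kappa Transition/transversion rate ratio.
#' @param t Expected substitutions per nucleotide site between orthologs.
#' @param promoterLength Promoter length in bp.
#' @param teRate TE insertion probability per gene region.
#' @param teEffect Additive methylation-rate shift in TE-carrying regions.
#' @param expressionFractions Fractions of specific/constitutive/silent
#'   genes.
#' @param expressedThreshold,fpkmScale Expression generator parameters.
#' @param methylationRates 5 x 3 region x context mean rates.
#' @param coverage,siteDensity,betaConc Methylome generator parameters.
#' @param retentionFractions Fractions of WGT retention classes 1/2/3
#'   (must sum to 1).
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1, nGenes = 200, nChroms = 10,
                             chromWeights = NULL, nCodons = 300,
                             psgFraction = 0.02, omegaPsg = 2,
                             omegaBackground = 0.2, kappa = 2, t = 0.05,
                             promoterLength = 2000, teRate = 0.15,
                             teEffect = 0.2,
                             expressionFractions = c(specific = 0.2,
                                                     constitutive = 0.3,
                                                     silent = 0.1),
                             expressedThreshold = 1, fpkmScale = 8,
                             methylationRates = defaultMethylationRates(),
                             coverage = 30, siteDensity = 0.05,
                             betaConc = 200,
                             retentionFractions = c(0.5, 0.35, 0.15)) {
  stopifnot(nGenes >= nChroms, psgFraction >= 0, psgFraction <= 1,
            kappa >= 0, t >= 0, nCodons >= 1,
            abs(sum(retentionFractions) - 1) < 1e-8,
            sum(expressionFractions) <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a substitution-estimate table with planted filter counts
#'
#' Generates a per-pair Ka/Ks table directly (no codon sequences), planting
#' an exact number of pairs above the Ks saturation threshold and, in the
#' retained stratum, an exact number of PSGs above the omega threshold.
#' Used to exercise the screen accounting chain at genome scale.
#'
#' @param nPairs Total pairs.
#' @param nHighKs Pairs with `Ks > maxKs` (planted exactly).
#' @param nPsg PSGs among the retained pairs (`omega > omegaThreshold`
#'   exactly); default scales the 468-of-23817 proportion.
#' @param maxKs,omegaThreshold The screen thresholds being planted around.
#' @param seed Integer seed.
#' @return data.frame with `pair_id`, `gene_a`, `gene_b`, `Ks`, `Ka`,
#'   `omega`, `method`; attributes record the planted counts.
#' @export
simulateEstimates <- function(nPairs, nHighKs, nPsg = NULL, maxKs = 0.3,
                              omegaThreshold = 1.2, seed = 1) {
  stopifnot(nHighKs <= nPairs)
  nRet <- nPairs - nHighKs
  if (is.null(nPsg)) nPsg <- round(nRet * 468 / 23817)
  stopifnot(nPsg <= nRet)
  set.seed(seed)
  ksRet <- maxKs * stats::rbeta(nRet, 2, 4)
  ksHigh <- maxKs + 1e-6 + stats::rexp(nHighKs, rate = 5)
  Ks <- c(ksRet, ksHigh)[sample.int(nPairs)]
  high <- Ks > maxKs
  omega <- numeric(nPairs)
  retIdx <- which(!high)
  psgIdx <- sample(retIdx, nPsg)
  omega[retIdx] <- stats::runif(nRet, 0, omegaThreshold * 0.98)
  omega[psgIdx] <- omegaThreshold + 1e-6 + stats::rexp(nPsg, rate = 2)
  omega[high] <- stats::runif(nHighKs, 0, omegaThreshold)
  ids <- sprintf("pair_%05d", seq_len(nPairs))
  out <- data.frame(pair_id = ids,
                    gene_a = sprintf("geneA_%05d", seq_len(nPairs)),
                    gene_b = sprintf("geneB_%05d", seq_len(nPairs)),
                    Ks = Ks, Ka = omega * Ks, omega = omega,
                    method = "simulated", stringsAsFactors = FALSE)
  attr(out, "n_high_ks") <- nHighKs
  attr(out, "n_psg") <- nPsg
  out
}

#' Simulate a complete study dataset with ground truth
#'
#' Runs every generator under one configuration: codon-evolved ortholog
#' pairs with a planted omega mixture, gene models and TE insertions,
#' six-tissue expression with planted specificity classes, per-cytosine
#' methylation with region/context/TE structure, and WGT retention
#' classes. Seeds for the individual streams are derived from
#' `config$seed`, so the whole dataset is reproducible byte for byte.
#'
#' @param config A [simulationConfig()].
#' @return list(pairs, estimatesTruth, genome (models/te/teLedger),
#'   expression (matrix/classes), methylation (calls/ledger), retention,
#'   config).
#' @export
simulateStudy <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  s <- config$seed
  genome <- simulateGenomeAnnotation(config$nGenes, config$nChroms,
                                     config$chromWeights,
                                     config$promoterLength,
                                     config$teRate, seed = s + 1)
  ids <- geneIds(genome$models)
  set.seed(s + 2)
  nPsg <- round(config$psgFraction * config$nGenes)
  trueOmega <- rep(config$omegaBackground, config$nGenes)
  trueOmega[sample.int(config$nGenes, nPsg)] <- config$omegaPsg
  pairs <- simulateOrthologPairs(config$nGenes, trueOmega, config$kappa,
                                 config$t, config$nCodons, seed = s + 3)
  pairs@pairId <- ids
  pairs@geneA <- ids
  pairs@geneB <- sub("^gene", "orth", ids)
  names(pairs@seqA) <- pairs@geneA
  names(pairs@seqB) <- pairs@geneB
  expr <- simulateExpression(ids, config$expressionFractions,
                             config$expressedThreshold, config$fpkmScale,
                             seed = s + 4)
  meth <- simulateMethylation(genome$models, genome$teLedger,
                              config$methylationRates, config$teEffect,
                              siteDensity = config$siteDensity,
                              coverage = config$coverage,
                              betaConc = config$betaConc,
                              promoterLength = config$promoterLength,
                              seed = s + 5)
  set.seed(s + 6)
  retention <- data.frame(gene_id = ids,
                          retention_class = sample(1:3, config$nGenes,
                                                   replace = TRUE,
                                                   prob = config$retentionFractions),
                          stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, true_omega = trueOmega,
                      is_true_psg = trueOmega > 1.2,
                      expression_class = expr$classes$class,
                      retention_class = retention$retention_class,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, estimatesTruth = truth, genome = genome,
       expression = expr, methylation = meth, retention = retention,
       config = config)
}

#' Write a simulated study to disk through the package writers
#'
#' Emits the FASTA pair files, pairing table, GFF3 gene models, TE BED,
#' expression TSV, cytosine report, retention TSV and a
#' `ground_truth.tsv` ledger.
#'
#' @param study Output of [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeOrthologPairs(study$pairs, p("cds_a.fasta"), p("cds_b.fasta"),
                     p("pairing.tsv"))
  writeGeneModels(study$genome$models, p("genes.gff3"))
  if (length(study$genome$te)) {
    writeTEIntervals(study$genome$te, p("te.bed"))
  }
  writeExpressionMatrix(study$expression$matrix, p("expression.tsv"))
  writeCytosineReport(study$methylation$calls, p("cytosine_report.tsv"))
  .writeTSV(study$retention, p("retention.tsv"))
  .writeTSV(study$estimatesTruth, p("ground_truth.tsv"),
            params = list(seed = study$config$seed))
  invisible(dir)
}
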