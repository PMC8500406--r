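## Genome-annotation and methylome generators with ground-truth ledgers.
## Only cytosine positions with context labels are placed, not full genome
## sequence; indels and recombination are out of scope.

#' Simulate gene models and TE insertions on a small genome
#'
#' Places `nGenes` gene models on `nChroms` chromosomes (evenly by
#' round-robin under uniform weights, or multinomially under `chromWeights`
#' to create known clustering), each with promoter, UTR5, one to three
#' exons with introns, and UTR3. Intergenic gaps always exceed the promoter
#' length so regions of neighbouring genes never collide. Transposable
#' elements are dropped into gene regions independently with probability
#' `teRate` per region, and the planted overlaps are recorded in a ledger.
#'
#' @param nGenes,nChroms Genome size (nGenes >= nChroms).
#' @param chromWeights Optional per-chromosome assignment weights.
#' @param promoterLength Promoter length in bp.
#' @param teRate Probability of a TE insertion per gene region.
#' @param seed Integer seed.
#' @return list(models = [GeneModelSet], te = GRanges,
#'   teLedger = data.frame(gene_id, region, te_overlap)).
#' @export
simulateGenomeAnnotation <- function(nGenes, nChroms = 10,
                                     chromWeights = NULL,
                                     promoterLength = 2000,
                                     teRate = 0.15, seed = 1) {
  stopifnot(nGenes >= nChroms, nChroms >= 1, teRate >= 0, teRate <= 1)
  set.seed(seed)
  chromNames <- sprintf("Chr%02d", seq_len(nChroms))
  chrom <- if (is.null(chromWeights)) {
    chromNames[rep(seq_len(nChroms), length.out = nGenes)]
  } else {
    stopifnot(length(chromWeights) == nChroms)
    sample(chromNames, nGenes, replace = TRUE,
           prob = chromWeights / sum(chromWeights))
  }
  cursor <- stats::setNames(rep(promoterLength + 1000, nChroms), chromNames)
  txStartV <- txEndV <- cdsStartV <- cdsEndV <- integer(nGenes)
  strandV <- character(nGenes)
  exAcc <- vector("list", nGenes)
  ids <- sprintf("gene_%04d", seq_len(nGenes))
  for (k in seq_len(nGenes)) {
    ch <- chrom[k]
    strand <- sample(c("+", "-"), 1)
    nEx <- sample(1:3, 1)
    utr5len <- sample(100:300, 1)
    utr3len <- sample(150:400, 1)
    cdsChunks <- 3 * sample(50:150, nEx, replace = TRUE)
    intronLens <- if (nEx > 1) sample(80:400, nEx - 1, replace = TRUE) else
      integer(0)
    txStart <- cursor[ch]
    # exon 1 carries the low-coordinate UTR, the last exon the high one
    exLens <- cdsChunks
    exLens[1] <- exLens[1] + utr5len
    exLens[nEx] <- exLens[nEx] + utr3len
    exStart <- txStart
    exStarts <- integer(nEx)
    exEnds <- integer(nEx)
    for (e in seq_len(nEx)) {
      exStarts[e] <- exStart
      exEnds[e] <- exStart + exLens[e] - 1
      exStart <- exEnds[e] + 1 + if (e < nEx) intronLens[e] else 0
    }
    txEnd <- exEnds[nEx]
    txStartV[k] <- txStart
    txEndV[k] <- txEnd
    cdsStartV[k] <- txStart + utr5len
    cdsEndV[k] <- txEnd - utr3len
    strandV[k] <- strand
    exAcc[[k]] <- cbind(exStarts, exEnds)
    # leave room for this gene's downstream promoter (minus strand) plus
    # the next gene's upstream promoter so regions never collide
    cursor[ch] <- txEnd + 2 * promoterLength + sample(1000:3000, 1)
  }
  chromF <- factor(chrom, levels = chromNames)
  tx <- GenomicRanges::GRanges(chromF, IRanges::IRanges(txStartV, txEndV),
                               strand = strandV, gene_id = ids)
  nExPerGene <- vapply(exAcc, nrow, integer(1))
  exFlat <- do.call(rbind, exAcc)
  exGr <- GenomicRanges::GRanges(
    rep(chromF, nExPerGene),
    IRanges::IRanges(exFlat[, 1], exFlat[, 2]),
    strand = rep(strandV, nExPerGene))
  exl <- GenomicRanges::split(exGr, factor(rep(ids, nExPerGene),
                                           levels = ids))
  cdg <- GenomicRanges::GRanges(chromF,
                                IRanges::IRanges(cdsStartV, cdsEndV),
                                strand = strandV)
  names(cdg) <- ids
  models <- GeneModelSet(transcripts = tx, exons = exl, cds = cdg)

  regions <- suppressWarnings(partitionGeneRegions(models, promoterLength))
  ledger <- expand.grid(gene_id = ids, region = GENE_REGIONS,
                        stringsAsFactors = FALSE)
  ledger$te_overlap <- FALSE
  teChr <- character(0)
  teStart <- teEnd <- integer(0)
  if (teRate > 0 && length(regions)) {
    regKey <- paste(regions$gene_id, as.character(regions$region),
                    sep = "\r")
    idxByKey <- split(seq_along(regions), regKey)
    regChr <- as.character(GenomicRanges::seqnames(regions))
    regStart <- GenomicRanges::start(regions)
    regWidth <- GenomicRanges::width(regions)
    for (r in seq_len(nrow(ledger))) {
      idx <- idxByKey[[paste(ledger$gene_id[r], ledger$region[r],
                             sep = "\r")]]
      if (is.null(idx)) next
      if (stats::runif(1) >= teRate) next
      i <- idx[sample.int(length(idx), 1)]
      w <- regWidth[i]
      teLen <- min(sample(50:300, 1), w)
      offset <- sample.int(w - teLen + 1, 1) - 1
      teChr <- c(teChr, regChr[i])
      teStart <- c(teStart, regStart[i] + offset)
      teEnd <- c(teEnd, regStart[i] + offset + teLen - 1)
      ledger$te_overlap[r] <- TRUE
    }
  }
  te <- if (length(teChr)) {
    sort(GenomicRanges::GRanges(factor(teChr, levels = chromNames),
                                IRanges::IRanges(teStart, teEnd)))
  } else {
    GenomicRanges::GRanges()
  }
  if (length(te)) names(te) <- sprintf("TE_%04d", seq_along(te))
  list(models = models, te = te, teLedger = ledger)
}

#' Default region x context methylation rates
#'
#' Mean site methylation probabilities per genic region and context used by
#' [simulateMethylation()]. The pattern follows what is typical of plant
#' gene bodies: substantial CG methylation in introns and UTRs, low CG in
#' exons and promoters, intron-concentrated CHG, and near-zero CHH.
#'
#' @return 5 x 3 numeric matrix (regions x contexts).
#' @export
defaultMethylationRates <- function() {
  m <- rbind(promoter = c(0.10, 0.05, 0.005),
             UTR5 = c(0.30, 0.03, 0.005),
             exon = c(0.05, 0.02, 0.005),
             intron = c(0.35, 0.30, 0.005),
             UTR3 = c(0.30, 0.05, 0.005))
  colnames(m) <- METH_CONTEXTS
  m
}

#' Simulate per-cytosine methylation calls over gene regions
#'
#' Cytosines are placed uniformly along every region interval at density
#' `siteDensity`, assigned a context, and given a per-site methylation
#' probability drawn from a beta distribution with the region x context
#' mean from `rates` (plus `teEffect` for sites whose gene region carries a
#' planted TE, clipped to \[0,1\]) and concentration `betaConc`. Read depth
#' per site is Poisson(`coverage`), methylated counts binomial.
#'
#' @param models A [GeneModelSet].
#' @param teLedger Ledger from [simulateGenomeAnnotation()] (or NULL for no
#'   TE effect).
#' @param rates 5 x 3 region x context mean rates.
#' @param teEffect Additive rate shift for TE-overlapped regions.
#' @param contextProbs Sampling probabilities of CG/CHG/CHH among placed
#'   cytosines.
#' @param siteDensity Cytosines per bp.
#' @param coverage Mean reads per site (0 gives all-uncovered calls).
#' @param betaConc Beta concentration; larger values give site rates closer
#'   to the mean.
#' @param promoterLength Passed to [partitionGeneRegions()].
#' @param seed Integer seed.
#' @return list(calls = GRanges (as [readCytosineReport()]),
#'   ledger = data.frame of true per region x context rates).
#' @export
simulateMethylation <- function(models, teLedger = NULL,
                                rates = defaultMethylationRates(),
                                teEffect = 0, contextProbs = c(0.35, 0.3, 0.35),
                                siteDensity = 0.05, coverage = 30,
                                betaConc = 200, promoterLength = 2000,
                                seed = 1) {
  stopifnot(is(models, "GeneModelSet"),
            all(rownames(rates) == GENE_REGIONS),
            all(colnames(rates) == METH_CONTEXTS))
  set.seed(seed)
  regions <- suppressWarnings(partitionGeneRegions(models, promoterLength))
  ovKey <- if (!is.null(teLedger)) {
    paste(teLedger$gene_id[teLedger$te_overlap],
          teLedger$region[teLedger$te_overlap], sep = "\r")
  } else {
    character(0)
  }
  regChr <- as.character(GenomicRanges::seqnames(regions))
  regStart <- GenomicRanges::start(regions)
  regWidth <- GenomicRanges::width(regions)
  regName <- as.character(regions$region)
  regHasTE <- paste(regions$gene_id, regName, sep = "\r") %in% ovKey
  acc <- list()
  for (i in seq_along(regions)) {
    w <- regWidth[i]
    nSites <- stats::rpois(1, w * siteDensity)
    if (nSites == 0) next
    pos <- regStart[i] + sort(sample.int(w, min(nSites, w))) - 1
    ctx <- sample(METH_CONTEXTS, length(pos), replace = TRUE,
                  prob = contextProbs)
    m <- pmin(pmax(rates[regName[i], ctx] +
                     if (regHasTE[i]) teEffect else 0, 1e-4), 1 - 1e-4)
    pSite <- stats::rbeta(length(pos), m * betaConc, (1 - m) * betaConc)
    tot <- stats::rpois(length(pos), coverage)
    meth <- stats::rbinom(length(pos), tot, pSite)
    acc[[length(acc) + 1L]] <- data.frame(
      chr = regChr[i], pos = pos, ctx = ctx, meth = meth, tot = tot,
      strand = sample(c("+", "-"), length(pos), replace = TRUE))
  }
  out <- if (length(acc)) {
    df <- do.call(rbind, acc)
    gr <- GenomicRanges::GRanges(
      factor(df$chr, levels = GenomeInfoDb::seqlevels(regions)),
      IRanges::IRanges(df$pos, width = 1), strand = df$strand,
      context = factor(df$ctx, levels = METH_CONTEXTS),
      meth = df$meth, total = df$tot, covered = df$tot > 0)
    sort(gr)
  } else {
    GenomicRanges::GRanges()
  }
  ledger <- expand.grid(region = GENE_REGIONS, context = METH_CONTEXTS,
                        stringsAsFactors = FALSE)
  ledger$base_rate <- rates[cbind(ledger$region, ledger$context)]
  ledger$te_effect <- teEffect
  list(calls = out, ledger = ledger)
}

#' Simulate a six-tissue FPKM matrix with planted expression classes
#'
#' Designated tissue-specific genes receive FPKM at or above `threshold` in
#' exactly one tissue and below it elsewhere; constitutive genes are above
#' threshold in all six; silent genes everywhere below; the remainder are
#' intermediate (2-5 expressed tissues). With `scale = 0` the matrix is all
#' zeros (every gene silent). The planted labels are returned as the
#' ground-truth ledger.
#'
#' @param geneIds Character vector of gene ids.
#' @param fractions Named fractions of `specific`, `constitutive` and
#'   `silent` genes (remainder intermediate); must sum to at most 1.
#' @param threshold FPKM threshold the planted classes are built around.
#' @param scale Median FPKM of expressed entries (log-normal).
#' @param seed Integer seed.
#' @return list(matrix, classes = data.frame(gene_id, class,
#'   specific_tissue)).
#' @export
simulateExpression <- function(geneIds,
                               fractions = c(specific = 0.2,
                                             constitutive = 0.3,
                                             silent = 0.1),
                               threshold = 1, scale = 8, seed = 1) {
  stopifnot(all(c("specific", "constitutive", "silent") %in%
                  names(fractions)),
            sum(fractions) <= 1, all(fractions >= 0))
  set.seed(seed)
  n <- length(geneIds)
  nSpec <- round(fractions["specific"] * n)
  nConst <- round(fractions["constitutive"] * n)
  nSil <- round(fractions["silent"] * n)
  cls <- rep("intermediate", n)
  ord <- sample.int(n)
  cls[ord[seq_len(nSpec)]] <- "specific"
  cls[ord[nSpec + seq_len(nConst)]] <- "constitutive"
  cls[ord[nSpec + nConst + seq_len(nSil)]] <- "silent"
  mat <- matrix(0, n, 6, dimnames = list(geneIds, TISSUES))
  specTissue <- rep(NA_character_, n)
  if (scale > 0) {
    hi <- function(m) threshold + stats::rlnorm(m, log(scale), 1)
    lo <- function(m) stats::runif(m, 0, threshold * 0.5)
    for (i in seq_len(n)) {
      if (cls[i] == "specific") {
        tis <- sample(6, 1)
        specTissue[i] <- TISSUES[tis]
        mat[i, ] <- lo(6)
        mat[i, tis] <- hi(1)
      } else if (cls[i] == "constitutive") {
        mat[i, ] <- hi(6)
      } else if (cls[i] == "silent") {
        mat[i, ] <- lo(6)
      } else {
        kTis <- sample(2:5, 1)
        tis <- sample(6, kTis)
        mat[i, ] <- lo(6)
        mat[i, tis] <- hi(kTis)
      }
    }
  } else {
    cls <- rep("silent", n)
  }
  list(matrix = mat,
       classes = data.frame(gene_id = geneIds, class = cls,
                            specific_tissue = specTissue,
                            stringsAsFactors = FALSE))
}
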