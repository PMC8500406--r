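## Chromosomal-distribution tests for the PSG set: contingency chi-square,
## exact / Monte-Carlo Fisher with fixed margins, and a randomization
## (permutation) test of per-chromosome counts against expectation
## proportional to chromosome gene totals.

# resolve a gene -> chromosome map from a GeneModelSet or a data.frame
.geneChromMap <- function(geneChrom) {
  if (is(geneChrom, "GeneModelSet")) {
    tx <- transcripts(geneChrom)
    data.frame(gene_id = tx$gene_id,
               chrom = as.character(GenomicRanges::seqnames(tx)),
               stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(geneChrom),
              all(c("gene_id", "chrom") %in% names(geneChrom)))
    geneChrom[, c("gene_id", "chrom")]
  }
}

#' Per-chromosome PSG counts and densities
#'
#' @param psgGenes Character vector of PSG gene ids.
#' @param geneChrom Gene universe with chromosome assignments: a
#'   [GeneModelSet] or a data.frame with `gene_id` and `chrom`.
#' @return A list with `distribution` (per chromosome: `n_psg`,
#'   `n_background`, `n_total`, `density` = PSGs per gene on that
#'   chromosome) and `table`, the 2 x C PSG/non-PSG contingency matrix.
#'   PSG genes absent from the universe are an error listing the ids.
#' @export
chromosomeCounts <- function(psgGenes, geneChrom) {
  map <- .geneChromMap(geneChrom)
  missing <- setdiff(psgGenes, map$gene_id)
  if (length(missing)) {
    stop("gene(s) without a chromosome assignment: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  chroms <- sort(unique(map$chrom))
  isPsg <- map$gene_id %in% psgGenes
  nPsg <- vapply(chroms, function(ch) sum(isPsg & map$chrom == ch), numeric(1))
  nTot <- vapply(chroms, function(ch) sum(map$chrom == ch), numeric(1))
  tab <- rbind(PSG = nPsg, `non-PSG` = nTot - nPsg)
  colnames(tab) <- chroms
  list(distribution = data.frame(chrom = chroms, n_psg = nPsg,
                                 n_background = nTot - nPsg, n_total = nTot,
                                 density = nPsg / nTot, row.names = NULL),
       table = tab)
}

#' Pearson chi-square test on a 2 x C contingency table
#'
#' No continuity correction; df = C - 1. All row and column margins must be
#' positive.
#'
#' @param table A 2 x C count matrix.
#' @return list(statistic, df, p).
#' @export
contingencyChisq <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

# log probability of an r x c table under fixed margins
.logTableProb <- function(x) {
  sum(lfactorial(rowSums(x))) + sum(lfactorial(colSums(x))) -
    lfactorial(sum(x)) - sum(lfactorial(x))
}

#' Fisher exact test on a 2 x C table (exact or Monte-Carlo)
#'
#' For 2 x 2 tables the exact two-sided hypergeometric p is available; for
#' wider tables (or on request) the p-value is estimated by Monte Carlo:
#' `B` tables are drawn with the observed margins fixed (Patefield
#' algorithm via [stats::r2dtable()]) and
#' \eqn{p = (1 + \#\{P(table) \le P(observed)\}) / (B + 1)} (plus-one rule,
#' so p is never 0).
#'
#' @param table A 2 x C count matrix with positive margins.
#' @param B Number of Monte-Carlo tables.
#' @param seed Integer seed for the table sampler.
#' @param method `"auto"` (exact for 2 x 2, Monte-Carlo otherwise),
#'   `"exact"` (2 x 2 only) or `"mc"`.
#' @return list(p, method, B, seed).
#' @export
contingencyFisher <- function(table, B = 2000, seed = 1,
                              method = c("auto", "exact", "mc")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero margin")
  }
  if (method == "auto") {
    method <- if (all(dim(table) == 2)) "exact" else "mc"
  }
  if (method == "exact") {
    if (!all(dim(table) == 2)) {
      stop("exact method implemented for 2 x 2 tables only; use method='mc'")
    }
    return(list(p = stats::fisher.test(table)$p.value, method = "exact",
                B = NA_integer_, seed = NA_integer_))
  }
  set.seed(seed)
  lpObs <- .logTableProb(table)
  tabs <- stats::r2dtable(B, rowSums(table), colSums(table))
  lp <- vapply(tabs, .logTableProb, numeric(1))
  m <- sum(lp <= lpObs + 1e-7)
  list(p = (1 + m) / (B + 1), method = "mc", B = B, seed = seed)
}

#' Randomization test of the chromosomal distribution of a gene set
#'
#' The observed statistic is the Pearson chi-square of per-chromosome PSG
#' counts against expectation proportional to per-chromosome gene totals.
#' The null distribution is built by drawing `B` uniform gene sets of equal
#' size from the universe; the empirical p follows the plus-one rule and is
#' never 0. Per-chromosome two-sided empirical enrichment/depletion
#' p-values are also returned.
#'
#' @param psgGenes Character vector of gene ids (at least one).
#' @param geneChrom Gene universe with chromosomes ([GeneModelSet] or
#'   data.frame `gene_id`/`chrom`).
#' @param B Number of permutations; below 100 a warning is issued.
#' @param seed Integer seed.
#' @return list(observed_statistic, null_samples, empirical_p, B, seed,
#'   per_chrom) where `per_chrom` holds observed and expected counts plus
#'   two-sided empirical p per chromosome.
#' @export
permutationDistributionTest <- function(psgGenes, geneChrom, B = 10000,
                                        seed = 1) {
  stopifnot(length(psgGenes) >= 1)
  if (B < 100) {
    warning("B < 100 permutations: empirical p will be unstable")
  }
  map <- .geneChromMap(geneChrom)
  missing <- setdiff(psgGenes, map$gene_id)
  if (length(missing)) {
    stop("gene(s) without a chromosome assignment: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  chroms <- sort(unique(map$chrom))
  chromIdx <- match(map$chrom, chroms)
  nTot <- tabulate(chromIdx, nbins = length(chroms))
  nPsg <- length(psgGenes)
  obs <- tabulate(chromIdx[map$gene_id %in% psgGenes],
                  nbins = length(chroms))
  expd <- nPsg * nTot / sum(nTot)
  stat <- function(o) sum((o - expd)^2 / expd)
  obsStat <- stat(obs)
  set.seed(seed)
  nullCounts <- matrix(0L, B, length(chroms))
  nullStat <- numeric(B)
  for (b in seq_len(B)) {
    o <- tabulate(chromIdx[sample.int(nrow(map), nPsg)],
                  nbins = length(chroms))
    nullCounts[b, ] <- o
    nullStat[b] <- stat(o)
  }
  pEmp <- (1 + sum(nullStat >= obsStat)) / (B + 1)
  pHi <- (1 + colSums(nullCounts >= rep(obs, each = B))) / (B + 1)
  pLo <- (1 + colSums(nullCounts <= rep(obs, each = B))) / (B + 1)
  perChrom <- data.frame(chrom = chroms, observed = obs, expected = expd,
                         p_two_sided = pmin(1, 2 * pmin(pHi, pLo)))
  list(observed_statistic = obsStat, null_samples = nullStat,
       empirical_p = pEmp, B = B, seed = seed, per_chrom = perChrom)
}
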