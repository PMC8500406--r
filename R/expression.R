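## Expression-breadth classification over the six tissues, group comparison
## tests, WGT-retention stratification and per-chromosome summaries.

#' Classify tissue-specificity of expression
#'
#' A gene is expressed in a tissue iff its FPKM is at or above
#' `expressedThreshold`. Classes: `specific` (exactly one expressed
#' tissue), `constitutive` (all six), `silent` (none), `intermediate`
#' (two to five).
#'
#' @param mat Genes x six-tissue FPKM matrix (canonical columns, see
#'   [TISSUES]).
#' @param expressedThreshold FPKM threshold defining "expressed".
#' @return data.frame: `gene_id`, `class`, `specific_tissue` (NA unless
#'   specific), `n_expressed_tissues`.
#' @export
classifyTissuePattern <- function(mat, expressedThreshold = 1.0) {
  stopifnot(is.matrix(mat), identical(colnames(mat), TISSUES))
  expressed <- mat >= expressedThreshold
  nExpr <- rowSums(expressed)
  cls <- ifelse(nExpr == 0, "silent",
                ifelse(nExpr == 1, "specific",
                       ifelse(nExpr == 6, "constitutive", "intermediate")))
  specTissue <- rep(NA_character_, nrow(mat))
  one <- which(nExpr == 1)
  if (length(one)) {
    specTissue[one] <- TISSUES[max.col(expressed[one, , drop = FALSE])]
  }
  data.frame(gene_id = rownames(mat), class = cls,
             specific_tissue = specTissue, n_expressed_tissues = nExpr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare expression (or methylation) levels between gene groups
#'
#' @param groupA,groupB Numeric vectors. For `kruskal_wallis`, `groupA` may
#'   be a list of two or more groups (`groupB` ignored).
#' @param test `"mann_whitney"` (two-sided Wilcoxon rank-sum),
#'   `"kruskal_wallis"` (two-sided) or `"welch_t_one_sided"` (Welch t-test,
#'   direction given by `alternative`).
#' @param alternative Direction for the Welch test: `"greater"` tests
#'   groupA > groupB.
#' @return list(statistic, p, test).
#' @export
compareExpressionGroups <- function(groupA, groupB = NULL,
                                    test = c("mann_whitney",
                                             "kruskal_wallis",
                                             "welch_t_one_sided"),
                                    alternative = c("greater", "less")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  if (test == "kruskal_wallis") {
    groups <- if (is.list(groupA)) groupA else list(groupA, groupB)
    if (any(vapply(groups, length, integer(1)) < 2)) {
      stop("each group needs at least 2 values for the Kruskal-Wallis test")
    }
    kt <- stats::kruskal.test(groups)
    return(list(statistic = unname(kt$statistic), p = kt$p.value,
                test = test))
  }
  if (length(groupA) == 0 || length(groupB) == 0) {
    stop("empty group")
  }
  if (test == "mann_whitney") {
    wt <- suppressWarnings(stats::wilcox.test(groupA, groupB))
    return(list(statistic = unname(wt$statistic), p = wt$p.value,
                test = test))
  }
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs at least 2 values for the Welch t-test")
  }
  tt <- stats::t.test(groupA, groupB, alternative = alternative,
                      var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value, test = test)
}

#' Dunn-style post-hoc pairwise comparisons after a Kruskal-Wallis test
#'
#' Pairwise z statistics on mean ranks with tie correction,
#' Benjamini-Hochberg adjusted.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of the same length.
#' @return data.frame: `group1`, `group2`, `z`, `p`, `q`.
#' @export
posthocDunn <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  N <- length(values)
  r <- rank(values)
  tieTab <- table(values)
  tieCorr <- sum(tieTab^3 - tieTab) / (12 * (N - 1))
  meanRank <- tapply(r, groups, mean)
  nG <- table(groups)
  levs <- levels(groups)
  combs <- utils::combn(levs, 2)
  z <- apply(combs, 2, function(pair) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) *
                 (1 / nG[pair[1]] + 1 / nG[pair[2]]))
    (meanRank[pair[1]] - meanRank[pair[2]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = as.numeric(z),
             p = p, q = stats::p.adjust(p, "BH"), row.names = NULL)
}

#' Stratify the PSG proportion and PSG expression by WGT retention class
#'
#' For each whole-genome-triplication retention class (1, 2 or 3 copies
#' retained) reports the PSG fraction and the mean (+/- standard error)
#' FPKM of PSGs (averaged over the six tissues per gene), tests the 2 x 3
#' PSG-by-class count table with the Fisher exact test, and compares PSG
#' expression across classes with a Kruskal-Wallis test.
#'
#' @param results Screen results from [classifyPSG()].
#' @param retention data.frame `gene_id` / `retention_class` (1..3).
#' @param mat Six-tissue FPKM matrix.
#' @return list(summary, fisher_p, kw_p); classes with zero genes get an
#'   NA fraction and a flag.
#' @export
wgtRetentionAnalysis <- function(results, retention, mat) {
  stopifnot(all(c("gene_id", "retention_class") %in% names(retention)))
  m <- merge(results[, c("gene_id", "is_psg", "psg_status")], retention,
             by = "gene_id")
  classes <- 1:3
  nGenes <- vapply(classes, function(cl)
    sum(m$retention_class == cl), numeric(1))
  nPsg <- vapply(classes, function(cl)
    sum(m$retention_class == cl & m$is_psg), numeric(1))
  frac <- ifelse(nGenes > 0, nPsg / nGenes, NA_real_)
  meanExpr <- seExpr <- rep(NA_real_, 3)
  exprByClass <- vector("list", 3)
  for (cl in classes) {
    ids <- m$gene_id[m$retention_class == cl & m$is_psg]
    ids <- intersect(ids, rownames(mat))
    if (length(ids)) {
      v <- rowMeans(mat[ids, , drop = FALSE])
      exprByClass[[cl]] <- v
      meanExpr[cl] <- mean(v)
      seExpr[cl] <- stats::sd(v) / sqrt(length(v))
    }
  }
  summary <- data.frame(retention_class = classes, n_genes = nGenes,
                        n_psg = nPsg, psg_fraction = frac,
                        psg_percent = 100 * frac,
                        mean_psg_fpkm = meanExpr, se_psg_fpkm = seExpr,
                        flag = ifelse(nGenes == 0, "no_genes", ""))
  nonEmpty <- nGenes > 0
  fisherP <- if (sum(nonEmpty) >= 2 && sum(nPsg) > 0) {
    tab <- rbind(PSG = nPsg[nonEmpty],
                 `non-PSG` = (nGenes - nPsg)[nonEmpty])
    stats::fisher.test(tab)$p.value
  } else {
    NA_real_
  }
  filled <- Filter(function(v) length(v) >= 2, exprByClass)
  kwP <- if (length(filled) >= 2) {
    stats::kruskal.test(filled)$p.value
  } else {
    NA_real_
  }
  list(summary = summary, fisher_p = fisherP, kw_p = kwP)
}

#' Per-chromosome, per-tissue expression summaries
#'
#' Mean and median FPKM per chromosome and tissue for a gene group, plus a
#' Kruskal-Wallis test of per-gene mean FPKM across chromosomes (skipped
#' with a message when only one chromosome is present).
#'
#' @param mat Six-tissue FPKM matrix.
#' @param geneChrom [GeneModelSet] or data.frame `gene_id`/`chrom`.
#' @param genes Optional subset of gene ids (e.g. the PSG set).
#' @return list(summary, kw_p).
#' @export
expressionByChromosome <- function(mat, geneChrom, genes = NULL) {
  map <- .geneChromMap(geneChrom)
  if (!is.null(genes)) {
    map <- map[map$gene_id %in% genes, , drop = FALSE]
  }
  map <- map[map$gene_id %in% rownames(mat), , drop = FALSE]
  sub <- mat[map$gene_id, , drop = FALSE]
  rows <- list()
  for (ch in sort(unique(map$chrom))) {
    s <- sub[map$chrom == ch, , drop = FALSE]
    for (tis in TISSUES) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, tissue = tis, n_genes = nrow(s),
        mean_fpkm = mean(s[, tis]), median_fpkm = stats::median(s[, tis]))
    }
  }
  geneMeans <- rowMeans(sub)
  groups <- split(geneMeans, map$chrom)
  groups <- Filter(function(v) length(v) >= 2, groups)
  kwP <- if (length(groups) >= 2) {
    stats::kruskal.test(groups)$p.value
  } else {
    message("fewer than two chromosomes with >= 2 genes: ",
            "Kruskal-Wallis test skipped")
    NA_real_
  }
  list(summary = do.call(rbind, rows), kw_p = kwP)
}
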