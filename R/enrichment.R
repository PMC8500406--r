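## Hypergeometric term enrichment against a background universe, plus the
## six-family contingency analysis of the PSG set.

#' The six gene families of the family contingency analysis
#' @export
GENE_FAMILIES <- c("R", "kinase", "TF", "flower", "auxin", "glucosinolate")

#' Hypergeometric term enrichment
#'
#' For each term with `K` background genes, of which `k` fall in the study
#' set of size `n` drawn from a background of size `N`, the
#' over-representation p-value is the hypergeometric upper tail
#' \eqn{P(X \ge k)}. p-values are adjusted across all tested terms with the
#' Benjamini-Hochberg step-up procedure. Depletion (lower-tail) p-values are
#' available behind `alternative = "under"`.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param terms Annotation map in long format (`term_id`, `term_name`,
#'   `gene_id`), as from [readAnnotationMap()]. Term genes must lie in the
#'   background.
#' @param alternative `"over"` (default) or `"under"`.
#' @return data.frame with one row per term: `term_id`, `term_name`, `k`,
#'   `n`, `K`, `N`, `p`, `q`, sorted by `q` then `p`.
#' @export
hypergeometricEnrichment <- function(study, background, terms,
                                     alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  study <- unique(study)
  background <- unique(background)
  bad <- setdiff(study, background)
  if (length(bad)) {
    stop("study gene(s) not in background: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  badT <- setdiff(terms$gene_id, background)
  if (length(badT)) {
    stop("annotation gene(s) not in background: ",
         paste(utils::head(badT, 5), collapse = ", "))
  }
  N <- length(background)
  n <- length(study)
  byTerm <- split(terms$gene_id, terms$term_id)
  termNames <- terms$term_name[!duplicated(terms$term_id)]
  names(termNames) <- terms$term_id[!duplicated(terms$term_id)]
  K <- vapply(byTerm, function(g) length(unique(g)), numeric(1))
  k <- vapply(byTerm, function(g) length(intersect(unique(g), study)),
              numeric(1))
  p <- if (alternative == "over") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  out <- data.frame(term_id = names(byTerm),
                    term_name = unname(termNames[names(byTerm)]),
                    k = k, n = n, K = K, N = N, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$q, out$p), ]
}

#' Gene-family contingency analysis of the PSG set
#'
#' Builds the 2 x F PSG / non-PSG count table over the gene families
#' (default the six canonical families: R genes, protein kinases,
#' transcription factors, flower genes, auxin genes, glucosinolate genes;
#' genes without a family are excluded), runs the chi-square and
#' Monte-Carlo Fisher tests, and reports the transcription-factor share of
#' family-assigned PSGs.
#'
#' @param results Screen results from [classifyPSG()], or a character
#'   vector of PSG gene ids together with `universe`.
#' @param familyMap data.frame with `gene_id` and `family`.
#' @param families Ordered family set; columns of the table.
#' @param tfFamily The family whose PSG share is reported.
#' @param B,seed Monte-Carlo Fisher parameters.
#' @param universe Optional character vector of all genes (needed when
#'   `results` is a plain PSG id vector).
#' @return list(table, chisq, fisher, tf_share_percent).
#' @export
familyContingency <- function(results, familyMap, families = GENE_FAMILIES,
                              tfFamily = "TF", B = 2000, seed = 1,
                              universe = NULL) {
  stopifnot(all(c("gene_id", "family") %in% names(familyMap)))
  if (is.data.frame(results)) {
    psg <- results$gene_id[results$psg_status == "PSG"]
  } else {
    psg <- as.character(results)
  }
  fm <- familyMap[familyMap$family %in% families, , drop = FALSE]
  if (nrow(fm) == 0) {
    stop("no genes carry one of the requested families")
  }
  isPsg <- fm$gene_id %in% psg
  fam <- factor(fm$family, levels = families)
  tab <- rbind(PSG = tapply(isPsg, fam, sum, default = 0),
               `non-PSG` = tapply(!isPsg, fam, sum, default = 0))
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2) {
    stop("fewer than two families with genes: contingency test undefined")
  }
  chisq <- contingencyChisq(tab)
  fisher <- contingencyFisher(tab, B = B, seed = seed, method = "mc")
  kTF <- if (tfFamily %in% colnames(tab)) tab["PSG", tfFamily] else 0
  tfShare <- 100 * kTF / sum(tab["PSG", ])
  list(table = tab, chisq = chisq, fisher = fisher,
       tf_share_percent = tfShare)
}

#' The published six-family PSG contingency table
#'
#' The 2 x 6 table of PSG and non-PSG counts across R genes, protein
#' kinases, transcription factors, flower genes, auxin genes and
#' glucosinolate genes used by the family contingency analysis.
#'
#' @return 2 x 6 integer matrix with family columns.
#' @export
familyTableBrassica <- function() {
  tab <- rbind(PSG = c(2, 1, 76, 1, 9, 0),
               `non-PSG` = c(54, 817, 2301, 95, 199, 65))
  colnames(tab) <- GENE_FAMILIES
  tab
}
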