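## Genic-region methylation profiling: five-region partition of each gene,
## read-weighted methylation per region x context, TE-overlap
## stratification and methylation-expression correlation.

#' Partition genes into the five genic regions
#'
#' Splits every gene into promoter (the `promoterLength` bp immediately 5'
#' of the transcription start, strand-aware, truncated at the chromosome
#' start with a warning), UTR5 (exonic sequence 5' of the CDS), exon
#' (CDS-overlapping exon segments), intron (gaps between exons) and UTR3.
#' UTR5, exon, intron and UTR3 tile the transcript span exactly; the
#' promoter lies outside it.
#'
#' @param models A [GeneModelSet].
#' @param promoterLength Promoter length in bp.
#' @return A GRanges with one range per region interval and metadata
#'   columns `gene_id` and `region` (levels [GENE_REGIONS]).
#' @export
partitionGeneRegions <- function(models, promoterLength = 2000) {
  stopifnot(is(models, "GeneModelSet"), promoterLength >= 0)
  tx <- transcripts(models)
  ids <- geneIds(models)
  chrAll <- as.character(GenomicRanges::seqnames(tx))
  strandAll <- as.character(GenomicRanges::strand(tx))
  txStartAll <- GenomicRanges::start(tx)
  txEndAll <- GenomicRanges::end(tx)
  exAll <- exonsByGene(models)
  cdAll <- cdsByGene(models)
  acc <- list(chr = list(), start = list(), end = list(),
              strand = list(), gene = list(), region = list())
  truncated <- character(0)
  for (k in seq_along(tx)) {
    gid <- ids[k]
    chr <- chrAll[k]
    strand <- strandAll[k]
    txStart <- txStartAll[k]
    txEnd <- txEndAll[k]
    ex <- IRanges::ranges(exAll[[k]])
    cd <- IRanges::ranges(cdAll[k])
    cdsIR <- IRanges::IRanges(IRanges::start(cd), IRanges::end(cd))

    exonReg <- IRanges::intersect(ex, cdsIR)
    upstream <- IRanges::IRanges(txStart, max(txStart, IRanges::start(cd) - 1))
    if (IRanges::start(cd) == txStart) upstream <- IRanges::IRanges()
    downstream <- if (IRanges::end(cd) == txEnd) IRanges::IRanges() else
      IRanges::IRanges(IRanges::end(cd) + 1, txEnd)
    lowUTR <- IRanges::intersect(ex, upstream)
    highUTR <- IRanges::intersect(ex, downstream)
    if (strand == "+") {
      utr5 <- lowUTR
      utr3 <- highUTR
    } else {
      utr5 <- highUTR
      utr3 <- lowUTR
    }
    intron <- IRanges::setdiff(IRanges::IRanges(txStart, txEnd), ex)
    if (promoterLength > 0) {
      if (strand == "+") {
        pStart <- txStart - promoterLength
        pEnd <- txStart - 1
      } else {
        pStart <- txEnd + 1
        pEnd <- txEnd + promoterLength
      }
      if (pStart < 1) {
        truncated <- c(truncated, gid)
        pStart <- 1
      }
      promoter <- if (pEnd >= pStart) IRanges::IRanges(pStart, pEnd) else
        IRanges::IRanges()
    } else {
      promoter <- IRanges::IRanges()
    }
    regs <- list(promoter = promoter, UTR5 = utr5, exon = exonReg,
                 intron = intron, UTR3 = utr3)
    for (rn in names(regs)) {
      ir <- regs[[rn]]
      if (length(ir) == 0) next
      i <- length(acc$chr) + 1L
      acc$chr[[i]] <- rep(chr, length(ir))
      acc$start[[i]] <- IRanges::start(ir)
      acc$end[[i]] <- IRanges::end(ir)
      acc$strand[[i]] <- rep(strand, length(ir))
      acc$gene[[i]] <- rep(gid, length(ir))
      acc$region[[i]] <- rep(rn, length(ir))
    }
  }
  if (length(truncated)) {
    warning("promoter truncated at chromosome start for gene(s): ",
            paste(utils::head(truncated, 5), collapse = ", "))
  }
  if (length(acc$chr) == 0) {
    return(GenomicRanges::GRanges())
  }
  res <- GenomicRanges::GRanges(
    factor(unlist(acc$chr), levels = GenomeInfoDb::seqlevels(tx)),
    IRanges::IRanges(unlist(acc$start), unlist(acc$end)),
    strand = unlist(acc$strand),
    gene_id = unlist(acc$gene),
    region = factor(unlist(acc$region), levels = GENE_REGIONS))
  res
}

#' Weighted methylation level over a set of intervals
#'
#' The weighted methylation level is the ratio of summed methylated reads
#' to summed total reads over the cytosines of the requested context that
#' fall inside the intervals (read-weighted, not a per-site average).
#'
#' @param calls Methylation calls GRanges (see [readCytosineReport()]).
#' @param intervals GRanges of intervals to aggregate over.
#' @param context One of [METH_CONTEXTS].
#' @return list(level, methylated_reads, total_reads, n_sites); `level` is
#'   NA when no reads cover the intervals.
#' @export
weightedMethylation <- function(calls, intervals, context) {
  stopifnot(context %in% METH_CONTEXTS)
  sel <- calls[as.character(calls$context) == context]
  hit <- IRanges::overlapsAny(sel, intervals, ignore.strand = TRUE)
  sel <- sel[hit]
  tot <- sum(sel$total)
  list(level = if (tot > 0) sum(sel$meth) / tot else NA_real_,
       methylated_reads = sum(sel$meth), total_reads = tot,
       n_sites = length(sel))
}

#' Per-gene region x context methylation profiles
#'
#' Computes the full 5-region x 3-context read-weighted methylation profile
#' for every gene covered by `regions`.
#'
#' @param calls Methylation calls GRanges.
#' @param regions Region GRanges from [partitionGeneRegions()].
#' @param contexts Contexts to profile.
#' @return data.frame: `gene_id`, `region`, `context`, `methylated_reads`,
#'   `total_reads`, `n_sites`, `level` (NA where total_reads is 0).
#' @export
profileGenes <- function(calls, regions, contexts = METH_CONTEXTS) {
  genes <- unique(regions$gene_id)
  grid <- expand.grid(gene_id = genes, region = GENE_REGIONS,
                      context = contexts, stringsAsFactors = FALSE)
  grid$methylated_reads <- 0
  grid$total_reads <- 0
  grid$n_sites <- 0L
  ov <- GenomicRanges::findOverlaps(calls, regions, ignore.strand = TRUE)
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    key <- paste(regions$gene_id[si], as.character(regions$region[si]),
                 as.character(calls$context[qi]), sep = "\r")
    meth <- tapply(calls$meth[qi], key, sum)
    tot <- tapply(calls$total[qi], key, sum)
    nsite <- tapply(rep(1L, length(qi)), key, sum)
    gkey <- paste(grid$gene_id, grid$region, grid$context, sep = "\r")
    idx <- match(names(meth), gkey)
    ok <- !is.na(idx)
    grid$methylated_reads[idx[ok]] <- meth[ok]
    grid$total_reads[idx[ok]] <- tot[ok]
    grid$n_sites[idx[ok]] <- nsite[ok]
  }
  grid$level <- ifelse(grid$total_reads > 0,
                       grid$methylated_reads / grid$total_reads, NA_real_)
  grid
}

#' Compare methylation between two gene groups per region and context
#'
#' For every region x context cell, compares the per-gene weighted
#' methylation levels of the study group (e.g. PSGs) against the background
#' group, delegating to [compareExpressionGroups()]. Cells where either
#' group has fewer than two genes with defined levels are skipped (NA p).
#'
#' @param profiles Profiles from [profileGenes()].
#' @param study,background Character vectors of gene ids.
#' @param test,alternative Passed to [compareExpressionGroups()].
#' @return data.frame: `region`, `context`, group sizes, mean levels, `p`.
#' @export
compareMethylationGroups <- function(profiles, study, background,
                                     test = "welch_t_one_sided",
                                     alternative = "greater") {
  rows <- list()
  for (rg in GENE_REGIONS) {
    for (cx in unique(profiles$context)) {
      sub <- profiles[profiles$region == rg & profiles$context == cx, ]
      a <- sub$level[sub$gene_id %in% study & !is.na(sub$level)]
      b <- sub$level[sub$gene_id %in% background & !is.na(sub$level)]
      p <- stat <- NA_real_
      if (length(a) >= 2 && length(b) >= 2) {
        r <- compareExpressionGroups(a, b, test = test,
                                     alternative = alternative)
        p <- r$p
        stat <- r$statistic
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, context = cx, n_study = length(a),
        n_background = length(b), mean_study = mean(a),
        mean_background = mean(b), statistic = stat, p = p)
    }
  }
  do.call(rbind, rows)
}

#' Stratify region methylation by transposable-element overlap
#'
#' For every region x context cell, splits genes by whether that gene's
#' region intervals share at least one base with a TE, and compares the
#' weighted methylation levels of the two strata with a Kruskal-Wallis
#' test. Adjacent-but-not-overlapping TEs (half-open BED adjacency) do not
#' count as overlap.
#'
#' @param profiles Profiles from [profileGenes()].
#' @param regions Region GRanges from [partitionGeneRegions()].
#' @param teIntervals TE GRanges (same chromosome namespace).
#' @return data.frame per region x context: group sizes, mean levels of
#'   genes with and without TE overlap, their difference, and the KW p
#'   (NA, flagged, when a stratum is empty or too small).
#' @export
teOverlapStratification <- function(profiles, regions, teIntervals) {
  hasTE <- IRanges::overlapsAny(regions, teIntervals, ignore.strand = TRUE)
  ovKey <- unique(paste(regions$gene_id[hasTE],
                        as.character(regions$region[hasTE]), sep = "\r"))
  rows <- list()
  for (rg in GENE_REGIONS) {
    for (cx in unique(profiles$context)) {
      sub <- profiles[profiles$region == rg & profiles$context == cx, ]
      withTE <- paste(sub$gene_id, rg, sep = "\r") %in% ovKey
      a <- sub$level[withTE & !is.na(sub$level)]
      b <- sub$level[!withTE & !is.na(sub$level)]
      p <- NA_real_
      flag <- ""
      if (length(a) >= 2 && length(b) >= 2) {
        p <- stats::kruskal.test(list(a, b))$p.value
      } else {
        flag <- "insufficient_group"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, context = cx, n_with_te = length(a),
        n_without_te = length(b),
        mean_with_te = if (length(a)) mean(a) else NA_real_,
        mean_without_te = if (length(b)) mean(b) else NA_real_,
        difference = (if (length(a)) mean(a) else NA_real_) -
          (if (length(b)) mean(b) else NA_real_),
        p = p, flag = flag)
    }
  }
  do.call(rbind, rows)
}

#' Spearman correlation of gene methylation with gene expression
#'
#' Correlates per-gene read-weighted methylation (over the chosen regions
#' and context) with per-gene mean FPKM over the six tissues.
#'
#' @param profiles Profiles from [profileGenes()].
#' @param mat Six-tissue FPKM matrix.
#' @param context Methylation context.
#' @param regions Region scope over which reads are pooled.
#' @return list(rho, p, n). Fewer than 3 genes with both quantities defined
#'   is an error.
#' @export
methylationExpressionCorrelation <- function(profiles, mat, context = "CG",
                                             regions = GENE_REGIONS) {
  sub <- profiles[profiles$context == context &
                    profiles$region %in% regions, ]
  meth <- tapply(sub$methylated_reads, sub$gene_id, sum)
  tot <- tapply(sub$total_reads, sub$gene_id, sum)
  level <- ifelse(tot > 0, meth / tot, NA_real_)
  common <- intersect(names(level)[!is.na(level)], rownames(mat))
  if (length(common) < 3) {
    stop("fewer than 3 genes with both methylation and expression defined")
  }
  expr <- rowMeans(mat[common, , drop = FALSE])
  ct <- suppressWarnings(stats::cor.test(level[common], expr,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common))
}
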