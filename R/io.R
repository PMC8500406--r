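## Readers and writers for every external format the pipeline touches.
## Coordinate conventions: GFF3 is 1-based inclusive, BED is 0-based
## half-open; both are converted by rtracklayer into 1-based closed GRanges,
## the convention used throughout the package.

#' The six canonical tissue labels
#'
#' Expression matrices must carry exactly these six tissues; extra columns
#' are rejected rather than ignored so configuration errors surface early.
#' @export
TISSUES <- c("root", "stem", "leaf", "flower", "silique", "callus")

#' The five genic regions
#' @export
GENE_REGIONS <- c("promoter", "UTR5", "exon", "intron", "UTR3")

#' The three cytosine methylation contexts
#' @export
METH_CONTEXTS <- c("CG", "CHG", "CHH")

# TSV writer with a comment block recording parameters
.writeTSV <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(params)) {
    writeLines(sprintf("# %s: %s", nm, paste(params[[nm]], collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTSV <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Read paired ortholog coding sequences from two FASTA files
#'
#' @param pathA,pathB FASTA files with the coding sequences of the focal and
#'   the comparison genome.
#' @param pairing A data.frame (or path to a TSV) with columns `gene_a` and
#'   `gene_b`, optionally `pair_id`.
#' @return An [OrthologPairSet], one pair per pairing row. Sequences are
#'   upper-cased. A sequence absent from its FASTA, a length mismatch within
#'   a pair, or a length not divisible by 3 is an error naming the offender.
#' @export
readOrthologPairs <- function(pathA, pathB, pairing) {
  fa <- Biostrings::readDNAStringSet(pathA)
  fb <- Biostrings::readDNAStringSet(pathB)
  names(fa) <- sub("\\s.*$", "", names(fa))
  names(fb) <- sub("\\s.*$", "", names(fb))
  if (is.character(pairing)) pairing <- .readTSV(pairing)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairing)))
  missA <- setdiff(pairing$gene_a, names(fa))
  missB <- setdiff(pairing$gene_b, names(fb))
  if (length(missA) || length(missB)) {
    stop("sequence(s) absent from FASTA: ",
         paste(c(missA, missB), collapse = ", "))
  }
  sa <- toupper(as.character(fa[pairing$gene_a]))
  sb <- toupper(as.character(fb[pairing$gene_b]))
  mism <- nchar(sa) != nchar(sb)
  if (any(mism)) {
    stop("length mismatch for pair(s): ",
         paste(pairing$gene_a[mism], pairing$gene_b[mism],
               sep = "/", collapse = ", "))
  }
  bad <- nchar(sa) %% 3 != 0
  if (any(bad)) {
    stop("sequence length not divisible by 3 (trailing incomplete codon?) ",
         "for pair(s): ", paste(pairing$gene_a[bad], collapse = ", "))
  }
  OrthologPairSet(pairId = pairing$pair_id, geneA = pairing$gene_a,
                  geneB = pairing$gene_b, seqA = sa, seqB = sb)
}

#' Write an OrthologPairSet to two FASTA files and a pairing table
#'
#' @param x An [OrthologPairSet].
#' @param pathA,pathB,pairingPath Output paths.
#' @export
writeOrthologPairs <- function(x, pathA, pathB, pairingPath) {
  stopifnot(is(x, "OrthologPairSet"))
  Biostrings::writeXStringSet(seqA(x), pathA)
  Biostrings::writeXStringSet(seqB(x), pathB)
  .writeTSV(data.frame(pair_id = pairIds(x), gene_a = geneIdsA(x),
                       gene_b = geneIdsB(x)), pairingPath)
  invisible(x)
}

.emptyGeneModelSet <- function() {
  GeneModelSet(transcripts = GenomicRanges::GRanges(gene_id = character(0)),
               exons = GenomicRanges::GRangesList(),
               cds = GenomicRanges::GRanges())
}

#' Read gene models from a GFF3 file
#'
#' Builds one [GeneModelSet] entry per gene from gene/mRNA/exon/CDS features
#' (first mRNA when a gene has several). GFF3 coordinates are 1-based
#' inclusive and are kept as such in the returned GRanges.
#'
#' @param path A GFF3 file.
#' @return A [GeneModelSet]; empty for a feature-less file.
#' @export
readGeneModels <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) GenomicRanges::GRanges())
  if (length(gr) == 0) {
    return(.emptyGeneModelSet())
  }
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0) {
    stop("no gene features in ", path)
  }
  if (any(as.character(GenomicRanges::strand(genes)) == "*")) {
    stop("gene(s) with unknown strand in ", path)
  }
  mrna <- gr[type %in% c("mRNA", "transcript")]
  exons <- gr[type == "exon"]
  cds <- gr[type == "CDS"]
  firstParent <- function(x) vapply(as.list(x$Parent), `[`, character(1), 1)
  geneIds <- as.character(genes$ID)
  txList <- vector("list", length(genes))
  exList <- vector("list", length(genes))
  cdsList <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    gid <- geneIds[k]
    m <- mrna[firstParent(mrna) == gid]
    if (length(m) >= 1) {
      m <- m[1]
      txId <- as.character(m$ID)
    } else {
      m <- genes[k]
      txId <- gid
    }
    ex <- exons[firstParent(exons) %in% c(txId, gid)]
    if (length(ex) == 0) ex <- m  # single-exon fallback: whole transcript
    ex <- GenomicRanges::sort(ex)
    cd <- cds[firstParent(cds) %in% c(txId, gid)]
    cdRange <- if (length(cd)) range(GenomicRanges::granges(cd)) else
      GenomicRanges::granges(m)
    if (GenomicRanges::start(cdRange) < GenomicRanges::start(m) ||
        GenomicRanges::end(cdRange) > GenomicRanges::end(m)) {
      stop("CDS outside the transcript span for gene ", gid)
    }
    tx <- GenomicRanges::granges(m)
    tx$gene_id <- gid
    txList[[k]] <- tx
    exList[[k]] <- GenomicRanges::granges(ex)
    cdsList[[k]] <- cdRange
  }
  tx <- do.call(c, txList)
  exl <- GenomicRanges::GRangesList(exList)
  names(exl) <- geneIds
  cdg <- do.call(c, cdsList)
  names(cdg) <- geneIds
  GeneModelSet(transcripts = tx, exons = exl, cds = cdg)
}

#' Write a GeneModelSet as GFF3
#'
#' @param models A [GeneModelSet].
#' @param path Output GFF3 path.
#' @export
writeGeneModels <- function(models, path) {
  stopifnot(is(models, "GeneModelSet"))
  tx <- transcripts(models)
  ids <- geneIds(models)
  feats <- list()
  for (k in seq_along(tx)) {
    gid <- ids[k]
    g <- GenomicRanges::granges(tx[k])
    g$type <- "gene"
    g$ID <- gid
    m <- GenomicRanges::granges(tx[k])
    m$type <- "mRNA"
    m$ID <- paste0(gid, ".1")
    m$Parent <- gid
    ex <- exonsByGene(models)[[k]]
    ex <- GenomicRanges::granges(ex)
    if (length(ex)) {
      ex$type <- "exon"
      ex$ID <- paste0(gid, ".1.exon", seq_along(ex))
      ex$Parent <- paste0(gid, ".1")
    }
    cd <- GenomicRanges::granges(cdsByGene(models)[k])
    cd$type <- "CDS"
    cd$ID <- paste0(gid, ".1.cds")
    cd$Parent <- paste0(gid, ".1")
    feats[[k]] <- c(g, m, ex, cd)
  }
  out <- do.call(c, feats)
  out$source <- "PSGscreen"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read transposable-element intervals from a BED file
#'
#' BED coordinates are 0-based half-open and are converted to the 1-based
#' closed GRanges convention on read, so a BED record `Chr1 0 10` covers
#' 1-based positions 1..10.
#'
#' @param path A BED3+ file.
#' @return A GRanges of TE intervals. Records with start >= end are an error.
#' @export
readTEIntervals <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (any(raw[[2]] >= raw[[3]])) {
    stop("BED interval with start >= end at line(s): ",
         paste(which(raw[[2]] >= raw[[3]]), collapse = ", "))
  }
  rtracklayer::import(path, format = "bed")
}

#' Write TE intervals as BED
#'
#' @param te A GRanges.
#' @param path Output BED path.
#' @export
writeTEIntervals <- function(te, path) {
  rtracklayer::export(te, path, format = "bed")
  invisible(path)
}

#' Read per-cytosine methylation calls (Bismark-style cytosine report)
#'
#' Expects a headerless TSV with columns chromosome, 1-based position,
#' strand, methylated count, unmethylated count, context (CG/CHG/CHH); a
#' seventh trinucleotide column, as in Bismark CX reports, is ignored.
#' Rows with zero total reads are retained and flagged uncovered.
#'
#' @param path Cytosine report path.
#' @return A GRanges (width-1 ranges) with metadata columns `context`,
#'   `meth`, `total` and `covered`.
#' @export
readCytosineReport <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(raw) < 6) {
    stop("cytosine report needs at least 6 columns")
  }
  ctx <- as.character(raw[[6]])
  bad <- !ctx %in% METH_CONTEXTS
  if (any(bad)) {
    stop("unknown methylation context token(s): ",
         paste(unique(ctx[bad]), collapse = ", "))
  }
  meth <- as.numeric(raw[[4]])
  unmeth <- as.numeric(raw[[5]])
  if (any(meth < 0 | unmeth < 0)) {
    stop("negative read counts in cytosine report")
  }
  gr <- GenomicRanges::GRanges(raw[[1]],
                               IRanges::IRanges(raw[[2]], width = 1),
                               strand = raw[[3]])
  gr$context <- factor(ctx, levels = METH_CONTEXTS)
  gr$meth <- meth
  gr$total <- meth + unmeth
  gr$covered <- gr$total > 0
  gr
}

#' Write methylation calls as a cytosine report
#'
#' @param calls GRanges as returned by [readCytosineReport()].
#' @param path Output path.
#' @export
writeCytosineReport <- function(calls, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(calls)),
                   GenomicRanges::start(calls),
                   as.character(GenomicRanges::strand(calls)),
                   calls$meth, calls$total - calls$meth,
                   as.character(calls$context))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a six-tissue FPKM expression matrix
#'
#' The TSV must have a `gene_id` column plus exactly the six canonical
#' tissue columns ([TISSUES]); extra columns are rejected, not ignored.
#'
#' @param path Expression TSV path.
#' @return Numeric matrix, genes x tissues (canonical column order).
#' @export
readExpressionMatrix <- function(path) {
  df <- .readTSV(path)
  if (!"gene_id" %in% names(df)) {
    stop("expression table needs a gene_id column")
  }
  extra <- setdiff(names(df), c("gene_id", TISSUES))
  if (length(extra)) {
    stop("unexpected expression column(s): ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(TISSUES, names(df))
  if (length(missing)) {
    stop("missing tissue column(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(df[, TISSUES])
  rownames(m) <- df$gene_id
  if (any(m < 0)) {
    stop("negative FPKM values")
  }
  m
}

#' Write an expression matrix as TSV
#' @param mat Genes x tissues matrix.
#' @param path Output path.
#' @export
writeExpressionMatrix <- function(mat, path) {
  .writeTSV(data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
            path)
}

#' Read a term annotation map (term_id, term_name, gene_id)
#' @param path Annotation TSV path.
#' @return data.frame in long format.
#' @export
readAnnotationMap <- function(path) {
  df <- .readTSV(path)
  stopifnot(all(c("term_id", "term_name", "gene_id") %in% names(df)))
  df
}

#' Read whole-genome-triplication retention classes
#'
#' @param path TSV with columns `gene_id` and `retention_class` (1, 2 or 3
#'   copies retained after the triplication).
#' @return data.frame with validated classes.
#' @export
readRetentionClasses <- function(path) {
  df <- .readTSV(path)
  stopifnot(all(c("gene_id", "retention_class") %in% names(df)))
  if (!all(df$retention_class %in% 1:3)) {
    stop("retention_class must be 1, 2 or 3")
  }
  df$retention_class <- as.integer(df$retention_class)
  df
}
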