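#' OrthologPairSet: paired in-frame coding sequences
#'
#' Container for a set of ortholog gene pairs, each holding an in-frame codon
#' alignment of the two coding sequences. This is the unit of Ka/Ks
#' estimation. Sequences are stored as [Biostrings::DNAStringSet] objects;
#' per pair the two sequences must have equal length divisible by 3, and may
#' contain A, C, G, T, N or the gap character.
#'
#' @slot pairId character, unique pair identifiers.
#' @slot geneA,geneB character, gene identifiers in the focal and the
#'   comparison genome.
#' @slot seqA,seqB [Biostrings::DNAStringSet] of equal-width in-frame
#'   sequences.
#' @aliases OrthologPairSet-class
#' @importClassesFrom Biostrings DNAStringSet
#' @exportClass OrthologPairSet
setClass("OrthologPairSet",
  representation(pairId = "character", geneA = "character",
                 geneB = "character", seqA = "DNAStringSet",
                 seqB = "DNAStringSet"))

setValidity("OrthologPairSet", function(object) {
  msg <- character(0)
  n <- length(object@pairId)
  if (length(object@geneA) != n || length(object@geneB) != n ||
      length(object@seqA) != n || length(object@seqB) != n) {
    msg <- c(msg, "slot lengths differ")
  }
  if (anyDuplicated(object@pairId)) {
    msg <- c(msg, "duplicated pair ids")
  }
  if (n > 0) {
    wa <- Biostrings::width(object@seqA)
    wb <- Biostrings::width(object@seqB)
    if (any(wa != wb)) {
      bad <- object@pairId[wa != wb][1]
      msg <- c(msg, paste0("length mismatch between sequences of pair ", bad))
    }
    if (any(wa %% 3 != 0)) {
      bad <- object@pairId[wa %% 3 != 0][1]
      msg <- c(msg, paste0("sequence length not divisible by 3 for pair ", bad))
    }
    alph <- Biostrings::alphabetFrequency(object@seqA, collapse = TRUE) +
      Biostrings::alphabetFrequency(object@seqB, collapse = TRUE)
    allowed <- c("A", "C", "G", "T", "N", "-")
    if (sum(alph) > sum(alph[allowed])) {
      msg <- c(msg, "sequences contain letters outside {A,C,G,T,N,-}")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OrthologPairSet
#'
#' @param pairId Character vector of unique pair identifiers; derived from
#'   `geneA`/`geneB` when omitted.
#' @param geneA,geneB Gene identifiers.
#' @param seqA,seqB In-frame coding sequences, as character vectors or
#'   [Biostrings::DNAStringSet]; per pair the two must have equal length
#'   divisible by 3.
#' @return An [OrthologPairSet].
#' @examples
#' ops <- OrthologPairSet(geneA = "g1", geneB = "h1",
#'                        seqA = "ATGGCT", seqB = "ATGGCC")
#' @export
OrthologPairSet <- function(pairId = NULL, geneA, geneB, seqA, seqB) {
  if (is.null(pairId)) {
    pairId <- paste(geneA, geneB, sep = "|")
  }
  if (is.character(seqA)) seqA <- Biostrings::DNAStringSet(toupper(seqA))
  if (is.character(seqB)) seqB <- Biostrings::DNAStringSet(toupper(seqB))
  names(seqA) <- geneA
  names(seqB) <- geneB
  new("OrthologPairSet", pairId = as.character(pairId),
      geneA = as.character(geneA), geneB = as.character(geneB),
      seqA = seqA, seqB = seqB)
}

#' @describeIn OrthologPairSet number of pairs
#' @param x An OrthologPairSet.
#' @export
setMethod("length", "OrthologPairSet", function(x) length(x@pairId))

#' @describeIn OrthologPairSet subset pairs by index, logical or pair id
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "OrthologPairSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@pairId)
  new("OrthologPairSet", pairId = x@pairId[i], geneA = x@geneA[i],
      geneB = x@geneB[i], seqA = x@seqA[i], seqB = x@seqB[i])
})

setMethod("show", "OrthologPairSet", function(object) {
  cat("OrthologPairSet with", length(object), "pair(s)\n")
  if (length(object)) {
    w <- Biostrings::width(object@seqA)
    cat("  alignment widths:", min(w), "-", max(w), "nt (",
        min(w) %/% 3, "-", max(w) %/% 3, "codons )\n")
    k <- min(3L, length(object))
    for (i in seq_len(k)) {
      cat("  ", object@pairId[i], ": ", object@geneA[i], " vs ",
          object@geneB[i], "\n", sep = "")
    }
    if (length(object) > k) cat("  ...\n")
  }
})

#' @rdname OrthologPairSet
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))
#' @describeIn OrthologPairSet pair identifiers
#' @export
setMethod("pairIds", "OrthologPairSet", function(x) x@pairId)

#' @rdname OrthologPairSet
#' @export
setGeneric("geneIdsA", function(x) standardGeneric("geneIdsA"))
#' @describeIn OrthologPairSet gene ids of the focal genome
#' @export
setMethod("geneIdsA", "OrthologPairSet", function(x) x@geneA)

#' @rdname OrthologPairSet
#' @export
setGeneric("geneIdsB", function(x) standardGeneric("geneIdsB"))
#' @describeIn OrthologPairSet gene ids of the comparison genome
#' @export
setMethod("geneIdsB", "OrthologPairSet", function(x) x@geneB)

#' @rdname OrthologPairSet
#' @export
setGeneric("seqA", function(x) standardGeneric("seqA"))
#' @describeIn OrthologPairSet coding sequences of the focal genome
#' @export
setMethod("seqA", "OrthologPairSet", function(x) x@seqA)

#' @rdname OrthologPairSet
#' @export
setGeneric("seqB", function(x) standardGeneric("seqB"))
#' @describeIn OrthologPairSet coding sequences of the comparison genome
#' @export
setMethod("seqB", "OrthologPairSet", function(x) x@seqB)

#' GeneModelSet: gene models with exon/CDS structure
#'
#' Transcript spans, exon structure and CDS extent for a set of genes,
#' stored as GenomicRanges objects (1-based closed coordinates, the
#' Bioconductor convention; BED input is converted on read). One model per
#' gene (the first mRNA when a gene has several).
#'
#' @slot transcripts [GenomicRanges::GRanges] of transcript spans with
#'   metadata column `gene_id`.
#' @slot exons [GenomicRanges::GRangesList] of exons per gene, named by
#'   gene id, sorted by start.
#' @slot cds [GenomicRanges::GRanges] of the CDS span (one range per gene,
#'   named by gene id).
#' @aliases GeneModelSet-class
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(transcripts = "GRanges", exons = "GRangesList",
                 cds = "GRanges"))

setValidity("GeneModelSet", function(object) {
  msg <- character(0)
  ids <- object@transcripts$gene_id
  n <- length(object@transcripts)
  if (is.null(ids) || anyDuplicated(ids)) {
    msg <- c(msg, "transcripts need a unique gene_id column")
  }
  if (length(object@exons) != n || length(object@cds) != n) {
    msg <- c(msg, "exons and cds must have one entry per transcript")
  } else if (n > 0) {
    if (!identical(names(object@exons), ids) ||
        !identical(names(object@cds), ids)) {
      msg <- c(msg, "exons/cds names must match transcript gene_ids")
    }
    nEx <- S4Vectors::elementNROWS(object@exons)
    if (any(nEx == 0)) {
      msg <- c(msg, paste0("gene ", ids[nEx == 0][1], " has no exons"))
    } else {
      exU <- unlist(object@exons, use.names = FALSE)
      grp <- rep(seq_len(n), nEx)
      exS <- GenomicRanges::start(exU)
      exE <- GenomicRanges::end(exU)
      same <- grp[-1] == grp[-length(grp)]
      if (length(same) && any(same & exS[-1] <= exE[-length(exE)])) {
        bad <- grp[-1][same & exS[-1] <= exE[-length(exE)]][1]
        msg <- c(msg, paste0("exons of gene ", ids[bad],
                             " overlap or are unsorted"))
      }
      txS <- GenomicRanges::start(object@transcripts)[grp]
      txE <- GenomicRanges::end(object@transcripts)[grp]
      if (any(exS < txS | exE > txE)) {
        bad <- grp[exS < txS | exE > txE][1]
        msg <- c(msg, paste0("exons of gene ", ids[bad],
                             " extend beyond the transcript span"))
      }
      cdS <- GenomicRanges::start(object@cds)
      cdE <- GenomicRanges::end(object@cds)
      badCds <- cdS < GenomicRanges::start(object@transcripts) |
        cdE > GenomicRanges::end(object@transcripts)
      if (any(badCds)) {
        msg <- c(msg, paste0("CDS of gene ", ids[badCds][1],
                             " lies outside the transcript span"))
      }
    }
  }
  if (length(msg)) msg[seq_len(min(3, length(msg)))] else TRUE
})

#' Construct a GeneModelSet
#'
#' @param transcripts GRanges of transcript spans with `gene_id` metadata.
#' @param exons GRangesList of exons per gene (named by gene id).
#' @param cds GRanges of CDS spans (named by gene id).
#' @return A [GeneModelSet].
#' @export
GeneModelSet <- function(transcripts, exons, cds) {
  new("GeneModelSet", transcripts = transcripts, exons = exons, cds = cds)
}

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object@transcripts), "gene model(s) on",
      length(unique(as.character(
        GenomicRanges::seqnames(object@transcripts)))), "chromosome(s)\n")
})

#' @describeIn GeneModelSet number of gene models
#' @param x A GeneModelSet.
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@transcripts))

#' @rdname GeneModelSet
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))
#' @describeIn GeneModelSet transcript spans
#' @export
setMethod("transcripts", "GeneModelSet", function(x) x@transcripts)

#' @rdname GeneModelSet
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))
#' @describeIn GeneModelSet exons per gene
#' @export
setMethod("exonsByGene", "GeneModelSet", function(x) x@exons)

#' @rdname GeneModelSet
#' @export
setGeneric("cdsByGene", function(x) standardGeneric("cdsByGene"))
#' @describeIn GeneModelSet CDS span per gene
#' @export
setMethod("cdsByGene", "GeneModelSet", function(x) x@cds)

#' @rdname GeneModelSet
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @describeIn GeneModelSet gene identifiers
#' @export
setMethod("geneIds", "GeneModelSet", function(x) x@transcripts$gene_id)
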