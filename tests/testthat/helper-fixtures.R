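# Small fixtures built in code; no binary files.

# a hand-built gene model: one gene, arbitrary exon/CDS layout
makeGeneModel <- function(chrom = "Chr01", strand = "+",
                          exonStarts, exonEnds, cdsStart, cdsEnd,
                          geneId = "g1") {
  tx <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(min(exonStarts), max(exonEnds)),
    strand = strand, gene_id = geneId)
  ex <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(exonStarts, exonEnds),
                           strand = strand))
  names(ex) <- geneId
  cd <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cdsStart, cdsEnd),
                               strand = strand)
  names(cd) <- geneId
  GeneModelSet(transcripts = tx, exons = ex, cds = cd)
}

# methylation calls from a compact spec matrix: chrom pos ctx meth total
makeCalls <- function(df, chrom = "Chr01") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(df$pos, width = 1),
                               strand = "+")
  gr$context <- factor(df$ctx, levels = METH_CONTEXTS)
  gr$meth <- df$meth
  gr$total <- df$total
  gr$covered <- df$total > 0
  gr
}

# write a minimal GFF3 gene (plus parents) to a temp file
writeTinyGFF <- function(path, chrom = "Chr01", strand = "+",
                         exons = list(c(101, 200), c(301, 400)),
                         cds = c(151, 350), geneId = "g1") {
  txS <- min(vapply(exons, `[`, numeric(1), 1))
  txE <- max(vapply(exons, `[`, numeric(1), 2))
  lines <- c("##gff-version 3",
             sprintf("%s\tsrc\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, txS,
                     txE, strand, geneId),
             sprintf("%s\tsrc\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                     chrom, txS, txE, strand, geneId, geneId))
  for (i in seq_along(exons)) {
    lines <- c(lines, sprintf(
      "%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.e%d;Parent=%s.1",
      chrom, exons[[i]][1], exons[[i]][2], strand, geneId, i, geneId))
  }
  lines <- c(lines, sprintf(
    "%s\tsrc\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.c;Parent=%s.1",
    chrom, cds[1], cds[2], strand, geneId, geneId))
  writeLines(lines, path)
  path
}
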