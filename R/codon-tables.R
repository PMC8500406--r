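## Codon bookkeeping shared by the NG86/YN00 estimators and the codon simulator.
## Everything is derived once per session from the standard genetic code
## (Biostrings::GENETIC_CODE) and cached; the code table is data, not logic,
## so a different nuclear code could be swapped in at this single point.

.pkgCache <- new.env(parent = emptyenv())

# nucleotide order used for all integer encodings
.NTS <- c("T", "C", "A", "G")

.isTransition <- function(nt1, nt2) {
  # T<->C and A<->G; integer codes per .NTS
  nt1 != nt2 & ((nt1 <= 2L & nt2 <= 2L) | (nt1 >= 3L & nt2 >= 3L))
}

#' @importFrom Biostrings GENETIC_CODE
.codonSetup <- function() {
  if (!is.null(.pkgCache$codons)) {
    return(invisible(.pkgCache))
  }
  grid <- expand.grid(p3 = 1:4, p2 = 1:4, p1 = 1:4)[, 3:1]
  codon64 <- paste0(.NTS[grid$p1], .NTS[grid$p2], .NTS[grid$p3])
  aa64 <- unname(Biostrings::GENETIC_CODE[codon64])
  sense <- aa64 != "*"
  codons <- codon64[sense]             # the 61 sense codons
  aa <- aa64[sense]
  trip <- as.matrix(grid)[sense, , drop = FALSE]  # 61 x 3 nt codes
  idx64 <- function(t1, t2, t3) (t1 - 1L) * 16L + (t2 - 1L) * 4L + t3
  map64to61 <- integer(64)
  map64to61[!sense] <- NA_integer_
  map64to61[sense] <- seq_len(sum(sense))

  ## 9 single-nucleotide neighbours per sense codon, ordered pos1 x 3, pos2 x 3, pos3 x 3
  n <- length(codons)
  nbrPos <- matrix(rep(rep(1:3, each = 3), n), n, 9, byrow = TRUE)
  nbrNt <- matrix(0L, n, 9)
  nbrIsStop <- matrix(FALSE, n, 9)
  nbrSyn <- matrix(FALSE, n, 9)
  nbrTs <- matrix(FALSE, n, 9)
  nbr61 <- matrix(NA_integer_, n, 9)
  for (i in seq_len(n)) {
    col <- 0L
    for (p in 1:3) {
      for (alt in setdiff(1:4, trip[i, p])) {
        col <- col + 1L
        t2 <- trip[i, ]
        t2[p] <- alt
        j64 <- idx64(t2[1], t2[2], t2[3])
        nbrNt[i, col] <- alt
        nbrIsStop[i, col] <- !sense[j64]
        nbr61[i, col] <- map64to61[j64]
        nbrSyn[i, col] <- sense[j64] && aa64[j64] == aa[i]
        nbrTs[i, col] <- .isTransition(trip[i, p], alt)
      }
    }
  }

  ## NG86 site counts: per position the synonymous fraction of the 3 mutations
  ## (mutations to stop codons count as nonsynonymous), summed over positions.
  S_sites <- rowSums(nbrSyn) / 3
  N_sites <- 3 - S_sites

  ## per-position degeneracy classes used by the YN00 kappa estimator
  posSyn <- sapply(1:3, function(p) rowSums(nbrSyn[, nbrPos[1, ] == p, drop = FALSE]))
  deg4 <- posSyn == 3   # fourfold degenerate
  deg0 <- posSyn == 0   # nondegenerate

  .pkgCache$codons <- codons
  .pkgCache$aa <- aa
  .pkgCache$trip <- trip
  .pkgCache$map64to61 <- map64to61
  .pkgCache$codon64 <- codon64
  .pkgCache$sense64 <- sense
  .pkgCache$nbrPos <- nbrPos
  .pkgCache$nbrNt <- nbrNt
  .pkgCache$nbrIsStop <- nbrIsStop
  .pkgCache$nbrSyn <- nbrSyn
  .pkgCache$nbrTs <- nbrTs
  .pkgCache$nbr61 <- nbr61
  .pkgCache$S_sites <- S_sites
  .pkgCache$N_sites <- N_sites
  .pkgCache$deg4 <- deg4
  .pkgCache$deg0 <- deg0
  invisible(.pkgCache)
}

## Enumerate the mutational pathways between two sense codons (61-indices).
## Returns a list of step matrices (columns pos, targetNt, syn, ts), one per
## pathway that avoids stop-codon intermediates; empty list if none survive.
.enumeratePathways <- function(i, j) {
  cache <- .codonSetup()
  trip <- cache$trip
  a <- trip[i, ]
  b <- trip[j, ]
  dpos <- which(a != b)
  k <- length(dpos)
  if (k == 0L) {
    return(list())
  }
  perms <- if (k == 1L) list(dpos) else if (k == 2L) {
    list(dpos, rev(dpos))
  } else {
    list(dpos[c(1, 2, 3)], dpos[c(1, 3, 2)], dpos[c(2, 1, 3)],
         dpos[c(2, 3, 1)], dpos[c(3, 1, 2)], dpos[c(3, 2, 1)])
  }
  idx64 <- function(t) (t[1] - 1L) * 16L + (t[2] - 1L) * 4L + t[3]
  out <- list()
  for (perm in perms) {
    cur <- a
    curAA <- cache$aa[i]
    steps <- matrix(0, k, 4, dimnames = list(NULL, c("pos", "targetNt", "syn", "ts")))
    ok <- TRUE
    for (s in seq_len(k)) {
      p <- perm[s]
      nxt <- cur
      nxt[p] <- b[p]
      j64 <- idx64(nxt)
      if (!cache$sense64[j64]) {
        ok <- FALSE
        break
      }
      nxtAA <- cache$aa[cache$map64to61[j64]]
      steps[s, ] <- c(p, b[p], as.numeric(nxtAA == curAA),
                      as.numeric(.isTransition(cur[p], b[p])))
      cur <- nxt
      curAA <- nxtAA
    }
    if (ok) out[[length(out) + 1L]] <- steps
  }
  out
}

## Fallback when every pathway passes through a stop codon: classify each
## differing position by mutating codon i at that position alone and comparing
## amino acids (a stop product counts as nonsynonymous).
.directSteps <- function(i, j) {
  cache <- .codonSetup()
  trip <- cache$trip
  a <- trip[i, ]
  b <- trip[j, ]
  dpos <- which(a != b)
  idx64 <- function(t) (t[1] - 1L) * 16L + (t[2] - 1L) * 4L + t[3]
  steps <- matrix(0, length(dpos), 4,
                  dimnames = list(NULL, c("pos", "targetNt", "syn", "ts")))
  for (s in seq_along(dpos)) {
    p <- dpos[s]
    mut <- a
    mut[p] <- b[p]
    j64 <- idx64(mut)
    syn <- cache$sense64[j64] && cache$aa[cache$map64to61[j64]] == cache$aa[i]
    steps[s, ] <- c(p, b[p], as.numeric(syn), as.numeric(.isTransition(a[p], b[p])))
  }
  steps
}

## Pathway cache plus NG86 difference matrices over all 61 x 61 codon pairs.
.pathwaySetup <- function() {
  cache <- .codonSetup()
  if (!is.null(cache$SdMat)) {
    return(invisible(cache))
  }
  n <- length(cache$codons)
  SdMat <- matrix(0, n, n)
  NdMat <- matrix(0, n, n)
  paths <- vector("list", n * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pw <- .enumeratePathways(i, j)
      fallback <- length(pw) == 0L
      if (fallback) pw <- list(.directSteps(i, j))
      paths[[(i - 1L) * n + j]] <- list(pathways = pw, fallback = fallback)
      sd <- mean(vapply(pw, function(m) sum(m[, "syn"]), numeric(1)))
      k <- nrow(pw[[1]])
      SdMat[i, j] <- sd
      NdMat[i, j] <- k - sd
    }
  }
  cache$SdMat <- SdMat
  cache$NdMat <- NdMat
  cache$paths <- paths
  invisible(cache)
}

## Encode an in-frame sequence as a vector of 61-indices; NA marks codons that
## are not analyzable (stop, gap, N or other ambiguity).
.encodeCodons <- function(seq) {
  cache <- .codonSetup()
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  stopifnot(length(chars) %% 3 == 0)
  ntIdx <- match(chars, .NTS)
  m <- matrix(ntIdx, ncol = 3, byrow = TRUE)
  bad <- is.na(m[, 1]) | is.na(m[, 2]) | is.na(m[, 3])
  i64 <- (m[, 1] - 1L) * 16L + (m[, 2] - 1L) * 4L + m[, 3]
  out <- rep(NA_integer_, nrow(m))
  out[!bad] <- cache$map64to61[i64[!bad]]
  out
}
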