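## Yang-Nielsen (2000)-style counting estimator: transition/transversion bias
## (kappa) and codon-usage (F3x4) weighted site and difference counting with
## K80-type per-class distance correction and iterative omega weighting. No
## claim of bit-compatibility with PAML's yn00 is made; the NG86 estimate is
## the cross-check baseline.

# K80 two-parameter distance from proportions of transitions (P) and
# transversions (Q); NA when the logs are undefined (saturation)
.k80Distance <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    return(NA_real_)
  }
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Estimate the transition/transversion rate ratio kappa
#'
#' Kappa is estimated from approximately neutral codon positions: positions
#' that are fourfold degenerate in both codons of a column, pooled with
#' positions that are nondegenerate in both (where selection affects
#' transitions and transversions equally so their ratio is preserved).
#' Transition and transversion proportions at those positions are corrected
#' with the K80 model and kappa is the ratio of the corrected transition to
#' (half the) transversion distance.
#'
#' @param pairs An [OrthologPairSet].
#' @return Estimated kappa (a single number). With no informative sites, or
#'   saturated proportions, kappa defaults to 2 with a warning.
#' @export
estimateKappaYN00 <- function(pairs) {
  stopifnot(is(pairs, "OrthologPairSet"), length(pairs) >= 1)
  cache <- .codonSetup()
  L <- 0
  nTs <- 0
  nTv <- 0
  sa <- as.character(seqA(pairs))
  sb <- as.character(seqB(pairs))
  for (k in seq_along(sa)) {
    ia <- .encodeCodons(sa[k])
    ib <- .encodeCodons(sb[k])
    keep <- !is.na(ia) & !is.na(ib)
    ia <- ia[keep]
    ib <- ib[keep]
    if (!length(ia)) next
    ta <- cache$trip[ia, , drop = FALSE]
    tb <- cache$trip[ib, , drop = FALSE]
    for (p in 1:3) {
      informative <- (cache$deg4[ia, p] & cache$deg4[ib, p]) |
        (cache$deg0[ia, p] & cache$deg0[ib, p])
      L <- L + sum(informative)
      diff <- informative & ta[, p] != tb[, p]
      if (any(diff)) {
        ts <- .isTransition(ta[diff, p], tb[diff, p])
        nTs <- nTs + sum(ts)
        nTv <- nTv + sum(!ts)
      }
    }
  }
  if (L == 0 || (nTs + nTv) == 0) {
    warning("no informative differences for kappa; defaulting to kappa = 2")
    return(2)
  }
  P <- nTs / L
  Q <- nTv / L
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    warning("saturated neutral sites; defaulting to kappa = 2")
    return(2)
  }
  A <- -0.5 * log(a1) + 0.25 * log(a2)  # transition distance
  B <- -0.5 * log(a2)                   # transversion distance (rate 2*beta)
  if (B <= 0) {
    warning("no transversions observed; kappa capped at 99")
    return(99)
  }
  max(2 * A / B, 1e-6)
}

#' Position-specific nucleotide frequencies (F3x4)
#'
#' @param pairs An [OrthologPairSet].
#' @return A 3 x 4 matrix of nucleotide frequencies (columns T, C, A, G) at
#'   the three codon positions, pooled over both sequences of every pair.
#' @export
estimateCodonFrequencies <- function(pairs) {
  stopifnot(is(pairs, "OrthologPairSet"))
  cache <- .codonSetup()
  counts <- matrix(0, 3, 4, dimnames = list(NULL, .NTS))
  for (s in c(as.character(seqA(pairs)), as.character(seqB(pairs)))) {
    idx <- .encodeCodons(s)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    for (p in 1:3) {
      tb <- tabulate(cache$trip[idx, p], nbins = 4)
      counts[p, ] <- counts[p, ] + tb
    }
  }
  if (sum(counts) == 0) {
    return(matrix(0.25, 3, 4, dimnames = list(NULL, .NTS)))
  }
  sweep(counts, 1, rowSums(counts), "/")
}

# kappa- and frequency-weighted site counts per sense codon: per position the
# weight of mutating to nucleotide n is freq(pos, n) * kappa^transition;
# mutations to stops stay in the weights and count as nonsynonymous
.yn00SiteVector <- function(kappa, pinuc) {
  cache <- .codonSetup()
  n <- length(cache$codons)
  W <- pinuc[cbind(as.vector(cache$nbrPos), as.vector(cache$nbrNt))]
  W <- matrix(W, n, 9) * ifelse(cache$nbrTs, kappa, 1)
  S <- numeric(n)
  for (p in 1:3) {
    cols <- which(cache$nbrPos[1, ] == p)
    wp <- W[, cols, drop = FALSE]
    sp <- rowSums(wp * cache$nbrSyn[, cols, drop = FALSE])
    tot <- rowSums(wp)
    frac <- ifelse(tot > 0, sp / tot,
                   rowSums(cache$nbrSyn[, cols, drop = FALSE]) / 3)
    S <- S + frac
  }
  S
}

# weighted difference counts for one ordered codon pair: pathways weighted by
# the product of step rates freq * kappa^ts * omega^nonsyn; returns the four
# class counts (syn/nonsyn x ts/tv)
.yn00PairCounts <- function(i, j, kappa, omega, pinuc) {
  cache <- .pathwaySetup()
  entry <- cache$paths[[(i - 1L) * length(cache$codons) + j]]
  pw <- entry$pathways
  wts <- vapply(pw, function(m) {
    prod(pinuc[cbind(m[, "pos"], m[, "targetNt"])] *
           ifelse(m[, "ts"] == 1, kappa, 1) *
           ifelse(m[, "syn"] == 1, 1, omega))
  }, numeric(1))
  if (all(wts == 0)) wts <- rep(1, length(wts))
  wts <- wts / sum(wts)
  out <- c(sdts = 0, sdtv = 0, ndts = 0, ndtv = 0)
  for (q in seq_along(pw)) {
    m <- pw[[q]]
    out["sdts"] <- out["sdts"] + wts[q] * sum(m[, "syn"] == 1 & m[, "ts"] == 1)
    out["sdtv"] <- out["sdtv"] + wts[q] * sum(m[, "syn"] == 1 & m[, "ts"] == 0)
    out["ndts"] <- out["ndts"] + wts[q] * sum(m[, "syn"] == 0 & m[, "ts"] == 1)
    out["ndtv"] <- out["ndtv"] + wts[q] * sum(m[, "syn"] == 0 & m[, "ts"] == 0)
  }
  out
}

.kaksYN00one <- function(pairId, sa, sb, kappa, pinuc, tol = 1e-6, maxIter = 100) {
  cache <- .pathwaySetup()
  ia <- .encodeCodons(sa)
  ib <- .encodeCodons(sb)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]
  ib <- ib[keep]
  n <- length(ia)
  if (n == 0L) {
    return(.emptyEstimate(pairId, "YN00"))
  }
  Svec <- .yn00SiteVector(kappa, pinuc)
  S <- (sum(Svec[ia]) + sum(Svec[ib])) / 2
  N <- 3 * n - S

  diffIdx <- which(ia != ib)
  flags <- character(0)
  if (!length(diffIdx)) {
    return(data.frame(pair_id = pairId, method = "YN00", n_codons_used = n,
                      S = S, N = N, Sd = 0, Nd = 0, pS = 0, pN = 0,
                      Ks = 0, Ka = 0, omega = NA_real_, kappa = kappa,
                      flags = "omega_undefined", stringsAsFactors = FALSE))
  }
  key <- (ia[diffIdx] - 1L) * 61L + ib[diffIdx]
  tab <- table(key)
  ukey <- as.integer(names(tab))
  cnt <- as.numeric(tab)
  ui <- (ukey - 1L) %/% 61L + 1L
  uj <- (ukey - 1L) %% 61L + 1L

  omega <- 1
  converged <- FALSE
  res <- NULL
  for (iter in seq_len(maxIter)) {
    acc <- c(sdts = 0, sdtv = 0, ndts = 0, ndtv = 0)
    for (q in seq_along(ukey)) {
      acc <- acc + cnt[q] * .yn00PairCounts(ui[q], uj[q], kappa, omega, pinuc)
    }
    PS <- acc["sdts"] / S
    QS <- acc["sdtv"] / S
    PN <- acc["ndts"] / N
    QN <- acc["ndtv"] / N
    ds <- .k80Distance(PS, QS)
    dn <- .k80Distance(PN, QN)
    res <- list(acc = acc, ds = ds, dn = dn)
    if (is.na(ds) || is.na(dn)) {
      flags <- c(flags, "saturated")
      break
    }
    if (ds == 0) {
      flags <- c(flags, "omega_undefined")
      break
    }
    omegaNew <- dn / ds
    if (abs(omegaNew - omega) < tol * max(omega, 1e-8)) {
      omega <- omegaNew
      converged <- TRUE
      break
    }
    omega <- omegaNew
  }
  if (!converged && !length(flags)) flags <- "not_converged"
  Sd <- unname(res$acc["sdts"] + res$acc["sdtv"])
  Nd <- unname(res$acc["ndts"] + res$acc["ndtv"])
  omegaOut <- if (!is.na(res$ds) && !is.na(res$dn) && res$ds > 0) {
    res$dn / res$ds
  } else {
    NA_real_
  }
  data.frame(pair_id = pairId, method = "YN00", n_codons_used = n,
             S = S, N = N, Sd = Sd, Nd = Nd, pS = Sd / S, pN = Nd / N,
             Ks = res$ds, Ka = res$dn, omega = omegaOut, kappa = kappa,
             flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
}

#' Ka/Ks estimation by the YN00-style counting method
#'
#' Counts synonymous and nonsynonymous sites with mutation opportunities
#' weighted by the transition/transversion ratio kappa and position-specific
#' (F3x4) nucleotide frequencies; counts differences by pathway averaging
#' with pathway weights proportional to the product of step rates (including
#' omega on nonsynonymous steps); corrects synonymous and nonsynonymous
#' proportions separately with the K80 two-parameter formula; and iterates
#' the omega-dependent pathway weighting to convergence (relative change
#' below `tol`, at most `maxIter` iterations; the last iterate is returned
#' flagged `not_converged` otherwise).
#'
#' @param pairs An [OrthologPairSet].
#' @param kappa Transition/transversion rate ratio; estimated from `pairs`
#'   via [estimateKappaYN00()] when NULL.
#' @param codonFreqs 3 x 4 position-specific nucleotide frequency matrix;
#'   estimated from `pairs` via [estimateCodonFrequencies()] when NULL.
#' @param tol,maxIter Convergence tolerance and iteration cap for the omega
#'   weighting.
#' @return A data.frame with the same columns as [kaksNG86()], with `method
#'   = "YN00"` and the kappa used.
#' @export
kaksYN00 <- function(pairs, kappa = NULL, codonFreqs = NULL,
                     tol = 1e-6, maxIter = 100) {
  stopifnot(is(pairs, "OrthologPairSet"))
  if (is.null(kappa)) kappa <- estimateKappaYN00(pairs)
  if (is.null(codonFreqs)) codonFreqs <- estimateCodonFrequencies(pairs)
  stopifnot(is.matrix(codonFreqs), all(dim(codonFreqs) == c(3, 4)))
  sa <- as.character(seqA(pairs))
  sb <- as.character(seqB(pairs))
  ids <- pairIds(pairs)
  out <- lapply(seq_along(ids), function(k) {
    .kaksYN00one(ids[k], sa[k], sb[k], kappa, codonFreqs, tol, maxIter)
  })
  do.call(rbind, out)
}
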