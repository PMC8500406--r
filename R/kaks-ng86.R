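## Nei-Gojobori (1986) counting estimator of synonymous (Ks) and
## nonsynonymous (Ka) divergence with Jukes-Cantor correction.

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For a sense codon, each of the nine single-nucleotide mutations is
#' classified as synonymous or nonsynonymous against the standard genetic
#' code (mutations producing a stop codon count as nonsynonymous). The
#' synonymous site count is the sum over the three codon positions of the
#' synonymous fraction of the three possible changes, so S + N = 3 for every
#' codon.
#'
#' @param codon A single 3-letter codon string (one of the 61 sense codons).
#' @return Named numeric vector with elements `S` and `N`.
#' @examples
#' codonSitesNG86("TTT")  # c(S = 1/3, N = 8/3)
#' codonSitesNG86("GGG")  # c(S = 1,   N = 2)
#' @export
codonSitesNG86 <- function(codon) {
  cache <- .codonSetup()
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop("'codon' must be a single 3-letter string")
  }
  i <- match(toupper(codon), cache$codons)
  if (is.na(i)) {
    stop("not a sense codon of the standard code: ", codon)
  }
  c(S = cache$S_sites[i], N = cache$N_sites[i])
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' With k differing positions, the k! mutational pathways between the codons
#' are enumerated; pathways passing through a stop codon are dropped and the
#' synonymous/nonsynonymous step counts are averaged over the remaining
#' pathways (NG86 convention). If every pathway passes through a stop, each
#' differing position is classified directly by single-position substitution
#' into the first codon.
#'
#' @param codonA,codonB Sense codon strings.
#' @return Named numeric vector with elements `Sd` and `Nd`; `Sd + Nd` equals
#'   the number of differing positions.
#' @examples
#' countDifferencesNG86("TTT", "GTA")  # c(Sd = 0.5, Nd = 1.5)
#' @export
countDifferencesNG86 <- function(codonA, codonB) {
  cache <- .pathwaySetup()
  i <- match(toupper(codonA), cache$codons)
  j <- match(toupper(codonB), cache$codons)
  if (is.na(i) || is.na(j)) {
    stop("both codons must be sense codons of the standard code")
  }
  c(Sd = cache$SdMat[i, j], Nd = cache$NdMat[i, j])
}

# Jukes-Cantor multiple-hit correction; NA (saturated) at p >= 3/4
.jcCorrect <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# one empty estimate row; shared by both estimators
.emptyEstimate <- function(pairId, method) {
  data.frame(pair_id = pairId, method = method, n_codons_used = 0L,
             S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
             pS = NA_real_, pN = NA_real_, Ks = NA_real_, Ka = NA_real_,
             omega = NA_real_, kappa = NA_real_, flags = "no_codons",
             stringsAsFactors = FALSE)
}

.kaksNG86one <- function(pairId, seqA, seqB) {
  cache <- .pathwaySetup()
  ia <- .encodeCodons(seqA)
  ib <- .encodeCodons(seqB)
  keep <- !is.na(ia) & !is.na(ib)   # pairwise deletion of unanalyzable columns
  ia <- ia[keep]
  ib <- ib[keep]
  n <- length(ia)
  if (n == 0L) {
    return(.emptyEstimate(pairId, "NG86"))
  }
  S <- (sum(cache$S_sites[ia]) + sum(cache$S_sites[ib])) / 2
  N <- 3 * n - S
  Sd <- sum(cache$SdMat[cbind(ia, ib)])
  Nd <- sum(cache$NdMat[cbind(ia, ib)])
  pS <- Sd / S
  pN <- Nd / N
  Ks <- .jcCorrect(pS)
  Ka <- .jcCorrect(pN)
  flags <- character(0)
  if (is.na(Ks) || is.na(Ka)) flags <- c(flags, "saturated")
  omega <- NA_real_
  if (!is.na(Ks) && !is.na(Ka)) {
    if (Ks > 0) {
      omega <- Ka / Ks
    } else {
      flags <- c(flags, "omega_undefined")
    }
  }
  data.frame(pair_id = pairId, method = "NG86", n_codons_used = n,
             S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka, omega = omega, kappa = NA_real_,
             flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
}

#' Ka/Ks estimation by the NG86 counting method
#'
#' Sites are counted per sequence and averaged; pathway-averaged differences
#' are summed over codon columns; proportions are corrected with the
#' Jukes-Cantor formula \eqn{d = -3/4 \log(1 - 4p/3)}. Columns in which
#' either codon is a stop, contains N, a gap or another ambiguity character
#' are excluded pairwise. Proportions at or beyond 3/4 are flagged
#' `saturated` and the distance is NA; `Ks = 0` leaves omega undefined
#' (`omega_undefined` flag).
#'
#' @param pairs An [OrthologPairSet].
#' @return A data.frame with one row per pair: `pair_id`, `method`,
#'   `n_codons_used`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega`,
#'   `kappa` (NA for NG86) and `flags`.
#' @seealso [kaksYN00()] for the kappa- and frequency-corrected estimator.
#' @export
kaksNG86 <- function(pairs) {
  stopifnot(is(pairs, "OrthologPairSet"))
  sa <- as.character(seqA(pairs))
  sb <- as.character(seqB(pairs))
  ids <- pairIds(pairs)
  out <- lapply(seq_along(ids), function(k) .kaksNG86one(ids[k], sa[k], sb[k]))
  do.call(rbind, out)
}
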