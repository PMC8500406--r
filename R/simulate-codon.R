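## GY94-style codon pair simulator: ancestor drawn uniformly from the 61
## sense codons, each descendant lineage evolved independently for time t/2
## by exact stochastic simulation (per-codon exponential waiting times).
## Single-nucleotide changes only; relative rate kappa for transitions and
## omega for nonsynonymous changes; changes to stop codons have rate zero.

# per-codon rate structure for given omega/kappa, scaled so the mean total
# rate over a uniform codon distribution is 3 (one expected substitution per
# nucleotide site per unit time)
.gy94Rates <- function(omega, kappa) {
  cache <- .codonSetup()
  R <- ifelse(cache$nbrTs, kappa, 1) * ifelse(cache$nbrSyn, 1, omega)
  R[cache$nbrIsStop] <- 0
  tot <- rowSums(R)
  scale <- 3 / mean(tot)
  list(R = R * scale, tot = tot * scale)
}

# evolve a vector of codon states (61-indices) for time tEnd
.evolveCodons <- function(state, tEnd, rates) {
  cache <- .codonSetup()
  if (tEnd <= 0) {
    return(state)
  }
  tleft <- rep(tEnd, length(state))
  active <- seq_along(state)
  while (length(active)) {
    r <- rates$tot[state[active]]
    dt <- stats::rexp(length(active)) / r
    hit <- dt < tleft[active]
    tleft[active] <- tleft[active] - dt
    active <- active[hit]
    if (!length(active)) break
    W <- rates$R[state[active], , drop = FALSE]
    cs <- t(apply(W, 1, cumsum))
    u <- stats::runif(length(active)) * cs[, 9]
    pick <- max.col(cs >= u, ties.method = "first")
    state[active] <- cache$nbr61[cbind(state[active], pick)]
  }
  state
}

#' Simulate ortholog codon-sequence pairs under known omega and kappa
#'
#' Each pair descends from a common ancestor of `nCodons` codons drawn
#' uniformly from the 61 sense codons; the two lineages evolve independently
#' for time `t/2` each so the expected pairwise divergence is `t`
#' substitutions per nucleotide site (rates normalized over a uniform codon
#' distribution). Deterministic given `seed`.
#'
#' @param nPairs Number of pairs to simulate.
#' @param omega Nonsynonymous/synonymous rate ratio (scalar, or one value
#'   per pair).
#' @param kappa Transition/transversion rate ratio.
#' @param t Expected substitutions per nucleotide site between the two
#'   sequences.
#' @param nCodons Codons per sequence.
#' @param seed Integer seed.
#' @return An [OrthologPairSet]; the true omega of each pair is recorded in
#'   the `pair_id` suffix-free companion attribute `trueOmega`.
#' @examples
#' ops <- simulateOrthologPairs(2, omega = 0.5, kappa = 2, t = 0.3,
#'                              nCodons = 100, seed = 1)
#' @export
simulateOrthologPairs <- function(nPairs, omega, kappa, t, nCodons, seed) {
  stopifnot(nPairs >= 1, nCodons >= 1, all(omega >= 0), kappa >= 0, t >= 0)
  cache <- .codonSetup()
  set.seed(seed)
  omega <- rep_len(omega, nPairs)
  sa <- character(nPairs)
  sb <- character(nPairs)
  for (k in seq_len(nPairs)) {
    rates <- .gy94Rates(omega[k], kappa)
    anc <- sample.int(61L, nCodons, replace = TRUE)
    a <- .evolveCodons(anc, t / 2, rates)
    b <- .evolveCodons(anc, t / 2, rates)
    sa[k] <- paste(cache$codons[a], collapse = "")
    sb[k] <- paste(cache$codons[b], collapse = "")
  }
  ids <- sprintf("sim_pair_%04d", seq_len(nPairs))
  out <- OrthologPairSet(pairId = ids,
                         geneA = sprintf("simA_%04d", seq_len(nPairs)),
                         geneB = sprintf("simB_%04d", seq_len(nPairs)),
                         seqA = sa, seqB = sb)
  attr(out, "trueOmega") <- omega
  out
}

#' Simulate a single codon pair
#'
#' Convenience wrapper around [simulateOrthologPairs()] for one pair.
#'
#' @inheritParams simulateOrthologPairs
#' @return An [OrthologPairSet] of length 1.
#' @export
simulateCodonPair <- function(omega, kappa, t, nCodons, seed) {
  simulateOrthologPairs(1L, omega, kappa, t, nCodons, seed)
}
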