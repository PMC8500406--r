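## The PSG screen: Ks saturation filter followed by the Ka/Ks threshold.
## Both thresholds are strict (>) and configurable; undefined-omega pairs are
## kept in a separate tier so the accounting chain
## (input -> Ks-removed -> retained -> PSG) stays auditable.

#' Discard pairs with extreme synonymous divergence
#'
#' Removes pairs whose `Ks` exceeds `maxKs` (strictly), the saturation
#' filter applied before PSG classification. Pairs with undefined (NA) `Ks`
#' are also removed and counted separately.
#'
#' @param estimates A data.frame of substitution estimates (from
#'   [kaksNG86()], [kaksYN00()] or [simulateEstimates()]) with a `Ks`
#'   column.
#' @param maxKs Retention threshold; a pair is kept iff `Ks <= maxKs`.
#' @return The retained rows, with attributes `n_input`, `n_removed`
#'   (Ks > maxKs) and `n_undefined` (NA Ks). `n_input = nrow(retained) +
#'   n_removed + n_undefined` always holds.
#' @export
applyKsFilter <- function(estimates, maxKs = 0.3) {
  stopifnot(is.data.frame(estimates), "Ks" %in% names(estimates), maxKs > 0)
  undef <- is.na(estimates$Ks)
  high <- !undef & estimates$Ks > maxKs
  out <- estimates[!undef & !high, , drop = FALSE]
  attr(out, "n_input") <- nrow(estimates)
  attr(out, "n_removed") <- sum(high)
  attr(out, "n_undefined") <- sum(undef)
  message(sum(high), " of ", nrow(estimates), " pairs removed at Ks > ",
          maxKs, if (sum(undef)) paste0(" (plus ", sum(undef),
                                        " with undefined Ks)") else "")
  out
}

#' Classify positively selected genes by the Ka/Ks threshold
#'
#' A pair is a PSG iff its omega is defined and strictly exceeds
#' `omegaThreshold`. Pairs with `Ks = 0` (omega undefined) are assigned the
#' status `undefined` rather than silently dropped.
#'
#' @param estimates Ks-filtered substitution estimates; if a `gene_a` column
#'   is present it provides the focal-genome gene ids, else `pair_id` is
#'   used.
#' @param omegaThreshold PSG threshold on omega (strict).
#' @return A screen-result data.frame: `gene_id`, `pair_id`, `Ks`, `Ka`,
#'   `omega`, `is_retained_after_ks_filter`, `is_psg`, `psg_status`.
#' @export
classifyPSG <- function(estimates, omegaThreshold = 1.2) {
  stopifnot(is.data.frame(estimates),
            all(c("pair_id", "Ks", "Ka", "omega") %in% names(estimates)))
  geneId <- if ("gene_a" %in% names(estimates)) {
    estimates$gene_a
  } else {
    estimates$pair_id
  }
  omega <- estimates$omega
  isPsg <- !is.na(omega) & omega > omegaThreshold
  status <- ifelse(is.na(omega), "undefined",
                   ifelse(isPsg, "PSG", "non-PSG"))
  data.frame(gene_id = geneId, pair_id = estimates$pair_id,
             Ks = estimates$Ks, Ka = estimates$Ka, omega = omega,
             is_retained_after_ks_filter = TRUE,
             is_psg = isPsg, psg_status = status,
             stringsAsFactors = FALSE)
}

#' Sample a random background gene set from the non-PSGs
#'
#' @param results Screen results from [classifyPSG()].
#' @param n Background size; must not exceed the number of non-PSGs.
#' @param seed Integer seed (sampling is reproducible).
#' @return Character vector of gene ids, sampled uniformly without
#'   replacement from the non-PSG tier.
#' @export
sampleBackground <- function(results, n, seed) {
  pool <- results$gene_id[results$psg_status == "non-PSG"]
  if (n > length(pool)) {
    stop("requested background of ", n, " but only ", length(pool),
         " non-PSGs are available")
  }
  if (n == 0) {
    return(character(0))
  }
  set.seed(seed)
  sample(pool, n)
}
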