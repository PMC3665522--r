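#' Shannon entropy of one alignment column
#'
#' \eqn{H_j = -\sum_i p(a_{i,j}) \ln p(a_{i,j})} over the 20 amino-acid
#' frequencies of column \eqn{j} (natural logarithm, the AL2CO convention);
#' zero-frequency terms contribute 0. A fully conserved column scores 0, a
#' uniform column \eqn{\ln 20 \approx 2.996} nats.
#'
#' @param frequencies numeric vector of 20 non-negative frequencies summing to
#'   1 within 1e-9.
#' @return entropy in nats.
#' @export
columnEntropy <- function(frequencies) {
  if (any(frequencies < 0))
    .dhStop("negative amino-acid frequency")
  if (abs(sum(frequencies) - 1) > 1e-9)
    .dhStop("column frequencies must sum to 1 (tolerance 1e-9)")
  p <- frequencies[frequencies > 0]
  -sum(p * log(p))
}

#' Entropy profiles from a frequency table
#'
#' @param freqs data.frame from [readFrequencyTable()].
#' @return named list of [EntropyProfile-class], one per domain, columns
#'   ordered by position.
#' @export
entropyProfiles <- function(freqs) {
  out <- lapply(split(freqs, freqs$domain_accession), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    H <- apply(as.matrix(d[, AA_ALPHABET, drop = FALSE]), 1L, columnEntropy)
    H <- pmin(pmax(unname(H), 0), log(20))
    new("EntropyProfile", domain = d$domain_accession[1L],
        entropies = H, meanEntropy = mean(H))
  })
  out[order(names(out))]
}

#' Global conservation threshold: mean plus one standard deviation
#'
#' Pools the column entropies of all supplied profiles and sets the
#' conservation cut-off at their mean plus one population (divide-by-N)
#' standard deviation; a column is conserved when its entropy is at or below
#' this value. The mean/SD convention is recorded in the returned object so
#' the choice is auditable.
#'
#' @param profiles list of [EntropyProfile-class] covering at least 2 columns
#'   in total.
#' @return a [ConservationThreshold-class].
#' @export
conservationThreshold <- function(profiles) {
  xs <- unlist(lapply(profiles, entropies), use.names = FALSE)
  if (length(xs) < 2L)
    .dhStop("conservation threshold needs at least 2 columns")
  m <- mean(xs)
  s <- sqrt(mean((xs - m)^2))
  new("ConservationThreshold", value = m + s, meanAll = m, sdAll = s)
}

#' Is a column conserved?
#'
#' Inclusive comparison: conserved iff \code{H <= thresholdValue(threshold)}.
#'
#' @param H entropy (nats), vectorised.
#' @param threshold a [ConservationThreshold-class].
#' @return logical vector.
#' @export
isConserved <- function(H, threshold) {
  if (any(H < 0)) .dhStop("entropy must be non-negative")
  H <= thresholdValue(threshold)
}
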