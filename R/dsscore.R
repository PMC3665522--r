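#' Binomial order-statistic domain significance score (DS-Score)
#'
#' Tests whether \code{c} of the \code{n} mutations aggregated onto a domain
#' of \code{L} match columns cluster at one column more than uniform placement
#' predicts. With \eqn{F} the CDF of Binomial(\eqn{n}, \eqn{1/L}), the score is
#' \deqn{-\log_{10}\left(1 - F(c-1)^L\right),}
#' i.e. \eqn{-\log_{10}} of the probability that the maximum of \eqn{L}
#' independent Binomial(\eqn{n}, \eqn{1/L}) counts reaches \code{c}. Columns
#' with equal counts automatically receive equal scores (the m-way tie rule),
#' and a single-column domain always scores 0 (no clustering information).
#' Scores of 1.6, 1.3 and 1.0 correspond to p-values of 0.025, 0.05 and 0.10
#' on Fisher's scale of evidence.
#'
#' Evaluation is log-space stable: the upper tail \eqn{S = P(X \ge c)} is
#' taken from \code{pbinom(..., log.p = TRUE)}; for moderate tails
#' \eqn{1 - F^L} is computed as \code{-expm1(L * log1p(-S))}, and for
#' \eqn{S < 10^{-12}} as \eqn{L \cdot S} (relative error below
#' \eqn{L \cdot S / 2}). Scores are capped at 300.
#'
#' @param c observed mutation count at a position (vectorised); \code{c = 0}
#'   scores 0.
#' @param n total mutations mapped to the domain; \code{n = 0} scores 0.
#' @param L domain model length (match columns), \code{L >= 1}.
#' @return numeric vector of scores in \eqn{[0, 300]}.
#' @export
dsScore <- function(c, n, L) {
  if (length(L) != 1L || is.na(L) || L < 1)
    .dhStop("L must be a single integer >= 1")
  if (length(n) != 1L || is.na(n) || n < 0)
    .dhStop("n must be a single non-negative integer")
  if (any(is.na(c)) || any(c < 0)) .dhStop("c must be non-negative")
  if (any(c > n)) .dhStop("c cannot exceed n")
  out <- numeric(length(c))
  act <- which(c > 0 & n > 0)
  if (length(act)) {
    logSF <- stats::pbinom(c[act] - 1, n, 1 / L,
                           lower.tail = FALSE, log.p = TRUE)
    small <- logSF < log(1e-12)
    s <- numeric(length(act))
    if (any(small))                     # 1 - (1-S)^L ~= L*S for tiny S
      s[small] <- -(log10(L) + logSF[small] / log(10))
    if (any(!small)) {
      SF <- exp(logSF[!small])
      p <- -expm1(L * log1p(-SF))
      s[!small] <- -log10(p)
    }
    out[act] <- pmin(pmax(s, 0), 300)
  }
  out
}

#' Position-based DS-Scores for a domain mutation table
#'
#' Pools the counts of the requested species (additively; pooling two species
#' is the multi-species variant of the score) and scores every mutated column
#' with [dsScore()]; zero-count columns score 0.
#'
#' @param table a [DomainMutationTable-class].
#' @param species character vector of species to pool; default all species in
#'   the table that carry at least one mutation there is NOT assumed — all
#'   rows are pooled when NULL.
#' @return a [ScoreVector-class] of kind \code{"position"} (one species) or
#'   \code{"multispecies_position"} (several).
#' @export
positionScores <- function(table, species = NULL) {
  cts <- mutationCounts(table)
  if (is.null(species)) species <- rownames(cts)
  if (!all(species %in% rownames(cts)))
    .dhStop("requested species not present in the table")
  pooled <- as.integer(colSums(cts[species, , drop = FALSE]))
  n <- sum(pooled)
  L <- modelLength(table)
  sc <- dsScore(pooled, n, L)
  new("ScoreVector", domain = domainAccession(table),
      kind = if (length(species) > 1L) "multispecies_position" else "position",
      speciesSet = species, scores = sc, counts = pooled,
      nTotal = as.integer(n), sourcePos = seq_len(L),
      featureOf = rep(NA_character_, L))
}

#' Feature-based DS-Scores
#'
#' Distributes, within each annotated functional feature, the largest
#' position-based score to every column of that feature; unannotated columns
#' keep their position-based score, and a column covered by several features
#' receives the maximum across them (tie broken to the alphabetically first
#' feature). Each column records the arg-max source column whose mutation set
#' backs its score (ties to the smallest column).
#'
#' @param positionVector a position-kind [ScoreVector-class] from
#'   [positionScores()].
#' @param features feature annotations ([readFeatureAnnotations()]); rows for
#'   other domains are ignored.
#' @return a [ScoreVector-class] of kind \code{"feature"} or
#'   \code{"multispecies_feature"}.
#' @export
featureScores <- function(positionVector, features) {
  if (!scoreKind(positionVector) %in% c("position", "multispecies_position"))
    .dhStop("featureScores expects a position-kind ScoreVector")
  L <- modelLength(positionVector)
  sc <- dsScores(positionVector)
  newSc <- sc
  srcPos <- positionVector@sourcePos
  featOf <- rep(NA_character_, L)
  ft <- features[features$domain_accession == domainAccession(positionVector), ,
                 drop = FALSE]
  if (nrow(ft)) {
    ft <- ft[order(ft$feature_name), , drop = FALSE]
    for (i in seq_len(nrow(ft))) {
      pos <- ft$positions[[i]]
      pos <- pos[pos >= 1L & pos <= L]
      if (length(pos) == 0L) next
      mx <- max(sc[pos])
      am <- pos[which.max(sc[pos])]       # smallest arg-max column
      upgrade <- pos[newSc[pos] < mx |
                       (newSc[pos] == mx & is.na(featOf[pos]))]
      newSc[upgrade] <- mx
      srcPos[upgrade] <- am
      featOf[upgrade] <- ft$feature_name[i]
    }
  }
  new("ScoreVector", domain = domainAccession(positionVector),
      kind = if (scoreKind(positionVector) == "multispecies_position")
        "multispecies_feature" else "feature",
      speciesSet = speciesSet(positionVector), scores = newSc,
      counts = positionVector@counts, nTotal = totalMutations(positionVector),
      sourcePos = srcPos, featureOf = featOf)
}

#' Call domain hotspots from a score vector
#'
#' One call per column whose score is at or above the threshold (inclusive).
#' The mutation-set key of a call is the sorted set of mutation ids at the
#' column backing the score — the column itself for position-kind scores, the
#' feature's arg-max column for feature-kind scores — and is the identity used
#' later to collapse redundant-domain copies of the same cluster.
#'
#' @param vector a [ScoreVector-class].
#' @param threshold positive score cut-off; the conventional levels are 1.6,
#'   1.3 and 1.0 (p of 0.025, 0.05, 0.10).
#' @param table the [DomainMutationTable-class] the vector was scored from.
#' @return data.frame of calls with columns \code{domain}, \code{position},
#'   \code{kind}, \code{species_set}, \code{threshold}, \code{score},
#'   \code{count}, \code{n_total}, \code{feature}, \code{source_pos},
#'   \code{mutation_set_key} (ids sorted, ";"-joined).
#' @export
callHotspots <- function(vector, threshold, table) {
  stopifnot(threshold > 0,
            identical(domainAccession(vector), domainAccession(table)))
  sc <- dsScores(vector)
  sel <- which(sc >= threshold & sc > 0)
  if (length(sel) == 0L) return(emptyHotspotCalls())
  sps <- speciesSet(vector)
  keys <- vapply(sel, function(j) {
    src <- vector@sourcePos[j]
    ids <- sort(unique(unlist(lapply(sps, function(s)
      mutationIds(table, s, src)))))
    paste(ids, collapse = ";")
  }, character(1))
  keep <- nzchar(keys)
  sel <- sel[keep]; keys <- keys[keep]
  if (length(sel) == 0L) return(emptyHotspotCalls())
  data.frame(domain = domainAccession(vector), position = sel,
             kind = scoreKind(vector),
             species_set = paste(sps, collapse = ","),
             threshold = threshold, score = sc[sel],
             count = vector@counts[sel],
             n_total = totalMutations(vector),
             feature = vector@featureOf[sel],
             source_pos = vector@sourcePos[sel],
             mutation_set_key = keys)
}

emptyHotspotCalls <- function() {
  data.frame(domain = character(), position = integer(), kind = character(),
             species_set = character(), threshold = numeric(),
             score = numeric(), count = integer(), n_total = integer(),
             feature = character(), source_pos = integer(),
             mutation_set_key = character())
}
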