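#' @import methods
NULL

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DOMAIN_SOURCES  <- c("CDD", "Pfam", "SMART", "COG", "synthetic")
PROTEIN_SOURCES <- c("swissprot", "refseq", "sgd", "synthetic")
SPECIES_LEVELS  <- c("human", "yeast", "other")
SCORE_KINDS     <- c("position", "feature",
                     "multispecies_position", "multispecies_feature")

#' Per-domain mutation count table
#'
#' Holds, for one domain model of length \code{L}, the per-position mutation
#' counts of each species (the sample \eqn{X_1, \dots, X_L} scored by
#' [dsScore()]) together with an index from (species, domain position) back to
#' the contributing mutation identifiers.
#'
#' @slot domain single domain accession.
#' @slot length model length \code{L} (number of match columns).
#' @slot counts integer matrix, species in rows, the \code{L} match columns
#'   in columns.
#' @slot mutationIndex named list (one element per species row) of
#'   length-\code{L} lists; element \code{j} is the character vector of
#'   mutation ids mapped to column \code{j}.
#'
#' @seealso [buildDomainTables()], [positionScores()]
#' @exportClass DomainMutationTable
setClass("DomainMutationTable",
  representation(domain = "character", length = "integer",
                 counts = "matrix", mutationIndex = "list"))

setValidity("DomainMutationTable", function(object) {
  msg <- character()
  if (length(object@domain) != 1L) msg <- c(msg, "'domain' must be a single accession")
  if (length(object@length) != 1L || is.na(object@length) || object@length < 1L)
    msg <- c(msg, "'length' must be a positive integer")
  if (ncol(object@counts) != object@length)
    msg <- c(msg, "counts matrix must have L columns")
  if (is.null(rownames(object@counts)))
    msg <- c(msg, "counts matrix must have species rownames")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!identical(sort(names(object@mutationIndex)), sort(rownames(object@counts))))
    msg <- c(msg, "mutationIndex names must match counts rownames")
  for (sp in rownames(object@counts)) {
    idx <- object@mutationIndex[[sp]]
    if (length(idx) != object@length) {
      msg <- c(msg, sprintf("mutationIndex[['%s']] must have L elements", sp))
      next
    }
    nn <- vapply(idx, length, integer(1))
    if (!all(nn == object@counts[sp, ]))
      msg <- c(msg, sprintf(
        "counts for species '%s' disagree with mutationIndex sizes", sp))
  }
  if (length(msg)) msg else TRUE
})

#' Per-position DS-Score vector for one domain
#'
#' @slot domain domain accession.
#' @slot kind one of \code{"position"}, \code{"feature"},
#'   \code{"multispecies_position"}, \code{"multispecies_feature"}.
#' @slot speciesSet species whose mutation counts were pooled.
#' @slot scores numeric vector of length \code{L}; \eqn{-\log_{10}} p at each
#'   column, 0 where no mutation maps (position kind) or no feature score
#'   applies.
#' @slot counts pooled integer counts per column.
#' @slot nTotal total pooled mutation count \code{n} for the domain.
#' @slot sourcePos for each column, the column whose mutation set backs the
#'   score (identity for position kind; the feature arg-max column for
#'   feature kind).
#' @slot featureOf for each column, the name of the feature whose maximum was
#'   distributed there (NA where the position-based score stands).
#'
#' @seealso [positionScores()], [featureScores()], [callHotspots()]
#' @exportClass ScoreVector
setClass("ScoreVector",
  representation(domain = "character", kind = "character",
                 speciesSet = "character", scores = "numeric",
                 counts = "integer", nTotal = "integer",
                 sourcePos = "integer", featureOf = "character"))

setValidity("ScoreVector", function(object) {
  msg <- character()
  if (!object@kind %in% SCORE_KINDS)
    msg <- c(msg, "unknown score kind")
  L <- length(object@scores)
  if (length(object@counts) != L || length(object@sourcePos) != L ||
      length(object@featureOf) != L)
    msg <- c(msg, "scores, counts, sourcePos and featureOf must share length L")
  if (any(!is.finite(object@scores)) || any(object@scores < 0))
    msg <- c(msg, "scores must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Column-entropy profile of a domain model
#'
#' Shannon entropies (natural log) of the amino-acid frequency columns of one
#' domain model, plus their arithmetic mean.
#'
#' @slot domain domain accession.
#' @slot entropies numeric vector of per-column entropies in nats, each in
#'   \eqn{[0, \ln 20]}.
#' @slot meanEntropy arithmetic mean of \code{entropies}.
#'
#' @seealso [columnEntropy()], [conservationThreshold()]
#' @exportClass EntropyProfile
setClass("EntropyProfile",
  representation(domain = "character", entropies = "numeric",
                 meanEntropy = "numeric"))

setValidity("EntropyProfile", function(object) {
  msg <- character()
  if (length(object@entropies) < 1L) msg <- c(msg, "need at least one column")
  if (any(object@entropies < -1e-12) ||
      any(object@entropies > log(20) + 1e-9))
    msg <- c(msg, "entropies must lie in [0, ln 20]")
  if (abs(object@meanEntropy - mean(object@entropies)) > 1e-9)
    msg <- c(msg, "meanEntropy must equal mean(entropies)")
  if (length(msg)) msg else TRUE
})

#' Global conservation threshold (mean + 1 SD of all column entropies)
#'
#' @slot value threshold in nats; columns with entropy \code{<= value} are
#'   conserved.
#' @slot meanAll mean entropy over all columns of all profiles.
#' @slot sdAll population standard deviation over the same columns.
#'
#' @seealso [conservationThreshold()], [isConserved()]
#' @exportClass ConservationThreshold
setClass("ConservationThreshold",
  representation(value = "numeric", meanAll = "numeric", sdAll = "numeric"))

setValidity("ConservationThreshold", function(object) {
  if (abs(object@value - (object@meanAll + object@sdAll)) > 1e-9)
    "value must equal meanAll + sdAll" else TRUE
})
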