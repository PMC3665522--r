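#' Accessors for domainHotspots S4 objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `domainAccession()` returns the domain accession of an object,
#' `modelLength()` its model length L, `mutationCounts()` the species-by-column
#' count matrix of a [DomainMutationTable-class], `mutationIds()` the ids
#' mapped to one (species, column), `dsScores()` / `scoreKind()` /
#' `speciesSet()` / `totalMutations()` the slots of a [ScoreVector-class],
#' `entropies()` / `meanEntropy()` those of an [EntropyProfile-class], and
#' `thresholdValue()` the cut-off of a [ConservationThreshold-class].
#'
#' @param x an object of the documented class.
#' @param species single species name (for `mutationIds`).
#' @param position 1-based domain column (for `mutationIds`).
#' @return the accessed component; see each method.
#' @name accessors
#' @aliases domainAccession modelLength mutationCounts mutationIds dsScores
#'   scoreKind speciesSet totalMutations entropies meanEntropy thresholdValue
NULL

#' @rdname accessors
#' @export
setGeneric("domainAccession", function(x) standardGeneric("domainAccession"))

#' @rdname accessors
#' @export
setGeneric("modelLength", function(x) standardGeneric("modelLength"))

#' @rdname accessors
#' @export
setGeneric("mutationCounts", function(x) standardGeneric("mutationCounts"))

#' @rdname accessors
#' @export
setGeneric("mutationIds",
           function(x, species, position) standardGeneric("mutationIds"))

#' @rdname accessors
#' @export
setGeneric("dsScores", function(x) standardGeneric("dsScores"))

#' @rdname accessors
#' @export
setGeneric("scoreKind", function(x) standardGeneric("scoreKind"))

#' @rdname accessors
#' @export
setGeneric("speciesSet", function(x) standardGeneric("speciesSet"))

#' @rdname accessors
#' @export
setGeneric("totalMutations", function(x) standardGeneric("totalMutations"))

#' @rdname accessors
#' @export
setGeneric("entropies", function(x) standardGeneric("entropies"))

#' @rdname accessors
#' @export
setGeneric("meanEntropy", function(x) standardGeneric("meanEntropy"))

#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname accessors
setMethod("domainAccession", "DomainMutationTable", function(x) x@domain)
#' @rdname accessors
setMethod("domainAccession", "ScoreVector", function(x) x@domain)
#' @rdname accessors
setMethod("domainAccession", "EntropyProfile", function(x) x@domain)

#' @rdname accessors
setMethod("modelLength", "DomainMutationTable", function(x) x@length)
#' @rdname accessors
setMethod("modelLength", "ScoreVector", function(x) length(x@scores))
#' @rdname accessors
setMethod("modelLength", "EntropyProfile", function(x) length(x@entropies))

#' @rdname accessors
setMethod("mutationCounts", "DomainMutationTable", function(x) x@counts)

#' @rdname accessors
setMethod("mutationIds", "DomainMutationTable", function(x, species, position) {
  stopifnot(species %in% rownames(x@counts),
            position >= 1L, position <= x@length)
  x@mutationIndex[[species]][[position]]
})

#' @rdname accessors
setMethod("dsScores", "ScoreVector", function(x) x@scores)
#' @rdname accessors
setMethod("scoreKind", "ScoreVector", function(x) x@kind)
#' @rdname accessors
setMethod("speciesSet", "ScoreVector", function(x) x@speciesSet)
#' @rdname accessors
setMethod("totalMutations", "ScoreVector", function(x) x@nTotal)

#' @rdname accessors
setMethod("entropies", "EntropyProfile", function(x) x@entropies)
#' @rdname accessors
setMethod("meanEntropy", "EntropyProfile", function(x) x@meanEntropy)

#' @rdname accessors
setMethod("thresholdValue", "ConservationThreshold", function(x) x@value)

setMethod("show", "DomainMutationTable", function(object) {
  cat("DomainMutationTable for", object@domain,
      sprintf("(L = %d)\n", object@length))
  tot <- rowSums(object@counts)
  for (sp in rownames(object@counts))
    cat(sprintf("  %s: %d domain mutations over %d mutated columns\n",
                sp, tot[[sp]], sum(object@counts[sp, ] > 0)))
})

setMethod("show", "ScoreVector", function(object) {
  cat(sprintf("ScoreVector [%s] for %s (L = %d, n = %d, species: %s)\n",
              object@kind, object@domain, length(object@scores),
              object@nTotal, paste(object@speciesSet, collapse = "+")))
  if (any(object@scores > 0))
    cat(sprintf("  max score %.3f at column %d\n",
                max(object@scores), which.max(object@scores)))
})

setMethod("show", "EntropyProfile", function(object) {
  cat(sprintf("EntropyProfile for %s (L = %d, mean H = %.4f nats)\n",
              object@domain, length(object@entropies), object@meanEntropy))
})

setMethod("show", "ConservationThreshold", function(object) {
  cat(sprintf(
    "ConservationThreshold: H <= %.4f nats (mean %.4f + population SD %.4f)\n",
    object@value, object@meanAll, object@sdAll))
})
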