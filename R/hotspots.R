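#' Select the representative domain of a redundant group
#'
#' Orders the candidate accessions alphanumerically (case-insensitive
#' lexicographic, lowest first) and returns the first hierarchy-root domain;
#' if the group has no root, the first domain carrying functional feature
#' annotation; otherwise the first domain outright.
#'
#' @param domains data.frame of candidate domain models (subset of a
#'   [readDomainTable()] table), non-empty.
#' @return single accession string.
#' @export
selectRepresentativeDomain <- function(domains) {
  stopifnot(nrow(domains) >= 1L)
  d <- domains[order(tolower(domains$accession), domains$accession), ,
               drop = FALSE]
  i <- which(d$is_root)[1L]
  if (is.na(i)) i <- which(d$has_features)[1L]
  if (is.na(i)) i <- 1L
  d$accession[i]
}

#' Collapse hotspot calls that arise from one mutation cluster
#'
#' Redundant domain copies (superfamily hierarchies, duplicate models from
#' different sources) each receive the same mutations, so one cluster can
#' surface as many hotspot calls. Calls sharing an identical underlying
#' mutation set (equal \code{mutation_set_key}) are grouped; the group count
#' is the non-redundant hotspot count, and each group is assigned a
#' representative domain by [selectRepresentativeDomain()]. For multi-species
#' calls, pass \code{sharedDomains} so the representative is chosen among
#' domains present in both species.
#'
#' @param calls data.frame from [callHotspots()]; all calls must share one
#'   kind and one threshold.
#' @param domains domain table ([readDomainTable()]).
#' @param sharedDomains optional accessions present in both species; when
#'   given, representative candidates are restricted to it (falling back to
#'   all members if the intersection is empty).
#' @return data.frame with one row per group: \code{mutation_set_key},
#'   \code{representative_domain}, \code{n_member_calls},
#'   \code{member_domains}, \code{max_score}, \code{kind}, \code{threshold},
#'   and a list-column \code{members} of member-call row indices into
#'   \code{calls}.
#' @export
deduplicateHotspots <- function(calls, domains, sharedDomains = NULL) {
  if (nrow(calls) == 0L) {
    out <- data.frame(mutation_set_key = character(),
                      representative_domain = character(),
                      n_member_calls = integer(), member_domains = character(),
                      max_score = numeric(), kind = character(),
                      threshold = numeric())
    out$members <- list()
    return(out)
  }
  if (length(unique(calls$kind)) != 1L || length(unique(calls$threshold)) != 1L)
    .dhStop("deduplicateHotspots expects calls of a single kind and threshold")
  grp <- split(seq_len(nrow(calls)), calls$mutation_set_key)
  rows <- lapply(names(grp), function(key) {
    ii <- grp[[key]]
    accs <- unique(calls$domain[ii])
    cand <- accs
    if (!is.null(sharedDomains)) {
      shared <- intersect(accs, sharedDomains)
      if (length(shared)) cand <- shared
    }
    rep <- selectRepresentativeDomain(
      domains[domains$accession %in% cand, , drop = FALSE])
    data.frame(mutation_set_key = key, representative_domain = rep,
               n_member_calls = length(ii),
               member_domains = paste(sort(accs), collapse = ";"),
               max_score = max(calls$score[ii]),
               kind = calls$kind[1L], threshold = calls$threshold[1L])
  })
  out <- do.call(rbind, rows)
  out$members <- unname(grp[out$mutation_set_key])
  out <- out[order(out$mutation_set_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link one species' hotspots to the other species' mutations
#'
#' A position-kind hotspot group links when any member (domain, column)
#' carries at least one mutation of the other species; a feature-kind group
#' links when any column of the same feature on a member domain does — the
#' feature-based flexibility that lets mutations at different columns of one
#' annotated site be related. Also reports the linked fraction and a
#' right-sided Fisher enrichment p-value whose 2x2 table classifies the
#' scoring species' mutated (domain, column) sites by hotspot status (rows)
#' and by presence of at least one other-species mutation (columns).
#'
#' @param groups output of [deduplicateHotspots()].
#' @param calls the call data.frame the groups were built from.
#' @param tables list of [DomainMutationTable-class] holding both species'
#'   counts.
#' @param speciesB the other species (whose mutations are searched).
#' @param features feature annotations (needed for feature-kind groups).
#' @return list with \code{groups} (input plus logical \code{linked}),
#'   \code{fraction} linked, \code{contingency} (named a/b/c/d vector) and
#'   \code{enrichment_p}.
#' @export
linkHotspots <- function(groups, calls, tables, speciesB, features = NULL) {
  countB <- function(acc, pos) {
    tb <- tables[[acc]]
    if (is.null(tb) || !speciesB %in% rownames(mutationCounts(tb))) return(0L)
    sum(mutationCounts(tb)[speciesB, pos])
  }
  featPositions <- function(acc, fname) {
    if (is.null(features)) return(integer(0))
    sel <- features$domain_accession == acc & features$feature_name == fname
    if (!any(sel)) return(integer(0))
    sort(unique(unlist(features$positions[sel])))
  }
  linked <- logical(nrow(groups))
  for (g in seq_len(nrow(groups))) {
    for (i in groups$members[[g]]) {
      acc <- calls$domain[i]
      hit <- if (calls$kind[i] %in% c("feature", "multispecies_feature") &&
                 !is.na(calls$feature[i])) {
        fp <- featPositions(acc, calls$feature[i])
        if (length(fp) == 0L) fp <- calls$position[i]
        countB(acc, fp) > 0L
      } else {
        countB(acc, calls$position[i]) > 0L
      }
      if (hit) { linked[g] <- TRUE; break }
    }
  }
  groups$linked <- linked
  # enrichment over the scoring species' mutated sites
  spA <- unique(unlist(strsplit(calls$species_set, ",", fixed = TRUE)))
  hotKey <- unique(paste(calls$domain, calls$position))
  a <- b <- cc <- d <- 0L
  for (tb in tables) {
    cts <- mutationCounts(tb)
    spAHere <- intersect(spA, rownames(cts))
    if (length(spAHere) == 0L) next
    mutA <- which(colSums(cts[spAHere, , drop = FALSE]) > 0)
    if (length(mutA) == 0L) next
    hasB <- if (speciesB %in% rownames(cts))
      cts[speciesB, mutA] > 0 else rep(FALSE, length(mutA))
    isHot <- paste(domainAccession(tb), mutA) %in% hotKey
    a <- a + sum(isHot & hasB);  b <- b + sum(isHot & !hasB)
    cc <- cc + sum(!isHot & hasB); d <- d + sum(!isHot & !hasB)
  }
  list(groups = groups,
       fraction = if (nrow(groups)) mean(linked) else NA_real_,
       contingency = c(a = a, b = b, c = cc, d = d),
       enrichment_p = enrichmentTest(a, b, cc, d))
}

#' Right-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric upper-tail probability \eqn{P(X \ge a)} given the
#' table margins (the one-sided "greater" Fisher test), computed with
#' [stats::phyper]. An all-zero table gives p = 1.
#'
#' @param a,b,c,d cell counts: row 1 = in-class yes/no, row 2 = out-of-class
#'   yes/no. \code{a} may also be a 2x2 matrix (remaining arguments ignored).
#' @return p-value.
#' @export
enrichmentTest <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) { b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1] }
  if (any(c(a, b, c, d) < 0)) .dhStop("contingency cells must be non-negative")
  if (a + b + c + d == 0) return(1)
  stats::phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

#' Classify how a mutation can be related to the other species
#'
#' A mutation is domain-relatable when it maps (through an E-value-filtered
#' hit, including the insertion gap rule) onto a domain shared by both
#' species' proteomes, and ortholog-relatable when its gene has an ortholog
#' pair to the other species. The two booleans give four classes:
#' \code{both}, \code{domain_only}, \code{ortholog_only}, \code{neither}.
#'
#' @param mutations data.frame from [readMutationTable()].
#' @param orthologs data.frame from [readOrthologPairs()].
#' @param hits list from [readDomainHits()].
#' @param sharedDomains accessions present in both species' proteomes.
#' @param eMax E-value cut-off.
#' @return data.frame with \code{mutation_id}, \code{species},
#'   \code{relatability} (factor over the four classes).
#' @export
classifyRelatability <- function(mutations, orthologs, hits, sharedDomains,
                                 eMax = 0.001) {
  fh <- filterHits(hits, eMax)
  hitsByProtein <- split(fh, vapply(fh, `[[`, character(1), "protein_id"))
  orthoKey <- unique(c(paste(orthologs$species_a, orthologs$gene_id_a),
                       paste(orthologs$species_b, orthologs$gene_id_b)))
  cls <- character(nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    hh <- hitsByProtein[[mutations$protein_id[i]]]
    dRel <- FALSE
    if (!is.null(hh)) for (h in hh) {
      if (h$domain_accession %in% sharedDomains &&
          !is.na(mapPosition(h, mutations$position[i]))) { dRel <- TRUE; break }
    }
    oRel <- paste(mutations$species[i], mutations$gene_id[i]) %in% orthoKey
    cls[i] <- if (dRel && oRel) "both" else if (dRel) "domain_only"
      else if (oRel) "ortholog_only" else "neither"
  }
  data.frame(mutation_id = mutations$mutation_id,
             species = mutations$species,
             relatability = factor(cls, levels = c("both", "domain_only",
                                                   "ortholog_only", "neither")))
}

#' Disease-phenotype co-occurrence tests at shared domain sites
#'
#' Enumerates overlap events — a human mutation and a yeast mutation
#' localised at the same column of the same domain — and tests every observed
#' (human disease, yeast phenotype) label pair with a right-sided Fisher
#' exact test on: a = co-occurrences of the pair, b = the disease with other
#' phenotypes, c = the phenotype with other diseases, d = all remaining
#' overlaps. To avoid overestimation from redundant domain copies, no
#' mutation is counted more than once as overlapping a given other-species
#' label: events are deduplicated greedily in deterministic (human id, yeast
#' id) order on the (human mutation, phenotype) and (yeast mutation, disease)
#' keys.
#'
#' @param tables list of [DomainMutationTable-class] with both species.
#' @param mutations mutation data.frame (labels looked up by id).
#' @param speciesHuman,speciesYeast species names used for the two sides.
#' @return data.frame sorted by ascending p: \code{H_label}, \code{Y_label},
#'   \code{a}, \code{b}, \code{c}, \code{d}, \code{p_value}; zero overlaps
#'   give an empty result.
#' @export
cooccurrenceTests <- function(tables, mutations,
                              speciesHuman = "human", speciesYeast = "yeast") {
  lab <- setNames(mutations$label, mutations$mutation_id)
  ev <- list()
  for (tb in tables) {
    cts <- mutationCounts(tb)
    if (!all(c(speciesHuman, speciesYeast) %in% rownames(cts))) next
    pos <- which(cts[speciesHuman, ] > 0 & cts[speciesYeast, ] > 0)
    for (j in pos) {
      hIds <- mutationIds(tb, speciesHuman, j)
      yIds <- mutationIds(tb, speciesYeast, j)
      ev[[length(ev) + 1L]] <-
        expand.grid(hm = hIds, ym = yIds,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(H_label = character(), Y_label = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p_value = numeric())
  if (length(ev) == 0L) return(empty)
  ev <- unique(do.call(rbind, ev))        # one event per mutation pair
  ev$H <- unname(lab[ev$hm]); ev$Y <- unname(lab[ev$ym])
  ev <- ev[order(ev$hm, ev$ym), , drop = FALSE]
  # greedy dedup: a kept event consumes its (human mutation, phenotype) and
  # (yeast mutation, disease) keys; dropped events consume nothing
  seen <- new.env(parent = emptyenv())
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    k1 <- paste0("h\r", ev$hm[i], "\r", ev$Y[i])
    k2 <- paste0("y\r", ev$ym[i], "\r", ev$H[i])
    if (is.null(seen[[k1]]) && is.null(seen[[k2]])) {
      keep[i] <- TRUE
      seen[[k1]] <- TRUE
      seen[[k2]] <- TRUE
    }
  }
  ev <- ev[keep, , drop = FALSE]
  N <- nrow(ev)
  if (N == 0L) return(empty)
  pairs <- unique(ev[, c("H", "Y")])
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    H <- pairs$H[i]; Y <- pairs$Y[i]
    a <- sum(ev$H == H & ev$Y == Y)
    b <- sum(ev$H == H) - a
    cc <- sum(ev$Y == Y) - a
    d <- N - a - b - cc
    data.frame(H_label = H, Y_label = Y, a = a, b = b, c = cc, d = d,
               p_value = enrichmentTest(a, b, cc, d))
  })
  res <- do.call(rbind, res)
  res <- res[order(res$p_value, res$H_label, res$Y_label), , drop = FALSE]
  rownames(res) <- NULL
  res
}
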