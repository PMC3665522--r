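#' Filter domain hits by E-value
#'
#' Keeps hits with \code{e_value <= eMax} (boundary inclusive), preserving
#' order. The default 0.001 is the conventional profile-HMM significance
#' cut-off for accepting a domain-protein alignment.
#'
#' @param hits list of hits from [readDomainHits()].
#' @param eMax maximum E-value retained (default 0.001).
#' @return filtered list of hits.
#' @export
filterHits <- function(hits, eMax = 0.001) {
  stopifnot(eMax > 0)
  hits[vapply(hits, function(h) h$e_value <= eMax, logical(1))]
}

#' Project a protein position into domain coordinates
#'
#' If the protein position aligns to a match column, that 1-based column is
#' returned. If it falls in an insertion relative to the domain model, the
#' mutation is assigned to the last match column preceding the insertion; an
#' insertion before any match column has no such column and returns NA
#' (logged). Positions outside the aligned span return NA.
#'
#' @param hit one hit from [readDomainHits()].
#' @param proteinPosition 1-based residue index (vectorised).
#' @param verbose log unmappable before-first-column insertions.
#' @return integer vector of domain columns (NA where unmapped).
#' @export
mapPosition <- function(hit, proteinPosition, verbose = FALSE) {
  m <- hit$map
  # last match column at or before each map row
  lastCol <- m$domain_col
  for (i in seq_along(lastCol))
    if (is.na(lastCol[i]) && i > 1L) lastCol[i] <- lastCol[i - 1L]
  idx <- match(proteinPosition, m$protein_pos)
  out <- rep(NA_integer_, length(proteinPosition))
  inMap <- !is.na(idx)
  out[inMap] <- lastCol[idx[inMap]]
  if (verbose && any(inMap & is.na(out)))
    .dhLog("insertion before the first match column: position(s) unmapped")
  out
}

#' Aggregate mutations into per-domain count tables
#'
#' Maps every retained mutation through every E-value-filtered hit on its
#' protein and aggregates counts per (domain, match column, species) — the
#' sample \eqn{X_1, \dots, X_L} scored by [positionScores()]. Mutations on
#' non-representative proteins are ignored. Redundant domain copies each
#' receive the mutation (one table per accession); a mutation contributes at
#' most once per (domain, column), while two hits of the same repeat domain
#' can legitimately place it on two different columns.
#'
#' @param mutations data.frame from [readMutationTable()].
#' @param hits list from [readDomainHits()].
#' @param representatives data.frame from [selectRepresentativeProteins()].
#' @param domains domain table from [readDomainTable()]; every domain gets a
#'   table (all-zero if no mutation maps).
#' @param proteins optional protein table; if given, a mutation position
#'   exceeding its protein length is a hard error.
#' @param eMax E-value cut-off passed to [filterHits()].
#' @param verbose log progress.
#' @return named list of [DomainMutationTable-class] objects (one per domain
#'   accession).
#' @export
buildDomainTables <- function(mutations, hits, representatives, domains,
                              proteins = NULL, eMax = 0.001, verbose = TRUE) {
  fh <- filterHits(hits, eMax)
  repIds <- unique(representatives$protein_id)
  keep <- mutations$protein_id %in% repIds
  mut <- mutations[keep, , drop = FALSE]
  if (!is.null(proteins) && nrow(mut)) {
    plen <- setNames(proteins$length, proteins$protein_id)
    bad <- which(mut$position > plen[mut$protein_id])
    if (length(bad))
      .dhStop(sprintf("mutation %s at position %d exceeds the length of protein %s",
                      mut$mutation_id[bad[1L]], mut$position[bad[1L]],
                      mut$protein_id[bad[1L]]))
  }
  speciesLevels <- sort(unique(mutations$species))
  if (length(speciesLevels) == 0L) speciesLevels <- "none"

  hitsByProtein <- split(fh, vapply(fh, `[[`, character(1), "protein_id"))
  # triples (domain, column, species, mutation_id)
  recs <- vector("list", nrow(mut))
  for (i in seq_len(nrow(mut))) {
    hh <- hitsByProtein[[mut$protein_id[i]]]
    if (is.null(hh)) next
    dom <- character(); col <- integer()
    for (h in hh) {
      dc <- mapPosition(h, mut$position[i])
      if (!is.na(dc)) { dom <- c(dom, h$domain_accession); col <- c(col, dc) }
    }
    if (length(dom)) {
      u <- !duplicated(paste(dom, col))   # once per (domain, position)
      recs[[i]] <- data.frame(domain = dom[u], col = col[u],
                              species = mut$species[i],
                              mutation_id = mut$mutation_id[i])
    }
  }
  recs <- do.call(rbind, recs)

  tables <- vector("list", nrow(domains))
  names(tables) <- domains$accession
  for (k in seq_len(nrow(domains))) {
    acc <- domains$accession[k]
    L <- domains$length[k]
    counts <- matrix(0L, nrow = length(speciesLevels), ncol = L,
                     dimnames = list(speciesLevels, NULL))
    idx <- lapply(speciesLevels, function(s)
      replicate(L, character(0), simplify = FALSE))
    names(idx) <- speciesLevels
    if (!is.null(recs)) {
      r <- recs[recs$domain == acc, , drop = FALSE]
      for (j in seq_len(nrow(r))) {
        sp <- r$species[j]; cc <- r$col[j]
        counts[sp, cc] <- counts[sp, cc] + 1L
        idx[[sp]][[cc]] <- c(idx[[sp]][[cc]], r$mutation_id[j])
      }
    }
    tables[[k]] <- new("DomainMutationTable", domain = acc,
                       length = as.integer(L), counts = counts,
                       mutationIndex = idx)
  }
  if (verbose)
    .dhLog(sprintf("%d mutations propagated to %d domain mutations over %d domains",
                   nrow(mut), if (is.null(recs)) 0L else nrow(recs),
                   nrow(domains)))
  tables
}

#' Tally domain mutations at functional and conserved sites
#'
#' Per species, counts the total number of domain mutations, those located at
#' feature-annotated columns, those at conserved columns (entropy at or below
#' the global threshold), and — when \code{mutations} and \code{hits} are
#' supplied — the fraction of protein mutations that fall inside any domain
#' region. Each class is paired with a right-sided Fisher exact enrichment
#' p-value against the domain's column composition (annotated/conserved
#' columns vs the rest, mutations at them vs elsewhere).
#'
#' @param tables list of [DomainMutationTable-class] from [buildDomainTables()].
#' @param features feature annotations from [readFeatureAnnotations()].
#' @param profiles named list of [EntropyProfile-class] (one per domain with
#'   mutations).
#' @param threshold a [ConservationThreshold-class].
#' @param mutations,hits optional; enable the inside-domain fraction.
#' @param eMax E-value cut-off for the inside-domain test.
#' @return data.frame, one row per species, with columns
#'   \code{domain_mutations}, \code{mutated_positions}, \code{at_feature},
#'   \code{at_conserved}, their fractions and enrichment p-values, and
#'   \code{fraction_in_domains} (NA when mutations/hits absent).
#' @export
tallySiteClasses <- function(tables, features, profiles, threshold,
                             mutations = NULL, hits = NULL, eMax = 0.001) {
  featCols <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(features))) {
    acc <- features$domain_accession[i]
    prev <- if (!is.null(featCols[[acc]])) featCols[[acc]] else integer(0)
    featCols[[acc]] <- union(prev, features$positions[[i]])
  }
  species <- rownames(mutationCounts(tables[[1L]]))
  res <- lapply(species, function(sp) {
    tot <- 0L; atF <- 0L; atC <- 0L; mutPos <- 0L
    colF <- 0L; colC <- 0L; colAll <- 0L
    for (tb in tables) {
      cts <- mutationCounts(tb)[sp, ]
      if (!any(cts > 0)) next
      acc <- domainAccession(tb)
      fc <- if (!is.null(featCols[[acc]])) featCols[[acc]] else integer(0)
      pr <- profiles[[acc]]
      if (is.null(pr))
        .dhStop(sprintf("no entropy profile supplied for domain %s", acc))
      cons <- which(isConserved(entropies(pr), threshold))
      tot <- tot + sum(cts)
      mutPos <- mutPos + sum(cts > 0)
      atF <- atF + sum(cts[fc])
      atC <- atC + sum(cts[cons])
      colAll <- colAll + modelLength(tb)
      colF <- colF + length(fc)
      colC <- colC + length(cons)
    }
    pF <- if (tot > 0) enrichmentTest(atF, tot - atF,
                                      colF, max(colAll - colF, 0L)) else NA_real_
    pC <- if (tot > 0) enrichmentTest(atC, tot - atC,
                                      colC, max(colAll - colC, 0L)) else NA_real_
    data.frame(species = sp, domain_mutations = tot, mutated_positions = mutPos,
               at_feature = atF, frac_feature = ifelse(tot > 0, atF / tot, NA),
               p_feature = pF,
               at_conserved = atC, frac_conserved = ifelse(tot > 0, atC / tot, NA),
               p_conserved = pC,
               fraction_in_domains = NA_real_)
  })
  res <- do.call(rbind, res)
  if (!is.null(mutations) && !is.null(hits) && nrow(mutations)) {
    fh <- filterHits(hits, eMax)
    hitsByProtein <- split(fh, vapply(fh, `[[`, character(1), "protein_id"))
    inside <- vapply(seq_len(nrow(mutations)), function(i) {
      hh <- hitsByProtein[[mutations$protein_id[i]]]
      if (is.null(hh)) return(FALSE)
      any(vapply(hh, function(h) !is.na(mapPosition(h, mutations$position[i])),
                 logical(1)))
    }, logical(1))
    for (k in seq_len(nrow(res))) {
      sel <- mutations$species == res$species[k]
      if (any(sel)) res$fraction_in_domains[k] <- mean(inside[sel])
    }
  }
  rownames(res) <- NULL
  res
}
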