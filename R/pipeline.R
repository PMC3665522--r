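.metaHeader <- function(con, stage, params, timestamp = FALSE) {
  writeLines(c(
    sprintf("# domainHotspots %s", as.character(utils::packageVersion("domainHotspots"))),
    sprintf("# stage: %s", stage),
    if (timestamp) sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("# %s", params)), con)
}

.writeStage <- function(df, path, stage, params, timestamp = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  .metaHeader(con, stage, params, timestamp)
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Run the full domain-hotspot pipeline on a directory of input tables
#'
#' Orchestrates the stages in order: representative-protein selection and
#' mutation-to-domain mapping; column entropy and the global conservation
#' threshold; position-based, feature-based and pooled multi-species
#' DS-Scores; hotspot calling at each threshold; de-redundification; linking
#' of the first species' hotspots to the second species' mutations;
#' relatability classification; and disease-phenotype co-occurrence tests.
#' Every output table carries a commented metadata header (package version,
#' stage, parameters; a timestamp only on request so reruns are
#' byte-identical).
#'
#' Multi-species scores are computed only for domains present in both
#' species' filtered hits, and multi-species hotspot groups are additionally
#' flagged \code{novel} when no member (domain, position) reached the same
#' threshold in either single-species analysis.
#'
#' @param inputDir directory containing mutations.tsv, proteins.tsv,
#'   domains.tsv, hits.tsv, features.tsv, orthologs.tsv, freqs.tsv (the
#'   dialects written by [writeScenario()]).
#' @param outDir output directory (created if needed).
#' @param thresholds DS-Score thresholds, default \code{c(1.6, 1.3, 1.0)}.
#' @param eValueMax hit E-value cut-off, default 0.001.
#' @param species length-2 character: the scoring species pair; hotspots of
#'   \code{species[2]} are linked to mutations of \code{species[1]} and vice
#'   versa is available from the returned tables.
#' @param timestamp include a wall-clock line in output headers.
#' @param verbose log stage progress.
#' @return (invisibly) list with \code{status} (0 on success), the per-stage
#'   objects (\code{tables}, \code{profiles}, \code{threshold},
#'   \code{scores}, \code{calls}, \code{groups}, \code{links},
#'   \code{relatability}, \code{cooccurrence}, \code{siteClasses}) and the
#'   paths written.
#' @export
runPipeline <- function(inputDir, outDir, thresholds = c(1.6, 1.3, 1.0),
                        eValueMax = 0.001, species = c("human", "yeast"),
                        timestamp = FALSE, verbose = TRUE) {
  if (any(thresholds <= 0)) .dhStop("thresholds must be positive")
  if (!dir.exists(inputDir))
    .dhStop(sprintf("input directory not found: %s", inputDir),
            class = "dh_missing_input")
  pth <- function(f) file.path(inputDir, f)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  params <- sprintf("thresholds: %s; e_value_max: %g; species: %s; sd: population",
                    paste(thresholds, collapse = ","), eValueMax,
                    paste(species, collapse = ","))

  .dhLog("reading inputs", verbose = verbose)
  mutations <- readMutationTable(pth("mutations.tsv"), verbose = verbose)
  proteins  <- readProteinTable(pth("proteins.tsv"))
  domains   <- readDomainTable(pth("domains.tsv"))
  hits      <- readDomainHits(pth("hits.tsv"), domains)
  features  <- readFeatureAnnotations(pth("features.tsv"), domains)
  orthologs <- readOrthologPairs(pth("orthologs.tsv"))
  freqs     <- readFrequencyTable(pth("freqs.tsv"))

  .dhLog("stage map: representatives and domain count tables", verbose = verbose)
  reps <- selectRepresentativeProteins(proteins)
  tables <- buildDomainTables(mutations, hits, reps, domains,
                              proteins = proteins, eMax = eValueMax,
                              verbose = verbose)
  cntRows <- list()
  for (tb in tables) {
    cts <- mutationCounts(tb)
    for (sp in rownames(cts)) {
      jj <- which(cts[sp, ] > 0)
      for (j in jj)
        cntRows[[length(cntRows) + 1L]] <- data.frame(
          domain_accession = domainAccession(tb), species = sp, position = j,
          count = cts[sp, j],
          mutation_ids = paste(sort(mutationIds(tb, sp, j)), collapse = ";"))
    }
  }
  domainCounts <- if (length(cntRows)) do.call(rbind, cntRows) else
    data.frame(domain_accession = character(), species = character(),
               position = integer(), count = integer(),
               mutation_ids = character())
  .writeStage(domainCounts, file.path(outDir, "domain_counts.tsv"),
              "map", params, timestamp)

  .dhLog("stage entropy", verbose = verbose)
  profiles <- entropyProfiles(freqs)
  thr <- conservationThreshold(profiles)
  entRows <- do.call(rbind, lapply(profiles, function(p) data.frame(
    domain_accession = domainAccession(p),
    position = seq_len(modelLength(p)),
    entropy = entropies(p),
    conserved = as.integer(isConserved(entropies(p), thr)))))
  .writeStage(entRows, file.path(outDir, "entropy.tsv"), "entropy",
              sprintf("%s; threshold: %.6f = mean %.6f + population sd %.6f",
                      params, thresholdValue(thr), thr@meanAll, thr@sdAll),
              timestamp)

  # species sharing per domain, from filtered hits
  fh <- filterHits(hits, eValueMax)
  protSpecies <- setNames(proteins$species, proteins$protein_id)
  domSpecies <- split(protSpecies[vapply(fh, `[[`, character(1), "protein_id")],
                      vapply(fh, `[[`, character(1), "domain_accession"))
  sharedDomains <- names(Filter(function(s) all(species %in% s), domSpecies))

  .dhLog("stage score", verbose = verbose)
  speciesInData <- intersect(species, unique(mutations$species))
  scores <- list(); scoreRows <- list()
  for (tb in tables) {
    acc <- domainAccession(tb)
    sets <- lapply(speciesInData, identity)
    if (length(speciesInData) > 1L && acc %in% sharedDomains)
      sets <- c(sets, list(speciesInData))
    for (ss in sets) {
      pv <- positionScores(tb, ss)
      if (totalMutations(pv) == 0L) next
      fv <- featureScores(pv, features)
      for (v in list(pv, fv)) {
        scores[[length(scores) + 1L]] <- list(vector = v, table = tb)
        jj <- which(dsScores(v) > 0)
        if (length(jj))
          scoreRows[[length(scoreRows) + 1L]] <- data.frame(
            domain_accession = acc, kind = scoreKind(v),
            species_set = paste(speciesSet(v), collapse = ","),
            position = jj, count = v@counts[jj], score = dsScores(v)[jj])
      }
    }
  }
  scoreTab <- if (length(scoreRows)) do.call(rbind, scoreRows) else
    data.frame(domain_accession = character(), kind = character(),
               species_set = character(), position = integer(),
               count = integer(), score = numeric())
  .writeStage(scoreTab, file.path(outDir, "scores.tsv"), "score", params,
              timestamp)

  .dhLog("stage hotspots + dedup", verbose = verbose)
  callRows <- list()
  for (sv in scores)
    for (th in thresholds) {
      cl <- callHotspots(sv$vector, th, sv$table)
      if (nrow(cl)) callRows[[length(callRows) + 1L]] <- cl
    }
  calls <- if (length(callRows)) do.call(rbind, callRows) else
    emptyHotspotCalls()
  .writeStage(calls[, setdiff(names(calls), "feature_positions"), drop = FALSE],
              file.path(outDir, "hotspots.tsv"), "hotspots", params, timestamp)

  groupRows <- list(); groupsBySlice <- list()
  for (kind in unique(calls$kind)) for (th in thresholds) {
    sel <- calls$kind == kind & calls$threshold == th
    if (!any(sel)) next
    multis <- grepl("^multispecies", kind)
    g <- deduplicateHotspots(calls[sel, , drop = FALSE], domains,
                             sharedDomains = if (multis) sharedDomains)
    if (multis && nrow(g)) {
      # novel: no member site reached this threshold in a single-species run
      singleKind <- sub("^multispecies_", "", kind)
      singles <- calls[calls$kind == singleKind & calls$threshold == th, ,
                       drop = FALSE]
      singleSites <- paste(singles$domain, singles$position)
      cl <- calls[sel, , drop = FALSE]
      g$novel <- vapply(g$members, function(ii)
        !any(paste(cl$domain[ii], cl$position[ii]) %in% singleSites),
        logical(1))
    }
    groupsBySlice[[paste(kind, th)]] <- list(groups = g,
                                             calls = calls[sel, , drop = FALSE])
    gg <- g; gg$members <- NULL
    groupRows[[length(groupRows) + 1L]] <- gg
  }
  groupTab <- if (length(groupRows)) {
    base <- do.call(rbind, lapply(groupRows, function(g) {
      g$novel <- if ("novel" %in% names(g)) g$novel else NA
      g
    }))
    base
  } else data.frame(mutation_set_key = character(),
                    representative_domain = character(),
                    n_member_calls = integer(), member_domains = character(),
                    max_score = numeric(), kind = character(),
                    threshold = numeric(), novel = logical())
  .writeStage(groupTab, file.path(outDir, "hotspot_groups.tsv"), "dedup",
              params, timestamp)

  .dhLog("stage link", verbose = verbose)
  spA <- species[1L]; spB <- species[2L]
  linkRows <- list(); links <- list()
  for (kind in c("position", "feature")) for (th in thresholds) {
    slice <- groupsBySlice[[paste(kind, th)]]
    if (is.null(slice)) next
    # hotspots of spB (e.g. yeast) linked to mutations of spA (e.g. human)
    selB <- slice$calls$species_set == spB
    if (!any(selB)) next
    gB <- deduplicateHotspots(slice$calls[selB, , drop = FALSE], domains)
    lk <- linkHotspots(gB, slice$calls[selB, , drop = FALSE], tables, spA,
                       features)
    links[[paste(kind, th)]] <- lk
    linkRows[[length(linkRows) + 1L]] <- data.frame(
      kind = kind, threshold = th, hotspot_species = spB,
      target_species = spA, n_groups = nrow(gB),
      n_linked = sum(lk$groups$linked), fraction = lk$fraction,
      a = lk$contingency[["a"]], b = lk$contingency[["b"]],
      c = lk$contingency[["c"]], d = lk$contingency[["d"]],
      p_value = lk$enrichment_p)
  }
  linkTab <- if (length(linkRows)) do.call(rbind, linkRows) else
    data.frame(kind = character(), threshold = numeric(),
               hotspot_species = character(), target_species = character(),
               n_groups = integer(), n_linked = integer(),
               fraction = numeric(), a = integer(), b = integer(),
               c = integer(), d = integer(), p_value = numeric())
  .writeStage(linkTab, file.path(outDir, "links.tsv"), "link", params,
              timestamp)

  .dhLog("stage relatability + cooccurrence + site classes", verbose = verbose)
  relat <- classifyRelatability(mutations, orthologs, hits, sharedDomains,
                                eMax = eValueMax)
  .writeStage(relat, file.path(outDir, "relatability.tsv"), "relate", params,
              timestamp)
  cooc <- cooccurrenceTests(tables, mutations,
                            speciesHuman = spA, speciesYeast = spB)
  .writeStage(cooc, file.path(outDir, "cooccurrence.tsv"), "cooccur", params,
              timestamp)
  siteClasses <- tallySiteClasses(tables, features, profiles, thr,
                                  mutations = mutations, hits = hits,
                                  eMax = eValueMax)
  .writeStage(siteClasses, file.path(outDir, "site_classes.tsv"),
              "site_classes", params, timestamp)

  invisible(list(status = 0L, tables = tables, profiles = profiles,
                 threshold = thr, scores = scores, calls = calls,
                 groups = groupsBySlice, links = links, relatability = relat,
                 cooccurrence = cooc, siteClasses = siteClasses,
                 sharedDomains = sharedDomains,
                 outputs = list.files(outDir, full.names = TRUE)))
}
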