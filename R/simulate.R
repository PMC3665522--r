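HUMAN_DISEASES <- c("Wilson_disease", "Costello_syndrome", "Crouzon_syndrome",
                    "Nemaline_myopathy", "Friedreich_ataxia",
                    "Night_blindness", "Hyperinsulinemic_hypoglycemia",
                    "Methemoglobinemia")
YEAST_PHENOTYPES <- c("metal_resistance_increased", "inviable", "slow_growth",
                      "mutation_frequency_increased",
                      "heat_sensitivity_increased",
                      "resistance_to_chemicals_decreased",
                      "protein_activity_decreased", "lifespan_decreased")
FEATURE_VOCAB <- c("Active_site", "ATP_binding_site", "GTP_Mg2_binding_site",
                   "Substrate_binding_site", "Activation_loop", "G1_box",
                   "Ca2_binding_site", "DNA_binding_site")

#' Configure a synthetic two-species mutation scenario
#'
#' Defines the joint structure of a generated dataset: a set of domain
#' superfamilies each copied \code{redundancyFactor} times (identical
#' alignment maps, exactly one hierarchy root per superfamily), two species
#' of proteins carrying those domains (yeast-like proteins single-domain,
#' human-like 1-3 domains), mutations that are uniform background over mapped
#' columns plus planted positional clusters and planted disease-phenotype
#' co-occurrence pairs, CDD-style feature annotations covering a fraction of
#' columns, Homologene-style ortholog pairs, and Dirichlet-drawn per-column
#' amino-acid frequencies with a configurable fraction of low-entropy
#' columns.
#'
#' @param seed integer driving every random draw (sub-streams per generation
#'   stage, so adding a stage never perturbs earlier draws).
#' @param nSuperfamilies number of independent domain superfamilies.
#' @param domainLengthRange inclusive range of model lengths L.
#' @param redundancyFactor identical-mapping domain copies per superfamily.
#' @param nProteinsPerSpecies proteins (= genes) per species.
#' @param nMutationsPerSpecies total mutations per species, planted included.
#' @param hotspotPlan NULL or data.frame with columns \code{superfamily}
#'   (1-based index), \code{position} (domain column), \code{species}
#'   (\code{"human"}, \code{"yeast"} or \code{"both"} = planted in each), and
#'   \code{fraction} of that species' mutations placed at the column.
#' @param featureCoverage fraction of columns annotated with functional
#'   features.
#' @param featureSizeRange inclusive range of feature sizes (columns).
#' @param orthologFraction fraction of genes given a cross-species ortholog.
#' @param sharedDomainFraction fraction of superfamilies present in both
#'   species.
#' @param cooccurrencePlan NULL or data.frame with columns \code{disease},
#'   \code{phenotype}, \code{count}: plants \code{count} human and
#'   \code{count} yeast mutations with those labels at one shared domain
#'   column.
#' @param offDomainFraction fraction of background mutations placed outside
#'   every domain region (exercises the relatability classes and the
#'   inside-domain tally).
#' @param conservedColumnFraction fraction of columns drawn low-entropy.
#' @param backgroundPlacement placement model for background mutations inside
#'   domains; only \code{"uniform"} is defined.
#' @return a validated \code{ScenarioConfig} list.
#' @export
scenarioConfig <- function(seed = 1L,
                           nSuperfamilies = 8L,
                           domainLengthRange = c(60L, 150L),
                           redundancyFactor = 3L,
                           nProteinsPerSpecies = 30L,
                           nMutationsPerSpecies = 300L,
                           hotspotPlan = data.frame(
                             superfamily = c(1L, 2L, 3L),
                             position = c(25L, 40L, 10L),
                             species = c("yeast", "human", "both"),
                             fraction = c(0.08, 0.08, 0.05)),
                           featureCoverage = 0.25,
                           featureSizeRange = c(3L, 10L),
                           orthologFraction = 0.2,
                           sharedDomainFraction = 0.87,
                           cooccurrencePlan = data.frame(
                             disease = "Wilson_disease",
                             phenotype = "metal_resistance_increased",
                             count = 6L),
                           offDomainFraction = 0.25,
                           conservedColumnFraction = 0.6,
                           backgroundPlacement = "uniform") {
  cfg <- list(seed = as.integer(seed), nSuperfamilies = as.integer(nSuperfamilies),
              domainLengthRange = as.integer(domainLengthRange),
              redundancyFactor = as.integer(redundancyFactor),
              nProteinsPerSpecies = as.integer(nProteinsPerSpecies),
              nMutationsPerSpecies = as.integer(nMutationsPerSpecies),
              hotspotPlan = hotspotPlan, featureCoverage = featureCoverage,
              featureSizeRange = as.integer(featureSizeRange),
              orthologFraction = orthologFraction,
              sharedDomainFraction = sharedDomainFraction,
              cooccurrencePlan = cooccurrencePlan,
              offDomainFraction = offDomainFraction,
              conservedColumnFraction = conservedColumnFraction,
              backgroundPlacement = match.arg(backgroundPlacement, "uniform"))
  fr <- c(cfg$featureCoverage, cfg$orthologFraction, cfg$sharedDomainFraction,
          cfg$offDomainFraction, cfg$conservedColumnFraction)
  if (any(fr < 0 | fr > 1)) .dhStop("config fractions must lie in [0, 1]")
  if (cfg$nSuperfamilies < 1L || cfg$redundancyFactor < 1L ||
      cfg$nProteinsPerSpecies < 1L || cfg$nMutationsPerSpecies < 0L)
    .dhStop("config sizes must be positive")
  if (!is.null(cfg$hotspotPlan) && nrow(cfg$hotspotPlan)) {
    hp <- cfg$hotspotPlan
    if (any(hp$fraction < 0) ||
        any(tapply(hp$fraction, hp$superfamily, sum) > 1))
      .dhStop("planted hotspot fractions per superfamily must sum to <= 1")
    if (any(hp$superfamily < 1L | hp$superfamily > cfg$nSuperfamilies))
      .dhStop("hotspot plan references an unknown superfamily")
  }
  class(cfg) <- "ScenarioConfig"
  cfg
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a complete synthetic two-species dataset
#'
#' Produces, deterministically for a given seed, every input table of the
#' pipeline (domains, proteins, hits, mutations, features, orthologs,
#' per-column frequencies) together with a ground-truth ledger that records
#' exactly where every mutation was placed, which clusters and co-occurrence
#' pairs were planted, the redundancy map, and which columns were drawn
#' low-entropy — so pipeline outputs can be recounted against the truth.
#'
#' @param config a [scenarioConfig()] object.
#' @param verbose log generation summary.
#' @return list with elements \code{domains}, \code{proteins}, \code{hits},
#'   \code{mutations}, \code{features}, \code{orthologs}, \code{freqs},
#'   \code{ledger}, \code{config}.
#' @seealso [generateNull()], [writeScenario()]
#' @export
generateScenario <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ScenarioConfig"))
  S <- config$nSuperfamilies
  R <- config$redundancyFactor
  srcPrefix <- c(CDD = "cd", Pfam = "pfam", SMART = "smart")

  ## stage 1: domain superfamilies and redundant copies -----------------
  set.seed(.subSeed(config$seed, 1L))
  lens <- .sampleFrom(seq(config$domainLengthRange[1L],
                          config$domainLengthRange[2L]), S, replace = TRUE)
  if (!is.null(config$hotspotPlan) && nrow(config$hotspotPlan)) {
    hp <- config$hotspotPlan
    bad <- hp$position > lens[hp$superfamily]
    if (any(bad))
      .dhStop("hotspot plan position exceeds the drawn domain length")
  }
  accCounter <- 0L
  domRows <- list(); sfAcc <- vector("list", S)
  for (s in seq_len(S)) {
    rootCopy <- sample.int(R, 1L)
    for (r in seq_len(R)) {
      accCounter <- accCounter + 1L
      src <- sample(names(srcPrefix), 1L)
      acc <- sprintf("%s%05d", srcPrefix[[src]], accCounter)
      domRows[[accCounter]] <- data.frame(
        accession = acc, source = src, length = lens[s],
        is_root = (r == rootCopy), superfamily_key = sprintf("sf%03d", s),
        has_features = FALSE)
      sfAcc[[s]] <- c(sfAcc[[s]], acc)
    }
  }
  domains <- do.call(rbind, domRows)

  ## stage 2: feature annotations ---------------------------------------
  set.seed(.subSeed(config$seed, 2L))
  featRows <- list(); sfFeatureCols <- vector("list", S)
  for (s in seq_len(S)) {
    L <- lens[s]
    nAnn <- round(config$featureCoverage * L)
    if (nAnn < 1L) next
    cols <- sort(sample.int(L, nAnn))
    sfFeatureCols[[s]] <- cols
    feats <- list(); i <- 1L; fidx <- 0L
    while (i <= length(cols)) {
      sz <- .sampleFrom(seq(config$featureSizeRange[1L],
                            config$featureSizeRange[2L]))
      fidx <- fidx + 1L
      feats[[fidx]] <- list(
        name = sprintf("%s_%d", sample(FEATURE_VOCAB, 1L), fidx),
        positions = cols[i:min(i + sz - 1L, length(cols))])
      i <- i + sz
    }
    # the root copy always carries annotation; other copies with prob 1/2
    annotated <- vapply(seq_len(R), function(r)
      domains$is_root[domains$accession == sfAcc[[s]][r]] ||
        stats::runif(1) < 0.5, logical(1))
    for (r in which(annotated)) {
      acc <- sfAcc[[s]][r]
      domains$has_features[domains$accession == acc] <- TRUE
      for (f in feats)
        featRows[[length(featRows) + 1L]] <- data.frame(
          domain_accession = acc, feature_name = f$name,
          positions = I(list(f$positions)))
    }
  }
  features <- if (length(featRows)) do.call(rbind, featRows) else
    data.frame(domain_accession = character(), feature_name = character(),
               positions = I(list()))

  ## stage 3: which superfamilies each species carries -------------------
  set.seed(.subSeed(config$seed, 3L))
  nShared <- max(1L, round(config$sharedDomainFraction * S))
  sharedSf <- sort(sample.int(S, min(nShared, S)))
  restSf <- setdiff(seq_len(S), sharedSf)
  humanOnly <- restSf[seq_along(restSf) %% 2L == 1L]
  yeastOnly <- setdiff(restSf, humanOnly)
  eligible <- list(human = sort(c(sharedSf, humanOnly)),
                   yeast = sort(c(sharedSf, yeastOnly)))
  if (!is.null(config$hotspotPlan) && nrow(config$hotspotPlan)) {
    # the plan defines the study conditions: a planned superfamily must be
    # carried by the species it targets
    for (k in seq_len(nrow(config$hotspotPlan))) {
      hp <- config$hotspotPlan[k, ]
      tg <- if (hp$species == "both") c("human", "yeast") else hp$species
      for (sp in tg)
        eligible[[sp]] <- sort(union(eligible[[sp]], hp$superfamily))
    }
    sharedSf <- sort(intersect(eligible$human, eligible$yeast))
  }

  ## stage 4: proteins and alignment hits --------------------------------
  set.seed(.subSeed(config$seed, 4L))
  protRows <- list(); hits <- list()
  carriers <- list(human = vector("list", S), yeast = vector("list", S))
  for (sp in c("human", "yeast")) {
    el <- eligible[[sp]]
    for (i in seq_len(config$nProteinsPerSpecies)) {
      gene <- sprintf("G_%s_%03d", sp, i)
      prot <- sprintf("P_%s_%03d", sp, i)
      nDom <- if (sp == "yeast") 1L else sample.int(3L, 1L)
      sfs <- el[((i - 1L) %% length(el)) + 1L]    # cyclic: every sf has carriers
      if (nDom > 1L && length(el) > 1L)
        sfs <- unique(c(sfs, .sampleFrom(el, min(nDom - 1L, length(el) - 1L))))
      pos <- sample(10:30, 1L)
      coveredPos <- integer(0)
      for (s in sfs) {
        L <- lens[s]
        pp <- integer(0); dc <- integer(0)
        for (col in seq_len(L)) {
          pp <- c(pp, pos); dc <- c(dc, col); pos <- pos + 1L
          if (stats::runif(1) < 0.08) {          # insertion after this column
            insLen <- sample.int(3L, 1L)
            pp <- c(pp, seq(pos, pos + insLen - 1L))
            dc <- c(dc, rep(NA_integer_, insLen))
            pos <- pos + insLen
          }
        }
        map <- data.frame(protein_pos = pp, domain_col = dc)
        inv <- integer(L); inv[dc[!is.na(dc)]] <- pp[!is.na(dc)]
        for (acc in sfAcc[[s]])
          hits[[length(hits) + 1L]] <- list(
            protein_id = prot, domain_accession = acc,
            e_value = 10^-stats::runif(1, 4, 10), map = map)
        carriers[[sp]][[s]] <- c(carriers[[sp]][[s]],
                                 list(list(protein = prot, inv = inv)))
        coveredPos <- c(coveredPos, pp)
        pos <- pos + sample(5:20, 1L)            # inter-domain linker
      }
      plen <- pos + sample(10:30, 1L)
      protRows[[length(protRows) + 1L]] <- data.frame(
        protein_id = prot, gene_id = gene, species = sp, length = plen,
        source = "synthetic", stringsAsFactors = FALSE)
      attr(protRows[[length(protRows)]], "covered") <- coveredPos
      if (stats::runif(1) < 0.10 && length(el) > 1L) {
        # decoy hit above the E-value cut-off, still a valid global alignment
        sD <- .sampleFrom(setdiff(el, sfs[1L]))
        LD <- lens[sD]
        mapD <- data.frame(protein_pos = seq_len(LD), domain_col = seq_len(LD))
        hits[[length(hits) + 1L]] <- list(
          protein_id = prot, domain_accession = sfAcc[[sD]][1L],
          e_value = sample(c(0.01, 0.5), 1L), map = mapD)
        if (LD > plen) protRows[[length(protRows)]]$length <- LD + 5L
      }
    }
  }
  proteins <- do.call(rbind, lapply(protRows, function(x) x))
  coveredByProtein <- lapply(protRows, attr, "covered")
  names(coveredByProtein) <- proteins$protein_id

  ## stage 5: mutations ---------------------------------------------------
  set.seed(.subSeed(config$seed, 5L))
  n <- config$nMutationsPerSpecies
  labVocab <- list(human = HUMAN_DISEASES, yeast = YEAST_PHENOTYPES)
  seenKeys <- new.env(parent = emptyenv())
  mutRows <- list(); placeRows <- list(); counter <- c(human = 0L, yeast = 0L)
  addMutation <- function(sp, protein, ppos, label, type, sf, col) {
    counter[[sp]] <<- counter[[sp]] + 1L
    id <- sprintf("m_%s_%04d", sp, counter[[sp]])
    repeat {
      aas <- sample(AA_ALPHABET, 2L)
      key <- paste(sp, protein, ppos, aas[1L], aas[2L], label, sep = "\r")
      if (is.null(seenKeys[[key]])) { seenKeys[[key]] <- TRUE; break }
    }
    mutRows[[length(mutRows) + 1L]] <<- data.frame(
      mutation_id = id, species = sp, protein_id = protein,
      gene_id = proteins$gene_id[proteins$protein_id == protein],
      position = ppos, ref_aa = aas[1L], alt_aa = aas[2L], label = label)
    placeRows[[length(placeRows) + 1L]] <<- data.frame(
      mutation_id = id, species = sp, protein_id = protein,
      position = ppos, type = type,
      superfamily = ifelse(is.na(sf), NA_integer_, sf),
      column = ifelse(is.na(col), NA_integer_, col))
    id
  }
  budget <- c(human = n, yeast = n)
  plantedLedger <- list()
  if (!is.null(config$hotspotPlan) && nrow(config$hotspotPlan)) {
    for (k in seq_len(nrow(config$hotspotPlan))) {
      hp <- config$hotspotPlan[k, ]
      targets <- if (hp$species == "both") c("human", "yeast") else hp$species
      for (sp in targets) {
        cnt <- round(hp$fraction * n)
        if (cnt > budget[[sp]])
          .dhStop("hotspot plan exceeds the mutation budget")
        cars <- carriers[[sp]][[hp$superfamily]]
        if (is.null(cars))
          .dhStop(sprintf("no %s protein carries superfamily %d",
                          sp, hp$superfamily))
        for (j in seq_len(cnt)) {
          car <- cars[[sample.int(length(cars), 1L)]]
          addMutation(sp, car$protein, car$inv[hp$position],
                      sample(labVocab[[sp]], 1L), "planted",
                      hp$superfamily, hp$position)
        }
        budget[[sp]] <- budget[[sp]] - cnt
        plantedLedger[[length(plantedLedger) + 1L]] <- data.frame(
          superfamily = hp$superfamily, position = hp$position,
          species = sp, count = cnt)
      }
    }
  }
  coocLedger <- list()
  if (!is.null(config$cooccurrencePlan) && nrow(config$cooccurrencePlan)) {
    usedCols <- if (length(plantedLedger))
      do.call(rbind, plantedLedger) else NULL
    bothSf <- Filter(function(s) !is.null(carriers$human[[s]]) &&
                       !is.null(carriers$yeast[[s]]), sharedSf)
    if (length(bothSf) == 0L)
      .dhStop("co-occurrence plan needs a superfamily carried by both species")
    for (k in seq_len(nrow(config$cooccurrencePlan))) {
      cp <- config$cooccurrencePlan[k, ]
      s <- bothSf[[((k - 1L) %% length(bothSf)) + 1L]]
      avoid <- if (!is.null(usedCols))
        usedCols$position[usedCols$superfamily == s] else integer(0)
      col <- .sampleFrom(setdiff(seq_len(lens[s]), avoid))
      if (cp$count > min(budget))
        .dhStop("co-occurrence plan exceeds the mutation budget")
      for (j in seq_len(cp$count)) {
        for (sp in c("human", "yeast")) {
          cars <- carriers[[sp]][[s]]
          car <- cars[[sample.int(length(cars), 1L)]]
          addMutation(sp, car$protein, car$inv[col],
                      if (sp == "human") cp$disease else cp$phenotype,
                      "cooccur", s, col)
          budget[[sp]] <- budget[[sp]] - 1L
        }
      }
      coocLedger[[length(coocLedger) + 1L]] <- data.frame(
        H_label = cp$disease, Y_label = cp$phenotype, count = cp$count,
        superfamily = s, column = col)
    }
  }
  for (sp in c("human", "yeast")) {
    spProteins <- proteins$protein_id[proteins$species == sp]
    for (j in seq_len(budget[[sp]])) {
      if (stats::runif(1) < config$offDomainFraction) {
        repeat {
          prot <- .sampleFrom(spProteins)
          plen <- proteins$length[proteins$protein_id == prot]
          free <- setdiff(seq_len(plen), coveredByProtein[[prot]])
          if (length(free)) break
        }
        addMutation(sp, prot, .sampleFrom(free), .sampleFrom(labVocab[[sp]]),
                    "offdomain", NA_integer_, NA_integer_)
      } else {
        sfsC <- which(!vapply(carriers[[sp]], is.null, logical(1)))
        s <- sfsC[[sample.int(length(sfsC), 1L)]]
        cars <- carriers[[sp]][[s]]
        car <- cars[[sample.int(length(cars), 1L)]]
        col <- sample.int(lens[s], 1L)
        addMutation(sp, car$protein, car$inv[col],
                    sample(labVocab[[sp]], 1L), "background", s, col)
      }
    }
  }
  emptyMut <- data.frame(mutation_id = character(), species = character(),
                         protein_id = character(), gene_id = character(),
                         position = integer(), ref_aa = character(),
                         alt_aa = character(), label = character())
  mutations <- if (length(mutRows)) do.call(rbind, mutRows) else emptyMut
  rownames(mutations) <- NULL

  ## stage 6: ortholog pairs ---------------------------------------------
  set.seed(.subSeed(config$seed, 6L))
  nPairs <- round(config$orthologFraction * config$nProteinsPerSpecies)
  orthoIdx <- if (nPairs > 0L)
    sort(sample.int(config$nProteinsPerSpecies, nPairs)) else integer(0)
  orthologs <- data.frame(
    gene_id_a = sprintf("G_human_%03d", orthoIdx),
    species_a = rep("human", length(orthoIdx)),
    gene_id_b = sprintf("G_yeast_%03d", orthoIdx),
    species_b = rep("yeast", length(orthoIdx)))

  ## stage 7: per-column amino-acid frequencies --------------------------
  set.seed(.subSeed(config$seed, 7L))
  freqRows <- list(); consLedger <- vector("list", S)
  for (s in seq_len(S)) {
    L <- lens[s]
    nCons <- round(config$conservedColumnFraction * L)
    cons <- if (nCons > 0L) sort(sample.int(L, nCons)) else integer(0)
    consLedger[[s]] <- cons
    fm <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA_ALPHABET))
    for (j in seq_len(L)) {
      alpha <- if (j %in% cons) {
        # one dominant residue: low entropy, like a conserved match column
        a <- rep(0.05, 20L); a[sample.int(20L, 1L)] <- 8; a
      } else rep(2, 20L)   # near-uniform: high entropy, variable column
      f <- round(.rdirichlet1(alpha), 12)
      mx <- which.max(f)
      f[mx] <- 1 - sum(f[-mx])       # exact unit sum after rounding
      fm[j, ] <- f
    }
    for (acc in sfAcc[[s]]) {
      df <- data.frame(domain_accession = acc, position = seq_len(L))
      for (aa in AA_ALPHABET) df[[aa]] <- fm[, aa]
      freqRows[[length(freqRows) + 1L]] <- df
    }
  }
  freqs <- do.call(rbind, freqRows)

  ledger <- list(
    seed = config$seed,
    plantedHotspots = if (length(plantedLedger))
      do.call(rbind, plantedLedger) else NULL,
    placements = if (length(placeRows)) do.call(rbind, placeRows) else
      data.frame(mutation_id = character(), species = character(),
                 protein_id = character(), position = integer(),
                 type = character(), superfamily = integer(),
                 column = integer()),
    redundancyMap = domains[, c("accession", "superfamily_key", "is_root")],
    cooccurrencePlanted = if (length(coocLedger))
      do.call(rbind, coocLedger) else NULL,
    conservedColumns = consLedger,
    superfamilyAccessions = sfAcc,
    superfamilyLengths = lens,
    sharedSuperfamilies = sharedSf,
    eligibleSuperfamilies = eligible)
  if (verbose)
    .dhLog(sprintf("generated %d domains, %d proteins, %d hits, %d mutations",
                   nrow(domains), nrow(proteins), length(hits),
                   nrow(mutations)))
  list(domains = domains, proteins = proteins, hits = hits,
       mutations = mutations, features = features, orthologs = orthologs,
       freqs = freqs, ledger = ledger, config = config)
}

#' Generate a null dataset (no planted structure)
#'
#' Same generator with the hotspot and co-occurrence plans emptied: all
#' mutations are placed uniformly (background/off-domain only), giving the
#' type-I calibration harness.
#'
#' @inheritParams generateScenario
#' @export
generateNull <- function(config, verbose = FALSE) {
  config$hotspotPlan <- NULL
  config$cooccurrencePlan <- NULL
  generateScenario(config, verbose = verbose)
}

#' Write a generated scenario to a directory of TSV inputs
#'
#' Emits mutations.tsv, proteins.tsv, domains.tsv, hits.tsv, features.tsv,
#' orthologs.tsv and freqs.tsv (the exact dialects the readers consume), plus
#' ledger.json when the jsonlite package is available.
#'
#' @param data result of [generateScenario()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeScenario <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMutationTable(data$mutations, file.path(dir, "mutations.tsv"))
  writeProteinTable(data$proteins, file.path(dir, "proteins.tsv"))
  writeDomainTable(data$domains, file.path(dir, "domains.tsv"))
  writeDomainHits(data$hits, file.path(dir, "hits.tsv"))
  writeFeatureAnnotations(data$features, file.path(dir, "features.tsv"))
  writeOrthologPairs(data$orthologs, file.path(dir, "orthologs.tsv"))
  writeFrequencyTable(data$freqs, file.path(dir, "freqs.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    led <- data$ledger
    led$conservedColumns <- lapply(led$conservedColumns, as.integer)
    jsonlite::write_json(led, file.path(dir, "ledger.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
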