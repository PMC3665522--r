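smallConfig <- function(seed = 3L, ...) {
  scenarioConfig(seed = seed, nSuperfamilies = 3L, redundancyFactor = 2L,
                 nProteinsPerSpecies = 8L, nMutationsPerSpecies = 60L,
                 domainLengthRange = c(40L, 60L),
                 hotspotPlan = data.frame(superfamily = 1L, position = 12L,
                                          species = "yeast", fraction = 0.2),
                 cooccurrencePlan = data.frame(
                   disease = "Costello_syndrome", phenotype = "inviable",
                   count = 3L),
                 ...)
}

test_that("generation is deterministic for a given seed", {
  d1 <- generateScenario(smallConfig())
  d2 <- generateScenario(smallConfig())
  expect_identical(d1, d2)
  dir1 <- tempfile(); dir2 <- tempfile()
  writeScenario(d1, dir1); writeScenario(d2, dir2)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  expect_false(identical(generateScenario(smallConfig(seed = 4L)), d1))
})

test_that("generated datasets satisfy their own structural contracts", {
  d <- generateScenario(smallConfig())
  cfg <- smallConfig()
  expect_equal(nrow(d$domains), cfg$nSuperfamilies * cfg$redundancyFactor)
  expect_equal(unname(table(d$mutations$species)["yeast"]),
               cfg$nMutationsPerSpecies, ignore_attr = TRUE)
  # exactly one root per superfamily
  roots <- tapply(d$domains$is_root, d$domains$superfamily_key, sum)
  expect_true(all(roots == 1L))
  # redundant copies share length
  lens <- tapply(d$domains$length, d$domains$superfamily_key,
                 function(x) length(unique(x)))
  expect_true(all(lens == 1L))
  # alignment maps contain insertions so the gap rule is exercised
  expect_true(any(vapply(d$hits, function(h) anyNA(h$map$domain_col),
                         logical(1))))
  # ledger reconstructs every mutation
  expect_setequal(d$ledger$placements$mutation_id, d$mutations$mutation_id)
  planted <- d$ledger$plantedHotspots
  expect_equal(planted$count, round(0.2 * cfg$nMutationsPerSpecies))
  co <- d$ledger$cooccurrencePlanted
  expect_equal(co$count, 3L)
  nPlanted <- sum(d$ledger$placements$type == "cooccur")
  expect_equal(nPlanted, 2L * 3L)       # count pairs => count per species
})

test_that("the null generator plants nothing and zero budgets give empty tables", {
  d0 <- generateNull(smallConfig())
  expect_null(d0$ledger$plantedHotspots)
  expect_null(d0$ledger$cooccurrencePlanted)
  expect_true(all(d0$ledger$placements$type %in% c("background", "offdomain")))
  dEmpty <- generateNull(scenarioConfig(seed = 1L, nSuperfamilies = 2L,
                                        redundancyFactor = 1L,
                                        nProteinsPerSpecies = 3L,
                                        nMutationsPerSpecies = 0L,
                                        hotspotPlan = NULL,
                                        cooccurrencePlan = NULL))
  expect_equal(nrow(dEmpty$mutations), 0L)
})

test_that("infeasible plans are rejected up front", {
  expect_error(scenarioConfig(hotspotPlan = data.frame(
    superfamily = c(1L, 1L), position = c(5L, 9L),
    species = "yeast", fraction = c(0.7, 0.6))), "sum to <= 1")
  expect_error(scenarioConfig(hotspotPlan = data.frame(
    superfamily = 99L, position = 5L, species = "yeast", fraction = 0.1)),
    "unknown superfamily")
  expect_error(generateScenario(scenarioConfig(
    domainLengthRange = c(30L, 30L),
    hotspotPlan = data.frame(superfamily = 1L, position = 31L,
                             species = "yeast", fraction = 0.1))),
    "exceeds the drawn domain length")
})

test_that("a planted cluster across redundant copies collapses to one group", {
  cfg <- scenarioConfig(seed = 42L, nSuperfamilies = 1L,
                        redundancyFactor = 5L, nProteinsPerSpecies = 4L,
                        nMutationsPerSpecies = 50L,
                        domainLengthRange = c(100L, 100L),
                        sharedDomainFraction = 1,
                        offDomainFraction = 0,
                        hotspotPlan = data.frame(superfamily = 1L,
                                                 position = 37L,
                                                 species = "yeast",
                                                 fraction = 0.4),
                        cooccurrencePlan = NULL)
  d <- generateScenario(cfg)
  reps <- selectRepresentativeProteins(d$proteins)
  tabs <- buildDomainTables(d$mutations, d$hits, reps, d$domains,
                            verbose = FALSE)
  calls <- do.call(rbind, lapply(tabs, function(tb)
    callHotspots(positionScores(tb, "yeast"), 1.6, tb)))
  planted <- calls[calls$position == 37L, ]
  expect_equal(nrow(planted), 5L)             # one call per redundant copy
  g <- deduplicateHotspots(planted, d$domains)
  expect_equal(nrow(g), 1L)
  expect_true(g$representative_domain %in%
                d$domains$accession[d$domains$is_root])
})
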