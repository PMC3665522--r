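test_that("representative domain follows the root/feature/alphanumeric rule", {
  d <- makeDomains(c("cd00882", "pfam00071", "smart00175"), 150L,
                   is_root = c(TRUE, FALSE, FALSE),
                   has_features = c(FALSE, TRUE, FALSE))
  expect_equal(selectRepresentativeDomain(d), "cd00882")
  d2 <- makeDomains(c("aaa", "bbb"), 50L, is_root = FALSE,
                    has_features = c(FALSE, TRUE))
  expect_equal(selectRepresentativeDomain(d2), "bbb")
  # two roots: alphanumerically lowest wins; ordering is case-insensitive
  d3 <- makeDomains(c("PFAM9", "cd180"), 50L, is_root = TRUE)
  expect_equal(selectRepresentativeDomain(d3), "cd180")
  expect_equal(selectRepresentativeDomain(makeDomains("x", 5L)), "x")
})

test_that("groups collapse identical mutation sets and preserve member counts", {
  doms <- makeDomains(sprintf("d%03d", 1:6), 50L,
                      is_root = c(FALSE, TRUE, rep(FALSE, 4)))
  calls <- data.frame(domain = sprintf("d%03d", 1:6), position = 7L,
                      kind = "position", species_set = "yeast",
                      threshold = 1.6, score = 2.5, count = 5L, n_total = 10L,
                      feature = NA_character_, source_pos = 7L,
                      mutation_set_key = c(rep("m1;m2;m3", 4),
                                           rep("m4;m5", 2)))
  g <- deduplicateHotspots(calls, doms)
  expect_equal(nrow(g), 2L)
  expect_equal(sum(g$n_member_calls), nrow(calls))
  expect_equal(g$representative_domain[g$mutation_set_key == "m1;m2;m3"],
               "d002")                       # the root among the members
  # idempotent: regrouping the groups' member calls changes nothing
  g2 <- deduplicateHotspots(calls, doms)
  expect_identical(g[, names(g) != "members"], g2[, names(g2) != "members"])
  expect_error(deduplicateHotspots(
    rbind(calls, transform(calls[1, ], threshold = 1.3)), doms), "single")
})

test_that("right-sided Fisher matches hypergeometric enumeration", {
  expect_equal(enrichmentTest(5, 0, 0, 5), 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(enrichmentTest(0, 5, 5, 0), 1)
  expect_equal(enrichmentTest(1, 1, 1, 1), 5 / 6, tolerance = 1e-12)
  expect_equal(enrichmentTest(0, 0, 0, 0), 1)
  set.seed(31)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    expect_equal(enrichmentTest(cells[1], cells[2], cells[3], cells[4]),
                 oracleFisherRight(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12, info = paste(cells, collapse = ","))
    # and agrees with the standard one-sided test
    expect_equal(enrichmentTest(cells[1], cells[2], cells[3], cells[4]),
                 fisher.test(matrix(cells, 2, byrow = TRUE),
                             alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("hotspot linking sees direct hits and same-feature hits", {
  tab <- makeCountTable("D", 30L, list(
    yeast = list(`17` = c("y1", "y2", "y3", "y4", "y5")),
    human = list(`17` = c("h1", "h2"), `21` = "h3")))
  doms <- makeDomains("D", 30L, has_features = TRUE)
  feats <- data.frame(domain_accession = "D", feature_name = "Active_site")
  feats$positions <- list(c(20L, 21L, 22L))
  sv <- positionScores(tab, "yeast")
  calls <- callHotspots(sv, 1.0, tab)
  g <- deduplicateHotspots(calls, doms)
  lk <- linkHotspots(g, calls, list(D = tab), "human", feats)
  expect_true(all(lk$groups$linked))           # human mutations at (D,17)
  expect_equal(lk$fraction, 1)
  # feature-kind: yeast hotspot on the feature, human mutation elsewhere in it
  tabF <- makeCountTable("D", 30L, list(
    yeast = list(`20` = c("y1", "y2", "y3", "y4", "y5")),
    human = list(`21` = "h3")))
  fv <- featureScores(positionScores(tabF, "yeast"), feats)
  callsF <- callHotspots(fv, 1.0, tabF)
  expect_true(20L %in% callsF$position)
  gF <- deduplicateHotspots(callsF, doms)
  lkF <- linkHotspots(gF, callsF, list(D = tabF), "human", feats)
  expect_true(all(lkF$groups$linked))
  # the same configuration scored position-based does NOT link at column 20
  callsP <- callHotspots(positionScores(tabF, "yeast"), 1.0, tabF)
  gP <- deduplicateHotspots(callsP, doms)
  lkP <- linkHotspots(gP, callsP, list(D = tabF), "human", feats)
  expect_false(any(lkP$groups$linked))
  # no other-species mutations anywhere: linked fraction 0
  tab0 <- makeCountTable("D", 30L, list(
    yeast = list(`17` = c("y1", "y2", "y3", "y4", "y5")),
    human = list()))
  calls0 <- callHotspots(positionScores(tab0, "yeast"), 1.0, tab0)
  lk0 <- linkHotspots(deduplicateHotspots(calls0, doms), calls0,
                      list(D = tab0), "human", feats)
  expect_equal(lk0$fraction, 0)
})

test_that("relatability classes cover hand fixtures and partition a dataset", {
  hits <- list(makeHit("P1", "shared1", 1:10, 1:10),
               makeHit("P2", "priv1", 1:10, 1:10))
  orth <- data.frame(gene_id_a = "g2", species_a = "yeast",
                     gene_id_b = "hg9", species_b = "human")
  mut <- data.frame(mutation_id = c("m1", "m2", "m3"),
                    species = "yeast",
                    protein_id = c("P1", "P2", "P3"),
                    gene_id = c("g1", "g2", "g3"),
                    position = c(5L, 5L, 5L),
                    ref_aa = "A", alt_aa = "V", label = "x")
  cls <- classifyRelatability(mut, orth, hits, sharedDomains = "shared1")
  expect_equal(as.character(cls$relatability),
               c("domain_only", "ortholog_only", "neither"))
  mut2 <- transform(mut[1, ], gene_id = "g2")
  expect_equal(as.character(classifyRelatability(
    mut2, orth, hits, "shared1")$relatability), "both")
  # four-way partition over a full synthetic dataset
  d <- sharedScenario()
  protSp <- setNames(d$proteins$species, d$proteins$protein_id)
  domSp <- split(protSp[vapply(d$hits, `[[`, character(1), "protein_id")],
                 vapply(d$hits, `[[`, character(1), "domain_accession"))
  shared <- names(Filter(function(s) all(c("human", "yeast") %in% s), domSp))
  cls2 <- classifyRelatability(d$mutations, d$orthologs, d$hits, shared)
  expect_equal(sum(table(cls2$relatability)), nrow(d$mutations))
  expect_false(any(is.na(cls2$relatability)))
})

test_that("co-occurrence tests count planted overlaps once and rank them first", {
  # planted pair: 6 overlaps of (H,Y) out of 60 total, margins 6 and 6
  pl <- list(human = list(), yeast = list())
  for (i in 1:6) {                    # planted co-occurrences, one per column
    pl$human[[as.character(i)]] <- sprintf("H%02d", i)
    pl$yeast[[as.character(i)]] <- sprintf("Y%02d", i)
  }
  for (i in 7:60) {                   # background overlaps with other labels
    pl$human[[as.character(i)]] <- sprintf("H%02d", i)
    pl$yeast[[as.character(i)]] <- sprintf("Y%02d", i)
  }
  tab <- makeCountTable("D", 60L, pl)
  lab <- c(setNames(rep("WD", 6), sprintf("H%02d", 1:6)),
           setNames(sprintf("disease_%d", 7:60), sprintf("H%02d", 7:60)),
           setNames(rep("metal", 6), sprintf("Y%02d", 1:6)),
           setNames(sprintf("pheno_%d", 7:60), sprintf("Y%02d", 7:60)))
  mut <- data.frame(mutation_id = names(lab),
                    species = rep(c("human", "yeast"), each = 60),
                    protein_id = "P", gene_id = "G", position = 1L,
                    ref_aa = "A", alt_aa = "V", label = unname(lab))
  res <- cooccurrenceTests(list(D = tab), mut)
  top <- res[1, ]
  expect_equal(top$H_label, "WD")
  expect_equal(c(top$a, top$b, top$c, top$d), c(6, 0, 0, 54))
  expect_equal(top$p_value, 1 / choose(60, 6), tolerance = 1e-12)
  expect_true(all(diff(res$p_value) >= 0))
  # a pair never co-occurring has p = 1 from the tail minimum
  expect_true(all(res$p_value[res$a == 0] == 1))
  # redundant domain copies do not double-count an overlap
  res2 <- cooccurrenceTests(list(D = tab, D2 = tab), mut)
  expect_equal(res2[1, c("a", "b", "c", "d", "p_value")],
               top[, c("a", "b", "c", "d", "p_value")], ignore_attr = TRUE)
  # no overlaps at all: empty result
  tabEmpty <- makeCountTable("D", 5L, list(human = list(`1` = "H01"),
                                           yeast = list(`2` = "Y01")))
  expect_equal(nrow(cooccurrenceTests(list(D = tabEmpty), mut)), 0L)
})
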