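test_that("hit filtering keeps the inclusive E-value boundary and order", {
  hits <- list(makeHit("P1", "d1", 1:3, 1:3, e = 1e-5),
               makeHit("P1", "d2", 1:3, 1:3, e = 0.001),
               makeHit("P1", "d3", 1:3, 1:3, e = 0.01))
  kept <- filterHits(hits, 0.001)
  expect_equal(vapply(kept, `[[`, character(1), "domain_accession"),
               c("d1", "d2"))
  expect_equal(filterHits(list(), 0.001), list())
  expect_equal(filterHits(hits, Inf), hits)
})

test_that("positions in insertions map to the last match column before the gap", {
  h <- makeHit("P1", "d1", pp = c(10, 11, 12, 13), dc = c(1, NA, NA, 2))
  expect_equal(mapPosition(h, 10), 1L)
  expect_equal(mapPosition(h, 12), 1L)   # inside the insertion
  expect_equal(mapPosition(h, 13), 2L)
  expect_true(is.na(mapPosition(h, 50))) # outside the aligned span
  # insertion before any match column has no preceding column
  h2 <- makeHit("P1", "d1", pp = c(5, 6, 7), dc = c(NA, 1, 2))
  expect_true(is.na(mapPosition(h2, 5)))
  expect_equal(mapPosition(h2, 6), 1L)
})

test_that("mapping is monotone and is the identity on insertion-free maps", {
  set.seed(404)
  for (rep in 1:20) {
    L <- sample(5:30, 1)
    pp <- integer(0); dc <- integer(0); pos <- sample(1:50, 1)
    for (col in seq_len(L)) {
      pp <- c(pp, pos); dc <- c(dc, col); pos <- pos + 1L
      if (runif(1) < 0.2) { ins <- sample(1:3, 1)
        pp <- c(pp, seq(pos, pos + ins - 1L)); dc <- c(dc, rep(NA, ins))
        pos <- pos + ins }
    }
    h <- makeHit("P", "d", pp, dc)
    cols <- mapPosition(h, pp)
    m <- !is.na(cols)
    expect_true(all(diff(cols[m]) >= 0))          # monotone over the span
    clean <- makeHit("P", "d", pp[!is.na(dc)], dc[!is.na(dc)])
    expect_equal(mapPosition(clean, clean$map$protein_pos),
                 clean$map$domain_col)            # identity without insertions
  }
})

test_that("mutations propagate to every redundant domain and pool by column", {
  doms <- makeDomains(c("d1", "d2"), c(10L, 10L))
  hits <- list(makeHit("P1", "d1", 1:10, 1:10), makeHit("P1", "d2", 1:10, 1:10),
               makeHit("P2", "d1", 21:30, 1:10), makeHit("P3", "d1", 1:10, 1:10))
  prot <- data.frame(protein_id = c("P1", "P2", "P3"),
                     gene_id = c("g1", "g2", "g3"), species = "yeast",
                     length = 40L, source = "synthetic")
  reps <- selectRepresentativeProteins(prot)
  mut <- data.frame(mutation_id = c("m1", "m2", "m3"),
                    species = "yeast",
                    protein_id = c("P1", "P2", "P3"),
                    gene_id = c("g1", "g2", "g3"),
                    position = c(5L, 25L, 5L),
                    ref_aa = "A", alt_aa = "V", label = "slow_growth")
  tabs <- buildDomainTables(mut, hits, reps, doms, proteins = prot,
                            verbose = FALSE)
  # m1 lands on both redundant copies (2 domain mutations from 1 protein mutation)
  expect_equal(unname(mutationCounts(tabs$d1)["yeast", 5]), 3L)  # pooled across genes
  expect_equal(unname(mutationCounts(tabs$d2)["yeast", 5]), 1L)
  expect_setequal(mutationIds(tabs$d1, "yeast", 5), c("m1", "m2", "m3"))
  expect_equal(sum(mutationCounts(tabs$d2)), 1L)
  # mutation position beyond the protein length is a hard error
  mutBad <- mut; mutBad$position[1] <- 99L
  expect_error(buildDomainTables(mutBad, hits, reps, doms, proteins = prot,
                                 verbose = FALSE), "exceeds")
  # zero mutations give all-zero tables
  tabs0 <- buildDomainTables(mut[0, ], hits, reps, doms, verbose = FALSE)
  expect_true(all(vapply(tabs0, function(t) sum(mutationCounts(t)) == 0L,
                         logical(1))))
})

test_that("domain count tables recount exactly against the generator ledger", {
  d <- sharedScenario()
  reps <- selectRepresentativeProteins(d$proteins)
  tabs <- buildDomainTables(d$mutations, d$hits, reps, d$domains,
                            proteins = d$proteins, verbose = FALSE)
  led <- d$ledger
  placed <- led$placements[!is.na(led$placements$superfamily), ]
  sfOf <- setNames(match(d$domains$superfamily_key,
                         sprintf("sf%03d", seq_along(led$superfamilyLengths))),
                   d$domains$accession)
  for (tb in tabs) {
    s <- sfOf[[domainAccession(tb)]]
    for (sp in c("human", "yeast")) {
      expected <- table(factor(
        placed$column[placed$species == sp & placed$superfamily == s],
        levels = seq_len(modelLength(tb))))
      expect_equal(unname(mutationCounts(tb)[sp, ]),
                   as.integer(expected),
                   info = domainAccession(tb))
    }
  }
  # off-domain placements never enter any table
  total <- sum(vapply(tabs, function(t) sum(mutationCounts(t)), numeric(1)))
  copies <- table(d$domains$superfamily_key)[
    sprintf("sf%03d", placed$superfamily)]
  expect_equal(total, sum(as.integer(copies)))
})

test_that("site-class tallies match a hand-built fixture", {
  doms <- makeDomains("d1", 5L)
  tab <- makeCountTable("d1", 5L, list(
    yeast = list(`1` = c("m1", "m2", "m3", "m4"), `3` = c("m5", "m6"),
                 `5` = c("m7", "m8", "m9", "m10"))))
  feats <- data.frame(domain_accession = "d1", feature_name = "Active_site")
  feats$positions <- list(c(1L, 2L))
  prof <- list(d1 = new("EntropyProfile", domain = "d1",
                        entropies = c(0.1, 0.2, 2.5, 2.6, 0.3),
                        meanEntropy = mean(c(0.1, 0.2, 2.5, 2.6, 0.3))))
  thr <- new("ConservationThreshold", value = 1.0, meanAll = 0.6, sdAll = 0.4)
  tl <- tallySiteClasses(list(tab), feats, prof, thr)
  expect_equal(tl$domain_mutations, 10L)
  expect_equal(tl$at_feature, 4L)          # only column 1 is annotated & mutated
  expect_equal(tl$frac_feature, 0.4)
  expect_equal(tl$at_conserved, 8L)        # columns 1 and 5 conserved
  expect_equal(tl$frac_conserved, 0.8)
})
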