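# Independent oracles and fixture builders shared by the test files.
# Oracles deliberately avoid the code paths they check: binomial tails come
# from hand-rolled choose()-based pmf summation (not pbinom), Fisher tails
# from explicit hypergeometric enumeration (not phyper/fisher.test).

# P(X = x) for X ~ Binomial(n, p), via choose()
oracleBinomPmf <- function(x, n, p) {
  choose(n, x) * p^x * (1 - p)^(n - x)
}

# P(max of L iid Binomial(n, 1/L) >= c) = 1 - F(c-1)^L.
# For small upper tails S the power is expanded binomially so the oracle
# stays accurate where 1 - (1-S)^L would cancel catastrophically.
oracleTailProb <- function(c, n, L) {
  if (c <= 0) return(1)
  S <- sum(oracleBinomPmf(c:n, n, 1 / L))
  if (S > 1e-3) 1 - (1 - S)^L
  else -sum(choose(L, 1:L) * (-S)^(1:L))
}

# right-sided Fisher p for a 2x2 table by exhaustive hypergeometric
# enumeration over the support of the a-cell given fixed margins
oracleFisherRight <- function(a, b, c, d) {
  N <- a + b + c + d
  if (N == 0) return(1)
  r1 <- a + b; c1 <- a + c
  xs <- max(0, c1 - (c + d)):min(r1, c1)
  probs <- choose(r1, xs) * choose(N - r1, c1 - xs) / choose(N, c1)
  sum(probs[xs >= a])
}

# quick builder for a domain hit
makeHit <- function(protein, acc, pp, dc, e = 1e-6) {
  list(protein_id = protein, domain_accession = acc, e_value = e,
       map = data.frame(protein_pos = as.integer(pp),
                        domain_col = as.integer(dc)))
}

# build a DomainMutationTable from per-species placement lists:
# placements[[species]] is a list mapping column -> character vector of ids
makeCountTable <- function(domain, L, placements) {
  species <- names(placements)
  counts <- matrix(0L, nrow = length(species), ncol = L,
                   dimnames = list(species, NULL))
  idx <- lapply(species, function(s) replicate(L, character(0), simplify = FALSE))
  names(idx) <- species
  for (s in species) {
    for (colStr in names(placements[[s]])) {
      j <- as.integer(colStr)
      ids <- placements[[s]][[colStr]]
      counts[s, j] <- length(ids)
      idx[[s]][[j]] <- ids
    }
  }
  new("DomainMutationTable", domain = domain, length = as.integer(L),
      counts = counts, mutationIndex = idx)
}

# minimal domain table row(s)
makeDomains <- function(accession, length, is_root = FALSE,
                        has_features = FALSE, superfamily = "sf001",
                        source = "CDD") {
  data.frame(accession = accession, source = source, length = length,
             is_root = is_root, superfamily_key = superfamily,
             has_features = has_features)
}

# small scenario shared by several slow-ish tests, built once per run
sharedScenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateScenario(scenarioConfig(
        seed = 11L, nSuperfamilies = 4L, redundancyFactor = 3L,
        nProteinsPerSpecies = 12L, nMutationsPerSpecies = 120L,
        domainLengthRange = c(50L, 90L),
        hotspotPlan = data.frame(superfamily = c(1L, 2L),
                                 position = c(20L, 9L),
                                 species = c("yeast", "both"),
                                 fraction = c(0.10, 0.06)),
        cooccurrencePlan = data.frame(disease = "Wilson_disease",
                                      phenotype = "metal_resistance_increased",
                                      count = 4L)))
    cache
  }
})
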