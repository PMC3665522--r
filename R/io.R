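#' Read a tab-separated mutation table
#'
#' Reads point mutations (one row per mutation) and applies the standard
#' curation filters: rows whose phenotype/disease label is \code{"normal"}
#' (case-insensitive) describe no phenotypic change and are dropped; rows
#' lacking allelic information (missing or malformed position, reference or
#' alternate residue, or with identical reference and alternate) are dropped
#' with a logged count; duplicate rows under the uniqueness key
#' (species, protein, position, ref, alt, label) are collapsed with a logged
#' count.
#'
#' @param path TSV file with header columns \code{mutation_id}, \code{species},
#'   \code{protein_id}, \code{gene_id}, \code{position}, \code{ref_aa},
#'   \code{alt_aa}, \code{label}.
#' @param verbose emit log messages about dropped rows.
#' @return data.frame of retained mutations with integer \code{position}, plus
#'   attributes \code{n_dropped_allelic}, \code{n_dropped_normal},
#'   \code{n_collapsed_duplicates}.
#' @export
readMutationTable <- function(path, verbose = TRUE) {
  cols <- c("mutation_id", "species", "protein_id", "gene_id",
            "position", "ref_aa", "alt_aa", "label")
  df <- .readTsv(path, cols)[, cols, drop = FALSE]
  if (nrow(df) == 0L) {
    df$position <- integer(0)
    attr(df, "n_dropped_allelic") <- 0L
    attr(df, "n_dropped_normal") <- 0L
    attr(df, "n_collapsed_duplicates") <- 0L
    return(df)
  }
  isNormal <- tolower(trimws(df$label)) == "normal"
  pos <- .asInt(df$position)
  okRes <- function(a) !is.na(a) & grepl("^[A-Za-z]$", a)
  badAllelic <- is.na(pos) | pos < 1L | !okRes(df$ref_aa) | !okRes(df$alt_aa) |
    (okRes(df$ref_aa) & okRes(df$alt_aa) & df$ref_aa == df$alt_aa)
  keep <- !isNormal & !badAllelic
  nNormal  <- sum(isNormal)
  nAllelic <- sum(badAllelic & !isNormal)
  df <- df[keep, , drop = FALSE]
  df$position <- pos[keep]
  key <- paste(df$species, df$protein_id, df$position,
               df$ref_aa, df$alt_aa, df$label, sep = "\r")
  dup <- duplicated(key)
  nDup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  if (nNormal)  .dhLog(nNormal, " row(s) with label 'normal' dropped", verbose = verbose)
  if (nAllelic) .dhLog(nAllelic, " row(s) lacking allelic information dropped", verbose = verbose)
  if (nDup)     .dhLog(nDup, " duplicate mutation row(s) collapsed", verbose = verbose)
  attr(df, "n_dropped_allelic") <- nAllelic
  attr(df, "n_dropped_normal") <- nNormal
  attr(df, "n_collapsed_duplicates") <- nDup
  df
}

#' @rdname readMutationTable
#' @param mutations data.frame as returned by [readMutationTable()].
#' @export
writeMutationTable <- function(mutations, path) {
  cols <- c("mutation_id", "species", "protein_id", "gene_id",
            "position", "ref_aa", "alt_aa", "label")
  .writeTsv(mutations[, cols, drop = FALSE], path)
}

#' Read and write protein tables
#'
#' Protein records carry only identifiers, species, residue length and
#' database source (\code{swissprot}, \code{refseq}, \code{sgd},
#' \code{synthetic}); no sequences are stored.
#'
#' @param path TSV with columns \code{protein_id}, \code{gene_id},
#'   \code{species}, \code{length}, \code{source}.
#' @return data.frame with integer \code{length}.
#' @export
readProteinTable <- function(path) {
  cols <- c("protein_id", "gene_id", "species", "length", "source")
  df <- .readTsv(path, cols)[, cols, drop = FALSE]
  df$length <- .asInt(df$length)
  if (nrow(df) && any(is.na(df$length) | df$length < 1L))
    .dhStop("protein table contains non-positive or malformed lengths")
  df
}

#' @rdname readProteinTable
#' @param proteins data.frame of protein records.
#' @export
writeProteinTable <- function(proteins, path) {
  .writeTsv(proteins[, c("protein_id", "gene_id", "species",
                         "length", "source"), drop = FALSE], path)
}

#' Read and write domain model tables
#'
#' @param path TSV with columns \code{accession}, \code{source}, \code{length},
#'   \code{is_root} (0/1), \code{superfamily_key}, \code{has_features} (0/1).
#' @return data.frame with integer \code{length} and logical flags.
#' @export
readDomainTable <- function(path) {
  cols <- c("accession", "source", "length", "is_root",
            "superfamily_key", "has_features")
  df <- .readTsv(path, cols)[, cols, drop = FALSE]
  df$length <- .asInt(df$length)
  df$is_root <- .asInt(df$is_root) > 0L
  df$has_features <- .asInt(df$has_features) > 0L
  if (nrow(df)) {
    if (any(is.na(df$length) | df$length < 1L))
      .dhStop("domain table contains non-positive lengths")
    if (anyDuplicated(df$accession))
      .dhStop("domain accessions must be unique within a dataset")
  }
  df
}

#' @rdname readDomainTable
#' @param domains data.frame of domain models.
#' @export
writeDomainTable <- function(domains, path) {
  .writeTsv(domains[, c("accession", "source", "length", "is_root",
                        "superfamily_key", "has_features"), drop = FALSE], path)
}

.parseHitMap <- function(mapString, row) {
  toks <- strsplit(mapString, ",", fixed = TRUE)[[1]]
  parts <- strsplit(toks, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    .dhStop(sprintf("hits row %d: malformed map token", row))
  pp <- .asInt(vapply(parts, `[`, character(1), 1L))
  dcRaw <- vapply(parts, `[`, character(1), 2L)
  dc <- ifelse(dcRaw == "-", NA_integer_, .asInt(dcRaw))
  if (any(is.na(pp)))
    .dhStop(sprintf("hits row %d: malformed protein position", row))
  data.frame(protein_pos = pp, domain_col = dc)
}

#' Read and write domain-hit alignment maps
#'
#' Each hit emulates one profile-HMM global alignment of a domain model onto a
#' protein: an E-value and an ordered column map over the aligned protein span.
#' Map tokens are \code{P:D} (protein position \code{P} aligned to match
#' column \code{D}) or \code{P:-} (\code{P} sits in an insertion relative to
#' the model). Validity enforced on read: protein positions strictly
#' increasing, match columns non-decreasing, complete model coverage
#' (columns 1..L all present when \code{domains} is supplied, global-alignment
#' semantics), and no column beyond the model length.
#'
#' @param path TSV with columns \code{protein_id}, \code{domain_accession},
#'   \code{e_value}, \code{map}.
#' @param domains optional domain table from [readDomainTable()]; enables the
#'   model-length and coverage checks (hard error naming the offending row).
#' @return list of hits; each a list with \code{protein_id},
#'   \code{domain_accession}, \code{e_value} and a \code{map} data.frame
#'   (\code{protein_pos}, \code{domain_col}, NA for insertions).
#' @export
readDomainHits <- function(path, domains = NULL) {
  cols <- c("protein_id", "domain_accession", "e_value", "map")
  df <- .readTsv(path, cols)
  lens <- if (!is.null(domains)) setNames(domains$length, domains$accession)
  hits <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    m <- .parseHitMap(df$map[i], i)
    if (any(diff(m$protein_pos) <= 0L))
      .dhStop(sprintf("hits row %d: protein positions not strictly increasing", i))
    dc <- m$domain_col[!is.na(m$domain_col)]
    if (length(dc) && any(diff(dc) < 0L))
      .dhStop(sprintf("hits row %d: domain columns decrease", i))
    ev <- .asNum(df$e_value[i])
    if (is.na(ev) || ev < 0)
      .dhStop(sprintf("hits row %d: malformed e_value", i))
    if (!is.null(lens)) {
      L <- lens[[df$domain_accession[i]]]
      if (is.null(L))
        .dhStop(sprintf("hits row %d: unknown domain %s", i, df$domain_accession[i]))
      if (length(dc) && max(dc) > L)
        .dhStop(sprintf("hits row %d: domain column %d exceeds model length %d of %s",
                        i, max(dc), L, df$domain_accession[i]))
      if (!all(seq_len(L) %in% dc))
        .dhStop(sprintf("hits row %d: hit does not cover all %d columns of %s (global alignment required)",
                        i, L, df$domain_accession[i]))
    }
    hits[[i]] <- list(protein_id = df$protein_id[i],
                      domain_accession = df$domain_accession[i],
                      e_value = ev, map = m)
  }
  hits
}

#' @rdname readDomainHits
#' @param hits list of hits as returned by [readDomainHits()].
#' @export
writeDomainHits <- function(hits, path) {
  df <- data.frame(
    protein_id = vapply(hits, `[[`, character(1), "protein_id"),
    domain_accession = vapply(hits, `[[`, character(1), "domain_accession"),
    e_value = vapply(hits, `[[`, numeric(1), "e_value"),
    map = vapply(hits, function(h) {
      paste0(h$map$protein_pos, ":",
             ifelse(is.na(h$map$domain_col), "-", h$map$domain_col),
             collapse = ",")
    }, character(1)))
  .writeTsv(df, path)
}

#' Read and write functional feature annotations
#'
#' A feature is a named functional role (e.g. a GTP/Mg2+ binding site)
#' attached to a set of 1-based match columns of a domain model, in the style
#' of CDD's curated site annotations.
#'
#' @param path TSV with columns \code{domain_accession}, \code{feature_name},
#'   \code{positions} (comma-separated 1-based columns).
#' @param domains optional domain table; positions outside the model length
#'   raise a hard error naming the row.
#' @return data.frame with a list-column \code{positions} of sorted integer
#'   vectors.
#' @export
readFeatureAnnotations <- function(path, domains = NULL) {
  cols <- c("domain_accession", "feature_name", "positions")
  df <- .readTsv(path, cols)
  lens <- if (!is.null(domains)) setNames(domains$length, domains$accession)
  posList <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- .asInt(strsplit(df$positions[i], ",", fixed = TRUE)[[1]])
    if (length(p) == 0L || any(is.na(p) | p < 1L))
      .dhStop(sprintf("features row %d: empty or malformed position list", i))
    if (!is.null(lens)) {
      L <- lens[[df$domain_accession[i]]]
      if (!is.null(L) && any(p > L))
        .dhStop(sprintf("features row %d: position %d exceeds length %d of %s",
                        i, max(p), L, df$domain_accession[i]))
    }
    posList[[i]] <- sort(unique(p))
  }
  out <- data.frame(domain_accession = df$domain_accession,
                    feature_name = df$feature_name)
  out$positions <- posList
  out
}

#' @rdname readFeatureAnnotations
#' @param features data.frame as returned by [readFeatureAnnotations()].
#' @export
writeFeatureAnnotations <- function(features, path) {
  df <- data.frame(
    domain_accession = features$domain_accession,
    feature_name = features$feature_name,
    positions = vapply(features$positions, paste, character(1), collapse = ","))
  .writeTsv(df, path)
}

#' Read and write ortholog pair tables
#'
#' @param path TSV with columns \code{gene_id_a}, \code{species_a},
#'   \code{gene_id_b}, \code{species_b}.
#' @return data.frame of cross-species gene pairs.
#' @export
readOrthologPairs <- function(path) {
  cols <- c("gene_id_a", "species_a", "gene_id_b", "species_b")
  df <- .readTsv(path, cols)[, cols, drop = FALSE]
  if (nrow(df) && any(df$species_a == df$species_b))
    .dhStop("ortholog pairs must join two different species")
  df
}

#' @rdname readOrthologPairs
#' @param orthologs data.frame of ortholog pairs.
#' @export
writeOrthologPairs <- function(orthologs, path) {
  .writeTsv(orthologs[, c("gene_id_a", "species_a",
                          "gene_id_b", "species_b"), drop = FALSE], path)
}

#' Read and write per-column amino-acid frequency tables
#'
#' One row per (domain, match column) with the 20 amino-acid frequencies in
#' fixed alphabetical one-letter order (A C D E F G H I K L M N P Q R S T V W
#' Y), summing to 1 per row.
#'
#' @param path TSV with columns \code{domain_accession}, \code{position} and
#'   the 20 amino-acid columns.
#' @return data.frame with numeric frequency columns.
#' @export
readFrequencyTable <- function(path) {
  cols <- c("domain_accession", "position", AA_ALPHABET)
  df <- .readTsv(path, cols)[, cols, drop = FALSE]
  df$position <- .asInt(df$position)
  for (aa in AA_ALPHABET) df[[aa]] <- .asNum(df[[aa]])
  df
}

#' @rdname readFrequencyTable
#' @param freqs data.frame as returned by [readFrequencyTable()].
#' @export
writeFrequencyTable <- function(freqs, path) {
  .writeTsv(freqs[, c("domain_accession", "position", AA_ALPHABET),
                  drop = FALSE], path)
}

#' Select one representative protein per gene
#'
#' Reduces protein redundancy before mutation mapping: for each
#' (gene, species), among Swiss-Prot entries the longest is chosen; if the
#' gene has none, the longest RefSeq entry; for sources without that
#' distinction (SGD, synthetic) the longest overall. Length ties break to the
#' lexicographically smallest \code{protein_id} so the choice is
#' deterministic.
#'
#' @param proteins data.frame from [readProteinTable()].
#' @return data.frame with one row per (gene_id, species):
#'   \code{gene_id}, \code{species}, \code{protein_id}.
#' @export
selectRepresentativeProteins <- function(proteins) {
  if (nrow(proteins) == 0L)
    return(data.frame(gene_id = character(), species = character(),
                      protein_id = character()))
  pick <- function(d) {
    cand <- d[d$source == "swissprot", , drop = FALSE]
    if (nrow(cand) == 0L) cand <- d[d$source == "refseq", , drop = FALSE]
    if (nrow(cand) == 0L) cand <- d
    cand <- cand[cand$length == max(cand$length), , drop = FALSE]
    cand$protein_id[order(cand$protein_id)][1L]
  }
  sp <- split(proteins, paste(proteins$gene_id, proteins$species, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(gene_id = d$gene_id[1L], species = d$species[1L],
               protein_id = pick(d))))
  rownames(out) <- NULL
  out[order(out$species, out$gene_id), , drop = FALSE]
}
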