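.dhLog <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[domainHotspots] ", ...)
}

.dhStop <- function(msg, class = "dh_validation") {
  stop(errorCondition(msg, class = c(class, "error", "condition")))
}

# TSV writer that preserves doubles exactly across a write/read round trip
# (numeric columns rendered with %.17g).
.writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    else if (is.logical(out[[j]])) out[[j]] <- as.integer(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, required, optional = FALSE) {
  if (!file.exists(path)) {
    if (optional) return(NULL)
    .dhStop(sprintf("input file not found: %s", path), class = "dh_missing_input")
  }
  if (file.size(path) == 0L) {
    df <- as.data.frame(setNames(rep(list(character()), length(required)),
                                 required))
    return(df)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          blank.lines.skip = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    .dhStop(sprintf("file %s lacks required column(s): %s",
                    path, paste(miss, collapse = ", ")))
  df
}

.asInt <- function(x) suppressWarnings(as.integer(x))
.asNum <- function(x) suppressWarnings(as.numeric(x))

# sample that never falls into the sample(x, 1) == sample.int(x) trap
.sampleFrom <- function(x, n = 1L, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# derived sub-stream seed; keeps everything below 2^31
.subSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + 7919 * stage) %% .Machine$integer.max
}
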