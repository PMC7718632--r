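# Internal helpers.

# Run code under a local RNG seeded from `seed`, restoring the caller's
# RNG state afterwards, so each generator stage is independently
# deterministic.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Sub-seed derivation: keeps derived seeds in 32-bit integer range.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% .Machine$integer.max)
}

#' Treatment label from factor levels
#'
#' Maps heat/drought indicators to the four treatment labels
#' C (control), D (drought), H (heat), HD (combined).
#'
#' @param heat,drought 0/1 indicators (vectorised)
#' @return character vector in \code{{"C","D","H","HD"}}
#' @export
treatmentLabel <- function(heat, drought) {
  c("C", "D", "H", "HD")[1 + as.integer(drought) + 2 * as.integer(heat)]
}

# Standardize a sample to mean 0, sd 1 (exact in-sample moments).
standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Orthogonalize y against x in-sample, then standardize.
orthoStandardize <- function(y, x) {
  zx <- standardize(x)
  r <- y - mean(y) - sum((y - mean(y)) * zx) / sum(zx^2) * zx
  standardize(r)
}

# Numeric formatting that round-trips doubles exactly through text.
fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a data frame as CSV with a provenance header
#'
#' Writes one observation per line, UTF-8, with a leading comment line
#' recording the RNG seed and configuration hash. Numeric columns are
#' serialized with 17 significant digits so values round-trip exactly.
#'
#' @param df data frame
#' @param path output file
#' @param seed integer seed to record
#' @param configHash character hash to record (optional)
#' @return \code{path}, invisibly
#' @export
writeTableCsv <- function(df, path, seed = NA, configHash = "") {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmtNum(out[[j]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s config=%s", seed, configHash), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a CSV written by \code{\link{writeTableCsv}}
#'
#' @param path input file
#' @return data frame (provenance comment lines are skipped)
#' @export
readTableCsv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Stable hash of an R object via serialization to a temp file.
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
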