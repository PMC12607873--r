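# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "",
                    stringsAsFactors = FALSE)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

# Parse character columns as numeric, pinpointing any offending cell.
parseNumericCells <- function(df, idCol) {
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(df[[idCol]], colnames(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1L]]) & nzchar(df[[j + 1L]]))
    if (length(bad) || anyNA(v))
      stop(sprintf(
        "non-numeric value in column '%s', row %d (taxon '%s')",
        colnames(df)[j + 1L],
        if (length(bad)) bad[1L] else which(is.na(v))[1L],
        df[[idCol]][if (length(bad)) bad[1L] else which(is.na(v))[1L]]))
    m[, j] <- v
  }
  m
}

# Clamp correlations into the open interval so atanh stays finite.
clampR <- function(r, eps = 1e-15, warn = FALSE) {
  if (warn && any(abs(r) >= 1, na.rm = TRUE))
    warning("correlation coefficients with |r| >= 1 clamped before atanh")
  pmin(pmax(r, -1 + eps), 1 - eps)
}
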