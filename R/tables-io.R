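#' Load a taxonomic relative-abundance table
#'
#' Reads a taxa-by-samples TSV of percent relative abundances in one of two
#' dialects: \code{plain_tsv} (first column \code{taxon}, remaining columns
#' samples) or \code{metaphlan_merged} (first column \code{clade_name}
#' holding full rank-prefixed taxonomy strings such as
#' \code{k__Bacteria|...|s__Bacteroides_uniformis}; only rows terminating at
#' the requested rank are kept and the terminal rank name, prefix stripped,
#' becomes the taxon identifier).
#'
#' Unclassified clades (\code{UNCLASSIFIED}/\code{unclassified} terminal
#' names) are dropped with a message. Columns that do not sum to 100 (within
#' 1e-6) load fine; the table is flagged via
#' \code{metadata(x)$needs_renormalization} so callers can
#' \code{\link{renormalize}} before dissimilarity work.
#'
#' @param path TSV file path.
#' @param dialect \code{"plain_tsv"} or \code{"metaphlan_merged"}.
#' @param rank taxonomic rank to extract, \code{"species"} or \code{"genus"}.
#' @return a \linkS4class{TaxonTable}.
#' @export
loadTaxonTable <- function(path, dialect = c("plain_tsv", "metaphlan_merged"),
                           rank = c("species", "genus")) {
  dialect <- match.arg(dialect)
  rank <- match.arg(rank)
  df <- readTsv(path)
  if (ncol(df) < 2L) stop("taxon table needs an id column plus >=1 sample")
  idCol <- colnames(df)[1L]
  if (dialect == "plain_tsv") {
    if (!identical(idCol, "taxon"))
      stop("plain_tsv dialect requires first column 'taxon', found '",
           idCol, "'")
    df[[1L]] <- trimws(df[[1L]])
  } else {
    if (!idCol %in% c("clade_name", "#clade_name"))
      stop("metaphlan_merged dialect requires first column 'clade_name'")
    prefix <- if (rank == "species") "s__" else "g__"
    parts <- strsplit(trimws(df[[1L]]), "|", fixed = TRUE)
    terminal <- vapply(parts, function(p) p[length(p)], character(1))
    keep <- startsWith(terminal, prefix)
    uncl <- grepl("unclassified", terminal, ignore.case = TRUE)
    if (any(keep & uncl)) {
      message(sum(keep & uncl), " unclassified ", rank, "-level rows dropped")
      keep <- keep & !uncl
    }
    df <- df[keep, , drop = FALSE]
    if (!nrow(df)) stop("no rows at rank '", rank, "' in ", path)
    df[[1L]] <- substring(terminal[keep], 4L)
  }
  dup <- unique(df[[1L]][duplicated(df[[1L]])])
  if (length(dup))
    stop("duplicate taxon identifier(s) after rank extraction: ",
         paste(dup, collapse = ", "))
  values <- parseNumericCells(df, idCol)
  tt <- TaxonTable(values, rank = rank)
  cs <- colSums(values)
  flag <- any(abs(cs - 100) > 1e-6)
  metadata(tt)$needs_renormalization <- flag
  if (flag)
    message("column sums deviate from 100 (range ",
            sprintf("%.4g-%.4g", min(cs), max(cs)),
            "); call renormalize() before dissimilarity analyses")
  tt
}

#' Write a TaxonTable as plain TSV
#'
#' Writers emit the \code{plain_tsv} dialect only (first column
#' \code{taxon}, then sample columns), regardless of input dialect.
#'
#' @param x a \linkS4class{TaxonTable}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTaxonTable <- function(x, path) {
  stopifnot(is(x, "TaxonTable"))
  df <- data.frame(taxon = rownames(x), raValues(x), check.names = FALSE)
  writeTsv(df, path)
}

#' Load and validate sample metadata
#'
#' The metadata TSV must carry columns \code{sample_id}, \code{host},
#' \code{donor_id}, \code{timepoint}, \code{study_id}, \code{route},
#' \code{replicate_group}. Controlled vocabularies: host in
#' \{human, mouse\}; timepoint in \{T0, T2, baseline, SPF, other\}; route in
#' \{HTR, MTR, none\}. Human rows must have route \code{none}.
#'
#' @param path metadata TSV path.
#' @return a validated \link[S4Vectors]{DataFrame}, one row per sample.
#' @export
loadSampleMeta <- function(path) {
  df <- readTsv(path)
  asSampleMeta(df)
}

META_COLS <- c("sample_id", "host", "donor_id", "timepoint", "study_id",
               "route", "replicate_group")

#' Coerce and validate a sample-metadata table
#'
#' @param df data.frame or DataFrame with the columns listed in
#'   \code{\link{loadSampleMeta}}.
#' @return a validated \link[S4Vectors]{DataFrame}.
#' @export
asSampleMeta <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(META_COLS, colnames(df))
  if (length(missing))
    stop("metadata missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[, META_COLS, drop = FALSE]
  for (cc in META_COLS) df[[cc]] <- trimws(as.character(df[[cc]]))
  checkVocab <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad))
      stop(sprintf("unknown %s value(s) %s; allowed: %s", col,
                   paste(sQuote(bad), collapse = ", "),
                   paste(allowed, collapse = ", ")))
  }
  checkVocab("host", HOST_LEVELS)
  checkVocab("timepoint", TIMEPOINT_LEVELS)
  checkVocab("route", ROUTE_LEVELS)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "))
  if (any(df$host == "human" & df$route != "none"))
    stop("human samples must have route 'none'")
  DataFrame(df, row.names = df$sample_id)
}

#' Pair donor samples with recipient mouse groups
#'
#' Every mouse \code{replicate_group} (cage mates seeded from one donor
#' stool) is paired with the human sample sharing its \code{donor_id} and
#' \code{timepoint}. Groups with no matching donor sample are excluded with
#' a warning listing them. Pairs are ordered deterministically by donor_id,
#' then timepoint, then group id.
#'
#' @param meta a sample-metadata DataFrame (see \code{\link{asSampleMeta}})
#'   containing at least one human and one mouse sample.
#' @return a \linkS4class{PairingMap}.
#' @export
buildPairing <- function(meta) {
  meta <- asSampleMeta(meta)
  humans <- meta[meta$host == "human", , drop = FALSE]
  mice <- meta[meta$host == "mouse", , drop = FALSE]
  if (!nrow(humans) || !nrow(mice))
    stop("pairing needs at least one human and one mouse sample")
  grp <- split(mice$sample_id, mice$replicate_group)
  gmeta <- mice[!duplicated(mice$replicate_group), , drop = FALSE]
  key <- paste(gmeta$donor_id, gmeta$timepoint)
  hkey <- paste(humans$donor_id, humans$timepoint)
  hit <- match(key, hkey)
  orphan <- gmeta$replicate_group[is.na(hit)]
  if (length(orphan))
    warning("recipient group(s) with no matching donor sample excluded: ",
            paste(sort(orphan), collapse = ", "))
  ok <- !is.na(hit)
  donor <- humans$sample_id[hit[ok]]
  group <- gmeta$replicate_group[ok]
  ord <- order(gmeta$donor_id[ok], gmeta$timepoint[ok], group)
  new("PairingMap", donor = donor[ord], group = group[ord],
      members = grp[group[ord]])
}

#' Renormalize columns to sum exactly 100
#'
#' @param x a \linkS4class{TaxonTable}.
#' @return the table with each sample column scaled to sum 100 and the
#'   \code{renormalized} flag set.
#' @export
renormalize <- function(x) {
  stopifnot(is(x, "TaxonTable"))
  ra <- raValues(x)
  cs <- colSums(ra)
  zero <- cs <= 0
  if (any(zero))
    stop("sample(s) with no positive abundance cannot be renormalized: ",
         paste(colnames(ra)[zero], collapse = ", "))
  out <- TaxonTable(sweep(ra, 2L, cs / 100, "/"), rank = x@rank,
                    renormalized = TRUE)
  metadata(out)$needs_renormalization <- FALSE
  out
}

#' Write a sample-metadata table as TSV
#' @param meta a metadata DataFrame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSampleMeta <- function(meta, path) {
  writeTsv(as.data.frame(meta)[, META_COLS], path)
}

#' Write a distance matrix as square TSV
#'
#' Square layout with a leading \code{id} header column mirroring the ids.
#' @param d a \linkS4class{DistMatrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDistMatrix <- function(d, path) {
  df <- data.frame(id = rownames(d), as.matrix(d), check.names = FALSE)
  writeTsv(df, path)
}
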