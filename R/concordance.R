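#' Per-entity change in percent relative abundance between timepoints
#'
#' For each entity of the requested host (humans: one profile per donor_id
#' per timepoint; mice: the mean profile over mouse samples sharing a
#' donor_id at each timepoint), returns RA(to) - RA(from) per taxon on the
#' percent scale. Absence is zero, so a taxon present only at the first
#' timepoint yields a negative delta. Entities missing either timepoint are
#' excluded with a warning.
#'
#' @param x a \linkS4class{TaxonTable} whose columns are sample ids in
#'   \code{meta}.
#' @param meta sample metadata.
#' @param from,to timepoint labels (default \code{"T0"} to \code{"T2"}).
#' @param host \code{"human"} or \code{"mouse"}.
#' @return taxa x entities matrix of deltas (entities keyed by donor_id).
#' @export
deltaRA <- function(x, meta, from = "T0", to = "T2",
                    host = c("human", "mouse")) {
  stopifnot(is(x, "TaxonTable"))
  host <- match.arg(host)
  meta <- asSampleMeta(meta)
  m <- meta[meta$sample_id %in% colnames(x) & meta$host == host, ,
            drop = FALSE]
  ra <- raValues(x)
  entities <- unique(m$donor_id)
  profileAt <- function(ent, tp) {
    ids <- m$sample_id[m$donor_id == ent & m$timepoint == tp]
    if (!length(ids)) return(NULL)
    rowMeans(ra[, ids, drop = FALSE])
  }
  cols <- list()
  for (ent in entities) {
    p0 <- profileAt(ent, from); p1 <- profileAt(ent, to)
    if (is.null(p0) || is.null(p1)) next
    cols[[ent]] <- p1 - p0
  }
  dropped <- setdiff(entities, names(cols))
  if (length(dropped))
    warning(host, " entit(ies) missing a timepoint excluded: ",
            paste(dropped, collapse = ", "))
  if (!length(cols)) stop("no entity has both timepoints")
  do.call(cbind, cols)
}

#' Donor-recipient concordance of abundance changes
#'
#' Pairs per-taxon deltas between donors and recipients (matrices are
#' averaged over entities first), restricts to the supplied overlap taxon
#' set (taxa observed in both hosts), computes the Pearson correlation with
#' t-test p-value, and reports the percent of taxa in each sign quadrant
#' (Q1 = both increase, Q2 = donor down/recipient up, Q3 = both decrease,
#' Q4 = donor up/recipient down). Taxa with a zero delta on either axis sit
#' on an axis, belong to no quadrant, and are excluded from the quadrant
#' denominator but retained in the correlation.
#'
#' @param donorDelta,recipientDelta named per-taxon delta vectors (or
#'   taxa x entities matrices, averaged by row).
#' @param overlapTaxa optional taxon subset to restrict to (e.g. taxa
#'   present in both humans and mice); default: all shared names.
#' @return list with \code{taxa}, \code{donor_delta}, \code{recipient_delta},
#'   \code{pearson_r}, \code{p_value}, \code{quadrant_fractions} (percent,
#'   named Q1..Q4) and \code{n_quadrant} (taxa with both deltas nonzero).
#' @export
deltaConcordance <- function(donorDelta, recipientDelta, overlapTaxa = NULL) {
  toVec <- function(v) if (is.matrix(v)) rowMeans(v) else v
  dd <- toVec(donorDelta); rd <- toVec(recipientDelta)
  shared <- intersect(names(dd), names(rd))
  if (!is.null(overlapTaxa)) shared <- intersect(shared, overlapTaxa)
  if (length(shared) < 3L)
    stop("need >= 3 overlapping taxa, got ", length(shared))
  dd <- dd[shared]; rd <- rd[shared]
  ct <- stats::cor.test(dd, rd, method = "pearson")
  nz <- dd != 0 & rd != 0
  q <- c(Q1 = sum(dd > 0 & rd > 0), Q2 = sum(dd < 0 & rd > 0),
         Q3 = sum(dd < 0 & rd < 0), Q4 = sum(dd > 0 & rd < 0))
  qf <- if (sum(nz)) 100 * q / sum(nz) else q * NA_real_
  list(taxa = shared, donor_delta = dd, recipient_delta = rd,
       pearson_r = unname(ct$estimate), p_value = ct$p.value,
       quadrant_fractions = qf, n_quadrant = sum(nz))
}

#' Taxa observed in both humans and mice
#'
#' The overlap set for concordance analyses: taxa with positive RA in at
#' least one human sample and at least one mouse sample/profile, across all
#' timepoints.
#'
#' @param x a \linkS4class{TaxonTable}.
#' @param meta metadata matching the table's columns.
#' @return character vector of taxon identifiers.
#' @export
overlapTaxa <- function(x, meta) {
  meta <- asSampleMeta(meta)
  ra <- raValues(x)
  m <- meta[meta$sample_id %in% colnames(ra), , drop = FALSE]
  inHuman <- rowSums(ra[, m$sample_id[m$host == "human"], drop = FALSE]) > 0
  inMouse <- rowSums(ra[, m$sample_id[m$host == "mouse"], drop = FALSE]) > 0
  rownames(ra)[inHuman & inMouse]
}

#' Paired log-abundance comparison across exposure routes
#'
#' For taxa shared between the two route tables, pairs the mean percent RA
#' per taxon on the log10 display scale (zeros floored; see
#' \code{\link{logDisplay}}), flags consortium membership, and reports the
#' Pearson correlation of the log values.
#'
#' @param tableHTR,tableMTR \linkS4class{TaxonTable}s for the two exposure
#'   routes (human-treated / mouse-treated).
#' @param consortium character vector of consortium taxon names.
#' @param floor zero floor for the log display (default -3).
#' @return list with \code{points} (data.frame taxon, log_ra_htr,
#'   log_ra_mtr, is_consortium), \code{r} and \code{p}.
#' @export
routeAbundanceScatter <- function(tableHTR, tableMTR, consortium = character(),
                                  floor = -3) {
  stopifnot(is(tableHTR, "TaxonTable"), is(tableMTR, "TaxonTable"))
  shared <- intersect(rownames(tableHTR), rownames(tableMTR))
  if (!length(shared)) stop("tables share no taxa")
  lh <- logDisplay(rowMeans(raValues(tableHTR)[shared, , drop = FALSE]),
                   floor = floor)
  lm_ <- logDisplay(rowMeans(raValues(tableMTR)[shared, , drop = FALSE]),
                    floor = floor)
  pts <- data.frame(taxon = shared, log_ra_htr = unname(lh),
                    log_ra_mtr = unname(lm_),
                    is_consortium = shared %in% consortium)
  if (length(shared) >= 3L && stats::sd(lh) > 0 && stats::sd(lm_) > 0) {
    ct <- stats::cor.test(lh, lm_, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- if (length(shared) >= 2L) stats::cor(lh, lm_) else NA_real_
    p <- NA_real_
  }
  list(points = pts, r = r, p = p)
}

#' Pairwise Pearson correlations between sample abundance profiles
#'
#' Pools one or more genus-rank tables (taxa unioned, zero-filled - absence
#' is a true zero on the percent scale), computes Pearson r between every
#' pair of sample columns on linear percent RA, and attaches the Fisher z
#' transform (|r| clamped to 1 - 1e-15 so z stays finite). Zero-variance
#' profiles yield undefined correlations, recorded as NA with a warning.
#'
#' @param tables a \linkS4class{TaxonTable} or list of them (sample ids
#'   must be globally unique).
#' @return a \linkS4class{CorrelationMatrix}.
#' @export
sampleCorrelationMatrix <- function(tables) {
  if (is(tables, "TaxonTable")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  allTaxa <- sort(unique(unlist(lapply(tables, rownames))))
  cols <- do.call(cbind, lapply(tables, function(tt) {
    m <- matrix(0, length(allTaxa), ncol(tt),
                dimnames = list(allTaxa, colnames(tt)))
    m[rownames(tt), ] <- raValues(tt)
    m
  }))
  if (anyDuplicated(colnames(cols)))
    stop("sample ids must be unique across tables")
  if (ncol(cols) < 2L) stop("need >= 2 samples in total")
  # a taxon absent from every sample is not an observation
  cols <- cols[rowSums(cols) > 0, , drop = FALSE]
  sds <- apply(cols, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance profile(s), correlations undefined (NA): ",
            paste(colnames(cols)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(cols, method = "pearson"))
  diag(r) <- ifelse(sds > 0, 1, NA_real_)
  z <- atanh(clampR(r))
  new("CorrelationMatrix", ids = colnames(cols), r = r, z = z)
}

#' Fisher z-transformation of a correlation coefficient
#'
#' z = atanh(r) = 0.5 * log((1 + r) / (1 - r)), the variance-stabilizing
#' transform applied before comparing groups of correlation coefficients.
#' Values with |r| >= 1 are clamped to 1 - 1e-15 with a warning.
#'
#' @param r numeric correlation coefficient(s).
#' @return transformed value(s).
#' @export
fisherZ <- function(r) {
  atanh(clampR(r, warn = TRUE))
}

#' Category means and z-test of cross-sample correlations
#'
#' Classifies every unordered sample pair of a correlation matrix by host
#' composition (\code{human_human}, \code{human_mouse}, \code{mouse_mouse})
#' and study scope (within/cross study), reporting per-category means of
#' the untransformed r (the display convention) while testing on the Fisher
#' z values (the variance-stabilized scale) with one-way ANOVA + Tukey HSD.
#' Self-pairs are excluded; each unordered pair counts once; categories
#' with no pairs are omitted with a warning.
#'
#' @param corr a \linkS4class{CorrelationMatrix}.
#' @param meta metadata covering the matrix ids (host, study_id).
#' @return list with \code{summary} (data.frame category, scope, n_pairs,
#'   mean_r, mean_z), \code{category_means} (overall mean r per category),
#'   \code{category_means_z} and \code{test} (\code{\link{compareGroups}}
#'   anova_tukey output on z, \code{NULL} if < 2 usable categories).
#' @export
groupCorrelationSummary <- function(corr, meta) {
  stopifnot(is(corr, "CorrelationMatrix"))
  meta <- asSampleMeta(meta)
  ids <- corr@ids
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss))
    stop("ids absent from metadata: ", paste(miss, collapse = ", "))
  host <- setNames(meta$host, meta$sample_id)[ids]
  study <- setNames(meta$study_id, meta$sample_id)[ids]
  n <- length(ids)
  ut <- which(upper.tri(corr@r), arr.ind = TRUE)
  cat_ <- ifelse(host[ut[, 1L]] == host[ut[, 2L]],
                 ifelse(host[ut[, 1L]] == "human", "human_human",
                        "mouse_mouse"),
                 "human_mouse")
  scope <- ifelse(study[ut[, 1L]] == study[ut[, 2L]], "within_study",
                  "cross_study")
  rv <- corr@r[ut]; zv <- corr@z[ut]
  ok <- !is.na(rv)
  df <- data.frame(category = cat_[ok], scope = scope[ok], r = rv[ok],
                   z = zv[ok])
  smry <- do.call(rbind, lapply(split(df, list(df$category, df$scope),
                                      drop = TRUE), function(s) {
    data.frame(category = s$category[1L], scope = s$scope[1L],
               n_pairs = nrow(s), mean_r = mean(s$r), mean_z = mean(s$z))
  }))
  rownames(smry) <- NULL
  empty <- setdiff(c("human_human", "human_mouse", "mouse_mouse"),
                   unique(df$category))
  if (length(empty))
    warning("categor(ies) with no pairs omitted: ",
            paste(empty, collapse = ", "))
  catMeans <- tapply(df$r, df$category, mean)
  catMeansZ <- tapply(df$z, df$category, mean)
  byCat <- split(df$z, df$category)
  test <- if (sum(lengths(byCat) >= 2L) >= 2L)
    compareGroups(byCat[lengths(byCat) >= 2L], method = "anova_tukey")
  else NULL
  list(summary = smry, category_means = catMeans,
       category_means_z = catMeansZ, test = test)
}
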