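#' Bray-Curtis dissimilarity between sample columns
#'
#' d(i, j) = sum_t |x_ti - x_tj| / sum_t (x_ti + x_tj) over the shared taxon
#' index: 0 for identical compositions, 1 for disjoint supports. Requires a
#' renormalized table (columns summing to 100) so that dissimilarities are
#' comparable across samples with different sequencing depth or dropped
#' unclassified fractions.
#'
#' @param x a renormalized \linkS4class{TaxonTable}.
#' @return a \linkS4class{DistMatrix} over the sample columns.
#' @export
brayCurtis <- function(x) {
  stopifnot(is(x, "TaxonTable"))
  ra <- raValues(x)
  cs <- colSums(ra)
  if (any(cs <= 0))
    stop("all-zero sample column(s): ",
         paste(colnames(ra)[cs <= 0], collapse = ", "))
  if (!x@renormalized && any(abs(cs - 100) > 1e-6))
    stop("table is not renormalized; call renormalize() first")
  num <- as.matrix(stats::dist(t(ra), method = "manhattan"))
  den <- outer(cs, cs, "+")
  DistMatrix(num / den)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers -d^2/2, eigendecomposes, and scales eigenvectors by the
#' square root of their (positive) eigenvalues. Axes with eigenvalue at or
#' below 1e-12 contribute zero coordinates. Negative eigenvalues (possible
#' for semi-metric dissimilarities such as Bray-Curtis) are retained in
#' \code{ordEigenvalues} for the dispersion correction used by
#' \code{\link{permdisp}}.
#'
#' @param d a \linkS4class{DistMatrix} (or symmetric matrix).
#' @param k number of axes to return (default all n).
#' @return an \linkS4class{Ordination}.
#' @export
pcoa <- function(d, k = nrow(d)) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  n <- nrow(d)
  if (k > n) stop("k may not exceed the number of samples")
  e <- pcoaEigen(d)
  pos <- e$values > 1e-12
  coords <- matrix(0, n, k, dimnames = list(rownames(d),
                                            paste0("Axis", seq_len(k))))
  for (j in seq_len(k))
    if (pos[j]) coords[, j] <- e$vectors[, j] * sqrt(e$values[j])
  pe <- numeric(k)
  if (any(pos)) {
    tot <- sum(e$values[pos])
    pe[seq_len(k)] <- ifelse(pos[seq_len(k)],
                             e$values[seq_len(k)] / tot, 0)
  }
  new("Ordination", coordinates = coords, eigenvalues = e$values,
      proportionExplained = pe)
}

# Gower-centered eigendecomposition shared by pcoa() and permdisp().
pcoaEigen <- function(d) {
  n <- nrow(d)
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  rownames(e$vectors) <- rownames(d)
  e
}

# One-way pseudo-F machinery shared by the observed statistic and the
# permutation loop. Groups are integer codes 1..a; perms is an n x m matrix
# of permuted codes (each column one relabeling).
pseudoFStats <- function(d2, codes, a) {
  n <- length(codes)
  ssTot <- sum(d2[upper.tri(d2)]) / n
  ssW <- 0
  for (g in seq_len(a)) {
    idx <- which(codes == g)
    ssW <- ssW + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssB <- ssTot - ssW
  f <- (ssB / (a - 1)) / (ssW / (n - a))
  list(f = f, r2 = ssB / ssTot)
}

# Vectorized pseudo-F over many permuted label columns.
pseudoFPerms <- function(d2, perms, a) {
  n <- nrow(perms)
  ssTot <- sum(d2[upper.tri(d2)]) / n
  ssW <- 0
  for (g in seq_len(a)) {
    v <- (perms == g) * 1
    ng <- colSums(v)
    ssW <- ssW + colSums(v * (d2 %*% v)) / (2 * ng)
  }
  ssB <- ssTot - ssW
  (ssB / (a - 1)) / (ssW / (n - a))
}

# Ties between a permuted statistic and the observed one must count as
# exceedances; the vectorized permutation algebra rounds differently from
# the observed-statistic path, so the tie tolerance is sqrt machine epsilon
# scaled by the statistic, not an exact comparison.
permTieTol <- function(f) {
  sqrt(.Machine$double.eps) * max(1, abs(f))
}

permCodes <- function(codes, nPerm) {
  n <- length(codes)
  vapply(seq_len(nPerm), function(i) codes[sample.int(n)], integer(n))
}

checkGroups <- function(d, groups) {
  d <- as.matrix(d)
  if (length(groups) != nrow(d))
    stop("one group label per sample is required")
  f <- factor(groups)
  if (nlevels(f) < 2L)
    stop("at least two groups are required (single group is degenerate)")
  list(d = d, codes = as.integer(f), a = nlevels(f), levels = levels(f))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way pseudo-F on a dissimilarity matrix: with total sum of squared
#' dissimilarities SS_total = sum_{i<j} d_ij^2 / n and within-group
#' SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g,
#' F = (SS_between / (a - 1)) / (SS_within / (n - a)) and
#' R^2 = SS_between / SS_total. Significance comes from permuting group
#' labels; the p-value uses the bias-avoiding (1 + b) / (1 + m) estimator,
#' so p is never smaller than 1/(m + 1).
#'
#' @param d a \linkS4class{DistMatrix}.
#' @param groups group label per sample (>= 2 groups).
#' @param nPerm number of label permutations (default 999).
#' @param seed integer RNG seed (mandatory; no hidden global RNG).
#' @return a \linkS4class{PermutationTestResult}.
#' @export
permanova <- function(d, groups, nPerm = 999, seed) {
  if (missing(seed)) stop("seed is mandatory")
  ck <- checkGroups(d, groups)
  d2 <- ck$d^2
  obs <- pseudoFStats(d2, ck$codes, ck$a)
  b <- 0L
  if (nPerm > 0) {
    perms <- withSeed(seed, permCodes(ck$codes, nPerm))
    fPerm <- pseudoFPerms(d2, perms, ck$a)
    b <- sum(fPerm >= obs$f - permTieTol(obs$f))
  }
  new("PermutationTestResult", statistic = obs$f, rSquared = obs$r2,
      pValue = (1 + b) / (1 + nPerm), nPermutations = as.integer(nPerm),
      seed = as.integer(seed), method = "permanova")
}

# Corrected PCoA embedding split into real and imaginary axes (negative
# eigenvalues of semi-metric dissimilarities live on the imaginary axes).
dispEmbedding <- function(d) {
  e <- pcoaEigen(as.matrix(d))
  tol <- max(abs(e$values)) * 1e-10 + 1e-12
  posAx <- e$values > tol
  negAx <- e$values < -tol
  list(
    xr = e$vectors[, posAx, drop = FALSE] %*%
      diag(sqrt(e$values[posAx]), sum(posAx)),
    xi = e$vectors[, negAx, drop = FALSE] %*%
      diag(sqrt(-e$values[negAx]), sum(negAx)))
}

# Distances to group centroids in corrected PCoA space: the squared
# distance is the real-axis contribution minus the imaginary-axis
# contribution, floored at 0 (handles Bray-Curtis negative eigenvalues).
centroidDistancesFromEmbedding <- function(emb, codes, a) {
  z2 <- numeric(length(codes))
  for (g in seq_len(a)) {
    idx <- which(codes == g)
    crReal <- colMeans(emb$xr[idx, , drop = FALSE])
    real <- rowSums(sweep(emb$xr[idx, , drop = FALSE], 2L, crReal)^2)
    imag <- 0
    if (ncol(emb$xi)) {
      crImag <- colMeans(emb$xi[idx, , drop = FALSE])
      imag <- rowSums(sweep(emb$xi[idx, , drop = FALSE], 2L, crImag)^2)
    }
    z2[idx] <- pmax(real - imag, 0)
  }
  sqrt(z2)
}

centroidDistances <- function(d, codes, a) {
  centroidDistancesFromEmbedding(dispEmbedding(d), codes, a)
}

# Fully recomputed dispersion F for every permuted label column, using the
# identity ||x_i - c_g||^2 = ||x_i||^2 - 2 x_i.c_g + ||c_g||^2 on the real
# and imaginary axes so all permutations reduce to a few matrix products.
permdispFPerms <- function(emb, perms, a) {
  n <- nrow(perms); m <- ncol(perms)
  z2 <- matrix(0, n, m)
  part <- function(X, V, ng) {
    if (!ncol(X)) return(0)
    C <- sweep(crossprod(X, V), 2L, ng, "/")   # centroids, k x m
    contrib <- sweep(-2 * (X %*% C), 1L, rowSums(X^2), "+")
    sweep(contrib, 2L, colSums(C^2), "+")
  }
  for (g in seq_len(a)) {
    V <- (perms == g) * 1
    ng <- colSums(V)
    z2 <- z2 + V * (part(emb$xr, V, ng) - part(emb$xi, V, ng))
  }
  z <- sqrt(pmax(z2, 0))
  tot <- colSums(z)
  sst <- colSums(z^2) - tot^2 / n
  ssb <- -tot^2 / n
  for (g in seq_len(a)) {
    V <- (perms == g)
    ssb <- ssb + colSums(z * V)^2 / colSums(V)
  }
  (ssb / (a - 1)) / ((sst - ssb) / (n - a))
}

onewayF <- function(z, codes, a) {
  n <- length(z)
  gm <- mean(z)
  ssb <- 0; ssw <- 0
  for (g in seq_len(a)) {
    zg <- z[codes == g]
    ssb <- ssb + length(zg) * (mean(zg) - gm)^2
    ssw <- ssw + sum((zg - mean(zg))^2)
  }
  (ssb / (a - 1)) / (ssw / (n - a))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Embeds the dissimilarity matrix in corrected principal-coordinate space,
#' measures each sample's distance to its group centroid (negative
#' eigenvalues subtract, floored at zero), and compares groups with a
#' one-way ANOVA F on those distances. Significance comes from permuting
#' group labels and recomputing the statistic in full - group centroids,
#' centroid distances and F - within the fixed embedding (which does not
#' depend on the labels), with the same (1+b)/(1+m) tail rule as
#' \code{\link{permanova}}.
#'
#' @inheritParams permanova
#' @return a \linkS4class{PermutationTestResult}; \code{testRSquared} is
#'   \code{NA}.
#' @export
permdisp <- function(d, groups, nPerm = 999, seed) {
  if (missing(seed)) stop("seed is mandatory")
  ck <- checkGroups(d, groups)
  sizes <- tabulate(ck$codes, ck$a)
  if (any(sizes < 2L))
    stop("every group needs >= 2 members (singleton centroid distance is degenerate)")
  emb <- dispEmbedding(ck$d)
  z <- centroidDistancesFromEmbedding(emb, ck$codes, ck$a)
  fObs <- onewayF(z, ck$codes, ck$a)
  b <- 0L
  if (nPerm > 0) {
    perms <- withSeed(seed, permCodes(ck$codes, nPerm))
    fPerm <- permdispFPerms(emb, perms, ck$a)
    b <- sum(fPerm >= fObs - permTieTol(fObs))
  }
  new("PermutationTestResult", statistic = fObs, rSquared = NA_real_,
      pValue = (1 + b) / (1 + nPerm), nPermutations = as.integer(nPerm),
      seed = as.integer(seed), method = "permdisp")
}

#' Extract pairwise dissimilarities by donor/recipient category
#'
#' Classifies every unordered off-diagonal pair of a dissimilarity matrix
#' computed on a replicate-averaged table (human donor samples + recipient
#' group profiles) into exactly one of: \code{donor_donor},
#' \code{mouse_mouse}, \code{donor_paired_recipient} (a donor against its
#' own recipient group) or \code{donor_other_recipient}.
#'
#' @param d a \linkS4class{DistMatrix} whose ids are human sample ids and
#'   recipient-group ids.
#' @param meta collapsed metadata (see \code{\link{collapseMeta}}).
#' @param pairing a \linkS4class{PairingMap}.
#' @return named list of numeric dissimilarity vectors, one per category.
#' @export
extractGroupDissimilarities <- function(d, meta, pairing) {
  m <- as.matrix(d)
  ids <- rownames(m)
  meta <- asSampleMeta(meta)
  unknown <- setdiff(ids, meta$sample_id)
  if (length(unknown))
    stop("ids absent from metadata: ", paste(unknown, collapse = ", "))
  host <- setNames(meta$host, meta$sample_id)[ids]
  pairedKey <- paste(pairDonors(pairing), pairGroups(pairing))
  out <- list(donor_donor = numeric(0), mouse_mouse = numeric(0),
              donor_paired_recipient = numeric(0),
              donor_other_recipient = numeric(0))
  n <- length(ids)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    hi <- host[i]; hj <- host[j]
    cat_ <- if (hi == "human" && hj == "human") "donor_donor"
      else if (hi == "mouse" && hj == "mouse") "mouse_mouse"
      else {
        dn <- if (hi == "human") ids[i] else ids[j]
        gp <- if (hi == "human") ids[j] else ids[i]
        if (paste(dn, gp) %in% pairedKey) "donor_paired_recipient"
        else "donor_other_recipient"
      }
    out[[cat_]] <- c(out[[cat_]], m[i, j])
  }
  out
}
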