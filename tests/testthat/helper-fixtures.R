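# Shared fixtures and independent oracles for the test suite.

# Small taxon table with controlled values.
toyTable <- function(values, rank = "species", renorm = FALSE) {
  tt <- TaxonTable(values, rank = rank)
  if (renorm) renormalize(tt) else tt
}

# A cohort metadata block: nDonors humans (one sample each at `timepoint`)
# plus nMice mice per donor sharing a replicate group.
toyMeta <- function(nDonors = 2, nMice = 3, timepoint = "T0") {
  donors <- sprintf("d%02d", seq_len(nDonors))
  rows <- list()
  for (dn in donors) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(dn, "_", timepoint), host = "human", donor_id = dn,
      timepoint = timepoint, study_id = "s1", route = "none",
      replicate_group = "none")
    for (k in seq_len(nMice))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_m%d", dn, k), host = "mouse", donor_id = dn,
        timepoint = timepoint, study_id = "s1", route = "HTR",
        replicate_group = paste0(dn, "_mice"))
  }
  do.call(rbind, rows)
}

# Naive double-loop Bray-Curtis, deliberately independent of the
# vectorized implementation.
naiveBray <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (t in seq_len(nrow(m))) {
      num <- num + abs(m[t, i] - m[t, j])
      den <- den + m[t, i] + m[t, j]
    }
    d[i, j] <- num / den
  }
  d
}

# Pseudo-F computed directly from the definition, for the enumeration
# oracle (independent of pseudoFStats internals).
oracleF <- function(d, labels) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  labs <- unique(labels)
  a <- length(labs)
  ssT <- sum(d2[upper.tri(d2)]) / n
  ssW <- 0
  for (g in labs) {
    idx <- which(labels == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssW <- ssW + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ((ssT - ssW) / (a - 1)) / (ssW / (n - a))
}

# Full enumeration of all distinct two-group label assignments with the
# observed group sizes; exact permutation p = share of assignments whose F
# meets or exceeds the observed one (identity included).
enumPermanovaP <- function(d, labels) {
  n <- length(labels)
  g1 <- which(labels == unique(labels)[1L])
  fObs <- oracleF(d, labels)
  combs <- utils::combn(n, length(g1))
  fAll <- apply(combs, 2L, function(idx) {
    lab <- rep("b", n); lab[idx] <- "a"
    oracleF(d, lab)
  })
  mean(fAll >= fObs - 1e-12)
}

# Enumeration oracle for dispersion on 1-D point configurations: distances
# to the group mean are computed directly from the coordinates (no
# embedding needed), the F statistic is recomputed for every distinct
# two-group label assignment.
enumDispPointsP <- function(pts, labels) {
  n <- length(labels)
  g1 <- which(labels == unique(labels)[1L])
  fOn <- function(lab) {
    z <- abs(pts - ave(pts, lab))
    gm <- mean(z); ssb <- 0; ssw <- 0
    for (g in unique(lab)) {
      zg <- z[lab == g]
      ssb <- ssb + length(zg) * (mean(zg) - gm)^2
      ssw <- ssw + sum((zg - mean(zg))^2)
    }
    (ssb / (length(unique(lab)) - 1)) / (ssw / (n - length(unique(lab))))
  }
  fObs <- fOn(labels)
  combs <- utils::combn(n, length(g1))
  fAll <- apply(combs, 2L, function(idx) {
    lab <- rep("b", n); lab[idx] <- "a"
    fOn(lab)
  })
  mean(fAll >= fObs - 1e-12)
}

# iid log-normal compositional samples: the exchangeable null for the
# type-I error checks.
nullComposition <- function(nTaxa, nSamples) {
  m <- matrix(exp(rnorm(nTaxa * nSamples, 0, 1)), nTaxa,
              dimnames = list(paste0("t", seq_len(nTaxa)),
                              paste0("s", seq_len(nSamples))))
  renormalize(TaxonTable(m, rank = "species"))
}

writeLines2 <- function(lines, path) {
  writeLines(lines, path)
  path
}
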