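test_that("Bray-Curtis matches hand values and the naive-loop oracle", {
  m <- matrix(c(60, 40, 0, 20, 30, 50), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("x", "y")))
  d <- brayCurtis(toyTable(m, renorm = TRUE))
  expect_equal(d["x", "y"], 0.5)

  same <- matrix(c(50, 50, 50, 50), 2,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(brayCurtis(toyTable(same, renorm = TRUE))["s1", "s2"], 0)

  disjoint <- matrix(c(100, 0, 0, 100), 2,
                     dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(brayCurtis(toyTable(disjoint, renorm = TRUE))["s1", "s2"], 1)

  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rexp(12 * 6), 12,
                dimnames = list(paste0("t", 1:12), paste0("s", 1:6)))
    tt <- renormalize(toyTable(m))
    expect_equal(as.matrix(brayCurtis(tt)), naiveBray(raValues(tt)),
                 tolerance = 1e-12)
  }
})

test_that("Bray-Curtis agrees with vegan and is scale-invariant", {
  skip_if_not_installed("vegan")
  set.seed(7)
  m <- matrix(rexp(60), 10,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  tt <- renormalize(toyTable(m))
  ref <- as.matrix(vegan::vegdist(t(raValues(tt)), method = "bray"))
  expect_equal(as.matrix(brayCurtis(tt)), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  # uniform rescaling of the input columns leaves the result unchanged
  # because renormalization restores the percent scale
  tt2 <- renormalize(toyTable(m * 7))
  expect_equal(as.matrix(brayCurtis(tt2)), as.matrix(brayCurtis(tt)),
               tolerance = 1e-12)
})

test_that("PCoA reproduces Euclidean geometry and normalizes axis shares", {
  # three collinear points at 0, 3, 4
  pts <- c(0, 3, 4)
  d <- DistMatrix(as.matrix(stats::dist(pts)) * 1)
  rownames(d) <- colnames(d) <- c("p1", "p2", "p3")
  ord <- pcoa(d)
  rec <- as.matrix(stats::dist(ordCoordinates(ord)[, 1]))
  expect_equal(unname(rec), unname(as.matrix(d)), tolerance = 1e-9)
  expect_equal(sum(proportionExplained(ord)), 1, tolerance = 1e-9)

  zero <- DistMatrix(matrix(0, 3, 3,
                            dimnames = list(letters[1:3], letters[1:3])))
  expect_true(all(ordCoordinates(pcoa(zero)) == 0))

  asym <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pcoa(asym), "symmetric")
})

test_that("PCoA agrees with classical cmdscale on random Euclidean data", {
  set.seed(9)
  x <- matrix(rnorm(7 * 3), 7)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("s", 1:7), paste0("s", 1:7))
  ord <- pcoa(DistMatrix(d), k = 3)
  ref <- stats::cmdscale(d, k = 3)
  for (j in 1:3)
    expect_equal(abs(ordCoordinates(ord)[, j]), abs(ref[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PERMANOVA recovers the exact enumeration p on the 2+2 toy design", {
  ids <- paste0("s", 1:4)
  d <- matrix(0.9, 4, 4, dimnames = list(ids, ids))
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  dm <- DistMatrix(d)
  groups <- c("a", "a", "b", "b")
  pExact <- enumPermanovaP(dm, groups)
  expect_equal(pExact, 2 / 6)
  res <- permanova(dm, groups, nPerm = 10000, seed = 5)
  se <- sqrt(pExact * (1 - pExact) / 10000)
  expect_lt(abs(testPValue(res) - pExact), 3 * se + 1e-4)
})

test_that("PERMANOVA F and R2 match vegan::adonis2 on a one-way design", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m <- matrix(rexp(15 * 9), 15,
              dimnames = list(paste0("t", 1:15), paste0("s", 1:9)))
  tt <- renormalize(toyTable(m))
  d <- brayCurtis(tt)
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- permanova(d, groups, nPerm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(testStatistic(res), ref$F[1], tolerance = 1e-10)
  expect_equal(testRSquared(res), ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA is invariant to consistent relabeling and flat on equal distances", {
  set.seed(13)
  m <- matrix(rexp(10 * 8), 10,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:8)))
  d <- brayCurtis(renormalize(toyTable(m)))
  g <- rep(c("a", "b"), each = 4)
  r1 <- permanova(d, g, nPerm = 199, seed = 2)
  gSwap <- ifelse(g == "a", "b", "a")
  r2 <- permanova(d, gSwap, nPerm = 199, seed = 2)
  expect_equal(testStatistic(r1), testStatistic(r2))

  ids <- paste0("s", 1:4)
  eq <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(eq) <- 0
  res <- permanova(DistMatrix(eq), c("a", "a", "b", "b"),
                   nPerm = 999, seed = 3)
  expect_gt(testPValue(res), 0.9)
  expect_error(permanova(d, rep("a", 8), nPerm = 9, seed = 1),
               "two groups")
})

test_that("PERMDISP flags unequal dispersion and respects its preconditions", {
  # group A coincident, group B spread out: maximal dispersion contrast
  ids <- paste0("s", 1:6)
  pts <- c(0, 0, 0, -3, 1, 6)
  d <- as.matrix(stats::dist(pts)); dimnames(d) <- list(ids, ids)
  g <- rep(c("A", "B"), each = 3)
  res <- permdisp(DistMatrix(d), g, nPerm = 999, seed = 7)
  expect_gt(testStatistic(res), 4)
  ck <- hmaFidelity:::checkGroups(d, g)
  z <- hmaFidelity:::centroidDistances(ck$d, ck$codes, ck$a)
  expect_true(all(z >= 0))
  expect_equal(z, abs(pts - ave(pts, g)), tolerance = 1e-9)
  pEnum <- enumDispPointsP(pts, g)
  # sampler p within Monte-Carlo error of full enumeration
  expect_lt(abs(testPValue(res) - pEnum), 3 * sqrt(pEnum / 999) + 2e-3)

  # mirrored geometry: identical dispersion profile, F exactly 0
  pts2 <- c(0, 1, 3, 10, 11, 13)
  d2 <- as.matrix(stats::dist(pts2))
  dimnames(d2) <- list(ids, ids)
  res2 <- permdisp(DistMatrix(d2), g, nPerm = 499, seed = 11)
  expect_lt(testStatistic(res2), 1e-10)
  expect_gt(testPValue(res2), 0.9)

  expect_error(permdisp(DistMatrix(d2), c("A", rep("B", 5)),
                        nPerm = 9, seed = 1), ">= 2 members")
})

test_that("PERMDISP F matches vegan::betadisper on Bray-Curtis input", {
  skip_if_not_installed("vegan")
  set.seed(31)
  m <- matrix(rexp(20 * 10)^2, 20,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:10)))
  tt <- renormalize(toyTable(m))
  d <- brayCurtis(tt)
  g <- rep(c("a", "b"), each = 5)
  res <- permdisp(d, g, nPerm = 99, seed = 1)
  bd <- vegan::betadisper(stats::as.dist(d), g, type = "centroid")
  ref <- stats::anova(bd)
  expect_equal(testStatistic(res), ref$`F value`[1], tolerance = 1e-8)
})

test_that("grouped dissimilarity extraction partitions every off-diagonal pair", {
  nD <- 3
  meta <- collapseMeta(toyMeta(nDonors = nD, nMice = 2))
  pairing <- buildPairing(toyMeta(nDonors = nD, nMice = 2))
  ids <- meta$sample_id
  set.seed(17)
  m <- matrix(rexp(10 * length(ids)), 10,
              dimnames = list(paste0("t", 1:10), ids))
  d <- brayCurtis(renormalize(toyTable(m)))
  gd <- extractGroupDissimilarities(d, meta, pairing)
  expect_identical(unname(lengths(gd)), c(3L, 3L, 3L, 6L))
  expect_equal(sum(lengths(gd)), choose(length(ids), 2))
  expect_setequal(unlist(gd), d[upper.tri(d)])

  donorsOnly <- meta[meta$host == "human", ]
  dHuman <- DistMatrix(as.matrix(d)[donorsOnly$sample_id,
                                    donorsOnly$sample_id])
  gdH <- extractGroupDissimilarities(dHuman, donorsOnly, pairing)
  expect_identical(unname(lengths(gdH)), c(3L, 0L, 0L, 0L))

  expect_error(extractGroupDissimilarities(d, donorsOnly, pairing),
               "absent from metadata")
})

test_that("Kruskal-Wallis/Dunn and ANOVA/Tukey comparisons behave on toys", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(10, 11, 12), g3 = c(20, 21, 22))
  kd <- compareGroups(groups, method = "kruskal_dunn")
  expect_equal(kd$statistic, 7.2)
  expect_identical(nrow(kd$pairwise), 3L)
  # extreme pair should have the largest |z|
  expect_gt(abs(kd$pairwise$statistic[kd$pairwise$group1 == "g1" &
                                      kd$pairwise$group2 == "g3"]),
            abs(kd$pairwise$statistic[1]))

  expect_warning(
    flat <- compareGroups(list(a = c(1, 1), b = c(1, 1)), "kruskal_dunn"),
    "identical")
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  at <- compareGroups(list(a = c(1, 2, 3), b = c(1.0, 2.0, 3.0)),
                      method = "anova_tukey")
  expect_lt(at$statistic, 1e-20)
  expect_gt(at$p_value, 0.99)
})

test_that("Dunn z-statistics match a direct midrank computation", {
  vals <- list(a = c(1, 5, 7), b = c(2, 2, 9), c = c(10, 12, 3))
  kd <- compareGroups(vals, method = "kruskal_dunn", adjust = "none")
  x <- unlist(vals); g <- rep(names(vals), each = 3)
  r <- rank(x); n <- length(x)
  ties <- table(r)
  sig2 <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  zab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / sqrt(sig2 * (2 / 3))
  got <- kd$pairwise$statistic[kd$pairwise$group1 == "a" &
                               kd$pairwise$group2 == "b"]
  expect_equal(got, zab, tolerance = 1e-12)
})
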