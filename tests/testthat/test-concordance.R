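makeTimepointCohort <- function() {
  # 2 donors, 2 mice each, profiles at T0 and T2
  meta0 <- toyMeta(nDonors = 2, nMice = 2, timepoint = "T0")
  meta2 <- toyMeta(nDonors = 2, nMice = 2, timepoint = "T2")
  mouse2 <- meta2$host == "mouse"
  meta2$sample_id[mouse2] <- paste0(meta2$sample_id[mouse2], "_T2")
  meta2$replicate_group[mouse2] <- paste0(meta2$replicate_group[mouse2],
                                          "_T2")
  rbind(meta0, meta2)
}

test_that("delta RA subtracts paired timepoint profiles on the percent scale", {
  meta <- makeTimepointCohort()
  ids <- meta$sample_id
  m <- matrix(0, 3, length(ids), dimnames = list(c("A", "B", "C"), ids))
  m["A", ] <- 50; m["B", ] <- 30; m["C", ] <- 20
  m["A", "d01_T2"] <- 65; m["C", "d01_T2"] <- 5  # +15 / -15
  tt <- toyTable(m)
  dd <- deltaRA(tt, meta, host = "human")
  expect_equal(dd["A", "d01"], 15)
  expect_equal(dd["C", "d01"], -15)
  expect_equal(unname(dd[, "d02"]), c(0, 0, 0))
  # mouse deltas averaged over cage mates; all-identical profiles give 0
  rd <- deltaRA(tt, meta, host = "mouse")
  expect_true(all(rd == 0))
  # a taxon present only at T0 yields a negative delta of its abundance
  m2 <- m
  m2["C", "d02_T2"] <- 0
  dd2 <- deltaRA(toyTable(m2), meta, host = "human")
  expect_equal(dd2["C", "d02"], -20)
})

test_that("entities missing one timepoint are excluded with a warning", {
  meta <- makeTimepointCohort()
  meta <- meta[meta$sample_id != "d02_T2", ]
  m <- matrix(10, 2, nrow(meta),
              dimnames = list(c("A", "B"), meta$sample_id))
  expect_warning(dd <- deltaRA(toyTable(m), meta, host = "human"), "d02")
  expect_identical(colnames(dd), "d01")
})

test_that("delta concordance reproduces the hand-computed toy correlation", {
  dd <- c(t1 = 1, t2 = 2, t3 = -1, t4 = -2)
  rd <- c(t1 = 1, t2 = -2, t3 = -1, t4 = 2)
  res <- deltaConcordance(dd, rd)
  expect_equal(res$pearson_r, -0.6, tolerance = 1e-12)
  expect_equal(unname(res$quadrant_fractions), rep(25, 4))

  perfect <- deltaConcordance(dd, dd)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(unname(perfect$quadrant_fractions[c("Q2", "Q4")]), c(0, 0))
  expect_equal(sum(perfect$quadrant_fractions), 100)
})

test_that("zero deltas drop out of quadrants but stay in the correlation", {
  dd <- c(t1 = 0, t2 = 2, t3 = -1, t4 = -2, t5 = 3)
  rd <- c(t1 = 5, t2 = 1, t3 = -2, t4 = -1, t5 = 2)
  res <- deltaConcordance(dd, rd)
  expect_identical(res$n_quadrant, 4L)
  expect_equal(sum(res$quadrant_fractions), 100)
  expect_equal(res$pearson_r, stats::cor(dd, rd), tolerance = 1e-12)
  expect_error(deltaConcordance(dd[1:2], rd[1:2]), ">= 3")
})

test_that("route scatter pairs log abundances and flags consortium taxa", {
  m1 <- matrix(c(10, 1, 89, 0.1, 40, 59.9), 3,
               dimnames = list(c("A", "B", "C"), c("h1", "h2")))
  tHTR <- toyTable(m1)
  tMTR <- toyTable(m1[, c(2, 1)] * 1)   # same values, different samples
  colnames(tMTR) <- c("m1", "m2")
  res <- routeAbundanceScatter(tHTR, tMTR, consortium = c("B", "zzz"))
  expect_identical(res$points$is_consortium, c(FALSE, TRUE, FALSE))
  expect_equal(res$points$log_ra_htr, unname(logDisplay(rowMeans(m1))))
  idem <- routeAbundanceScatter(tHTR, tHTR)
  expect_equal(idem$r, 1)
  expect_error(routeAbundanceScatter(tHTR,
    toyTable(matrix(1, 1, 1, dimnames = list("zz", "s")))), "no taxa")
})

test_that("route scatter r matches a direct formula on a 4-taxon toy", {
  m1 <- matrix(c(1, 10, 0.1, 5), 4, 1,
               dimnames = list(paste0("t", 1:4), "a"))
  m2 <- matrix(c(2, 8, 0.2, 9), 4, 1,
               dimnames = list(paste0("t", 1:4), "b"))
  res <- routeAbundanceScatter(toyTable(m1), toyTable(m2))
  x <- log10(m1[, 1]); y <- log10(m2[, 1])
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, rHand, tolerance = 1e-12)
})

test_that("sample correlation matrix unions taxa and matches direct Pearson", {
  t1 <- toyTable(matrix(c(50, 30, 20, 10, 60, 30), 3,
                        dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
  t2 <- toyTable(matrix(c(40, 40, 20), 3, 1,
                        dimnames = list(c("B", "C", "D"), "s3")))
  cm <- sampleCorrelationMatrix(list(t1, t2))
  expect_identical(sampleIds(cm), c("s1", "s2", "s3"))
  # hand-build the zero-filled union vectors for s1 vs s3
  u1 <- c(A = 50, B = 30, C = 20, D = 0)
  u3 <- c(A = 0, B = 40, C = 40, D = 20)
  expect_equal(corValues(cm)["s1", "s3"], stats::cor(u1, u3),
               tolerance = 1e-12)
  expect_equal(corValues(cm)["s1", "s1"], 1)
  # two equal columns correlate exactly 1
  t3 <- toyTable(matrix(c(50, 30, 20, 50, 30, 20), 3,
                        dimnames = list(c("A", "B", "C"), c("x", "y"))))
  expect_equal(sampleCorrelationMatrix(t3)@r["x", "y"], 1)
  # appending an all-zero taxon to every table changes nothing
  withZero <- toyTable(rbind(raValues(t1),
                             ZZ = c(0, 0)))
  cmz <- sampleCorrelationMatrix(list(withZero, t2))
  expect_equal(corValues(cmz), corValues(cm), tolerance = 1e-12)
})

test_that("zero-variance profiles are reported as missing with a warning", {
  flat <- toyTable(matrix(c(25, 25, 25, 25, 70, 10, 10, 10), 4,
                          dimnames = list(paste0("t", 1:4), c("flat", "ok"))))
  expect_warning(cm <- sampleCorrelationMatrix(flat), "flat")
  expect_true(is.na(corValues(cm)["flat", "ok"]))
})

test_that("Fisher z is the closed-form atanh with clamping and oddness", {
  expect_equal(fisherZ(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisherZ(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(fisherZ(0), 0)
  r <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(fisherZ(-r), -fisherZ(r), tolerance = 1e-12)
  # inverse property over a wide z range
  z <- seq(-4.9, 4.9, by = 0.35)
  expect_equal(fisherZ(tanh(z)), z, tolerance = 1e-12)
  expect_warning(zc <- fisherZ(1), "clamped")
  expect_true(is.finite(zc))
})

test_that("group correlation summary reports r means and tests on z", {
  meta <- collapseMeta(toyMeta(nDonors = 3, nMice = 2))
  ids <- meta$sample_id
  set.seed(23)
  m <- matrix(rexp(30 * length(ids)), 30,
              dimnames = list(paste0("t", 1:30), ids))
  cm <- sampleCorrelationMatrix(renormalize(toyTable(m)))
  gs <- groupCorrelationSummary(cm, meta)
  # arithmetic oracle: recompute one category mean directly
  hh <- utils::combn(ids[meta$host == "human"], 2)
  rHH <- mean(apply(hh, 2, function(p) corValues(cm)[p[1], p[2]]))
  expect_equal(unname(gs$category_means["human_human"]), rHH,
               tolerance = 1e-12)
  # reporting is on r, testing on z: the test input means equal mean z
  zHH <- mean(apply(hh, 2, function(p) zValues(cm)[p[1], p[2]]))
  expect_equal(unname(gs$category_means_z["human_human"]), zHH,
               tolerance = 1e-12)
  expect_identical(gs$test$method, "anova_tukey")
  expect_false(isTRUE(all.equal(unname(gs$category_means["human_human"]),
                                unname(gs$category_means_z["human_human"]))))
  # all-identical profiles: every defined category mean is 1
  same <- toyTable(matrix(rep(c(60, 30, 10), length(ids)), 3,
                          dimnames = list(c("A", "B", "C"), ids)))
  cm1 <- sampleCorrelationMatrix(same)
  gs1 <- suppressWarnings(groupCorrelationSummary(cm1, meta))
  expect_true(all(abs(gs1$category_means - 1) < 1e-12))
})

test_that("self-concordant deltas always give r = 1 with empty off-quadrants", {
  set.seed(4)
  for (i in 1:5) {
    v <- setNames(rnorm(8), paste0("t", 1:8))
    res <- deltaConcordance(v, v)
    expect_equal(res$pearson_r, 1)
    expect_equal(unname(res$quadrant_fractions[c("Q2", "Q4")]), c(0, 0))
  }
})
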