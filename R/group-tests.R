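#' Omnibus + post-hoc comparison of grouped values
#'
#' \code{kruskal_dunn}: Kruskal-Wallis rank-sum omnibus (midranks, tie
#' correction; via \code{stats::kruskal.test}) followed by Dunn's pairwise
#' z-tests on mean ranks with multiplicity adjustment (default Bonferroni).
#' \code{anova_tukey}: one-way ANOVA omnibus followed by Tukey's HSD
#' (\code{stats::aov} + \code{stats::TukeyHSD}).
#'
#' If every value is identical across all groups the rank statistic is
#' undefined; the omnibus is reported as statistic 0, p 1 with a warning.
#'
#' @param valuesByGroup named list mapping group label to numeric values
#'   (>= 2 groups, >= 2 values each).
#' @param method \code{"kruskal_dunn"} or \code{"anova_tukey"}.
#' @param adjust p-adjustment for Dunn pairwise tests (see
#'   \code{\link[stats]{p.adjust}}).
#' @return list with \code{method}, omnibus \code{statistic} and
#'   \code{p_value}, and \code{pairwise} data.frame (group1, group2,
#'   statistic, p_adj).
#' @export
compareGroups <- function(valuesByGroup,
                          method = c("kruskal_dunn", "anova_tukey"),
                          adjust = "bonferroni") {
  method <- match.arg(method)
  if (length(valuesByGroup) < 2L)
    stop("at least two groups are required")
  if (is.null(names(valuesByGroup)) || any(!nzchar(names(valuesByGroup))))
    stop("groups must be named")
  if (any(lengths(valuesByGroup) < 2L))
    stop("every group needs >= 2 values")
  x <- unlist(valuesByGroup, use.names = FALSE)
  g <- factor(rep(names(valuesByGroup), lengths(valuesByGroup)),
              levels = names(valuesByGroup))
  if (method == "kruskal_dunn") {
    if (length(unique(x)) == 1L) {
      warning("all values identical across groups; H undefined, reporting 0")
      omnibus <- list(statistic = 0, p_value = 1)
    } else {
      kw <- stats::kruskal.test(x, g)
      omnibus <- list(statistic = unname(kw$statistic),
                      p_value = kw$p.value)
    }
    pw <- dunnTest(x, g, adjust = adjust)
  } else {
    fit <- stats::aov(x ~ g)
    ss <- summary(fit)[[1L]]
    omnibus <- list(statistic = ss[["F value"]][1L],
                    p_value = ss[["Pr(>F)"]][1L])
    tk <- stats::TukeyHSD(fit)$g
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- data.frame(group1 = vapply(nm, `[`, "", 2L),
                     group2 = vapply(nm, `[`, "", 1L),
                     statistic = tk[, "diff"], p_adj = tk[, "p adj"],
                     row.names = NULL)
  }
  list(method = method, statistic = omnibus$statistic,
       p_value = omnibus$p_value, pairwise = pw)
}

# Dunn's test on midranks with tie correction; two-sided normal p-values.
dunnTest <- function(x, g, adjust = "bonferroni") {
  n <- length(x)
  r <- rank(x)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tieCorr
  levs <- levels(g)
  combs <- utils::combn(levs, 2L)
  rbar <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  z <- p <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    a <- combs[1L, k]; b <- combs[2L, k]
    se <- sqrt(sigma2 * (1 / ng[[a]] + 1 / ng[[b]]))
    z[k] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = combs[1L, ], group2 = combs[2L, ], statistic = z,
             p_adj = stats::p.adjust(p, method = adjust), row.names = NULL)
}
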