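# Statistical chain: one-sample Kolmogorov-Smirnov normality check,
# Mann-Whitney U independence check, Kruskal-Wallis omnibus with pairwise
# post-hoc comparisons (uncorrected), at a fixed 0.05 significance level.

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests the sample against a normal distribution with the sample's own
#' mean and SD. The plain KS p-value is reported by default; because the
#' reference parameters are estimated from the same sample this p-value is
#' conservative, and `lilliefors = TRUE` switches to the Lilliefors
#' correction.
#'
#' @param x numeric sample, `n >= 3`, non-constant.
#' @param lilliefors use the Lilliefors-corrected test (default FALSE).
#' @return list with `test`, `statistic`, `p`, `n`.
#' @export
normalityTest <- function(x, lilliefors = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("normality test requires n >= 3")
  if (stats::sd(x) == 0) stop("zero-variance sample")
  if (lilliefors) {
    ht <- nortest::lillie.test(x)
    list(test = "lilliefors", statistic = unname(ht$statistic),
         p = ht$p.value, n = length(x))
  } else {
    ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    list(test = "kolmogorov-smirnov", statistic = unname(ht$statistic),
         p = ht$p.value, n = length(x))
  }
}

#' Two-sided Mann-Whitney U test
#'
#' Wilcoxon rank-sum test with tie correction (normal approximation),
#' two-sided.
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @return list with `test`, `statistic` (U for the first sample), `p`,
#'   `n` (both group sizes).
#' @export
independenceTest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need n >= 2")
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(test = "mann-whitney-u", statistic = unname(ht$statistic),
       p = ht$p.value, n = c(length(a), length(b)))
}

# Dunn-style pairwise z tests on the pooled ranks, tie-corrected.
.dunnPairwise <- function(groups) {
  k <- length(groups)
  x <- unlist(groups)
  g <- rep(seq_len(k), lengths(groups))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  meanR <- tapply(r, g, mean)
  n <- lengths(groups)
  p <- matrix(1, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[i] + 1 / n[j]))
    z <- (meanR[i] - meanR[j]) / se
    p[i, j] <- p[j, i] <- 2 * stats::pnorm(-abs(z))
  }
  p
}

# Tukey HSD on the rank-transformed data.
.tukeyPairwise <- function(groups) {
  k <- length(groups)
  x <- rank(unlist(groups))
  g <- factor(rep(seq_len(k), lengths(groups)))
  tk <- stats::TukeyHSD(stats::aov(x ~ g))$g
  p <- matrix(1, k, k)
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (m in seq_along(pairs)) {
    i <- as.integer(pairs[[m]][1]); j <- as.integer(pairs[[m]][2])
    p[i, j] <- p[j, i] <- tk[m, "p adj"]
  }
  p
}

#' Kruskal-Wallis omnibus test with pairwise post-hoc comparisons
#'
#' The H statistic is referred to its chi-square distribution. The
#' post-hoc is, by default, Dunn-style pairwise z comparisons on the pooled
#' ranks with no multiplicity correction; `posthoc = "tukey"` switches to
#' Tukey HSD on the rank-transformed data. With exactly two groups the
#' comparison is routed to [independenceTest()].
#'
#' @param groups list of `>= 3` numeric samples (each `n >= 2`).
#' @param posthoc `"dunn"` (default) or `"tukey"`.
#' @return list with `test`, `statistic` (H), `df`, `p`, `n` (group
#'   sizes), `posthoc`, and `pairwise` (symmetric p-value matrix with unit
#'   diagonal).
#' @export
kruskalPosthoc <- function(groups, posthoc = c("dunn", "tukey")) {
  posthoc <- match.arg(posthoc)
  if (!is.list(groups)) stop("groups must be a list of samples")
  if (length(groups) == 2)
    return(independenceTest(groups[[1]], groups[[2]]))
  if (length(groups) < 3) stop("need at least 3 groups (or 2 for the U test)")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  nm <- if (!is.null(names(groups))) names(groups) else
    paste0("group", seq_along(groups))
  if (length(unique(unlist(groups))) == 1L) {
    # fully tied data: no rank variation, H is 0 by convention
    pw <- matrix(1, length(groups), length(groups), dimnames = list(nm, nm))
    return(list(test = "kruskal-wallis", statistic = 0,
                df = length(groups) - 1, p = 1, n = lengths(groups),
                posthoc = posthoc, pairwise = pw))
  }
  ht <- stats::kruskal.test(groups)
  pw <- if (posthoc == "dunn") .dunnPairwise(groups) else
    .tukeyPairwise(groups)
  dimnames(pw) <- list(nm, nm)
  list(test = "kruskal-wallis", statistic = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value,
       n = lengths(groups), posthoc = posthoc, pairwise = pw)
}
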