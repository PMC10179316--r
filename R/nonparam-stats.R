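## Nonparametric battery: Friedman RM ANOVA on ranks + SNK, Wilcoxon signed
## rank, Mann-Whitney, Kruskal-Wallis + Dunn. All statistics are computed on
## (mid-)ranks with the standard tie corrections, so every test is invariant
## under strictly monotone transforms of the data.

## sum over tie groups of (t^3 - t); groups taken from the rank partition so
## floating-point-distinct but rank-tied values are handled consistently
.tieTerm <- function(v) {
  t <- table(rank(v))
  sum(t^3 - t)
}

#' Friedman repeated-measures ANOVA on ranks
#'
#' Ranks the \eqn{k} conditions within each of the \eqn{n} subjects (ties get
#' mid-ranks) and computes the tie-corrected chi-square statistic
#' \deqn{\chi^2 = \frac{12 \sum_j (R_j - n(k+1)/2)^2}
#'   {nk(k+1) - \frac{1}{k-1}\sum_i \sum_g (t_{ig}^3 - t_{ig})}}
#' referred to the \eqn{\chi^2_{k-1}} distribution. Complete blocks are
#' required. When every subject ranks all conditions identically the
#' statistic attains its maximum \eqn{n\,k(k+1)... }; when all cells are
#' tied the statistic is 0 and \eqn{p = 1}.
#'
#' @param block_matrix numeric matrix, subjects x conditions, no missing
#'   cells.
#' @return An object of class \code{"htest"} with the chi-square statistic,
#'   degrees of freedom, p-value and the condition rank sums in
#'   \code{$rank_sums}.
#' @export
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 4, 6), c(0, 5, 9))  # identical orderings
#' friedmanRanks(m)$statistic   # 6.0 for n = 3, k = 3
friedmanRanks <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (any(is.na(m))) stop("complete blocks required: no missing cells")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 3) stop("need n >= 2 subjects and k >= 3 conditions")
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  denom <- n * k * (k + 1) - sum(apply(m, 1, .tieTerm)) / (k - 1)
  stat <- if (num == 0) 0 else num / denom
  p <- if (num == 0) 1 else pchisq(stat, df = k - 1, lower.tail = FALSE)
  structure(list(
    statistic = c("Friedman chi-square" = unname(stat)),
    parameter = c(df = k - 1), p.value = p,
    rank_sums = Rj, n = n,
    method = "Friedman repeated-measures ANOVA on ranks",
    data.name = deparse(substitute(block_matrix))),
    class = "htest")
}

#' Student-Newman-Keuls post hoc on condition rank sums
#'
#' Orders the condition rank sums of a complete-block design and applies the
#' classic SNK stepdown: for a pair spanning \eqn{p} ordered conditions the
#' studentized-range statistic \eqn{q = |R_a - R_b| / \sqrt{nk(k+1)/12}} is
#' compared against \eqn{q_{1-\alpha}(p, \infty)}; a non-significant span
#' blocks all comparisons nested inside it.
#'
#' @param block_matrix subjects x conditions matrix.
#' @param alpha familywise level of the stepdown (default 0.05).
#' @return data.frame with one row per pair: conditions, span, \code{q},
#'   critical value, p-value (from the studentized range distribution),
#'   \code{blocked} and \code{significant}.
#' @export
snkPosthocRanks <- function(block_matrix, alpha = 0.05) {
  m <- as.matrix(block_matrix)
  n <- nrow(m)
  k <- ncol(m)
  if (k < 3) stop("SNK post hoc needs k >= 3 conditions")
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(k))
  r <- t(apply(m, 1, rank))
  Rj <- sort(colSums(r), decreasing = TRUE)
  se <- sqrt(n * k * (k + 1) / 12)
  ord <- names(Rj)
  res <- list()
  ## spans from widest to narrowest; record blocking
  nonsig_span <- matrix(FALSE, k, k)   # [i, j] marks a non-significant span
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      blocked <- FALSE
      ## blocked if nested inside any wider non-significant span
      for (a in seq_len(i)) for (b in j:k)
        if ((b - a) > (j - i) && nonsig_span[a, b]) blocked <- TRUE
      q <- abs(Rj[i] - Rj[j]) / se
      qcrit <- qtukey(1 - alpha, nmeans = span, df = Inf)
      pval <- ptukey(q, nmeans = span, df = Inf, lower.tail = FALSE)
      sig <- !blocked && q >= qcrit
      if (!sig) nonsig_span[i, j] <- TRUE
      res[[length(res) + 1]] <- data.frame(
        cond_a = ord[i], cond_b = ord[j], span = span, q = unname(q),
        q_crit = qcrit, p = unname(pval), blocked = blocked,
        significant = sig, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Ranks the absolute differences (zeros dropped, mid-ranks for ties) and
#' sums the ranks of the positive differences (statistic \eqn{W}). For
#' \eqn{n \le 25} the exact null distribution is computed by convolution over
#' the (mid-)ranks — identical to the classical signed-rank distribution when
#' untied, and still exact under ties; above that, a normal approximation
#' with tie and continuity corrections.
#'
#' @param x,y paired numeric vectors of equal length (or \code{y = NULL} for
#'   a one-sample test of symmetry about 0).
#' @param alternative "two.sided", "greater" (x tends above y) or "less".
#' @return An \code{"htest"} with statistic \eqn{W}, p-value, the number of
#'   non-zero pairs in \code{$parameter}, \code{$exact}, and
#'   \code{$degenerate} (all differences zero: p = 1).
#' @export
#' @examples
#' wilcoxonSignedRank(1:10, 1:10 + 1, alternative = "less")$p.value  # 2^-10
wilcoxonSignedRank <- function(x, y = NULL,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(
      statistic = c(W = NA_real_), parameter = c(n = 0), p.value = 1,
      exact = TRUE, degenerate = TRUE,
      method = "Wilcoxon signed-rank test (degenerate: all differences zero)",
      data.name = "paired differences"), class = "htest"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  exact <- n <= 25
  if (exact) {
    ## exact null distribution of W by convolution over the (mid-)ranks;
    ## identical to the classical signed-rank distribution when untied, and
    ## exact in the presence of ties as well (doubled ranks keep it integer)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L)        # index i holds P(2W = i - 1)
    dist[1L] <- 1
    for (rr in r2)
      dist <- dist + c(rep(0, rr), dist[seq_len(total + 1L - rr)])
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * W))
    p_greater <- sum(dist[(w2 + 1L):(total + 1L)])
    p_less <- sum(dist[seq_len(w2 + 1L)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_greater, p_less)),
                greater = p_greater,
                less = p_less)
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - .tieTerm(abs(d)) / 48
    cc <- 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = 2 * pnorm(-abs(z)),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
  }
  structure(list(
    statistic = c(W = W), parameter = c(n = n), p.value = min(1, p),
    exact = exact, degenerate = FALSE,
    method = paste0("Wilcoxon signed-rank test (",
                    if (exact) "exact" else "normal approximation", ")"),
    data.name = "paired differences", alternative = alternative),
    class = "htest")
}

## Mann-Whitney U for two groups
.mannWhitney <- function(g1, g2, alternative = "two.sided") {
  n1 <- length(g1)
  n2 <- length(g2)
  r <- rank(c(g1, g2))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2       # U of group 1 (larger when g1 larger)
  ties <- any(duplicated(c(g1, g2)))
  exact <- !ties && n1 <= 50 && n2 <= 50
  if (exact) {
    p_greater <- pwilcox(U1 - 1, n1, n2, lower.tail = FALSE)
    p_less <- pwilcox(U1, n1, n2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_greater, p_less)),
                greater = p_greater, less = p_less)
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - .tieTerm(c(g1, g2)) / (N * (N - 1)))
    cc <- 0.5 * sign(U1 - mu)
    z <- (U1 - mu - cc) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = 2 * pnorm(-abs(z)),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
  }
  structure(list(
    statistic = c(U = min(U1, n1 * n2 - U1)),
    parameter = c(n1 = n1, n2 = n2), p.value = min(1, p),
    exact = exact, U1 = U1,
    method = paste0("Mann-Whitney rank-sum test (",
                    if (exact) "exact" else
                      "normal approximation with tie correction", ")"),
    data.name = "two groups", alternative = alternative),
    class = "htest")
}

## Kruskal-Wallis H with tie correction + Dunn pairwise z statistics
.kruskalDunn <- function(groups, alpha = 0.05,
                         p_adjust = c("none", "bonferroni", "sidak")) {
  p_adjust <- match.arg(p_adjust)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  v <- unlist(groups, use.names = FALSE)
  N <- length(v)
  gidx <- rep(seq_len(k), vapply(groups, length, integer(1)))
  r <- rank(v)
  nj <- tabulate(gidx, k)
  Rbar <- tapply(r, gidx, mean)
  H <- 12 / (N * (N + 1)) * sum(nj * (Rbar - (N + 1) / 2)^2)
  tie <- .tieTerm(v)
  C <- 1 - tie / (N^3 - N)
  if (C > 0) H <- H / C
  p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  ## Dunn pairwise comparisons on mean ranks
  var_base <- N * (N + 1) / 12 - tie / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  pw <- data.frame(
    group_a = names(groups)[pairs[1, ]],
    group_b = names(groups)[pairs[2, ]],
    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (c_ in seq_len(m)) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    se <- sqrt(var_base * (1 / nj[i] + 1 / nj[j]))
    pw$z[c_] <- (Rbar[i] - Rbar[j]) / se
    pw$p[c_] <- 2 * pnorm(-abs(pw$z[c_]))
  }
  pw$p_adj <- switch(p_adjust,
                     none = pw$p,
                     bonferroni = pmin(1, pw$p * m),
                     sidak = 1 - (1 - pw$p)^m)
  pw$significant <- pw$p_adj < alpha
  structure(list(
    statistic = c(H = unname(H)), parameter = c(df = k - 1),
    p.value = p, pairwise = pw, mean_ranks = Rbar,
    method = paste("Kruskal-Wallis ANOVA on ranks with Dunn's method",
                   sprintf("(p adjustment: %s)", p_adjust)),
    data.name = "groups"), class = "htest")
}

#' Rank-sum tests between groups
#'
#' Between-group battery: \code{variant = "mann_whitney"} runs the
#' Mann-Whitney rank-sum test on exactly two groups (exact null distribution
#' when there are no ties and both groups have at most 50 observations,
#' otherwise a tie-corrected normal approximation with continuity
#' correction); \code{variant = "kruskal_dunn"} runs the Kruskal-Wallis
#' ANOVA on ranks with tie correction followed by Dunn's pairwise
#' z-statistics on mean ranks (unadjusted p-values by default, Bonferroni or
#' Sidak on request).
#'
#' @param groups list of numeric vectors (named if you want named pairs).
#' @param variant "mann_whitney" or "kruskal_dunn".
#' @param alternative for Mann-Whitney: "two.sided", "greater", "less".
#' @param alpha significance level for the Dunn pairwise table.
#' @param p_adjust multiplicity adjustment for Dunn p-values.
#' @return An \code{"htest"}; for \code{kruskal_dunn} the element
#'   \code{$pairwise} holds the Dunn table.
#' @export
#' @examples
#' ranksumTests(list(1:3, 4:6), "mann_whitney")$p.value  # 0.1
ranksumTests <- function(groups, variant = c("mann_whitney", "kruskal_dunn"),
                         alternative = "two.sided", alpha = 0.05,
                         p_adjust = "none") {
  variant <- match.arg(variant)
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of at least two numeric vectors")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("empty group")
  if (variant == "mann_whitney") {
    if (length(groups) != 2)
      stop("mann_whitney requires exactly two groups")
    .mannWhitney(groups[[1]], groups[[2]], alternative = alternative)
  } else {
    .kruskalDunn(groups, alpha = alpha, p_adjust = p_adjust)
  }
}
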