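test_that("Friedman statistic matches the closed form and base R", {
  ## identical orderings, n = 3, k = 3: rank sums (3, 6, 9), chi-square 6
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(0, 5, 9))
  res <- friedmanRanks(m)
  expect_equal(unname(res$statistic), 6)
  expect_equal(unname(res$parameter), 2)
  expect_equal(unname(res$rank_sums), c(3, 6, 9))

  ## all cells equal: statistic 0, p = 1 (tie correction saturates)
  res0 <- friedmanRanks(matrix(5, 4, 3))
  expect_equal(unname(res0$statistic), 0)
  expect_equal(res0$p.value, 1)

  ## agreement with stats::friedman.test on random data, with and without ties
  set.seed(5)
  for (i in 1:5) {
    x <- matrix(rnorm(60), 15, 4)
    if (i > 3) x <- round(x, 1)            # induce ties
    ours <- friedmanRanks(x)
    ref <- friedman.test(x)
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }

  expect_error(friedmanRanks(matrix(c(1, NA, 3, 4, 5, 6), 2, 3)), "complete")
  expect_error(friedmanRanks(matrix(1:4, 2, 2)), "k >= 3")
})

test_that("SNK stepdown separates a shifted condition and only it", {
  set.seed(8)
  n <- 20
  m <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  ## identical conditions: nothing significant
  none <- snkPosthocRanks(m)
  expect_false(any(none$significant))

  ## one condition shifted far up: significant against all others,
  ## the others mutually not
  m2 <- m
  m2[, "c"] <- m2[, "c"] + 100
  tab <- snkPosthocRanks(m2)
  with_c <- tab$cond_a == "c" | tab$cond_b == "c"
  expect_true(all(tab$significant[with_c]))
  expect_false(any(tab$significant[!with_c]))

  ## critical values agree with tabulated studentized-range quantiles
  expect_equal(unique(tab$q_crit[tab$span == 2]), 2.772, tolerance = 1e-3)
  expect_equal(unique(tab$q_crit[tab$span == 3]), 3.314, tolerance = 1e-3)
  expect_equal(unique(tab$q_crit[tab$span == 4]), 3.633, tolerance = 1e-3)

  expect_error(snkPosthocRanks(m[, 1:2]), "k >= 3")
})

test_that("Wilcoxon signed-rank matches brute-force enumeration", {
  ## constant positive shift: the one-sided p is the single most extreme
  ## of the 2^10 equally likely sign patterns
  x <- 1:10
  res <- wilcoxonSignedRank(x, x + 1, alternative = "less")
  expect_true(res$exact)
  expect_equal(res$p.value, 2^-10)

  ## n = 1 non-zero pair: two-sided exact p = 1
  expect_equal(wilcoxonSignedRank(c(3), c(1))$p.value, 1)

  ## all differences zero: degenerate, p = 1 with flag
  deg <- wilcoxonSignedRank(1:5, 1:5)
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 1)

  ## exact p equals full enumeration for n <= 8, all alternatives
  set.seed(12)
  for (i in 1:6) {
    d <- round(rnorm(sample(4:8, 1)), 3)
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    for (alt in c("two.sided", "greater", "less")) {
      ours <- wilcoxonSignedRank(d, alternative = alt)
      expect_equal(ours$p.value, enumSignedRankP(d, alt), tolerance = 1e-12,
                   label = paste("wilcoxon", alt))
    }
  }

  ## tied data fall back to the corrected normal approximation and stay
  ## close to base R's
  set.seed(13)
  x <- round(rnorm(40), 1)
  y <- round(rnorm(40), 1)
  ours <- wilcoxonSignedRank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_false(ours$exact)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
})

test_that("Mann-Whitney matches enumeration and handles separation", {
  ## complete separation at n1 = n2 = 3: U = 0, exact two-sided p = 0.1
  res <- ranksumTests(list(1:3, 4:6), "mann_whitney")
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 0.1)

  ## exact p equals full enumeration for small untied samples
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1))
    for (alt in c("two.sided", "greater", "less")) {
      ours <- ranksumTests(list(x, y), "mann_whitney", alternative = alt)
      expect_equal(ours$p.value, enumMannWhitneyP(x, y, alt),
                   tolerance = 1e-12, label = paste("mw", alt))
    }
  }

  ## tie-corrected approximation against base R
  set.seed(22)
  x <- round(rnorm(30), 1)
  y <- round(rnorm(25, 0.3), 1)
  ours <- ranksumTests(list(x, y), "mann_whitney")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)

  expect_error(ranksumTests(list(1:3, 2:4, 3:5), "mann_whitney"),
               "exactly two")
  expect_error(ranksumTests(list(1:3, numeric(0)), "mann_whitney"), "empty")
})

test_that("Kruskal-Wallis + Dunn flag exactly the shifted group", {
  ## identical groups: H ~ 0 and no significant Dunn pairs
  g <- list(a = rep(1:5, 4), b = rep(1:5, 4), c = rep(1:5, 4))
  res0 <- ranksumTests(g, "kruskal_dunn")
  expect_equal(unname(res0$statistic), 0, tolerance = 1e-12)
  expect_false(any(res0$pairwise$significant))

  ## H and p agree with stats::kruskal.test (tie-corrected)
  set.seed(30)
  gs <- list(a = round(rnorm(20), 1), b = round(rnorm(20, 0.4), 1),
             c = round(rnorm(20), 1))
  ours <- ranksumTests(gs, "kruskal_dunn")
  ref <- kruskal.test(gs)
  expect_equal(unname(ours$statistic), unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)

  ## one strongly shifted group: Dunn flags only its two pairs
  set.seed(31)
  gshift <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20) + 50)
  dn <- ranksumTests(gshift, "kruskal_dunn")$pairwise
  with_c <- dn$group_a == "c" | dn$group_b == "c"
  expect_true(all(dn$significant[with_c]))
  expect_false(any(dn$significant[!with_c]))

  ## Bonferroni adjustment only scales the p-values
  dn_b <- ranksumTests(gshift, "kruskal_dunn", p_adjust = "bonferroni")
  expect_equal(dn_b$pairwise$p_adj, pmin(1, dn$p * 3))
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(40)
  f <- function(v) log(v + 1) * 3 + 2          # strictly increasing
  x <- matrix(rexp(48), 12, 4)
  expect_equal(friedmanRanks(x)$p.value, friedmanRanks(f(x))$p.value)
  a <- rexp(15)
  b <- rexp(12)
  cc <- rexp(10)
  expect_equal(ranksumTests(list(a, b), "mann_whitney")$p.value,
               ranksumTests(list(f(a), f(b)), "mann_whitney")$p.value)
  expect_equal(
    unname(ranksumTests(list(a, b, cc), "kruskal_dunn")$statistic),
    unname(ranksumTests(list(f(a), f(b), f(cc)), "kruskal_dunn")$statistic))
  d <- rnorm(14)
  e <- d + rnorm(14)
  g <- function(v) atan(v) * 5                 # monotone, order-preserving
  expect_equal(wilcoxonSignedRank(sign(d - e))$p.value,
               wilcoxonSignedRank(sign(g(d) - g(e)))$p.value)
})
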