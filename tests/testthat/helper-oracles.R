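## Independent oracles used to cross-check the package's implementations.
## These deliberately use brute force / first principles, never the code
## paths they validate.

## Exact Wilcoxon signed-rank p by enumerating all 2^n sign patterns.
## Assumes no zero differences and no ties in |d|.
enumSignedRankP <- function(d, alternative = "two.sided") {
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_ge, p_le)),
         greater = p_ge,
         less = p_le)
}

## Exact Mann-Whitney p by enumerating all choose(n1+n2, n1) group
## assignments of the pooled ranks. Assumes no ties.
enumMannWhitneyP <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  U_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_ge <- mean(U_all >= U_obs)
  p_le <- mean(U_all <= U_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_ge, p_le)),
         greater = p_ge,
         less = p_le)
}

## Logistic regression by hand-rolled Newton-Raphson (IRLS).
newtonLogistic <- function(X, y, tol = 1e-10, maxit = 50) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * w)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(info)))
  list(coef = beta, se = se)
}

## Truth-table re-evaluation of the classification rule set: every rule is
## evaluated as a predicate and precedence applied explicitly, independent of
## the package's decision-order implementation.
truthTableClassify <- function(m_AW, m_NREM, m_REM) {
  r_NA <- m_NREM / m_AW
  r_RA <- m_REM / m_AW
  r_RN <- m_REM / m_NREM
  rems <- r_RA > 2 & r_RN > 2
  nrem <- r_NA > 1.25
  wake <- r_NA < 0.75
  sub <- ifelse(rems, "REMS-active",
         ifelse(nrem & r_RN > 0.5, "nonREMS/REMS-max",
         ifelse(nrem, "nonREMS-max",
         ifelse(wake & r_RA > 0.75 & r_RA < 2, "wake/REMS-max",
         ifelse(wake, "wake-max", "none")))))
  cat_ <- ifelse(rems | nrem, "sleep-active",
          ifelse(!rems & !nrem & wake, "wake-active", "state-indifferent"))
  data.frame(category = cat_, subtype = sub, stringsAsFactors = FALSE)
}

## Tiny helper: build a FluorescenceTrace list from a matrix (frames x units).
tracesFromMatrix <- function(m, frame_rate = 10) {
  out <- lapply(seq_len(ncol(m)), function(j)
    FluorescenceTrace(m[, j], unit_id = sprintf("u%02d", j),
                      frame_rate = frame_rate))
  names(out) <- vapply(out, unitId, character(1))
  out
}

## Profile row from explicit state means (for classifier tests).
profileFromMeans <- function(m_AW, m_QW, m_NREM, m_REM, unit_id = "u1") {
  data.frame(unit_id = unit_id, m_AW = m_AW, m_QW = m_QW, m_NREM = m_NREM,
             m_REM = m_REM, r_NA = m_NREM / m_AW, r_RA = m_REM / m_AW,
             r_RN = m_REM / m_NREM, stringsAsFactors = FALSE)
}
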