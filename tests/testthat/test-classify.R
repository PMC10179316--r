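test_that("published group-mean profiles map to their named subtypes", {
  ## the five reported group-mean activity vectors (AW, QW, NREM, REM)
  cases <- list(
    list(m = c(1.04, 1.86, 2.54, 2.76), subtype = "nonREMS/REMS-max",
         category = "sleep-active"),
    list(m = c(0.87, 1.33, 1.90, 0.61), subtype = "nonREMS-max",
         category = "sleep-active"),
    list(m = c(0.60, 1.31, 1.08, 3.47), subtype = "REMS-active",
         category = "sleep-active"),
    list(m = c(2.96, 1.75, 0.82, 0.60), subtype = "wake-max",
         category = "wake-active"),
    list(m = c(2.62, 1.71, 0.76, 2.50), subtype = "wake/REMS-max",
         category = "wake-active"))
  for (cs in cases) {
    prof <- profileFromMeans(cs$m[1], cs$m[2], cs$m[3], cs$m[4])
    call <- classifyNeurons(prof)
    expect_equal(call$category, cs$category)
    expect_equal(call$subtype, cs$subtype)
  }

  ## flat profile is state-indifferent with no subtype or grade
  flat <- classifyNeurons(profileFromMeans(1, 1, 1, 1))
  expect_equal(flat$category, "state-indifferent")
  expect_equal(flat$subtype, "none")
  expect_equal(flat$grade, "none")
  expect_true(flat$si_band_ok)
})

test_that("profiles average per state and expose the three ratios", {
  ## epochs: AW = [1, 3], NREM = [4], REM = [2]
  tr <- list(FluorescenceTrace(rep(c(1, 3, 4, 2), each = 100), unit_id = "u1"))
  h <- Hypnogram(c("AW", "AW", "NREM", "REM"))
  sem <- epochMatrix(tr, h)
  prof <- stateActivityProfile(sem)
  expect_equal(prof$m_AW, 2)
  expect_equal(prof$m_NREM, 4)
  expect_equal(prof$m_REM, 2)
  expect_true(is.na(prof$m_QW))
  expect_equal(prof$r_NA, 2)
  expect_equal(prof$r_RA, 1)
  expect_equal(prof$r_RN, 0.5)
  expect_equal(prof$n_AW, 2)

  ## constant unit: all means equal, all ratios 1
  trc <- list(FluorescenceTrace(rep(1, 400), unit_id = "c1"))
  pc <- stateActivityProfile(epochMatrix(trc, h))
  expect_equal(unlist(pc[, c("r_NA", "r_RA", "r_RN")]),
               c(r_NA = 1, r_RA = 1, r_RN = 1))

  ## a unit without REM epochs is reported unclassifiable
  h_norem <- Hypnogram(c("AW", "QW", "NREM", "NREM"))
  expect_message(
    p2 <- stateActivityProfile(epochMatrix(trc, h_norem)),
    "unclassifiable")
  expect_false(p2$classifiable)
  expect_true(is.na(p2$r_RA))
})

test_that("calls are scale-free and partition every classifiable unit", {
  set.seed(7)
  n <- 400
  prof <- data.frame(unit_id = sprintf("u%04d", 1:n),
                     m_AW = exp(rnorm(n)), m_QW = exp(rnorm(n)),
                     m_NREM = exp(rnorm(n)), m_REM = exp(rnorm(n)))
  prof$r_NA <- prof$m_NREM / prof$m_AW
  prof$r_RA <- prof$m_REM / prof$m_AW
  prof$r_RN <- prof$m_REM / prof$m_NREM
  calls <- suppressMessages(classifyNeurons(prof))
  expect_true(all(!is.na(calls$category)))
  expect_true(all(calls$category %in%
    c("sleep-active", "wake-active", "state-indifferent")))

  ## scaling all means of a unit by c > 0 leaves the call unchanged
  prof2 <- prof
  for (col in c("m_AW", "m_QW", "m_NREM", "m_REM"))
    prof2[[col]] <- prof2[[col]] * 7.3
  calls2 <- suppressMessages(classifyNeurons(prof2))
  expect_identical(calls$category, calls2$category)
  expect_identical(calls$subtype, calls2$subtype)
  expect_identical(calls$grade, calls2$grade)

  ## the default cuts are the +/-25 percent band boundaries
  th <- classifierThresholds()
  expect_equal(th$sleep_cut, 2 - th$wake_cut)
})

test_that("decision order agrees with a truth-table oracle on 10k profiles", {
  set.seed(99)
  n <- 10000
  m_AW <- exp(rnorm(n, 0, 0.8))
  m_NREM <- exp(rnorm(n, 0, 0.8))
  m_REM <- exp(rnorm(n, 0, 0.8))
  oracle <- truthTableClassify(m_AW, m_NREM, m_REM)
  prof <- data.frame(unit_id = sprintf("u%05d", 1:n),
                     m_AW = m_AW, m_QW = m_AW, m_NREM = m_NREM, m_REM = m_REM,
                     r_NA = m_NREM / m_AW, r_RA = m_REM / m_AW,
                     r_RN = m_REM / m_NREM)
  calls <- suppressMessages(suppressWarnings(classifyNeurons(prof)))
  expect_identical(calls$category, oracle$category)
  sub <- ifelse(calls$category == "state-indifferent", "none", calls$subtype)
  expect_identical(sub, oracle$subtype)
})

test_that("strength grades follow the fold-change bands", {
  ## nonREM sleep-active: NREM/AW fold change minus one
  p_weak <- profileFromMeans(1, 1, 1.4, 1.0)
  expect_equal(gradeStrength(p_weak, "nonREMS/REMS-max"), "weak")
  p_strong <- profileFromMeans(1, 1, 2.5, 2.0)
  expect_equal(gradeStrength(p_strong, "nonREMS/REMS-max"), "strong")
  p_mod <- profileFromMeans(1, 1, 1.8, 1.2)
  expect_equal(gradeStrength(p_mod, "nonREMS-max"), "moderate")

  ## wake-max: smaller of AW/NREM and AW/REM, minus one
  p_wm <- profileFromMeans(2, 1.5, 0.8, 0.9)
  expect_equal(gradeStrength(p_wm, "wake-max"), "strong")  # 2/0.9 - 1 = 1.22
  p_wm2 <- profileFromMeans(2, 1.5, 0.8, 1.5)
  expect_equal(gradeStrength(p_wm2, "wake-max"), "weak")   # 2/1.5 - 1 = 0.33

  ## REMS-active: smaller of REM/AW and REM/NREM, minus one
  p_ra <- profileFromMeans(0.6, 1.3, 1.08, 3.47)
  expect_equal(gradeStrength(p_ra, "REMS-active"), "strong")

  ## an effect below the weak band is flagged as a contract violation
  p_bad <- profileFromMeans(1, 1, 1.1, 1)
  expect_warning(g <- gradeStrength(p_bad, "nonREMS-max"), "contract")
  expect_equal(g, "none")
})

test_that("logistic validation recovers coefficients and flags separation", {
  ## noisy membership generated from a known logistic law
  set.seed(31)
  n <- 200
  r_NA <- exp(rnorm(n, 0, 0.7))
  y <- rbinom(n, 1, plogis(2 - 3 * r_NA)) == 1   # low ratio -> wake-active
  prof <- data.frame(unit_id = sprintf("u%03d", 1:n), r_NA = r_NA)
  calls <- data.frame(unit_id = prof$unit_id,
                      category = ifelse(y, "wake-active", "sleep-active"),
                      subtype = ifelse(y, "wake-max", "nonREMS-max"))
  res <- logisticValidation(prof, calls, "wake-active")
  expect_false(res$separated)
  expect_lt(res$coefficients["r_NA", "Estimate"], 0)
  expect_lt(res$coefficients["r_NA", "Pr(>|z|)"], 0.05)

  ## agreement with an independent Newton-Raphson solver
  oracle <- newtonLogistic(matrix(r_NA, ncol = 1), as.numeric(y))
  expect_equal(unname(res$coefficients[, "Estimate"]), oracle$coef,
               tolerance = 1e-6)
  expect_equal(unname(res$coefficients[, "Std. Error"]), oracle$se,
               tolerance = 1e-6)

  ## permuted labels: small coefficients, roughly uniform p-values
  set.seed(77)
  ps <- replicate(120, {
    yp <- sample(y)
    cp <- calls
    cp$category <- ifelse(yp, "wake-active", "sleep-active")
    logisticValidation(prof, cp, "wake-active")$
      coefficients["r_NA", "Pr(>|z|)"]
  })
  expect_gt(mean(ps < 0.05), 0.0)   # not degenerate
  expect_lt(mean(ps < 0.05), 0.15)  # near the nominal 5 percent
  expect_gt(mean(ps > 0.5), 0.3)

  ## two units per class, one per side: perfect separation is flagged
  prof2 <- data.frame(unit_id = c("a", "b", "c", "d"),
                      r_NA = c(0.2, 0.3, 1.8, 2.0))
  calls2 <- data.frame(unit_id = prof2$unit_id,
                       category = c("wake-active", "wake-active",
                                    "sleep-active", "sleep-active"),
                       subtype = c("wake-max", "wake-max",
                                   "nonREMS-max", "nonREMS-max"))
  res2 <- logisticValidation(prof2, calls2, "wake-active")
  expect_true(res2$separated)

  ## single-class membership is rejected
  calls3 <- calls2
  calls3$category <- "wake-active"
  expect_error(logisticValidation(prof2, calls3, "wake-active"),
               "single class")
})
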