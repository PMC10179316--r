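test_that("semi-Markov hypnogram respects structure, duration and seeds", {
  cfg <- simConfig()

  ## absorbing state: all weight on AW self-transition
  tw <- cfg@transitionWeights
  tw["AW", ] <- 0
  tw["AW", "AW"] <- 1
  cfg_abs <- simConfig(transitionWeights = tw)
  h_abs <- simulateHypnogram(cfg_abs, 1200, seed = 1)
  expect_true(all(epochStates(h_abs) == "AW"))

  ## structural constraints of the default architecture over several seeds
  for (s in 1:3) {
    h <- simulateHypnogram(cfg, 3600, seed = s)
    expect_equal(nEpochs(h), 360)
    st <- epochStates(h)
    expect_setequal(unique(st), sleepStates())
    ## REM never entered from AW (only from NREM)
    expect_false(any(st[-1] == "REM" & head(st, -1) == "AW"))
    ## AW never goes straight to sleep: transitions out of AW hit QW
    after_aw <- st[-1][head(st, -1) == "AW"]
    expect_true(all(after_aw %in% c("AW", "QW")))
    ## at least one full AW -> QW -> NREM -> REM cycle in an hour
    runs <- rle(st)$values
    cyc <- FALSE
    if (length(runs) >= 4)
      for (i in seq_len(length(runs) - 3))
        if (all(runs[i:(i + 3)] == c("AW", "QW", "NREM", "REM"))) cyc <- TRUE
    expect_true(cyc)
  }

  ## determinism and error cases
  expect_identical(epochStates(simulateHypnogram(cfg, 1800, seed = 9)),
                   epochStates(simulateHypnogram(cfg, 1800, seed = 9)))
  expect_error(simulateHypnogram(cfg, 5), "shorter than one epoch")
  tw_bad <- cfg@transitionWeights
  tw_bad["QW", "AW"] <- 0.9                       # row no longer sums to 1
  expect_error(simConfig(transitionWeights = tw_bad), "sum to 1")
})

test_that("homeostatic pressure is bounded and monotone within bouts", {
  cfg <- simConfig()
  h <- simulateHypnogram(cfg, 7200, seed = 11)
  p <- computePressure(h, cfg)
  expect_true(all(p >= 0 & p <= 1))
  wake <- epochStates(h) %in% c("AW", "QW")
  dp <- diff(p)
  expect_true(all(dp[wake[-1]] >= 0))    # non-decreasing during wake
  expect_true(all(dp[!wake[-1]] <= 0))   # non-increasing during sleep
})

test_that("deprivation protocol builds pressure and rebound architecture", {
  cfg <- simConfig()
  sd <- simulateSdProtocol(cfg, seed = 7)
  seg <- segments(sd$timeline)
  st <- epochStates(sd$hypnogram)
  start_s <- epochStart(sd$hypnogram)

  ## imaged SD windows are exactly the last 10 min of each hour
  for (h in paste0("SD_h", 1:3)) {
    rows <- seg[seg$label == h, ]
    expect_equal(nrow(rows), 2)
    img <- rows[rows$imaged, ]
    expect_equal(img$end_s - img$start_s, 600)
    expect_equal(img$end_s, max(rows$end_s))
  }

  ## SD segments contain no sleep except flagged one-epoch attempts
  in_sd <- start_s >= 3600 & start_s < 3600 + 3 * 3600
  sleep_in_sd <- in_sd & st %in% c("NREM", "REM")
  expect_true(all(sleep_in_sd == (in_sd & sd$sleep_attempt)))
  expect_false(any(st[sleep_in_sd] == "REM"))
  att <- which(sd$sleep_attempt)
  att <- att[att < 360 + 3 * 360]                # not the final SD epoch
  expect_true(all(st[att + 1] == "AW"))          # attempts terminated

  ## pressure accumulates monotonically across deprivation hours
  p <- sd$pressure
  p_at <- function(t) p[max(which(start_s < t))]
  expect_gt(p_at(3600 + 3 * 3600), p_at(3600 + 3600))

  ## recovery favours NREM relative to baseline
  base_nrem <- mean(st[start_s < 3600] == "NREM")
  rec_nrem <- mean(st[start_s >= 3600 + 3 * 3600] == "NREM")
  expect_gt(rec_nrem, base_nrem)

  ## zero-drive limit: infinite wake tau freezes pressure during SD
  cfg_inf <- simConfig(pressureTauWakeS = Inf, sdAttemptRate = 0)
  sd_inf <- simulateSdProtocol(cfg_inf, seed = 7)
  st_i <- epochStates(sd_inf$hypnogram)
  start_i <- epochStart(sd_inf$hypnogram)
  in_sd_i <- start_i >= 3600 & start_i < 3600 + 3 * 3600
  expect_equal(diff(range(sd_inf$pressure[in_sd_i])), 0)
})

test_that("unit fluorescence reflects state-dependent rates and pressure", {
  cfg <- simConfig(noiseSd = 0)

  ## silent unit: zero rate and zero noise give an identically zero trace
  pr <- cfg@phenotypeRates
  pr["state-indifferent", ] <- 0
  cfg0 <- simConfig(noiseSd = 0, phenotypeRates = pr)
  h <- simulateHypnogram(cfg0, 600, seed = 2)
  u0 <- simulateUnit("state-indifferent", h, NULL, cfg0, seed = 2)
  expect_true(all(traceValues(u0$trace) == 0))

  ## wake-max unit: epoch-mean activity higher in AW than NREM
  cfgq <- simConfig(noiseSd = 0.01)
  hq <- simulateHypnogram(cfgq, 3600, seed = 6)
  uw <- simulateUnit("wake-max", hq, NULL, cfgq, seed = 6)
  em <- alignAndEpoch(uw$trace, hq)
  st <- epochStates(hq)[seq_along(em)]
  expect_gt(mean(em[st == "AW"]), mean(em[st == "NREM"]))

  ## pressure gain boosts sleep-active firing
  p_hi <- rep(1, nEpochs(hq))
  p_lo <- rep(0, nEpochs(hq))
  u_hi <- simulateUnit("nonREMS/REMS-max", hq, p_hi, cfgq, seed = 8)
  u_lo <- simulateUnit("nonREMS/REMS-max", hq, p_lo, cfgq, seed = 8)
  expect_gt(sum(u_hi$spike_counts), sum(u_lo$spike_counts) * 1.5)

  ## unknown phenotype rejected
  expect_error(simulateUnit("astrocyte", hq, NULL, cfgq), "unknown phenotype")
})

test_that("empirical spike rates converge to the configured rates", {
  cfg <- simConfig()
  h <- simulateHypnogram(cfg, 7200, seed = 13)
  st <- epochStates(h)
  u <- simulateUnit("nonREMS/REMS-max", h, NULL, cfg, seed = 13)
  counts <- u$spike_counts
  fpe <- 100
  for (s in sleepStates()) {
    t_occ <- sum(st == s) * 10
    if (t_occ < 600) next
    frames <- which(rep(st, each = fpe) == s)
    lam_hat <- sum(counts[frames]) / t_occ
    lam <- cfg@phenotypeRates["nonREMS/REMS-max", s]
    se <- sqrt(lam / t_occ)
    expect_lt(abs(lam_hat - lam), 3 * se)
  }
})

test_that("identical config and seed reproduce sessions exactly", {
  cfg <- simConfig()
  s1 <- simulateSession(cfg, n_units = 3, duration_s = 1200, seed = 21,
                        with_eeg = TRUE)
  s2 <- simulateSession(cfg, n_units = 3, duration_s = 1200, seed = 21,
                        with_eeg = TRUE)
  expect_identical(epochStates(s1$hypnogram), epochStates(s2$hypnogram))
  expect_identical(lapply(s1$traces, traceValues),
                   lapply(s2$traces, traceValues))
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("synthetic EEG/EMG carries the state signatures", {
  cfg <- simConfig()
  h <- simulateHypnogram(cfg, 1800, seed = 4)
  p <- computePressure(h, cfg)
  sig <- simulateEegEmg(h, p, cfg, seed = 4)
  st <- epochStates(h)
  spe <- sig$fs * 10
  rms <- function(i, x) sqrt(mean(x[(i - 1) * spe + seq_len(spe)]^2))
  emg_aw <- vapply(which(st == "AW"), rms, numeric(1), x = sig$emg)
  emg_nrem <- vapply(which(st == "NREM"), rms, numeric(1), x = sig$emg)
  expect_gt(mean(emg_aw), mean(emg_nrem))

  ## REM epochs are theta-dominant
  rem_idx <- which(st == "REM")
  td <- vapply(rem_idx, function(i) {
    seg <- sig$eeg[(i - 1) * spe + seq_len(spe)]
    vlpoCalcium:::.bandPower(seg, sig$fs, 6, 9) /
      vlpoCalcium:::.bandPower(seg, sig$fs, 2, 4)
  }, numeric(1))
  expect_true(all(td > 1))
})
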