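#' Simulate a spontaneous sleep-wake hypnogram
#'
#' Draws a semi-Markov state sequence: bout durations are exponential with
#' state-specific means (floored at one epoch and quantised to whole epochs),
#' successors are drawn from the per-state transition weights. Under the
#' default weights wake-to-sleep transitions pass through QW and REM is
#' entered only from NREM, as in mouse light-phase sleep.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param duration_s session duration in seconds (>= one epoch).
#' @param seed integer random seed; defaults to \code{cfg@seed}.
#' @param start_state state of the first bout.
#' @return A \linkS4class{Hypnogram} covering \code{duration_s}.
#' @export
#' @examples
#' h <- simulateHypnogram(simConfig(), 3600, seed = 1)
#' table(epochStates(h))
simulateHypnogram <- function(cfg, duration_s, seed = cfg@seed,
                              start_state = "AW") {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  if (duration_s < cfg@epochS)
    stop("duration_s is shorter than one epoch")
  n_target <- floor(duration_s / cfg@epochS)
  set.seed(as.integer(seed))
  state <- start_state
  out <- character(0)
  while (length(out) < n_target) {
    bout <- max(cfg@epochS, rexp(1, rate = 1 / cfg@meanBoutS[state]))
    n_ep <- max(1L, as.integer(round(bout / cfg@epochS)))
    out <- c(out, rep(state, n_ep))
    state <- sample(.STATES, 1L, prob = cfg@transitionWeights[state, ])
  }
  Hypnogram(out[seq_len(n_target)], epoch_s = cfg@epochS)
}

#' Homeostatic pressure along a hypnogram
#'
#' Integrates the Process-S-like two-time-constant model over the epochs of a
#' hypnogram: during wake (AW/QW) pressure relaxes toward 1 with time
#' constant \code{pressureTauWakeS}, during sleep (NREM/REM) it decays toward
#' 0 with \code{pressureTauSleepS}. The exact exponential update per epoch is
#' used, so \eqn{0 \le P \le 1} always, \eqn{P} is non-decreasing during
#' sustained wake and non-increasing during sleep.
#'
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param cfg a \linkS4class{SimConfig}.
#' @param p0 initial pressure; defaults to \code{cfg@pressureInit}.
#' @return Numeric vector of pressure at the END of each epoch.
#' @export
computePressure <- function(hypnogram, cfg, p0 = cfg@pressureInit) {
  st <- epochStates(hypnogram)
  dt <- epochDuration(hypnogram)
  aw <- exp(-dt / cfg@pressureTauWakeS)
  as_ <- exp(-dt / cfg@pressureTauSleepS)
  p <- numeric(length(st))
  cur <- p0
  wake <- st %in% .WAKE_STATES
  for (i in seq_along(st)) {
    cur <- if (wake[i]) 1 - (1 - cur) * aw else cur * as_
    p[i] <- cur
  }
  p
}

## wake-only epoch sequence for enforced wakefulness. Default is pure AW
## (handling keeps the animal in active wake), so deprivation wake epochs are
## state-matched to baseline AW; set p_aw_to_qw > 0 for AW/QW alternation.
.simulateEnforcedWake <- function(n_epochs, p_aw_to_qw = 0,
                                  p_qw_to_aw = 0.45) {
  st <- character(n_epochs)
  cur <- "AW"
  for (i in seq_len(n_epochs)) {
    st[i] <- cur
    cur <- if (cur == "AW") {
      if (p_aw_to_qw > 0 && runif(1) < p_aw_to_qw) "QW" else "AW"
    } else {
      if (runif(1) < p_qw_to_aw) "AW" else "QW"
    }
  }
  st
}

#' Simulate a sleep-deprivation/recovery protocol
#'
#' Builds a full session: a baseline segment of spontaneous cycling, three
#' hours of enforced wakefulness (AW/QW alternation with optional brief
#' one-epoch NREM "sleep attempts" whose probability grows with pressure,
#' each terminated by a forced AW epoch), and a recovery segment in which
#' sleep is favoured (NREM bouts lengthened and wake bouts shortened in
#' proportion to the accumulated pressure). Imaging during the deprivation
#' hours covers exactly the last 10 minutes of each hour; baseline and
#' recovery are imaged throughout. Pressure accumulates during enforced wake
#' and discharges during recovery sleep.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param seed integer random seed.
#' @param baseline_s baseline duration (s); at least 45 min by default.
#' @param sd_hours number of enforced-wake hours.
#' @param recovery_s recovery duration (s).
#' @param sd_qw_prob per-epoch probability of slipping from AW into QW during
#'   enforced wakefulness. The default 0 keeps deprivation wake in active
#'   waking, so deprivation-hour activity is state-matched to baseline AW.
#' @return A list with elements \code{timeline}
#'   (\linkS4class{SessionTimeline}), \code{hypnogram}
#'   (\linkS4class{Hypnogram} for the whole session) and \code{pressure}
#'   (numeric, per epoch).
#' @export
#' @examples
#' sd <- simulateSdProtocol(simConfig(), seed = 7)
#' segments(sd$timeline)
simulateSdProtocol <- function(cfg, seed = cfg@seed, baseline_s = 3600,
                               sd_hours = 3, recovery_s = 3600,
                               sd_qw_prob = 0) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  if (baseline_s < 2700)
    stop("baseline_s must be at least 45 min of spontaneous cycling")
  ep <- cfg@epochS
  base <- simulateHypnogram(cfg, baseline_s, seed = seed)
  set.seed(as.integer(seed) + 1L)

  states <- epochStates(base)
  pressure <- computePressure(base, cfg)
  p_cur <- tail(pressure, 1)
  aw_fac <- exp(-ep / cfg@pressureTauWakeS)
  sl_fac <- exp(-ep / cfg@pressureTauSleepS)

  ## enforced wakefulness, epoch by epoch, with pressure-scaled sleep attempts
  n_sd_ep <- as.integer(sd_hours * 3600 / ep)
  sd_states <- .simulateEnforcedWake(n_sd_ep, p_aw_to_qw = sd_qw_prob)
  attempt <- rep(FALSE, n_sd_ep)
  p_sd <- numeric(n_sd_ep)
  i <- 1L
  while (i <= n_sd_ep) {
    if (i > 1L && !attempt[i - 1L] && runif(1) < cfg@sdAttemptRate * p_cur) {
      sd_states[i] <- "NREM"           # brief sleep attempt
      attempt[i] <- TRUE
      if (i < n_sd_ep) sd_states[i + 1L] <- "AW"  # terminated by handling
    }
    p_cur <- if (sd_states[i] %in% .WAKE_STATES)
      1 - (1 - p_cur) * aw_fac else p_cur * sl_fac
    p_sd[i] <- p_cur
    i <- i + 1L
  }

  ## recovery: sleep-biased architecture scaled by pressure at recovery onset
  rec_cfg <- cfg
  rec_cfg@meanBoutS["NREM"] <- cfg@meanBoutS["NREM"] * (1 + p_cur)
  rec_cfg@meanBoutS["AW"] <- max(ep + 1, cfg@meanBoutS["AW"] / (1 + p_cur))
  rec_cfg@meanBoutS["QW"] <- max(ep + 1, cfg@meanBoutS["QW"] / (1 + p_cur))
  rec <- simulateHypnogram(rec_cfg, recovery_s,
                           seed = as.integer(seed) + 2L, start_state = "NREM")
  p_rec <- computePressure(rec, cfg, p0 = p_cur)

  all_states <- c(states, sd_states, epochStates(rec))
  hyp <- Hypnogram(all_states, epoch_s = ep)
  pressure_all <- c(pressure, p_sd, p_rec)

  sd_start <- baseline_s
  seg <- data.frame(label = "baseline", start_s = 0, end_s = baseline_s,
                    imaged = TRUE)
  for (h in seq_len(sd_hours)) {
    h0 <- sd_start + (h - 1) * 3600
    seg <- rbind(seg,
      data.frame(label = paste0("SD_h", h),
                 start_s = c(h0, h0 + 3000), end_s = c(h0 + 3000, h0 + 3600),
                 imaged = c(FALSE, TRUE)))
  }
  rec_start <- sd_start + sd_hours * 3600
  seg <- rbind(seg, data.frame(label = "recovery", start_s = rec_start,
                               end_s = rec_start + recovery_s, imaged = TRUE))
  timeline <- SessionTimeline(
    segments = seg,
    pressure = data.frame(time_s = epochStart(hyp), P = pressure_all))
  list(timeline = timeline, hypnogram = hyp, pressure = pressure_all,
       sleep_attempt = c(rep(FALSE, nEpochs(base)), attempt,
                         rep(FALSE, nEpochs(rec))))
}
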