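## Single-unit fluorescence synthesis.

## Convolve an event train with the double-exponential kernel
## h(t) = (exp(-t/tau_d) - exp(-t/tau_r)) / peak, peak-normalised to 1.
## Each exponential is applied as an exact recursive (AR(1)) filter.
.kernelConvolve <- function(events, frame_rate, rise_s, decay_s) {
  dt <- 1 / frame_rate
  a_d <- exp(-dt / decay_s)
  a_r <- exp(-dt / rise_s)
  y_d <- as.numeric(stats::filter(events, a_d, method = "recursive"))
  y_r <- as.numeric(stats::filter(events, a_r, method = "recursive"))
  t_peak <- log(decay_s / rise_s) / (1 / rise_s - 1 / decay_s)
  peak <- exp(-t_peak / decay_s) - exp(-t_peak / rise_s)
  (y_d - y_r) / peak
}

## Running lower-percentile baseline; evaluated on a coarse grid (every
## `stride` frames) and linearly interpolated, which is standard practice for
## slow F0 estimates.
.runningPercentile <- function(x, window, prob, stride = 10L) {
  n <- length(x)
  half <- window %/% 2L
  centers <- unique(c(seq(1L, n, by = stride), n))
  vals <- vapply(centers, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    quantile(x[lo:hi], probs = prob, names = FALSE, type = 7)
  }, numeric(1))
  approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Simulate the fluorescence trace of one unit
#'
#' Spikes are drawn as an inhomogeneous Poisson process whose rate is the
#' phenotype's state-dependent rate \eqn{\lambda(\mathrm{state}(t))} times a
#' pressure gain: \eqn{g(t) = 1 + \mathrm{pressureGain}\cdot P(t)} for
#' sleep-active phenotypes, a mild suppression
#' \eqn{g(t) = 1 - \mathrm{wakeSuppressGain}\cdot P(t)} for wake-active
#' phenotypes (reproducing the reported decline of wake-active activity once
#' pressure is high), and 1 for state-indifferent units. The event train is
#' convolved with a peak-normalised double-exponential calcium kernel and
#' scaled by \code{eventAmplitude}; Gaussian frame noise is added on top of a
#' resting fluorescence of 1. \eqn{\Delta F/F_0} is then formed against a
#' lower-percentile baseline \eqn{F_0} (session-global by default, running
#' window optional).
#'
#' @param phenotype one of \code{phenotypeLevels()}.
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param pressure per-epoch pressure values (as from
#'   \code{\link{computePressure}}), or \code{NULL} for no pressure
#'   modulation.
#' @param cfg a \linkS4class{SimConfig}.
#' @param seed integer random seed.
#' @param unit_id,animal_id,genotype_tag identifiers stored on the trace.
#' @return A list with \code{trace} (a \linkS4class{FluorescenceTrace} of
#'   per-frame \eqn{\Delta F/F_0}) and \code{spike_frames} (integer frame
#'   indices of the generated events, the ground-truth spike train).
#' @export
#' @examples
#' cfg <- simConfig()
#' h <- simulateHypnogram(cfg, 600, seed = 2)
#' u <- simulateUnit("wake-max", h, NULL, cfg, seed = 2)
#' length(traceValues(u$trace))
simulateUnit <- function(phenotype, hypnogram, pressure, cfg, seed = cfg@seed,
                         unit_id = "unit", animal_id = "animal",
                         genotype_tag = "VGAT") {
  stopifnot(is(cfg, "SimConfig"), is(hypnogram, "Hypnogram"))
  if (!phenotype %in% rownames(cfg@phenotypeRates))
    stop("unknown phenotype: ", phenotype)
  fpe <- as.integer(round(cfg@frameRate * cfg@epochS))
  n_ep <- nEpochs(hypnogram)
  st <- epochStates(hypnogram)
  lam_ep <- cfg@phenotypeRates[phenotype, st]       # events/s per epoch
  if (!is.null(pressure)) {
    stopifnot(length(pressure) == n_ep)
    categ <- .categoryOf(phenotype)
    if (categ == "sleep-active")
      lam_ep <- lam_ep * (1 + cfg@pressureGain * pressure)
    else if (categ == "wake-active")
      lam_ep <- lam_ep * (1 - cfg@wakeSuppressGain * pressure)
  }
  lam_frame <- rep(lam_ep, each = fpe) / cfg@frameRate  # events/frame
  set.seed(as.integer(seed))
  events <- rpois(length(lam_frame), lam_frame)
  signal <- cfg@eventAmplitude *
    .kernelConvolve(events, cfg@frameRate, cfg@kernelRiseS, cfg@kernelDecayS)
  f <- 1 + signal +
    if (cfg@noiseSd > 0) rnorm(length(signal), sd = cfg@noiseSd) else 0
  f0 <- if (is.infinite(cfg@baselineWindowS)) {
    quantile(f, probs = cfg@baselinePercentile, names = FALSE, type = 7)
  } else {
    window <- as.integer(round(cfg@baselineWindowS * cfg@frameRate)) + 1L
    .runningPercentile(f, window, cfg@baselinePercentile)
  }
  f0 <- pmax(f0, 0.1)                       # guard against degenerate F0
  dff <- (f - f0) / f0
  trace <- FluorescenceTrace(dff, unit_id = unit_id, animal_id = animal_id,
                             genotype_tag = genotype_tag,
                             frame_rate = cfg@frameRate, normalized = FALSE)
  list(trace = trace, spike_frames = which(events > 0),
       spike_counts = events)
}

#' Simulate a complete imaging session
#'
#' Convenience wrapper generating a hypnogram (spontaneous) or a full
#' sleep-deprivation protocol, a population of units with known phenotypes,
#' and optionally EEG/EMG signals.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param n_units number of units; phenotypes are drawn from
#'   \code{phenotype_probs}. Ignored when \code{phenotypes} is given.
#' @param phenotypes explicit character vector of per-unit phenotypes.
#' @param paradigm "spontaneous" or "sd".
#' @param duration_s session length for the spontaneous paradigm.
#' @param seed integer random seed.
#' @param phenotype_probs named sampling weights over
#'   \code{phenotypeLevels()}; the default mirrors the mixture reported for
#'   GABAergic preoptic populations (roughly half sleep-active).
#' @param with_eeg also synthesise EEG/EMG.
#' @param animal_id,genotype_tag identifiers stored on all traces.
#' @return A list: \code{hypnogram}, \code{pressure}, \code{timeline}
#'   (\code{NULL} for spontaneous sessions), \code{traces} (list of
#'   \linkS4class{FluorescenceTrace}), \code{ground_truth} (data.frame
#'   \code{unit_id}, \code{phenotype}, \code{category}), \code{sleep_attempt}
#'   (logical per epoch, sd paradigm), and \code{eeg}/\code{emg}/\code{fs}
#'   when \code{with_eeg}.
#' @export
simulateSession <- function(cfg = simConfig(), n_units = 20,
                            phenotypes = NULL,
                            paradigm = c("spontaneous", "sd"),
                            duration_s = 3600, seed = cfg@seed,
                            phenotype_probs = c(
                              "nonREMS/REMS-max" = 0.30,
                              "nonREMS-max" = 0.08,
                              "REMS-active" = 0.10,
                              "wake-max" = 0.33,
                              "wake/REMS-max" = 0.07,
                              "state-indifferent" = 0.12),
                            with_eeg = FALSE, animal_id = "m1",
                            genotype_tag = "VGAT") {
  paradigm <- match.arg(paradigm)
  seed <- as.integer(seed)
  if (paradigm == "spontaneous") {
    hyp <- simulateHypnogram(cfg, duration_s, seed = seed)
    pressure <- computePressure(hyp, cfg)
    timeline <- NULL
    sleep_attempt <- rep(FALSE, nEpochs(hyp))
  } else {
    sd <- simulateSdProtocol(cfg, seed = seed)
    hyp <- sd$hypnogram
    pressure <- sd$pressure
    timeline <- sd$timeline
    sleep_attempt <- sd$sleep_attempt
  }
  if (is.null(phenotypes)) {
    set.seed(seed + 1000L)
    phenotypes <- sample(names(phenotype_probs), n_units, replace = TRUE,
                         prob = phenotype_probs)
  }
  n_units <- length(phenotypes)
  ids <- sprintf("u%03d", seq_len(n_units))
  traces <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    sim <- simulateUnit(phenotypes[i], hyp, pressure, cfg,
                        seed = seed + 2000L + i, unit_id = ids[i],
                        animal_id = animal_id, genotype_tag = genotype_tag)
    traces[[i]] <- sim$trace
  }
  names(traces) <- ids
  out <- list(hypnogram = hyp, pressure = pressure, timeline = timeline,
              traces = traces,
              ground_truth = data.frame(unit_id = ids,
                                        phenotype = phenotypes,
                                        category = .categoryOf(phenotypes),
                                        stringsAsFactors = FALSE),
              sleep_attempt = sleep_attempt)
  if (with_eeg) {
    sig <- simulateEegEmg(hyp, pressure, cfg, seed = seed + 9000L)
    out$eeg <- sig$eeg
    out$emg <- sig$emg
    out$fs <- sig$fs
  }
  out
}
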