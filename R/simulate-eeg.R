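#' Synthesise EEG and EMG signals for a hypnogram
#'
#' Per 10-s epoch the EEG is Gaussian background noise plus a state-specific
#' oscillation: a 2-4 Hz slow wave during NREM (its power scaled by
#' \eqn{1 + \mathrm{deltaGain}\, P} with \eqn{P} the homeostatic pressure), a
#' 6-9 Hz theta rhythm during REM, and low-amplitude broadband activity during
#' waking. The EMG is white noise whose RMS is high in AW, intermediate in QW
#' and low (atonia) in sleep.
#'
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param pressure per-epoch pressure (or \code{NULL} for none).
#' @param cfg a \linkS4class{SimConfig}; synthesis parameters come from
#'   \code{cfg@eegParams}.
#' @param seed integer random seed.
#' @return A list with \code{eeg}, \code{emg} (numeric vectors) and \code{fs}
#'   (sampling rate, Hz).
#' @export
#' @examples
#' cfg <- simConfig()
#' h <- simulateHypnogram(cfg, 300, seed = 4)
#' sig <- simulateEegEmg(h, NULL, cfg, seed = 4)
#' length(sig$eeg) / sig$fs
simulateEegEmg <- function(hypnogram, pressure, cfg, seed = cfg@seed) {
  stopifnot(is(cfg, "SimConfig"), is(hypnogram, "Hypnogram"))
  pars <- cfg@eegParams
  fs <- pars$fs
  if (fs < 100) stop("EEG sampling rate must be >= 100 Hz")
  n_ep <- nEpochs(hypnogram)
  spe <- as.integer(round(fs * epochDuration(hypnogram)))  # samples/epoch
  st <- epochStates(hypnogram)
  if (is.null(pressure)) pressure <- rep(0, n_ep)
  stopifnot(length(pressure) == n_ep)

  set.seed(as.integer(seed))
  t_ep <- seq_len(spe) / fs
  eeg <- numeric(n_ep * spe)
  emg <- numeric(n_ep * spe)
  for (i in seq_len(n_ep)) {
    idx <- (i - 1L) * spe + seq_len(spe)
    bg <- rnorm(spe, sd = pars$background_rms)
    osc <- switch(st[i],
      NREM = {
        amp <- pars$delta_rms * sqrt(2) *
          sqrt(1 + cfg@deltaGain * pressure[i])
        amp * sin(2 * pi * runif(1, 2.3, 3.7) * t_ep + runif(1, 0, 2 * pi))
      },
      REM = pars$theta_rms * sqrt(2) *
        sin(2 * pi * runif(1, 6.5, 8.5) * t_ep + runif(1, 0, 2 * pi)),
      rnorm(spe, sd = pars$wake_broadband_rms))   # AW / QW broadband
    eeg[idx] <- bg + osc
    emg[idx] <- rnorm(spe, sd = pars$emg_rms[st[i]])
  }
  list(eeg = eeg, emg = emg, fs = fs)
}
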