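#' Configuration for the synthetic session generator
#'
#' Bundles every tunable of the generator: sleep architecture (mean bout
#' durations and state transition weights of the semi-Markov hypnogram),
#' imaging readout (frame rate, GCaMP-like kernel, event amplitude, noise),
#' per-phenotype firing rates, the Process-S-like homeostatic pressure model,
#' EEG/EMG synthesis parameters and the sleep-deprivation paradigm. None of
#' these values is estimated from real recordings; the defaults describe a
#' plausible mouse light-phase session and are all configurable.
#'
#' @slot meanBoutS named numeric, mean bout duration per state (s).
#' @slot transitionWeights 4x4 matrix of successor-state probabilities
#'   (rows = current state, rows sum to 1).
#' @slot frameRate imaging frame rate (Hz).
#' @slot epochS scoring epoch duration (s); \code{frameRate * epochS} must be
#'   an integer.
#' @slot phenotypeRates matrix phenotype x state of firing rates (events/s).
#' @slot kernelRiseS,kernelDecayS rise/decay time constants (s) of the
#'   double-exponential calcium kernel.
#' @slot eventAmplitude fluorescence amplitude of a single event (peak of the
#'   unit kernel), in units of resting fluorescence.
#' @slot noiseSd standard deviation of Gaussian frame noise on fluorescence.
#' @slot baselineWindowS,baselinePercentile the \eqn{F_0} estimate used to
#'   form \eqn{\Delta F/F_0}: the given percentile of fluorescence over a
#'   running window of this length (s), or over the whole session when the
#'   window is \code{Inf} (the default; the generator simulates no slow
#'   drift, so a session-global baseline is the efficient estimator and does
#'   not track bout-scale activity).
#' @slot pressureTauWakeS,pressureTauSleepS time constants (s) of homeostatic
#'   pressure accumulation during wake and discharge during sleep.
#' @slot pressureGain multiplicative gain of firing of sleep-active
#'   phenotypes: \eqn{g(t) = 1 + \mathrm{gain}\, P(t)}.
#' @slot wakeSuppressGain mild pressure-linked suppression of wake-active
#'   firing, \eqn{g(t) = 1 - \mathrm{gain}\, P(t)} (0 disables; must not
#'   exceed 1).
#' @slot pressureInit pressure at session start.
#' @slot deltaGain scaling of NREM delta-band EEG power by pressure:
#'   power scales with \eqn{1 + \mathrm{deltaGain}\, P}.
#' @slot sdAttemptRate per-epoch probability (scaled by \eqn{P}) of a brief
#'   one-epoch NREM "sleep attempt" during enforced wakefulness.
#' @slot eegParams list of EEG/EMG synthesis parameters: \code{fs} (Hz),
#'   \code{emg_rms} (named per state), \code{delta_rms}, \code{theta_rms},
#'   \code{background_rms}, \code{wake_broadband_rms}.
#' @slot seed default random seed used when a caller does not supply one.
#'
#' @seealso \code{\link{simConfig}} for the constructor with defaults.
#' @export
setClass("SimConfig",
  representation(
    meanBoutS = "numeric", transitionWeights = "matrix",
    frameRate = "numeric", epochS = "numeric",
    phenotypeRates = "matrix",
    kernelRiseS = "numeric", kernelDecayS = "numeric",
    eventAmplitude = "numeric", noiseSd = "numeric",
    baselineWindowS = "numeric", baselinePercentile = "numeric",
    pressureTauWakeS = "numeric", pressureTauSleepS = "numeric",
    pressureGain = "numeric", pressureInit = "numeric",
    wakeSuppressGain = "numeric",
    deltaGain = "numeric", sdAttemptRate = "numeric",
    eegParams = "list", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@meanBoutS)), sort(.STATES)))
    msg <- c(msg, "meanBoutS must be named with the four states")
  if (any(object@meanBoutS <= object@epochS))
    msg <- c(msg, "mean_bout_s must exceed epoch_s for every state")
  tw <- object@transitionWeights
  if (!identical(rownames(tw), .STATES) || !identical(colnames(tw), .STATES))
    msg <- c(msg, "transitionWeights must be a 4x4 matrix with state dimnames")
  else {
    if (any(tw < 0)) msg <- c(msg, "transition weights must be non-negative")
    if (any(abs(rowSums(tw) - 1) > 1e-8))
      msg <- c(msg, "transition weights must sum to 1 for every state")
  }
  if (abs(object@frameRate * object@epochS -
          round(object@frameRate * object@epochS)) > 1e-9)
    msg <- c(msg, "frameRate * epochS must be an integer number of frames")
  pr <- object@phenotypeRates
  if (!identical(colnames(pr), .STATES))
    msg <- c(msg, "phenotypeRates must have the four states as columns")
  if (any(pr < 0)) msg <- c(msg, "firing rates must be non-negative")
  if (object@kernelRiseS >= object@kernelDecayS)
    msg <- c(msg, "kernelRiseS must be smaller than kernelDecayS")
  for (s in c("noiseSd", "pressureGain", "deltaGain", "sdAttemptRate",
              "wakeSuppressGain"))
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be >= 0"))
  if (object@wakeSuppressGain > 1)
    msg <- c(msg, "wakeSuppressGain must be <= 1 (firing gain must stay >= 0)")
  if (object@baselinePercentile <= 0 || object@baselinePercentile >= 1)
    msg <- c(msg, "baselinePercentile must be in (0, 1)")
  if (object@pressureInit < 0 || object@pressureInit > 1)
    msg <- c(msg, "pressureInit must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

.defaultTransitionWeights <- function() {
  tw <- matrix(0, 4, 4, dimnames = list(.STATES, .STATES))
  tw["AW", "QW"] <- 1                      # wake -> sleep passes through QW
  tw["QW", c("AW", "NREM")] <- c(0.35, 0.65)
  tw["NREM", c("AW", "QW", "REM")] <- c(0.15, 0.25, 0.60)
  tw["REM", c("AW", "QW")] <- c(0.65, 0.35)  # REM entered only from NREM
  tw
}

## Rate vectors are calibrated so that the MEASURED dF/F0 state-mean ratios
## of each phenotype land near the group-mean ratios reported for GABAergic
## preoptic populations (e.g. wake/REMS-max units show REM/AW close to 0.95
## and NREM/AW close to 0.29 after the F0 offset of the dF/F0 transform).
.defaultPhenotypeRates <- function() {
  pr <- rbind(
    "nonREMS/REMS-max"  = c(0.10, 0.18, 0.24, 0.27),
    "nonREMS-max"       = c(0.10, 0.15, 0.22, 0.07),
    "REMS-active"       = c(0.06, 0.13, 0.11, 0.35),
    "wake-max"          = c(0.40, 0.24, 0.11, 0.08),
    "wake/REMS-max"     = c(0.40, 0.26, 0.12, 0.42),
    "state-indifferent" = c(0.20, 0.20, 0.20, 0.20))
  colnames(pr) <- .STATES
  pr
}

#' Create a generator configuration
#'
#' Returns a \linkS4class{SimConfig} populated with defaults; any field can
#' be overridden by name. Defaults: exponential bouts with means AW 90 s,
#' QW 40 s, NREM 180 s, REM 60 s; 10 Hz imaging in 10-s epochs; a
#' double-exponential calcium kernel (rise 0.2 s, decay 1.8 s); sparse
#' state-dependent Poisson firing per phenotype; running 20th-percentile
#' baseline for \eqn{\Delta F/F_0} (session-global by default); Process-S
#' pressure with \eqn{\tau_{wake}} = 2 h, \eqn{\tau_{sleep}} = 1 h.
#'
#' @param ... named fields of \linkS4class{SimConfig} to override, e.g.
#'   \code{noiseSd = 0}, \code{pressureGain = 0}.
#' @return A validated \linkS4class{SimConfig}.
#' @export
#' @examples
#' cfg <- simConfig(noiseSd = 0.02)
#' cfg
simConfig <- function(...) {
  defaults <- list(
    meanBoutS = c(AW = 90, QW = 40, NREM = 180, REM = 60),
    transitionWeights = .defaultTransitionWeights(),
    frameRate = 10, epochS = 10,
    phenotypeRates = .defaultPhenotypeRates(),
    kernelRiseS = 0.2, kernelDecayS = 1.8,
    eventAmplitude = 1.5, noiseSd = 0.05,
    baselineWindowS = Inf, baselinePercentile = 0.2,
    pressureTauWakeS = 7200, pressureTauSleepS = 3600,
    pressureGain = 1.5, pressureInit = 0.25, wakeSuppressGain = 0.4,
    deltaGain = 1.0, sdAttemptRate = 0.02,
    eegParams = list(fs = 100,
                     emg_rms = c(AW = 1.0, QW = 0.45, NREM = 0.1, REM = 0.08),
                     delta_rms = 0.8, theta_rms = 0.6,
                     background_rms = 0.25, wake_broadband_rms = 0.35),
    seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown SimConfig fields: ", paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  do.call(new, c(list("SimConfig"), defaults))
}

#' @rdname simConfig
#' @param object a \code{SimConfig}.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat("  bouts (s):",
      paste(names(object@meanBoutS), object@meanBoutS, sep = "=",
            collapse = "  "), "\n")
  cat(sprintf("  imaging: %g Hz, %g-s epochs; kernel %g/%g s; amp %g; noise sd %g\n",
              object@frameRate, object@epochS, object@kernelRiseS,
              object@kernelDecayS, object@eventAmplitude, object@noiseSd))
  cat(sprintf("  pressure: tau_wake %g s, tau_sleep %g s, gain %g, delta gain %g\n",
              object@pressureTauWakeS, object@pressureTauSleepS,
              object@pressureGain, object@deltaGain))
  cat("  phenotypes:", paste(rownames(object@phenotypeRates), collapse = ", "),
      "\n")
  invisible(NULL)
})
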