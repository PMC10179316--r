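## Rule-based sleep staging and NREM delta-band power.

## Welch power spectral density: Hann-windowed segments, 50% overlap.
## Returns data.frame(freq, psd) with a one-sided density (power per Hz).
.welchPsd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nseg <- as.integer(round(seg_s * fs))
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  n <- length(x)
  if (n < nseg) stop("signal shorter than one Welch segment")
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]   # fold negative frequencies
    acc <- acc + p
  }
  data.frame(freq = (seq_len(nf) - 1L) * fs / nseg, psd = acc / length(starts))
}

## Integrate a Welch PSD over [f_lo, f_hi] (inclusive) by the trapezoid rule.
.bandPower <- function(x, fs, f_lo, f_hi, seg_s = 2, overlap = 0.5) {
  spec <- .welchPsd(x, fs, seg_s = seg_s, overlap = overlap)
  keep <- spec$freq >= f_lo - 1e-9 & spec$freq <= f_hi + 1e-9
  f <- spec$freq[keep]
  p <- spec$psd[keep]
  if (length(f) < 2) return(sum(p) * (f_hi - f_lo))
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Scoring rule thresholds
#'
#' Thresholds of the rule-based stager, calibrated to the synthetic EEG/EMG
#' generator (they are a stand-in for manual scoring and carry no claim about
#' real recordings): epochs with EMG RMS above \code{emg_high} are AW,
#' between the thresholds QW; atonic epochs are REM when the theta/delta
#' power ratio exceeds \code{theta_delta_ratio}, NREM otherwise.
#'
#' @param emg_high,emg_low EMG RMS cuts separating AW / QW / atonia.
#' @param theta_delta_ratio REM vs NREM boundary on theta(6-9 Hz) /
#'   delta(2-4 Hz) band power.
#' @param epoch_s epoch duration (s).
#' @return A named list of thresholds.
#' @export
scoringConfig <- function(emg_high = 0.7, emg_low = 0.25,
                          theta_delta_ratio = 1, epoch_s = 10) {
  stopifnot(emg_high > emg_low, emg_low > 0, theta_delta_ratio > 0)
  list(emg_high = emg_high, emg_low = emg_low,
       theta_delta_ratio = theta_delta_ratio, epoch_s = epoch_s)
}

#' Score a hypnogram from EEG and EMG
#'
#' Splits the signals into epochs and applies the threshold rules of
#' \code{\link{scoringConfig}}: per epoch it computes the EMG RMS and the
#' EEG delta (2-4 Hz) and theta (6-9 Hz) band powers (Welch periodogram,
#' 2-s Hann segments, 50% overlap), then assigns AW, QW, NREM or REM.
#'
#' @param eeg,emg numeric signals spanning the same time range.
#' @param fs sampling rate in Hz (>= 100).
#' @param scoring_cfg thresholds from \code{\link{scoringConfig}}.
#' @return A \linkS4class{Hypnogram}.
#' @export
#' @examples
#' cfg <- simConfig()
#' h <- simulateHypnogram(cfg, 300, seed = 5)
#' sig <- simulateEegEmg(h, NULL, cfg, seed = 5)
#' h2 <- scoreHypnogram(sig$eeg, sig$emg, sig$fs)
#' mean(epochStates(h2) == epochStates(h))
scoreHypnogram <- function(eeg, emg, fs, scoring_cfg = scoringConfig()) {
  if (length(eeg) != length(emg))
    stop("EEG and EMG must cover an identical time span")
  if (fs < 100) stop("sampling rate must be >= 100 Hz")
  spe <- as.integer(round(fs * scoring_cfg$epoch_s))
  n_ep <- length(eeg) %/% spe
  if (n_ep < 1) stop("signals shorter than one epoch")
  st <- character(n_ep)
  for (i in seq_len(n_ep)) {
    idx <- (i - 1L) * spe + seq_len(spe)
    emg_rms <- sqrt(mean(emg[idx]^2))
    if (emg_rms > scoring_cfg$emg_high) {
      st[i] <- "AW"
    } else if (emg_rms > scoring_cfg$emg_low) {
      st[i] <- "QW"
    } else {
      delta <- .bandPower(eeg[idx], fs, 2, 4)
      theta <- .bandPower(eeg[idx], fs, 6, 9)
      st[i] <- if (theta / delta > scoring_cfg$theta_delta_ratio)
        "REM" else "NREM"
    }
  }
  Hypnogram(st, epoch_s = scoring_cfg$epoch_s)
}

#' Delta-band power of every NREM epoch
#'
#' Integrates the Welch power spectral density over 2-4 Hz for each epoch the
#' hypnogram scores as NREM. Non-NREM epochs are absent from the output.
#'
#' @param eeg numeric EEG signal.
#' @param hypnogram a \linkS4class{Hypnogram} aligned to the EEG.
#' @param fs sampling rate (Hz).
#' @param timeline optional \linkS4class{SessionTimeline} used to label each
#'   NREM epoch with its segment.
#' @return data.frame with columns \code{epoch_index}, \code{start_s},
#'   \code{segment} (NA without a timeline) and \code{delta_power}; zero rows
#'   (with a warning) when the hypnogram has no NREM epochs.
#' @export
nremDeltaPower <- function(eeg, hypnogram, fs, timeline = NULL) {
  spe <- as.integer(round(fs * epochDuration(hypnogram)))
  n_ep <- min(nEpochs(hypnogram), length(eeg) %/% spe)
  idx_nrem <- which(epochStates(hypnogram)[seq_len(n_ep)] == "NREM")
  if (!length(idx_nrem)) {
    warning("hypnogram contains no NREM epochs")
    return(data.frame(epoch_index = integer(0), start_s = numeric(0),
                      segment = character(0), delta_power = numeric(0)))
  }
  power <- vapply(idx_nrem, function(i) {
    .bandPower(eeg[(i - 1L) * spe + seq_len(spe)], fs, 2, 4)
  }, numeric(1))
  start_s <- epochStart(hypnogram)[idx_nrem]
  segment <- rep(NA_character_, length(idx_nrem))
  if (!is.null(timeline)) {
    seg <- segments(timeline)
    for (r in seq_len(nrow(seg)))
      segment[start_s >= seg$start_s[r] & start_s < seg$end_s[r]] <-
        seg$label[r]
  }
  data.frame(epoch_index = idx_nrem, start_s = start_s, segment = segment,
             delta_power = power)
}

#' NREM delta-power rebound after sleep deprivation
#'
#' The recovery-to-baseline ratio of mean NREM delta power, in percent:
#' \eqn{100 \times \mathrm{mean}(\mathrm{recovery})/\mathrm{mean}(\mathrm{baseline})}.
#' Values above 100 indicate the slow-wave-activity rebound that marks
#' elevated homeostatic sleep pressure.
#'
#' @param delta data.frame from \code{\link{nremDeltaPower}} with a
#'   \code{segment} column.
#' @return The rebound in percent (single numeric).
#' @export
deltaRebound <- function(delta) {
  stopifnot("segment" %in% names(delta))
  base <- delta$delta_power[delta$segment == "baseline"]
  rec <- delta$delta_power[delta$segment == "recovery"]
  if (!length(base) || !length(rec))
    stop("need NREM epochs in both the baseline and the recovery segment")
  100 * mean(rec) / mean(base)
}
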