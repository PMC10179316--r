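#' Run the full classification pipeline on one session
#'
#' Chains the conditioning and classification stages: per-trace
#' normalisation, alignment and 10-s epoch downsampling against the
#' hypnogram, per-unit state-activity profiling, quality filtering (units
#' whose mean state activity falls below \code{quality_threshold} are
#' removed and logged) and ratio-threshold phenotype classification with
#' strength grading.
#'
#' The default normalisation (\code{"scale"}) divides each trace by its
#' whole-session standard deviation without centring, keeping state means
#' positive so that both the 0.5 quality cut and the ratio thresholds retain
#' their intended meaning; \code{"zscore"} (centre and scale) and
#' \code{"none"} are available.
#'
#' @param traces list of \linkS4class{FluorescenceTrace}.
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param start_offset_s acquisition-start alignment offset (s).
#' @param normalize normalisation method, see \code{\link{normalizeTrace}}.
#' @param quality_threshold quality cut, see \code{\link{qualityFilter}}.
#' @param thresholds classifier cuts from \code{\link{classifierThresholds}}.
#' @param timeline optional \linkS4class{SessionTimeline} to annotate epochs
#'   with segments.
#' @param profile_epochs epochs used for profiling (default: baseline-segment
#'   epochs when a timeline is given, otherwise all).
#' @return A list: \code{sem} (the \linkS4class{StateEpochMatrix}),
#'   \code{profiles} (all units), \code{kept}/\code{removed} (quality
#'   filter) and \code{calls} (classification of the kept units).
#' @export
#' @examples
#' cfg <- simConfig()
#' ses <- simulateSession(cfg, n_units = 4, duration_s = 1200, seed = 11)
#' res <- processSession(ses$traces, ses$hypnogram)
#' res$calls[, c("unit_id", "category", "subtype", "grade")]
processSession <- function(traces, hypnogram, start_offset_s = 0,
                           normalize = c("scale", "zscore", "none"),
                           quality_threshold = 0.5,
                           thresholds = classifierThresholds(),
                           timeline = NULL, profile_epochs = NULL) {
  normalize <- match.arg(normalize)
  traces <- lapply(traces, normalizeTrace, method = normalize)
  sem <- epochMatrix(traces, hypnogram, start_offset_s = start_offset_s,
                     timeline = timeline)
  if (is.null(profile_epochs)) {
    profile_epochs <- if (!is.null(timeline)) {
      which(colData(sem)$segment == "baseline")
    } else {
      seq_len(ncol(sem))
    }
  }
  profiles <- stateActivityProfile(sem, epochs = profile_epochs)
  qf <- qualityFilter(profiles, threshold = quality_threshold)
  calls <- classifyNeurons(qf$kept, thresholds = thresholds)
  list(sem = sem, profiles = profiles, kept = qf$kept, removed = qf$removed,
       calls = calls)
}
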