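## Trace conditioning: normalisation, epoch downsampling, quality filtering.

#' Z-score a fluorescence trace
#'
#' Standardises the whole-session trace to mean 0 and standard deviation 1.
#' \code{normalizeTrace} generalises this: \code{method = "scale"} divides by
#' the session standard deviation without centring (keeping state means
#' positive, the scale on which ratio thresholds and the 0.5 quality cut are
#' interpretable), \code{"zscore"} centres as well, \code{"none"} is the
#' identity.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param method normalisation method.
#' @return The trace with transformed values and \code{normalized = TRUE}
#'   (except for \code{"none"}).
#' @export
#' @examples
#' tr <- FluorescenceTrace(c(1, 2, 3))
#' mean(traceValues(zscoreTrace(tr)))  # 0
#' sd(traceValues(zscoreTrace(tr)))    # 1
zscoreTrace <- function(trace) normalizeTrace(trace, method = "zscore")

#' @rdname zscoreTrace
#' @export
normalizeTrace <- function(trace, method = c("scale", "zscore", "none")) {
  stopifnot(is(trace, "FluorescenceTrace"))
  method <- match.arg(method)
  if (method == "none") return(trace)
  v <- trace@values
  if (length(v) < 2)
    stop("degenerate input: need at least 2 frames to normalise")
  s <- sd(v)
  if (!is.finite(s) || s < .Machine$double.eps^0.5)
    stop("degenerate input: trace has zero variance")
  trace@values <- if (method == "zscore") (v - mean(v)) / s else v / s
  trace@normalized <- TRUE
  trace
}

#' Align a trace to the hypnogram and average into 10-s epochs
#'
#' Drops the first \code{start_offset_s} of the trace (compensating the
#' acquisition-start lag between imaging and EEG), then averages consecutive
#' blocks of \code{frame_rate * epoch_s} frames into per-epoch means. A
#' trailing partial epoch is dropped, never padded; the result is truncated
#' to the hypnogram length.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param start_offset_s alignment offset in seconds (0-10);
#'   \code{start_offset_s * frame_rate} must be integral.
#' @return Numeric vector of epoch means, of length
#'   \code{min(full trace epochs, nEpochs(hypnogram))}.
#' @export
#' @examples
#' tr <- FluorescenceTrace(c(rep(0, 100), rep(1, 100)))
#' h <- Hypnogram(c("AW", "NREM"))
#' alignAndEpoch(tr, h)   # c(0, 1)
alignAndEpoch <- function(trace, hypnogram, start_offset_s = 0) {
  stopifnot(is(trace, "FluorescenceTrace"), is(hypnogram, "Hypnogram"))
  if (start_offset_s < 0 || start_offset_s > 10)
    stop("start_offset_s must lie in [0, 10]")
  off <- start_offset_s * trace@frameRate
  if (abs(off - round(off)) > 1e-9)
    stop("start_offset_s * frame_rate must be an integral number of frames")
  off <- as.integer(round(off))
  v <- trace@values
  if (off > 0) v <- v[-seq_len(min(off, length(v)))]
  fpe <- as.integer(round(trace@frameRate * epochDuration(hypnogram)))
  n_full <- length(v) %/% fpe
  n_use <- min(n_full, nEpochs(hypnogram))
  if (n_use < 1)
    stop("no complete epoch overlaps the hypnogram after alignment")
  colMeans(matrix(v[seq_len(n_use * fpe)], nrow = fpe))
}

#' Build the epoch-by-unit activity matrix
#'
#' Applies \code{\link{alignAndEpoch}} to every trace and assembles a
#' \linkS4class{StateEpochMatrix} (units x epochs) carrying the aligned
#' hypnogram in \code{colData}. All traces are truncated to the shortest
#' common epoch count.
#'
#' @param traces list of \linkS4class{FluorescenceTrace}.
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param start_offset_s alignment offset, passed to
#'   \code{\link{alignAndEpoch}}.
#' @param timeline optional \linkS4class{SessionTimeline}; when given, each
#'   epoch is annotated with its segment label and imaged flag.
#' @return A \linkS4class{StateEpochMatrix}.
#' @export
epochMatrix <- function(traces, hypnogram, start_offset_s = 0,
                        timeline = NULL) {
  stopifnot(length(traces) > 0)
  cols <- lapply(traces, alignAndEpoch, hypnogram = hypnogram,
                 start_offset_s = start_offset_s)
  n_ep <- min(vapply(cols, length, integer(1)))
  mat <- t(vapply(cols, function(x) x[seq_len(n_ep)], numeric(n_ep)))
  ids <- unname(vapply(traces, unitId, character(1)))
  rownames(mat) <- ids
  cd <- DataFrame(epoch_index = seq_len(n_ep),
                  start_s = epochStart(hypnogram)[seq_len(n_ep)],
                  state = epochStates(hypnogram)[seq_len(n_ep)])
  if (!is.null(timeline)) {
    seg <- segments(timeline)
    lab <- rep(NA_character_, n_ep)
    img <- rep(NA, n_ep)
    for (r in seq_len(nrow(seg))) {
      in_seg <- cd$start_s >= seg$start_s[r] & cd$start_s < seg$end_s[r]
      lab[in_seg] <- seg$label[r]
      img[in_seg] <- seg$imaged[r]
    }
    cd$segment <- lab
    cd$imaged <- img
  }
  rd <- DataFrame(
    unit_id = ids,
    animal_id = unname(vapply(traces, function(t) t@animalId, character(1))),
    genotype_tag = unname(vapply(traces, function(t) t@genotypeTag,
                                 character(1))),
    normalized = unname(vapply(traces, isNormalized, logical(1))))
  se <- SummarizedExperiment(assays = list(dff = mat), colData = cd,
                             rowData = rd)
  S4Vectors::metadata(se)$epoch_s <- epochDuration(hypnogram)
  new("StateEpochMatrix", se)
}

#' Quality-filter units on their mean state activity
#'
#' A unit is removed when the mean of its per-state mean activities (over the
#' states actually present in the session) falls below \code{threshold};
#' the boundary value itself is kept (strict \code{<}). The removal list,
#' with the offending values, is returned for logging.
#'
#' @param profiles data.frame from \code{\link{stateActivityProfile}}.
#' @param threshold quality cut on the mean of per-state means (default 0.5,
#'   on the normalised activity scale).
#' @return A list with \code{kept} and \code{removed} (both subsets of
#'   \code{profiles}, with a \code{quality} column added).
#' @export
qualityFilter <- function(profiles, threshold = 0.5) {
  mcols <- paste0("m_", .STATES)
  stopifnot(all(mcols %in% names(profiles)))
  mm <- as.matrix(profiles[, mcols])
  if (all(is.na(mm)))
    stop("no states present: cannot compute quality metric")
  quality <- rowMeans(mm, na.rm = TRUE)
  profiles$quality <- quality
  drop <- !is.na(quality) & quality < threshold
  list(kept = profiles[!drop, , drop = FALSE],
       removed = profiles[drop, , drop = FALSE])
}
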