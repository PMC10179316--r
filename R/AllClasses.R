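## S4 classes for the central data objects.

#' Hypnogram of scored 10-s epochs
#'
#' Ordered sleep-wake states in contiguous, non-overlapping epochs of fixed
#' duration (10 s by convention). Epoch \eqn{i} covers
#' \eqn{[(i-1)\,\mathrm{epoch}_s,\; i\,\mathrm{epoch}_s)}.
#'
#' @slot state character vector, one entry per epoch, each one of
#'   \code{sleepStates()}.
#' @slot epochS epoch duration in seconds (default 10).
#'
#' @export
#' @examples
#' h <- Hypnogram(c("AW", "AW", "QW", "NREM", "NREM", "REM"))
#' nEpochs(h)
#' table(epochStates(h))
setClass("Hypnogram",
  representation(state = "character", epochS = "numeric"),
  prototype(state = character(0), epochS = 10))

setValidity("Hypnogram", function(object) {
  msg <- character(0)
  if (length(object@epochS) != 1L || !is.finite(object@epochS) ||
      object@epochS <= 0)
    msg <- c(msg, "epochS must be a single positive number")
  bad <- setdiff(unique(object@state), .STATES)
  if (length(bad))
    msg <- c(msg, paste0("unknown states: ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#'
#' @param state character vector of per-epoch states (subset of
#'   \code{sleepStates()}).
#' @param epoch_s epoch duration in seconds.
#' @return A \linkS4class{Hypnogram}.
#' @export
Hypnogram <- function(state, epoch_s = 10) {
  new("Hypnogram", state = as.character(state), epochS = epoch_s)
}

#' @describeIn Hypnogram number of epochs.
#' @param x,object a \code{Hypnogram}.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname Hypnogram
#' @export
setMethod("nEpochs", "Hypnogram", function(x) length(x@state))

#' @describeIn Hypnogram per-epoch state labels.
#' @export
setGeneric("epochStates", function(x) standardGeneric("epochStates"))

#' @rdname Hypnogram
#' @export
setMethod("epochStates", "Hypnogram", function(x) x@state)

#' @describeIn Hypnogram epoch start times in seconds.
#' @export
setGeneric("epochStart", function(x) standardGeneric("epochStart"))

#' @rdname Hypnogram
#' @export
setMethod("epochStart", "Hypnogram",
          function(x) (seq_along(x@state) - 1) * x@epochS)

#' @describeIn Hypnogram epoch duration in seconds.
#' @export
setGeneric("epochDuration", function(x) standardGeneric("epochDuration"))

#' @rdname Hypnogram
#' @export
setMethod("epochDuration", "Hypnogram", function(x) x@epochS)

#' @rdname Hypnogram
#' @export
setMethod("show", "Hypnogram", function(object) {
  cat("Hypnogram:", nEpochs(object), "epochs of", object@epochS, "s (",
      format(nEpochs(object) * object@epochS / 60, digits = 3), "min )\n")
  if (nEpochs(object)) {
    tab <- table(factor(object@state, levels = .STATES))
    cat("  state occupancy:",
        paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  }
  invisible(NULL)
})

#' @rdname Hypnogram
#' @param row.names,optional,... passed on as in
#'   \code{\link[base]{as.data.frame}}.
#' @export
as.data.frame.Hypnogram <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(epoch_index = seq_along(x@state),
             start_s = epochStart(x),
             state = x@state,
             stringsAsFactors = FALSE)
}

#' Session timeline with paradigm segments and homeostatic pressure
#'
#' Labels stretches of a recording session as baseline, sleep-deprivation
#' hours (SD_h1..SD_h3) or recovery, records which windows were imaged (during
#' SD only the last 10 min of each hour), and carries the homeostatic
#' pressure trace \eqn{P(t) \in [0, 1]} sampled at epoch starts.
#'
#' @slot segments data.frame with columns \code{label}, \code{start_s},
#'   \code{end_s}, \code{imaged}; rows ordered and non-overlapping.
#' @slot pressure data.frame with columns \code{time_s}, \code{P}.
#'
#' @export
setClass("SessionTimeline",
  representation(segments = "data.frame", pressure = "data.frame"))

setValidity("SessionTimeline", function(object) {
  seg <- object@segments
  msg <- character(0)
  need <- c("label", "start_s", "end_s", "imaged")
  if (!all(need %in% names(seg)))
    msg <- c(msg, "segments needs columns label, start_s, end_s, imaged")
  else {
    if (nrow(seg) > 1 && any(diff(seg$start_s) < 0))
      msg <- c(msg, "segments must be ordered by start_s")
    if (any(seg$end_s <= seg$start_s))
      msg <- c(msg, "each segment must have end_s > start_s")
    if (nrow(seg) > 1 && any(seg$start_s[-1] < seg$end_s[-nrow(seg)] - 1e-9))
      msg <- c(msg, "segments must not overlap")
    bad <- setdiff(unique(seg$label),
                   c("baseline", "SD_h1", "SD_h2", "SD_h3", "recovery"))
    if (length(bad))
      msg <- c(msg, paste0("unknown segment labels: ",
                           paste(bad, collapse = ", ")))
  }
  p <- object@pressure
  if (!all(c("time_s", "P") %in% names(p)))
    msg <- c(msg, "pressure needs columns time_s, P")
  else if (nrow(p) && (any(p$P < -1e-9) || any(p$P > 1 + 1e-9)))
    msg <- c(msg, "pressure values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SessionTimeline
#'
#' @param segments data.frame with columns \code{label} (one of baseline,
#'   SD_h1, SD_h2, SD_h3, recovery), \code{start_s}, \code{end_s},
#'   \code{imaged} (logical).
#' @param pressure data.frame with columns \code{time_s}, \code{P}.
#' @return A \linkS4class{SessionTimeline}.
#' @export
SessionTimeline <- function(segments,
                            pressure = data.frame(time_s = numeric(0),
                                                  P = numeric(0))) {
  new("SessionTimeline", segments = segments, pressure = pressure)
}

#' @describeIn SessionTimeline the segment table.
#' @param x,object a \code{SessionTimeline}.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname SessionTimeline
#' @export
setMethod("segments", "SessionTimeline", function(x) x@segments)

#' @describeIn SessionTimeline the homeostatic pressure trace.
#' @export
setGeneric("pressureSeries", function(x) standardGeneric("pressureSeries"))

#' @rdname SessionTimeline
#' @export
setMethod("pressureSeries", "SessionTimeline", function(x) x@pressure)

#' @rdname SessionTimeline
#' @export
setMethod("show", "SessionTimeline", function(object) {
  seg <- object@segments
  cat("SessionTimeline:", nrow(seg), "segments over",
      format(max(seg$end_s) / 3600, digits = 3), "h\n")
  agg <- aggregate(cbind(start_s, end_s) ~ label, data = seg,
                   FUN = function(v) v[1])
  for (lab in unique(seg$label)) {
    rows <- seg[seg$label == lab, , drop = FALSE]
    cat(sprintf("  %-9s %7.0f-%7.0f s  imaged: %s\n", lab,
                min(rows$start_s), max(rows$end_s),
                paste(unique(rows$imaged), collapse = "/")))
  }
  invisible(NULL)
})

#' Single-unit fluorescence trace
#'
#' Per-frame \eqn{\Delta F/F_0} values for one imaged unit, sampled at a
#' fixed frame rate (10 Hz by convention).
#'
#' @slot unitId unit identifier.
#' @slot animalId animal identifier.
#' @slot genotypeTag "VGAT" (GABAergic, marker-identified) or "UNID"
#'   (unidentified neurotransmitter phenotype).
#' @slot frameRate frames per second.
#' @slot values numeric vector of per-frame \eqn{\Delta F/F_0}.
#' @slot normalized whether the trace has been variance-normalised.
#'
#' @export
setClass("FluorescenceTrace",
  representation(unitId = "character", animalId = "character",
                 genotypeTag = "character", frameRate = "numeric",
                 values = "numeric", normalized = "logical"),
  prototype(unitId = "unit", animalId = "animal", genotypeTag = "VGAT",
            frameRate = 10, values = numeric(0), normalized = FALSE))

setValidity("FluorescenceTrace", function(object) {
  msg <- character(0)
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must all be finite")
  if (!object@genotypeTag %in% c("VGAT", "UNID"))
    msg <- c(msg, "genotypeTag must be 'VGAT' or 'UNID'")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorescenceTrace
#'
#' @param values numeric vector of per-frame \eqn{\Delta F/F_0}.
#' @param unit_id,animal_id identifiers.
#' @param genotype_tag "VGAT" or "UNID".
#' @param frame_rate frames per second.
#' @param normalized logical; has the trace been variance-normalised?
#' @return A \linkS4class{FluorescenceTrace}.
#' @export
FluorescenceTrace <- function(values, unit_id = "unit", animal_id = "animal",
                              genotype_tag = "VGAT", frame_rate = 10,
                              normalized = FALSE) {
  new("FluorescenceTrace", unitId = unit_id, animalId = animal_id,
      genotypeTag = genotype_tag, frameRate = frame_rate,
      values = as.numeric(values), normalized = normalized)
}

#' @describeIn FluorescenceTrace per-frame values.
#' @param x,object a \code{FluorescenceTrace}.
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname FluorescenceTrace
#' @export
setMethod("traceValues", "FluorescenceTrace", function(x) x@values)

#' @describeIn FluorescenceTrace frames per second.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname FluorescenceTrace
#' @export
setMethod("frameRate", "FluorescenceTrace", function(x) x@frameRate)

#' @describeIn FluorescenceTrace unit identifier.
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))

#' @rdname FluorescenceTrace
#' @export
setMethod("unitId", "FluorescenceTrace", function(x) x@unitId)

#' @describeIn FluorescenceTrace whether the trace is normalised.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname FluorescenceTrace
#' @export
setMethod("isNormalized", "FluorescenceTrace", function(x) x@normalized)

#' @rdname FluorescenceTrace
#' @export
setMethod("length", "FluorescenceTrace", function(x) length(x@values))

#' @rdname FluorescenceTrace
#' @export
setMethod("show", "FluorescenceTrace", function(object) {
  cat(sprintf(
    "FluorescenceTrace %s (%s, %s): %d frames @ %g Hz%s\n",
    object@unitId, object@animalId, object@genotypeTag,
    length(object@values), object@frameRate,
    if (object@normalized) ", normalised" else ""))
  invisible(NULL)
})

#' Epoch-by-unit activity matrix aligned to a hypnogram
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"dff"} holds
#' per-epoch mean \eqn{\Delta F/F_0} with units as rows and 10-s epochs as
#' columns. \code{colData} carries the aligned hypnogram (\code{epoch_index},
#' \code{start_s}, \code{state}, optionally \code{segment});
#' \code{rowData} carries \code{unit_id}, \code{animal_id},
#' \code{genotype_tag} and \code{normalized}.
#'
#' @export
setClass("StateEpochMatrix", contains = "SummarizedExperiment")

setValidity("StateEpochMatrix", function(object) {
  msg <- character(0)
  if (!"dff" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dff' is required")
  cd <- colData(object)
  if (!all(c("epoch_index", "start_s", "state") %in% names(cd)))
    msg <- c(msg, "colData needs epoch_index, start_s and state")
  else if (length(setdiff(unique(cd$state), .STATES)))
    msg <- c(msg, "colData$state contains unknown states")
  if (!all(c("unit_id") %in% names(rowData(object))))
    msg <- c(msg, "rowData needs unit_id")
  if (length(msg)) msg else TRUE
})
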