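## Plain-text interchange: traces.csv, hypnogram.csv, eeg/emg.csv,
## timeline.json, ground_truth.json. All CSV is RFC-4180, UTF-8, '.' decimal.
## Numeric values are written with 15 significant digits so a write/read
## round trip reproduces values to well below 1e-9 relative error.

.fmtNum <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

#' Read and write trace tables
#'
#' \code{writeTracesCsv} writes a list of \linkS4class{FluorescenceTrace}
#' as a CSV with one column per unit (header row of unit IDs) and one row per
#' frame; \code{readTracesCsv} reads it back. Frame rate and identifiers are
#' not stored in the CSV and are supplied on read.
#'
#' @param traces list of \linkS4class{FluorescenceTrace} (equal lengths).
#' @param path file path.
#' @return \code{readTracesCsv}: a named list of
#'   \linkS4class{FluorescenceTrace}.
#' @export
writeTracesCsv <- function(traces, path) {
  stopifnot(length(traces) > 0)
  lens <- vapply(traces, length, integer(1))
  stopifnot(length(unique(lens)) == 1)
  df <- as.data.frame(lapply(traces, function(t) .fmtNum(traceValues(t))),
                      check.names = FALSE)
  names(df) <- vapply(traces, unitId, character(1))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTracesCsv
#' @param frame_rate,animal_id,genotype_tag metadata attached to each trace
#'   on read.
#' @export
readTracesCsv <- function(path, frame_rate = 10, animal_id = "animal",
                          genotype_tag = "VGAT") {
  df <- read.csv(path, check.names = FALSE)
  out <- lapply(names(df), function(id)
    FluorescenceTrace(df[[id]], unit_id = id, animal_id = animal_id,
                      genotype_tag = genotype_tag, frame_rate = frame_rate))
  names(out) <- names(df)
  out
}

#' Read and write hypnograms
#'
#' CSV with columns \code{epoch_index}, \code{start_s}, \code{state}.
#'
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param path file path.
#' @return \code{readHypnogramCsv}: a \linkS4class{Hypnogram}.
#' @export
writeHypnogramCsv <- function(hypnogram, path) {
  write.csv(as.data.frame(hypnogram), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHypnogramCsv
#' @export
readHypnogramCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  epoch_s <- if (nrow(df) > 1) df$start_s[2] - df$start_s[1] else 10
  Hypnogram(df$state, epoch_s = epoch_s)
}

#' Read and write EEG/EMG signals
#'
#' CSV with columns \code{time_s}, \code{value}.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param path file path.
#' @return \code{readSignalCsv}: list with \code{value} and \code{fs}.
#' @export
writeSignalCsv <- function(x, fs, path) {
  df <- data.frame(time_s = .fmtNum((seq_along(x) - 1) / fs),
                   value = .fmtNum(x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSignalCsv
#' @export
readSignalCsv <- function(path) {
  df <- read.csv(path)
  fs <- if (nrow(df) > 1) 1 / (df$time_s[2] - df$time_s[1]) else NA_real_
  list(value = df$value, fs = round(fs, 6))
}

#' Read and write session timelines
#'
#' JSON with the segment table (labels, boundaries, imaged flags) and the
#' homeostatic pressure series.
#'
#' @param timeline a \linkS4class{SessionTimeline}.
#' @param path file path.
#' @return \code{readTimelineJson}: a \linkS4class{SessionTimeline}.
#' @export
writeTimelineJson <- function(timeline, path) {
  jsonlite::write_json(
    list(segments = segments(timeline), pressure = pressureSeries(timeline)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTimelineJson
#' @export
readTimelineJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  SessionTimeline(segments = as.data.frame(obj$segments),
                  pressure = as.data.frame(obj$pressure))
}

#' Read and write ground-truth phenotype assignments
#'
#' JSON mapping each simulated unit to its assigned phenotype (and category).
#'
#' @param ground_truth data.frame with \code{unit_id}, \code{phenotype},
#'   \code{category}.
#' @param path file path.
#' @return \code{readGroundTruthJson}: the data.frame.
#' @export
writeGroundTruthJson <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruthJson
#' @export
readGroundTruthJson <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write classification calls and group responses
#'
#' Deterministic writers for the two main result tables: \code{calls.csv}
#' (RFC-4180 CSV) and \code{responses.tsv} (tab-separated). Identical inputs
#' produce byte-identical files.
#'
#' @param calls data.frame from \code{\link{classifyNeurons}}.
#' @param responses data.frame from
#'   \code{\link{groupStateResponse}}\code{$responses}.
#' @param path file path.
#' @export
writeCallsCsv <- function(calls, path) {
  write.csv(calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCallsCsv
#' @export
writeResponsesTsv <- function(responses, path) {
  out <- responses
  for (col in c("mean", "sem"))
    if (col %in% names(out)) out[[col]] <- .fmtNum(out[[col]])
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a generator configuration from YAML
#'
#' Reads a YAML file whose keys mirror the fields of
#' \code{\link{simConfig}}. Scalar fields map directly; \code{meanBoutS} and
#' \code{eegParams$emg_rms} are maps keyed by state;
#' \code{transitionWeights} and \code{phenotypeRates} are maps of maps
#' (row label to column-value map), missing cells defaulting to 0.
#'
#' @param path YAML file path.
#' @return A validated \linkS4class{SimConfig}.
#' @export
readSimConfigYaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  states <- sleepStates()
  asMatrix <- function(lst, rows) {
    m <- matrix(0, length(rows), length(states),
                dimnames = list(rows, states))
    for (r in names(lst)) m[r, names(lst[[r]])] <- unlist(lst[[r]])
    m
  }
  if (!is.null(raw$meanBoutS)) raw$meanBoutS <- unlist(raw$meanBoutS)
  if (!is.null(raw$transitionWeights))
    raw$transitionWeights <- asMatrix(raw$transitionWeights, states)
  if (!is.null(raw$phenotypeRates))
    raw$phenotypeRates <- asMatrix(raw$phenotypeRates,
                                   names(raw$phenotypeRates))
  if (!is.null(raw$eegParams) && !is.null(raw$eegParams$emg_rms))
    raw$eegParams$emg_rms <- unlist(raw$eegParams$emg_rms)
  do.call(simConfig, raw)
}
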