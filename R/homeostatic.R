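## Sleep-deprivation / recovery group analysis.

#' Assign epochs to experimental conditions
#'
#' Maps every epoch of a deprivation-protocol session to one of the analysis
#' conditions: state-matched baseline conditions (baseline-AW/QW/NREM/REM),
#' the imaged 10-min window at the end of each deprivation hour (SD_h1..3;
#' wake epochs only, with NREM "sleep attempt" epochs excluded and counted
#' separately) and state-matched recovery conditions
#' (recovery-AW/NREM/REM). Epochs outside imaged windows are never used.
#'
#' @param timeline a \linkS4class{SessionTimeline}.
#' @param hypnogram the session \linkS4class{Hypnogram}.
#' @return Named list of integer epoch-index vectors, one per non-empty
#'   condition, with attribute \code{"sleep_attempts"} (count of excluded SD
#'   sleep epochs). Conditions with no epochs are omitted with a warning.
#' @export
segmentSdSession <- function(timeline, hypnogram) {
  stopifnot(is(timeline, "SessionTimeline"), is(hypnogram, "Hypnogram"))
  seg <- segments(timeline)
  st <- epochStates(hypnogram)
  start_s <- epochStart(hypnogram)
  if (max(seg$end_s) < max(start_s) + epochDuration(hypnogram) - 1e-9)
    warning("timeline does not cover the full hypnogram span")
  lab <- rep(NA_character_, length(st))
  img <- rep(FALSE, length(st))
  for (r in seq_len(nrow(seg))) {
    sel <- start_s >= seg$start_s[r] & start_s < seg$end_s[r]
    lab[sel] <- seg$label[r]
    img[sel] <- seg$imaged[r]
  }
  out <- list()
  base_states <- c("AW", "QW", "NREM", "REM")
  for (s in base_states) {
    idx <- which(lab == "baseline" & img & st == s)
    if (length(idx)) out[[paste0("baseline-", s)]] <- idx
  }
  n_attempts <- 0L
  for (h in c("SD_h1", "SD_h2", "SD_h3")) {
    if (!h %in% lab) next
    in_win <- lab == h & img
    n_attempts <- n_attempts + sum(in_win & st %in% .SLEEP_STATES)
    idx <- which(in_win & st %in% .WAKE_STATES)
    if (length(idx)) out[[h]] <- idx
  }
  for (s in c("AW", "NREM", "REM")) {
    idx <- which(lab == "recovery" & img & st == s)
    if (length(idx)) out[[paste0("recovery-", s)]] <- idx
    else if (any(lab == "recovery"))
      warning("no ", s, " epochs in the recovery segment; condition omitted")
  }
  attr(out, "sleep_attempts") <- n_attempts
  out
}

#' Group activity responses across baseline, deprivation and recovery
#'
#' For each classified unit, averages its epoch activity within every
#' condition from \code{\link{segmentSdSession}}; aggregates units by major
#' category (sleep-active / wake-active / state-indifferent) as group mean
#' +/- SEM per condition. Optionally runs the within-group statistics: a
#' Friedman RM ANOVA on ranks across the wake-sampled conditions
#' (baseline-AW, SD hours, recovery-AW) with SNK post hoc, and Wilcoxon
#' signed-rank contrasts of recovery vs baseline for state-matched NREM, REM
#' and AW.
#'
#' @param sem a \linkS4class{StateEpochMatrix} of the whole session.
#' @param calls data.frame from \code{\link{classifyNeurons}}.
#' @param condition_sets named list of epoch indices from
#'   \code{\link{segmentSdSession}}.
#' @param tests run the nonparametric battery per group.
#' @param cv_max optional instability screen: units whose coefficient of
#'   variation across baseline condition means exceeds \code{cv_max} are
#'   excluded (NULL disables; the screen is a configurable stand-in, not a
#'   published criterion).
#' @return A list of class \code{"groupResponse"}: \code{responses}
#'   (data.frame group, condition, n_units, mean, sem), \code{per_unit}
#'   (units x conditions matrix of condition means), \code{excluded}
#'   (unit ids dropped by the instability screen) and, with
#'   \code{tests = TRUE}, \code{stats} (named list per group).
#' @export
groupStateResponse <- function(sem, calls, condition_sets, tests = TRUE,
                               cv_max = NULL) {
  stopifnot(is(sem, "StateEpochMatrix"))
  mat <- assay(sem, "dff")
  missing_units <- setdiff(calls$unit_id, rownames(mat))
  if (length(missing_units))
    stop("units missing from the epoch matrix: ",
         paste(missing_units, collapse = ", "))
  conds <- names(condition_sets)
  pu <- sapply(condition_sets, function(idx)
    rowMeans(mat[calls$unit_id, idx, drop = FALSE]))
  pu <- matrix(pu, nrow = length(calls$unit_id),
               dimnames = list(calls$unit_id, conds))

  excluded <- character(0)
  if (!is.null(cv_max)) {
    base_cols <- grep("^baseline-", conds, value = TRUE)
    if (length(base_cols) >= 2) {
      bm <- pu[, base_cols, drop = FALSE]
      cv <- apply(bm, 1, function(v) sd(v) / max(mean(v), 1e-12))
      excluded <- rownames(pu)[cv > cv_max]
      if (length(excluded))
        message(length(excluded), " unit(s) excluded by the instability",
                " screen (CV > ", cv_max, ")")
    }
  }
  keep <- !calls$unit_id %in% excluded
  calls <- calls[keep, , drop = FALSE]
  pu <- pu[keep, , drop = FALSE]

  groups <- intersect(.CATEGORIES, unique(calls$category))
  resp <- do.call(rbind, lapply(groups, function(g) {
    rows <- pu[calls$category == g, , drop = FALSE]
    data.frame(group = g, condition = conds, n_units = nrow(rows),
               mean = colMeans(rows),
               sem = apply(rows, 2, sd) / sqrt(nrow(rows)),
               stringsAsFactors = FALSE)
  }))
  rownames(resp) <- NULL
  out <- list(responses = resp, per_unit = pu, excluded = excluded,
              calls = calls)
  if (tests) {
    wake_conds <- intersect(
      c("baseline-AW", "SD_h1", "SD_h2", "SD_h3", "recovery-AW"), conds)
    out$stats <- lapply(setNames(groups, groups), function(g) {
      rows <- pu[calls$category == g, , drop = FALSE]
      res <- list()
      if (nrow(rows) >= 2 && length(wake_conds) >= 3) {
        blocks <- rows[, wake_conds, drop = FALSE]
        res$friedman <- friedmanRanks(blocks)
        res$snk <- snkPosthocRanks(blocks)
      }
      for (s in c("AW", "NREM", "REM")) {
        b <- paste0("baseline-", s)
        r <- paste0("recovery-", s)
        if (all(c(b, r) %in% conds) && nrow(rows) >= 2)
          res[[paste0("wilcoxon_", s)]] <-
            wilcoxonSignedRank(rows[, r], rows[, b])
      }
      res
    })
  }
  class(out) <- "groupResponse"
  out
}

#' @export
print.groupResponse <- function(x, ...) {
  cat("Group responses across conditions\n")
  print(x$responses, digits = 3, ...)
  if (length(x$excluded))
    cat("excluded (instability):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
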