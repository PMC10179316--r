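## Ratio-threshold phenotype classification.

#' Classification thresholds
#'
#' The ratio cuts of the phenotype classifier. \code{wake_cut} (0.75) and
#' \code{sleep_cut} (1.25) are the boundaries of the +/-25 percent
#' state-indifferent band on the NREM/AW ratio; \code{rem_cut} (2.0) defines
#' REM-selective activation on both REM/AW and REM/NREM;
#' \code{rem_retention_cut} (0.5) splits nonREM sleep-active units by whether
#' REM retains at least half of the NREM activity. Grade bands are
#' fold-change-minus-one intervals: weak 0.25-0.5, moderate (0.5-1.0],
#' strong > 1.0.
#'
#' @param wake_cut,sleep_cut,rem_cut,rem_retention_cut ratio thresholds.
#' @param grade_weak,grade_moderate lower edges of the weak and moderate
#'   bands on the effect size \eqn{e} (fold change minus 1).
#' @return Named list of thresholds.
#' @export
classifierThresholds <- function(wake_cut = 0.75, sleep_cut = 1.25,
                                 rem_cut = 2.0, rem_retention_cut = 0.5,
                                 grade_weak = 0.25, grade_moderate = 0.5) {
  stopifnot(wake_cut > 0, wake_cut < 1, sleep_cut > 1, rem_cut > 1,
            grade_weak < grade_moderate)
  list(wake_cut = wake_cut, sleep_cut = sleep_cut, rem_cut = rem_cut,
       rem_retention_cut = rem_retention_cut,
       grade_weak = grade_weak, grade_moderate = grade_moderate)
}

#' Per-unit state activity profile
#'
#' Averages each unit's per-epoch activity over ALL epochs of each state and
#' derives the three classification ratios: \code{r_NA} = NREM/AW,
#' \code{r_RA} = REM/AW, \code{r_RN} = REM/NREM. Ratios are \code{NA} when a
#' state is absent or its mean is not positive; such units are excluded from
#' rules that need the missing ratio and reported via the \code{classifiable}
#' flag.
#'
#' @param sem a \linkS4class{StateEpochMatrix}.
#' @param epochs integer indices of the epochs to profile (default all);
#'   e.g. restrict to the baseline segment of a deprivation session.
#' @return data.frame with one row per unit: identifiers, per-state epoch
#'   counts \code{n_*}, per-state means \code{m_*}, the three ratios and a
#'   \code{classifiable} flag.
#' @export
stateActivityProfile <- function(sem, epochs = seq_len(ncol(sem))) {
  stopifnot(is(sem, "StateEpochMatrix"))
  mat <- assay(sem, "dff")[, epochs, drop = FALSE]
  st <- colData(sem)$state[epochs]
  rd <- as.data.frame(rowData(sem))
  prof <- data.frame(unit_id = rd$unit_id,
                     animal_id = rd$animal_id,
                     genotype_tag = rd$genotype_tag,
                     stringsAsFactors = FALSE)
  for (s in .STATES) {
    sel <- st == s
    prof[[paste0("n_", s)]] <- sum(sel)
    prof[[paste0("m_", s)]] <- if (any(sel))
      rowMeans(mat[, sel, drop = FALSE]) else NA_real_
  }
  ratio <- function(num, den) ifelse(!is.na(den) & den > 0 & !is.na(num),
                                     num / den, NA_real_)
  prof$r_NA <- ratio(prof$m_NREM, prof$m_AW)
  prof$r_RA <- ratio(prof$m_REM, prof$m_AW)
  prof$r_RN <- ratio(prof$m_REM, prof$m_NREM)
  prof$classifiable <- !is.na(prof$r_NA) & !is.na(prof$r_RA) &
    !is.na(prof$r_RN)
  if (any(!prof$classifiable))
    message(sum(!prof$classifiable),
            " unit(s) lack a state or have undefined ratios and are",
            " unclassifiable")
  rownames(prof) <- prof$unit_id
  prof
}

## Decision-order rules on one profile row. REM selectivity is tested first:
## REM-selective units can carry NREM/AW above the sleep cut and must not be
## absorbed by the nonREM rule.
.classifyOne <- function(r_NA, r_RA, r_RN, th) {
  if (is.na(r_NA) || is.na(r_RA) || is.na(r_RN))
    return(c(category = NA_character_, subtype = NA_character_))
  if (r_RA > th$rem_cut && r_RN > th$rem_cut)
    return(c(category = "sleep-active", subtype = "REMS-active"))
  if (r_NA > th$sleep_cut) {
    sub <- if (r_RN > th$rem_retention_cut) "nonREMS/REMS-max" else
      "nonREMS-max"
    return(c(category = "sleep-active", subtype = sub))
  }
  if (r_NA < th$wake_cut) {
    sub <- if (r_RA > th$wake_cut && r_RA < th$rem_cut) "wake/REMS-max" else
      "wake-max"
    return(c(category = "wake-active", subtype = sub))
  }
  c(category = "state-indifferent", subtype = "none")
}

#' Classify units into sleep-wake phenotypes
#'
#' Applies the ratio-threshold rules in fixed decision order to every row of
#' a profile table: (1) REMS-active when both REM/AW and REM/NREM exceed
#' \code{rem_cut}; (2) otherwise nonREM sleep-active when NREM/AW exceeds
#' \code{sleep_cut}, split into nonREMS/REMS-max (REM/NREM >
#' \code{rem_retention_cut}) and nonREMS-max; (3) otherwise wake-active when
#' NREM/AW is below \code{wake_cut}, split into wake/REMS-max (REM/AW
#' strictly between \code{wake_cut} and \code{rem_cut}) and wake-max;
#' (4) otherwise state-indifferent. The rules are scale-free: multiplying
#' all state means of a unit by a positive constant leaves its call
#' unchanged. Strength grades are attached via \code{\link{gradeStrength}}.
#'
#' @param profiles data.frame from \code{\link{stateActivityProfile}} (or any
#'   data.frame with columns \code{unit_id}, \code{m_*} and the ratios).
#' @param thresholds from \code{\link{classifierThresholds}}.
#' @return data.frame with columns \code{unit_id}, \code{animal_id},
#'   \code{genotype_tag} (when present), \code{category}, \code{subtype},
#'   \code{grade} and \code{si_band_ok} (for state-indifferent calls, whether
#'   all state means really lie within the +/-25 percent band of the AW
#'   mean; units parked there by the literal rules while exceeding the band
#'   are flagged \code{FALSE} and counted in a message).
#' @export
#' @examples
#' prof <- data.frame(unit_id = "u1", m_AW = 1.04, m_QW = 1.86,
#'                    m_NREM = 2.54, m_REM = 2.76)
#' prof$r_NA <- prof$m_NREM / prof$m_AW
#' prof$r_RA <- prof$m_REM / prof$m_AW
#' prof$r_RN <- prof$m_REM / prof$m_NREM
#' classifyNeurons(prof)
classifyNeurons <- function(profiles, thresholds = classifierThresholds()) {
  th <- thresholds
  n <- nrow(profiles)
  cat_ <- sub_ <- grade_ <- rep(NA_character_, n)
  band_ok <- rep(NA, n)
  for (i in seq_len(n)) {
    cl <- .classifyOne(profiles$r_NA[i], profiles$r_RA[i], profiles$r_RN[i],
                       th)
    cat_[i] <- cl[["category"]]
    sub_[i] <- cl[["subtype"]]
    if (is.na(cat_[i])) next
    if (cat_[i] == "state-indifferent") {
      grade_[i] <- "none"
      ms <- unlist(profiles[i, c("m_QW", "m_NREM", "m_REM")])
      band <- profiles$m_AW[i] * c(th$wake_cut, 2 - th$wake_cut)
      band_ok[i] <- all(is.na(ms) | (ms >= band[1] & ms <= band[2]))
    } else {
      grade_[i] <- gradeStrength(profiles[i, ], sub_[i], th)
    }
  }
  n_off <- sum(!is.na(band_ok) & !band_ok)
  if (n_off)
    message(n_off, " state-indifferent call(s) fall outside the +/-25% band",
            " (intermediate REM elevation); see si_band_ok")
  out <- data.frame(unit_id = profiles$unit_id, stringsAsFactors = FALSE)
  for (col in c("animal_id", "genotype_tag"))
    if (col %in% names(profiles)) out[[col]] <- profiles[[col]]
  out$category <- cat_
  out$subtype <- sub_
  out$grade <- grade_
  out$si_band_ok <- band_ok
  rownames(out) <- out$unit_id
  out
}

#' Grade the strength of a phenotype call
#'
#' The effect size is the fold change minus one, always expressed relative to
#' the LOWER state mean so that the printed bands (weak 25-50 percent,
#' moderate >50-100 percent, strong >100 percent) apply to activations and
#' suppressions alike: sleep-active units use NREM/AW - 1 (REMS-active units
#' the smaller of REM/AW and REM/NREM, minus 1); wake-active units use the
#' smaller of AW/NREM (and, for wake-max, AW/REM) minus 1. An effect below
#' the weak band for a classified unit indicates a rule/grade inconsistency
#' and is flagged with a warning (grade \code{"none"}).
#'
#' @param profile single-row profile (state means and ratios).
#' @param subtype the unit's subtype call.
#' @param thresholds from \code{\link{classifierThresholds}}.
#' @return One of \code{"weak"}, \code{"moderate"}, \code{"strong"},
#'   \code{"none"}.
#' @export
gradeStrength <- function(profile, subtype,
                          thresholds = classifierThresholds()) {
  th <- thresholds
  e <- switch(subtype,
    "nonREMS/REMS-max" = ,
    "nonREMS-max" = profile$r_NA - 1,
    "REMS-active" = min(profile$r_RA, profile$r_RN) - 1,
    "wake-max" = min(profile$m_AW / profile$m_NREM,
                     profile$m_AW / profile$m_REM) - 1,
    "wake/REMS-max" = profile$m_AW / profile$m_NREM - 1,
    stop("no strength grade is defined for subtype '", subtype, "'"))
  if (!is.finite(e) || e < th$grade_weak) {
    warning("effect size ", signif(e, 3), " below the weak band for a ",
            subtype, " unit (contract violation)")
    return("none")
  }
  if (e <= th$grade_moderate) "weak"
  else if (e <= 1) "moderate"
  else "strong"
}

#' Validate a classification rule by logistic regression
#'
#' Fits, by maximum likelihood, a logistic regression of rule membership on
#' the ratio(s) the rule uses, mirroring the validation step of the
#' classification procedure. Rules using two ratios are fitted jointly.
#' Perfect separation (the fitted probabilities collapse to 0/1 and the
#' coefficients are unbounded) is detected and reported rather than treated
#' as a finite estimate.
#'
#' @param profiles profile table with the ratio columns.
#' @param calls matching call table from \code{\link{classifyNeurons}}.
#' @param rule one of \code{"wake-active"}, \code{"nonREM-sleep-active"},
#'   \code{"nonREMS/REMS-max"}, \code{"wake/REMS-max"}, \code{"REMS-active"}.
#' @return A list of class \code{"logisticValidation"}: \code{rule},
#'   \code{predictors}, \code{n}, \code{coefficients} (with standard errors,
#'   Wald z and p-values), \code{separated}, \code{converged}.
#' @export
logisticValidation <- function(profiles, calls,
                               rule = c("wake-active", "nonREM-sleep-active",
                                        "nonREMS/REMS-max", "wake/REMS-max",
                                        "REMS-active")) {
  rule <- match.arg(rule)
  stopifnot(identical(profiles$unit_id, calls$unit_id))
  keep <- !is.na(calls$category)
  profiles <- profiles[keep, ]
  calls <- calls[keep, ]
  spec <- switch(rule,
    "wake-active" = list(pred = "r_NA",
                         y = calls$category == "wake-active"),
    "nonREM-sleep-active" = list(
      pred = "r_NA",
      y = calls$subtype %in% c("nonREMS/REMS-max", "nonREMS-max")),
    "nonREMS/REMS-max" = list(pred = c("r_NA", "r_RN"),
                              y = calls$subtype == "nonREMS/REMS-max"),
    "wake/REMS-max" = list(pred = c("r_NA", "r_RA"),
                           y = calls$subtype == "wake/REMS-max"),
    "REMS-active" = list(pred = c("r_RA", "r_RN"),
                         y = calls$subtype == "REMS-active"))
  dat <- profiles[, spec$pred, drop = FALSE]
  dat$y <- spec$y
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$y)) < 2)
    stop("rule membership has a single class; nothing to validate")
  if (sum(dat$y) < 2 || sum(!dat$y) < 2)
    stop("need at least 2 units per outcome class")
  fit <- suppressWarnings(
    glm(y ~ ., data = dat, family = binomial()))
  mu <- fit$fitted.values
  separated <- all(mu < 1e-6 | mu > 1 - 1e-6) ||
    any(abs(coef(fit)[-1]) > 20)
  sm <- summary(fit)$coefficients
  res <- list(rule = rule, predictors = spec$pred, n = nrow(dat),
              coefficients = sm, separated = separated,
              converged = fit$converged)
  class(res) <- "logisticValidation"
  res
}

#' @export
print.logisticValidation <- function(x, ...) {
  cat("Logistic-regression validation of rule:", x$rule, "\n")
  cat("  n =", x$n, " predictors:", paste(x$predictors, collapse = ", "),
      "\n")
  if (x$separated)
    cat("  PERFECT SEPARATION: coefficients unbounded;",
        "p-values not interpretable\n")
  printCoefmat(x$coefficients, ...)
  invisible(x)
}
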