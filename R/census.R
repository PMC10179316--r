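## Census tabulation across animals and genotypes.

.CENSUS_SUBTYPES <- c("nonREMS/REMS-max", "nonREMS-max", "REMS-active",
                      "wake-max", "wake/REMS-max", "state-indifferent")

#' Tabulate the phenotype census
#'
#' Counts units per subtype for every animal and genotype, in the layout of a
#' per-mouse census table: one row per animal plus a total row per genotype.
#' State-indifferent calls count under "state-indifferent"; unclassifiable
#' units (NA category) are excluded with a message.
#'
#' @param calls data.frame from \code{\link{classifyNeurons}} carrying
#'   \code{animal_id} and \code{genotype_tag}.
#' @return A list of class \code{"censusTable"} with \code{by_animal} (counts
#'   per animal) and \code{by_genotype} (summed counts, one row per
#'   genotype), each with a \code{total} column.
#' @export
tabulateCensus <- function(calls) {
  stopifnot(all(c("animal_id", "genotype_tag") %in% names(calls)))
  drop <- is.na(calls$category)
  if (any(drop)) {
    message(sum(drop), " unclassifiable unit(s) excluded from the census")
    calls <- calls[!drop, , drop = FALSE]
  }
  pheno <- ifelse(calls$category == "state-indifferent",
                  "state-indifferent", calls$subtype)
  if (!nrow(calls)) {
    empty <- as.data.frame(matrix(integer(0), ncol = length(.CENSUS_SUBTYPES),
                                  dimnames = list(NULL, .CENSUS_SUBTYPES)))
    empty$total <- integer(0)
    res <- list(by_animal = cbind(data.frame(animal_id = character(0),
                                             genotype_tag = character(0)),
                                  empty),
                by_genotype = cbind(data.frame(genotype_tag = character(0)),
                                    empty))
    class(res) <- "censusTable"
    return(res)
  }
  tab <- table(animal = calls$animal_id,
               subtype = factor(pheno, levels = .CENSUS_SUBTYPES))
  by_animal <- as.data.frame.matrix(tab)
  by_animal <- cbind(
    data.frame(animal_id = rownames(by_animal),
               genotype_tag = calls$genotype_tag[
                 match(rownames(by_animal), calls$animal_id)],
               stringsAsFactors = FALSE),
    by_animal)
  rownames(by_animal) <- NULL
  by_animal$total <- rowSums(by_animal[, .CENSUS_SUBTYPES])
  gt <- split(by_animal, by_animal$genotype_tag)
  by_genotype <- do.call(rbind, lapply(names(gt), function(g) {
    cbind(data.frame(genotype_tag = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(colSums(
            gt[[g]][, c(.CENSUS_SUBTYPES, "total")])), check.names = FALSE))
  }))
  rownames(by_genotype) <- NULL
  res <- list(by_animal = by_animal, by_genotype = by_genotype)
  class(res) <- "censusTable"
  res
}

#' @export
print.censusTable <- function(x, ...) {
  cat("Phenotype census\n")
  print(x$by_animal, ...)
  cat("Genotype totals\n")
  print(x$by_genotype, ...)
  invisible(x)
}

#' Census fractions at every aggregation level
#'
#' Derives from subtype counts the percentages a census report prints:
#' category shares of the total (sleep-active, wake-active,
#' state-indifferent), subtype shares of their parent group (nonREM
#' sleep-active and REMS-active within sleep-active; wake-max and
#' wake/REMS-max within wake-active) and the nonREMS/REMS-max vs nonREMS-max
#' split within the nonREM sleep-active subgroup. Counts are integer
#' arithmetic; percentages are rounded to the nearest integer for report
#' parity. Pass either a \code{"censusTable"} (fractions per genotype) or a
#' named count vector.
#'
#' @param counts named numeric with entries \code{nonREMS/REMS-max},
#'   \code{nonREMS-max}, \code{REMS-active}, \code{wake-max},
#'   \code{wake/REMS-max}, \code{state-indifferent}, or a
#'   \code{"censusTable"}.
#' @param digits rounding for the percentages (0 = report parity).
#' @return data.frame with columns \code{quantity}, \code{numerator},
#'   \code{denominator}, \code{pct} (one block per genotype when given a
#'   census table).
#' @export
#' @examples
#' cts <- c("nonREMS/REMS-max" = 96, "nonREMS-max" = 24, "REMS-active" = 32,
#'          "wake-max" = 116, "wake/REMS-max" = 16, "state-indifferent" = 19)
#' censusFractions(cts)
censusFractions <- function(counts, digits = 0) {
  if (inherits(counts, "censusTable")) {
    bg <- counts$by_genotype
    out <- do.call(rbind, lapply(seq_len(nrow(bg)), function(i) {
      v <- unlist(bg[i, .CENSUS_SUBTYPES])
      f <- censusFractions(v, digits = digits)
      cbind(data.frame(genotype_tag = bg$genotype_tag[i]), f)
    }))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(all(.CENSUS_SUBTYPES %in% names(counts)))
  nrem <- counts[["nonREMS/REMS-max"]] + counts[["nonREMS-max"]]
  sleep <- nrem + counts[["REMS-active"]]
  wake <- counts[["wake-max"]] + counts[["wake/REMS-max"]]
  total <- sleep + wake + counts[["state-indifferent"]]
  row <- function(q, num, den)
    data.frame(quantity = q, numerator = num, denominator = den,
               pct = if (den > 0) round(100 * num / den, digits) else NA_real_,
               stringsAsFactors = FALSE)
  out <- rbind(
    row("sleep-active / total", sleep, total),
    row("wake-active / total", wake, total),
    row("state-indifferent / total", counts[["state-indifferent"]], total),
    row("nonREM sleep-active / sleep-active", nrem, sleep),
    row("REMS-active / sleep-active", counts[["REMS-active"]], sleep),
    row("nonREMS/REMS-max / nonREM sleep-active",
        counts[["nonREMS/REMS-max"]], nrem),
    row("nonREMS-max / nonREM sleep-active", counts[["nonREMS-max"]], nrem),
    row("wake-max / wake-active", counts[["wake-max"]], wake),
    row("wake/REMS-max / wake-active", counts[["wake/REMS-max"]], wake))
  rownames(out) <- NULL
  out
}

#' Published census counts shipped with the package
#'
#' Reads the bundled per-animal census of preoptic units from an in-vivo
#' miniscope study (seven VGAT-Cre and three wild-type mice) and the
#' genotype-level split of the nonREM sleep-active group into its two
#' subtypes, which the per-animal table does not break out.
#'
#' @return A list with \code{by_animal} (per-animal counts; the nonREM
#'   sleep-active column is the two subtypes combined) and
#'   \code{by_genotype} (full six-subtype counts per genotype).
#' @export
#' @examples
#' counts <- referenceCensusCounts()
#' colSums(counts$by_animal[counts$by_animal$genotype_tag == "VGAT", -(1:2)])
referenceCensusCounts <- function() {
  by_animal <- read.csv(system.file("extdata", "vlpo_census_counts.csv",
                                    package = "vlpoCalcium"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  by_genotype <- read.csv(system.file("extdata",
                                      "vlpo_census_subtype_split.csv",
                                      package = "vlpoCalcium"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  list(by_animal = by_animal, by_genotype = by_genotype)
}
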