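#' Run the estimate pipeline: classify (optional), estimate, cutoff
#'
#' Orchestrates the downstream half of the workflow from already-classified
#' alignments (TSV or [ClassifiedAlignments]) or from raw alignments plus a
#' site table: per-length corrected spurious-fraction estimates for the
#' requested filter, length cutoffs for each threshold, and a small
#' human-readable summary.
#'
#' @param classified a [ClassifiedAlignments] object, or the path of a
#'   classified-alignment TSV.
#' @param filter filter applied (`"none"`, `"indel"`, `"deam"`,
#'   `"deam+indel"`).
#' @param taus spurious-fraction thresholds (default `c(0.01, 0.1)`).
#' @param baseline baseline length for fold changes (default 35).
#' @param minLen smallest cutoff considered (default 20).
#' @param outDir optional output directory; when given, writes
#'   `estimates_<filter>.tsv` and `cutoffs_<filter>.json`.
#' @return A list with `estimates` (per-bin table), `cutoffs` (one
#'   [findLengthCutoff] result per tau) and `summary` (character).
#' @export
runEstimatePipeline <- function(classified, filter = "deam+indel",
                                taus = c(0.01, 0.1), baseline = 35L,
                                minLen = 20L, outDir = NULL) {
  if (is.character(classified)) {
    if (!file.exists(classified))
      stop("classified-alignment file not found: ", classified)
    classified <- readClassified(classified)
  }
  usable <- sum(classified$class %in% c("TRUE_HOMININ", "SPURIOUS"))
  if (usable == 0) stop("no alignments of at least ", minLen,
                        " bp overlap a mutated site")
  estimates <- fractionByLength(classified, filter)
  cutoffs <- lapply(taus, function(tau)
    findLengthCutoff(classified, filter, tau, minLen = minLen,
                     baseline = baseline))
  names(cutoffs) <- sprintf("L%g%%", 100 * taus)
  summary <- c(
    sprintf("alignments classified true/spurious: %d", usable),
    sprintf("filter: %s", filter),
    vapply(seq_along(cutoffs), function(i) {
      co <- cutoffs[[i]]
      if (is.na(co$L))
        sprintf("%s: not reached", names(cutoffs)[i])
      else
        sprintf("%s = %d bp (fraction %.4f, %.0f bases vs %.0f at %d bp, fold %.2f)",
                names(cutoffs)[i], co$L, co$frac, co$basesAtL,
                co$basesAtBaseline, baseline, co$fold)
    }, character(1)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeEstimates(estimates,
                   file.path(outDir, sprintf("estimates_%s.tsv",
                                             gsub("\\+", "_", filter))))
    writeCutoffReport(cutoffs, filter,
                      file.path(outDir, sprintf("cutoffs_%s.json",
                                                gsub("\\+", "_", filter))))
    writeLines(summary, file.path(outDir, "summary.txt"))
  }
  list(estimates = estimates, cutoffs = cutoffs, summary = summary)
}

#' Run the lineage pipeline: sharing percentages and the exact test
#'
#' Applies the configured length cutoff, counts derived-allele sharing per
#' lineage class and performs the Neandertal-vs-Denisovan Fisher exact test.
#'
#' @param alns alignment records (see [alignmentRecords]), aligned to the
#'   unmutated reference, or a path readable by [readAlignments].
#' @param sites informative sites (GRanges or TSV path, see
#'   [readInformativeSites]).
#' @param minLen length cutoff applied before counting (default 35).
#' @param level confidence level for sharing intervals (default 0.90).
#' @param outDir optional output directory; writes `sharing.json`.
#' @return A list with `sharing` (per-class table), `p` (Fisher exact
#'   p-value, `NA` when either class has no observations).
#' @export
runLineagePipeline <- function(alns, sites, minLen = 35L, level = 0.90,
                               outDir = NULL) {
  if (is.character(alns)) alns <- readAlignments(alns)
  if (is.character(sites)) sites <- readInformativeSites(sites)
  sharing <- derivedSharing(alns, sites, minLen = minLen, level = level)
  nNea <- sharing$n[sharing$class == "Neandertal"]
  nDen <- sharing$n[sharing$class == "Denisovan"]
  p <- if (nNea > 0 && nDen > 0) lineageTest(sharing) else NA_real_
  if (all(sharing$n == 0))
    warning("no informative sites overlap the alignments")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    payload <- list(
      minLen = minLen,
      classes = stats::setNames(lapply(seq_len(nrow(sharing)), function(i)
        list(n = sharing$n[i], k = sharing$k[i], pct = sharing$pct[i],
             ci = c(sharing$ciLo[i], sharing$ciHi[i]))), sharing$class),
      fisher_p = p)
    jsonlite::write_json(payload, file.path(outDir, "sharing.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  list(sharing = sharing, p = p)
}
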