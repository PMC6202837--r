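#' Maximum mismatches allowed by the aligner's edit-distance rule
#'
#' Reproduces the Poisson-tail maximum-edit-distance rule used by `bwa aln`
#' with a fractional `-n` argument: for a read of length `l` the ceiling `m`
#' is the smallest integer k such that the upper tail P(X > k) of a Poisson
#' with mean `l * errorRate` falls below `tailThreshold`. The tail is formed
#' by exact cumulative summation of the Poisson mass.
#'
#' @param l integer vector of read lengths (>= 1).
#' @param errorRate assumed per-base error rate (default 0.02).
#' @param tailThreshold tail probability threshold (default 0.01, i.e.
#'   `-n 0.01`).
#' @return Integer vector of maximum allowed mismatch counts.
#' @examples
#' maxMismatches(c(20, 30, 40))  # 2, 3, 3
#' @export
maxMismatches <- function(l, errorRate = 0.02, tailThreshold = 0.01) {
  l <- as.integer(l)
  stopifnot(all(l >= 1))
  vapply(l, function(li) {
    lambda <- li * errorRate
    term <- exp(-lambda)  # P(X = 0)
    cum <- term
    k <- 0L
    while (1 - cum >= tailThreshold) {
      k <- k + 1L
      term <- term * lambda / k
      cum <- cum + term
    }
    k
  }, integer(1))
}

#' Maximum mismatch proportion M(l)
#'
#' @inheritParams maxMismatches
#' @return Numeric vector `maxMismatches(l) / l`.
#' @examples
#' maxMismatchProportion(20)  # 0.1
#' @export
maxMismatchProportion <- function(l, errorRate = 0.02, tailThreshold = 0.01) {
  maxMismatches(l, errorRate, tailThreshold) / as.integer(l)
}

#' Expected site-match probabilities for a spurious alignment
#'
#' Assuming a spuriously aligning sequence carries the maximum allowed
#' mismatch proportion `M`, the artificially mutated site matches the mutated
#' state with probability `1 - M` and each of the three remaining states with
#' probability `M / 3`.
#'
#' @param M maximum mismatch proportion in `[0, 1)`.
#' @return Named numeric vector `c(pMutated, pEachOther)`.
#' @examples
#' expectedMatchProbs(0.10)  # 0.90 and 0.0333...
#' @export
expectedMatchProbs <- function(M) {
  stopifnot(all(M >= 0), all(M < 1))
  c(pMutated = 1 - M, pEachOther = M / 3)
}

#' Misclassification-corrected true/spurious counts
#'
#' A spurious alignment shows the original reference base by chance with
#' probability at most `M / 3`, deflating the spurious count. The corrected
#' counts are
#' \deqn{N'_T = N_T - N_{\neg T} \frac{M}{3 - M}, \qquad
#'       N'_{\neg T} = \frac{N_{\neg T}}{1 - M/3},}
#' which conserve the total \eqn{N'_T + N'_{\neg T} = N_T + N_{\neg T}}
#' exactly. Negative corrected true counts (possible under heavy
#' contamination) are clamped at zero with a warning.
#'
#' @param nTrue,nSpur non-negative counts of alignments classified true and
#'   spurious.
#' @param M maximum mismatch proportion in `[0, 1)`; recycled.
#' @param warn warn when clamping occurs (default TRUE).
#' @return A data.frame with columns `nTrueCorr` and `nSpurCorr`.
#' @examples
#' correctCounts(100, 90, 0.1)
#' @export
correctCounts <- function(nTrue, nSpur, M, warn = TRUE) {
  stopifnot(all(nTrue >= 0), all(nSpur >= 0), all(M >= 0), all(M < 1))
  nTrueCorr <- nTrue - nSpur * M / (3 - M)
  nSpurCorr <- nSpur / (1 - M / 3)
  clamped <- nTrueCorr < 0
  if (any(clamped)) {
    if (warn)
      warning(sum(clamped), " corrected true count(s) were negative and ",
              "clamped at 0")
    nTrueCorr[clamped] <- 0
  }
  data.frame(nTrueCorr = nTrueCorr, nSpurCorr = nSpurCorr)
}

#' Corrected spurious-alignment fraction with binomial confidence interval
#'
#' The fraction \eqn{N'_{\neg T} / (N'_{\neg T} + N'_T)} formed from the
#' corrected counts of [correctCounts], with a Wilson score interval computed
#' at the effective sample size \eqn{N_T + N_{\neg T}}.
#'
#' @inheritParams correctCounts
#' @param level confidence level (default 0.95).
#' @return A data.frame with columns `frac`, `ciLo`, `ciHi` (all `NA` when
#'   `nTrue + nSpur == 0`).
#' @examples
#' spuriousFraction(100, 90, 0.1)
#' @export
spuriousFraction <- function(nTrue, nSpur, M, level = 0.95, warn = TRUE) {
  cc <- correctCounts(nTrue, nSpur, M, warn = warn)
  n <- nTrue + nSpur
  frac <- ifelse(n > 0, cc$nSpurCorr / (cc$nSpurCorr + cc$nTrueCorr),
                 NA_real_)
  frac <- pmin(1, pmax(0, frac))
  ci <- t(mapply(function(f, ni) {
    if (ni <= 0 || is.na(f)) c(NA_real_, NA_real_)
    else wilsonCI(f * ni, ni, level)
  }, frac, n))
  data.frame(frac = frac, ciLo = ci[, 1], ciHi = ci[, 2])
}

# subset classified alignments to TRUE/SPURIOUS rows passing a feature filter
applyAlignmentFilter <- function(classified,
                                 filter = c("none", "indel", "deam",
                                            "deam+indel")) {
  filter <- match.arg(filter)
  keep <- classified$class %in% c("TRUE_HOMININ", "SPURIOUS")
  if (filter %in% c("indel", "deam+indel"))
    keep <- keep & classified$indels == 0
  if (filter %in% c("deam", "deam+indel"))
    keep <- keep & (classified$ct5 | classified$ct3)
  classified[keep, , drop = FALSE]
}

#' Per-length-bin corrected spurious-alignment fractions
#'
#' Bins classified alignments by exact length (1-bp bins), optionally applies
#' the indel filter (drop alignments with indels), the deamination filter
#' (keep only alignments with a terminal C-to-T substitution at either end),
#' or both, and corrects each bin's counts with `M` evaluated at the bin
#' length.
#'
#' @param classified a [ClassifiedAlignments] object (or data.frame with the
#'   same columns).
#' @param filter one of `"none"`, `"indel"`, `"deam"`, `"deam+indel"`.
#' @param errorRate,tailThreshold parameters of the mismatch-ceiling rule
#'   (see [maxMismatches]).
#' @param level confidence level for the per-bin interval.
#' @return A data.frame with one row per non-empty bin: `len`, `filter`,
#'   `nTrue`, `nSpur`, `M`, `nTrueCorr`, `nSpurCorr`, `frac`, `ciLo`, `ciHi`.
#' @export
fractionByLength <- function(classified, filter = "none", errorRate = 0.02,
                             tailThreshold = 0.01, level = 0.95) {
  kept <- applyAlignmentFilter(classified, filter)
  if (!nrow(kept)) {
    return(data.frame(len = integer(0), filter = character(0),
                      nTrue = integer(0), nSpur = integer(0), M = numeric(0),
                      nTrueCorr = numeric(0), nSpurCorr = numeric(0),
                      frac = numeric(0), ciLo = numeric(0),
                      ciHi = numeric(0)))
  }
  lens <- sort(unique(kept$len))
  nTrue <- vapply(lens, function(l)
    sum(kept$len == l & kept$class == "TRUE_HOMININ"), numeric(1))
  nSpur <- vapply(lens, function(l)
    sum(kept$len == l & kept$class == "SPURIOUS"), numeric(1))
  M <- maxMismatchProportion(lens, errorRate, tailThreshold)
  cc <- correctCounts(nTrue, nSpur, M, warn = FALSE)
  sf <- spuriousFraction(nTrue, nSpur, M, level, warn = FALSE)
  data.frame(len = lens, filter = filter, nTrue = nTrue, nSpur = nSpur,
             M = M, nTrueCorr = cc$nTrueCorr, nSpurCorr = cc$nSpurCorr,
             frac = sf$frac, ciLo = sf$ciLo, ciHi = sf$ciHi)
}

#' Cumulative corrected spurious fraction for length cutoffs
#'
#' For each candidate cutoff `L`, the correction is applied per 1-bp length
#' stratum to all alignments of length `>= L`, the corrected counts are
#' summed over strata and the spurious fraction is formed from the sums.
#'
#' @inheritParams fractionByLength
#' @param minLen smallest cutoff considered (default 20).
#' @return A data.frame with columns `L`, `nTrue`, `nSpur`, `nTrueCorr`,
#'   `nSpurCorr`, `frac` (NA where no alignments remain).
#' @export
cumulativeFraction <- function(classified, filter = "deam+indel",
                               minLen = 20L, errorRate = 0.02,
                               tailThreshold = 0.01) {
  perBin <- fractionByLength(classified, filter, errorRate, tailThreshold)
  maxLen <- if (nrow(perBin)) max(perBin$len) else minLen
  Ls <- seq.int(minLen, max(minLen, maxLen))
  idx <- match(Ls, perBin$len)
  at <- function(col) ifelse(is.na(idx), 0, perBin[[col]][idx])
  revcum <- function(x) rev(cumsum(rev(x)))
  nTrue <- revcum(at("nTrue"))
  nSpur <- revcum(at("nSpur"))
  nTrueCorr <- revcum(at("nTrueCorr"))
  nSpurCorr <- revcum(at("nSpurCorr"))
  tot <- nTrueCorr + nSpurCorr
  data.frame(L = Ls, nTrue = nTrue, nSpur = nSpur, nTrueCorr = nTrueCorr,
             nSpurCorr = nSpurCorr,
             frac = ifelse(tot > 0, nSpurCorr / tot, NA_real_))
}

#' Sample-specific length cutoff L_tau
#'
#' The minimal length cutoff `L` at which the cumulative corrected spurious
#' fraction among retained alignments drops below `tau` (e.g. `L_1%` for
#' `tau = 0.01`, `L_10%` for `tau = 0.1`). Reported as `NA` ("not reached")
#' when no cutoff qualifies.
#'
#' @inheritParams cumulativeFraction
#' @param tau spurious-fraction threshold in (0, 1).
#' @param baseline baseline cutoff for the usable-bases fold change
#'   (default 35).
#' @return A list with elements `tau`, `L` (NA if not reached), `frac` (the
#'   cumulative fraction at `L`), `basesAtL`, `basesAtBaseline`, `fold`.
#' @export
findLengthCutoff <- function(classified, filter = "deam+indel", tau,
                             minLen = 20L, baseline = 35L, errorRate = 0.02,
                             tailThreshold = 0.01) {
  stopifnot(tau > 0, tau < 1)
  cum <- cumulativeFraction(classified, filter, minLen, errorRate,
                            tailThreshold)
  ok <- which(!is.na(cum$frac) & cum$frac < tau)
  if (!length(ok)) {
    return(list(tau = tau, L = NA_integer_, frac = NA_real_,
                basesAtL = NA_real_, basesAtBaseline = NA_real_,
                fold = NA_real_))
  }
  L <- cum$L[ok[1]]
  ub <- usableBasesFoldChange(classified, L, baseline, filter)
  list(tau = tau, L = L, frac = cum$frac[ok[1]], basesAtL = ub$basesAtCutoff,
       basesAtBaseline = ub$basesAtBaseline, fold = ub$fold)
}

#' Usable hominin bases recovered at a length cutoff
#'
#' Sums the lengths of TRUE-classified, filter-passing alignments at least
#' `cutoff` bp long, and the fold change relative to the same sum at the
#' baseline cutoff (35 bp by default).
#'
#' @inheritParams fractionByLength
#' @param cutoff length cutoff in bp.
#' @param baseline baseline cutoff in bp (default 35).
#' @return A list with `basesAtCutoff`, `basesAtBaseline`, `fold` (NA when
#'   the baseline sum is zero).
#' @export
usableBasesFoldChange <- function(classified, cutoff, baseline = 35L,
                                  filter = "none") {
  kept <- applyAlignmentFilter(classified, filter)
  tl <- kept$len[kept$class == "TRUE_HOMININ"]
  atCut <- sum(tl[tl >= cutoff])
  atBase <- sum(tl[tl >= baseline])
  list(basesAtCutoff = atCut, basesAtBaseline = atBase,
       fold = if (atBase > 0) atCut / atBase else NA_real_)
}
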