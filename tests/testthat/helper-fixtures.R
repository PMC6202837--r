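# shared fixtures built in code

# deterministic random genome
testGenome <- function(len = 3000, seed = 11, name = "chr1") {
  simulateReference(len, seed = seed, name = name)
}

# independent Poisson-tail oracle via stats::ppois (the implementation sums
# the mass itself)
oracleMaxMismatches <- function(l, rate = 0.02, thr = 0.01) {
  vapply(l, function(li) {
    k <- 0L
    while (stats::ppois(k, li * rate, lower.tail = FALSE) >= thr) k <- k + 1L
    k
  }, integer(1))
}

# independent brute-force mappability oracle: per-pattern scans with
# Biostrings::vcountPattern (forward + reverse-complement occurrences)
oracleMappability <- function(genome, k, maxMismatch = 1L) {
  seqs <- as.character(genome)
  subj <- lapply(seqs, Biostrings::DNAString)
  out <- lapply(names(genome), function(sq) {
    L <- nchar(seqs[[sq]])
    n <- L - k + 1L
    if (n < 1L) return(logical(0))
    kmers <- substring(seqs[[sq]], seq_len(n), seq_len(n) + k - 1L)
    vapply(seq_len(n), function(i) {
      if (grepl("[^ACGT]", kmers[i])) return(FALSE)
      pat <- Biostrings::DNAString(kmers[i])
      fwd <- sum(vapply(subj, function(s)
        Biostrings::countPattern(pat, s, max.mismatch = maxMismatch),
        integer(1)))
      if (fwd != 1L) return(FALSE)
      rcp <- Biostrings::reverseComplement(pat)
      bwd <- sum(vapply(subj, function(s)
        Biostrings::countPattern(rcp, s, max.mismatch = maxMismatch),
        integer(1)))
      bwd == 0L
    }, logical(1))
  })
  names(out) <- names(genome)
  out
}

# brute-force all-pairs Hamming oracle for a single-sequence genome: dense
# n x n mismatch-count matrices, no hashing shortcuts
oracleMappabilityAllPairs <- function(genome, k, maxMismatch = 1L) {
  stopifnot(length(genome) == 1L)
  s <- as.character(genome[[1]])
  L <- nchar(s)
  n <- L - k + 1L
  if (n < 1L) return(stats::setNames(list(logical(0)), names(genome)))
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  X <- vapply(0:(k - 1L), function(j) code[seq_len(n) + j],
              numeric(n))            # n x k forward k-mer codes
  Y <- 5 - X[, k:1, drop = FALSE]    # reverse-complement codes
  DF <- matrix(0L, n, n)
  DR <- matrix(0L, n, n)
  for (j in seq_len(k)) {
    DF <- DF + outer(X[, j], X[, j], "!=")
    DR <- DR + outer(X[, j], Y[, j], "!=")
  }
  AF <- DF <= maxMismatch
  diag(AF) <- FALSE                  # self-match does not count
  AR <- DR <= maxMismatch            # own reverse complement does count
  valid <- !apply(is.na(X), 1L, any)
  flags <- valid & !(rowSums(AF) > 0 | rowSums(AR) > 0)
  stats::setNames(list(flags), names(genome))
}

# independent arithmetic oracle for the count correction, written directly
# from the displayed formulas at high precision
oracleCorrect <- function(nT, nS, M) {
  c(nTrue = nT - nS * M / (3 - M), nSpur = nS / (1 - M / 3))
}

# independent cumulative-curve oracle over per-length count vectors
oracleCumulativeFraction <- function(lens, nT, nS) {
  M <- oracleMaxMismatches(lens) / lens
  a <- rev(cumsum(rev(nT - nS * M / (3 - M))))
  b <- rev(cumsum(rev(nS / (1 - M / 3))))
  data.frame(L = lens, frac = b / (a + b))
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
oracleFisher <- function(k1, n1, k2, n2) {
  if (n1 == 0 || n2 == 0) return(1)
  K <- k1 + k2
  if (K == 0 || K == n1 + n2) return(1)
  support <- max(0, K - n2):min(n1, K)
  p <- stats::dhyper(support, n1, n2, K)
  obs <- stats::dhyper(k1, n1, n2, K)
  sum(p[p <= obs * (1 + 1e-7)])
}

# frozen per-length counts whose cumulative corrected curve crosses 10% at
# L = 27 and 1% at L = 32 (verified against oracleCumulativeFraction below)
cutoffFixture <- function() {
  lens <- 20:40
  nT <- rep(1000L, length(lens))
  nS <- c(1512L, 1324L, 1135L, 990L, 1065L, 803L, 277L, 612L, 380L, 203L,
          114L, 24L, 24L, 14L, 12L, 9L, 8L, 6L, 4L, 1L, 1L)
  cls <- data.frame(
    qname = sprintf("r%07d", seq_len(sum(nT) + sum(nS))),
    seqname = "chr1", pos = NA_integer_,
    len = c(rep(lens, nT), rep(lens, nS)),
    strand = "+",
    class = c(rep("TRUE_HOMININ", sum(nT)), rep("SPURIOUS", sum(nS))),
    allele = c(rep("reference", sum(nT)), rep("mutated", sum(nS))),
    mmRaw = 0L, mmCorr = 0L, mmProp = 0, indels = 0L, ct5 = TRUE,
    ct3 = FALSE)
  list(classified = ClassifiedAlignments(cls), lens = lens, nT = nT, nS = nS)
}
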