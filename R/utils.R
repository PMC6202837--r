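# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`; NULL seed uses
# (and advances) the session RNG so that callers remain composable
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# genome accessors: a genome is a Biostrings::DNAStringSet with unique names
checkGenome <- function(genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome sequences must carry unique names")
  invisible(genome)
}

#' Base composition of a genome
#'
#' Frequencies of A, C, G, T over all sequences; N and other ambiguity codes
#' are ignored.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return Named numeric vector of length 4 summing to 1.
#' @examples
#' baseComposition(Biostrings::DNAStringSet(c(chr1 = "ACGTACGT")))
#' @export
baseComposition <- function(genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  counts <- colSums(Biostrings::alphabetFrequency(genome)[, DNA_BASES,
                                                          drop = FALSE])
  counts / sum(counts)
}

complementBase <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")[b]
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Wilson score interval for a proportion; returns c(lo, hi)
wilsonCI <- function(k, n, level = 0.95) {
  if (n <= 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
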