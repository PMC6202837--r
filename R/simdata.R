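#' Configuration of the synthetic ancient-DNA read generator
#'
#' Bundles the parameters of the generative model used throughout the test
#' machinery: an endogenous organism diverged from the reference at a fixed
#' per-base rate, with short fragments and terminal cytosine deamination
#' decaying geometrically inward, mixed with contaminant fragments that can
#' only align by chance and therefore carry near-maximal mismatch counts and
#' frequent indels.
#'
#' @slot composition named A/C/G/T frequencies of the simulated reference.
#' @slot divergence endogenous divergence from the reference (subs/bp).
#' @slot fragLens discrete support of the fragment-length distribution (bp).
#' @slot fragProbs probabilities over `fragLens`.
#' @slot deamProb terminal C-to-T probability p0 at the outermost position.
#' @slot deamDecay geometric decay d per position inward (prob p0 * d^i).
#' @slot endoIndelProb probability an endogenous alignment contains an indel.
#' @slot contamIndelProb probability a spurious alignment contains an indel.
#' @slot contamCtProb terminal C-to-T probability of spurious alignments;
#'   `NA` means the background level f(C) * M(l) / 3 implied by random
#'   mismatches.
#' @slot pSpur spurious mixture proportion: a single number, or a function of
#'   read length.
#' @slot errorRate,tailThreshold parameters of the aligner mismatch-ceiling
#'   rule (see [maxMismatches]).
#' @slot seed integer seed; every stochastic call derives from it.
#' @export
setClass("SimConfig",
         representation(composition = "numeric", divergence = "numeric",
                        fragLens = "integer", fragProbs = "numeric",
                        deamProb = "numeric", deamDecay = "numeric",
                        endoIndelProb = "numeric",
                        contamIndelProb = "numeric",
                        contamCtProb = "numeric", pSpur = "function",
                        errorRate = "numeric", tailThreshold = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  probs <- c(object@divergence, object@deamProb, object@deamDecay,
             object@endoIndelProb, object@contamIndelProb)
  if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0,1]")
  if (any(object@fragLens < 20L)) return("fragment lengths must be >= 20 bp")
  if (abs(sum(object@fragProbs) - 1) > 1e-9)
    return("fragment-length probabilities must sum to 1")
  if (length(object@fragProbs) != length(object@fragLens))
    return("fragProbs must match fragLens")
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: divergence %.4g/bp, deamination p0 = %.2f (decay %.2f),\n",
    "  fragments %d-%d bp, indel prob %.3g (endogenous) / %.3g (spurious),\n",
    "  seed %d\n"),
    object@divergence, object@deamProb, object@deamDecay,
    min(object@fragLens), max(object@fragLens), object@endoIndelProb,
    object@contamIndelProb, object@seed))
  invisible(NULL)
})

#' Create a simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: endogenous
#' divergence of 0.002 substitutions per bp; fragment lengths uniform over
#' 20-40 bp (the design of the in-silico fragmented contaminant control,
#' which also gives every length bin equal power); terminal C-to-T
#' probability 0.3 decaying geometrically (factor 0.5) inward; indels in
#' 0.5% of endogenous and 52% of spurious alignments; and a spurious mixture
#' proportion declining with length from 0.5 at 20 bp (rate 0.15/bp),
#' mirroring the enrichment of chance alignments among the shortest reads.
#'
#' @param composition named A/C/G/T frequencies (default uniform).
#' @param divergence endogenous divergence rate (default 0.002).
#' @param fragLens,fragProbs fragment-length distribution (default uniform
#'   over 20:40).
#' @param deamProb,deamDecay terminal C-to-T model (defaults 0.3, 0.5).
#' @param endoIndelProb,contamIndelProb indel probabilities (defaults 0.005,
#'   0.52).
#' @param contamCtProb terminal C-to-T probability of spurious alignments;
#'   `NA` (default) uses the background f(C) * M(l) / 3.
#' @param pSpur spurious mixture proportion: a single number in `[0,1]` or a
#'   function of length; `NULL` (default) uses the declining profile
#'   `min(1, 0.5 * exp(-0.15 * (l - 20)))`.
#' @param errorRate,tailThreshold mismatch-ceiling rule parameters.
#' @param seed integer seed (mandatory for reproducibility; default 1).
#' @return A [SimConfig] object.
#' @examples
#' simConfig(seed = 42)
#' @export
simConfig <- function(composition = c(A = .25, C = .25, G = .25, T = .25),
                      divergence = 0.002, fragLens = 20:40,
                      fragProbs = NULL, deamProb = 0.3, deamDecay = 0.5,
                      endoIndelProb = 0.005, contamIndelProb = 0.52,
                      contamCtProb = NA_real_, pSpur = NULL,
                      errorRate = 0.02, tailThreshold = 0.01, seed = 1L) {
  fragLens <- as.integer(fragLens)
  if (is.null(fragProbs))
    fragProbs <- rep(1 / length(fragLens), length(fragLens))
  if (is.null(pSpur)) {
    pSpurFun <- function(l) pmin(1, 0.5 * exp(-0.15 * (l - 20)))
  } else if (is.function(pSpur)) {
    pSpurFun <- pSpur
  } else {
    stopifnot(length(pSpur) == 1, pSpur >= 0, pSpur <= 1)
    force(pSpur)
    pSpurFun <- function(l) rep_len(pSpur, length(l))
  }
  new("SimConfig", composition = composition / sum(composition),
      divergence = divergence, fragLens = fragLens,
      fragProbs = fragProbs / sum(fragProbs), deamProb = deamProb,
      deamDecay = deamDecay, endoIndelProb = endoIndelProb,
      contamIndelProb = contamIndelProb, contamCtProb = contamCtProb,
      pSpur = pSpurFun, errorRate = errorRate,
      tailThreshold = tailThreshold, seed = as.integer(seed))
}

#' Simulate a reference genome with i.i.d. bases
#'
#' @param length sequence length in bp (>= 200).
#' @param composition named A/C/G/T frequencies (default uniform).
#' @param seed integer seed.
#' @param name sequence name (default `"sim1"`).
#' @return A named [Biostrings::DNAStringSet] of one sequence.
#' @examples
#' simulateReference(500, seed = 1)
#' @export
simulateReference <- function(length,
                              composition = c(A = .25, C = .25, G = .25,
                                              T = .25),
                              seed = NULL, name = "sim1") {
  stopifnot(length >= 200)
  composition <- composition / sum(composition)
  s <- withSeed(seed, paste(
    sample(DNA_BASES, length, replace = TRUE, prob = composition[DNA_BASES]),
    collapse = ""))
  out <- Biostrings::DNAStringSet(s)
  names(out) <- name
  out
}

# apply terminal C->T deamination to reads given in read orientation
applyDeamination <- function(readChr, p0, d) {
  if (p0 <= 0) return(readChr)
  vapply(readChr, function(s) {
    ch <- strsplit(s, "")[[1]]
    len <- length(ch)
    isC <- ch == "C"
    if (any(isC)) {
      i <- seq_len(len)
      p5 <- p0 * d^(i - 1)
      p3 <- p0 * d^(len - i)
      p <- 1 - (1 - p5) * (1 - p3)  # a C near both ends gets both chances
      hit <- isC & stats::runif(len) < p
      ch[hit] <- "T"
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate endogenous ancient-DNA reads from a reference
#'
#' Each read is a substring of the reference carrying (i) divergence
#' substitutions at the configured rate, (ii) terminal C-to-T deamination in
#' read orientation with probability `p0 * d^i` at position `i` from either
#' end, and (iii) a uniformly drawn strand. Sequences are stored in SAM
#' convention (reference-forward orientation).
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param n number of reads.
#' @param config a [SimConfig].
#' @param seed integer seed (defaults to the config's seed).
#' @return Alignment records (see [alignmentRecords]) with an extra `origin`
#'   column set to `"endogenous"`.
#' @export
simulateEndogenous <- function(genome, n, config = simConfig(),
                               seed = config@seed) {
  checkGenome(genome)
  withSeed(seed, {
    seqLens <- Biostrings::width(genome)
    lens <- sample(config@fragLens, n, replace = TRUE,
                   prob = config@fragProbs)
    if (any(lens > max(seqLens)))
      stop("fragment longer than every reference sequence")
    sq <- sample(names(genome), n, replace = TRUE,
                 prob = seqLens / sum(seqLens))
    maxStart <- seqLens[match(sq, names(genome))] - lens + 1L
    if (any(maxStart < 1L)) {
      bad <- maxStart < 1L  # resample overly long fragments per sequence
      lens[bad] <- pmin(lens[bad], seqLens[match(sq[bad], names(genome))])
      maxStart <- seqLens[match(sq, names(genome))] - lens + 1L
    }
    start <- floor(stats::runif(n, 1, maxStart + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    refChr <- vapply(seq_len(n), function(i)
      toupper(as.character(Biostrings::subseq(genome[[sq[i]]], start[i],
                                              start[i] + lens[i] - 1L))),
      character(1))
    # divergence substitutions, uniform over the three other bases
    seqChr <- vapply(refChr, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(ch)) < config@divergence &
                     ch %in% DNA_BASES)
      for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    # deamination acts in read orientation
    readOri <- ifelse(strand == "-", revcompChar(seqChr), seqChr)
    readOri <- applyDeamination(readOri, config@deamProb, config@deamDecay)
    samOri <- ifelse(strand == "-", revcompChar(readOri), readOri)
    out <- alignmentRecords(sprintf("endo_%06d", seq_len(n)), sq, start,
                            strand, paste0(lens, "M"), samOri)
    out$origin <- "endogenous"
    out
  })
}

#' Simulate contaminant reads
#'
#' Fragments that are unrelated to the reference: either i.i.d. bases at the
#' configured composition or substrings of an independently simulated
#' (unrelated) genome. Lengths are uniform over the configured fragment
#' range, emulating in-silico fragmentation of contaminant genomes with the
#' same number of sequences at each length.
#'
#' @param n number of reads.
#' @param config a [SimConfig].
#' @param mode `"iid"` (default) or `"genome"`.
#' @param seed integer seed (defaults to the config's seed).
#' @return A [S4Vectors::DataFrame] with columns `qname`, `seq`, `len`,
#'   `origin` (= `"contaminant"`).
#' @export
simulateContaminant <- function(n, config = simConfig(),
                                mode = c("iid", "genome"),
                                seed = config@seed) {
  mode <- match.arg(mode)
  withSeed(seed, {
    lens <- sample(config@fragLens, n, replace = TRUE)  # uniform over range
    if (mode == "iid") {
      seqs <- vapply(lens, function(l)
        paste(sample(DNA_BASES, l, replace = TRUE,
                     prob = config@composition[DNA_BASES]), collapse = ""),
        character(1))
    } else {
      g <- simulateReference(max(10000L, 4L * max(lens)),
                             config@composition, seed = NULL,
                             name = "contig1")
      L <- length(g[[1]])
      start <- floor(stats::runif(n, 1, L - lens + 1))
      seqs <- vapply(seq_len(n), function(i)
        as.character(Biostrings::subseq(g[[1]], start[i],
                                        start[i] + lens[i] - 1L)),
        character(1))
    }
    DataFrame(qname = sprintf("contam_%06d", seq_len(n)), seq = seqs,
              len = lens, origin = "contaminant")
  })
}

#' Simulate a pre-classified true/spurious mixture with ground truth
#'
#' Bypasses alignment entirely and draws classified-alignment records
#' directly from the generative model underlying the correction: endogenous
#' records carry the original reference allele at their site (up to the
#' divergence rate), near-zero corrected mismatches, rare indels and
#' deamination flags per the damage model; spurious records carry the
#' mutated allele with probability `1 - M(l)` and each other allele with
#' probability `M(l) / 3`, the maximum mismatch count `m(l)`, and indels at
#' the configured rate. The mixture proportion may vary with length.
#'
#' @param n number of records.
#' @param config a [SimConfig].
#' @param seed integer seed (defaults to the config's seed).
#' @return A [ClassifiedAlignments] object with an extra `origin` column
#'   (the ground-truth label, `"endogenous"` or `"contaminant"`); estimators
#'   must not read it.
#' @export
simulateClassifiedMixture <- function(n, config = simConfig(),
                                      seed = config@seed) {
  withSeed(seed, {
    lens <- sample(config@fragLens, n, replace = TRUE,
                   prob = config@fragProbs)
    m <- maxMismatches(lens, config@errorRate, config@tailThreshold)
    M <- m / lens
    spur <- stats::runif(n) < config@pSpur(lens)
    fC <- config@composition[["C"]]
    allele <- character(n)
    mmRaw <- integer(n)
    ct5 <- logical(n); ct3 <- logical(n)
    indels <- integer(n)
    nE <- sum(!spur); nS <- sum(spur)
    if (nE) {
      # endogenous: original allele unless residual divergence hits the site
      err <- stats::runif(nE) < config@divergence
      alleleE <- ifelse(err,
                        ifelse(stats::runif(nE) < 1 / 3, "mutated", "other"),
                        "reference")
      baseMM <- stats::rbinom(nE, lens[!spur], config@divergence)
      ctp <- fC * config@deamProb
      c5 <- stats::runif(nE) < ctp
      c3 <- stats::runif(nE) < ctp
      allele[!spur] <- alleleE
      # raw count includes the forced mismatch at the site unless the read
      # happens to show the mutated allele, plus deaminated termini
      mmRaw[!spur] <- baseMM + c5 + c3 + (alleleE != "mutated")
      ct5[!spur] <- c5; ct3[!spur] <- c3
      indels[!spur] <- stats::rbinom(nE, 1L, config@endoIndelProb)
    }
    if (nS) {
      MS <- M[spur]
      u <- stats::runif(nS)
      alleleS <- ifelse(u < 1 - MS, "mutated",
                        ifelse(u < 1 - MS + MS / 3, "reference", "other"))
      ctp <- if (is.na(config@contamCtProb)) fC * MS / 3
             else rep_len(config@contamCtProb, nS)
      allele[spur] <- alleleS
      mmRaw[spur] <- m[spur]
      ct5[spur] <- stats::runif(nS) < ctp
      ct3[spur] <- stats::runif(nS) < ctp
      indels[spur] <- stats::rbinom(nS, 1L, config@contamIndelProb)
    }
    nNonAlt <- as.integer(allele != "mutated")
    cm <- correctedMismatches(mmRaw, nNonAlt, lens)
    df <- data.frame(
      qname = sprintf("sim_%06d", seq_len(n)), seqname = "sim1",
      pos = NA_integer_, len = lens,
      strand = sample(c("+", "-"), n, replace = TRUE),
      class = ifelse(allele == "reference", "TRUE_HOMININ", "SPURIOUS"),
      allele = allele, mmRaw = mmRaw, mmCorr = cm$mmCorr,
      mmProp = cm$mmProp, indels = indels, ct5 = ct5, ct3 = ct3,
      origin = ifelse(spur, "contaminant", "endogenous"))
    ClassifiedAlignments(df)
  })
}

#' Write reads to a FASTQ file with constant quality
#'
#' @param seqs character vector (or `DataFrame` with columns `qname`, `seq`)
#'   of read sequences.
#' @param path output path.
#' @param qname read names (ignored when `seqs` is a `DataFrame`).
#' @param quality constant quality character (default `"I"`).
#' @export
writeReadsFastq <- function(seqs, path, qname = NULL, quality = "I") {
  if (is(seqs, "DataFrame") || is.data.frame(seqs)) {
    qname <- seqs$qname
    seqs <- seqs$seq
  }
  if (is.null(qname)) qname <- sprintf("read_%06d", seq_along(seqs))
  lines <- as.vector(rbind(paste0("@", qname), seqs, "+",
                           strrep(quality, nchar(seqs))))
  writeLines(lines, path)
  invisible(path)
}
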