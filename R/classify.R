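#' Construct alignment records
#'
#' The internal alignment representation: one row per single-end alignment
#' with the read sequence in SAM convention (reference-forward orientation,
#' reverse-complemented for minus-strand alignments) and its CIGAR string.
#'
#' @param qname read names.
#' @param seqname reference sequence names.
#' @param start 1-based leftmost reference positions.
#' @param strand `"+"` or `"-"`.
#' @param cigar CIGAR strings (M/I/D/S operations supported).
#' @param seq read sequences, reference-forward orientation.
#' @return A [S4Vectors::DataFrame] with the above columns plus `len` (read
#'   length in bp) and `end` (1-based closed reference end).
#' @export
alignmentRecords <- function(qname, seqname, start, strand, cigar, seq) {
  seq <- toupper(as.character(seq))
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  if (!all(qw == nchar(seq)))
    stop("CIGAR query width disagrees with sequence length")
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  DataFrame(qname = as.character(qname), seqname = as.character(seqname),
            start = as.integer(start), strand = as.character(strand),
            cigar = as.character(cigar), seq = seq, len = nchar(seq),
            end = as.integer(start) + rw - 1L)
}

#' Read single-end alignments from a BAM (or SAM) file
#'
#' Unmapped and paired-end records are discarded, matching the upstream
#' treatment of single-stranded-library data. SAM text files are converted
#' on the fly via [Rsamtools::asBam].
#'
#' @param file path to a BAM or SAM file.
#' @return Alignment records as produced by [alignmentRecords].
#' @export
readAlignments <- function(file) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("readAlignments requires the Rsamtools package")
  if (grepl("\\.sam$", file, ignore.case = TRUE))
    file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "seq", "flag"))
  b <- Rsamtools::scanBam(file, param = p)[[1]]
  keep <- !is.na(b$pos) & bitwAnd(b$flag, 1L) == 0L &
    bitwAnd(b$flag, 4L) == 0L
  alignmentRecords(b$qname[keep], as.character(b$rname)[keep], b$pos[keep],
                   as.character(b$strand)[keep], b$cigar[keep],
                   as.character(b$seq)[keep])
}

# read sequences laid out in reference space ("-" at deletions, insertions
# removed) and the matching reference substrings, as character vectors
layerOnReference <- function(alns, genome) {
  checkGenome(genome)
  laid <- as.character(GenomicAlignments::sequenceLayer(
    Biostrings::BStringSet(alns$seq), alns$cigar,
    from = "query", to = "reference"))
  refs <- vapply(seq_len(nrow(alns)), function(i) {
    sq <- genome[[alns$seqname[i]]]
    toupper(as.character(Biostrings::subseq(sq, alns$start[i], alns$end[i])))
  }, character(1))
  list(read = laid, ref = refs)
}

# reference sequences laid out in query space ("-" at insertions), plus the
# query itself, both in SAM (reference-forward) orientation
layerOnQuery <- function(alns, genome) {
  checkGenome(genome)
  refs <- vapply(seq_len(nrow(alns)), function(i) {
    sq <- genome[[alns$seqname[i]]]
    toupper(as.character(Biostrings::subseq(sq, alns$start[i], alns$end[i])))
  }, character(1))
  cig <- alns$cigar
  laid <- as.character(GenomicAlignments::sequenceLayer(
    Biostrings::BStringSet(refs), cig, from = "reference", to = "query"))
  list(ref = laid, read = alns$seq)
}

#' Count substitution mismatches against a reference
#'
#' Counts aligned positions (CIGAR `M`) where the read base differs from the
#' reference base; deletions, insertions and positions where either base is
#' not A/C/G/T are not counted.
#'
#' @param alns alignment records (see [alignmentRecords]).
#' @param genome the reference the alignments refer to.
#' @return Integer vector of raw mismatch counts.
#' @export
rawMismatches <- function(alns, genome) {
  lay <- layerOnReference(alns, genome)
  vapply(seq_along(lay$read), function(i) {
    r <- strsplit(lay$read[i], "")[[1]]
    f <- strsplit(lay$ref[i], "")[[1]]
    sum(r != f & r %in% DNA_BASES & f %in% DNA_BASES)
  }, integer(1))
}

#' Count indel events in alignments
#'
#' The number of insertion plus deletion events (CIGAR runs, not bases).
#'
#' @param cigar CIGAR strings.
#' @return Integer vector of indel event counts.
#' @examples
#' countIndels(c("25M", "10M1I9M", "5M2D10M1I5M"))  # 0 1 2
#' @export
countIndels <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  vapply(ops, function(o) sum(o %in% c("I", "D")), integer(1))
}

#' Classify a read base observed at a mutated site
#'
#' Applies the single-stranded-library strand guard first: alignments in
#' forward orientation are disregarded when either the original or the
#' mutated reference state is `C`, and alignments in reverse orientation when
#' either state is `G` (deamination-induced C-to-T / G-to-A changes could
#' otherwise convert alleles between the states being compared). Surviving
#' observations are classified `TRUE_HOMININ` if the read shows the original
#' reference base and `SPURIOUS` if it shows the mutated or any other base.
#'
#' @param readBase observed read base at the site (reference-forward
#'   orientation); `"-"` for a deletion.
#' @param strand alignment strand, `"+"` or `"-"`.
#' @param ref,alt original and mutated reference base at the site.
#' @return A data.frame with columns `class` (`TRUE_HOMININ`, `SPURIOUS`,
#'   `EXCLUDED_STRAND`, `NO_SITE`) and `allele` (`reference`, `mutated`,
#'   `other`, or `NA`).
#' @examples
#' classifyAtSite("A", "+", "A", "G")  # TRUE_HOMININ
#' classifyAtSite("A", "+", "A", "C")  # EXCLUDED_STRAND (mutated state is C)
#' @export
classifyAtSite <- function(readBase, strand, ref, alt) {
  n <- max(length(readBase), length(strand), length(ref), length(alt))
  readBase <- rep_len(toupper(readBase), n)
  strand <- rep_len(as.character(strand), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  guarded <- (strand == "+" & (ref == "C" | alt == "C")) |
    (strand == "-" & (ref == "G" | alt == "G"))
  cls <- ifelse(guarded, "EXCLUDED_STRAND",
         ifelse(!readBase %in% DNA_BASES, "NO_SITE",
         ifelse(readBase == ref, "TRUE_HOMININ", "SPURIOUS")))
  allele <- ifelse(cls %in% c("EXCLUDED_STRAND", "NO_SITE"), NA_character_,
            ifelse(readBase == ref, "reference",
            ifelse(readBase == alt, "mutated", "other")))
  data.frame(class = cls, allele = allele)
}

#' Mismatch count corrected for artificially mutated sites
#'
#' Alignments that do not show the mutated reference's allele at an
#' overlapped site necessarily carry a mismatch there; one mismatch per such
#' site is subtracted (applied to true and spurious alignments alike) and
#' the result floored at zero.
#'
#' @param mmRaw raw mismatch counts against the mutated reference.
#' @param nNonAltSites number of overlapped mutated sites at which the read
#'   base is a called base differing from the mutated allele.
#' @param len read lengths in bp.
#' @return A data.frame with columns `mmCorr` and `mmProp`.
#' @examples
#' correctedMismatches(2, 1, 30)  # 1 mismatch, 1/30 per bp
#' @export
correctedMismatches <- function(mmRaw, nNonAltSites, len) {
  mmCorr <- pmax(0L, mmRaw - nNonAltSites)
  data.frame(mmCorr = mmCorr, mmProp = mmCorr / len)
}

#' Terminal C-to-T substitution flags
#'
#' Flags whether the first (5') and last (3') read base, in read orientation,
#' shows a C-to-T substitution relative to the unmutated reference. For
#' minus-strand alignments this corresponds to a G-to-A difference at the
#' opposite end in reference-forward orientation. A terminal base lying in
#' an insertion has no reference counterpart and yields `FALSE`.
#'
#' @param alns alignment records (see [alignmentRecords]).
#' @param genome the unmutated reference.
#' @return A data.frame with logical columns `ct5` and `ct3`.
#' @export
terminalCtFlags <- function(alns, genome) {
  lay <- layerOnQuery(alns, genome)
  n <- nrow(alns)
  ct5 <- logical(n); ct3 <- logical(n)
  for (i in seq_len(n)) {
    len <- nchar(lay$read[i])
    rFirst <- substr(lay$read[i], 1L, 1L)
    fFirst <- substr(lay$ref[i], 1L, 1L)
    rLast <- substr(lay$read[i], len, len)
    fLast <- substr(lay$ref[i], len, len)
    if (alns$strand[i] == "+") {
      ct5[i] <- fFirst == "C" && rFirst == "T"
      ct3[i] <- fLast == "C" && rLast == "T"
    } else {
      # read 5' end = reference-forward right end, complemented
      ct5[i] <- fLast == "G" && rLast == "A"
      ct3[i] <- fFirst == "G" && rFirst == "A"
    }
  }
  data.frame(ct5 = ct5, ct3 = ct3)
}

#' Substitution spectrum along read positions
#'
#' For each read position (in read orientation) and each of the 12 ordered
#' substitution types X>Y, the frequency of reads showing Y at a position
#' whose unmutated reference base is X, among reads with reference X at that
#' position. Positions with a zero denominator are reported as `NA`.
#'
#' @param alns alignment records (see [alignmentRecords]).
#' @param genome the unmutated reference.
#' @param maxPos largest read position reported (default: longest read).
#' @return A data.frame with columns `pos`, `sub` (e.g. `"C>T"`), `count`,
#'   `denom`, `freq`.
#' @export
substitutionSpectrum <- function(alns, genome, maxPos = NULL) {
  stopifnot(nrow(alns) > 0)
  lay <- layerOnQuery(alns, genome)
  readChr <- lay$read
  refChr <- lay$ref
  rev <- alns$strand == "-"
  if (any(rev)) {
    # flip into read orientation: reverse-complement both layers
    flip <- function(x) chartr("ACGT-", "TGCA-",
                               vapply(strsplit(x, ""), function(ch)
                                 paste(rev(ch), collapse = ""), character(1)))
    readChr[rev] <- flip(readChr[rev])
    refChr[rev] <- flip(refChr[rev])
  }
  lens <- nchar(readChr)
  pos <- sequence(lens)
  readB <- unlist(strsplit(readChr, ""), use.names = FALSE)
  refB <- unlist(strsplit(refChr, ""), use.names = FALSE)
  ok <- refB %in% DNA_BASES & readB %in% DNA_BASES
  pos <- pos[ok]; readB <- readB[ok]; refB <- refB[ok]
  if (is.null(maxPos)) maxPos <- max(lens)
  keep <- pos <= maxPos
  pos <- pos[keep]; readB <- readB[keep]; refB <- refB[keep]
  subs <- expand.grid(from = DNA_BASES, to = DNA_BASES,
                      stringsAsFactors = FALSE)
  subs <- subs[subs$from != subs$to, ]
  out <- do.call(rbind, lapply(seq_len(nrow(subs)), function(j) {
    fb <- subs$from[j]; tb <- subs$to[j]
    denom <- vapply(seq_len(maxPos), function(p)
      sum(pos == p & refB == fb), integer(1))
    count <- vapply(seq_len(maxPos), function(p)
      sum(pos == p & refB == fb & readB == tb), integer(1))
    data.frame(pos = seq_len(maxPos), sub = paste0(fb, ">", tb),
               count = count, denom = denom,
               freq = ifelse(denom > 0, count / denom, NA_real_))
  }))
  rownames(out) <- NULL
  out
}

#' Classify alignments against a mutated-site table
#'
#' The full per-alignment evaluation: reads shorter than `minLen` are
#' discarded; alignments failing the length-dependent mappability filter (if
#' tracks are supplied) are labelled `UNMAPPABLE`; alignments overlapping no
#' mutated site are `NO_SITE`; at overlapped sites the strand guard and the
#' true/spurious call of [classifyAtSite] are applied, classifying by the
#' 5'-most (in read orientation) non-guarded site. Mismatch counts against
#' the mutated reference are corrected for the artificial sites, indel events
#' are counted from the CIGAR, and terminal C-to-T flags are computed against
#' the unmutated reference when it is supplied.
#'
#' @param alns alignment records (see [alignmentRecords] / [readAlignments]).
#' @param sites a [MutatedSites] table.
#' @param mutatedGenome the mutated reference the reads were aligned to.
#' @param originalGenome the unmutated reference (optional; terminal C-to-T
#'   flags are `NA` without it).
#' @param tracks optional [MappabilityTracks] for the mappability filter.
#' @param minLen minimum read length retained (default 20).
#' @return A [ClassifiedAlignments] object.
#' @export
classifyAlignments <- function(alns, sites, mutatedGenome,
                               originalGenome = NULL, tracks = NULL,
                               minLen = 20L) {
  alns <- alns[alns$len >= minLen, , drop = FALSE]
  n <- nrow(alns)
  if (!n) stop("no alignments of at least ", minLen, " bp")
  cls <- rep("NO_SITE", n)
  allele <- rep(NA_character_, n)
  sitePos <- rep(NA_integer_, n)
  mappable <- rep(TRUE, n)
  if (!is.null(tracks)) {
    um <- isUniquelyMappable(tracks, alns$seqname, alns$start, alns$end,
                             alns$len)
    mappable <- !is.na(um) & um
  }
  lay <- layerOnReference(alns, mutatedGenome)
  spanGr <- GRanges(alns$seqname, IRanges(alns$start, alns$end))
  ov <- GenomicRanges::findOverlaps(spanGr, sites)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  siteRef <- mcols(sites)$ref; siteAlt <- mcols(sites)$alt
  siteStart <- start(sites)
  nNonAlt <- integer(n)
  for (i in which(mappable)) {
    js <- sh[qh == i]
    if (!length(js)) next
    sp <- siteStart[js]
    off <- sp - alns$start[i] + 1L
    obs <- substr(rep(lay$read[i], length(off)), off, off)
    # subtraction: one mismatch per overlapped site where the read shows a
    # called base other than the mutated allele
    nNonAlt[i] <- sum(obs %in% DNA_BASES & obs != siteAlt[js])
    # 5'-most in read orientation: leftmost for +, rightmost for -
    ord <- if (alns$strand[i] == "+") order(sp) else order(-sp)
    call <- classifyAtSite(obs[ord], alns$strand[i], siteRef[js][ord],
                           siteAlt[js][ord])
    usable <- which(call$class %in% c("TRUE_HOMININ", "SPURIOUS"))
    if (length(usable)) {
      u <- usable[1]
      cls[i] <- call$class[u]
      allele[i] <- call$allele[u]
      sitePos[i] <- sp[ord][u]
    } else if (all(call$class == "EXCLUDED_STRAND")) {
      cls[i] <- "EXCLUDED_STRAND"
    } else {
      cls[i] <- "NO_SITE"
    }
  }
  cls[!mappable] <- "UNMAPPABLE"
  mmRaw <- rawMismatches(alns, mutatedGenome)
  cm <- correctedMismatches(mmRaw, nNonAlt, alns$len)
  if (!is.null(originalGenome)) {
    ct <- terminalCtFlags(alns, originalGenome)
  } else {
    ct <- data.frame(ct5 = rep(NA, n), ct3 = rep(NA, n))
  }
  ClassifiedAlignments(data.frame(
    qname = alns$qname, seqname = alns$seqname, pos = sitePos,
    len = alns$len, strand = alns$strand, class = cls, allele = allele,
    mmRaw = mmRaw, mmCorr = cm$mmCorr, mmProp = cm$mmProp,
    indels = countIndels(alns$cigar), ct5 = ct$ct5, ct3 = ct$ct3))
}
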