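#' Build length-dependent unique-mappability tracks for a small genome
#'
#' For each k in `kValues`, every start position of the genome is flagged as
#' uniquely mappable if and only if its k-mer matches no other forward-strand
#' start position within `maxMismatch` mismatches, and its reverse complement
#' matches no start position at all within the same tolerance. Positions
#' whose k-mer contains a non-ACGT base are never flagged.
#'
#' The search uses the exact-half pigeonhole trick: two k-mers within one
#' mismatch must agree exactly on their first or second half, so candidate
#' pairs are generated by hashing both halves and verified by direct
#' comparison. This is exhaustive (no heuristics) but intended for small
#' genomes; the total length should not exceed a few hundred kb.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param kValues integer k-mer lengths (default `c(20, 23, 26, 29, 32, 35)`).
#' @param maxMismatch mismatch tolerance (default 1; 0 and 1 supported).
#' @return A [MappabilityTracks] object.
#' @export
buildMappabilityTracks <- function(genome,
                                   kValues = c(20L, 23L, 26L, 29L, 32L, 35L),
                                   maxMismatch = 1L) {
  checkGenome(genome)
  kValues <- sort(as.integer(kValues))
  maxMismatch <- as.integer(maxMismatch)
  stopifnot(maxMismatch %in% c(0L, 1L))
  seqs <- toupper(as.character(genome))
  tracks <- lapply(kValues, function(k) {
    perSeq <- lapply(names(genome), function(sq) {
      L <- nchar(seqs[[sq]])
      n <- L - k + 1L
      if (n < 1L) return(logical(0))
      rep(FALSE, n)
    })
    names(perSeq) <- names(genome)
    # gather all forward k-mers with (sequence, position) ids
    fw <- lapply(names(genome), function(sq) {
      L <- nchar(seqs[[sq]])
      n <- L - k + 1L
      if (n < 1L) return(character(0))
      substring(seqs[[sq]], seq_len(n), seq_len(n) + k - 1L)
    })
    ids <- data.frame(
      seq = rep(names(genome), lengths(fw)),
      pos = unlist(lapply(fw, seq_along), use.names = FALSE))
    fw <- unlist(fw, use.names = FALSE)
    if (!length(fw)) return(perSeq)
    valid <- !grepl("[^ACGT]", fw)
    nF <- length(fw)
    rc <- revcompChar(fw[valid])
    # pool: forward k-mers then reverse complements; `origin` maps each pool
    # entry back to the forward position it belongs to
    pool <- c(fw[valid], rc)
    origin <- c(which(valid), which(valid))
    isFwd <- c(rep(TRUE, sum(valid)), rep(FALSE, sum(valid)))
    nonUnique <- rep(FALSE, nF)
    half <- k %/% 2L
    keys1 <- substr(pool, 1L, half)
    keys2 <- substr(pool, half + 1L, k)
    markGroup <- function(gidx) {
      m <- length(gidx)
      if (m < 2L) return()
      gs <- pool[gidx]
      for (i in seq_len(m - 1L)) {
        rest <- gidx[(i + 1L):m]
        d <- hammingDist(gs[i], gs[(i + 1L):m])
        hit <- d <= maxMismatch
        if (!any(hit)) next
        # a hit marks every forward member of the pair non-unique, except a
        # forward k-mer paired with itself
        self <- origin[rest] == origin[gidx[i]] &
          isFwd[rest] == isFwd[gidx[i]]
        hit <- hit & !self
        if (any(hit)) {
          # the pool carries both strands of every k-mer, so each hit pair is
          # rediscovered in mirrored orientation; marking the forward members
          # of this pair is sufficient
          if (isFwd[gidx[i]]) nonUnique[origin[gidx[i]]] <<- TRUE
          fh <- rest[hit & isFwd[rest]]
          if (length(fh)) nonUnique[origin[fh]] <<- TRUE
        }
      }
    }
    for (keys in list(keys1, keys2)) {
      grp <- split(seq_along(pool), keys)
      grp <- grp[lengths(grp) > 1L]
      for (g in grp) markGroup(g)
    }
    flag <- valid & !nonUnique
    for (sq in names(genome)) {
      sel <- ids$seq == sq
      if (any(sel)) perSeq[[sq]][ids$pos[sel]] <- flag[sel]
    }
    perSeq
  })
  names(tracks) <- as.character(kValues)
  new("MappabilityTracks", kValues = kValues, tracks = tracks,
      maxMismatch = maxMismatch)
}

# Hamming distance between one string and a vector of equal-length strings
hammingDist <- function(x, ys) {
  xs <- strsplit(x, "")[[1]]
  vapply(strsplit(ys, ""), function(y) sum(xs != y), numeric(1))
}

#' Decide unique mappability of an alignment from the track set
#'
#' Selects the largest track length `k` not exceeding the read length, then
#' deems the alignment uniquely mappable if any position `p` within its
#' reference span (`start <= p <= end - k + 1`) carries the unique flag.
#' Reads shorter than the smallest track length cannot be assessed and
#' return `NA` (such reads are discarded upstream).
#'
#' @param tracks a [MappabilityTracks] object.
#' @param seqname sequence name of the alignment.
#' @param start,end 1-based closed reference span of the alignment.
#' @param readLen read length in bp (drives the choice of k).
#' @return `TRUE`, `FALSE`, or `NA` when `readLen < min(kValues(tracks))`.
#' @export
isUniquelyMappable <- function(tracks, seqname, start, end, readLen) {
  stopifnot(is(tracks, "MappabilityTracks"))
  ks <- tracks@kValues
  n <- max(length(seqname), length(start))
  seqname <- rep_len(as.character(seqname), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  readLen <- rep_len(as.integer(readLen), n)
  vapply(seq_len(n), function(i) {
    fit <- ks[ks <= readLen[i]]
    if (!length(fit)) return(NA)
    k <- max(fit)
    tr <- tracks@tracks[[as.character(k)]][[seqname[i]]]
    if (is.null(tr)) return(FALSE)
    lo <- start[i]
    hi <- min(end[i] - k + 1L, length(tr))
    if (hi < lo) return(FALSE)
    any(tr[lo:hi])
  }, logical(1))
}
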