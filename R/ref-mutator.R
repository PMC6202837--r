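#' Select mutation sites on a regular grid with exclusion-aware relocation
#'
#' Candidate sites are placed every `spacing` bp along each sequence (the
#' first at position `spacing`, 1-based). A candidate falling inside the
#' exclusion track (or on an `N` base) is relocated to the nearest included
#' position (ties broken leftward) and kept only if that position is at least
#' `minAdjacent` bp from the previously accepted site and from the next grid
#' candidate; otherwise the site is dropped. The result is deterministic.
#'
#' @param genome a named [Biostrings::DNAStringSet]. Lowercase (soft-masked)
#'   bases are treated as valid; `N` bases are treated as excluded.
#' @param exclusions a [GenomicRanges::GRanges] of regions to avoid (empty by
#'   default). Intervals are merged internally; sequences absent from
#'   `genome` are ignored.
#' @param spacing grid period in bp (default 100).
#' @param minAdjacent minimum distance in bp between a relocated site and its
#'   neighbours (default 75). Must be smaller than `spacing`.
#' @return Named list (one element per sequence) of sorted 1-based site
#'   positions.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 250), collapse = "")))
#' selectMutationSites(g)[["chr1"]]  # 100, 200, ..., 1000
#' @export
selectMutationSites <- function(genome, exclusions = GenomicRanges::GRanges(),
                                spacing = 100L, minAdjacent = 75L) {
  checkGenome(genome)
  spacing <- as.integer(spacing)
  minAdjacent <- as.integer(minAdjacent)
  stopifnot(spacing > minAdjacent, minAdjacent > 0L)
  exclusions <- GenomicRanges::reduce(exclusions)
  out <- vector("list", length(genome))
  names(out) <- names(genome)
  for (sq in names(genome)) {
    L <- length(genome[[sq]])
    included <- rep(TRUE, L)
    excl <- exclusions[as.character(seqnames(exclusions)) == sq]
    if (length(excl)) {
      s <- pmax(1L, start(excl)); e <- pmin(L, end(excl))
      keep <- s <= e
      for (i in which(keep)) included[s[i]:e[i]] <- FALSE
    }
    letter <- strsplit(toupper(as.character(genome[[sq]])), "")[[1]]
    included[!(letter %in% DNA_BASES)] <- FALSE
    inclPos <- which(included)
    grid <- seq.int(spacing, L, by = spacing)
    accepted <- integer(0)
    prev <- -Inf
    for (gi in seq_along(grid)) {
      g <- grid[gi]
      nxt <- if (gi < length(grid)) grid[gi + 1L] else NA_integer_
      if (included[g]) {
        accepted <- c(accepted, g)
        prev <- g
        next
      }
      if (!length(inclPos)) next
      # nearest included position, ties leftward
      idx <- findInterval(g, inclPos)
      cand <- c(if (idx >= 1L) inclPos[idx],
                if (idx < length(inclPos)) inclPos[idx + 1L])
      cand <- cand[order(abs(cand - g), cand)][1L]
      ok <- cand > prev && (cand - prev) >= minAdjacent &&
        (is.na(nxt) || (cand < nxt && (nxt - cand) >= minAdjacent))
      if (ok) {
        accepted <- c(accepted, cand)
        prev <- cand
      }
    }
    out[[sq]] <- accepted
  }
  out
}

#' Build a composition-preserving base-replacement scheme
#'
#' In `batch` mode the replacement is an exact multiset permutation of the
#' original bases across all sites (applied later in [mutateReference]); the
#' genome-wide base counts are preserved exactly. In `matrix` mode a
#' zero-diagonal flow matrix `F` with row and column sums equal to the base
#' frequencies `f` is obtained by iterative proportional fitting and
#' row-normalised into replacement probabilities `Q`, so that the expected
#' composition is stationary (`f Q = f`).
#'
#' @param composition named numeric of A/C/G/T frequencies summing to 1.
#' @param mode `"batch"` (default) or `"matrix"`.
#' @param tol convergence tolerance for the proportional fitting.
#' @return A [ReplacementScheme].
#' @examples
#' buildReplacementScheme(c(A = .25, C = .25, G = .25, T = .25), "matrix")
#' @export
buildReplacementScheme <- function(composition, mode = c("batch", "matrix"),
                                   tol = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(length(composition) == 4, abs(sum(composition) - 1) < 1e-6)
  if (is.null(names(composition))) names(composition) <- DNA_BASES
  composition <- composition[DNA_BASES]
  if (mode == "matrix") {
    if (any(composition <= 0))
      stop("matrix mode requires strictly positive base frequencies")
    f <- composition / sum(composition)
    F <- outer(f, f)
    diag(F) <- 0
    for (it in seq_len(10000L)) {
      F <- F * (f / rowSums(F))        # match row sums
      F <- t(t(F) * (f / colSums(F)))  # match column sums
      if (max(abs(rowSums(F) - f)) < tol && max(abs(colSums(F) - f)) < tol)
        break
    }
    Q <- F / rowSums(F)
    dimnames(Q) <- list(DNA_BASES, DNA_BASES)
  } else {
    Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  }
  new("ReplacementScheme", mode = mode, Q = Q,
      composition = composition / sum(composition))
}

# multiset-preserving fixed-point-free reassignment of `orig`;
# errors when no such assignment exists (one base on more than half the sites)
batchReplacement <- function(orig) {
  n <- length(orig)
  counts <- table(factor(orig, levels = DNA_BASES))
  if (any(counts > n / 2))
    stop("batch replacement infeasible: one base occupies more than half ",
         "of the sites")
  mut <- sample(orig, n)
  for (it in seq_len(200L)) {
    bad <- which(mut == orig)
    if (!length(bad)) return(mut)
    for (i in bad) {
      if (mut[i] != orig[i]) next
      # swap with a random partner such that both positions end up valid
      ok <- which(mut != orig[i] & orig != mut[i])
      ok <- ok[ok != i]
      if (!length(ok)) next
      j <- if (length(ok) == 1L) ok else sample(ok, 1L)
      tmp <- mut[i]; mut[i] <- mut[j]; mut[j] <- tmp
    }
  }
  stop("batch replacement failed to converge")  # nocov
}

#' Inject composition-preserving mutations into a reference genome
#'
#' Applies single-base changes at the selected sites according to the
#' replacement scheme and returns both the mutated genome and the site table
#' that makes the operation reversible (see [revertReference]). Sites falling
#' on an `N` base are skipped with a warning.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param sites named list of 1-based positions per sequence, as returned by
#'   [selectMutationSites].
#' @param scheme a [ReplacementScheme]; defaults to batch mode at the
#'   genome's own composition.
#' @param seed optional integer seed for the (seeded) replacement draws.
#' @return A list with elements `genome` (mutated [Biostrings::DNAStringSet])
#'   and `sites` (a [MutatedSites] table).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 250), collapse = "")))
#' res <- mutateReference(g, selectMutationSites(g), seed = 1)
#' res$sites
#' @export
mutateReference <- function(genome, sites, scheme = NULL, seed = NULL) {
  checkGenome(genome)
  if (is.null(scheme))
    scheme <- buildReplacementScheme(baseComposition(genome), "batch")
  sites <- sites[intersect(names(sites), names(genome))]
  seqn <- rep(names(sites), lengths(sites))
  pos <- unlist(sites, use.names = FALSE)
  if (!length(pos)) {
    return(list(genome = genome,
                sites = MutatedSites(character(0), integer(0),
                                     character(0), character(0))))
  }
  orig <- toupper(mapply(function(sq, p)
    as.character(Biostrings::subseq(genome[[sq]], p, p)), seqn, pos))
  bad <- !(orig %in% DNA_BASES)
  if (any(bad)) {
    warning(sum(bad), " site(s) at non-ACGT bases skipped")
    seqn <- seqn[!bad]; pos <- pos[!bad]; orig <- orig[!bad]
  }
  mut <- withSeed(seed, {
    if (scheme@mode == "batch") {
      batchReplacement(orig)
    } else {
      vapply(orig, function(b)
        sample(DNA_BASES, 1L, prob = scheme@Q[b, ]), character(1),
        USE.NAMES = FALSE)
    }
  })
  mutated <- genome
  for (sq in unique(seqn)) {
    i <- seqn == sq
    mutated[[sq]] <- Biostrings::replaceLetterAt(
      mutated[[sq]], pos[i], paste(mut[i], collapse = ""))
  }
  list(genome = mutated, sites = MutatedSites(seqn, pos, orig, mut))
}

#' Revert a mutated genome using its site table
#'
#' @param genome a mutated [Biostrings::DNAStringSet].
#' @param sites the [MutatedSites] table produced by [mutateReference].
#' @return The restored [Biostrings::DNAStringSet].
#' @export
revertReference <- function(genome, sites) {
  checkGenome(genome)
  restored <- genome
  seqn <- as.character(seqnames(sites))
  for (sq in unique(seqn)) {
    i <- seqn == sq
    restored[[sq]] <- Biostrings::replaceLetterAt(
      restored[[sq]], start(sites)[i], paste(mcols(sites)$ref[i],
                                             collapse = ""))
  }
  restored
}
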