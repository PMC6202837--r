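#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

DNA_BASES <- c("A", "C", "G", "T")

ALN_CLASSES <- c("TRUE_HOMININ", "SPURIOUS", "EXCLUDED_STRAND",
                 "NO_SITE", "UNMAPPABLE")

#' Table of artificially mutated reference sites
#'
#' A [GenomicRanges::GRanges] of width-1 positions carrying the original
#' (`ref`) and injected (`alt`) base in its metadata columns. This table is
#' the ground truth used to classify overlapping alignments as true or
#' spurious and to revert a mutated genome back to the original.
#'
#' @slot . inherits all slots from `GRanges`; metadata columns `ref` and
#'   `alt` are required, both single bases in `A`/`C`/`G`/`T` and unequal.
#' @export
setClass("MutatedSites", contains = "GRanges")

setValidity("MutatedSites", function(object) {
  mc <- mcols(object)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    return("metadata columns 'ref' and 'alt' are required")
  ref <- as.character(mc$ref)
  alt <- as.character(mc$alt)
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES))
    return("'ref' and 'alt' must be in {A,C,G,T}")
  if (any(ref == alt))
    return("'ref' must differ from 'alt' at every site")
  if (!all(width(object) == 1L))
    return("all sites must have width 1")
  pos <- split(start(object), as.character(seqnames(object)))
  if (any(vapply(pos, is.unsorted, logical(1), strictly = TRUE)))
    return("positions must be strictly increasing within each sequence")
  TRUE
})

#' Construct a MutatedSites object
#'
#' @param seqnames character vector of sequence names.
#' @param pos integer vector of 1-based site positions.
#' @param ref,alt character vectors of original and mutated bases.
#' @return A [MutatedSites] object.
#' @examples
#' MutatedSites("chr1", 100L, "A", "G")
#' @export
MutatedSites <- function(seqnames, pos, ref, alt) {
  gr <- GRanges(seqnames, IRanges(as.integer(pos), width = 1L),
                ref = as.character(ref), alt = as.character(alt))
  new("MutatedSites", gr)
}

#' Length-dependent unique-mappability tracks
#'
#' For each k-mer length k, a per-sequence logical vector flagging the start
#' positions (1 .. L - k + 1) whose k-mer is uniquely mappable in the genome
#' within a mismatch tolerance.
#'
#' @slot kValues integer vector of k-mer lengths, sorted increasing.
#' @slot tracks named list (one element per k, names `as.character(k)`), each
#'   a named list of logical vectors per sequence.
#' @slot maxMismatch integer, the mismatch tolerance the tracks were built
#'   with.
#' @export
setClass("MappabilityTracks",
         representation(kValues = "integer", tracks = "list",
                        maxMismatch = "integer"))

setValidity("MappabilityTracks", function(object) {
  if (is.unsorted(object@kValues, strictly = TRUE))
    return("kValues must be strictly increasing")
  if (!identical(names(object@tracks), as.character(object@kValues)))
    return("tracks must be named by kValues")
  TRUE
})

#' @describeIn MappabilityTracks the k-mer lengths of the track set
#' @param x,object a `MappabilityTracks` object.
#' @export
kValues <- function(x) x@kValues

setMethod("show", "MappabilityTracks", function(object) {
  ns <- length(object@tracks[[1]])
  cat(sprintf(
    "MappabilityTracks: k = {%s}, %d sequence(s), max %d mismatch(es)\n",
    paste(object@kValues, collapse = ","), ns, object@maxMismatch))
  invisible(NULL)
})

#' Classified alignment records
#'
#' A [S4Vectors::DataFrame] subclass holding one row per alignment that was
#' evaluated against the mutated-site table, with its class label
#' (`TRUE_HOMININ`, `SPURIOUS`, `EXCLUDED_STRAND`, `NO_SITE`, `UNMAPPABLE`),
#' the allele carried at the classifying site (`reference`, `mutated`,
#' `other`), the mismatch count corrected for the artificial site, the indel
#' event count and terminal C-to-T flags in read orientation.
#'
#' @export
setClass("ClassifiedAlignments", contains = "DFrame")

CLASSIFIED_COLS <- c("qname", "seqname", "pos", "len", "strand", "class",
                     "allele", "mmRaw", "mmCorr", "mmProp", "indels",
                     "ct5", "ct3")

setValidity("ClassifiedAlignments", function(object) {
  miss <- setdiff(CLASSIFIED_COLS, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(object$class %in% ALN_CLASSES))
    return("invalid class labels")
  if (any(object$mmCorr < 0, na.rm = TRUE))
    return("corrected mismatch counts must be non-negative")
  TRUE
})

#' Construct a ClassifiedAlignments object
#'
#' @param df a data.frame or DataFrame with the required columns (`qname`,
#'   `seqname`, `pos`, `len`, `strand`, `class`, `allele`, `mmRaw`, `mmCorr`,
#'   `mmProp`, `indels`, `ct5`, `ct3`); extra columns are kept.
#' @return A [ClassifiedAlignments] object.
#' @export
ClassifiedAlignments <- function(df) {
  new("ClassifiedAlignments", as(as.data.frame(df), "DFrame"))
}

setMethod("show", "ClassifiedAlignments", function(object) {
  tab <- table(factor(object$class, levels = ALN_CLASSES))
  cat(sprintf("ClassifiedAlignments: %d alignments\n", nrow(object)))
  for (cl in names(tab))
    if (tab[[cl]] > 0) cat(sprintf("  %-16s %d\n", cl, tab[[cl]]))
  invisible(NULL)
})

#' Replacement scheme for reference mutation
#'
#' Describes how original bases at selected sites are replaced. In `batch`
#' mode the mutated bases are a multiset-preserving reassignment of the
#' original bases (composition preserved exactly). In `matrix` mode each base
#' is replaced by sampling from a zero-diagonal row-stochastic matrix `Q`
#' fitted so the base-composition flow is stationary (f Q = f).
#'
#' @slot mode `"batch"` or `"matrix"`.
#' @slot Q 4x4 replacement-probability matrix (matrix mode; zero otherwise).
#' @slot composition named numeric of genome base frequencies.
#' @export
setClass("ReplacementScheme",
         representation(mode = "character", Q = "matrix",
                        composition = "numeric"))

setValidity("ReplacementScheme", function(object) {
  if (!object@mode %in% c("batch", "matrix"))
    return("mode must be 'batch' or 'matrix'")
  if (object@mode == "matrix") {
    Q <- object@Q
    if (any(abs(diag(Q)) > 1e-12)) return("Q diagonal must be zero")
    if (any(abs(rowSums(Q) - 1) > 1e-9)) return("Q rows must sum to 1")
    f <- object@composition
    if (max(abs(as.vector(f %*% Q) - f)) >= 1e-9)
      return("flow balance violated: f Q != f")
  }
  TRUE
})

setMethod("show", "ReplacementScheme", function(object) {
  cat(sprintf("ReplacementScheme: mode = %s\n", object@mode))
  if (object@mode == "matrix") {
    cat("Q (row base -> column base):\n")
    print(round(object@Q, 4))
  }
  invisible(NULL)
})
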