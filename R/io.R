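# Plain-text interchange formats. Genomic positions are written 0-based
# (`pos0` columns, BED) and converted to the 1-based internal convention on
# read.

#' Write / read a mutated-site table as TSV
#'
#' Columns `chrom`, `pos0` (0-based), `ref`, `alt`.
#'
#' @param sites a [MutatedSites] object.
#' @param path file path.
#' @return `readSiteTable` returns a [MutatedSites] object.
#' @export
writeSiteTable <- function(sites, path) {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   pos0 = start(sites) - 1L, ref = mcols(sites)$ref,
                   alt = mcols(sites)$alt)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  MutatedSites(df$chrom, df$pos0 + 1L, df$ref, df$alt)
}

#' Write / read classified alignments as TSV
#'
#' Columns `qname`, `chrom`, `pos0`, `len`, `strand`, `class`, `allele`,
#' `mm_raw`, `mm_corr`, `indels`, `ct5`, `ct3`.
#'
#' @param classified a [ClassifiedAlignments] object.
#' @param path file path.
#' @return `readClassified` returns a [ClassifiedAlignments] object.
#' @export
writeClassified <- function(classified, path) {
  df <- data.frame(qname = classified$qname, chrom = classified$seqname,
                   pos0 = classified$pos - 1L, len = classified$len,
                   strand = classified$strand, class = classified$class,
                   allele = classified$allele, mm_raw = classified$mmRaw,
                   mm_corr = classified$mmCorr, indels = classified$indels,
                   ct5 = as.integer(classified$ct5),
                   ct3 = as.integer(classified$ct3))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClassified
#' @export
readClassified <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  ClassifiedAlignments(data.frame(
    qname = df$qname, seqname = df$chrom, pos = df$pos0 + 1L, len = df$len,
    strand = df$strand, class = df$class, allele = df$allele,
    mmRaw = df$mm_raw, mmCorr = df$mm_corr, mmProp = df$mm_corr / df$len,
    indels = df$indels, ct5 = df$ct5 == 1L, ct3 = df$ct3 == 1L))
}

#' Write / read per-length spurious-fraction estimates as TSV
#'
#' Columns `len`, `filter`, `n_true`, `n_spur`, `M`, `n_true_corr`,
#' `n_spur_corr`, `frac`, `ci_lo`, `ci_hi`.
#'
#' @param estimates a data.frame from [fractionByLength].
#' @param path file path.
#' @return `readEstimates` returns the estimates data.frame.
#' @export
writeEstimates <- function(estimates, path) {
  df <- data.frame(len = estimates$len, filter = estimates$filter,
                   n_true = estimates$nTrue, n_spur = estimates$nSpur,
                   M = estimates$M, n_true_corr = estimates$nTrueCorr,
                   n_spur_corr = estimates$nSpurCorr, frac = estimates$frac,
                   ci_lo = estimates$ciLo, ci_hi = estimates$ciHi)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEstimates
#' @export
readEstimates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(len = df$len, filter = df$filter, nTrue = df$n_true,
             nSpur = df$n_spur, M = df$M, nTrueCorr = df$n_true_corr,
             nSpurCorr = df$n_spur_corr, frac = df$frac, ciLo = df$ci_lo,
             ciHi = df$ci_hi)
}

#' Write a length-cutoff report as JSON
#'
#' @param cutoffs list of results from [findLengthCutoff] (optionally named).
#' @param filter the filter the cutoffs were computed under.
#' @param path file path.
#' @export
writeCutoffReport <- function(cutoffs, filter, path) {
  if (!is.null(cutoffs$tau)) cutoffs <- list(cutoffs)
  recs <- lapply(cutoffs, function(co)
    list(filter = filter, tau = co$tau,
         L = if (is.na(co$L)) "not reached" else co$L,
         bases_L = co$basesAtL, bases_35 = co$basesAtBaseline,
         fold = co$fold))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write / read mappability tracks as BED plus a JSON sidecar
#'
#' One BED file per k (`mappability_k<k>.bed`, 0-based half-open intervals
#' of uniquely mappable start positions) and a `mappability.json` sidecar
#' recording the k-values, mismatch tolerance and per-sequence lengths.
#'
#' @param tracks a [MappabilityTracks] object.
#' @param dir output directory (created if needed).
#' @return `readMappabilityTracks` returns a [MappabilityTracks] object.
#' @export
writeMappabilityTracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ks <- tracks@kValues
  seqLens <- lapply(tracks@tracks[[1]], length)
  seqLens <- lapply(names(seqLens), function(sq)
    seqLens[[sq]] + ks[1] - 1L)
  names(seqLens) <- names(tracks@tracks[[1]])
  jsonlite::write_json(
    list(kValues = ks, maxMismatch = tracks@maxMismatch,
         seqLengths = seqLens),
    file.path(dir, "mappability.json"), auto_unbox = FALSE, digits = NA)
  for (k in ks) {
    rows <- list()
    for (sq in names(tracks@tracks[[as.character(k)]])) {
      flags <- tracks@tracks[[as.character(k)]][[sq]]
      if (!length(flags) || !any(flags)) next
      r <- rle(flags)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      rows[[sq]] <- data.frame(chrom = sq, start0 = starts[keep] - 1L,
                               end0 = ends[keep])
    }
    bed <- if (length(rows)) do.call(rbind, rows)
           else data.frame(chrom = character(0), start0 = integer(0),
                           end0 = integer(0))
    utils::write.table(bed, file.path(dir, sprintf("mappability_k%d.bed", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeMappabilityTracks
#' @export
readMappabilityTracks <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "mappability.json"),
                              simplifyVector = TRUE)
  ks <- as.integer(meta$kValues)
  seqLens <- unlist(meta$seqLengths)
  tracksList <- lapply(ks, function(k) {
    perSeq <- lapply(names(seqLens), function(sq) {
      n <- seqLens[[sq]] - k + 1L
      if (n < 1L) logical(0) else rep(FALSE, n)
    })
    names(perSeq) <- names(seqLens)
    f <- file.path(dir, sprintf("mappability_k%d.bed", k))
    if (file.exists(f) && file.size(f) > 0) {
      bed <- utils::read.delim(f, header = FALSE,
                               col.names = c("chrom", "start0", "end0"))
      for (j in seq_len(nrow(bed))) {
        sq <- as.character(bed$chrom[j])
        perSeq[[sq]][(bed$start0[j] + 1L):bed$end0[j]] <- TRUE
      }
    }
    perSeq
  })
  names(tracksList) <- as.character(ks)
  new("MappabilityTracks", kValues = ks, tracks = tracksList,
      maxMismatch = as.integer(meta$maxMismatch))
}

#' Read genotype and primate-allele tables
#'
#' Genotypes: TSV with columns `chrom`, `pos0`, `ref`, `alt`, `gt_mh`,
#' `gt_nea`, `gt_den`. Primate columns: TSV with `chrom`, `pos0` and one
#' column per primate. Both are returned 1-based in a `pos` column.
#'
#' @param path file path.
#' @return A data.frame.
#' @export
readGenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$pos <- df$pos0 + 1L
  df
}

#' @rdname readGenotypes
#' @export
readPrimateColumns <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "", ".", "-"))
  df$pos <- df$pos0 + 1L
  df$pos0 <- NULL
  df
}

#' Write / read an informative-site table as TSV
#'
#' Columns `chrom`, `pos0`, `anc`, `der`, `class`.
#'
#' @param sites a GRanges from [buildInformativeSites].
#' @param path file path.
#' @return `readInformativeSites` returns the GRanges.
#' @export
writeInformativeSites <- function(sites, path) {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   pos0 = start(sites) - 1L, anc = mcols(sites)$anc,
                   der = mcols(sites)$der, class = mcols(sites)$class)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeInformativeSites
#' @export
readInformativeSites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  GRanges(df$chrom, IRanges(df$pos0 + 1L, width = 1L), anc = df$anc,
          der = df$der, class = df$class)
}
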