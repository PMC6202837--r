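LINEAGE_CLASSES <- c("ModernHuman", "Neandertal", "Denisovan",
                     "NeandertalDenisovan")

#' Call the ancestral allele from a primate alignment column
#'
#' The ancestral state at a site is the allele shared by at least four of the
#' five aligned primate genomes; fewer than four informative (non-missing)
#' alleles, or no allele reaching four copies, yields `NA`.
#'
#' @param alleles character vector (or matrix with one row per site and one
#'   column per primate) of primate alleles; `NA` or `"."`, `"-"`, `"N"` mark
#'   missing data.
#' @param minAgree minimum number of agreeing primates (default 4).
#' @return The ancestral allele per site, or `NA`.
#' @examples
#' callAncestral(c("A", "A", "A", "A", "C"))  # "A"
#' callAncestral(c("A", "A", "A", "C", "C"))  # NA
#' @export
callAncestral <- function(alleles, minAgree = 4L) {
  one <- function(a) {
    a <- toupper(as.character(a))
    a <- a[a %in% DNA_BASES]
    if (length(a) < minAgree) return(NA_character_)
    tab <- table(a)
    top <- names(tab)[which.max(tab)]
    if (tab[[top]] >= minAgree) top else NA_character_
  }
  if (is.matrix(alleles) || is.data.frame(alleles)) {
    apply(as.matrix(alleles), 1L, one)
  } else {
    one(alleles)
  }
}

#' Sample one allele from each diploid genotype
#'
#' Genotypes are given as `"A/G"`-style strings (separator `/` or `|`); each
#' of the two alleles is drawn with probability one half. Missing genotypes
#' (`"./."` or `NA`) yield `NA`.
#'
#' @param gt character vector of diploid genotypes.
#' @param seed optional integer seed making the draw reproducible.
#' @return Character vector of sampled alleles.
#' @examples
#' sampleAllele(c("A/A", "A/G", "./."), seed = 1)
#' @export
sampleAllele <- function(gt, seed = NULL) {
  parts <- strsplit(toupper(as.character(gt)), "[/|]")
  withSeed(seed, {
    vapply(parts, function(p) {
      if (length(p) != 2L || !all(p %in% DNA_BASES)) return(NA_character_)
      if (p[1] == p[2]) p[1] else sample(p, 1L)
    }, character(1))
  })
}

#' Assign lineage-informative sites from sampled alleles
#'
#' Given one sampled allele per individual (modern human, Neandertal,
#' Denisovan) plus the ancestral allele, a site is informative when it is
#' biallelic across the four alleles and the set of derived-allele carriers
#' is one of: only the modern human (`ModernHuman`), only the Neandertal
#' (`Neandertal`), only the Denisovan (`Denisovan`), or both archaics but not
#' the modern human (`NeandertalDenisovan`). All other carrier patterns
#' (none, all three, modern human plus one archaic) are uninformative.
#'
#' @param mh,nea,den sampled alleles of the three individuals.
#' @param anc ancestral alleles.
#' @return A data.frame with columns `anc`, `der`, `class`; `class` is `NA`
#'   for uninformative sites.
#' @examples
#' classifyInformativeSite("A", "G", "A", "A")  # Neandertal, derived G
#' @export
classifyInformativeSite <- function(mh, nea, den, anc) {
  n <- max(length(mh), length(nea), length(den), length(anc))
  mh <- rep_len(toupper(mh), n); nea <- rep_len(toupper(nea), n)
  den <- rep_len(toupper(den), n); anc <- rep_len(toupper(anc), n)
  der <- rep(NA_character_, n)
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    al <- c(mh[i], nea[i], den[i], anc[i])
    if (any(is.na(al)) || !all(al %in% DNA_BASES)) next
    obs <- unique(al)
    if (length(obs) != 2L) next  # monomorphic or multiallelic
    d <- setdiff(obs, anc[i])
    carriers <- c(mh[i] == d, nea[i] == d, den[i] == d)
    cls[i] <- if (identical(carriers, c(TRUE, FALSE, FALSE))) "ModernHuman"
      else if (identical(carriers, c(FALSE, TRUE, FALSE))) "Neandertal"
      else if (identical(carriers, c(FALSE, FALSE, TRUE))) "Denisovan"
      else if (identical(carriers, c(FALSE, TRUE, TRUE))) "NeandertalDenisovan"
      else NA_character_
    if (!is.na(cls[i])) der[i] <- d
  }
  data.frame(anc = anc, der = der, class = cls)
}

#' Build the informative-site table from genotypes and primate columns
#'
#' @param genotypes data.frame with columns `chrom`, `pos` (1-based), and
#'   diploid genotypes `gt_mh`, `gt_nea`, `gt_den`.
#' @param primates data.frame with columns `chrom`, `pos` and five primate
#'   allele columns (all remaining columns are taken as primates).
#' @param seed integer seed for the genotype allele sampling.
#' @return A [GenomicRanges::GRanges] of informative sites with metadata
#'   columns `anc`, `der`, `class`.
#' @export
buildInformativeSites <- function(genotypes, primates, seed = NULL) {
  key <- function(d) paste(d$chrom, d$pos)
  m <- match(key(genotypes), key(primates))
  keep <- !is.na(m)
  gt <- genotypes[keep, , drop = FALSE]
  pcols <- setdiff(colnames(primates), c("chrom", "pos"))
  anc <- callAncestral(primates[m[keep], pcols, drop = FALSE])
  withSeed(seed, {
    mh <- sampleAllele(gt$gt_mh)
    nea <- sampleAllele(gt$gt_nea)
    den <- sampleAllele(gt$gt_den)
    info <- classifyInformativeSite(mh, nea, den, anc)
    ok <- !is.na(info$class)
    GRanges(gt$chrom[ok], IRanges(gt$pos[ok], width = 1L),
            anc = info$anc[ok], der = info$der[ok], class = info$class[ok])
  })
}

#' Derived-allele sharing per lineage class
#'
#' Iterates over read-site overlaps of alignments (against the unmutated
#' reference) with lineage-informative sites. Observations whose read base,
#' in read orientation, is a `T` within the three terminal positions of
#' either read end are discarded to minimise the impact of deamination;
#' observations showing neither the ancestral nor the derived allele are
#' discarded as errors. For each class the percentage of derived-allele
#' observations is reported with a binomial confidence interval.
#'
#' @param alns alignment records (see [alignmentRecords]), deduplicated and
#'   length-filtered upstream or via `minLen`.
#' @param sites informative sites as returned by [buildInformativeSites].
#' @param minLen optional minimum read length applied before counting.
#' @param level confidence level (default 0.90).
#' @return A data.frame with one row per lineage class: `class`, `n`, `k`,
#'   `pct`, `ciLo`, `ciHi` (percent scale; `NA` where `n = 0`), plus an
#'   attribute `nRemovedTerminalT` counting discarded terminal-T
#'   observations.
#' @export
derivedSharing <- function(alns, sites, minLen = NULL, level = 0.90) {
  if (!is.null(minLen)) alns <- alns[alns$len >= minLen, , drop = FALSE]
  spanGr <- GRanges(alns$seqname, IRanges(alns$start, alns$end))
  ov <- GenomicRanges::findOverlaps(spanGr, sites)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  nRemoved <- 0L
  obs <- data.frame(class = character(0), derived = logical(0))
  if (length(qh)) {
    rows <- lapply(seq_along(qh), function(j) {
      i <- qh[j]; s <- sh[j]
      qpos <- refOffsetToQuery(alns$cigar[i], start(sites)[s] - alns$start[i])
      if (is.na(qpos)) return(NULL)
      base <- substr(alns$seq[i], qpos, qpos)
      len <- alns$len[i]
      pos5 <- if (alns$strand[i] == "+") qpos else len - qpos + 1L
      readBase <- if (alns$strand[i] == "+") base else complementBase(base)
      terminal <- pos5 <= 3L || pos5 >= len - 2L
      if (readBase == "T" && terminal) return("removedT")
      anc <- mcols(sites)$anc[s]; der <- mcols(sites)$der[s]
      if (!base %in% c(anc, der)) return(NULL)
      data.frame(class = mcols(sites)$class[s], derived = base == der)
    })
    nRemoved <- sum(vapply(rows, identical, logical(1), "removedT"))
    rows <- Filter(is.data.frame, rows)
    if (length(rows)) obs <- do.call(rbind, rows)
  }
  out <- do.call(rbind, lapply(LINEAGE_CLASSES, function(cl) {
    sel <- obs$class == cl
    n <- sum(sel); k <- sum(obs$derived[sel])
    if (n > 0) {
      # exact (Clopper-Pearson) binomial interval
      ci <- as.numeric(stats::binom.test(k, n,
                                         conf.level = level)$conf.int) * 100
      data.frame(class = cl, n = n, k = k, pct = 100 * k / n,
                 ciLo = ci[1], ciHi = ci[2])
    } else {
      data.frame(class = cl, n = 0L, k = 0L, pct = NA_real_,
                 ciLo = NA_real_, ciHi = NA_real_)
    }
  }))
  attr(out, "nRemovedTerminalT") <- nRemoved
  out
}

# map a 0-based reference offset within an alignment to the 1-based query
# position; NA when the site falls in a deletion
refOffsetToQuery <- function(cigar, offset) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  refPos <- 0L; qPos <- 0L
  for (j in seq_along(ops)) {
    op <- ops[j]; w <- lens[j]
    if (op %in% c("M", "=", "X")) {
      if (offset < refPos + w) return(qPos + (offset - refPos) + 1L)
      refPos <- refPos + w; qPos <- qPos + w
    } else if (op == "D" || op == "N") {
      if (offset < refPos + w) return(NA_integer_)
      refPos <- refPos + w
    } else if (op %in% c("I", "S")) {
      qPos <- qPos + w
    }
  }
  NA_integer_
}

#' Fisher exact test on derived-allele sharing of two lineages
#'
#' Two-sided Fisher exact test comparing the derived-sharing counts of two
#' classes (Neandertal vs Denisovan by default) as a 2x2 table
#' `[(k1, n1 - k1), (k2, n2 - k2)]`. Degenerate tables (a zero margin) give
#' p = 1.
#'
#' @param sharing a sharing table from [derivedSharing], or `NULL` when the
#'   counts are given directly.
#' @param classes the two classes compared (default Neandertal, Denisovan).
#' @param k1,n1,k2,n2 direct counts (used when `sharing` is `NULL`).
#' @return The two-sided p-value.
#' @examples
#' lineageTest(k1 = 9, n1 = 10, k2 = 1, n2 = 10)
#' @export
lineageTest <- function(sharing = NULL,
                        classes = c("Neandertal", "Denisovan"),
                        k1 = NULL, n1 = NULL, k2 = NULL, n2 = NULL) {
  if (!is.null(sharing)) {
    r1 <- sharing[sharing$class == classes[1], ]
    r2 <- sharing[sharing$class == classes[2], ]
    k1 <- r1$k; n1 <- r1$n; k2 <- r2$k; n2 <- r2$n
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Multiplicity adjustment across a family of lineage tests
#'
#' @param p numeric vector of p-values (one per sample x cutoff combination).
#' @param method adjustment method passed to [stats::p.adjust]
#'   (default `"BH"`).
#' @return Adjusted p-values.
#' @export
adjustLineagePValues <- function(p, method = "BH") {
  stats::p.adjust(p, method = method)
}
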