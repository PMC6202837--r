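# a tiny handcrafted reference pair: original vs one mutated site
miniRefs <- function() {
  orig <- Biostrings::DNAStringSet(c(
    chr1 = "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"))
  sites <- MutatedSites("chr1", 21L, "A", "G")  # A at position 21 -> G
  mut <- Biostrings::DNAStringSet(c(
    chr1 = paste0(substr(as.character(orig[[1]]), 1, 20), "G",
                  substr(as.character(orig[[1]]), 22, 40))))
  list(orig = orig, mut = mut, sites = sites)
}

test_that("site classification applies the strand guard and allele rule", {
  # forward strand, A->G site, read shows A: true hominin
  expect_identical(classifyAtSite("A", "+", "A", "G")$class, "TRUE_HOMININ")
  expect_identical(classifyAtSite("A", "+", "A", "G")$allele, "reference")
  # mutated or third allele: spurious
  expect_identical(classifyAtSite("G", "+", "A", "G")$class, "SPURIOUS")
  expect_identical(classifyAtSite("G", "+", "A", "G")$allele, "mutated")
  expect_identical(classifyAtSite("T", "+", "A", "G")$allele, "other")
  # forward guard: mutated state C
  expect_identical(classifyAtSite("A", "+", "A", "C")$class,
                   "EXCLUDED_STRAND")
  # forward guard: original state C
  expect_identical(classifyAtSite("C", "+", "C", "T")$class,
                   "EXCLUDED_STRAND")
  # reverse guard: original state G
  expect_identical(classifyAtSite("G", "-", "G", "A")$class,
                   "EXCLUDED_STRAND")
  # reverse guard: mutated state G
  expect_identical(classifyAtSite("A", "-", "A", "G")$class,
                   "EXCLUDED_STRAND")
  # reverse orientation without G involved is not guarded
  expect_identical(classifyAtSite("A", "-", "A", "T")$class, "TRUE_HOMININ")
  # unknown base at the site
  expect_identical(classifyAtSite("N", "+", "A", "G")$class, "NO_SITE")
  # deletion over the site
  expect_identical(classifyAtSite("-", "+", "A", "G")$class, "NO_SITE")
})

test_that("the guard fires on exactly the enumerated site/strand combinations", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(ref = bases, alt = bases, strand = c("+", "-"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  got <- classifyAtSite("A", combos$strand, combos$ref, combos$alt)$class ==
    "EXCLUDED_STRAND"
  want <- ifelse(combos$strand == "+",
                 combos$ref == "C" | combos$alt == "C",
                 combos$ref == "G" | combos$alt == "G")
  expect_identical(got, want)
})

test_that("mismatch correction subtracts one per non-mutated-allele site", {
  # true alignment (original base), 2 raw mismatches, 1 site -> 1
  expect_identical(correctedMismatches(2, 1, 30)$mmCorr, 1)
  # spurious carrying the mutated allele: no subtraction
  expect_identical(correctedMismatches(2, 0, 30)$mmCorr, 2)
  # floors at zero
  expect_identical(correctedMismatches(0, 1, 30)$mmCorr, 0)
  expect_equal(correctedMismatches(3, 1, 40)$mmProp, 2 / 40)
})

test_that("raw mismatches and indel events are read off the alignment", {
  r <- miniRefs()
  alns <- alignmentRecords(
    qname = c("m0", "m2", "ins", "del"),
    seqname = "chr1",
    start = c(1L, 1L, 11L, 11L),
    strand = "+",
    cigar = c("25M", "25M", "10M1I9M", "5M2D10M1I5M"),
    seq = c(substr(as.character(r$mut[[1]]), 1, 25),
            paste0("TT", substr(as.character(r$mut[[1]]), 3, 25)),
            paste0(substr(as.character(r$mut[[1]]), 11, 20), "A",
                   substr(as.character(r$mut[[1]]), 21, 29)),
            paste0(substr(as.character(r$mut[[1]]), 11, 15),
                   substr(as.character(r$mut[[1]]), 18, 27), "A",
                   substr(as.character(r$mut[[1]]), 28, 32))))
  expect_identical(rawMismatches(alns, r$mut), c(0L, 2L, 0L, 0L))
  expect_identical(countIndels(alns$cigar), c(0L, 0L, 1L, 2L))
})

test_that("terminal C-to-T flags respect read orientation", {
  orig <- Biostrings::DNAStringSet(c(chr1 = "CCGTACGTACGTACGTACGTACGTACGG"))
  # forward read, reference C at first position, read shows T
  fwd <- alignmentRecords("f1", "chr1", 1L, "+", "24M",
                          paste0("T", substr(as.character(orig[[1]]), 2, 24)))
  expect_identical(unlist(terminalCtFlags(fwd, orig)),
                   c(ct5 = TRUE, ct3 = FALSE))
  # reverse read: reference-forward G at the last aligned base reads A,
  # i.e. a 5' C-to-T in read orientation
  rev <- alignmentRecords("r1", "chr1", 5L, "-", "24M",
                          paste0(substr(as.character(orig[[1]]), 5, 27), "A"))
  expect_identical(unlist(terminalCtFlags(rev, orig)),
                   c(ct5 = TRUE, ct3 = FALSE))
  # read identical to reference: no flags
  same <- alignmentRecords("s1", "chr1", 3L, "+", "20M",
                           substr(as.character(orig[[1]]), 3, 22))
  expect_identical(unlist(terminalCtFlags(same, orig)),
                   c(ct5 = FALSE, ct3 = FALSE))
  # terminal base inside an insertion has no reference counterpart
  ins <- alignmentRecords("i1", "chr1", 2L, "+", "1I20M",
                          paste0("T", substr(as.character(orig[[1]]), 2, 21)))
  expect_false(terminalCtFlags(ins, orig)$ct5)
})

test_that("substitution spectrum counts per read position", {
  orig <- Biostrings::DNAStringSet(c(chr1 = strrep("C", 10)))
  seqs <- c(rep("TCCCC", 4), rep("CCCCC", 6))
  alns <- alignmentRecords(sprintf("q%d", 1:10), "chr1", 1L, "+", "5M", seqs)
  sp <- substitutionSpectrum(alns, orig)
  ct1 <- sp[sp$sub == "C>T" & sp$pos == 1, ]
  expect_identical(ct1$count, 4L)
  expect_identical(ct1$denom, 10L)
  expect_equal(ct1$freq, 0.4)
  # no reference A anywhere: frequency undefined
  expect_true(is.na(sp[sp$sub == "A>G" & sp$pos == 1, "freq"]))
  # mismatch-free alignments: all frequencies 0 where defined
  clean <- alignmentRecords("c", "chr1", 1L, "+", "5M", "CCCCC")
  sp0 <- substitutionSpectrum(clean, orig)
  expect_true(all(sp0$freq[!is.na(sp0$freq)] == 0))
})

test_that("simulated deamination produces a terminal-heavy C>T spectrum", {
  g <- testGenome(4000, seed = 31)
  cfg <- simConfig(divergence = 0, deamProb = 0.3, deamDecay = 0.5,
                   seed = 17)
  reads <- simulateEndogenous(g, 3000, cfg)
  sp <- substitutionSpectrum(reads, g, maxPos = 10)
  ct <- sp[sp$sub == "C>T", ]
  # terminal rate near p0, decaying inward (binomial error margins)
  expect_gt(ct$freq[ct$pos == 1], 0.25)
  expect_lt(ct$freq[ct$pos == 4], 0.12)
  expect_gt(ct$freq[ct$pos == 1], 2 * ct$freq[ct$pos == 3])
  # non-C>T substitutions stay at background zero (divergence 0)
  other <- sp[!sp$sub %in% c("C>T"), ]
  expect_true(all(other$count == 0))
})

test_that("full classification partitions site-overlapping alignments", {
  g <- testGenome(6000, seed = 41)
  mutres <- mutateReference(g, selectMutationSites(g), seed = 6)
  cfg <- simConfig(seed = 19)
  reads <- simulateEndogenous(g, 1500, cfg)
  ca <- classifyAlignments(reads, mutres$sites, mutres$genome,
                           originalGenome = g)
  expect_s4_class(ca, "ClassifiedAlignments")
  expect_true(all(ca$class %in% c("TRUE_HOMININ", "SPURIOUS",
                                  "EXCLUDED_STRAND", "NO_SITE")))
  overl <- ca[ca$class %in% c("TRUE_HOMININ", "SPURIOUS"), ]
  # endogenous reads overwhelmingly carry the original base
  expect_gt(mean(overl$class == "TRUE_HOMININ"), 0.97)
  # corrected mismatch counts never negative; zero-mismatch true alignments
  # dominate at divergence 0.002
  expect_true(all(ca$mmCorr >= 0))
  expect_gt(mean(overl$mmCorr == 0), 0.5)
})

test_that("classification uses the 5'-most non-guarded site", {
  orig <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGTTAGTAC", 20)))
  sites <- MutatedSites(c("chr1", "chr1"), c(21L, 101L), c("A", "A"),
                        c("G", "T"))
  mutseq <- as.character(orig[[1]])
  substr(mutseq, 21, 21) <- "G"; substr(mutseq, 101, 101) <- "T"
  mut <- Biostrings::DNAStringSet(c(chr1 = mutseq))
  # read spanning both sites, showing the mutated allele at 21 and the
  # original at 101: classified by site 21 on the forward strand
  rseq <- mutseq
  substr(rseq, 101, 101) <- "A"
  fwd <- alignmentRecords("f", "chr1", 11L, "+", "100M",
                          substr(rseq, 11, 110))
  caF <- classifyAlignments(fwd, sites, mut, originalGenome = orig)
  expect_identical(caF$class, "SPURIOUS")
  expect_identical(caF$pos, 21L)
  # the same span on the reverse strand classifies by site 101 (read 5' end)
  rev <- alignmentRecords("r", "chr1", 11L, "-", "100M",
                          substr(rseq, 11, 110))
  caR <- classifyAlignments(rev, sites, mut, originalGenome = orig)
  expect_identical(caR$pos, 101L)
  expect_identical(caR$class, "TRUE_HOMININ")
})

test_that("mappability filter marks unmappable alignments", {
  core <- simulateReference(300, seed = 51, name = "chr1")
  s <- as.character(core[[1]])
  dup <- paste0(s, substr(s, 1, 60))  # 60-bp duplicated tail
  g <- Biostrings::DNAStringSet(c(chr1 = dup))
  tr <- buildMappabilityTracks(g, kValues = c(20L, 23L, 26L, 29L, 32L, 35L))
  sites <- MutatedSites("chr1", 25L, substr(s, 25, 25),
                        setdiff(c("A", "C", "G", "T"),
                                c(substr(s, 25, 25), "C", "G"))[1])
  aln <- alignmentRecords(c("inDup", "uniq"), "chr1", c(10L, 150L), "+",
                          c("30M", "30M"),
                          c(substr(dup, 10, 39), substr(dup, 150, 179)))
  ca <- classifyAlignments(aln, sites, g, tracks = tr)
  expect_identical(ca$class[ca$qname == "inDup"], "UNMAPPABLE")
  expect_false(ca$class[ca$qname == "uniq"] == "UNMAPPABLE")
})

test_that("reads shorter than 20 bp are discarded", {
  g <- testGenome(1000, seed = 61)
  aln <- alignmentRecords(c("short", "ok"), "chr1", c(1L, 50L), "+",
                          c("15M", "25M"),
                          c(substr(as.character(g[[1]]), 1, 15),
                            substr(as.character(g[[1]]), 50, 74)))
  sites <- MutatedSites("chr1", 60L, "A", "T")
  ca <- classifyAlignments(aln, sites, g)
  expect_identical(nrow(ca), 1L)
  expect_identical(ca$qname, "ok")
  expect_error(classifyAlignments(aln[aln$len < 20, ], sites, g),
               "no alignments")
})

test_that("contaminant features separate from endogenous features", {
  cfg <- simConfig(pSpur = 0.5, seed = 23)
  mix <- simulateClassifiedMixture(10000, cfg)
  spur <- mix[mix$origin == "contaminant", ]
  endo <- mix[mix$origin == "endogenous", ]
  expect_gt(mean(spur$mmProp), mean(endo$mmProp))
  expect_gt(mean(spur$indels), mean(endo$indels))
  expect_lt(stats::wilcox.test(spur$mmProp, endo$mmProp)$p.value, 0.01)
  expect_lt(stats::wilcox.test(spur$indels, endo$indels)$p.value, 0.01)
})
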