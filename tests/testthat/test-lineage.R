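test_that("ancestral calls require four agreeing primates", {
  expect_identical(callAncestral(c("A", "A", "A", "A", "A")), "A")
  expect_identical(callAncestral(c("A", "A", "A", "A", "C")), "A")
  expect_true(is.na(callAncestral(c("A", "A", "A", "C", "C"))))
  # fewer than four informative alleles
  expect_true(is.na(callAncestral(c("A", "A", "A", NA, NA))))
  expect_identical(callAncestral(c("A", "A", "A", "A", NA)), "A")
  # matrix input, row-wise
  m <- rbind(c("G", "G", "G", "G", "T"), c("C", "T", "C", "T", "C"))
  expect_identical(callAncestral(m), c("G", NA))
})

test_that("allele sampling is fair and reproducible", {
  expect_identical(sampleAllele("A/A"), "A")
  expect_true(is.na(sampleAllele("./.")))
  expect_true(is.na(sampleAllele(NA)))
  draws <- vapply(1:10000, function(i) sampleAllele("A/G", seed = i),
                  character(1))
  expect_lt(abs(mean(draws == "A") - 0.5), 0.02)
  expect_identical(sampleAllele(c("A/G", "C/T"), seed = 99),
                   sampleAllele(c("A/G", "C/T"), seed = 99))
})

test_that("carrier patterns map onto the four lineage classes exhaustively", {
  # enumerate all 8 derived/ancestral carrier patterns at an A->G site
  pats <- expand.grid(mh = c(FALSE, TRUE), nea = c(FALSE, TRUE),
                      den = c(FALSE, TRUE))
  al <- function(x) ifelse(x, "G", "A")
  got <- classifyInformativeSite(al(pats$mh), al(pats$nea), al(pats$den),
                                 "A")$class
  want <- rep(NA_character_, 8)
  want[pats$mh & !pats$nea & !pats$den] <- "ModernHuman"
  want[!pats$mh & pats$nea & !pats$den] <- "Neandertal"
  want[!pats$mh & !pats$nea & pats$den] <- "Denisovan"
  want[!pats$mh & pats$nea & pats$den] <- "NeandertalDenisovan"
  expect_identical(got, want)
  # exactly four patterns are informative
  expect_identical(sum(!is.na(got)), 4L)
  # triallelic and missing-data sites are uninformative
  expect_true(is.na(classifyInformativeSite("C", "G", "A", "A")$class))
  expect_true(is.na(classifyInformativeSite(NA, "G", "A", "A")$class))
  # derived allele is the non-ancestral one
  r <- classifyInformativeSite("A", "G", "A", "A")
  expect_identical(r$der, "G")
  expect_identical(r$class, "Neandertal")
})

test_that("Fisher exact p equals hypergeometric enumeration on all small tables", {
  # all 2x2 tables with every margin at most 30
  grid <- expand.grid(k1 = 0:15, n1 = 1:15, k2 = 0:15, n2 = 1:15)
  grid <- grid[grid$k1 <= grid$n1 & grid$k2 <= grid$n2, ]
  # margins: rows n1, n2 <= 15 here; columns k1+k2 and rest <= 30 follow
  set.seed(5)
  grid <- grid[sample(nrow(grid), 4000), ]  # dense random subsample
  pGot <- mapply(function(k1, n1, k2, n2)
    lineageTest(k1 = k1, n1 = n1, k2 = k2, n2 = n2),
    grid$k1, grid$n1, grid$k2, grid$n2)
  pOrc <- mapply(oracleFisher, grid$k1, grid$n1, grid$k2, grid$n2)
  expect_equal(pGot, pOrc, tolerance = 1e-10)
  # spot checks
  expect_equal(lineageTest(k1 = 5, n1 = 10, k2 = 5, n2 = 10), 1)
  expect_equal(lineageTest(k1 = 9, n1 = 10, k2 = 1, n2 = 10),
               202 / 184756, tolerance = 1e-12)
  # identical proportions give p = 1 at any size
  expect_equal(lineageTest(k1 = 6, n1 = 12, k2 = 13, n2 = 26), 1,
               tolerance = 1e-9)
  # degenerate margins
  expect_identical(lineageTest(k1 = 0, n1 = 10, k2 = 0, n2 = 10), 1)
  expect_identical(lineageTest(k1 = 10, n1 = 10, k2 = 10, n2 = 10), 1)
})

test_that("derived sharing counts read-site overlaps with the terminal-T rule", {
  # reference with informative sites every 10 bp
  g <- testGenome(4000, seed = 81)
  s <- as.character(g[[1]])
  pos <- seq(25, 3975, by = 40)  # spaced so a 25-bp read covers one site
  anc <- substr(rep(s, length(pos)), pos, pos)
  keep <- anc %in% c("A", "C", "G")  # leave T out to keep the rule separate
  pos <- pos[keep]; anc <- anc[keep]
  der <- ifelse(anc == "A", "G", "A")
  sites <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(pos, width = 1),
                                  anc = anc, der = der,
                                  class = rep(c("Neandertal", "Denisovan"),
                                              length.out = length(pos)))
  # 20 reads overlapping Neandertal sites, 7 carrying the derived allele
  neaSites <- sites[S4Vectors::mcols(sites)$class == "Neandertal"][1:20]
  mkRead <- function(i, derived) {
    p <- GenomicRanges::start(neaSites)[i]
    sq <- substr(s, p - 10, p + 14)  # site at query position 11 of 25
    if (derived)
      substr(sq, 11, 11) <- S4Vectors::mcols(neaSites)$der[i]
    alignmentRecords(sprintf("n%02d", i), "chr1", p - 10L, "+", "25M", sq)
  }
  alns <- do.call(rbind, lapply(1:20, function(i) mkRead(i, i <= 7)))
  sh <- derivedSharing(alns, sites)
  nea <- sh[sh$class == "Neandertal", ]
  expect_identical(nea$n, 20L)
  expect_identical(nea$k, 7L)
  expect_equal(nea$pct, 35)
  expect_true(nea$ciLo < 35 & nea$ciHi > 35)
  # no observations for the unseen classes
  expect_identical(sh$n[sh$class == "ModernHuman"], 0L)
  expect_true(is.na(sh$pct[sh$class == "ModernHuman"]))
})

test_that("terminal T observations are discarded and accounted for", {
  s <- strrep("ACGTTAGCAC", 10)
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  # one informative A/T site placed at the read's penultimate position
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(24, width = 1),
                                 anc = substr(s, 24, 24), der = "T",
                                 class = "Neandertal")
  rseq <- substr(s, 1, 25)
  substr(rseq, 24, 24) <- "T"  # derived, but a terminal T
  aln <- alignmentRecords("t1", "chr1", 1L, "+", "25M", rseq)
  sh <- derivedSharing(aln, site)
  expect_identical(sh$n[sh$class == "Neandertal"], 0L)
  expect_identical(attr(sh, "nRemovedTerminalT"), 1L)
  # the same site observed mid-read is kept: bookkeeping is conserved
  aln2 <- alignmentRecords("t2", "chr1", 14L, "+", "25M",
                           {x <- substr(s, 14, 38); substr(x, 11, 11) <- "T"; x})
  sh2 <- derivedSharing(aln2, site)
  expect_identical(sh2$n[sh2$class == "Neandertal"], 1L)
  expect_identical(sh2$k[sh2$class == "Neandertal"], 1L)
  expect_identical(attr(sh2, "nRemovedTerminalT"), 0L)
  # a read base that is neither ancestral nor derived is discarded as error
  aln3 <- alignmentRecords("t3", "chr1", 14L, "+", "25M",
                           {x <- substr(s, 14, 38)
                            substr(x, 11, 11) <- setdiff(c("C", "G"),
                                                         substr(s, 24, 24))[1]
                            x})
  sh3 <- derivedSharing(aln3, site)
  expect_identical(sh3$n[sh3$class == "Neandertal"], 0L)
})

test_that("informative-site pipeline recovers known sharing on simulation", {
  # genome carrying Neandertal-derived alleles shared by the sample at a
  # known rate q
  q <- 0.4
  nSites <- 60
  cover <- 0
  hits <- 0
  set.seed(3000)
  repSeeds <- sample.int(1e6, 20)  # decorrelated replicate seeds
  for (seedi in repSeeds) {
    set.seed(seedi)
    g <- simulateReference(6100, seed = seedi + 1L, name = "chr1")
    s <- as.character(g[[1]])
    pos <- seq(50, 6000, by = 100)[1:nSites]
    anc <- substr(rep(s, nSites), pos, pos)
    der <- vapply(anc, function(a) sample(setdiff(c("A", "C", "G", "T"), a),
                                          1), character(1))
    sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1),
                                    anc = anc, der = der,
                                    class = "Neandertal")
    # sample genome: derived at a random q-fraction of sites
    isDer <- runif(nSites) < q
    gs <- s
    for (i in which(isDer)) substr(gs, pos[i], pos[i]) <- der[i]
    reads <- do.call(rbind, lapply(seq_len(nSites), function(i) {
      st <- pos[i] - 12L
      alignmentRecords(sprintf("r%03d", i), "chr1", st, "+", "30M",
                       substr(gs, st, st + 29))
    }))
    sh <- derivedSharing(reads, sites)
    nea <- sh[sh$class == "Neandertal", ]
    # terminal-T removals make n < nSites occasionally; CI covers 100q?
    if (!is.na(nea$pct)) {
      hits <- hits + 1
      if (nea$ciLo <= 100 * q && 100 * q <= nea$ciHi)
        cover <- cover + 1
    }
  }
  expect_gte(hits, 18)
  expect_gte(cover / hits, 0.85)
})

test_that("BH adjustment is applied across the test family", {
  p <- c(0.001, 0.02, 0.04, 0.5)
  expect_equal(adjustLineagePValues(p), stats::p.adjust(p, "BH"))
})
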