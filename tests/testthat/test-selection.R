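test_that("NG86 site counts match a genetic-code enumeration oracle", {
  s <- ng86Sites("TTT")
  expect_equal(unname(s["s"]), 1 / 3)
  expect_equal(unname(ng86Sites("ATG")["s"]), 0)
  expect_error(ng86Sites("TAA"), "stop")
  skip_if_not_installed("seqinr")
  for (cd in SENSE_CODONS) {
    got <- ng86Sites(cd)
    expect_equal(unname(got["s"]), oracleNg86S(cd), tolerance = 1e-12,
                 label = paste("s of", cd))
    expect_equal(unname(got["s"] + got["n"]), 3)
  }
})

test_that("pairwise NG86 reproduces the worked example with JC correction", {
  r <- ng86Pair("TTTAAAGGG", "TTCAAAGGG")
  expect_equal(r$S, 5 / 3, tolerance = 1e-12)
  expect_equal(r$N, 9 - 5 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 0.6, tolerance = 1e-12)
  expect_equal(r$dS, -0.75 * log(1 - 0.8), tolerance = 1e-12)
  expect_equal(r$dN, 0)
  # identical sequences: zero differences, undefined ratio
  r0 <- ng86Pair("TTTAAAGGG", "TTTAAAGGG")
  expect_equal(r0$Sd + r0$Nd, 0)
  expect_true(is.na(r0$dNdS))
  expect_error(ng86Pair("TTT", "TTTAAA"), "mismatch")
  expect_error(ng86Pair("TAATTT", "TAATTC"), "stop")
})

test_that("pathway averaging matches brute-force ordering enumeration", {
  skip_if_not_installed("seqinr")
  # symmetry plus conservation on a spread of multi-difference codon pairs
  set.seed(13)
  pairs2 <- list()
  for (i in 1:150) {
    ca <- sample(SENSE_CODONS, 1); cb <- sample(SENSE_CODONS, 1)
    k <- sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (k >= 1) pairs2[[length(pairs2) + 1]] <- c(ca, cb)
  }
  for (pr in pairs2) {
    a <- ng86Pair(paste0(pr[1]), paste0(pr[2]))
    b <- ng86Pair(paste0(pr[2]), paste0(pr[1]))
    expect_equal(a$Sd, b$Sd, tolerance = 1e-12)
    want <- oraclePathways(pr[1], pr[2])
    expect_equal(a$Sd, unname(want["sd"]), tolerance = 1e-12,
                 label = paste(pr[1], pr[2]))
    expect_equal(a$Nd, unname(want["nd"]), tolerance = 1e-12)
    k <- sum(strsplit(pr[1], "")[[1]] != strsplit(pr[2], "")[[1]])
    expect_equal(a$Sd + a$Nd, k, tolerance = 1e-12)
  }
})

test_that("between-group dN/dS distinguishes synonymous from replacement", {
  # two groups separated by one synonymous fixed difference
  seqs <- c(B1 = "TTTAAAGGG", B2 = "TTTAAAGGG",
            R1 = "TTCAAAGGG", R2 = "TTCAAAGGG")
  g <- c(B1 = "Blue", B2 = "Blue", R1 = "Red", R2 = "Red")
  r <- geneGroupDnds(seqs, g)
  expect_equal(r$meanBetween, 0)
  expect_false(r$flagged)
  # a replacement fixed difference instead: dS = 0, ratio undefined
  seqs2 <- c(B1 = "TTTAAAGGG", B2 = "TTTAAAGGG",
             R1 = "TGTAAAGGG", R2 = "TGTAAAGGG")
  r2 <- geneGroupDnds(seqs2, g)
  expect_true(is.na(r2$meanBetween))
  # the mean is taken over defined pairs only
  expect_true(all(c("between", "dNdS") %in% colnames(r$pairs)))
})

test_that("the McDonald-Kreitman table counts codon changes by class", {
  # build a gene with known Dn, Ds, Pn, Ps on 4+4 strains
  # fixed nonsyn: AAA (Lys) vs GAA (Glu); fixed syn: GGA vs GGC (Gly)
  # poly nonsyn: AAA/GAA inside group 1; poly syn: GGA/GGC inside group 1
  cods <- function(fn, fs, pn, ps) {
    g1 <- character(0); g2 <- character(0)
    for (i in seq_len(fn)) { g1 <- c(g1, "AAA"); g2 <- c(g2, "GAA") }
    for (i in seq_len(fs)) { g1 <- c(g1, "GGA"); g2 <- c(g2, "GGC") }
    for (i in seq_len(pn)) { g1 <- c(g1, "AAA"); g2 <- c(g2, "AAA") }
    for (i in seq_len(ps)) { g1 <- c(g1, "GGA"); g2 <- c(g2, "GGA") }
    list(g1 = g1, g2 = g2)
  }
  cc <- cods(10, 5, 2, 1)
  nC <- length(cc$g1)
  mk1 <- function(v, flip) {
    # flip: indices of polymorphic codons to toggle in the first strain
    out <- v
    out[flip] <- ifelse(out[flip] == "AAA", "GAA",
                        ifelse(out[flip] == "GGA", "GGC", out[flip]))
    out
  }
  polyN <- 15 + seq_len(2); polyS <- 17 + 1
  s1 <- mk1(cc$g1, c(polyN, polyS)); s234 <- cc$g1
  aln <- c(a1 = paste(s1, collapse = ""),
           a2 = paste(s234, collapse = ""),
           a3 = paste(s234, collapse = ""),
           a4 = paste(s234, collapse = ""),
           b1 = paste(cc$g2, collapse = ""),
           b2 = paste(cc$g2, collapse = ""),
           b3 = paste(cc$g2, collapse = ""),
           b4 = paste(cc$g2, collapse = ""))
  g <- setNames(rep(c("Blue", "Red"), each = 4), names(aln))
  mk <- mkTest(aln, g)
  expect_equal(mk$Dn, 10)
  expect_equal(mk$Ds, 5)
  expect_equal(mk$Pn, 2)
  expect_equal(mk$Ps, 1)
  expect_equal(mk$NI, (2 / 1) / (10 / 5))
  expect_equal(mk$p, 1.0)
  # Ds = 0 leaves NI undefined
  cc0 <- cods(3, 0, 1, 2)
  s1b <- mk1(cc0$g1, c(4, 5, 6))
  aln0 <- c(a1 = paste(s1b, collapse = ""), a2 = paste(cc0$g1, collapse = ""),
            b1 = paste(cc0$g2, collapse = ""), b2 = paste(cc0$g2, collapse = ""))
  g0 <- setNames(rep(c("Blue", "Red"), each = 2), names(aln0))
  expect_true(is.na(mkTest(aln0, g0)$NI))
})

test_that("the Fisher p-value equals direct hypergeometric enumeration", {
  cods <- function(fn, fs, pn, ps, flipIdx) {
    g1 <- c(rep("AAA", fn), rep("GGA", fs), rep("AAA", pn), rep("GGA", ps))
    g2 <- c(rep("GAA", fn), rep("GGC", fs), rep("AAA", pn), rep("GGA", ps))
    s1 <- g1
    s1[flipIdx] <- ifelse(s1[flipIdx] == "AAA", "GAA", "GGC")
    list(s1 = s1, g1 = g1, g2 = g2)
  }
  # Dn=20, Ds=2, Pn=2, Ps=20
  cc <- cods(20, 2, 2, 20, flipIdx = 23:44)
  aln <- c(a1 = paste(cc$s1, collapse = ""), a2 = paste(cc$g1, collapse = ""),
           b1 = paste(cc$g2, collapse = ""), b2 = paste(cc$g2, collapse = ""))
  g <- setNames(c("Blue", "Blue", "Red", "Red"), names(aln))
  mk <- mkTest(aln, g)
  expect_equal(mk$Dn, 20); expect_equal(mk$Ds, 2)
  expect_equal(mk$Pn, 2); expect_equal(mk$Ps, 20)
  expect_equal(mk$NI, 0.01)
  expect_equal(mk$p, oracleFisherP(20, 2, 2, 20), tolerance = 1e-9)
})

test_that("the MK Fisher p-value is a valid (conservative) test under neutrality", {
  # the exact two-sided p-value is discrete, with a large atom at 1 when
  # the observed table is the modal one; validity (P(p <= a) <= a) is the
  # calibration property a discrete exact test can and must satisfy
  set.seed(909)
  pc <- simulationParams(L = 900, thetaSite = 0.02, rhoSite = 0,
                         coding = TRUE)
  pvals <- numeric(0)
  for (g in 1:150) {
    tg <- simulateTwoGroupTree()
    sim <- simulateAlignment(tg$tree, drawEvents(tg$tree, pc), pc)
    mk <- mkTest(sim$alignment, tg$groups)
    if (!is.na(mk$p)) pvals <- c(pvals, mk$p)
  }
  expect_gt(length(pvals), 120)
  for (a in c(0.01, 0.05, 0.1, 0.25)) {
    se <- sqrt(a * (1 - a) / length(pvals))
    expect_lte(mean(pvals <= a), a + 3 * se)
  }
})
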