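strains10 <- c(paste0("B", 1:7), paste0("R", 1:3))
groups10 <- setNames(rep(c("Blue", "Red"), c(7, 3)), strains10)

test_that("SNP extraction drops gaps, ambiguity and monomorphic columns", {
  m <- rbind(s1 = c("A", "A", "A", "C", "G", "N"),
             s2 = c("A", "A", "-", "C", "T", "A"),
             s3 = c("A", "T", "T", "C", "G", "A"))
  sn <- extractSnps(m)
  # col 1 monomorphic, col 3 gap, col 4 monomorphic, col 6 ambiguity
  expect_equal(sn$pos, c(1L, 4L))
  expect_equal(sn$s3, c("T", "G"))
  # identical sequences give an empty table
  expect_equal(nrow(extractSnps(matrix("A", 3, 10,
    dimnames = list(c("a", "b", "c"), NULL)))), 0)
  # minor-allele-count filter
  m2 <- rbind(s1 = c("A", "A"), s2 = c("T", "A"),
              s3 = c("A", "T"), s4 = c("A", "T"))
  expect_equal(nrow(extractSnps(m2)), 2)
  expect_equal(extractSnps(m2, minMinorCount = 2)$pos, 1L)
})

test_that("SNP extraction maps alignment columns to reference coordinates", {
  blocks <- list(
    list(seqs = c(ref = "ACGTAC", alt = "ACTTAC", oth = "ACGTAC"),
         refStart = 100L),
    # reference gap shifts downstream coordinates; gappy column dropped
    list(seqs = c(ref = "A-GGT", alt = "ATGCT", oth = "A-GAT"),
         refStart = 200L))
  core <- coreAlignment(blocks, "ref")
  sn <- extractSnps(core)
  # block 1: column 3 (G/T/G) is at reference position 102
  # block 2: alignment column 4 (G/C/A) is reference position 202
  expect_equal(sn$pos, c(102L, 202L))
  expect_error(extractSnps(coreAlignment(blocks, "ref"), strains = c("zz")),
               "absent")
})

test_that("SNP classification separates fixed, within and shared variation", {
  am <- rbind(c(rep("A", 7), rep("T", 3)),   # fixed between
              c("T", rep("A", 6), rep("A", 3)),  # polymorphic within Blue
              c("T", rep("A", 6), "T", "A", "A"), # shared
              c(rep("A", 7), rep("A", 2), "G"))  # polymorphic within Red
  cl <- classifySnps(snpTableFromMatrix(am, strains10), groups10)
  expect_equal(unname(cl$class),
               c("fixed_between", "polymorphic_within", "shared",
                 "polymorphic_within"))
  expect_equal(cl$nFixed, 1)
  expect_equal(sum(cl$counts), 4)
  expect_equal(cl$percentFixed, 25)
  expect_error(classifySnps(snpTableFromMatrix(am, strains10),
                            setNames(rep("X", 10), strains10)), "two")
})

test_that("Hudson F_ST matches hand computations and the enumeration oracle", {
  expect_equal(hudsonFst(c("A", "A"), c("T", "T")), 1.0)
  # worked case: Hw = (0.5 + 0)/2, Hb = 9/12
  expect_equal(hudsonFst(c("A", "A", "A", "T"), c("T", "T", "T")), 2 / 3)
  # identical allele compositions: the unbiased within-group estimator
  # exceeds the between-group diversity, giving a negative value (retained)
  expect_equal(hudsonFst(c("A", "T"), c("A", "T")), -1)
  expect_true(is.na(hudsonFst(c("A", "A"), c("A", "A"))))
  expect_error(hudsonFst(c("A"), c("T", "T")), ">= 2")
  # random multi-SNP tables against exhaustive pair enumeration
  set.seed(31)
  for (i in 1:60) {
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    am <- randomAlleles(nA + nB, sample(1:20, 1))
    strains <- paste0("s", seq_len(nA + nB))
    colGroups <- setNames(rep(c("g1", "g2"), c(nA, nB)), strains)
    got <- hudsonFst(snpTableFromMatrix(am, strains), groups = colGroups)
    want <- oracleFst(am, seq_len(nA), nA + seq_len(nB))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("window F_ST follows the anchoring, emptiness and coverage rules", {
  am <- rbind(c(rep("A", 7), rep("T", 3)),
              c(rep("C", 7), rep("G", 3)),
              c("T", rep("A", 6), rep("A", 3)))
  sn <- snpTableFromMatrix(am, strains10)
  sn$pos <- c(100L, 200L, 12000L)
  w <- windowFst(sn, groups10, refLength = 25000)
  expect_equal(w$start, c(0, 5000, 10000, 15000))
  expect_equal(w$fst[1], 1.0)       # only fixed SNPs
  expect_false(w$computed[4])       # empty window
  # a window overlapping uncovered positions is not computed
  cov <- rep(TRUE, 25000); cov[300] <- FALSE
  w2 <- windowFst(sn, groups10, refLength = 25000, coverage = cov)
  expect_false(w2$computed[1])
  expect_true(w2$computed[3])
  expect_error(windowFst(sn, groups10, refLength = 25000, window = 0), "positive")
})

test_that("low-F_ST regions merge across short differentiated stretches", {
  mkw <- function(start, fst) data.frame(start = start, end = start + 10000,
                                         n_snps = 5L, computed = TRUE,
                                         fst = fst)
  # all high: no low regions, one continent
  wHigh <- mkw(seq(0, 590000, 5000), 0.9)
  rg <- callRegions(wHigh)
  expect_true(all(rg$class == "continent"))
  # a single low window forms its own region
  w1 <- mkw(seq(0, 590000, 5000), 0.9)
  w1$fst[60] <- 0.2
  rg1 <- callRegions(w1)
  low1 <- rg1[rg1$class == "low", ]
  expect_equal(nrow(low1), 1)
  expect_equal(low1$start, w1$start[60])
  expect_equal(low1$end, w1$end[60])
  # two low windows 100 kb apart merge under the 250 kb rule
  w2 <- mkw(seq(0, 590000, 5000), 0.9)
  w2$fst[c(20, 40)] <- 0.1   # starts 95000 and 195000
  rg2 <- callRegions(w2)
  low2 <- rg2[rg2$class == "low", ]
  expect_equal(nrow(low2), 1)
  expect_equal(low2$start, w2$start[20])
  expect_equal(low2$end, w2$end[40])
  # and stay separate when the gap exceeds the merge distance
  w3 <- mkw(seq(0, 990000, 5000), 0.9)
  w3$fst[c(20, 90)] <- 0.1   # 255 kb apart
  expect_equal(sum(callRegions(w3)$class == "low"), 2)
})

test_that("per-gene F_ST agrees with windows and summarizes the low fraction", {
  am <- rbind(c(rep("A", 7), rep("T", 3)),
              c(rep("C", 7), rep("G", 3)),
              c("A", "T", rep("A", 5), "A", "T", "T"))
  sn <- snpTableFromMatrix(am, strains10)
  sn$pos <- c(500L, 800L, 3000L)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      start = c(0L, 2500L, 9000L),
                      end = c(1000L, 3500L, 9900L))
  gf <- geneFst(sn, genes, groups10)
  expect_equal(gf$perGene$fst[1], 1.0)
  expect_equal(gf$nVariable, 2)       # g3 has no SNPs
  expect_equal(gf$percentBelow, 50)
  # a gene spanning exactly one window's SNPs equals that window
  w <- windowFst(sn, groups10, refLength = 10000, window = 1000, step = 1000)
  expect_equal(gf$perGene$fst[1], w$fst[1])
  # toy fraction: 2 of 8 variable genes below 0.5
  am8 <- do.call(rbind, c(rep(list(c(rep("A", 7), rep("T", 3))), 6),
                          rep(list(c("A", "T", "A", "T", "A", "T", "A",
                                     "A", "T", "T")), 2)))
  sn8 <- snpTableFromMatrix(am8, strains10)
  sn8$pos <- seq(0L, 70L, 10L)
  g8 <- data.frame(gene_id = paste0("g", 1:8), start = seq(0L, 70L, 10L),
                   end = seq(10L, 80L, 10L))
  expect_equal(geneFst(sn8, g8, groups10)$percentBelow, 25)
})

test_that("the permutation test calibrates significance", {
  # maximally distinct groups: no permutation can beat the observed value,
  # except those reproducing the same partition
  am <- do.call(rbind, rep(list(c(rep("A", 5), rep("T", 5))), 10))
  strains <- paste0("s", 1:10)
  g <- setNames(rep(c("x", "y"), each = 5), strains)
  res <- fstPermutationTest(snpTableFromMatrix(am, strains), g,
                            nPerm = 999, seed = 1)
  expect_equal(res$fst, 1.0)
  expect_lt(res$p, 0.02)
  # label-symmetry of the observed statistic
  gSwap <- setNames(rep(c("y", "x"), each = 5), strains)
  expect_equal(hudsonFst(snpTableFromMatrix(am, strains), groups = g),
               hudsonFst(snpTableFromMatrix(am, strains), groups = gSwap))
  # panmictic data: p should rarely be small
  set.seed(77)
  ps <- replicate(40, {
    amr <- randomAlleles(10, 20)
    fstPermutationTest(snpTableFromMatrix(amr, strains), g, nPerm = 99)$p
  })
  expect_lt(mean(ps < 0.05), 0.2)
  expect_error(fstPermutationTest(snpTableFromMatrix(am, strains), g,
                                  nPerm = 10), "nPerm")
})

test_that("divergence-recombination regression behaves at its fixed points", {
  tg <- simulateTwoGroupTree(seed = 41)
  p <- simulationParams(L = 10000)
  ev <- drawEvents(tg$tree, p, seed = 42)
  sim <- simulateAlignment(tg$tree, ev, p, seed = 43)
  # no events: y constant at zero, slope exactly 0
  r0 <- divergenceRecombinationRegression(ev[0, ], sim$alignment)
  expect_equal(r0$slope, 0)
  # events everywhere uniformly: R^2 near zero in most random draws
  set.seed(44)
  r2s <- replicate(30, {
    fake <- data.frame(start = sample(0:9000, 40, TRUE))
    fake$end <- fake$start + 500
    divergenceRecombinationRegression(fake, sim$alignment, window = 500)$r2
  })
  expect_gt(mean(r2s < 0.2), 0.8)
  expect_error(divergenceRecombinationRegression(ev, sim$alignment,
                                                 window = 6000), "3 windows")
})
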