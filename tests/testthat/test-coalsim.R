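twoLeaf <- function(tau) readNewickGenealogy(sprintf("(A:%g,B:%g);", tau, tau))

test_that("departure process matches the piecewise-exponential law", {
  tau <- 0.6
  tr <- twoLeaf(tau)
  d <- sampleDeparture(tr, arrivalTime = 0, n = 20000, seed = 1)
  # below-root probability: lineage coalesces with k=2 lineages at rate 2
  pBelow <- 1 - exp(-2 * tau)
  phat <- mean(d$donor_branch != 0)
  se <- sqrt(pBelow * (1 - pBelow) / nrow(d))
  expect_lt(abs(phat - pBelow), 3 * se)
  # conditional on below-root, each leaf lineage is chosen half the time
  below <- d$donor_branch[d$donor_branch != 0]
  p1 <- mean(below == below[1])
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / length(below)))
  # departure times below the root are within the epoch
  expect_true(all(d$departure_time[d$donor_branch != 0] <= tau))
  expect_true(all(d$departure_time >= 0))
  # a vanishing tree forces ABOVE_ROOT
  trTiny <- twoLeaf(1e-8)
  dT <- sampleDeparture(trTiny, 0, n = 500, seed = 2)
  expect_true(all(dT$donor_branch == 0))
  expect_error(sampleDeparture(tr, arrivalTime = tau + 1), "arrival_time")
})

test_that("event draws follow the stated intensities", {
  tr <- simulateKingmanTree(6, seed = 5)
  totlen <- totalBranchLength(tr)
  p0 <- simulationParams(L = 1000, rhoSite = 0)
  expect_equal(nrow(drawEvents(tr, p0, seed = 1)), 0)
  # Monte-Carlo check of the Poisson mean and geometric tract mean
  L <- 5000; delta <- 10
  rho <- 50 / (L * totlen)  # ~50 events per draw
  p <- simulationParams(L = L, rhoSite = rho, delta = delta)
  set.seed(99)
  nrep <- 400
  counts <- integer(nrep); tracts <- numeric(0)
  for (i in seq_len(nrep)) {
    ev <- drawEvents(tr, p)
    counts[i] <- nrow(ev)
    tracts <- c(tracts, ev$end - ev$start)
  }
  seCount <- stats::sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - 50), 3 * seCount)
  seTract <- stats::sd(tracts) / sqrt(length(tracts))
  expect_lt(abs(mean(tracts) - delta), 3 * seTract)
  # event geometry invariants
  ev <- drawEvents(tr, p, seed = 7)
  bt <- branchTable(tr)
  expect_true(all(ev$arrival_time >= bt$childTime[match(ev$recipient_branch, bt$branch)]))
  expect_true(all(ev$arrival_time <= bt$parentTime[match(ev$recipient_branch, bt$branch)]))
  expect_true(all(ev$departure_time >= ev$arrival_time))
  expect_true(all(ev$start >= 0 & ev$end <= p$L & ev$start < ev$end))
})

test_that("a complete barrier removes all between-group events", {
  tg <- simulateTwoGroupTree(seed = 3)
  p <- simulationParams(L = 50000, barrier = 0)
  ev <- drawEvents(tg$tree, p, groups = tg$groups, seed = 4)
  bg <- branchGroup(tg$tree, tg$groups)
  dg <- ifelse(ev$donor_branch == 0, UNASSIGNED, bg[pmax(ev$donor_branch, 1)])
  rg <- bg[ev$recipient_branch]
  cross <- dg != UNASSIGNED & rg != UNASSIGNED & dg != rg
  expect_equal(sum(cross), 0)
  expect_error(drawEvents(tg$tree, p, seed = 4), "group labeling")
})

test_that("the Monte-Carlo flux prior is a probability distribution", {
  tr <- twoLeaf(0.8)
  ef <- expectedFlux(tr, nMc = 20000, seed = 6)
  expect_equal(sum(ef$prob), 1, tolerance = 1e-12)
  # symmetry of the two cross-lineage cells on a symmetric tree
  p12 <- ef$prob["1", "2"]; p21 <- ef$prob["2", "1"]
  se <- sqrt(ef$se["1", "2"]^2 + ef$se["2", "1"]^2)
  expect_lt(abs(p12 - p21), 3 * se)
  expect_error(expectedFlux(tr, nMc = 10), "nMc")
})

test_that("the Monte-Carlo flux prior matches analytic integration", {
  tr <- readNewickGenealogy("((A:0.4,B:0.4):0.7,C:1.1);")
  oracle <- oracleFluxProb(tr)
  ef <- expectedFlux(tr, nMc = 40000, seed = 8)
  tol <- 3 * ef$se + 1e-6
  expect_true(all(abs(ef$prob - oracle) <= tol))
})

test_that("mutation-free and event-free simulations behave as limits", {
  tr <- simulateKingmanTree(5, seed = 10)
  p <- simulationParams(L = 300, thetaSite = 0)
  sim <- simulateAlignment(tr, drawEvents(tr, p, seed = 1), p, seed = 2)
  expect_equal(nrow(sim$snps), 0)
  expect_true(all(apply(sim$alignment, 2, function(col)
    length(unique(col)) == 1)))
})

test_that("pairwise divergence matches the Jukes-Cantor closed form", {
  tau <- 0.5
  tr <- twoLeaf(tau)
  theta <- 0.01 / (2 * tau)  # so theta * 2 tau = 0.01
  p <- simulationParams(L = 2000, thetaSite = theta, rhoSite = 0)
  noEv <- drawEvents(tr, p, seed = 1)
  set.seed(123)
  diffs <- replicate(300, {
    a <- simulateAlignment(tr, noEv, p)$alignment
    mean(a[1, ] != a[2, ])
  })
  expected <- 3 / 4 * (1 - exp(-4 / 3 * 0.01))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - expected), 3 * se)
})

test_that("an imported tract clusters the recipient with its donor", {
  # deep symmetric 4-leaf tree; an event transfers C's lineage onto A's
  # recent past, so inside the tract C matches A, outside it matches D
  tr <- readNewickGenealogy("((A:0.05,B:0.05):1.95,(C:0.05,D:0.05):1.95);")
  bt <- branchTable(tr)
  bC <- tr@branch[which(leafNames(tr) == "C")]
  bA <- tr@branch[which(leafNames(tr) == "A")]
  ev <- data.frame(event_id = 1L, recipient_branch = bC,
                   arrival_time = 0.02, donor_branch = bA,
                   departure_time = 0.03, start = 1000L, end = 3000L)
  p <- simulationParams(L = 4000, thetaSite = 0.02, rhoSite = 0)
  sim <- simulateAlignment(tr, ev, p, seed = 42)
  a <- sim$alignment
  tract <- 1001:3000; flank <- c(1:1000, 3001:4000)
  dCA_t <- mean(a["C", tract] != a["A", tract])
  dCD_t <- mean(a["C", tract] != a["D", tract])
  dCA_f <- mean(a["C", flank] != a["A", flank])
  dCD_f <- mean(a["C", flank] != a["D", flank])
  expect_lt(dCA_t, dCD_t)  # tract: C travels with A
  expect_lt(dCD_f, dCA_f)  # flanks: C stays with its clonal sister D
})

test_that("coding mode produces stop-free sense-codon sequences", {
  tg <- simulateTwoGroupTree(seed = 21)
  p <- simulationParams(L = 300, thetaSite = 0.02, rhoSite = 0, coding = TRUE)
  sim <- simulateAlignment(tg$tree, drawEvents(tg$tree, p, seed = 1), p,
                           seed = 2)
  aln <- sim$alignment
  for (s in rownames(aln)) {
    seq <- paste(aln[s, ], collapse = "")
    codons <- substring(seq, seq(1, 298, 3), seq(3, 300, 3))
    aas <- Biostrings::GENETIC_CODE[codons]
    expect_false(any(aas == "*"))
  }
  expect_error(simulationParams(L = 100, coding = TRUE), "divisible by 3")
})
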