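# Generative model: recombination events under the coalescent with gene
# conversion, and sequence evolution along per-site marginal genealogies.

#' Parameters of the synthetic-data generator
#'
#' Bundles and validates the simulation settings. Intensities are expressed
#' per site per unit branch length (coalescent units), matching the scale on
#' which absolute recombination rates are reported by genealogy-based
#' inference tools; there is no hidden factor of 1/2.
#'
#' Defaults emulate a small, recently diverged pair of clonal lineages:
#' a mutation intensity that puts average pairwise nucleotide diversity in
#' the 0.01\%-0.35\% range on a genealogy with TMRCA near 2 coalescent
#' units, a recombination intensity of 2.41e-4 events/site/unit, and a mean
#' conversion tract of 2 kb.
#'
#' @param L alignment length in sites (>= 1).
#' @param thetaSite mutation intensity per site per unit branch length.
#' @param rhoSite recombination-event intensity per site per unit branch
#'   length.
#' @param delta mean recombination tract length in sites (>= 1); tracts are
#'   geometric with support >= 1, truncated at the alignment end.
#' @param barrier between-group acceptance probability m in [0,1] (1 = free
#'   gene flow), or a function of arrival time returning such a probability
#'   (for barriers whose strength changes through time).
#' @param coding logical; simulate codon-structured sequences (L divisible
#'   by 3) under a stop-avoiding neutral codon chain.
#' @return a list of class \code{SimulationParams}.
#' @export
simulationParams <- function(L = 30000, thetaSite = 1e-3, rhoSite = 2.41e-4,
                             delta = 2000, barrier = 1, coding = FALSE) {
  stopifnot(L >= 1, L == round(L), thetaSite >= 0, rhoSite >= 0, delta >= 1)
  if (is.function(barrier)) {
    # time-varying barrier; validated pointwise at use
  } else {
    stopifnot(length(barrier) == 1, barrier >= 0, barrier <= 1)
  }
  if (coding && L %% 3 != 0) stop("coding mode requires L divisible by 3")
  structure(list(L = as.integer(L), thetaSite = thetaSite, rhoSite = rhoSite,
                 delta = delta, barrier = barrier, coding = coding),
            class = "SimulationParams")
}

# Vectorized departure sampler. Returns list(donor = integer (0 = above
# root), time = numeric). The recombinant lineage traced backwards from each
# arrival time coalesces with the k(t) contemporaneous clonal lineages at
# total rate k(t), uniformly among them; above the root it coalesces with
# the root lineage at rate 1.
.sampleDepartures <- function(tree, arrivals) {
  M <- length(arrivals)
  ep <- branchEpochs(tree)
  extant <- .epochBranches(tree)
  tm <- tmrca(tree)
  if (any(arrivals < 0 | arrivals > tm + 1e-9))
    stop("arrival_time outside [0, TMRCA]")
  donor <- integer(M)
  dep <- numeric(M)
  done <- logical(M)
  cur <- arrivals
  for (j in seq_len(nrow(ep) - 1L)) {
    sel <- which(!done & cur < ep$end[j])
    if (!length(sel)) next
    k <- ep$k[j]
    t2 <- cur[sel] + stats::rexp(length(sel), rate = k)
    hit <- t2 < ep$end[j]
    hs <- sel[hit]
    if (length(hs)) {
      dep[hs] <- t2[hit]
      donor[hs] <- extant[[j]][sample.int(k, length(hs), replace = TRUE)]
      done[hs] <- TRUE
    }
    cur[sel[!hit]] <- ep$end[j]
  }
  rest <- which(!done)
  if (length(rest)) {
    dep[rest] <- tm + stats::rexp(length(rest), rate = 1)
    donor[rest] <- 0L
  }
  list(donor = donor, time = dep)
}

#' Sample the origin of a recombinant lineage
#'
#' Traces a recombinant lineage backwards in time from its arrival point on
#' the recipient branch until it coalesces with one of the contemporaneous
#' clonal lineages (total rate k(t), uniform choice among them) or, above
#' the root, with the root lineage at rate 1 (reported as the pseudo-donor
#' \code{ABOVE_ROOT}, donor branch 0).
#'
#' @param tree a [ClonalGenealogy-class]
#' @param arrivalTime arrival time(s) on the recipient branch, in [0, TMRCA].
#' @param n draws per arrival time (arrival is recycled if n > 1).
#' @param seed optional integer seed.
#' @return data.frame with columns donor_branch (0 = above root) and
#'   departure_time.
#' @export
sampleDeparture <- function(tree, arrivalTime, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arr <- rep(arrivalTime, length.out = max(n, length(arrivalTime)))
  d <- .sampleDepartures(tree, arr)
  data.frame(donor_branch = d$donor, departure_time = d$time)
}

#' Draw recombination events under the coalescent-with-gene-conversion prior
#'
#' The number of events is Poisson with mean rhoSite x L x total branch
#' length; each arrival point is uniform over branch length and over sites;
#' the tract starts at the arrival site with geometric length (mean delta,
#' support >= 1) truncated at the alignment end; the donor is sampled by
#' [sampleDeparture()]. With a barrier m < 1, an event whose donor group
#' differs from its recipient group (both attributable via [branchGroup()])
#' is retained with probability m; events with UNASSIGNED donors or
#' recipients are always kept. Thinning leaves the arrival/departure
#' geometry of retained events untouched, so the prior expectation remains
#' the correct null for flux ratios.
#'
#' @param tree a [ClonalGenealogy-class]
#' @param params a [simulationParams()] list.
#' @param groups named strain -> group vector; required when barrier < 1.
#' @param seed optional integer seed.
#' @return data.frame with columns event_id, recipient_branch, arrival_time,
#'   donor_branch (0 = above root), departure_time, start, end (0-based
#'   half-open site interval).
#' @export
drawEvents <- function(tree, params, groups = NULL, seed = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  if (!is.null(seed)) set.seed(seed)
  hasBarrier <- is.function(params$barrier) ||
    (is.numeric(params$barrier) && params$barrier < 1)
  if (hasBarrier && is.null(groups))
    stop("a group labeling is required when barrier < 1")
  bt <- branchTable(tree)
  totlen <- sum(bt$length)
  M <- stats::rpois(1, params$rhoSite * params$L * totlen)
  empty <- data.frame(event_id = integer(0), recipient_branch = integer(0),
                      arrival_time = numeric(0), donor_branch = integer(0),
                      departure_time = numeric(0), start = integer(0),
                      end = integer(0))
  if (M == 0) return(empty)
  rb <- sample.int(nrow(bt), M, replace = TRUE, prob = bt$length)
  arr <- stats::runif(M, bt$childTime[rb], bt$parentTime[rb])
  start <- sample.int(params$L, M, replace = TRUE) - 1L
  len <- stats::rgeom(M, prob = 1 / params$delta) + 1L
  end <- pmin(start + len, params$L)
  d <- .sampleDepartures(tree, arr)
  ev <- data.frame(event_id = seq_len(M), recipient_branch = bt$branch[rb],
                   arrival_time = arr, donor_branch = d$donor,
                   departure_time = d$time, start = start, end = end)
  if (hasBarrier) {
    bg <- branchGroup(tree, groups)
    dg <- ifelse(ev$donor_branch == 0L, UNASSIGNED, bg[pmax(ev$donor_branch, 1L)])
    rg <- bg[ev$recipient_branch]
    cross <- dg != UNASSIGNED & rg != UNASSIGNED & dg != rg
    m <- if (is.function(params$barrier)) params$barrier(ev$arrival_time)
         else rep(params$barrier, M)
    keep <- !cross | (stats::runif(M) < m)
    ev <- ev[keep, , drop = FALSE]
    ev$event_id <- seq_len(nrow(ev))
  }
  rownames(ev) <- NULL
  ev
}

#' Prior flux probabilities per (donor, recipient) branch pair
#'
#' Monte-Carlo estimate of the probability, under the neutral
#' coalescent-with-gene-conversion prior, that an event has recipient branch
#' r and donor branch d (or the ABOVE_ROOT pseudo-donor): arrivals uniform
#' over branch length, departures via [sampleDeparture()]. Entries sum to 1
#' up to Monte-Carlo error; the per-cell binomial standard error is
#' returned. Expected event counts are these probabilities times the total
#' number of observed events (the global total, not per-recipient totals).
#'
#' @param tree a [ClonalGenealogy-class]
#' @param nMc number of Monte-Carlo draws (>= 1000).
#' @param seed optional integer seed.
#' @return list with elements prob ((2n-1) x (2n-2) matrix, last row
#'   ABOVE_ROOT), se (matching standard errors) and nMc.
#' @export
expectedFlux <- function(tree, nMc = 10000, seed = NULL) {
  stopifnot(nMc >= 1000)
  if (!is.null(seed)) set.seed(seed)
  bt <- branchTable(tree)
  nb <- nrow(bt)
  rb <- sample.int(nb, nMc, replace = TRUE, prob = bt$length)
  arr <- stats::runif(nMc, bt$childTime[rb], bt$parentTime[rb])
  d <- .sampleDepartures(tree, arr)
  counts <- matrix(0, nb + 1L, nb,
                   dimnames = list(c(as.character(seq_len(nb)), ABOVE_ROOT),
                                   as.character(seq_len(nb))))
  di <- ifelse(d$donor == 0L, nb + 1L, d$donor)
  tab <- table(factor(di, levels = seq_len(nb + 1L)),
               factor(bt$branch[rb], levels = seq_len(nb)))
  counts[] <- as.numeric(tab)
  prob <- counts / nMc
  se <- sqrt(prob * (1 - prob) / nMc)
  list(prob = prob, se = se, nMc = nMc)
}

# ---- sequence simulation --------------------------------------------------

NUC <- c("A", "C", "G", "T")

# Marginal genealogy at one genomic segment: the clonal tree with, for every
# active event, the recipient lineage detached at its arrival time and
# re-attached at the donor point (departure time on the donor branch, or on
# the extended root lineage). Events are independent deviations from the
# clonal genealogy; jumps always move up in time, so the construction is
# acyclic. Returns parent/time vectors over clonal + event nodes plus the
# set of edges carrying sampled material.
.marginalTree <- function(tree, events) {
  n <- nLeaves(tree)
  N <- 2L * n - 1L
  nev <- nrow(events)
  parent <- c(tree@parent, integer(nev))
  time <- c(tree@time, events$departure_time)
  xnode <- if (nev) N + seq_len(nev) else integer(0)
  # per clonal branch: insertion points (attach = donor side, detach =
  # recipient side), processed in time order
  root <- which(tree@parent[seq_len(N)] == 0L)
  if (nev) {
    pts <- rbind(
      data.frame(node = tree@branchNode[pmax(events$recipient_branch, 1L)],
                 t = events$arrival_time, type = "detach", x = xnode),
      data.frame(node = ifelse(events$donor_branch == 0L, root,
                               tree@branchNode[pmax(events$donor_branch, 1L)]),
                 t = events$departure_time, type = "attach", x = xnode,
                 row.names = NULL)
    )
    # the ABOVE_ROOT chain hangs off the root node; ordinary chains off the
    # branch's child node
    for (v in unique(pts$node)) {
      pp <- pts[pts$node == v, , drop = FALSE]
      pp <- pp[order(pp$t), , drop = FALSE]
      prev <- v
      origParent <- parent[v]
      for (i in seq_len(nrow(pp))) {
        if (pp$type[i] == "attach") {
          if (!is.na(prev)) parent[prev] <- pp$x[i]
          prev <- pp$x[i]
        } else {
          # jump: material below follows the event to its attachment node
          if (!is.na(prev)) parent[prev] <- pp$x[i]
          prev <- NA_integer_
        }
      }
      if (!is.na(prev)) parent[prev] <- origParent
    }
  }
  # walk up from each leaf; count paths through each node
  count <- integer(length(parent))
  for (lf in seq_len(n)) {
    v <- lf
    repeat {
      count[v] <- count[v] + 1L
      if (count[v] > n) stop("cycle in marginal genealogy")  # defensive
      p <- parent[v]
      if (p == 0L) break
      v <- p
    }
  }
  onPath <- which(count >= 1L & count < n)
  margRoot <- which(count == n)
  margRoot <- margRoot[which.min(time[margRoot])]
  list(parent = parent, time = time, nodes = onPath, root = margRoot)
}

# simulate one segment of iid sites down a marginal tree under Jukes-Cantor
# (mutation intensity theta per site; each change uniform among the other
# three nucleotides); returns integer matrix leaves x width with codes 1..4
.simulateSegmentJC <- function(tree, mt, theta, width) {
  n <- nLeaves(tree)
  ord <- mt$nodes[order(mt$time[mt$nodes], decreasing = TRUE)]
  states <- vector("list", length(mt$parent))
  states[[mt$root]] <- sample.int(4L, width, replace = TRUE)
  for (v in ord) {
    p <- mt$parent[v]
    len <- mt$time[p] - mt$time[v]
    ps <- if (is.null(states[[p]])) states[[mt$root]] else states[[p]]
    # p is always processed before v (greater time); root handled above
    pSame <- 0.25 + 0.75 * exp(-4 / 3 * theta * len)
    u <- stats::runif(width)
    s <- ps
    ch <- which(u >= pSame)
    if (length(ch))
      s[ch] <- 1L + (s[ch] - 1L + sample.int(3L, length(ch), replace = TRUE)) %% 4L
    states[[v]] <- s
  }
  out <- matrix(0L, n, width)
  for (lf in seq_len(n)) out[lf, ] <- states[[lf]]
  out
}

# ---- neutral codon chain (coding mode) ------------------------------------

.codonEnv <- new.env(parent = emptyenv())

.codonTables <- function() {
  if (!is.null(.codonEnv$tab)) return(.codonEnv$tab)
  codons <- apply(expand.grid(NUC, NUC, NUC, stringsAsFactors = FALSE)[, 3:1],
                  1, paste0, collapse = "")
  aa <- vapply(codons, function(cd) .translateCodon(cd), character(1))
  sense <- codons[aa != "*"]
  S <- length(sense)
  # symmetric rate matrix: theta/3 between sense codons one substitution
  # apart (changes through stop codons never occur)
  A <- matrix(0, S, S, dimnames = list(sense, sense))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j) next
    d <- sum(strsplit(sense[i], "")[[1]] != strsplit(sense[j], "")[[1]])
    if (d == 1L) A[i, j] <- 1 / 3
  }
  diag(A) <- -rowSums(A)
  eg <- eigen(A, symmetric = TRUE)
  .codonEnv$tab <- list(sense = sense, aa = aa[aa != "*"], U = eg$vectors,
                        lambda = eg$values)
  .codonEnv$tab
}

.codonTransition <- function(thetaLen) {
  tb <- .codonTables()
  P <- tb$U %*% (exp(tb$lambda * thetaLen) * t(tb$U))
  P[P < 0] <- 0
  P / rowSums(P)
}

.simulateSegmentCodon <- function(tree, mt, theta, width) {
  tb <- .codonTables()
  n <- nLeaves(tree)
  S <- length(tb$sense)
  ord <- mt$nodes[order(mt$time[mt$nodes], decreasing = TRUE)]
  states <- vector("list", length(mt$parent))
  init <- which(tb$sense != "ATG")  # start-codon-free initial sequence
  states[[mt$root]] <- init[sample.int(length(init), width, replace = TRUE)]
  for (v in ord) {
    p <- mt$parent[v]
    len <- mt$time[p] - mt$time[v]
    ps <- states[[p]]
    P <- .codonTransition(3 * theta * len)  # theta per nt site, 3 nt per codon
    s <- integer(width)
    for (st in unique(ps)) {
      idx <- which(ps == st)
      s[idx] <- sample.int(S, length(idx), replace = TRUE, prob = P[st, ])
    }
    states[[v]] <- s
  }
  out <- matrix(0L, n, width)
  for (lf in seq_len(n)) out[lf, ] <- states[[lf]]
  out
}

#' Simulate a core alignment along the clonal genealogy with recombination
#'
#' For every site, the marginal genealogy is the clonal tree with the
#' recipient lineage re-attached at the donor point for each event covering
#' the site (when several tracts overlap on one recipient lineage the
#' younger, i.e. later-arriving, event wins). Mutations occur as a Poisson
#' process of intensity thetaSite per site per unit of marginal branch
#' length under the Jukes-Cantor model. Coding mode runs the analogous
#' neutral chain on sense codons (substitutions creating stop codons never
#' occur, matching the stop-excluded site counting of the NG86 estimator)
#' from a random start-codon-free sense-codon sequence.
#'
#' @param tree a [ClonalGenealogy-class]
#' @param events event table from [drawEvents()] (may be empty).
#' @param params a [simulationParams()] list.
#' @param seed optional integer seed.
#' @return list with \code{alignment} (character matrix, strains x sites)
#'   and \code{snps} (true SNP table: data.frame pos plus one allele column
#'   per strain, positions 0-based).
#' @export
simulateAlignment <- function(tree, events, params, seed = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  if (!is.null(seed)) set.seed(seed)
  L <- params$L
  if (nrow(events) && any(events$end > L))
    stop("event tract exceeds alignment length")
  n <- nLeaves(tree)
  unit <- if (params$coding) 3L else 1L
  Lu <- L %/% unit
  if (nrow(events)) {
    us <- events$start %/% unit
    ue <- pmin((events$end + unit - 1L) %/% unit, Lu)
  } else us <- ue <- integer(0)
  bks <- sort(unique(c(0L, Lu, us, ue)))
  out <- matrix(0L, n, Lu)
  for (i in seq_len(length(bks) - 1L)) {
    s0 <- bks[i]; s1 <- bks[i + 1L]
    width <- s1 - s0
    act <- if (nrow(events)) which(us <= s0 & ue > s0) else integer(0)
    ev <- events[act, , drop = FALSE]
    if (nrow(ev) > 1L) {
      # younger (most recent arrival) event wins per recipient lineage
      ev <- ev[order(ev$arrival_time), , drop = FALSE]
      ev <- ev[!duplicated(ev$recipient_branch), , drop = FALSE]
    }
    mt <- .marginalTree(tree, ev)
    seg <- if (params$coding)
      .simulateSegmentCodon(tree, mt, params$thetaSite, width)
    else
      .simulateSegmentJC(tree, mt, params$thetaSite, width)
    out[, (s0 + 1L):s1] <- seg
  }
  if (params$coding) {
    sense <- .codonTables()$sense
    aln <- matrix("", n, L, dimnames = list(tree@leaves, NULL))
    for (lf in seq_len(n)) {
      aln[lf, ] <- unlist(strsplit(paste(sense[out[lf, ]], collapse = ""), ""))
    }
  } else {
    aln <- matrix(NUC[out], n, L, dimnames = list(tree@leaves, NULL))
  }
  poly <- which(apply(aln, 2, function(col) length(unique(col)) > 1L))
  snps <- cbind(data.frame(pos = poly - 1L),
                as.data.frame(t(aln[, poly, drop = FALSE]),
                              stringsAsFactors = FALSE))
  rownames(snps) <- NULL
  list(alignment = aln, snps = snps)
}

#' Write an alignment matrix as FASTA
#'
#' @param alignment character matrix (strains x sites), e.g. from
#'   [simulateAlignment()].
#' @param path output file.
#' @export
writeFastaAlignment <- function(alignment, path) {
  seqs <- apply(alignment, 1, paste0, collapse = "")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- rownames(alignment)
  Biostrings::writeXStringSet(x, path)
}

#' Read a FASTA alignment into a character matrix
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return character matrix strains x sites.
#' @export
readFastaAlignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  w <- unique(Biostrings::width(x))
  if (length(w) != 1L) stop("ragged alignment: unequal sequence lengths")
  m <- t(vapply(as.character(x), function(s) strsplit(s, "")[[1]],
                character(w)))
  rownames(m) <- names(x)
  toupper(m)
}
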