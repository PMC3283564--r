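# Observed vs expected recombination flux, its change through coalescent
# time, and the r/m summary of recombination relative to mutation.

#' Tabulate observed recombination events per (donor, recipient) branch pair
#'
#' @param events event table (columns recipient_branch, donor_branch; donor
#'   0 means ABOVE_ROOT).
#' @param tree a [ClonalGenealogy-class]
#' @return numeric matrix, donors (2n-2 branches + ABOVE_ROOT row) x
#'   recipients (2n-2 branches); grand total equals the event count.
#' @export
observedFlux <- function(events, tree) {
  nb <- nBranches(tree)
  counts <- matrix(0, nb + 1L, nb,
                   dimnames = list(c(as.character(seq_len(nb)), ABOVE_ROOT),
                                   as.character(seq_len(nb))))
  if (nrow(events)) {
    bad <- which(events$recipient_branch < 1 | events$recipient_branch > nb |
                 events$donor_branch < 0 | events$donor_branch > nb)
    if (length(bad))
      stop("event ", events$event_id[bad[1]], " references an unknown branch ID")
    di <- ifelse(events$donor_branch == 0L, nb + 1L, events$donor_branch)
    tab <- table(factor(di, levels = seq_len(nb + 1L)),
                 factor(events$recipient_branch, levels = seq_len(nb)))
    counts[] <- as.numeric(tab)
  }
  counts
}

#' Observed/expected flux ratios with the <4 significance mask
#'
#' The expected matrix (prior probabilities from [expectedFlux()], or an
#' already-scaled count matrix) is scaled to the global observed total.
#' Cells with fewer than four observed AND fewer than four expected events
#' are masked as non-significant, following the convention of flux heat
#' maps where sparse cells are greyed out. For unmasked cells with positive
#' expectation an exact two-sided Poisson p-value (observed count against
#' mean = expected) is attached; p-values are descriptive and not adjusted
#' for multiple testing.
#'
#' @param observed count matrix from [observedFlux()].
#' @param expected [expectedFlux()] result, or a conformable matrix of
#'   probabilities/counts.
#' @param computeP logical; attach exact Poisson p-values.
#' @return a [FluxMatrix-class]
#' @export
fluxRatio <- function(observed, expected, computeP = FALSE) {
  if (is.list(expected) && !is.null(expected$prob)) expected <- expected$prob
  if (!all(dim(observed) == dim(expected)))
    stop("observed and expected matrices are not conformable")
  if (any(observed < 0) || any(expected < 0))
    stop("negative counts are not allowed")
  nEv <- sum(observed)
  tot <- sum(expected)
  exp_ <- if (tot > 0) expected / tot * nEv else expected
  ratio <- ifelse(exp_ > 0, observed / exp_, NA_real_)
  masked <- observed < 4 & exp_ < 4
  pv <- matrix(NA_real_, nrow(observed), ncol(observed),
               dimnames = dimnames(observed))
  if (computeP) {
    idx <- which(!masked & exp_ > 0)
    for (i in idx)
      pv[i] <- stats::poisson.test(round(observed[i]), r = exp_[i])$p.value
  }
  new("FluxMatrix", observed = unname(observed) + 0, expected = unname(exp_),
      ratio = unname(ratio), masked = unname(masked), pvalue = unname(pv),
      nEvents = as.integer(round(nEv)))
}

setMethod("show", "FluxMatrix", function(object) {
  cat(sprintf("FluxMatrix: %d events over %d x %d (donor x recipient) cells\n",
              object@nEvents, nrow(object@observed), ncol(object@observed)))
  cat(sprintf("  %d cells masked (<4 observed and expected); ratio range %s\n",
              sum(object@masked),
              paste(signif(range(object@ratio[!object@masked &
                                              !is.na(object@ratio)]), 3),
                    collapse = " - ")))
})

#' @describeIn fluxRatio flux table in long format (one row per cell)
#' @param x a [FluxMatrix-class]
#' @export
fluxTable <- function(x) {
  nb <- ncol(x@observed)
  donors <- c(as.character(seq_len(nb)), ABOVE_ROOT)
  data.frame(
    donor = rep(donors, nb),
    recipient = rep(as.character(seq_len(nb)), each = nb + 1L),
    observed = as.vector(x@observed),
    expected = as.vector(x@expected),
    ratio = as.vector(x@ratio),
    masked = as.vector(x@masked),
    p = as.vector(x@pvalue)
  )
}

#' Recombination flux between groups through coalescent time
#'
#' Events are binned by arrival time into equal-width intervals of
#' [0, TMRCA]; bin indices run from 1 at the common ancestor to \code{bins}
#' at the most recent divergence (bin = bins - floor(bins t / TMRCA),
#' clamped). Events whose donor cannot be attributed to a group, or whose
#' recipient group is UNASSIGNED or "excluded", are dropped. For each
#' recipient group and bin the proportion of events from each donor group
#' is reported.
#'
#' @param events event table from [drawEvents()].
#' @param tree a [ClonalGenealogy-class]
#' @param groups named strain -> group vector.
#' @param bins number of time bins (default 10).
#' @return data.frame with columns recipient_group, bin, donor_group,
#'   n_events, proportion.
#' @export
temporalFlux <- function(events, tree, groups, bins = 10) {
  stopifnot(bins >= 1)
  bg <- branchGroup(tree, groups)
  tm <- tmrca(tree)
  dg <- ifelse(events$donor_branch == 0L, UNASSIGNED,
               bg[pmax(events$donor_branch, 1L)])
  rg <- bg[events$recipient_branch]
  keep <- dg != UNASSIGNED & dg != "excluded" &
          rg != UNASSIGNED & rg != "excluded"
  if (!any(keep)) {
    warning("no assignable events")
    return(data.frame(recipient_group = character(0), bin = integer(0),
                      donor_group = character(0), n_events = integer(0),
                      proportion = numeric(0)))
  }
  ev <- data.frame(t = events$arrival_time[keep], donor = dg[keep],
                   recipient = rg[keep])
  ev$bin <- pmin(pmax(bins - floor(bins * ev$t / tm), 1L), bins)
  out <- do.call(rbind, lapply(split(ev, list(ev$recipient, ev$bin),
                                     drop = TRUE), function(d) {
    tab <- table(d$donor)
    data.frame(recipient_group = d$recipient[1], bin = d$bin[1],
               donor_group = names(tab), n_events = as.integer(tab),
               proportion = as.numeric(tab) / nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$recipient_group, out$bin, out$donor_group), ]
}

#' Relative effect of recombination versus mutation (r/m)
#'
#' r/m = (rho/theta) x delta x pi: the relative probability that a site is
#' altered by recombination rather than mutation, given the ratio of event
#' frequencies rho/theta, the mean tract length delta, and the average
#' pairwise distance pi between two genomes. Because recombination is more
#' frequent within than between lineages, evaluating the formula with the
#' overall pi overestimates and with the within-lineage pi underestimates
#' r/m; the two together bound it.
#'
#' @param rhoOverTheta ratio of recombination to mutation event frequencies.
#' @param delta mean recombination tract length (sites).
#' @param pi average pairwise distance per site.
#' @return a single value ([rOverM()]) or c(lower, upper)
#'   ([rOverMBounds()]).
#' @examples
#' rOverM(2, 500, 0.003)  # 3
#' @export
rOverM <- function(rhoOverTheta, delta, pi) {
  stopifnot(rhoOverTheta >= 0, delta >= 0, pi >= 0)
  rhoOverTheta * delta * pi
}

#' @rdname rOverM
#' @param piOverall average pairwise distance over all pairs of genomes.
#' @param piWithin average pairwise distance over same-lineage pairs.
#' @export
rOverMBounds <- function(rhoOverTheta, delta, piOverall, piWithin) {
  if (piWithin > piOverall)
    warning("piWithin exceeds piOverall; bounds will be inverted")
  c(lower = rOverM(rhoOverTheta, delta, piWithin),
    upper = rOverM(rhoOverTheta, delta, piOverall))
}

#' Average pairwise nucleotide diversity
#'
#' Mean per-site difference over all pairs of sequences, and over
#' within-group pairs for each group with at least two members. Columns
#' where either sequence of a pair carries a gap are skipped for that pair.
#'
#' @param alignment character matrix strains x sites (rownames = strains).
#' @param groups optional named strain -> group vector.
#' @return list with \code{overall} and (if groups given) \code{within}, a
#'   named numeric vector (NA for groups with < 2 members).
#' @export
pairwisePi <- function(alignment, groups = NULL) {
  strains <- rownames(alignment)
  n <- length(strains)
  stopifnot(n >= 2)
  gapish <- function(x) !(x %in% NUC)
  pairDist <- function(i, j) {
    a <- alignment[i, ]; b <- alignment[j, ]
    ok <- !gapish(a) & !gapish(b)
    if (!any(ok)) return(NA_real_)
    mean(a[ok] != b[ok])
  }
  pairs <- utils::combn(n, 2)
  d <- apply(pairs, 2, function(p) pairDist(p[1], p[2]))
  overall <- mean(d, na.rm = TRUE)
  out <- list(overall = overall)
  if (!is.null(groups)) {
    gl <- groups[strains]
    within <- vapply(unique(gl[!is.na(gl)]), function(g) {
      sel <- which(gl == g)
      if (length(sel) < 2) return(NA_real_)
      same <- pairs[, gl[pairs[1, ]] == g & gl[pairs[2, ]] == g, drop = FALSE]
      mean(d[gl[pairs[1, ]] == g & gl[pairs[2, ]] == g], na.rm = TRUE)
    }, numeric(1))
    out$within <- within
  }
  out
}
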