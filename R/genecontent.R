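# Variable (non-core) genome segments: filtering, minimum gain/loss
# reconstruction on the clonal genealogy, and group-exclusive islands.

#' Filter variable segments by length and variable-gene fraction
#'
#' Keeps segments whose length is at least \code{minLen} and whose fraction
#' of variable genes is at least \code{minVariableFraction} (boundaries
#' inclusive). Segments must be present in at least one and fewer than all
#' strains to be variable at all.
#'
#' @param segments data.frame with columns segment_id, start, end (or
#'   length), variable_fraction, plus one 0/1 presence column per strain.
#' @param minLen minimum segment length in bp (default 5000).
#' @param minVariableFraction minimum variable-gene fraction (default 0.5).
#' @return the filtered data.frame.
#' @export
filterSegments <- function(segments, minLen = 5000,
                           minVariableFraction = 0.5) {
  len <- if ("length" %in% colnames(segments)) segments$length
         else segments$end - segments$start
  vf <- if ("variable_fraction" %in% colnames(segments))
    segments$variable_fraction else rep(1, nrow(segments))
  keep <- len >= minLen & vf >= minVariableFraction
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum gain/loss history of a presence/absence character
#'
#' Sankoff parsimony for a binary character on the clonal genealogy with
#' unit gain and loss costs, minimized over root states. One minimal
#' scenario is returned with deterministic tie-breaking: absence is
#' preferred at the root, and below it a child keeps its parent's state
#' whenever that is optimal.
#'
#' @param tree a [ClonalGenealogy-class]
#' @param presence named logical or 0/1 vector over all leaves.
#' @param gainCost,lossCost state-change costs (default 1 each).
#' @return list: \code{minEvents}, \code{events} (data.frame branch, type
#'   in gain/loss), \code{class} ("none", "single_event" or "multi_event"),
#'   \code{nodeStates}.
#' @export
minGainLoss <- function(tree, presence, gainCost = 1, lossCost = 1) {
  n <- nLeaves(tree)
  N <- 2L * n - 1L
  if (!all(tree@leaves %in% names(presence)))
    stop("presence vector must cover every leaf; missing: ",
         paste(setdiff(tree@leaves, names(presence)), collapse = ", "))
  pv <- as.integer(as.logical(presence[tree@leaves]))
  children <- vector("list", N)
  for (v in seq_len(N)) if (tree@parent[v] > 0L)
    children[[tree@parent[v]]] <- c(children[[tree@parent[v]]], v)
  cost <- matrix(Inf, N, 2)  # columns: state 0 (absent), 1 (present)
  for (v in seq_len(n)) cost[v, pv[v] + 1L] <- 0
  ord <- order(tree@time)  # children before parents
  trans <- matrix(c(0, lossCost, gainCost, 0), 2, 2)  # trans[from,to]... rows=parent
  for (v in ord) {
    if (v <= n) next
    for (s in 1:2) {
      tot <- 0
      for (ch in children[[v]])
        tot <- tot + min(cost[ch, 1] + trans[s, 1], cost[ch, 2] + trans[s, 2])
      cost[v, s] <- tot
    }
  }
  root <- which(tree@parent == 0L)
  minEvents <- min(cost[root, ])
  state <- integer(N)
  state[root] <- if (cost[root, 1] <= cost[root, 2]) 0L else 1L  # prefer absence
  for (v in rev(ord)) {  # parents before children
    if (v <= n) next
    for (ch in children[[v]]) {
      s <- state[v] + 1L
      c0 <- cost[ch, 1] + trans[s, 1]
      c1 <- cost[ch, 2] + trans[s, 2]
      state[ch] <- if (c0 < c1) 0L else if (c1 < c0) 1L else state[v]
    }
  }
  nonroot <- which(tree@parent > 0L)
  chg <- nonroot[state[nonroot] != state[tree@parent[nonroot]]]
  events <- data.frame(
    branch = tree@branch[chg],
    type = ifelse(state[chg] == 1L, "gain", "loss")
  )
  events <- events[order(events$branch), , drop = FALSE]
  rownames(events) <- NULL
  cls <- if (minEvents == 0) "none" else
    if (minEvents == 1) "single_event" else "multi_event"
  list(minEvents = minEvents, events = events, class = cls,
       nodeStates = state)
}

#' Classify variable segments by their minimum gain/loss history
#'
#' Segments explicable by one event on one branch are "single_event"; the
#' rest require multiple events (gene flow between strains, or gain
#' followed by differential loss). A multi-event segment present in at
#' least one strain of each group and absent from at least one strain of
#' each group is flagged as a candidate for non-homologous exchange
#' between the groups.
#'
#' @param segments data.frame with segment_id plus one 0/1 presence column
#'   per strain (values other than 0/1, e.g. "partial", are rejected).
#' @param tree a [ClonalGenealogy-class]
#' @param groups named strain -> group vector.
#' @return list: \code{perSegment} (segment_id, min_events, class,
#'   inter_group), \code{counts} (per class), \code{nInterGroup}.
#' @export
classifySegments <- function(segments, tree, groups) {
  strains <- intersect(colnames(segments), tree@leaves)
  if (length(strains) != nLeaves(tree))
    stop("segment table lacks presence columns for: ",
         paste(setdiff(tree@leaves, colnames(segments)), collapse = ", "))
  pm <- as.matrix(segments[, strains, drop = FALSE])
  if (!all(pm %in% c(0, 1, "0", "1")))
    stop("presence values must be 0/1; pre-split segments with 'partial' presence")
  mode(pm) <- "numeric"
  gl <- groups[strains]
  gs <- setdiff(unique(gl[!is.na(gl)]), "excluded")
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    pr <- stats::setNames(pm[i, ], strains)
    r <- minGainLoss(tree, pr)
    inter <- FALSE
    if (r$class == "multi_event" && length(gs) == 2) {
      g1 <- pr[gl == gs[1]]; g2 <- pr[gl == gs[2]]
      # exchange candidate: the segment straddles the group boundary (present
      # in part of each group) and cannot be a single clonal gain or loss
      inter <- any(g1 == 1) && any(g2 == 1) && any(pr == 0)
    }
    data.frame(segment_id = segments$segment_id[i], min_events = r$minEvents,
               class = r$class, inter_group = inter)
  })
  perSegment <- do.call(rbind, rows)
  list(perSegment = perSegment, counts = table(perSegment$class),
       nInterGroup = sum(perSegment$inter_group))
}

#' Group-exclusive gene islands
#'
#' A gene is exclusive to a group when it is present in all members of that
#' group and absent from every member of the other. Contiguous runs of
#' genes are grown greedily from each exclusive gene as long as strictly
#' more than \code{minFractionExclusive} of the run's genes stay exclusive;
#' runs spanning strictly more than \code{minLen} bp are reported as
#' islands.
#'
#' @param geneTable ordered data.frame with gene_id, start, end (0-based
#'   half-open) plus one 0/1 presence column per strain.
#' @param groups named strain -> group vector (two non-excluded groups).
#' @param minLen minimum island span in bp (exclusive bound; default 5000).
#' @param minFractionExclusive exclusive-gene fraction bound (exclusive;
#'   default 0.5).
#' @return data.frame: start, end, group, n_genes, n_exclusive.
#' @export
exclusiveIslands <- function(geneTable, groups, minLen = 5000,
                             minFractionExclusive = 0.5) {
  strains <- intersect(colnames(geneTable), names(groups))
  gl <- groups[strains]
  gs <- setdiff(unique(gl), "excluded")
  if (length(gs) != 2) stop("two non-excluded groups required")
  pm <- as.matrix(geneTable[, strains, drop = FALSE])
  mode(pm) <- "numeric"
  gt <- geneTable[order(geneTable$start), , drop = FALSE]
  pm <- pm[order(geneTable$start), , drop = FALSE]
  out <- list()
  for (g in gs) {
    other <- setdiff(gs, g)
    excl <- rowSums(pm[, gl == g, drop = FALSE] == 1) == sum(gl == g) &
            rowSums(pm[, gl == other, drop = FALSE] == 1) == 0
    idx <- which(excl)
    if (!length(idx)) next
    i <- 1
    while (i <= length(idx)) {
      lo <- idx[i]; hi <- idx[i]
      j <- i + 1
      while (j <= length(idx)) {
        cand <- idx[j]
        frac <- sum(excl[lo:cand]) / (cand - lo + 1)
        if (frac > minFractionExclusive) { hi <- cand; j <- j + 1 }
        else break
      }
      span <- gt$end[hi] - gt$start[lo]
      ng <- hi - lo + 1
      if (span > minLen && sum(excl[lo:hi]) / ng > minFractionExclusive)
        out[[length(out) + 1L]] <- data.frame(
          start = gt$start[lo], end = gt$end[hi], group = g,
          n_genes = ng, n_exclusive = sum(excl[lo:hi]))
      i <- j
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      group = character(0), n_genes = integer(0),
                      n_exclusive = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}
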