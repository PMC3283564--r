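# Construction, IO and elementary structure of clonal genealogies.

.makeGenealogy <- function(leaves, parent, time) {
  n <- length(leaves)
  N <- 2L * n - 1L
  stopifnot(length(parent) == N, length(time) == N)
  # deterministic post-order branch IDs: DFS from the root, children visited
  # in increasing node index, nodes numbered on the way back up
  children <- vector("list", N)
  root <- which(parent == 0L)
  for (v in seq_len(N)) if (parent[v] > 0L)
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  children <- lapply(children, sort)
  branch <- rep(NA_integer_, N)
  nextId <- 0L
  # iterative post-order
  todo <- c(root)
  out <- integer(0)
  while (length(todo)) {
    v <- todo[length(todo)]
    todo <- todo[-length(todo)]
    out <- c(out, v)
    todo <- c(todo, children[[v]])
  }
  post <- rev(out)  # children before parents, deterministic
  for (v in post) {
    if (v != root) {
      nextId <- nextId + 1L
      branch[v] <- nextId
    }
  }
  branchNode <- integer(N - 1L)
  branchNode[branch[!is.na(branch)]] <- which(!is.na(branch))
  new("ClonalGenealogy", leaves = leaves, parent = as.integer(parent),
      time = as.numeric(time), branch = branch, branchNode = branchNode)
}

#' @describeIn ClonalGenealogy number of leaves
#' @param x,object a \code{ClonalGenealogy}
#' @export
nLeaves <- function(x) length(x@leaves)

#' @describeIn ClonalGenealogy strain names at the tips
#' @export
leafNames <- function(x) x@leaves

#' @describeIn ClonalGenealogy number of branches (2n - 2)
#' @export
nBranches <- function(x) length(x@branchNode)

#' @describeIn ClonalGenealogy time of the most recent common ancestor
#' @export
tmrca <- function(x) max(x@time)

#' @describeIn ClonalGenealogy sum of all branch lengths, in coalescent units
#' @export
totalBranchLength <- function(x) {
  nonroot <- which(x@parent > 0L)
  sum(x@time[x@parent[nonroot]] - x@time[nonroot])
}

#' Per-branch bookkeeping table
#'
#' One row per branch: its ID, the node below it, the parent node, the time
#' span it covers and its length. Used throughout the event simulator and
#' the flux tabulations.
#'
#' @param tree a [ClonalGenealogy-class]
#' @return data.frame with columns branch, node, parentNode, childTime,
#'   parentTime, length, isLeaf.
#' @export
branchTable <- function(tree) {
  nodes <- tree@branchNode
  data.frame(
    branch = seq_along(nodes),
    node = nodes,
    parentNode = tree@parent[nodes],
    childTime = tree@time[nodes],
    parentTime = tree@time[tree@parent[nodes]],
    length = tree@time[tree@parent[nodes]] - tree@time[nodes],
    isLeaf = nodes <= nLeaves(tree)
  )
}

setMethod("show", "ClonalGenealogy", function(object) {
  cat(sprintf(
    "ClonalGenealogy: %d leaves, %d branches, TMRCA %.4f coalescent units\n",
    nLeaves(object), nBranches(object), tmrca(object)))
  cat("  leaves:", paste(utils::head(object@leaves, 8), collapse = ", "),
      if (nLeaves(object) > 8) "..." else "", "\n")
})

#' Simulate a standard neutral (Kingman) coalescent genealogy
#'
#' While k lineages remain, the waiting time to the next coalescence is
#' Exponential with rate k(k-1)/2 and the merging pair is chosen uniformly.
#' The pair-coalescence rate is fixed at 1, so times come out in coalescent
#' units (N_e generations) directly.
#'
#' @param n number of leaves (>= 2).
#' @param seed optional integer seed.
#' @param leaves optional character vector of leaf names (default S1..Sn).
#' @return a [ClonalGenealogy-class]
#' @examples
#' tr <- simulateKingmanTree(12, seed = 1)
#' nBranches(tr)  # 22
#' @export
simulateKingmanTree <- function(n, seed = NULL, leaves = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(leaves)) leaves <- paste0("S", seq_len(n))
  N <- 2L * n - 1L
  parent <- integer(N)
  time <- numeric(N)
  active <- seq_len(n)
  t <- 0
  nxt <- n
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pair <- sample(active, 2L)
    nxt <- nxt + 1L
    parent[pair] <- nxt
    time[nxt] <- t
    active <- c(setdiff(active, pair), nxt)
  }
  .makeGenealogy(leaves, parent, time)
}

#' Simulate a two-group (split) genealogy with labeled leaves
#'
#' An island-divergence genealogy emulating two incipient species: within
#' each group, lineages coalesce under the neutral coalescent with a
#' subpopulation effective size of \code{withinNe} (relative to the
#' ancestral population, so the within-group pair rate is 1/withinNe); no
#' between-group coalescence is possible more recently than the split time,
#' after which all surviving lineages coalesce at the standard rate. Small
#' \code{withinNe} gives shallow, well-separated groups: with the defaults,
#' within-group pairwise diversity sits near the bottom and between-group
#' diversity near the top of the 0.01\%-0.35\% range when combined with the
#' default mutation intensity. Default sizes 7 and 3 strains mirror a small
#' two-lineage clonal population sample.
#'
#' @param nA,nB group sizes.
#' @param split time of the population split, in coalescent units.
#' @param withinNe relative effective size of each subpopulation (default
#'   0.1).
#' @param labels length-2 character vector of group names.
#' @param seed optional integer seed.
#' @return list with elements \code{tree} (a [ClonalGenealogy-class]) and
#'   \code{groups} (named character vector strain -> group).
#' @export
simulateTwoGroupTree <- function(nA = 7, nB = 3, split = 0.5, withinNe = 0.1,
                                 labels = c("Blue", "Red"), seed = NULL) {
  stopifnot(nA >= 1, nB >= 1, split >= 0, withinNe > 0, length(labels) == 2)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nA + nB)
  leaves <- c(paste0(labels[1], "_", seq_len(nA)),
              paste0(labels[2], "_", seq_len(nB)))
  N <- 2L * n - 1L
  parent <- integer(N)
  time <- numeric(N)
  nxt <- n
  coalesceUntil <- function(active, t0, tmax, ne = 1) {
    # coalesce within 'active' until tmax (Inf = to completion)
    t <- t0
    while (length(active) > 1L) {
      k <- length(active)
      w <- stats::rexp(1, rate = k * (k - 1) / 2 / ne)
      if (t + w > tmax) return(list(active = active, t = tmax))
      t <- t + w
      pair <- sample(active, 2L)
      nxt <<- nxt + 1L
      parent[pair] <<- nxt
      time[nxt] <<- t
      active <- c(setdiff(active, pair), nxt)
    }
    list(active = active, t = t)
  }
  a <- coalesceUntil(seq_len(nA), 0, split, ne = withinNe)
  b <- coalesceUntil(nA + seq_len(nB), 0, split, ne = withinNe)
  coalesceUntil(c(a$active, b$active), split, Inf)
  groups <- stats::setNames(rep(labels, c(nA, nB)), leaves)
  list(tree = .makeGenealogy(leaves, parent, time), groups = groups)
}

#' Read / write a clonal genealogy in Newick format
#'
#' Parsing enforces the invariants every downstream stage relies on: branch
#' lengths present, strictly binary topology, and ultrametric leaves within
#' a relative tolerance of 1e-6 of the TMRCA. Branch IDs are assigned by the
#' deterministic post-order rule, so a tree written and re-read keeps its
#' IDs.
#'
#' @param x a Newick string or the path of a file containing one tree.
#' @return a [ClonalGenealogy-class]
#' @examples
#' tr <- readNewickGenealogy("(A:1,B:1);")
#' tmrca(tr)  # 1
#' @export
readNewickGenealogy <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[(;]", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "") else x
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: no tree found")
  if (is.null(phy$edge.length)) stop("Newick parse error: missing branch lengths")
  n <- length(phy$tip.label)
  if (phy$Nnode != n - 1L)
    stop("polytomies are not supported: tree is not strictly binary")
  N <- 2L * n - 1L
  parent <- integer(N)
  depth <- numeric(N)
  root <- n + 1L
  # edges are parent->child; compute depths from the root
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; v <- ord$edge[i, 2]
    parent[v] <- p
    depth[v] <- depth[p] + ord$edge.length[i]
  }
  tm <- max(depth[seq_len(n)])
  tol <- 1e-6 * max(tm, 1)
  bad <- which(abs(depth[seq_len(n)] - tm) > tol)
  if (length(bad))
    stop("tree is not ultrametric: leaf '", phy$tip.label[bad[1]],
         "' is at depth ", format(depth[bad[1]]), " but TMRCA is ", format(tm))
  time <- tm - depth
  time[seq_len(n)] <- 0
  .makeGenealogy(phy$tip.label, parent, time)
}

#' @rdname readNewickGenealogy
#' @param tree a [ClonalGenealogy-class]
#' @param file optional path; if NULL the Newick string is returned.
#' @export
writeNewickGenealogy <- function(tree, file = NULL) {
  phy <- asPhylo(tree)
  txt <- ape::write.tree(phy)
  if (is.null(file)) txt else writeLines(txt, file)
}

#' Convert a ClonalGenealogy to an ape "phylo" object
#'
#' Internal nodes are renumbered in preorder (root first) as \pkg{ape}
#' requires; leaf order is preserved.
#'
#' @param tree a [ClonalGenealogy-class]
#' @export
asPhylo <- function(tree) {
  n <- nLeaves(tree)
  N <- 2L * n - 1L
  root <- which(tree@parent == 0L)
  children <- vector("list", N)
  for (v in seq_len(N)) if (tree@parent[v] > 0L)
    children[[tree@parent[v]]] <- c(children[[tree@parent[v]]], v)
  # preorder renumbering of internal nodes
  newId <- integer(N)
  newId[seq_len(n)] <- seq_len(n)
  ctr <- n
  todo <- root
  while (length(todo)) {
    v <- todo[1]; todo <- todo[-1]
    if (v > n) { ctr <- ctr + 1L; newId[v] <- ctr }
    todo <- c(sort(children[[v]]), todo)
  }
  nonroot <- setdiff(seq_len(N), root)
  edge <- cbind(newId[tree@parent[nonroot]], newId[nonroot])
  elen <- tree@time[tree@parent[nonroot]] - tree@time[nonroot]
  o <- order(edge[, 1], edge[, 2])
  phy <- list(edge = edge[o, , drop = FALSE], edge.length = elen[o],
              tip.label = tree@leaves, Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Lineage count through time
#'
#' The piecewise-constant number of clonal lineages k(t): n at the present,
#' decreasing by one at each coalescence, 1 above the root. The integral of
#' k(t) over [0, TMRCA] equals the total branch length, which the
#' coalescent-with-gene-conversion departure process relies on.
#'
#' @param tree a [ClonalGenealogy-class]
#' @return data.frame with columns start, end, k (last row has end = Inf,
#'   k = 1).
#' @export
branchEpochs <- function(tree) {
  n <- nLeaves(tree)
  ct <- sort(tree@time[tree@time > 0])
  starts <- c(0, ct)
  ends <- c(ct, Inf)
  data.frame(start = starts, end = ends, k = seq(n, 1))
}

#' Branches extant in each inter-coalescence epoch (internal)
#' @noRd
.epochBranches <- function(tree) {
  ep <- branchEpochs(tree)
  bt <- branchTable(tree)
  lapply(seq_len(nrow(ep) - 1L), function(i) {
    bt$branch[bt$childTime <= ep$start[i] + 1e-12 &
              bt$parentTime >= ep$end[i] - 1e-12]
  })
}

#' Leaves descending from each node (internal)
#' @noRd
.leavesBelow <- function(tree) {
  n <- nLeaves(tree)
  N <- 2L * n - 1L
  below <- vector("list", N)
  for (v in seq_len(n)) below[[v]] <- v
  ord <- order(tree@time)  # children always precede parents
  for (v in ord) {
    p <- tree@parent[v]
    if (p > 0L) below[[p]] <- c(below[[p]], below[[v]])
  }
  below
}

#' Group attribution of a branch
#'
#' A branch belongs to a group G if and only if every leaf below it is
#' labeled G; mixed subtrees, branches above a group's MRCA and the root
#' side are UNASSIGNED. Events donated by UNASSIGNED branches cannot be
#' attributed to either lineage in group-level flux summaries.
#'
#' @param tree a [ClonalGenealogy-class]
#' @param groups named character vector strain -> group label.
#' @param branch integer vector of branch IDs (default: all).
#' @return character vector of group labels or \code{UNASSIGNED}.
#' @export
branchGroup <- function(tree, groups, branch = seq_len(nBranches(tree))) {
  if (!all(tree@leaves %in% names(groups)))
    stop("every leaf needs a group label; missing: ",
         paste(setdiff(tree@leaves, names(groups)), collapse = ", "))
  if (any(branch < 1 | branch > nBranches(tree)))
    stop("unknown branch ID: ",
         paste(branch[branch < 1 | branch > nBranches(tree)], collapse = ", "))
  below <- .leavesBelow(tree)
  vapply(branch, function(b) {
    lv <- below[[tree@branchNode[b]]]
    g <- unique(unname(groups[tree@leaves[lv]]))
    if (length(g) == 1L) g else UNASSIGNED
  }, character(1))
}

#' Read strain -> group labels from a two-column TSV
#'
#' Columns: strain, group (no header by default). Strains labeled
#' \code{"excluded"} stay on the tree but are dropped from group contrasts.
#'
#' @param path file path.
#' @param header logical.
#' @return named character vector.
#' @export
readGroupLabels <- function(path, header = FALSE) {
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  stats::setNames(as.character(d[[2]]), as.character(d[[1]]))
}
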