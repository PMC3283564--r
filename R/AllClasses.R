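#' ClonalGenealogy: a rooted, binary, ultrametric clonal genealogy
#'
#' Represents the tree of vertical descent of a clonal sample. Leaves sit at
#' time 0 and internal nodes at their coalescence times, measured backwards
#' in coalescent units (one unit = effective population size times the
#' generation length). Every non-root node is identified with the branch
#' above it; branches carry stable integer IDs assigned by a deterministic
#' post-order traversal, so that recombination-event tables written from one
#' session resolve to the same branches in another.
#'
#' Node numbering follows the \pkg{ape} convention: leaves are nodes
#' \code{1..n} (in the order of \code{leaves}), internal nodes are
#' \code{n+1..2n-1}.
#'
#' @slot leaves character vector of strain names, one per tip.
#' @slot parent integer vector over all \code{2n-1} nodes; \code{0} marks the
#'   root.
#' @slot time numeric vector of node times before present (leaves at 0).
#' @slot branch integer vector mapping node -> branch ID (\code{NA} at the
#'   root).
#' @slot branchNode integer vector mapping branch ID -> node.
#'
#' @seealso [simulateKingmanTree()], [readNewickGenealogy()],
#'   [branchEpochs()], [branchGroup()]
#' @export
setClass("ClonalGenealogy",
  representation(
    leaves     = "character",
    parent     = "integer",
    time       = "numeric",
    branch     = "integer",
    branchNode = "integer"
  )
)

.validClonalGenealogy <- function(object) {
  n <- length(object@leaves)
  N <- 2L * n - 1L
  msg <- character()
  if (n < 2)
    msg <- c(msg, "a genealogy needs at least 2 leaves")
  if (length(object@parent) != N || length(object@time) != N)
    msg <- c(msg, sprintf("parent/time must have length 2n-1 = %d", N))
  if (length(msg)) return(msg)
  roots <- which(object@parent == 0L)
  if (length(roots) != 1L)
    msg <- c(msg, "exactly one root required")
  nchild <- tabulate(object@parent[object@parent > 0L], nbins = N)
  if (any(nchild[seq_len(n)] != 0L))
    msg <- c(msg, "leaves must not have children")
  internal <- setdiff(seq_len(N), seq_len(n))
  if (any(nchild[internal] != 2L))
    msg <- c(msg, "tree must be binary (every internal node has 2 children)")
  tm <- tmrca_times(object@time, n)
  tol <- 1e-6 * max(tm, 1)
  if (any(abs(object@time[seq_len(n)]) > tol))
    msg <- c(msg, "leaves must sit at time 0 (ultrametric)")
  nonroot <- which(object@parent > 0L)
  if (any(object@time[object@parent[nonroot]] <= object@time[nonroot] - tol))
    msg <- c(msg, "parent time must exceed child time")
  if (length(object@branchNode) != N - 1L)
    msg <- c(msg, "a genealogy with n leaves has 2n-2 branches")
  if (length(msg)) msg else TRUE
}
setValidity("ClonalGenealogy", .validClonalGenealogy)

tmrca_times <- function(time, n) max(time)

#' FluxMatrix: observed vs expected recombination flux per branch pair
#'
#' Holds, for every ordered (donor, recipient) pair of branches of a clonal
#' genealogy (plus a pseudo-donor row for lineages coalescing above the
#' root), the observed number of recombination events, the number expected
#' under the neutral coalescent-with-gene-conversion prior scaled to the
#' global observed total, their ratio, a per-cell significance mask
#' (cells with fewer than four observed and expected events are flagged
#' non-significant), and optionally an exact two-sided Poisson p-value.
#'
#' @slot observed numeric matrix, donors (rows) x recipients (columns).
#' @slot expected numeric matrix, same shape, scaled to the observed total.
#' @slot ratio numeric matrix, observed/expected (NA where expected is 0).
#' @slot masked logical matrix; TRUE = non-significant per the <4 rule.
#' @slot pvalue numeric matrix of exact Poisson p-values (NA where masked or
#'   expected is 0).
#' @slot nEvents integer, total number of events tabulated.
#'
#' @seealso [fluxRatio()], [observedFlux()], [expectedFlux()]
#' @export
setClass("FluxMatrix",
  representation(
    observed = "matrix",
    expected = "matrix",
    ratio    = "matrix",
    masked   = "matrix",
    pvalue   = "matrix",
    nEvents  = "integer"
  )
)

#' CoreAlignment: a blockwise core-genome multiple alignment
#'
#' An ordered list of alignment blocks shared by all included strains, each
#' mapped onto the coordinate system of a designated reference strain.
#' Intervals are 0-based half-open throughout.
#'
#' @slot blocks list; each element is a list with \code{seqs} (named
#'   character vector of equal-length aligned sequences) and \code{refStart}
#'   (0-based start of the block on the reference strain).
#' @slot reference name of the reference strain.
#'
#' @seealso [readXmfa()], [splitCoreBlocks()], [extractSnps()]
#' @export
setClass("CoreAlignment",
  representation(blocks = "list", reference = "character")
)

.validCoreAlignment <- function(object) {
  msg <- character()
  for (i in seq_along(object@blocks)) {
    b <- object@blocks[[i]]
    if (!all(c("seqs", "refStart") %in% names(b)))
      return(sprintf("block %d lacks seqs/refStart", i))
    w <- nchar(b$seqs)
    if (length(unique(w)) != 1L)
      msg <- c(msg, sprintf("block %d is ragged (unequal aligned lengths)", i))
    if (anyDuplicated(names(b$seqs)))
      msg <- c(msg, sprintf("block %d has a duplicated strain", i))
    if (!(object@reference %in% names(b$seqs)))
      msg <- c(msg, sprintf("reference strain absent from block %d", i))
  }
  if (length(msg)) msg else TRUE
}
setValidity("CoreAlignment", .validCoreAlignment)

#' Sentinel donor label for lineages coalescing above the root
#'
#' Recombinant lineages traced backwards past the most recent common
#' ancestor coalesce with the root lineage; such events carry this label in
#' place of a donor branch ID. The pseudo-donor keeps flux matrices
#' conservative (their grand total equals the event count) but is always
#' UNASSIGNED for group-level analyses.
#'
#' @export
ABOVE_ROOT <- "ABOVE_ROOT"

#' Group label for branches not attributable to a single group
#' @rdname ABOVE_ROOT
#' @export
UNASSIGNED <- "UNASSIGNED"
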