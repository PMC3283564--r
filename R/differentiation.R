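# SNP extraction and classification, haploid Hudson-style F_ST at SNP, gene
# and window resolution, low-differentiation region calling, and the
# divergence-vs-recombination regression.

.alleleMatrix <- function(snps) {
  as.matrix(snps[, setdiff(colnames(snps), "pos"), drop = FALSE])
}

#' Extract clean polymorphic SNP columns from a core alignment
#'
#' Columns containing a gap or ambiguity character in any included strain
#' are dropped (indels and partially covered columns carry no usable SNP),
#' as are monomorphic columns. By default every clean polymorphic column is
#' reported ("informative" in the broad sense); \code{minMinorCount = 2}
#' restricts to columns whose minor allele is seen at least twice.
#'
#' @param x a [CoreAlignment-class], or a character matrix (strains x sites,
#'   alignment coordinates used as reference coordinates).
#' @param strains strains to include (default: all).
#' @param minMinorCount minimum minor-allele count (default 1).
#' @return SNP table: data.frame with column \code{pos} (0-based position on
#'   the reference) and one allele column per included strain; positions
#'   strictly increasing.
#' @export
extractSnps <- function(x, strains = NULL, minMinorCount = 1) {
  blocks <- if (is(x, "CoreAlignment")) {
    if (!is.null(strains) && !all(vapply(x@blocks, function(b)
      all(strains %in% names(b$seqs)), logical(1))))
      stop("some included strains are absent from a core block")
    lapply(x@blocks, function(b) {
      m <- do.call(rbind, strsplit(toupper(b$seqs), ""))
      rownames(m) <- names(b$seqs)
      list(m = m, refStart = b$refStart, ref = x@reference)
    })
  } else {
    list(list(m = toupper(x), refStart = 0L, ref = rownames(x)[1]))
  }
  out <- list()
  for (b in blocks) {
    m <- b$m
    if (!is.null(strains)) m <- m[strains, , drop = FALSE]
    if (!(b$ref %in% rownames(b$m)))
      stop("reference strain '", b$ref, "' absent from alignment")
    refRow <- b$m[b$ref, ]
    refPos <- b$refStart + cumsum(refRow %in% NUC) - 1L
    clean <- apply(m, 2, function(col) all(col %in% NUC))
    poly <- apply(m, 2, function(col) length(unique(col)) > 1L)
    keep <- clean & poly & (refRow %in% NUC)
    if (minMinorCount > 1) {
      mac <- apply(m, 2, function(col) {
        tb <- sort(table(col), decreasing = TRUE)
        if (length(tb) < 2) 0L else sum(tb[-1])
      })
      keep <- keep & mac >= minMinorCount
    }
    if (!any(keep)) next
    d <- cbind(data.frame(pos = refPos[keep]),
               as.data.frame(t(m[, keep, drop = FALSE]),
                             stringsAsFactors = FALSE))
    out[[length(out) + 1L]] <- d
  }
  if (!length(out)) {
    strains2 <- if (!is.null(strains)) strains else
      rownames(if (is(x, "CoreAlignment")) NULL else x)
    d <- data.frame(pos = integer(0))
    for (s in strains2) d[[s]] <- character(0)
    return(d)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify SNPs as fixed between, polymorphic within, or shared
#'
#' A SNP is a fixed difference when each of the two groups is monomorphic
#' and their alleles differ; polymorphic-within when exactly one group
#' segregates; shared when both groups segregate. Strains labeled
#' "excluded" are dropped before classification. The summary reports the
#' fixed-difference count and its percentage of the table (rounded to the
#' nearest integer), the headline statistic of between-lineage
#' differentiation.
#'
#' @param snps SNP table from [extractSnps()].
#' @param groups named strain -> group vector with exactly two non-excluded
#'   groups among the table's strains.
#' @return list: \code{class} (character vector per SNP), \code{counts},
#'   \code{nFixed}, \code{percentFixed}.
#' @export
classifySnps <- function(snps, groups) {
  am <- .alleleMatrix(snps)
  gl <- groups[colnames(am)]
  use <- !is.na(gl) & gl != "excluded"
  gs <- unique(gl[use])
  if (length(gs) != 2) stop("exactly two non-excluded groups required, got: ",
                            paste(gs, collapse = ", "))
  ia <- which(use & gl == gs[1]); ib <- which(use & gl == gs[2])
  if (!length(ia) || !length(ib)) stop("a group has zero included strains")
  cls <- apply(am, 1, function(row) {
    a <- unique(row[ia]); b <- unique(row[ib])
    if (length(a) == 1 && length(b) == 1) {
      if (a != b) "fixed_between" else "monomorphic"
    } else if (length(a) > 1 && length(b) > 1) "shared"
    else "polymorphic_within"
  })
  nFixed <- sum(cls == "fixed_between")
  list(class = cls, counts = table(cls), nFixed = nFixed,
       percentFixed = round(100 * nFixed / length(cls)))
}

# pooled within/between diversity sums over the rows of an allele matrix
.hwHb <- function(am, ia, ib) {
  nA <- length(ia); nB <- length(ib)
  hw <- 0; hb <- 0
  for (r in seq_len(nrow(am))) {
    a <- am[r, ia]; b <- am[r, ib]
    ta <- table(a); tb <- table(b)
    wA <- if (nA >= 2) (nA^2 - sum(ta^2)) / (nA * (nA - 1)) else NA_real_
    wB <- if (nB >= 2) (nB^2 - sum(tb^2)) / (nB * (nB - 1)) else NA_real_
    alleles <- union(names(ta), names(tb))
    cab <- sum(as.numeric(ta[alleles]) * as.numeric(tb[alleles]), na.rm = TRUE)
    btw <- (nA * nB - cab) / (nA * nB)
    hw <- hw + mean(c(wA, wB))
    hb <- hb + btw
  }
  c(hw = hw, hb = hb)
}

#' Haploid Hudson-style F_ST
#'
#' F_ST = 1 - H_w / H_b, where H_w is the unweighted mean over the two
#' groups of the mean pairwise difference within each group and H_b is the
#' mean pairwise difference between groups. Over multiple SNPs (a window or
#' a gene) the diversities are pooled (summed) across sites before the
#' ratio. Undefined (NA) when H_b = 0; negative values are retained, not
#' clamped.
#'
#' Call either with two per-group allele vectors for a single site, or with
#' a SNP table and a group labeling for a pooled value.
#'
#' @param x allele vector of group A, or a SNP table from [extractSnps()].
#' @param y allele vector of group B (vector form only).
#' @param groups named strain -> group vector (table form only; "excluded"
#'   strains dropped).
#' @return a single F_ST value.
#' @examples
#' hudsonFst(c("A", "A", "A", "T"), c("T", "T", "T"))  # 2/3
#' @export
hudsonFst <- function(x, y = NULL, groups = NULL) {
  if (!is.null(y)) {
    if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 members")
    am <- matrix(c(x, y), nrow = 1)
    h <- .hwHb(am, seq_along(x), length(x) + seq_along(y))
  } else {
    if (is.null(groups)) stop("groups required for the SNP-table form")
    am <- .alleleMatrix(x)
    gl <- groups[colnames(am)]
    use <- !is.na(gl) & gl != "excluded"
    gs <- unique(gl[use])
    if (length(gs) != 2) stop("exactly two non-excluded groups required")
    ia <- which(use & gl == gs[1]); ib <- which(use & gl == gs[2])
    if (length(ia) < 2 || length(ib) < 2)
      stop("each group needs >= 2 members")
    if (nrow(am) == 0) return(NA_real_)
    h <- .hwHb(am, ia, ib)
  }
  if (h["hb"] == 0) return(NA_real_)
  unname(1 - h["hw"] / h["hb"])
}

#' Sliding-window F_ST along the reference
#'
#' Windows are anchored at position 0 of the reference with the stated size
#' and step (0-based half-open; partial terminal windows are dropped). A
#' window is not computed when it contains no SNPs or overlaps reference
#' positions not covered in all included strains. Diversities are pooled
#' across the window's SNPs before the ratio.
#'
#' @param snps SNP table from [extractSnps()].
#' @param groups named strain -> group vector.
#' @param refLength length of the reference coordinate system.
#' @param coverage optional logical vector of length refLength, TRUE where
#'   the reference position is present in all strains (default: everywhere).
#' @param window,step window size and step in bp.
#' @return data.frame with columns start, end, n_snps, computed, fst.
#' @export
windowFst <- function(snps, groups, refLength, coverage = NULL,
                      window = 10000, step = 5000) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  starts <- seq(0L, refLength - window, by = step)
  if (!length(starts)) stop("reference shorter than one window")
  am <- .alleleMatrix(snps)
  gl <- groups[colnames(am)]
  use <- !is.na(gl) & gl != "excluded"
  gs <- unique(gl[use])
  ia <- which(use & gl == gs[1]); ib <- which(use & gl == gs[2])
  res <- data.frame(start = starts, end = starts + window,
                    n_snps = 0L, computed = FALSE, fst = NA_real_)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- s + window
    if (!is.null(coverage) && !all(coverage[(s + 1):e])) next
    rows <- which(snps$pos >= s & snps$pos < e)
    res$n_snps[i] <- length(rows)
    if (!length(rows)) next
    h <- .hwHb(am[rows, , drop = FALSE], ia, ib)
    res$computed[i] <- TRUE
    res$fst[i] <- if (h["hb"] == 0) NA_real_ else unname(1 - h["hw"] / h["hb"])
  }
  res
}

#' Call low-differentiation regions and differentiated continents
#'
#' Low regions begin and end with a window whose F_ST value is below the
#' threshold; low windows separated by a differentiated stretch shorter
#' than \code{mergeGap} are merged into one region. Complementary
#' differentiated stretches spanning at least \code{mergeGap} are reported
#' as continents.
#'
#' @param windows data.frame from [windowFst()].
#' @param threshold F_ST threshold (default 0.5).
#' @param mergeGap minimum span (bp) of a differentiated stretch that
#'   separates two low regions (default 250 kb).
#' @return data.frame with columns start, end, class ("low" or
#'   "continent").
#' @export
callRegions <- function(windows, threshold = 0.5, mergeGap = 250000) {
  w <- windows[windows$computed & !is.na(windows$fst), , drop = FALSE]
  w <- w[order(w$start), , drop = FALSE]
  low <- w[w$fst < threshold, , drop = FALSE]
  regions <- data.frame(start = integer(0), end = integer(0),
                        class = character(0))
  if (nrow(low)) {
    rs <- low$start[1]; re <- low$end[1]
    for (i in seq_len(nrow(low))[-1]) {
      if (low$start[i] - re < mergeGap) {
        re <- max(re, low$end[i])
      } else {
        regions <- rbind(regions,
                         data.frame(start = rs, end = re, class = "low"))
        rs <- low$start[i]; re <- low$end[i]
      }
    }
    regions <- rbind(regions, data.frame(start = rs, end = re, class = "low"))
  }
  # continents: high stretches >= mergeGap between/around low regions
  bounds <- c(min(w$start), max(w$end))
  gaps <- if (nrow(regions))
    data.frame(start = c(bounds[1], regions$end),
               end = c(regions$start, bounds[2]))
  else data.frame(start = bounds[1], end = bounds[2])
  gaps <- gaps[gaps$end - gaps$start >= mergeGap, , drop = FALSE]
  if (nrow(gaps))
    regions <- rbind(regions, data.frame(start = gaps$start, end = gaps$end,
                                         class = "continent"))
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Per-gene pooled F_ST and the fraction of weakly differentiated genes
#'
#' Applies gene coordinates to the SNP table; each gene's F_ST pools the
#' diversities of its SNPs. Genes without SNPs (no detected variation) are
#' excluded from the denominator of the summary percentage.
#'
#' @param snps SNP table from [extractSnps()].
#' @param geneTable data.frame with columns gene_id, start, end (0-based
#'   half-open; see [readGeneTable()] for 1-based input).
#' @param groups named strain -> group vector.
#' @param threshold F_ST threshold for the summary (default 0.5).
#' @return list: \code{perGene} (gene_id, n_snps, fst), \code{nVariable},
#'   \code{nBelow}, \code{percentBelow}.
#' @export
geneFst <- function(snps, geneTable, groups, threshold = 0.5) {
  am <- .alleleMatrix(snps)
  gl <- groups[colnames(am)]
  use <- !is.na(gl) & gl != "excluded"
  gs <- unique(gl[use])
  ia <- which(use & gl == gs[1]); ib <- which(use & gl == gs[2])
  bad <- is.na(geneTable$start) | is.na(geneTable$end) |
    geneTable$end <= geneTable$start
  if (any(bad)) {
    warning(sum(bad), " malformed gene coordinates skipped")
    geneTable <- geneTable[!bad, , drop = FALSE]
  }
  fst <- rep(NA_real_, nrow(geneTable))
  nsn <- integer(nrow(geneTable))
  for (i in seq_len(nrow(geneTable))) {
    rows <- which(snps$pos >= geneTable$start[i] & snps$pos < geneTable$end[i])
    nsn[i] <- length(rows)
    if (!length(rows)) next
    h <- .hwHb(am[rows, , drop = FALSE], ia, ib)
    fst[i] <- if (h["hb"] == 0) NA_real_ else unname(1 - h["hw"] / h["hb"])
  }
  perGene <- data.frame(gene_id = geneTable$gene_id, n_snps = nsn, fst = fst)
  defined <- which(!is.na(fst))
  nBelow <- sum(fst[defined] < threshold)
  list(perGene = perGene, nVariable = length(defined), nBelow = nBelow,
       percentBelow = round(100 * nBelow / max(length(defined), 1)))
}

#' Permutation test for F_ST significance
#'
#' Group labels are permuted uniformly across the included strains;
#' p = (1 + number of permuted F_ST >= observed) / (1 + nPerm).
#'
#' @param snps SNP table from [extractSnps()].
#' @param groups named strain -> group vector.
#' @param nPerm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @return list: \code{fst} observed, \code{p}.
#' @export
fstPermutationTest <- function(snps, groups, nPerm = 999, seed = NULL) {
  stopifnot(nPerm >= 99)
  if (!is.null(seed)) set.seed(seed)
  am <- .alleleMatrix(snps)
  gl <- groups[colnames(am)]
  use <- which(!is.na(gl) & gl != "excluded")
  labs <- gl[use]
  if (length(unique(labs)) != 2) stop("two non-excluded groups required")
  obs <- hudsonFst(snps, groups = groups)
  if (is.na(obs)) stop("observed F_ST undefined (H_b = 0)")
  cnt <- 0L
  for (i in seq_len(nPerm)) {
    perm <- stats::setNames(sample(labs), colnames(am)[use])
    f <- hudsonFst(snps, groups = perm)
    if (!is.na(f) && f >= obs) cnt <- cnt + 1L
  }
  list(fst = obs, p = (1 + cnt) / (1 + nPerm))
}

#' Recombination frequency versus local polymorphism
#'
#' Splits the alignment into windows (default 1 kb); per window, x is the
#' mean pairwise diversity and y the number of recombination events whose
#' tract overlaps the window, normalized so the maximum window count is 1.
#' Returns the ordinary least-squares slope and R-squared: under mismatch-
#' driven inhibition of recombination a negative correlation is expected,
#' while values near zero indicate recombination insensitive to local
#' divergence.
#'
#' @param events event table with columns start, end.
#' @param alignment character matrix strains x sites.
#' @param window window size in bp (default 1000).
#' @return list: \code{slope}, \code{r2}, \code{data} (per-window x/y).
#' @export
divergenceRecombinationRegression <- function(events, alignment,
                                              window = 1000) {
  L <- ncol(alignment)
  n <- nrow(alignment)
  starts <- seq(0L, L - window, by = window)
  if (length(starts) < 3) stop("fewer than 3 windows")
  # per-column diversity from allele counts
  counts <- sapply(NUC, function(b) colSums(alignment == b))
  m <- rowSums(counts)  # non-gap copies per column
  divcol <- ifelse(m >= 2, (m^2 - rowSums(counts^2)) / (m * (m - 1)), 0)
  x <- vapply(starts, function(s) mean(divcol[(s + 1):(s + window)]),
              numeric(1))
  y <- vapply(starts, function(s)
    sum(events$start < s + window & events$end > s), numeric(1))
  if (max(y) > 0) y <- y / max(y)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       r2 = summary(fit)$r.squared,
       data = data.frame(start = starts, diversity = x, recombination = y))
}
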