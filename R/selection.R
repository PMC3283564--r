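# Nei-Gojobori (1986) synonymous/nonsynonymous counting with Jukes-Cantor
# correction, and the McDonald-Kreitman contrast of fixed vs polymorphic
# variants between two lineages.

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (any(is.na(aa))) stop("not a valid codon: ",
                           paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

.isStop <- function(codon) .translateCodon(codon) == "*"

# memoized per-codon site counts and per-pair difference counts
.ng86Env <- new.env(parent = emptyenv())

.ng86SiteTable <- function() {
  if (is.null(.ng86Env$sites)) {
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    .ng86Env$sites <- vapply(sense, function(cd) ng86Sites(cd)["s"],
                             numeric(1))
    names(.ng86Env$sites) <- sense
  }
  .ng86Env$sites
}

.codonDiffsCached <- function(ca, cb) {
  key <- paste0(ca, cb)
  v <- .ng86Env$pairs[[key]]
  if (is.null(v)) {
    v <- .codonDiffs(ca, cb)
    if (is.null(.ng86Env$pairs)) .ng86Env$pairs <- list()
    .ng86Env$pairs[[key]] <- v
  }
  v
}

#' Potential synonymous and nonsynonymous sites of a codon (NG86)
#'
#' At each of the three positions, the synonymous-site contribution is the
#' fraction of the possible single-nucleotide changes that are synonymous,
#' with changes to stop codons excluded from the denominator; the
#' nonsynonymous contribution is the complement, so s + n = 3 for every
#' sense codon.
#'
#' @param codon a 3-letter sense codon (standard genetic code).
#' @return named numeric c(s, n).
#' @examples
#' ng86Sites("TTT")  # s = 1/3
#' ng86Sites("ATG")  # s = 0
#' @export
ng86Sites <- function(codon) {
  codon <- toupper(codon)
  if (.isStop(codon)) stop("stop codon input: ", codon)
  cs <- strsplit(codon, "")[[1]]
  aa0 <- .translateCodon(codon)
  s <- 0
  for (p in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in setdiff(NUC, cs[p])) {
      alt <- cs; alt[p] <- b
      altc <- paste(alt, collapse = "")
      if (.isStop(altc)) next
      nonstop <- nonstop + 1
      if (.translateCodon(altc) == aa0) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(s = s, n = 3 - s)
}

# average synonymous/nonsynonymous difference counts between two codons,
# over all orderings of single-step mutational pathways; pathways passing
# through a stop codon are excluded (if every pathway is blocked, all are
# used as a fallback)
.codonDiffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(pos) else {
    idx <- if (k == 2) list(c(1, 2), c(2, 1)) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(o) pos[o])
  }
  paths <- lapply(perms, function(ord) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (.isStop(c2)) blocked <- TRUE
      if (.translateCodon0(c1) == .translateCodon0(c2)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  ok <- !vapply(paths, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  sd <- mean(vapply(paths[ok], `[[`, numeric(1), "sd"))
  nd <- mean(vapply(paths[ok], `[[`, numeric(1), "nd"))
  c(sd = sd, nd = nd)
}

# translation that tolerates stop codons (used inside pathway enumeration)
.translateCodon0 <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

#' Pairwise dN/dS by the Nei-Gojobori method with Jukes-Cantor correction
#'
#' Potential sites are averaged over the two sequences; observed differences
#' at codons differing at more than one position are averaged over all
#' orderings of single-step pathways, excluding pathways through stop
#' codons. Proportions pS = Sd/S and pN = Nd/N are corrected for multiple
#' hits as d = -(3/4) ln(1 - (4/3) p); d is undefined when p >= 3/4, and
#' the ratio is undefined when dS = 0.
#'
#' @param seqA,seqB equal-length, gap-free, stop-free coding sequences
#'   (strings, length divisible by 3).
#' @return list with S, N (mean potential sites), Sd, Nd, pS, pN, dS, dN,
#'   dNdS (NA when undefined).
#' @export
ng86Pair <- function(seqA, seqB) {
  a <- toupper(seqA); b <- toupper(seqB)
  if (nchar(a) != nchar(b)) stop("sequence length mismatch")
  if (nchar(a) %% 3 != 0) stop("length not divisible by 3")
  nc <- nchar(a) / 3
  ca <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cb <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  if (any(.translateCodon0(ca) == "*") || any(.translateCodon0(cb) == "*"))
    stop("internal stop codon")
  st <- .ng86SiteTable()
  S <- (sum(st[ca]) + sum(st[cb])) / 2
  N <- 3 * nc - S
  Sd <- 0; Nd <- 0
  for (i in which(ca != cb)) {
    d <- .codonDiffsCached(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  ratio <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
       dNdS = ratio)
}

#' Mean between-group dN/dS for a gene
#'
#' Runs [ng86Pair()] over every between-group pair of strains (and over all
#' pairs for comparison) and averages the defined ratios. Genes whose
#' between-group mean exceeds 1 are candidates for diversifying selection.
#'
#' @param alignment named character vector of equal-length coding sequences,
#'   or a character matrix strains x sites.
#' @param groups named strain -> group vector ("excluded" strains dropped).
#' @return list: \code{meanBetween}, \code{meanAll}, \code{flagged}
#'   (between-group mean > 1), \code{pairs} (per-pair table).
#' @export
geneGroupDnds <- function(alignment, groups) {
  seqs <- .asSeqVector(alignment)
  gl <- groups[names(seqs)]
  use <- !is.na(gl) & gl != "excluded"
  seqs <- seqs[use]; gl <- gl[use]
  gs <- unique(gl)
  if (length(gs) != 2) stop("two non-excluded groups required")
  cmb <- utils::combn(length(seqs), 2)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    i1 <- cmb[1, i]; i2 <- cmb[2, i]
    r <- ng86Pair(seqs[i1], seqs[i2])
    data.frame(strainA = names(seqs)[i1], strainB = names(seqs)[i2],
               between = gl[i1] != gl[i2], dN = r$dN, dS = r$dS,
               dNdS = r$dNdS)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  mb <- mean(tab$dNdS[tab$between], na.rm = TRUE)
  ma <- mean(tab$dNdS, na.rm = TRUE)
  if (all(is.na(tab$dNdS[tab$between]))) mb <- NA_real_
  list(meanBetween = mb, meanAll = ma,
       flagged = !is.na(mb) && mb > 1, pairs = tab)
}

.asSeqVector <- function(alignment) {
  if (is.matrix(alignment))
    stats::setNames(apply(alignment, 1, paste0, collapse = ""),
                    rownames(alignment))
  else alignment
}

#' McDonald-Kreitman test on a per-gene codon alignment
#'
#' Each clean variable codon position is classified as a fixed difference
#' or a polymorphism between the two groups (the same monomorphism
#' semantics as [classifySnps()]) and as synonymous or nonsynonymous
#' against its codon context. Codons with more than one segregating
#' position, or with more than two alleles at the segregating position, are
#' excluded by default to avoid ambiguous calls. The neutrality index is
#' NI = (Pn/Ps)/(Dn/Ds) and the p-value is the exact two-sided Fisher test
#' on the 2x2 table (no continuity or multiple-testing correction).
#'
#' @param alignment named character vector of coding sequences or a matrix
#'   strains x sites.
#' @param groups named strain -> group vector.
#' @return list: Dn, Ds, Pn, Ps, NI (NA when undefined), p (NA when the
#'   table is empty or degenerate).
#' @export
mkTest <- function(alignment, groups) {
  seqs <- .asSeqVector(alignment)
  gl <- groups[names(seqs)]
  use <- !is.na(gl) & gl != "excluded"
  seqs <- seqs[use]; gl <- gl[use]
  gs <- unique(gl)
  if (length(gs) != 2) stop("two non-excluded groups required")
  len <- unique(nchar(seqs))
  if (length(len) != 1 || len %% 3 != 0)
    stop("sequences must be aligned with length divisible by 3")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  Dn <- Ds <- Pn <- Ps <- 0L
  for (cd in seq_len(len / 3)) {
    cols <- (3 * cd - 2):(3 * cd)
    sub <- m[, cols, drop = FALSE]
    if (!all(sub %in% NUC)) next
    seg <- which(apply(sub, 2, function(x) length(unique(x)) > 1L))
    if (length(seg) != 1L) next  # multi-segregating codons excluded
    alleles <- unique(sub[, seg])
    if (length(alleles) != 2L) next
    # synonymous or nonsynonymous in codon context
    base <- sub[1, ]
    c1 <- base; c1[seg] <- alleles[1]
    c2 <- base; c2[seg] <- alleles[2]
    t1 <- .translateCodon0(paste(c1, collapse = ""))
    t2 <- .translateCodon0(paste(c2, collapse = ""))
    if (t1 == "*" || t2 == "*") next
    syn <- t1 == t2
    a <- unique(sub[gl == gs[1], seg]); b <- unique(sub[gl == gs[2], seg])
    fixed <- length(a) == 1 && length(b) == 1 && a != b
    if (fixed) {
      if (syn) Ds <- Ds + 1L else Dn <- Dn + 1L
    } else {
      if (syn) Ps <- Ps + 1L else Pn <- Pn + 1L
    }
  }
  NI <- if (Ps > 0 && Dn > 0 && Ds > 0) (Pn / Ps) / (Dn / Ds) else NA_real_
  p <- if (Dn + Ds > 0 && Pn + Ps > 0 && Dn + Pn > 0 && Ds + Ps > 0)
    stats::fisher.test(matrix(c(Dn, Ds, Pn, Ps), 2))$p.value
  else NA_real_
  list(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps, NI = NI, p = p)
}
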