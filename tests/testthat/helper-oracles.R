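# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exhaustive enumeration, closed-form integration
# and a second genetic-code source (seqinr).

# ---- analytic flux prior --------------------------------------------------

# Exact P(donor = d, recipient = r) under the coalescent-with-gene-conversion
# prior by piecewise-exponential integration: the inner survival integral is
# closed-form per epoch, the outer integral over the arrival point uses
# adaptive quadrature.
oracleFluxProb <- function(tree) {
  bt <- branchTable(tree)
  ep <- branchEpochs(tree)
  tm <- tmrca(tree)
  totlen <- sum(bt$length)
  epF <- ep[is.finite(ep$end), , drop = FALSE]
  # cumulative k-integral from t to u (t <= u)
  K <- function(t, u) {
    s <- 0
    for (j in seq_len(nrow(epF))) {
      lo <- max(t, epF$start[j]); hi <- min(u, epF$end[j])
      if (hi > lo) s <- s + epF$k[j] * (hi - lo)
    }
    s + max(0, u - max(t, tm))
  }
  # integral over u in [x0, x1] of exp(-K(t, u)), x1 <= tmrca
  survInt <- function(t, x0, x1) {
    if (x1 <= x0) return(0)
    tot <- 0
    for (j in seq_len(nrow(epF))) {
      lo <- max(x0, epF$start[j]); hi <- min(x1, epF$end[j])
      if (hi <= lo) next
      k <- epF$k[j]
      tot <- tot + exp(-K(t, lo)) * (1 - exp(-k * (hi - lo))) / k
    }
    tot
  }
  nb <- nrow(bt)
  P <- matrix(0, nb + 1, nb,
              dimnames = list(c(as.character(seq_len(nb)), "ABOVE_ROOT"),
                              as.character(seq_len(nb))))
  for (r in seq_len(nb)) {
    a_r <- bt$childTime[r]; b_r <- bt$parentTime[r]
    for (d in seq_len(nb)) {
      f <- function(t) vapply(t, function(tt)
        survInt(tt, max(tt, bt$childTime[d]), bt$parentTime[d]), numeric(1))
      P[d, r] <- stats::integrate(f, a_r, b_r, rel.tol = 1e-9,
                                  subdivisions = 500L)$value / totlen
    }
    fA <- function(t) vapply(t, function(tt) exp(-K(tt, tm)), numeric(1))
    P[nb + 1, r] <- stats::integrate(fA, a_r, b_r, rel.tol = 1e-9,
                                     subdivisions = 500L)$value / totlen
  }
  P
}

# ---- exhaustive F_ST ------------------------------------------------------

# pooled Hudson-type F_ST by explicit enumeration of every pair of strains
oracleFst <- function(am, ia, ib) {
  hwA <- 0; hwB <- 0; hb <- 0
  nA <- length(ia); nB <- length(ib)
  for (r in seq_len(nrow(am))) {
    dA <- 0; cA <- 0
    for (i in ia) for (j in ia) if (i < j) { dA <- dA + (am[r, i] != am[r, j]); cA <- cA + 1 }
    dB <- 0; cB <- 0
    for (i in ib) for (j in ib) if (i < j) { dB <- dB + (am[r, i] != am[r, j]); cB <- cB + 1 }
    dX <- 0; cX <- 0
    for (i in ia) for (j in ib) { dX <- dX + (am[r, i] != am[r, j]); cX <- cX + 1 }
    hwA <- hwA + dA / cA
    hwB <- hwB + dB / cB
    hb <- hb + dX / cX
  }
  hw <- (hwA + hwB) / 2
  if (hb == 0) NA_real_ else 1 - hw / hb
}

# ---- NG86 via an independent genetic-code source --------------------------

oracleTranslate <- function(codon) {
  toupper(seqinr::translate(strsplit(tolower(codon), "")[[1]]))
}

oracleNg86S <- function(codon) {
  nuc <- c("A", "C", "G", "T")
  cs <- strsplit(codon, "")[[1]]
  aa0 <- oracleTranslate(codon)
  s <- 0
  for (p in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in setdiff(nuc, cs[p])) {
      alt <- cs; alt[p] <- b
      aa <- oracleTranslate(paste(alt, collapse = ""))
      if (aa == "*") next
      nonstop <- nonstop + 1
      if (aa == aa0) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  s
}

# brute-force pathway averaging between two codons (all orderings of the
# differing positions; pathways through stops excluded, with all-pathways
# fallback)
oraclePathways <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  allperm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in allperm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  res <- list()
  for (ord in allperm(pos)) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      if (oracleTranslate(paste(nxt, collapse = "")) == "*") blocked <- TRUE
      if (oracleTranslate(paste(cur, collapse = "")) ==
          oracleTranslate(paste(nxt, collapse = ""))) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- c(sd = sd, nd = nd, blocked = blocked)
  }
  m <- do.call(rbind, res)
  ok <- m[, "blocked"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
}

SENSE_CODONS <- {
  nuc <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(nuc, nuc, nuc, stringsAsFactors = FALSE)[, 3:1],
                1, paste0, collapse = "")
  all3[vapply(all3, oracleTranslate, character(1)) != "*"]
}

# ---- exhaustive parsimony -------------------------------------------------

# minimum number of state changes for a binary character by trying every
# assignment of states to internal nodes
oracleParsimony <- function(tree, presence) {
  n <- nLeaves(tree)
  N <- 2L * n - 1L
  pv <- as.integer(as.logical(presence[leafNames(tree)]))
  internal <- setdiff(seq_len(N), seq_len(n))
  parent <- tree@parent
  best <- Inf
  for (mask in 0:(2^length(internal) - 1)) {
    st <- integer(N)
    st[seq_len(n)] <- pv
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    chg <- sum(st[parent > 0] != st[parent[parent > 0]])
    if (chg < best) best <- chg
  }
  best
}

# ---- Fisher two-sided by hypergeometric enumeration -----------------------

oracleFisherP <- function(Dn, Ds, Pn, Ps) {
  # margins fixed; sum probabilities of tables as or less probable
  m <- Dn + Ds; n2 <- Pn + Ps; k <- Dn + Pn
  x <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(x, m, n2, k)
  p0 <- stats::dhyper(Dn, m, n2, k)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# ---- misc helpers ---------------------------------------------------------

randomAlleles <- function(nStrains, nSnps) {
  matrix(sample(c("A", "C", "G", "T"), nStrains * nSnps, replace = TRUE,
                prob = c(0.4, 0.1, 0.1, 0.4)),
         nrow = nSnps)
}

snpTableFromMatrix <- function(am, strains) {
  d <- cbind(data.frame(pos = seq_len(nrow(am)) - 1L),
             as.data.frame(am, stringsAsFactors = FALSE))
  colnames(d) <- c("pos", strains)
  d
}
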