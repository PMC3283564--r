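# Readers and writers for the formats the pipeline exchanges: XMFA / FASTA
# core alignments, event tables, gene and segment tables, BED intervals.
# Intervals are 0-based half-open internally; 1-based inclusive coordinates
# are accepted at the gene-table boundary and converted on read.

#' Construct a CoreAlignment
#'
#' @param blocks list of blocks, each a list with \code{seqs} (named
#'   character vector of aligned sequences) and \code{refStart} (0-based).
#' @param reference name of the reference strain.
#' @return a [CoreAlignment-class]
#' @export
coreAlignment <- function(blocks, reference) {
  new("CoreAlignment", blocks = blocks, reference = reference)
}

setMethod("show", "CoreAlignment", function(object) {
  w <- vapply(object@blocks, function(b) nchar(b$seqs[[1]]), numeric(1))
  cat(sprintf("CoreAlignment: %d block(s), %d aligned columns, reference '%s'\n",
              length(object@blocks), sum(w), object@reference))
})

#' @describeIn coreAlignment number of blocks
#' @param x a [CoreAlignment-class]
#' @export
nBlocks <- function(x) length(x@blocks)

#' Read / write a multi-block alignment in XMFA format
#'
#' Headers follow the Mauve convention \code{> strain:start-end strand},
#' with 1-based inclusive sequence coordinates; blocks end with \code{=}.
#' The reference strain's header coordinates build the block -> reference
#' map.
#'
#' @param path file path.
#' @param reference reference strain (default: first strain of the first
#'   block).
#' @return a [CoreAlignment-class]
#' @export
readXmfa <- function(path, reference = NULL) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- list(); curseq <- character(0); curname <- NULL; curstart <- NULL
  starts <- list()
  flushSeq <- function() {
    if (!is.null(curname)) {
      if (curname %in% names(cur)) stop("duplicate strain '", curname,
                                        "' in a block")
      cur[[curname]] <<- paste(curseq, collapse = "")
      starts[[curname]] <<- curstart
    }
    curseq <<- character(0); curname <<- NULL; curstart <<- NULL
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flushSeq()
      m <- regmatches(ln,
        regexec("^>[ \t]*([^: \t]+):([0-9]+)-([0-9]+)", ln))[[1]]
      if (length(m) != 4) stop("unparseable XMFA header: ", ln)
      curname <- m[2]
      curstart <- as.integer(m[3]) - 1L  # to 0-based
    } else if (startsWith(ln, "=")) {
      flushSeq()
      if (length(cur)) {
        if (length(unique(nchar(unlist(cur)))) != 1)
          stop("ragged block: unequal aligned lengths")
        blocks[[length(blocks) + 1L]] <- list(seqs = unlist(cur),
                                              starts = starts)
        cur <- list(); starts <- list()
      }
    } else if (nzchar(trimws(ln))) {
      curseq <- c(curseq, trimws(ln))
    }
  }
  flushSeq()
  if (length(cur)) {
    if (length(unique(nchar(unlist(cur)))) != 1)
      stop("ragged block: unequal aligned lengths")
    blocks[[length(blocks) + 1L]] <- list(seqs = unlist(cur), starts = starts)
  }
  if (!length(blocks)) stop("no alignment blocks found in ", path)
  if (is.null(reference)) reference <- names(blocks[[1]]$seqs)[1]
  blocks <- lapply(blocks, function(b) {
    if (!(reference %in% names(b$seqs)))
      stop("reference strain '", reference, "' absent from a block")
    list(seqs = b$seqs, refStart = b$starts[[reference]])
  })
  coreAlignment(blocks, reference)
}

#' @rdname readXmfa
#' @param core a [CoreAlignment-class]
#' @export
writeXmfa <- function(core, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in core@blocks) {
    # reconstruct per-strain coordinates; only the reference offset is
    # tracked, other strains are written from 1
    reflen <- sum(strsplit(b$seqs[[core@reference]], "")[[1]] %in% NUC)
    for (s in names(b$seqs)) {
      st <- if (s == core@reference) b$refStart + 1L else 1L
      ln <- if (s == core@reference) b$refStart + reflen else
        sum(strsplit(b$seqs[[s]], "")[[1]] %in% NUC)
      writeLines(sprintf("> %s:%d-%d +", s, st, ln), con)
      writeLines(b$seqs[[s]], con)
    }
    writeLines("=", con)
  }
  invisible(path)
}

#' Split core blocks at long gap runs
#'
#' Any run of more than \code{maxGap} consecutive alignment columns that
#' contain a gap in some strain splits its block at the run (the run itself
#' is dropped from the core); shorter gap runs are retained. Reference
#' coordinates of the resulting fragments are recomputed.
#'
#' @param core a [CoreAlignment-class]
#' @param maxGap largest retained gap run, in alignment columns (default
#'   20).
#' @return a [CoreAlignment-class] with the refined block structure.
#' @export
splitCoreBlocks <- function(core, maxGap = 20) {
  out <- list()
  for (b in core@blocks) {
    m <- do.call(rbind, strsplit(b$seqs, ""))
    rownames(m) <- names(b$seqs)
    gapcol <- apply(m, 2, function(col) any(!(col %in% NUC)))
    r <- rle(gapcol)
    ends <- cumsum(r$lengths)
    startsR <- ends - r$lengths + 1L
    longGap <- r$values & r$lengths > maxGap
    # fragment boundaries: columns not inside long gap runs
    keepRun <- !longGap
    refRow <- m[core@reference, ]
    refCum <- cumsum(refRow %in% NUC)
    fragStart <- integer(0); fragEnd <- integer(0)
    open <- FALSE
    for (i in seq_along(r$lengths)) {
      if (longGap[i]) { open <- FALSE; next }
      if (!open) {
        fragStart <- c(fragStart, startsR[i]); fragEnd <- c(fragEnd, ends[i])
        open <- TRUE
      } else fragEnd[length(fragEnd)] <- ends[i]
    }
    for (f in seq_along(fragStart)) {
      cols <- fragStart[f]:fragEnd[f]
      seqs <- apply(m[, cols, drop = FALSE], 1, paste0, collapse = "")
      refBefore <- if (fragStart[f] == 1L) 0L else refCum[fragStart[f] - 1L]
      out[[length(out) + 1L]] <- list(seqs = seqs,
                                      refStart = b$refStart + refBefore)
    }
  }
  coreAlignment(out, core@reference)
}

#' Reference-coordinate coverage mask of a core alignment
#'
#' TRUE at reference positions that fall inside a core block and whose
#' alignment column is gap-free in every strain.
#'
#' @param core a [CoreAlignment-class]
#' @param refLength length of the reference coordinate system.
#' @return logical vector of length refLength.
#' @export
coverageMask <- function(core, refLength) {
  mask <- rep(FALSE, refLength)
  for (b in core@blocks) {
    m <- do.call(rbind, strsplit(b$seqs, ""))
    rownames(m) <- names(b$seqs)
    refRow <- m[core@reference, ]
    isRef <- refRow %in% NUC
    refPos <- b$refStart + cumsum(isRef) - 1L
    full <- apply(m, 2, function(col) all(col %in% NUC))
    pos <- refPos[isRef & full]
    mask[pos + 1L] <- TRUE
  }
  mask
}

#' Read / write recombination-event tables (TSV)
#'
#' Columns: event_id, recipient_branch, arrival_time, donor_branch (a
#' branch ID or the literal \code{ABOVE_ROOT}), departure_time, start, end
#' (0-based half-open).
#'
#' @param events event table (data.frame).
#' @param path file path.
#' @export
writeEventsTsv <- function(events, path) {
  ev <- events
  ev$donor_branch <- ifelse(ev$donor_branch == 0L, ABOVE_ROOT,
                            as.character(ev$donor_branch))
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEventsTsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ev$donor_branch <- ifelse(ev$donor_branch == ABOVE_ROOT, 0L,
                            suppressWarnings(as.integer(ev$donor_branch)))
  if (any(is.na(ev$donor_branch))) stop("unparseable donor_branch value")
  ev
}

#' Read a gene coordinate table (TSV)
#'
#' Expected columns: gene_id, start, end, optionally strand (ignored for
#' F_ST). Input coordinates are 1-based inclusive by default and converted
#' to the package's internal 0-based half-open convention.
#'
#' @param path file path.
#' @param oneBased logical; input is 1-based inclusive (default TRUE).
#' @return data.frame with gene_id, start, end (0-based half-open).
#' @export
readGeneTable <- function(path, oneBased = TRUE) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "start", "end") %in% colnames(d)))
    stop("gene table needs columns gene_id, start, end")
  if (oneBased) d$start <- d$start - 1L
  d
}

#' Read a segment presence/absence table (TSV)
#'
#' Columns: segment_id, start, end, then one 0/1 column per strain. Rows
#' with non-0/1 presence values (e.g. "partial") are rejected: composite
#' segments with heterogeneous internal presence must be pre-split.
#'
#' @param path file path.
#' @export
readSegmentTable <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  strainCols <- setdiff(colnames(d), c("segment_id", "start", "end", "length",
                                       "variable_fraction"))
  vals <- unlist(d[, strainCols])
  if (!all(vals %in% c(0, 1, "0", "1")))
    stop("presence values must be 0/1; pre-split segments with 'partial' presence")
  d
}

#' Write intervals with a value column as BED
#'
#' @param intervals data.frame with start, end and optionally name/value
#'   columns.
#' @param path file path.
#' @param chrom chromosome/reference name for column 1.
#' @export
writeBed <- function(intervals, path, chrom = "ref") {
  name <- if ("class" %in% colnames(intervals)) intervals$class
          else if ("gene_id" %in% colnames(intervals)) intervals$gene_id
          else "."
  value <- if ("fst" %in% colnames(intervals)) intervals$fst
           else if ("value" %in% colnames(intervals)) intervals$value else 0
  d <- data.frame(chrom = chrom, start = intervals$start,
                  end = intervals$end, name = name, score = value)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
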