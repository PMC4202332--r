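# Per-cell classification of ancestral intron sites.  A row whose intron
# span contains sequence is PRESENT when the splice signals check out; an
# empty span is classified by the net indel at the junction, measured
# against the modal ungapped exon length among present rows over an
# adaptive column window that stretches across alignment indel blocks
# until `flankCodons` codons of exon are covered on each side.

#' Create a ClassifyConfig
#'
#' @param perfectMaxCodons maximum |k| for a perfect (cDNA-mediated) loss
#'   (default 2).
#' @param imperfectMinCodons,imperfectMaxCodons imperfect-loss codon range
#'   (defaults 3 and 40).
#' @param flankCodons exon codons per junction side for indel accounting
#'   (default 10).
#' @param utrPolicy state for unresolvable 5'-UTR sites (default
#'   \code{"lost_unknown"}).
#' @return a \linkS4class{ClassifyConfig}.
#' @export
classifyConfig <- function(perfectMaxCodons = 2L, imperfectMinCodons = 3L,
                           imperfectMaxCodons = 40L, flankCodons = 10L,
                           utrPolicy = "lost_unknown") {
  new("ClassifyConfig", perfectMaxCodons = as.integer(perfectMaxCodons),
      imperfectMinCodons = as.integer(imperfectMinCodons),
      imperfectMaxCodons = as.integer(imperfectMaxCodons),
      flankCodons = as.integer(flankCodons), utrPolicy = utrPolicy)
}

# Character matrix (rows x alignment columns) for fast column counting.
.charMatrix <- function(seqs) {
  do.call(rbind, strsplit(unname(seqs), ""))
}

.intronFeature <- function(aln, siteId) {
  f <- aln@features
  hit <- which(f$type == "intron" & f$site_id == siteId)
  if (length(hit) != 1)
    .pipelineError(sprintf("site '%s' not annotated in family '%s'",
                           siteId, aln@family), "input_error")
  f[hit, ]
}

# Rows whose span content passes the >=2-of-3 signal rule (PRESENT rows).
.presentRowsForSite <- function(chars, spanStart, spanEnd, spliceCfg) {
  rn <- rownames(chars)
  ok <- vapply(rn, function(r) {
    content <- paste(chars[r, (spanStart + 1):spanEnd], collapse = "")
    content <- gsub("-", "", content, fixed = TRUE)
    nchar(content) > 0 &&
      .scanIntronSignals(content, spliceCfg)$nSignals >= 2
  }, TRUE)
  rn[ok]
}

# Adaptive junction window on one side: walk away from the junction until
# the focal row and every present reference row have accumulated needNt
# exon bases (indel blocks are gap-only for some rows and stretch the
# window), stopping at another intron span.  Returns column indices.
.windowSide <- function(chars, presentRows, focalRow, cols, needNt,
                        forbidden) {
  if (length(cols) == 0) return(integer(0))
  stopAt <- which(forbidden[cols])
  if (length(stopAt) > 0) cols <- cols[seq_len(stopAt[1] - 1L)]
  if (length(cols) == 0) return(integer(0))
  m <- chars[c(focalRow, presentRows), cols, drop = FALSE] != "-"
  cum <- apply(m, 1, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)   # single column side
  done <- rowSums(cum >= needNt) == ncol(cum)           # all rows satisfied
  cut <- which(done)[1]
  if (is.na(cut)) cut <- length(cols)
  cols[seq_len(cut)]
}

.statMode <- function(x) {
  tb <- table(x)
  as.integer(min(as.integer(names(tb)[tb == max(tb)])))
}

# Core per-cell classifier over a precomputed character matrix.
.classifyCell <- function(chars, feat, allIntronSpans, rowName, presentRows,
                          spliceCfg, clsCfg) {
  if (!rowName %in% rownames(chars))
    return(list(state = .STATE_NO_DATA, k = NA_integer_,
                note = "row absent from alignment"))
  s <- feat$start; e <- feat$end
  content <- gsub("-", "", paste(chars[rowName, (s + 1):e], collapse = ""),
                  fixed = TRUE)
  if (nchar(content) > 0) {
    ann <- tryCatch(annotateIntron(content, spliceCfg),
                    introndollo_error = function(e) NULL)
    if (!is.null(ann))
      return(list(state = .STATE_PRESENT, k = NA_integer_, note = "",
                  annotation = ann))
    if (.scanIntronSignals(content, spliceCfg)$nSignals >= 2)
      return(list(state = .STATE_PRESENT, k = NA_integer_,
                  note = "degenerate signals"))
    return(list(state = .STATE_LOST_UNKNOWN, k = NA_integer_,
                note = "sequence in span but degenerate signals"))
  }
  refRows <- setdiff(presentRows, rowName)
  if (length(refRows) == 0)
    return(list(state = .STATE_LOST_UNKNOWN, k = NA_integer_,
                note = "no present reference row"))
  width <- ncol(chars)
  forbidden <- logical(width)
  for (i in seq_len(nrow(allIntronSpans))) {
    sp <- allIntronSpans[i, ]
    forbidden[(sp$start + 1):sp$end] <- TRUE
  }
  needNt <- 3L * clsCfg@flankCodons
  left <- .windowSide(chars, refRows, rowName, if (s >= 1) s:1 else integer(0),
                      needNt, forbidden)
  right <- .windowSide(chars, refRows, rowName,
                       if (e + 1 <= width) (e + 1):width else integer(0),
                       needNt, forbidden)
  win <- c(left, right)
  if (length(win) == 0)
    return(list(state = .unresolvedState(feat, clsCfg),
                k = NA_integer_, note = "no junction window"))
  focal <- sum(chars[rowName, win] != "-")
  refCounts <- vapply(refRows, function(r) sum(chars[r, win] != "-"), 0L)
  kNt <- focal - .statMode(refCounts)
  if (kNt %% 3 != 0)
    return(list(state = .unresolvedState(feat, clsCfg), k = NA_integer_,
                note = sprintf("frameshift: net indel %+d nt", kNt)))
  k <- as.integer(kNt / 3)
  if (abs(k) <= clsCfg@perfectMaxCodons)
    return(list(state = .STATE_LOST_PERFECT, k = k, note = ""))
  if (abs(k) >= clsCfg@imperfectMinCodons &&
      abs(k) <= clsCfg@imperfectMaxCodons)
    return(list(state = .STATE_LOST_IMPERFECT, k = k, note = ""))
  list(state = .STATE_LOST_UNKNOWN, k = NA_integer_,
       note = sprintf("net indel %+d codons beyond imperfect range", k))
}

# 5'-UTR sites without resolvable flanks follow the configured policy.
.unresolvedState <- function(feat, clsCfg) {
  if (isTRUE(feat$utr5)) clsCfg@utrPolicy else .STATE_LOST_UNKNOWN
}

#' Classify the state of one intron site in one row
#'
#' PRESENT when the row's intron span contains sequence passing the splice
#' signals (at least two of 5'ss / branch point / 3'ss); otherwise the net
#' junction indel in codons decides between perfect loss (|k| small,
#' cDNA-mediated gene replacement), imperfect loss (3-40 codons), and
#' unknown-mechanism loss (frameshift or out-of-range indel); rows missing
#' from the alignment are NO_DATA.
#'
#' @param aln an \linkS4class{AnnotatedAlignment}.
#' @param siteId intron site id (must be annotated in \code{aln}).
#' @param row \code{"species|locus"} row name.
#' @param spliceCfg,clsCfg configuration objects.
#' @return list: \code{state}, \code{k} (net codon indel or NA),
#'   \code{note}.
#' @export
classifySiteState <- function(aln, siteId, row, spliceCfg = spliceConfig(),
                              clsCfg = classifyConfig()) {
  chars <- .charMatrix(aln@seqs)
  rownames(chars) <- names(aln@seqs)
  feat <- .intronFeature(aln, siteId)
  spans <- aln@features[aln@features$type == "intron", c("start", "end")]
  presentRows <- .presentRowsForSite(chars, feat$start, feat$end, spliceCfg)
  .classifyCell(chars, feat, spans, row, presentRows, spliceCfg, clsCfg)
}

#' Detect intron sliding
#'
#' For rows not PRESENT at the annotated span, scans the row's ungapped
#' sequence for a valid intron (full splice grammar) whose 5'ss lies at a
#' different alignment column, and reports the column offset and whether
#' the move crosses the annotated start codon.
#'
#' @param aln an \linkS4class{AnnotatedAlignment}.
#' @param siteId intron site id.
#' @param spliceCfg a \linkS4class{SpliceConfig}.
#' @return data.frame: \code{row}, \code{offset_cols}, \code{length},
#'   \code{s2}, \code{crosses_start_codon}; empty when nothing is found.
#' @export
detectSliding <- function(aln, siteId, spliceCfg = spliceConfig()) {
  chars <- .charMatrix(aln@seqs)
  rownames(chars) <- names(aln@seqs)
  feat <- .intronFeature(aln, siteId)
  presentRows <- .presentRowsForSite(chars, feat$start, feat$end, spliceCfg)
  scFeat <- aln@features[aln@features$type == "start_codon", , drop = FALSE]
  scCol <- if (nrow(scFeat) > 0) scFeat$start[1] else NA_integer_
  empty <- data.frame(row = character(0), offset_cols = integer(0),
                      length = integer(0), s2 = integer(0),
                      crosses_start_codon = logical(0))
  out <- list()
  for (r in setdiff(rownames(chars), presentRows)) {
    isBase <- chars[r, ] != "-"
    seq <- paste(chars[r, isBase], collapse = "")
    colOf <- which(isBase)                      # ungapped index -> column
    starts <- gregexpr(spliceCfg@fiveSS, seq, fixed = TRUE)[[1]]
    if (starts[1] == -1) next
    ends <- gregexpr(spliceCfg@threeSS, seq, fixed = TRUE)[[1]]
    if (ends[1] == -1) next
    ends <- ends + nchar(spliceCfg@threeSS) - 1L   # last base, 1-based
    found <- NULL
    for (p in starts) {
      for (q in ends) {
        len <- q - p + 1L
        if (len < spliceCfg@minIntronLen || len > spliceCfg@maxIntronLen)
          next
        ann <- tryCatch(annotateIntron(substr(seq, p, q), spliceCfg),
                        introndollo_error = function(e) NULL)
        if (!is.null(ann)) { found <- list(p = p, ann = ann); break }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) next
    newCol <- colOf[found$p] - 1L                  # 0-based column of 5'ss
    if (newCol == feat$start) next                 # same position: not sliding
    lo <- min(newCol, feat$start); hi <- max(newCol, feat$start)
    # offset in exon frame: columns of the annotated intron block between
    # the two 5'ss positions do not count (a +3-codon slide reads as +9)
    spans <- aln@features[aln@features$type == "intron", , drop = FALSE]
    inBlock <- sum(vapply(seq_len(nrow(spans)), function(i) {
      length(intersect(seq(lo, hi - 1),
                       seq(spans$start[i], spans$end[i] - 1)))
    }, 0L))
    off <- (hi - lo - inBlock) * sign(newCol - feat$start)
    out[[length(out) + 1]] <- data.frame(
      row = r, offset_cols = off,
      length = found$ann$length, s2 = found$ann$s2,
      crosses_start_codon = if (is.na(scCol)) NA else scCol > lo & scCol <= hi,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) empty else do.call(rbind, out)
}

#' Build the site-by-locus state matrix
#'
#' One row per ancestral intron site (multiple introns in one gene are
#' separate sites), one column per pillar \code{species|locus} slot.  Cells
#' without a pillar gene are NO_DATA; sites with no PRESENT call are
#' dropped (a site only exists where at least one species carries the
#' intron), as are families left without any site.
#'
#' @param alignments named list of \linkS4class{AnnotatedAlignment}
#'   (names = family ids matching pillar rows).
#' @param pillar a \linkS4class{PillarTable}.
#' @param spliceCfg,clsCfg configuration objects.
#' @return a \linkS4class{StateMatrix}.
#' @export
buildStateMatrix <- function(alignments, pillar,
                             spliceCfg = spliceConfig(),
                             clsCfg = classifyConfig()) {
  cols <- colnames(pillar@entries)
  rowsOut <- list(); kOut <- list(); noteOut <- list(); infoOut <- list()
  for (fam in names(alignments)) {
    aln <- alignments[[fam]]
    if (!fam %in% rownames(pillar@entries))
      .pipelineError(sprintf("family '%s' missing from pillar", fam),
                     "validation_error")
    pRow <- pillar@entries[fam, ]
    withGene <- cols[pRow != "-"]
    missingRows <- setdiff(withGene, names(aln@seqs))
    extraRows <- setdiff(names(aln@seqs), withGene)
    if (length(missingRows) > 0 || length(extraRows) > 0)
      .pipelineError(sprintf(
        "pillar/alignment inconsistency in '%s': missing rows [%s], extra rows [%s]",
        fam, paste(missingRows, collapse = ","),
        paste(extraRows, collapse = ",")), "validation_error")
    chars <- .charMatrix(aln@seqs)
    rownames(chars) <- names(aln@seqs)
    feats <- aln@features[aln@features$type == "intron", , drop = FALSE]
    spans <- feats[, c("start", "end")]
    for (i in seq_len(nrow(feats))) {
      feat <- feats[i, ]
      presentRows <- .presentRowsForSite(chars, feat$start, feat$end,
                                         spliceCfg)
      if (length(presentRows) == 0) next     # not an intron site
      st <- setNames(rep(.STATE_NO_DATA, length(cols)), cols)
      kk <- setNames(rep(NA_integer_, length(cols)), cols)
      nn <- setNames(rep("", length(cols)), cols)
      anyPresent <- FALSE
      for (cl in withGene) {
        res <- .classifyCell(chars, feat, spans, cl, presentRows,
                             spliceCfg, clsCfg)
        st[cl] <- res$state; kk[cl] <- res$k; nn[cl] <- res$note
        if (res$state == .STATE_PRESENT) anyPresent <- TRUE
      }
      if (!anyPresent) next
      rowsOut[[feat$site_id]] <- st
      kOut[[feat$site_id]] <- kk
      noteOut[[feat$site_id]] <- nn
      infoOut[[feat$site_id]] <- data.frame(
        site_id = feat$site_id, family = fam, utr5 = feat$utr5,
        rpg = feat$rpg, snorna = feat$snorna, stringsAsFactors = FALSE)
    }
  }
  if (length(rowsOut) == 0)
    .pipelineError("no intron sites with a PRESENT call", "validation_error")
  sm <- new("StateMatrix",
            states = do.call(rbind, rowsOut),
            k = do.call(rbind, kOut),
            notes = do.call(rbind, noteOut),
            siteInfo = do.call(rbind, c(infoOut, make.row.names = FALSE)))
  methods::validObject(sm)
  sm
}

#' @rdname accessors
#' @export
setMethod("states", "StateMatrix", function(x, ...) x@states)

#' @rdname accessors
#' @export
setMethod("codonIndels", "StateMatrix", function(x, ...) x@k)

#' @rdname accessors
#' @export
setMethod("siteInfo", "StateMatrix", function(x, ...) x@siteInfo)

setMethod("show", "StateMatrix", function(object) {
  tb <- table(factor(object@states, levels = .STATES))
  cat(sprintf("StateMatrix: %d sites x %d species|locus columns (%s)\n",
              nrow(object@states), ncol(object@states),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
})

#' Tally a state matrix
#'
#' Counts cells by state (NO_DATA excluded from the defined-site total),
#' the missing rate (absent cells / defined cells), the fraction of absent
#' cells that are perfect (cDNA-mediated) losses, and per-species per-state
#' counts with the two post-WGD loci summed.
#'
#' @param matrix a \linkS4class{StateMatrix}.
#' @return list of class \code{StateTally}: \code{counts},
#'   \code{definedCells}, \code{absentCells}, \code{presentCells},
#'   \code{missingRate}, \code{perfectFraction} (NA when nothing is
#'   absent), \code{perSpecies}.
#' @export
tallyStates <- function(matrix) {
  s <- matrix@states
  if (length(s) == 0) .pipelineError("empty state matrix", "input_error")
  counts <- table(factor(s, levels = .STATES))
  defined <- sum(counts[setdiff(.STATES, .STATE_NO_DATA)])
  absent <- sum(counts[.LOST_STATES])
  info <- .splitRowName(colnames(s))
  perSpecies <- do.call(rbind, lapply(unique(info$species), function(sp) {
    sub <- s[, info$species == sp, drop = FALSE]
    tb <- table(factor(sub, levels = .STATES))
    data.frame(species = sp, as.list(tb), check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    counts = counts, definedCells = defined,
    presentCells = unname(counts[.STATE_PRESENT]), absentCells = absent,
    missingRate = absent / defined,
    perfectFraction = if (absent > 0)
      unname(counts[.STATE_LOST_PERFECT]) / absent else NA_real_,
    perSpecies = perSpecies), class = "StateTally")
}

#' @export
print.StateTally <- function(x, ...) {
  cat(sprintf("StateTally: %d defined cells, %d with intron, %d absent (%.3f missing/site/species)\n",
              x$definedCells, x$presentCells, x$absentCells, x$missingRate))
  if (!is.na(x$perfectFraction))
    cat(sprintf("  perfect (cDNA) fraction of absences: %.3f\n",
                x$perfectFraction))
  invisible(x)
}
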