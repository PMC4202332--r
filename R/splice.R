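# Splice-signal grammar: yeast introns start with GTATGT, branch at TACTAAC
# and end in AG.  The S2 distance is the number of nucleotides from the end
# of the branch-point heptamer to the final intron base (terminal AG
# included): s2 = length - bp_pos - nchar(bpMotif).

#' Create a SpliceConfig
#'
#' @param fiveSS,bpMotif,threeSS motifs (defaults GTATGT / TACTAAC / AG).
#' @param fiveSSMaxMismatch,bpMaxMismatch allowed mismatches (default 0;
#'   the signals follow a strict consensus in Saccharomycetaceae).
#' @param minIntronLen,maxIntronLen length bounds in nt (defaults 49 / 1050).
#' @param minS2 minimum S2 distance (default 1).
#' @return a \linkS4class{SpliceConfig}.
#' @export
spliceConfig <- function(fiveSS = "GTATGT", bpMotif = "TACTAAC",
                         threeSS = "AG", fiveSSMaxMismatch = 0L,
                         bpMaxMismatch = 0L, minIntronLen = 49L,
                         maxIntronLen = 1050L, minS2 = 1L) {
  new("SpliceConfig", fiveSS = fiveSS, bpMotif = bpMotif, threeSS = threeSS,
      fiveSSMaxMismatch = as.integer(fiveSSMaxMismatch),
      bpMaxMismatch = as.integer(bpMaxMismatch),
      minIntronLen = as.integer(minIntronLen),
      maxIntronLen = as.integer(maxIntronLen), minS2 = as.integer(minS2))
}

.mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Rightmost start (0-based) of `motif` in `seq` with <= maxMismatch
# mismatches, searching only starts in [from, to]; NA if none.
.rightmostMotif <- function(seq, motif, maxMismatch, from, to) {
  w <- nchar(motif)
  if (to < from) return(NA_integer_)
  if (maxMismatch == 0) {
    hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(NA_integer_)
    hits <- hits - 1L                      # to 0-based
    hits <- hits[hits >= from & hits <= to]
    if (length(hits) == 0) return(NA_integer_)
    return(max(hits))
  }
  for (p in seq(to, from)) {
    if (.mismatches(substr(seq, p + 1, p + w), motif) <= maxMismatch)
      return(as.integer(p))
  }
  NA_integer_
}

# Which of the three signals match (used by the >=2-of-3 presence rule).
.scanIntronSignals <- function(seq, cfg) {
  len <- nchar(seq)
  f <- nchar(cfg@fiveSS); t3 <- nchar(cfg@threeSS); b <- nchar(cfg@bpMotif)
  fiveOk <- len >= f &&
    .mismatches(substr(seq, 1, f), cfg@fiveSS) <= cfg@fiveSSMaxMismatch
  threeOk <- len >= t3 && substr(seq, len - t3 + 1, len) == cfg@threeSS
  bpPos <- if (len >= f + b + cfg@minS2)
    .rightmostMotif(seq, cfg@bpMotif, cfg@bpMaxMismatch,
                    from = f, to = len - b - cfg@minS2)
  else NA_integer_
  list(fiveOk = fiveOk, threeOk = threeOk, bpPos = bpPos,
       nSignals = fiveOk + threeOk + !is.na(bpPos))
}

#' Annotate an intron sequence
#'
#' Verifies the 5' splice site at position 0, the exact terminal 3' splice
#' site, and the intron length bounds; locates the branch point as the
#' rightmost qualifying motif upstream of the 3' end with
#' \code{s2 >= minS2} (the yeast branch point is 3'-proximal, which makes S2
#' well defined); and computes the S2 distance.
#'
#' @param seq uppercase DNA string, no gaps.
#' @param cfg a \linkS4class{SpliceConfig}.
#' @return list of class \code{IntronAnnotation}: \code{length},
#'   \code{bpPos} (0-based offset of the branch-point motif), \code{s2},
#'   \code{mismatches}.
#' @section Errors: classed conditions \code{length_violation},
#'   \code{invalid_splice_site}, \code{no_branch_point}.
#' @examples
#' seq <- paste0("GTATGT", strrep("T", 20), "TACTAAC", strrep("T", 25), "AG")
#' annotateIntron(seq)$s2   # 27
#' @export
annotateIntron <- function(seq, cfg = spliceConfig()) {
  if (grepl("[^ACGT]", seq))
    .pipelineError("sequence must be ungapped uppercase DNA", "input_error")
  len <- nchar(seq)
  if (len < cfg@minIntronLen || len > cfg@maxIntronLen)
    .pipelineError(sprintf("length violation: %d nt outside [%d, %d]",
                           len, cfg@minIntronLen, cfg@maxIntronLen),
                   "length_violation")
  f <- nchar(cfg@fiveSS)
  mm5 <- .mismatches(substr(seq, 1, f), cfg@fiveSS)
  if (mm5 > cfg@fiveSSMaxMismatch)
    .pipelineError(sprintf("invalid splice site: 5'ss '%s'", substr(seq, 1, f)),
                   "invalid_splice_site")
  t3 <- nchar(cfg@threeSS)
  if (substr(seq, len - t3 + 1, len) != cfg@threeSS)
    .pipelineError(sprintf("invalid splice site: 3'ss '%s'",
                           substr(seq, len - t3 + 1, len)),
                   "invalid_splice_site")
  b <- nchar(cfg@bpMotif)
  bpPos <- .rightmostMotif(seq, cfg@bpMotif, cfg@bpMaxMismatch,
                           from = f, to = len - b - cfg@minS2)
  if (is.na(bpPos))
    .pipelineError("no branch point", "no_branch_point")
  mmBp <- .mismatches(substr(seq, bpPos + 1, bpPos + b), cfg@bpMotif)
  structure(list(fiveSSPos = 0L, bpPos = bpPos, s2 = len - bpPos - b,
                 length = len,
                 mismatches = c(fiveSS = mm5, bp = mmBp, threeSS = 0L)),
            class = "IntronAnnotation")
}

#' @export
print.IntronAnnotation <- function(x, ...) {
  cat(sprintf("IntronAnnotation: length %d nt, BP at %d, S2 = %d\n",
              x$length, x$bpPos, x$s2))
  invisible(x)
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Validate a splice junction against a genome
#'
#' Extracts the junction's intron sequence (reverse-complemented for minus
#' strand) and delegates to \code{\link{annotateIntron}}.  Motif or length
#' failures are expected outcomes and are returned as a failure verdict;
#' missing chromosomes or out-of-range coordinates are input errors.
#'
#' @param genome named character vector or \code{Biostrings::DNAStringSet}.
#' @param junction list/row with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand}.
#' @param cfg a \linkS4class{SpliceConfig}.
#' @return list with \code{ok}; on success \code{annotation}, on failure
#'   \code{reason} (the condition class) and \code{message}.
#' @export
validateJunction <- function(genome, junction, cfg = spliceConfig()) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  chrom <- as.character(junction$chrom)
  if (!chrom %in% names(genome))
    .pipelineError(sprintf("chromosome '%s' not in genome", chrom),
                   "input_error")
  start <- as.integer(junction$start); end <- as.integer(junction$end)
  if (start < 0 || end > nchar(genome[[chrom]]) || end <= start)
    .pipelineError("junction coordinates out of range", "input_error")
  seq <- substr(genome[[chrom]], start + 1, end)
  if (identical(as.character(junction$strand), "-")) seq <- .revcomp(seq)
  tryCatch(list(ok = TRUE, annotation = annotateIntron(seq, cfg)),
           introndollo_error = function(e)
             list(ok = FALSE, reason = class(e)[1], message = conditionMessage(e)))
}

#' Validate a table of junctions
#'
#' @param genome as in \code{\link{validateJunction}}.
#' @param junctions data.frame of junctions (from
#'   \code{\link{readJunctionBed}}).
#' @param cfg a \linkS4class{SpliceConfig}.
#' @return data.frame with columns \code{name}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{count}, \code{ok}, \code{reason},
#'   \code{s2}, \code{bp_pos}, \code{length}.
#' @export
validateJunctions <- function(genome, junctions, cfg = spliceConfig()) {
  res <- lapply(seq_len(nrow(junctions)), function(i)
    validateJunction(genome, junctions[i, ], cfg))
  data.frame(
    name = junctions$name, chrom = junctions$chrom,
    start = junctions$start, end = junctions$end,
    strand = junctions$strand, count = junctions$count,
    ok = vapply(res, `[[`, TRUE, "ok"),
    reason = vapply(res, function(r) if (r$ok) "" else r$reason, ""),
    s2 = vapply(res, function(r) if (r$ok) r$annotation$s2 else NA_integer_,
                0L),
    bp_pos = vapply(res, function(r)
      if (r$ok) r$annotation$bpPos else NA_integer_, 0L),
    length = vapply(res, function(r)
      if (r$ok) r$annotation$length else NA_integer_, 0L),
    stringsAsFactors = FALSE)
}

#' Per-species S2 summary
#'
#' @param s2 numeric vector of S2 distances (natural scale).
#' @param species character vector of the same length.
#' @return data.frame per species: \code{n}, \code{median}, \code{mean},
#'   \code{median_log2}, \code{mean_log2}.  Empty groups are skipped with a
#'   warning.
#' @export
s2Summary <- function(s2, species) {
  stopifnot(length(s2) == length(species))
  keep <- !is.na(s2)
  if (any(!keep)) warning("dropping NA S2 values")
  sp <- unique(species)
  empty <- setdiff(sp, unique(species[keep]))
  if (length(empty) > 0)
    warning(sprintf("no S2 values for species: %s; skipped",
                    paste(empty, collapse = ", ")))
  s2 <- s2[keep]; species <- species[keep]
  out <- do.call(rbind, lapply(sort(unique(species)), function(s) {
    v <- s2[species == s]
    data.frame(species = s, n = length(v), median = median(v), mean = mean(v),
               median_log2 = median(log2(v)), mean_log2 = mean(log2(v)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Normalize junction read counts
#'
#' \code{per_million}: count x 1e6 / library size (reads per million).
#' \code{per_kb_per_million}: additionally divided by the intron length in
#' kb (reads per kb per million mapped).
#'
#' @param junctions data.frame with \code{name}, \code{start}, \code{end},
#'   \code{count}.
#' @param librarySize total mapped reads (> 0).
#' @param mode \code{"per_million"} or \code{"per_kb_per_million"}.
#' @return named numeric vector keyed by junction name.
#' @export
normalizeJunctionCounts <- function(junctions, librarySize,
                                    mode = c("per_million",
                                             "per_kb_per_million")) {
  mode <- match.arg(mode)
  if (librarySize <= 0)
    .pipelineError("librarySize must be > 0", "input_error")
  v <- junctions$count * 1e6 / librarySize
  if (mode == "per_kb_per_million") {
    len <- junctions$end - junctions$start
    if (any(len <= 0))
      .pipelineError("zero-length intron in per_kb_per_million mode",
                     "input_error")
    v <- v / (len / 1000)
  }
  setNames(v, junctions$name)
}

#' Pearson correlation of two named value vectors
#'
#' Pairs values by shared names (intersection only) and computes the Pearson
#' product-moment correlation with a two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param x,y named numeric vectors.
#' @return list of class \code{CorrelationResult}: \code{r}, \code{p},
#'   \code{n}.
#' @export
correlateCounts <- function(x, y) {
  ids <- intersect(names(x), names(y))
  if (length(ids) < 3)
    .pipelineError("need at least 3 shared ids", "input_error")
  xv <- x[ids]; yv <- y[ids]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    .pipelineError("zero variance: correlation undefined", "undefined_r")
  ct <- cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(ids)),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (p = %.3g, n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}
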