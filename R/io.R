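# Readers and writers for every format the pipeline touches.  All readers
# validate and reject rather than silently repair; all writers emit
# deterministic, sorted output.  Coordinate conversions (GFF3 1-based
# inclusive, BED 0-based half-open, internal 0-based half-open) happen here
# and nowhere else.

#' Read a rooted Newick species tree
#'
#' A node labeled \code{wgdLabel} becomes the WGD node; unlabeled internal
#' nodes receive deterministic labels so every branch has a stable id.
#'
#' @param path Newick file.
#' @param wgdLabel label marking the WGD node (default \code{"WGD"}).
#' @return a \linkS4class{SpeciesTree}.
#' @export
readNewickTree <- function(path, wgdLabel = "WGD") {
  if (!file.exists(path))
    .pipelineError(sprintf("file not found: %s", path), "input_error")
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (length(depth) > 0 && (any(depth < 0) || depth[length(depth)] != 0)) {
    pos <- if (any(depth < 0)) which(depth < 0)[1] else length(depth)
    .pipelineError(sprintf("malformed Newick: unbalanced parenthesis near character %d",
                           pos), "parse_error")
  }
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e)
                    .pipelineError(sprintf("malformed Newick: %s",
                                           conditionMessage(e)), "parse_error"))
  if (is.null(phy))
    .pipelineError("malformed Newick: no tree parsed", "parse_error")
  speciesTree(phy, wgdLabel = wgdLabel)
}

#' Write a SpeciesTree as Newick
#'
#' Round-trips through \code{\link{readNewickTree}}: internal node labels
#' (including the WGD tag) are preserved.
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @param path output file.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree@phy, file = path)
  invisible(path)
}

.featureCols <- c("site_id", "type", "start", "end", "utr5", "rpg",
                  "snorna", "present_in")

.emptyFeatures <- function() {
  data.frame(site_id = character(0), type = character(0),
             start = integer(0), end = integer(0), utr5 = logical(0),
             rpg = logical(0), snorna = character(0),
             present_in = character(0), stringsAsFactors = FALSE)
}

#' Read an annotated gene-family alignment
#'
#' The FASTA holds gapped rows named \code{"species|locus"}; the companion
#' GFF3 (1-based inclusive, in alignment-column space) holds \code{intron},
#' \code{branch_point}, \code{snoRNA} and \code{start_codon} features, which
#' are converted to the internal 0-based half-open convention.
#'
#' @param fastaPath,gffPath input files.
#' @param family family id; default: the GFF seqid.
#' @return an \linkS4class{AnnotatedAlignment}.
#' @export
readAnnotatedAlignment <- function(fastaPath, gffPath, family = NULL) {
  for (p in c(fastaPath, gffPath))
    if (!file.exists(p))
      .pipelineError(sprintf("file not found: %s", p), "input_error")
  seqs <- as.character(Biostrings::readBStringSet(fastaPath))
  gr <- rtracklayer::import.gff3(gffPath)
  mc <- S4Vectors::mcols(gr)
  seqids <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (is.null(family)) family <- seqids[1]
  if (length(gr) > 0 && !all(seqids == family))
    .pipelineError(sprintf("GFF seqids (%s) do not match family '%s'",
                           paste(seqids, collapse = ","), family),
                   "validation_error")
  getTag <- function(tag, default) {
    if (tag %in% names(mc)) as.character(mc[[tag]])
    else rep(default, length(gr))
  }
  feat <- data.frame(
    site_id = getTag("site", NA_character_),
    type = as.character(mc$type),
    start = GenomicRanges::start(gr) - 1L,     # GFF 1-based -> half-open
    end = GenomicRanges::end(gr),
    utr5 = getTag("utr5", "0") %in% c("1", "true", "TRUE"),
    rpg = getTag("rpg", "0") %in% c("1", "true", "TRUE"),
    snorna = getTag("snorna", NA_character_),
    present_in = getTag("present_in", NA_character_),
    stringsAsFactors = FALSE)
  if (nrow(feat) == 0) feat <- .emptyFeatures()
  aln <- new("AnnotatedAlignment", family = family, seqs = seqs,
             features = feat, rpg = any(feat$rpg[feat$type == "intron"]))
  methods::validObject(aln)
  aln
}

#' Write an annotated alignment (FASTA + GFF3)
#'
#' @param aln an \linkS4class{AnnotatedAlignment}.
#' @param fastaPath,gffPath output files.
#' @export
writeAnnotatedAlignment <- function(aln, fastaPath, gffPath) {
  ss <- Biostrings::BStringSet(aln@seqs)
  Biostrings::writeXStringSet(ss, fastaPath)
  f <- aln@features
  if (nrow(f) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = aln@family,
      ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
      strand = "+")
    S4Vectors::mcols(gr)$type <- f$type
    S4Vectors::mcols(gr)$ID <- paste0(f$site_id, "_", f$type)
    S4Vectors::mcols(gr)$site <- f$site_id
    S4Vectors::mcols(gr)$utr5 <- ifelse(f$utr5, "1", "0")
    S4Vectors::mcols(gr)$rpg <- ifelse(f$rpg, "1", "0")
    if (any(!is.na(f$snorna))) S4Vectors::mcols(gr)$snorna <- f$snorna
    if (any(!is.na(f$present_in)))
      S4Vectors::mcols(gr)$present_in <- f$present_in
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export.gff3(gr, gffPath)
  invisible(aln)
}

#' @rdname accessors
#' @export
setMethod("alignmentRows", "AnnotatedAlignment", function(x, ...) x@seqs)

#' @rdname accessors
#' @export
setMethod("alignmentFeatures", "AnnotatedAlignment", function(x, ...) x@features)

setMethod("show", "AnnotatedAlignment", function(object) {
  cat(sprintf("AnnotatedAlignment '%s': %d rows x %d columns, %d intron site(s)%s\n",
              object@family, length(object@seqs), nchar(object@seqs[[1]]),
              sum(object@features$type == "intron"),
              if (object@rpg) " [RPG]" else ""))
})

#' Read an ortholog pillar table
#'
#' TSV with header: first column \code{ancestral}, remaining columns
#' \code{"species|locus"} slots holding gene ids or the absent marker
#' \code{"-"}.  If \code{tree} is given, every post-WGD species must
#' contribute exactly the two locus columns A and B and every pre-WGD
#' species exactly one.
#'
#' @param path TSV file.
#' @param tree optional \linkS4class{SpeciesTree} for locus validation.
#' @return a \linkS4class{PillarTable}.
#' @export
readPillar <- function(path, tree = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "ancestral")
    .pipelineError("pillar table must start with an 'ancestral' column",
                   "validation_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$ancestral
  if (!is.null(tree)) .checkPillarColumns(colnames(m), tree)
  p <- new("PillarTable", entries = m)
  methods::validObject(p)
  p
}

.checkPillarColumns <- function(cols, tree) {
  info <- .splitRowName(cols)
  post <- postWgdSpecies(tree)
  for (sp in speciesNames(tree)) {
    loci <- sort(info$locus[info$species == sp])
    want <- if (sp %in% post) c("A", "B") else "0"
    if (!identical(loci, want))
      .pipelineError(sprintf(
        "pillar columns for %s are {%s}; expected {%s}",
        sp, paste(loci, collapse = ","), paste(want, collapse = ",")),
        "validation_error")
  }
  invisible(TRUE)
}

#' Write a pillar table
#'
#' @param pillar a \linkS4class{PillarTable}.
#' @param path output TSV.
#' @export
writePillar <- function(pillar, path) {
  m <- pillar@entries
  df <- data.frame(ancestral = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("pillarEntries", "PillarTable", function(x, ...) x@entries)

setMethod("show", "PillarTable", function(object) {
  cat(sprintf("PillarTable: %d ancestral genes x %d species|locus slots\n",
              nrow(object@entries), ncol(object@entries)))
})

#' Read a BED6 junction file
#'
#' Score column carries the spanning read count.  Coordinates stay 0-based
#' half-open.
#'
#' @param path BED6 file.
#' @return data.frame: \code{chrom}, \code{start}, \code{end}, \code{name},
#'   \code{count}, \code{strand}.
#' @export
readJunctionBed <- function(path) {
  gr <- tryCatch(rtracklayer::import.bed(path),
                 error = function(e)
                   .pipelineError(sprintf("malformed BED: %s",
                                          conditionMessage(e)), "parse_error"))
  count <- S4Vectors::mcols(gr)$score
  if (is.null(count) || any(is.na(count)) || any(count < 0))
    .pipelineError("BED score column must hold non-negative read counts",
                   "validation_error")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = as.character(S4Vectors::mcols(gr)$name),
             count = as.numeric(count),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write junctions as BED6
#'
#' @param junctions data.frame as returned by \code{\link{readJunctionBed}}.
#' @param path output file.
#' @export
writeJunctionBed <- function(junctions, path) {
  j <- junctions[order(junctions$chrom, junctions$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = j$chrom,
    ranges = IRanges::IRanges(start = j$start + 1L, end = j$end),
    strand = ifelse(j$strand %in% c("+", "-"), j$strand, "*"))
  S4Vectors::mcols(gr)$name <- j$name
  S4Vectors::mcols(gr)$score <- j$count
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read/write per-species library sizes
#'
#' @param path TSV with columns \code{species}, \code{library_size}.
#' @return named numeric vector.
#' @export
readLibrarySizes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$library_size, df$species)
}

#' @rdname readLibrarySizes
#' @param sizes named numeric vector.
#' @export
writeLibrarySizes <- function(sizes, path) {
  write.table(data.frame(species = names(sizes), library_size = unname(sizes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a StateMatrix as long-format TSV
#'
#' Columns: \code{site_id}, \code{family}, \code{species}, \code{locus},
#' \code{state}, \code{k_codons}, \code{utr5}, \code{rpg}, \code{snorna},
#' \code{note}; rows ordered site-major then species|locus column order.
#'
#' @param matrix a \linkS4class{StateMatrix}.
#' @param path output TSV.
#' @export
writeStateMatrix <- function(matrix, path) {
  s <- matrix@states
  cols <- colnames(s)
  info <- .splitRowName(cols)
  long <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    data.frame(site_id = rownames(s)[i],
               family = matrix@siteInfo$family[i],
               species = info$species, locus = info$locus,
               state = s[i, ], k_codons = matrix@k[i, ],
               utr5 = matrix@siteInfo$utr5[i], rpg = matrix@siteInfo$rpg[i],
               snorna = matrix@siteInfo$snorna[i], note = matrix@notes[i, ],
               stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a long-format state matrix TSV
#'
#' Inverse of \code{\link{writeStateMatrix}}.
#'
#' @param path TSV file.
#' @return a \linkS4class{StateMatrix}.
#' @export
readStateMatrix <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  long$note[is.na(long$note)] <- ""
  long$snorna[long$snorna == "" | is.na(long$snorna)] <- NA_character_
  sites <- unique(long$site_id)
  cols <- unique(.rowName(long$species, long$locus))
  mk <- function(v, default) {
    m <- base::matrix(default, nrow = length(sites), ncol = length(cols),
                      dimnames = list(sites, cols))
    m[cbind(match(long$site_id, sites),
            match(.rowName(long$species, long$locus), cols))] <- v
    m
  }
  states <- mk(long$state, .STATE_NO_DATA)
  k <- mk(suppressWarnings(as.integer(long$k_codons)), NA_integer_)
  notes <- mk(long$note, "")
  first <- long[!duplicated(long$site_id), ]
  si <- data.frame(site_id = first$site_id, family = first$family,
                   utr5 = first$utr5, rpg = first$rpg, snorna = first$snorna,
                   stringsAsFactors = FALSE)
  sm <- new("StateMatrix", states = states, k = k, notes = notes,
            siteInfo = si)
  methods::validObject(sm)
  sm
}

#' Write per-site events and per-branch summaries
#'
#' @param eventmap an \linkS4class{EventMap}.
#' @param path per-site events TSV (\code{site_id}, \code{branch},
#'   \code{simplified}, \code{locus}, \code{event}).
#' @param summaryPath optional per-simplified-branch totals TSV.
#' @export
writeEvents <- function(eventmap, path, summaryPath = NULL) {
  ps <- eventmap@perSite
  ps <- ps[order(ps$site_id, ps$event, ps$branch), , drop = FALSE]
  write.table(ps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summaryPath)) {
    br <- eventmap@branches
    br <- br[order(br$branch), , drop = FALSE]
    write.table(br, summaryPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
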