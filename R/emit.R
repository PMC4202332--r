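# Emission of pipeline input files from a TruthTable.  Alignments are
# correct by construction: exons are aligned codon blocks, introns are
# motif-bearing rows padded with gaps so that 5'ss, branch point and 3'ss
# are column-aligned, and every loss signature is an explicit indel block
# at the junction (insertions get private gap columns in all other rows,
# deletions gap the tail of the preceding exon block).

.BASES <- c("A", "C", "G", "T")

.randomBases <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                  collapse = "")

.gaps <- function(n) strrep("-", n)

.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(.BASES, b), 1), "")
  paste(ch, collapse = "")
}

# Build one intron sequence of given length and S2 under the splice
# grammar, regenerating random spacers until the rightmost qualifying
# branch-point occurrence is the intended one.
.buildIntronSeq <- function(len, s2, cfg) {
  f <- cfg@fiveSS; b <- cfg@bpMotif; t3 <- cfg@threeSS
  sp1 <- len - nchar(f) - nchar(b) - s2
  stopifnot(sp1 >= 0, s2 >= nchar(t3) + 1)
  bpPos <- nchar(f) + sp1
  for (try in 1:200) {
    seq <- paste0(f, .randomBases(sp1), b, .randomBases(s2 - nchar(t3)), t3)
    occ <- gregexpr(b, seq, fixed = TRUE)[[1]] - 1L
    occ <- occ[occ >= 0 & occ <= len - nchar(b) - cfg@minS2]
    if (max(occ) == bpPos) return(seq)
  }
  .pipelineError("could not place branch point uniquely", "simulation_error")
}

# Retained species|locus columns for one gene.
.retainedCols <- function(truth, fam) {
  g <- truth@genes[truth@genes$family == fam, ]
  cols <- colnames(truth@states)
  info <- .splitRowName(cols)
  keep <- info$locus == "0" | (info$locus == "A" & g$retA) |
    (info$locus == "B" & g$retB)
  cols[keep]
}

.emitFamilyAlignment <- function(truth, fam, spliceCfg, config) {
  si <- truth@siteInfo
  famSites <- si[si$family == fam & si$observable, , drop = FALSE]
  rows <- .retainedCols(truth, fam)
  rpg <- any(famSites$rpg)
  exonW <- 3L * config@flankExonCodons
  seqs <- setNames(rep("", length(rows)), rows)
  col <- 0L
  feats <- list()
  append <- function(chunk) {                 # named character over rows
    seqs <<- setNames(paste0(seqs, chunk[rows]), rows)
    col <<- col + nchar(chunk[[1]])
  }
  addExon <- function(delNt = NULL) {         # delNt: named negative tails
    base <- .randomBases(exonW)
    chunk <- setNames(vapply(rows, function(r) .mutate(base, config@exonNoise),
                             ""), rows)
    if (!is.null(delNt)) {
      for (r in names(delNt)) {
        d <- delNt[[r]]
        chunk[r] <- paste0(substr(chunk[r], 1, exonW - d), .gaps(d))
      }
    }
    append(chunk)
  }
  addFeature <- function(type, start, end, site = NA_character_,
                         utr5 = FALSE, snorna = NA_character_,
                         present_in = NA_character_) {
    feats[[length(feats) + 1]] <<- data.frame(
      site_id = site, type = type, start = start, end = end, utr5 = utr5,
      rpg = rpg, snorna = snorna, present_in = present_in,
      stringsAsFactors = FALSE)
  }
  startCodonAt <- NA_integer_

  for (j in seq_len(nrow(famSites))) {
    site <- famSites$site_id[j]
    st <- truth@states[site, rows]
    kNt <- truth@kNt[site, rows]
    # preceding exon block, with deletion tails for deleting rows
    del <- -kNt[st %in% .LOST_STATES & !is.na(kNt) & kNt < 0]
    addExon(if (length(del) > 0) as.list(del) else NULL)
    # insertion blocks, one per inserting row
    ins <- kNt[st %in% .LOST_STATES & !is.na(kNt) & kNt > 0]
    for (r in names(ins)) {
      w <- ins[[r]]
      chunk <- setNames(rep(.gaps(w), length(rows)), rows)
      chunk[r] <- .randomBases(w)
      append(chunk)
    }
    # intron block
    present <- names(st)[st == .STATE_PRESENT]
    lens <- setNames(truth@intronLen[site, present], present)
    s2s <- setNames(truth@s2[site, present], present)
    sp1s <- lens - nchar(spliceCfg@fiveSS) - nchar(spliceCfg@bpMotif) - s2s
    maxSp1 <- max(sp1s); maxS2 <- max(s2s)
    width <- nchar(spliceCfg@fiveSS) + maxSp1 + nchar(spliceCfg@bpMotif) +
      maxS2
    blockStart <- col
    chunk <- setNames(rep(.gaps(width), length(rows)), rows)
    for (r in present) {
      iseq <- .buildIntronSeq(lens[[r]], s2s[[r]], spliceCfg)
      f <- nchar(spliceCfg@fiveSS); b <- nchar(spliceCfg@bpMotif)
      sp1 <- sp1s[[r]]; s2 <- s2s[[r]]
      chunk[r] <- paste0(substr(iseq, 1, f + sp1), .gaps(maxSp1 - sp1),
                         substr(iseq, f + sp1 + 1, f + sp1 + b),
                         .gaps(maxS2 - s2),
                         substr(iseq, f + sp1 + b + 1, nchar(iseq)))
    }
    append(chunk)
    bpCol <- blockStart + nchar(spliceCfg@fiveSS) + maxSp1
    snoId <- famSites$snorna[j]
    addFeature("intron", blockStart, blockStart + width, site = site,
               utr5 = famSites$utr5[j], snorna = snoId)
    addFeature("branch_point", bpCol, bpCol + nchar(spliceCfg@bpMotif),
               site = site)
    if (!is.na(snoId)) {
      # all loci carrying a snoRNA copy, including paralogous regions whose
      # host gene is absent (deintronized copies have no alignment row)
      allCols <- colnames(truth@snoPresence)
      tokens <- allCols[truth@snoPresence[site, ]]
      addFeature("snoRNA", blockStart + 16L, blockStart + 106L, site = site,
                 snorna = snoId,
                 present_in = paste(tokens, collapse = ","))
    }
    if (j == 1 && famSites$utr5[j]) startCodonAt <- col
  }
  addExon()
  if (is.na(startCodonAt)) startCodonAt <- 0L
  addFeature("start_codon", startCodonAt, startCodonAt + 3L)

  new("AnnotatedAlignment", family = fam, seqs = seqs,
      features = do.call(rbind, feats), rpg = rpg)
}

#' Emit per-family alignments (FASTA + GFF3) from a TruthTable
#'
#' One alignment per gene family with at least one observable intron site.
#' Rows are the retained loci; loci whose gene was lost after WGD are
#' excluded from the alignment (the sequence is "missing from the
#' assembly").  Fully deterministic given the SimConfig seed.
#'
#' @param truth a \linkS4class{TruthTable}.
#' @param outdir directory for \code{<family>.fa} / \code{<family>.gff3},
#'   or \code{NULL} to only return the objects.
#' @param spliceCfg a \linkS4class{SpliceConfig}.
#' @return named list of \linkS4class{AnnotatedAlignment}, invisibly when
#'   writing.
#' @export
emitGeneAlignments <- function(truth, outdir = NULL,
                               spliceCfg = spliceConfig()) {
  config <- truth@config
  set.seed(config@seed + 1L)
  si <- truth@siteInfo
  fams <- unique(si$family[si$observable])
  alns <- lapply(fams, function(fam)
    .emitFamilyAlignment(truth, fam, spliceCfg, config))
  names(alns) <- fams
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (fam in fams)
      writeAnnotatedAlignment(alns[[fam]],
                              file.path(outdir, paste0(fam, ".fa")),
                              file.path(outdir, paste0(fam, ".gff3")))
    return(invisible(alns))
  }
  alns
}

#' Build the pillar table implied by a TruthTable
#'
#' @param truth a \linkS4class{TruthTable}.
#' @return a \linkS4class{PillarTable} (gene ids
#'   \code{<family>_<species>_<locus>}, absent marker \code{"-"}).
#' @export
truthPillar <- function(truth) {
  cols <- .lociForTree(truth@tree)
  g <- truth@genes
  m <- matrix("-", nrow = nrow(g), ncol = length(cols),
              dimnames = list(g$family, cols))
  for (i in seq_len(nrow(g))) {
    keep <- .retainedCols(truth, g$family[i])
    m[i, keep] <- paste0(g$family[i], "_", gsub("|", "_", keep, fixed = TRUE))
  }
  p <- new("PillarTable", entries = m)
  methods::validObject(p)
  p
}

#' Emit junction BED files with read counts
#'
#' For each requested species, one BED6 record per present intron instance
#' (score = spanning read count) against that species' ungapped gene
#' sequences, plus the per-species genome FASTA and library sizes.  Counts
#' are negative binomial around a shared per-site mean scaled by library
#' size, which induces positive cross-species correlation; with
#' \code{dispersion = 0} counts are deterministic.
#'
#' @param truth a \linkS4class{TruthTable}.
#' @param alignments result of \code{\link{emitGeneAlignments}} (regenerated
#'   if \code{NULL}).
#' @param species species to emit (default: the four RNAseq-profiled
#'   species Scer/Skud/Suva/Ncas when present in the tree; any tree
#'   species works).
#' @param outdir optional output directory (\code{<sp>.junctions.bed},
#'   \code{<sp>.genome.fa}, \code{library_sizes.tsv}).
#' @param librarySizes named numeric, default 1e6 per species.
#' @param sharedMean draw the per-site mean once and share it across
#'   species (TRUE, the realistic regime) or independently per species
#'   (FALSE, the null regime used to check the correlation machinery).
#' @param dispersion override the config's dispersion.
#' @return list with \code{junctions} (named list of data.frames),
#'   \code{genomes} (named list of named character vectors),
#'   \code{librarySizes}.
#' @export
emitJunctionCounts <- function(truth, alignments = NULL, species = NULL,
                               outdir = NULL, librarySizes = NULL,
                               sharedMean = TRUE, dispersion = NULL) {
  config <- truth@config
  if (is.null(alignments)) alignments <- emitGeneAlignments(truth)
  if (is.null(species)) {
    species <- intersect(c("Scer", "Skud", "Suva", "Ncas"),
                         speciesNames(truth@tree))
    if (length(species) == 0)
      species <- utils::head(speciesNames(truth@tree), 4)
  }
  bad <- setdiff(species, speciesNames(truth@tree))
  if (length(bad) > 0)
    .pipelineError(sprintf("species not in tree: %s",
                           paste(bad, collapse = ", ")), "input_error")
  if (is.null(dispersion)) dispersion <- config@dispersion
  if (is.null(librarySizes))
    librarySizes <- setNames(rep(1e6, length(species)), species)
  set.seed(config@seed + 2L)
  si <- truth@siteInfo
  obs <- si$site_id[si$observable]
  mu <- setNames(rlnorm(length(obs), config@junctionMeanLog,
                        config@junctionSdLog), obs)
  junctions <- list(); genomes <- list()
  for (sp in species) {
    ls <- librarySizes[[sp]]
    rows <- list()
    genome <- character(0)
    for (fam in names(alignments)) {
      aln <- alignments[[fam]]
      rnames <- grep(paste0("^", sp, "\\|"), names(aln@seqs), value = TRUE)
      for (rn in rnames) {
        locus <- .splitRowName(rn)$locus
        chrom <- paste0(fam, "|", locus)
        genome[chrom] <- gsub("-", "", aln@seqs[[rn]], fixed = TRUE)
        ints <- aln@features[aln@features$type == "intron", , drop = FALSE]
        for (fi in seq_len(nrow(ints))) {
          site <- ints$site_id[fi]
          if (truth@states[site, rn] != .STATE_PRESENT) next
          pre <- substr(aln@seqs[[rn]], 1, ints$start[fi])
          start <- nchar(gsub("-", "", pre, fixed = TRUE))
          len <- truth@intronLen[site, rn]
          m <- if (sharedMean) mu[[site]]
               else rlnorm(1, config@junctionMeanLog, config@junctionSdLog)
          base <- m * ls / 1e6
          count <- if (dispersion == 0) round(base)
                   else rnbinom(1, mu = base, size = 1 / dispersion)
          rows[[length(rows) + 1]] <- data.frame(
            chrom = chrom, start = start, end = start + len,
            name = paste0(site, "|", locus), count = count, strand = "+",
            stringsAsFactors = FALSE)
        }
      }
    }
    junctions[[sp]] <- if (length(rows) > 0) do.call(rbind, rows)
                       else data.frame(chrom = character(0), start = integer(0),
                                       end = integer(0), name = character(0),
                                       count = numeric(0), strand = character(0))
    genomes[[sp]] <- genome
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (sp in species) {
      writeJunctionBed(junctions[[sp]],
                       file.path(outdir, paste0(sp, ".junctions.bed")))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(genomes[[sp]]),
        file.path(outdir, paste0(sp, ".genome.fa")))
    }
    writeLibrarySizes(librarySizes, file.path(outdir, "library_sizes.tsv"))
  }
  list(junctions = junctions, genomes = genomes,
       librarySizes = librarySizes)
}

#' Emit the complete simulated data set
#'
#' Writes every pipeline input (tree, pillar, alignments, junctions,
#' genomes, library sizes) plus the ground-truth state and event tables.
#'
#' @param truth a \linkS4class{TruthTable}.
#' @param outdir output directory.
#' @param species species for junction emission (see
#'   \code{\link{emitJunctionCounts}}).
#' @return \code{outdir}, invisibly.
#' @export
emitSimulatedData <- function(truth, outdir, species = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeNewickTree(truth@tree, file.path(outdir, "tree.nwk"))
  writePillar(truthPillar(truth), file.path(outdir, "pillar.tsv"))
  alns <- emitGeneAlignments(truth, file.path(outdir, "alignments"))
  emitJunctionCounts(truth, alignments = alns, species = species,
                     outdir = file.path(outdir, "junctions"))
  write.table(truth@events, file.path(outdir, "truth_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  long <- data.frame(site_id = rep(rownames(truth@states),
                                   ncol(truth@states)),
                     cell = rep(colnames(truth@states),
                                each = nrow(truth@states)),
                     state = as.vector(truth@states),
                     stringsAsFactors = FALSE)
  long <- long[!is.na(long$state), ]
  long <- long[order(long$site_id, long$cell), ]
  write.table(long, file.path(outdir, "truth_states.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
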