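# Downstream tables: per-species loss profiles, post-WGD fates of intronic
# snoRNAs, ribosomal-protein-gene intron statistics, and the ordered
# presence/loss heatmap export.

#' Per-species loss profile
#'
#' Per species: introns found (PRESENT cells over both loci), gains and
#' losses on its terminal branch (A + B summed), and the proportion of
#' intron-containing ancestral genes with at least one lost intron in that
#' species (denominator: ancestral genes with at least one defined locus
#' there).
#'
#' @param matrix a \linkS4class{StateMatrix}.
#' @param eventmap the \linkS4class{EventMap} from the same run.
#' @return data.frame: \code{species}, \code{introns_found},
#'   \code{terminal_gains}, \code{terminal_losses},
#'   \code{genes_with_loss}, \code{genes_defined},
#'   \code{prop_genes_with_loss}.
#' @export
speciesLossTable <- function(matrix, eventmap) {
  s <- matrix@states
  info <- .splitRowName(colnames(s))
  spAll <- unique(info$species)
  if (!setequal(spAll, eventmap@speciesTotals$species))
    .pipelineError("state matrix and event map cover different species",
                   "input_error")
  fam <- matrix@siteInfo$family
  out <- lapply(spAll, function(sp) {
    sub <- s[, info$species == sp, drop = FALSE]
    defined <- sub != .STATE_NO_DATA
    lost <- matrix(sub %in% .LOST_STATES, nrow = nrow(sub))
    byGene <- tapply(seq_len(nrow(sub)), fam, function(ix) {
      c(def = any(defined[ix, ]), loss = any(lost[ix, ]))
    })
    nDef <- sum(vapply(byGene, `[`, TRUE, "def"))
    nLoss <- sum(vapply(byGene, function(x) x["def"] && x["loss"], TRUE))
    st <- eventmap@speciesTotals
    data.frame(species = sp,
               introns_found = sum(sub == .STATE_PRESENT),
               terminal_gains = st$gains[st$species == sp],
               terminal_losses = st$losses[st$species == sp],
               genes_with_loss = nLoss, genes_defined = nDef,
               prop_genes_with_loss = if (nDef > 0) nLoss / nDef else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Post-WGD fate of a snoRNA-hosting gene from locus-level flags
# (g = gene present, i = intron present, s = snoRNA copy present).
# Precedence makes the five categories exhaustive and mutually exclusive
# over the full flag space: a snoRNA surviving outside an intact host
# intron is deintronized; otherwise every surviving snoRNA sits in an
# intact (gene, intron) locus and the host-gene/intron pattern decides.
.snoFateCategory <- function(gA, iA, sA, gB, iB, sB) {
  intactA <- gA && iA && sA
  intactB <- gB && iB && sB
  if ((sA && !(gA && iA)) || (sB && !(gB && iB))) return("DEINTRONIZED")
  if (intactA && intactB) return("BOTH_RETAINED")
  if ((intactA && !gB) || (intactB && !gA))
    return("ONE_COPY_RETAINED_WITH_SNORNA")
  if ((intactA && gB) || (intactB && gA))
    return("INTRON_LOST_SNORNA_IN_PARALOG_INTRON")
  "SNORNA_REMOVED"
}

#' Post-WGD fates of intronic snoRNAs
#'
#' Classifies each (snoRNA-hosting ancestral gene, post-WGD species) into
#' the five post-duplication fate categories from locus-level flags: gene
#' present (pillar), intron present (state matrix), snoRNA copy present
#' (snoRNA presence annotation, e.g. \code{\link{snoPresenceFromAlignments}}
#' or the simulator's truth).
#'
#' @param matrix a \linkS4class{StateMatrix} with snoRNA site metadata.
#' @param snoPresence logical matrix (sites x species|locus columns).
#' @param pillar a \linkS4class{PillarTable}.
#' @param tree the \linkS4class{SpeciesTree} (for the post-WGD species set).
#' @return list: \code{fates} (data.frame site_id, family, snorna, species,
#'   category) and \code{counts} (category counts).
#' @export
snornaFates <- function(matrix, snoPresence, pillar, tree) {
  si <- matrix@siteInfo
  snoSites <- si$site_id[!is.na(si$snorna)]
  if (length(snoSites) == 0)
    .pipelineError("no snoRNA-carrying sites in matrix", "input_error")
  post <- postWgdSpecies(tree)
  rows <- list()
  for (site in snoSites) {
    fam <- si$family[si$site_id == site]
    pRow <- pillar@entries[fam, ]
    if (!any(pRow[paste0(post, "|A")] != "-" |
             pRow[paste0(post, "|B")] != "-")) {
      warning(sprintf("snoRNA site '%s' has no post-WGD locus; excluded",
                      site))
      next
    }
    for (sp in post) {
      cA <- paste0(sp, "|A"); cB <- paste0(sp, "|B")
      gA <- pRow[cA] != "-"; gB <- pRow[cB] != "-"
      iA <- matrix@states[site, cA] == .STATE_PRESENT
      iB <- matrix@states[site, cB] == .STATE_PRESENT
      sA <- isTRUE(snoPresence[site, cA])
      sB <- isTRUE(snoPresence[site, cB])
      rows[[length(rows) + 1]] <- data.frame(
        site_id = site, family = fam,
        snorna = si$snorna[si$site_id == site], species = sp,
        category = .snoFateCategory(gA, iA, sA, gB, iB, sB),
        stringsAsFactors = FALSE)
    }
  }
  fates <- do.call(rbind, rows)
  cats <- c("BOTH_RETAINED", "ONE_COPY_RETAINED_WITH_SNORNA",
            "INTRON_LOST_SNORNA_IN_PARALOG_INTRON", "DEINTRONIZED",
            "SNORNA_REMOVED")
  list(fates = fates, counts = table(factor(fates$category, levels = cats)))
}

#' snoRNA presence flags from emitted alignments
#'
#' Reads the \code{present_in} attribute of snoRNA features back into a
#' logical site-by-column matrix aligned with a state matrix.
#'
#' @param alignments named list of \linkS4class{AnnotatedAlignment}.
#' @param matrix the \linkS4class{StateMatrix} defining dimensions.
#' @return logical matrix.
#' @export
snoPresenceFromAlignments <- function(alignments, matrix) {
  m <- base::matrix(FALSE, nrow = nrow(matrix@states),
                    ncol = ncol(matrix@states),
                    dimnames = dimnames(matrix@states))
  for (aln in alignments) {
    f <- aln@features[aln@features$type == "snoRNA", , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      if (!f$site_id[i] %in% rownames(m)) next
      if (is.na(f$present_in[i]) || f$present_in[i] == "") next
      toks <- strsplit(f$present_in[i], ",", fixed = TRUE)[[1]]
      m[f$site_id[i], intersect(toks, colnames(m))] <- TRUE
    }
  }
  m
}

#' Intron lengths measured from alignments
#'
#' Ungapped length of each PRESENT row's intron span, as a site-by-column
#' matrix aligned with a state matrix.
#'
#' @param alignments named list of \linkS4class{AnnotatedAlignment}.
#' @param matrix the \linkS4class{StateMatrix} defining dimensions.
#' @return numeric matrix (NA where no intron).
#' @export
intronLengthsFromAlignments <- function(alignments, matrix) {
  m <- base::matrix(NA_real_, nrow = nrow(matrix@states),
                    ncol = ncol(matrix@states),
                    dimnames = dimnames(matrix@states))
  for (aln in alignments) {
    f <- aln@features[aln@features$type == "intron", , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      site <- f$site_id[i]
      if (!site %in% rownames(m)) next
      for (rn in intersect(names(aln@seqs), colnames(m))) {
        if (matrix@states[site, rn] != .STATE_PRESENT) next
        content <- gsub("-", "",
                        substr(aln@seqs[[rn]], f$start[i] + 1, f$end[i]),
                        fixed = TRUE)
        m[site, rn] <- nchar(content)
      }
    }
  }
  m
}

#' Ribosomal-protein-gene intron statistics
#'
#' Loss-per-locus rates for RPG versus other sites (losses divided by
#' defined loci), per-species log2 intron length samples split RPG/other,
#' and a per-species bimodality verdict: a two-component Gaussian mixture
#' on log2 length is preferred over one component when its BIC exceeds the
#' one-component BIC by at least \code{delta}.
#'
#' @param matrix a \linkS4class{StateMatrix} with RPG flags.
#' @param eventmap the matching \linkS4class{EventMap} (loss events at RPG
#'   sites feed the event-based rate).
#' @param intronLengths numeric site-by-column matrix (e.g.
#'   \code{\link{intronLengthsFromAlignments}}).
#' @param delta BIC margin for calling bimodality (default 10).
#' @return list of class \code{RPGStats}: \code{ancestralRpgIntrons},
#'   \code{rpgLossRate}, \code{otherLossRate}, \code{rpgEventLossRate},
#'   \code{lengths} (long data.frame), \code{bimodality} (per species).
#' @export
rpgStats <- function(matrix, eventmap, intronLengths, delta = 10) {
  rpg <- matrix@siteInfo$rpg
  if (!any(rpg)) .pipelineError("no RPG sites in matrix", "input_error")
  s <- matrix@states
  rate <- function(idx) {
    sub <- s[idx, , drop = FALSE]
    defined <- sum(sub != .STATE_NO_DATA)
    if (defined == 0) return(NA_real_)
    sum(sub %in% .LOST_STATES) / defined
  }
  rpgSites <- matrix@siteInfo$site_id[rpg]
  ev <- eventmap@perSite
  rpgLossEvents <- sum(ev$event == "loss" & ev$site_id %in% rpgSites)
  definedRpgLoci <- sum(s[rpg, , drop = FALSE] != .STATE_NO_DATA)
  info <- .splitRowName(colnames(s))
  lengths <- do.call(rbind, lapply(which(!is.na(intronLengths)), function(ix) {
    i <- (ix - 1) %% nrow(s) + 1; j <- (ix - 1) %/% nrow(s) + 1
    data.frame(species = info$species[j], rpg = rpg[i],
               length = intronLengths[ix], stringsAsFactors = FALSE)
  }))
  bim <- do.call(rbind, lapply(unique(info$species), function(sp) {
    v <- lengths$length[lengths$species == sp]
    if (length(v) < 10)
      return(data.frame(species = sp, bic1 = NA_real_, bic2 = NA_real_,
                        margin = NA_real_, bimodal = NA))
    x <- log2(v)
    bic <- mclust::mclustBIC(x, G = 1:2, modelNames = "V", verbose = FALSE)
    b1 <- bic["1", "V"]; b2 <- bic["2", "V"]
    data.frame(species = sp, bic1 = b1, bic2 = b2, margin = b2 - b1,
               bimodal = isTRUE(b2 - b1 > delta), stringsAsFactors = FALSE)
  }))
  rownames(bim) <- NULL
  structure(list(
    ancestralRpgIntrons = sum(rpg),
    rpgLossRate = rate(rpg), otherLossRate = rate(!rpg),
    rpgEventLossRate = if (definedRpgLoci > 0)
      rpgLossEvents / definedRpgLoci else NA_real_,
    lengths = lengths, bimodality = bim), class = "RPGStats")
}

#' @export
print.RPGStats <- function(x, ...) {
  cat(sprintf("RPGStats: %d ancestral RPG introns; loss rate %.3f (RPG) vs %.3f (other)\n",
              x$ancestralRpgIntrons, x$rpgLossRate, x$otherLossRate))
  invisible(x)
}

#' Ordered heatmap export of the state matrix
#'
#' Rows are species|locus sub-rows in tree traversal order (two sub-rows
#' for post-WGD species), columns are intron sites; cells carry the
#' four-way code \code{present} / \code{loss_cdna} / \code{loss_indel} /
#' \code{unknown} (unknown-mechanism loss or no data).
#'
#' @param matrix a \linkS4class{StateMatrix}.
#' @param tree the \linkS4class{SpeciesTree} (row order).
#' @return data.frame, first column \code{row}, then one column per site.
#' @export
heatmapMatrix <- function(matrix, tree) {
  code <- c(present = "present", lost_perfect = "loss_cdna",
            lost_imperfect = "loss_indel", lost_unknown = "unknown",
            no_data = "unknown")
  rows <- intersect(.lociForTree(tree), colnames(matrix@states))
  out <- data.frame(row = rows, stringsAsFactors = FALSE)
  for (site in rownames(matrix@states))
    out[[site]] <- unname(code[matrix@states[site, rows]])
  out
}

#' Write / read a heatmap export
#'
#' @param heatmap data.frame from \code{\link{heatmapMatrix}}.
#' @param path TSV path.
#' @export
writeHeatmap <- function(heatmap, path) {
  write.table(heatmap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHeatmap
#' @export
readHeatmap <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
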