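# Central S4 containers for the intron-evolution pipeline.
#
# Internal coordinate convention: 0-based half-open everywhere.  GFF3 input
# and output is 1-based inclusive, BED 0-based half-open; the io functions
# are the only place conversions happen.

.STATE_PRESENT <- "present"
.STATE_LOST_PERFECT <- "lost_perfect"
.STATE_LOST_IMPERFECT <- "lost_imperfect"
.STATE_LOST_UNKNOWN <- "lost_unknown"
.STATE_NO_DATA <- "no_data"
.STATE_GENE_ABSENT <- "gene_absent"

.STATES <- c(.STATE_PRESENT, .STATE_LOST_PERFECT, .STATE_LOST_IMPERFECT,
             .STATE_LOST_UNKNOWN, .STATE_NO_DATA)
.LOST_STATES <- c(.STATE_LOST_PERFECT, .STATE_LOST_IMPERFECT,
                  .STATE_LOST_UNKNOWN)

.pipelineError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "introndollo_error")))
}

#' SpeciesTree: a rooted species tree with a tagged WGD node
#'
#' Wraps an \code{ape} \code{phylo} object.  Exactly one root; tip names are
#' unique; multifurcations are permitted.  One internal node may be tagged as
#' the whole-genome duplication (WGD); the clade it subtends is the post-WGD
#' group, whose genes occur at duplicated A/B loci.  All internal nodes carry
#' unique labels (filled deterministically on construction) so that every
#' branch has a stable identifier, namely the label of its child node.
#'
#' @slot phy an \code{ape::phylo}, rooted, with unique tip and node labels.
#' @slot wgdNode integer node number of the WGD node, or \code{NA}.
#' @export
setClass("SpeciesTree", representation(phy = "ANY", wgdNode = "integer"))

setValidity("SpeciesTree", function(object) {
  phy <- object@phy
  if (!inherits(phy, "phylo")) return("phy must be an ape phylo object")
  if (!ape::is.rooted(phy)) return("tree must be rooted")
  if (anyDuplicated(phy$tip.label)) return("tip names must be unique")
  if (is.null(phy$node.label) || any(phy$node.label == "") ||
      anyDuplicated(c(phy$tip.label, phy$node.label)))
    return("all internal nodes must carry unique non-empty labels")
  w <- object@wgdNode
  if (!is.na(w)) {
    if (w <= length(phy$tip.label) || w > length(phy$tip.label) + phy$Nnode)
      return("wgdNode must be an internal node number")
  }
  TRUE
})

#' ExpandedTree: the WGD-duplicated locus tree
#'
#' The species tree with the post-WGD clade duplicated into two isomorphic
#' copies (locus A and locus B) attached at the WGD node.  Tips and internal
#' nodes of the duplicated copies carry the suffix \code{"|A"} / \code{"|B"};
#' pre-WGD parts keep their labels (locus \code{"0"}).  \code{branchMap} maps
#' every expanded branch (identified by its child-node label) to the
#' corresponding branch of the simplified species tree and its locus; the
#' two branches joining the WGD node to the copy roots map to the branch
#' subtending the WGD node.
#'
#' @slot phy the expanded \code{phylo}.
#' @slot species the originating \linkS4class{SpeciesTree}.
#' @slot branchMap data.frame with columns \code{branch}, \code{simplified},
#'   \code{locus}.
#' @export
setClass("ExpandedTree",
         representation(phy = "ANY", species = "SpeciesTree",
                        branchMap = "data.frame"))

setValidity("ExpandedTree", function(object) {
  bm <- object@branchMap
  need <- c("branch", "simplified", "locus")
  if (!all(need %in% names(bm))) return("branchMap needs branch/simplified/locus")
  phy <- object@phy
  ids <- c(phy$tip.label, phy$node.label)
  root <- .rootLabel(phy)
  if (!setequal(bm$branch, setdiff(ids, root)))
    return("branchMap must cover every non-root branch exactly once")
  TRUE
})

#' AnnotatedAlignment: a gene-family alignment with intron features
#'
#' Rows are gapped sequences of equal length keyed by \code{"species|locus"}
#' (locus \code{"A"}/\code{"B"} for post-WGD species, \code{"0"} otherwise).
#' Features live in alignment-column space, 0-based half-open.  An intron
#' span in a row either contains sequence (intron present in that row) or
#' only gaps.
#'
#' @slot family family (ancestral gene) identifier.
#' @slot seqs named character vector of gapped rows, equal width.
#' @slot features data.frame: \code{site_id}, \code{type} (\code{intron},
#'   \code{branch_point}, \code{snoRNA}, \code{start_codon}), \code{start},
#'   \code{end} (0-based half-open columns), \code{utr5}, \code{snorna}
#'   (snoRNA id or NA), \code{present_in} (comma-separated
#'   \code{species|locus} tokens carrying a snoRNA copy, NA otherwise).
#' @slot rpg logical; is the family a ribosomal protein gene.
#' @export
setClass("AnnotatedAlignment",
         representation(family = "character", seqs = "character",
                        features = "data.frame", rpg = "logical"))

setValidity("AnnotatedAlignment", function(object) {
  if (length(object@seqs) == 0) return("alignment needs at least one row")
  w <- unique(nchar(object@seqs))
  if (length(w) != 1) return("ragged alignment: rows differ in width")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    return("rows must have unique species|locus names")
  f <- object@features
  need <- c("site_id", "type", "start", "end")
  if (!all(need %in% names(f))) return("features need site_id/type/start/end")
  if (nrow(f) > 0) {
    if (any(f$start < 0) || any(f$end > w) || any(f$end <= f$start))
      return(sprintf("feature span out of bounds in family %s", object@family))
    bad <- setdiff(f$type, c("intron", "branch_point", "snoRNA", "start_codon"))
    if (length(bad) > 0)
      return(sprintf("unknown feature type(s): %s", paste(bad, collapse = ", ")))
  }
  TRUE
})

#' PillarTable: ortholog pillars across species and WGD loci
#'
#' One row per ancestral gene; one column per \code{"species|locus"} slot
#' holding a gene identifier or the absent marker \code{"-"}.  Post-WGD
#' species contribute two columns (loci A and B), pre-WGD species one
#' (locus 0); columns are ordered species-then-locus.
#'
#' @slot entries character matrix, rownames = ancestral gene ids,
#'   colnames = \code{"species|locus"}.
#' @export
setClass("PillarTable", representation(entries = "matrix"))

setValidity("PillarTable", function(object) {
  m <- object@entries
  if (!is.character(m)) return("entries must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("entries needs row (gene) and column (species|locus) names")
  if (any(apply(m, 1, function(r) all(r == "-"))))
    return("a pillar row must have at least one non-absent entry")
  TRUE
})

#' StateMatrix: ancestral intron site by (species, locus) classification grid
#'
#' Cell values are one of \code{present}, \code{lost_perfect},
#' \code{lost_imperfect}, \code{lost_unknown}, \code{no_data}.  For
#' imperfect (and perfect) losses the net codon indel k is held in the
#' parallel \code{k} matrix.  Site metadata (family, 5'-UTR flag, RPG flag,
#' snoRNA id) lives in \code{siteInfo}.
#'
#' @slot states character matrix, rows = site ids, cols = species|locus.
#' @slot k integer matrix of net codon indels (NA where not applicable).
#' @slot notes character matrix of provenance notes.
#' @slot siteInfo data.frame: \code{site_id}, \code{family}, \code{utr5},
#'   \code{rpg}, \code{snorna}.
#' @export
setClass("StateMatrix",
         representation(states = "matrix", k = "matrix", notes = "matrix",
                        siteInfo = "data.frame"))

setValidity("StateMatrix", function(object) {
  s <- object@states
  if (!identical(dim(s), dim(object@k)) || !identical(dim(s), dim(object@notes)))
    return("states, k and notes must have identical dimensions")
  bad <- setdiff(unique(as.vector(s)), .STATES)
  if (length(bad) > 0)
    return(sprintf("invalid state value(s): %s", paste(bad, collapse = ", ")))
  if (!identical(rownames(s), object@siteInfo$site_id))
    return("siteInfo rows must match state matrix rows")
  TRUE
})

#' TruthTable: simulator ground truth
#'
#' States use the pipeline vocabulary plus \code{gene_absent} for loci whose
#' gene was not retained after WGD.  \code{events} holds the canonical
#' (unique minimal Dollo) per-site branch events on the observable expanded
#' tree; \code{rawEvents} the raw generative events before canonicalization
#' (sibling losses merged upward, gains slid to the MRCA of surviving tips
#' are the only differences).  Per present intron instance the true length,
#' S2 distance and branch-point offset are recorded.
#'
#' @slot states character matrix sites x (species|locus).
#' @slot k integer matrix of codon indels for lost states.
#' @slot siteInfo data.frame with site metadata plus \code{observable}.
#' @slot events data.frame: \code{site_id}, \code{branch}, \code{event}.
#' @slot rawEvents data.frame, same columns.
#' @slot kNt integer matrix of net nucleotide indels (frameshifting for
#'   unknown-type losses).
#' @slot intronLen,s2,bpPos numeric matrices (NA where no intron).
#' @slot snoPresence logical matrix (snoRNA copy present per cell).
#' @slot tree,etree the species tree and its WGD expansion.
#' @slot config the generating \linkS4class{SimConfig}.
#' @slot genes data.frame of gene-level draws (RPG flag, locus retention).
#' @export
setClass("TruthTable",
         representation(states = "matrix", k = "matrix", kNt = "matrix",
                        siteInfo = "data.frame",
                        events = "data.frame", rawEvents = "data.frame",
                        intronLen = "matrix", s2 = "matrix", bpPos = "matrix",
                        snoPresence = "matrix", tree = "SpeciesTree",
                        etree = "ExpandedTree", config = "ANY",
                        genes = "data.frame"))

#' EventMap: per-branch event totals on the simplified tree
#'
#' Gains and losses per simplified-tree branch (A and B locus branches
#' summed), the per-site event lists with their expanded-tree provenance,
#' per-species terminal totals, and the sites skipped for lack of a Dollo
#' anchor (no present tip).
#'
#' @slot branches data.frame: \code{branch}, \code{gains}, \code{losses}.
#' @slot perSite data.frame: \code{site_id}, \code{branch},
#'   \code{simplified}, \code{locus}, \code{event}.
#' @slot speciesTotals data.frame: \code{species}, \code{gains},
#'   \code{losses}.
#' @slot multiLossSites character vector of sites lost more than once.
#' @slot skippedSites character vector.
#' @export
setClass("EventMap",
         representation(branches = "data.frame", perSite = "data.frame",
                        speciesTotals = "data.frame",
                        multiLossSites = "character",
                        skippedSites = "character"))

#' SpliceConfig: splice-signal grammar parameters
#'
#' The Saccharomycetaceae splicing grammar: GTATGT at the 5' splice site,
#' TACTAAC at the branch point, a terminal AG at the 3' splice site, and
#' intron length bounds matching the minimum and maximum intron lengths of
#' annotated S. cerevisiae genes (49-1050 nt).  The S2 distance of an
#' intron is the number of nucleotides from the end of the branch-point
#' heptamer to the final intron base, inclusive of the terminal AG.
#'
#' @slot fiveSS,bpMotif,threeSS uppercase DNA motifs.
#' @slot fiveSSMaxMismatch,bpMaxMismatch allowed motif mismatches.
#' @slot minIntronLen,maxIntronLen,minS2 length bounds in nt.
#' @export
setClass("SpliceConfig",
         representation(fiveSS = "character", bpMotif = "character",
                        threeSS = "character", fiveSSMaxMismatch = "integer",
                        bpMaxMismatch = "integer", minIntronLen = "integer",
                        maxIntronLen = "integer", minS2 = "integer"))

setValidity("SpliceConfig", function(object) {
  for (m in c(object@fiveSS, object@bpMotif, object@threeSS)) {
    if (nchar(m) == 0 || grepl("[^ACGT]", m))
      return("motifs must be non-empty uppercase DNA")
  }
  if (object@minIntronLen <= 0 || object@minIntronLen > object@maxIntronLen)
    return("need 0 < minIntronLen <= maxIntronLen")
  if (object@fiveSSMaxMismatch < 0 || object@bpMaxMismatch < 0 ||
      object@minS2 < 1)
    return("mismatch counts must be >= 0 and minS2 >= 1")
  TRUE
})

#' ClassifyConfig: intron-loss classification parameters
#'
#' Perfect losses (cDNA-mediated gene replacement) add or delete at most
#' \code{perfectMaxCodons}; imperfect losses carry a net indel of
#' \code{imperfectMinCodons}..\code{imperfectMaxCodons} whole codons; net
#' indels that are not a multiple of three (frameshifts), or beyond the
#' imperfect range, are classed as unknown-mechanism losses.
#' \code{flankCodons} is the amount of exon sequence accumulated on each
#' side of the junction for indel accounting (the column window stretches
#' over alignment indel blocks until that much exon is covered).
#'
#' @slot perfectMaxCodons,imperfectMinCodons,imperfectMaxCodons codon bounds.
#' @slot flankCodons exon codons per junction side used for indel accounting.
#' @slot utrPolicy state assigned to unresolvable 5'-UTR sites.
#' @export
setClass("ClassifyConfig",
         representation(perfectMaxCodons = "integer",
                        imperfectMinCodons = "integer",
                        imperfectMaxCodons = "integer",
                        flankCodons = "integer", utrPolicy = "character"))

setValidity("ClassifyConfig", function(object) {
  if (!(object@perfectMaxCodons < object@imperfectMinCodons &&
        object@imperfectMinCodons <= object@imperfectMaxCodons))
    return("need perfectMaxCodons < imperfectMinCodons <= imperfectMaxCodons")
  if (!object@utrPolicy %in% .LOST_STATES)
    return("utrPolicy must be a lost_* state")
  TRUE
})

#' SimConfig: synthetic intron-evolution parameters
#'
#' Defaults emulate the study conditions: nearly all intron sites present in
#' the common ancestor, rare gains, irreversible per-branch loss, a loss-type
#' mixture of 71\% perfect / 3\% imperfect / 26\% unknown, WGD locus
#' retention with at least one surviving copy per gene, longer introns in
#' ribosomal protein genes (RPGs) with a reduced loss rate, and a handful of
#' snoRNA-carrying introns.
#'
#' @slot nGenes number of gene families.
#' @slot intronsPerGene named numeric: probability of 1, 2, ... introns.
#' @slot pRootPresent probability a site is present at the root.
#' @slot perBranchLossProb per-branch loss probability.
#' @slot lossTypeProbs named triple (perfect, imperfect, unknown), sums to 1.
#' @slot gainRate per-site probability of a single gain below the root.
#' @slot pLocusRetained post-WGD per-locus gene retention probability.
#' @slot rpgFraction fraction of families flagged RPG.
#' @slot rpgLossMultiplier multiplier on the loss probability at RPG sites.
#' @slot intronLenMeanlog,intronLenSdlog log-normal length parameters (nt).
#' @slot rpgLenMeanlog,rpgLenSdlog longer component used for RPG introns.
#' @slot s2Mean,s2Sd S2 distance distribution; \code{s2Mean} may be a named
#'   per-species vector.
#' @slot snornaSites number of introns carrying a snoRNA.
#' @slot pDeintronized probability a snoRNA copy survives at a locus whose
#'   host gene was lost.
#' @slot utrFraction fraction of sites flagged as 5'-UTR introns.
#' @slot exonNoise per-site substitution probability on exon sequence.
#' @slot flankExonCodons codons of exon emitted on each side of a junction.
#' @slot junctionMeanLog,junctionSdLog log-normal shared per-site junction
#'   read-count mean.
#' @slot dispersion negative-binomial dispersion of junction counts
#'   (0 = deterministic counts).
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
         representation(nGenes = "integer", intronsPerGene = "numeric",
                        pRootPresent = "numeric", perBranchLossProb = "numeric",
                        lossTypeProbs = "numeric", gainRate = "numeric",
                        pLocusRetained = "numeric", rpgFraction = "numeric",
                        rpgLossMultiplier = "numeric",
                        intronLenMeanlog = "numeric", intronLenSdlog = "numeric",
                        rpgLenMeanlog = "numeric", rpgLenSdlog = "numeric",
                        s2Mean = "numeric", s2Sd = "numeric",
                        snornaSites = "integer", pDeintronized = "numeric",
                        utrFraction = "numeric", exonNoise = "numeric",
                        flankExonCodons = "integer",
                        junctionMeanLog = "numeric", junctionSdLog = "numeric",
                        dispersion = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  probs <- c(object@pRootPresent, object@perBranchLossProb, object@gainRate,
             object@pLocusRetained, object@rpgFraction, object@pDeintronized,
             object@utrFraction, object@exonNoise, object@lossTypeProbs,
             object@intronsPerGene)
  if (any(probs < 0) || any(probs > 1))
    return("all probabilities must lie in [0, 1]")
  if (abs(sum(object@lossTypeProbs) - 1) > 1e-9)
    return("lossTypeProbs must sum to 1")
  if (!identical(names(object@lossTypeProbs),
                 c("perfect", "imperfect", "unknown")))
    return("lossTypeProbs must be named (perfect, imperfect, unknown)")
  if (abs(sum(object@intronsPerGene) - 1) > 1e-9)
    return("intronsPerGene probabilities must sum to 1")
  if (object@nGenes < 1) return("nGenes must be >= 1")
  TRUE
})
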