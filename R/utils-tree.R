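# Low-level tree plumbing shared by the io, simulation and Dollo modules.
# Branches are identified by the label of their child node, so labels must
# be unique and non-empty; .fillNodeLabels guarantees that.

.nTips <- function(phy) length(phy$tip.label)

.rootNode <- function(phy) .nTips(phy) + 1L

.rootLabel <- function(phy) phy$node.label[1L]

.nodeLabels <- function(phy) c(phy$tip.label, phy$node.label)

.labelOf <- function(phy, node) .nodeLabels(phy)[node]

.nodeOf <- function(phy, label) {
  i <- match(label, .nodeLabels(phy))
  if (is.na(i)) .pipelineError(sprintf("unknown node label '%s'", label),
                               "tree_error")
  i
}

.parentVec <- function(phy) {
  p <- integer(.nTips(phy) + phy$Nnode)
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

.childrenList <- function(phy) {
  n <- .nTips(phy) + phy$Nnode
  split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(n)))
}

.cladeTips <- function(phy, node) {
  nt <- .nTips(phy)
  if (node <= nt) return(phy$tip.label[node])
  kids <- .childrenList(phy)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= nt) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  phy$tip.label[sort(out)]
}

# Deterministically label unlabeled internal nodes n1, n2, ... in node-number
# order, avoiding clashes with existing labels.
.fillNodeLabels <- function(phy) {
  nl <- phy$node.label
  if (is.null(nl)) nl <- rep("", phy$Nnode)
  nl[is.na(nl)] <- ""
  taken <- c(phy$tip.label, nl[nl != ""])
  k <- 0L
  for (i in seq_along(nl)) {
    if (nl[i] == "") {
      repeat {
        k <- k + 1L
        cand <- sprintf("n%d", k)
        if (!cand %in% taken) break
      }
      nl[i] <- cand
      taken <- c(taken, cand)
    }
  }
  phy$node.label <- nl
  phy
}

#' Construct a SpeciesTree from an ape phylo
#'
#' Internal node labels are filled deterministically where missing; the node
#' labeled \code{wgdLabel} (if any) becomes the WGD node.
#'
#' @param phy a rooted \code{ape::phylo}.
#' @param wgdLabel node label marking the WGD node (default \code{"WGD"}).
#' @return a \linkS4class{SpeciesTree}.
#' @export
speciesTree <- function(phy, wgdLabel = "WGD") {
  if (!inherits(phy, "phylo"))
    .pipelineError("phy must be an ape phylo object", "validation_error")
  if (anyDuplicated(phy$tip.label))
    .pipelineError("duplicate tip names in tree", "validation_error")
  phy <- .fillNodeLabels(phy)
  w <- NA_integer_
  if (!is.na(wgdLabel) && wgdLabel %in% phy$node.label)
    w <- .nTips(phy) + match(wgdLabel, phy$node.label)
  new("SpeciesTree", phy = phy, wgdNode = w)
}

#' @rdname accessors
#' @export
setMethod("treePhylo", "SpeciesTree", function(x, ...) x@phy)

#' @rdname accessors
#' @export
setMethod("treePhylo", "ExpandedTree", function(x, ...) x@phy)

#' @rdname accessors
#' @export
setMethod("wgdNode", "SpeciesTree", function(x, ...) x@wgdNode)

#' @rdname accessors
#' @export
setMethod("speciesNames", "SpeciesTree", function(x, ...) x@phy$tip.label)

#' @rdname accessors
#' @export
setMethod("postWgdSpecies", "SpeciesTree", function(x, ...) {
  if (is.na(x@wgdNode)) return(character(0))
  .cladeTips(x@phy, x@wgdNode)
})

#' @rdname accessors
#' @export
setMethod("speciesNames", "ExpandedTree",
          function(x, ...) speciesNames(x@species))

#' @rdname accessors
#' @export
setMethod("postWgdSpecies", "ExpandedTree",
          function(x, ...) postWgdSpecies(x@species))

#' @rdname accessors
#' @export
setMethod("branchMap", "ExpandedTree", function(x, ...) x@branchMap)

setMethod("show", "SpeciesTree", function(object) {
  cat(sprintf("SpeciesTree: %d tips", .nTips(object@phy)))
  if (!is.na(object@wgdNode)) {
    cat(sprintf(", WGD node '%s' subtending %d post-WGD species",
                .labelOf(object@phy, object@wgdNode),
                length(postWgdSpecies(object))))
  }
  cat("\n")
})

setMethod("show", "ExpandedTree", function(object) {
  cat(sprintf("ExpandedTree: %d locus tips (%d pre-WGD + 2 x %d post-WGD)\n",
              .nTips(object@phy),
              length(speciesNames(object)) - length(postWgdSpecies(object)),
              length(postWgdSpecies(object))))
})

# Split "species|locus" tokens; plain species names are locus "0".
.splitRowName <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  data.frame(species = vapply(parts, `[`, "", 1L),
             locus = vapply(parts, function(p) if (length(p) > 1) p[2] else "0",
                            ""),
             stringsAsFactors = FALSE)
}

.rowName <- function(species, locus) {
  ifelse(locus == "0", paste0(species, "|0"), paste0(species, "|", locus))
}

# Column order for matrices/pillars: tree tip order, locus A before B.
.lociForTree <- function(tree) {
  post <- postWgdSpecies(tree)
  unlist(lapply(speciesNames(tree), function(sp) {
    if (sp %in% post) paste0(sp, c("|A", "|B")) else paste0(sp, "|0")
  }), use.names = FALSE)
}
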