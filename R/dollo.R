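# Dollo parsimony on the WGD-expanded locus tree.  A binary intron
# character may be gained at most once and is lost irreversibly; for a
# fixed gain node the minimal loss set is unique: one loss per maximal
# all-absent clade inside the gain clade.  The gain node under pure Dollo
# is the MRCA of the present tips, which is always globally minimal
# (moving the gain up adds at least one loss for the absent subtrees it
# newly covers).

# Recursive Newick writer used for WGD expansion: at the WGD node the clade
# is emitted twice with "|A" / "|B" suffixes on every contained label.
.expandNewick <- function(phy, node, wgdNode, kids, suffix = NULL) {
  lab <- .labelOf(phy, node)
  if (!is.null(suffix)) lab <- paste0(lab, "|", suffix)
  if (node <= .nTips(phy)) return(lab)
  if (is.null(suffix) && !is.na(wgdNode) && node == wgdNode) {
    a <- .expandNewick(phy, node, wgdNode, kids, suffix = "A")
    b <- .expandNewick(phy, node, wgdNode, kids, suffix = "B")
    return(sprintf("(%s,%s)%s", a, b, .labelOf(phy, node)))
  }
  parts <- vapply(kids[[node]], function(ch)
    .expandNewick(phy, ch, wgdNode, kids, suffix = suffix), "")
  sprintf("(%s)%s", paste(parts, collapse = ","), lab)
}

# Identity "expansion" for trees without a WGD tag (single-locus analyses
# and small simulation studies): every branch maps to itself, locus "0".
.identityExpansion <- function(tree) {
  phy <- tree@phy
  ids <- setdiff(.nodeLabels(phy), .rootLabel(phy))
  new("ExpandedTree", phy = phy, species = tree,
      branchMap = data.frame(branch = ids, simplified = ids, locus = "0",
                             stringsAsFactors = FALSE))
}

#' Locus tree for a species tree
#'
#' \code{\link{expandWgdTree}} when a WGD node is tagged, otherwise the
#' identity expansion (each species a single locus "0").
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @return an \linkS4class{ExpandedTree}.
#' @export
locusTree <- function(tree) {
  if (is.na(tree@wgdNode)) .identityExpansion(tree) else expandWgdTree(tree)
}

#' Expand the WGD clade into duplicated A/B locus copies
#'
#' Returns the tree in which the post-WGD clade appears twice, as locus A
#' and locus B lineages both attached at the WGD node, together with the
#' map from every expanded branch back to its simplified-tree branch and
#' locus.  Labeling is deterministic (A = first copy, B = second).
#'
#' @param tree a \linkS4class{SpeciesTree} with a tagged WGD node.
#' @return an \linkS4class{ExpandedTree}.
#' @export
expandWgdTree <- function(tree) {
  if (is.na(tree@wgdNode))
    .pipelineError("tree has no tagged WGD node", "input_error")
  phy <- tree@phy
  kids <- .childrenList(phy)
  nwk <- paste0(.expandNewick(phy, .rootNode(phy), tree@wgdNode, kids), ";")
  ephy <- ape::read.tree(text = nwk)
  ids <- setdiff(.nodeLabels(ephy), .rootLabel(ephy))
  locus <- ifelse(grepl("\\|A$", ids), "A",
                  ifelse(grepl("\\|B$", ids), "B", "0"))
  simplified <- sub("\\|[AB]$", "", ids)
  bm <- data.frame(branch = ids, simplified = simplified, locus = locus,
                   stringsAsFactors = FALSE)
  et <- new("ExpandedTree", phy = ephy, species = tree, branchMap = bm)
  methods::validObject(et)
  et
}

# Expanded-tree tip label for a matrix column ("Sp|0" tips have no suffix).
.tipForColumn <- function(cols) sub("\\|0$", "", cols)
.columnForTip <- function(tips) {
  ifelse(grepl("|", tips, fixed = TRUE), tips, paste0(tips, "|0"))
}

#' Prune the expanded tree for one site
#'
#' Removes tips with no data (absent gene or excluded sequence) and
#' suppresses the resulting unifurcations; surviving branch labels are kept,
#' so the branch map remains valid.  Sites with no present tip cannot
#' anchor a Dollo character and yield \code{NULL} with a warning.
#'
#' @param etree an \linkS4class{ExpandedTree}.
#' @param siteStates named character vector of states, names =
#'   \code{"species|locus"} matrix columns.
#' @return list with \code{phy} (pruned phylo) and \code{present} (named
#'   logical over its tips), or \code{NULL} if no tip is present.
#' @export
pruneForSite <- function(etree, siteStates) {
  tips <- .tipForColumn(names(siteStates))
  states <- setNames(as.character(siteStates), tips)
  hasData <- states != .STATE_NO_DATA & states != .STATE_GENE_ABSENT
  if (!any(states[hasData] == .STATE_PRESENT)) {
    warning("site has no present tip; skipped (no Dollo anchor)")
    return(NULL)
  }
  phy <- etree@phy
  drop <- setdiff(phy$tip.label, tips[hasData])
  if (length(drop) > 0)
    phy <- ape::drop.tip(phy, drop, collapse.singles = TRUE)
  keep <- intersect(tips[hasData], phy$tip.label)
  list(phy = phy, present = setNames(states[keep] == .STATE_PRESENT, keep),
       states = states[keep])
}

# All-absent flag for every node: postorder AND over the edge matrix
# (child rows precede their parent row in ape::postorder).
.allAbsentFlags <- function(phy, present) {
  nt <- .nTips(phy)
  n <- nt + phy$Nnode
  res <- rep(TRUE, n)
  res[seq_len(nt)] <- !present[phy$tip.label]
  for (i in ape::postorder(phy)) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    res[p] <- res[p] && res[ch]
  }
  res
}

#' Dollo parsimony assignment for one site
#'
#' The gain node is the MRCA of the present tips (or the root when
#' \code{assumeRootPresence}); the loss set is the unique minimal one for
#' that gain node: one loss per maximal all-absent clade strictly inside
#' the gain clade (under a multifurcation, one loss per absent child
#' subtree).  A gain is reported as an event only when the gain node is not
#' the root of the pruned tree.
#'
#' @param phy pruned phylo with unique labels.
#' @param present named logical vector over the tips.
#' @param assumeRootPresence place the character at the root regardless of
#'   the MRCA (used for gain overrides).
#' @return list of class \code{EventAssignment}: \code{gainBranch} (branch
#'   id, or \code{NA} for root presence), \code{gainIsEvent},
#'   \code{lossBranches} (sorted branch ids), \code{nEvents}.
#' @export
dolloAssign <- function(phy, present, assumeRootPresence = FALSE) {
  nt <- .nTips(phy)
  presTips <- names(present)[present]
  if (length(presTips) == 0)
    .pipelineError("no present tips: cannot anchor a Dollo character",
                   "input_error")
  root <- .rootNode(phy)
  gain <- if (assumeRootPresence) root
          else if (length(presTips) == 1) match(presTips, phy$tip.label)
          else ape::getMRCA(phy, presTips)
  absent <- .allAbsentFlags(phy, present)
  parent <- .parentVec(phy)
  # maximal all-absent nodes strictly inside the gain clade
  losses <- character(0)
  if (gain > nt) {
    inClade <- logical(nt + phy$Nnode)
    stack <- gain
    kids <- .childrenList(phy)
    while (length(stack) > 0) {
      v <- stack[[1]]; stack <- stack[-1]
      inClade[v] <- TRUE
      if (v > nt) stack <- c(stack, kids[[v]])
    }
    cand <- which(inClade & absent)
    cand <- cand[cand != gain]
    # maximal: parent not all-absent (the gain node never is, it has
    # present tips below it)
    cand <- cand[!absent[parent[cand]]]
    losses <- sort(.nodeLabels(phy)[cand])
  }
  gainIsEvent <- gain != root
  structure(list(gainBranch = if (gainIsEvent) .labelOf(phy, gain) else NA_character_,
                 gainIsEvent = gainIsEvent,
                 lossBranches = losses,
                 nEvents = length(losses) + gainIsEvent),
            class = "EventAssignment")
}

#' @export
print.EventAssignment <- function(x, ...) {
  cat(sprintf("EventAssignment: %s, %d loss(es)%s\n",
              if (x$gainIsEvent) sprintf("gain on '%s'", x$gainBranch)
              else "root presence",
              length(x$lossBranches),
              if (length(x$lossBranches) > 0)
                paste0(" [", paste(x$lossBranches, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Exhaustive Dollo oracle (test reference)
#'
#' Enumerates every admissible gain placement (any node whose clade covers
#' all present tips, including root presence) and, for each, the forced
#' minimal loss set; returns the global minimum event count.  Refuses trees
#' with more than 14 tips.
#'
#' @param phy pruned phylo.
#' @param present named logical over tips.
#' @return minimal total event count (gain events + losses).
#' @export
dolloOracle <- function(phy, present) {
  nt <- .nTips(phy)
  if (nt > 14)
    .pipelineError("oracle refuses trees with more than 14 tips",
                   "input_error")
  presTips <- names(present)[present]
  if (length(presTips) == 0)
    .pipelineError("no present tips", "input_error")
  root <- .rootNode(phy)
  absent <- .allAbsentFlags(phy, present)
  parent <- .parentVec(phy)
  kids <- .childrenList(phy)
  cladeOf <- function(v) .cladeTips(phy, v)
  best <- Inf
  for (g in seq_len(nt + phy$Nnode)) {
    if (!all(presTips %in% cladeOf(g))) next
    # forced losses: maximal all-absent nodes strictly inside clade(g)
    nl <- 0L
    if (g > nt) {
      stack <- kids[[g]]
      while (length(stack) > 0) {
        v <- stack[[1]]; stack <- stack[-1]
        if (absent[v]) nl <- nl + 1L
        else if (v > nt) stack <- c(stack, kids[[v]])
      }
    }
    cost <- nl + as.integer(g != root)
    if (cost < best) best <- cost
  }
  best
}

#' Assign Dollo events for every site of a state matrix
#'
#' Prunes the expanded tree per site, runs \code{\link{dolloAssign}}, and
#' applies gain curation: sites listed in \code{overrides} (and, when
#' \code{maxGainSpan} is finite, sites whose gain clade spans more species)
#' are recomputed under root presence, converting the gain into losses on
#' alternative branches.
#'
#' @param matrix a \linkS4class{StateMatrix}.
#' @param etree an \linkS4class{ExpandedTree}.
#' @param overrides character vector of site ids whose gain is rejected.
#' @param maxGainSpan automatic rule: reject gains whose clade spans more
#'   than this many species (default \code{Inf} = off).
#' @return list with \code{assignments} (named list of
#'   \code{EventAssignment}, each carrying its pruned tree) and
#'   \code{skipped} (sites with no present tip).
#' @export
assignEvents <- function(matrix, etree, overrides = character(0),
                         maxGainSpan = Inf) {
  s <- matrix@states
  assignments <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(s))) {
    site <- rownames(s)[i]
    pr <- withCallingHandlers(
      pruneForSite(etree, s[i, ]),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(pr)) { skipped <- c(skipped, site); next }
    a <- dolloAssign(pr$phy, pr$present)
    reject <- site %in% overrides
    if (!reject && a$gainIsEvent && is.finite(maxGainSpan)) {
      span <- length(unique(.splitRowName(.columnForTip(
        .cladeTips(pr$phy, .nodeOf(pr$phy, a$gainBranch))))$species))
      reject <- span > maxGainSpan
    }
    if (reject && a$gainIsEvent)
      a <- dolloAssign(pr$phy, pr$present, assumeRootPresence = TRUE)
    a$site <- site
    a$prunedPhy <- pr$phy
    a$tipPresent <- pr$present
    a$tipStates <- pr$states
    assignments[[site]] <- a
  }
  list(assignments = assignments, skipped = skipped)
}

#' Apply gain overrides to existing assignments
#'
#' Recomputes the named sites with root presence assumed, so the former
#' gain becomes one or more losses on alternative branches.  Overriding a
#' site already at root presence is a no-op with a warning.
#'
#' @param assignResult result of \code{\link{assignEvents}}.
#' @param overrides character vector of site ids.
#' @return an updated \code{assignEvents} result.
#' @export
applyOverrides <- function(assignResult, overrides) {
  for (site in overrides) {
    a <- assignResult$assignments[[site]]
    if (is.null(a)) {
      warning(sprintf("override for unknown/skipped site '%s' ignored", site))
      next
    }
    if (!a$gainIsEvent) {
      warning(sprintf("site '%s' already has root presence; override is a no-op",
                      site))
      next
    }
    b <- dolloAssign(a$prunedPhy, a$tipPresent, assumeRootPresence = TRUE)
    b$site <- site
    b$prunedPhy <- a$prunedPhy
    b$tipPresent <- a$tipPresent
    b$tipStates <- a$tipStates
    assignResult$assignments[[site]] <- b
  }
  assignResult
}

#' Sum events per branch of the simplified tree
#'
#' Projects every per-site event through the branch map (A and B locus
#' branches fold onto the corresponding simplified branch; the copy-root
#' branches fold onto the branch subtending the WGD node) and sums gains
#' and losses per simplified branch.  Also reports per-species terminal
#' totals and the sites lost more than once.
#'
#' @param assignResult result of \code{\link{assignEvents}} (or a plain
#'   named list of \code{EventAssignment}s under \code{$assignments}).
#' @param etree the \linkS4class{ExpandedTree} used for assignment.
#' @return an \linkS4class{EventMap}.
#' @export
summarizeEvents <- function(assignResult, etree) {
  bm <- etree@branchMap
  simpOf <- setNames(bm$simplified, bm$branch)
  locOf <- setNames(bm$locus, bm$branch)
  rows <- list()
  for (a in assignResult$assignments) {
    if (a$gainIsEvent)
      rows[[length(rows) + 1]] <- data.frame(
        site_id = a$site, branch = a$gainBranch, event = "gain",
        stringsAsFactors = FALSE)
    for (lb in a$lossBranches)
      rows[[length(rows) + 1]] <- data.frame(
        site_id = a$site, branch = lb, event = "loss",
        stringsAsFactors = FALSE)
  }
  perSite <- if (length(rows) > 0) do.call(rbind, rows)
             else data.frame(site_id = character(0), branch = character(0),
                             event = character(0), stringsAsFactors = FALSE)
  perSite$simplified <- unname(simpOf[perSite$branch])
  perSite$locus <- unname(locOf[perSite$branch])
  perSite <- perSite[, c("site_id", "branch", "simplified", "locus", "event")]
  allBranches <- sort(unique(bm$simplified))
  branches <- data.frame(
    branch = allBranches,
    gains = vapply(allBranches, function(b)
      sum(perSite$event == "gain" & perSite$simplified == b), 0L),
    losses = vapply(allBranches, function(b)
      sum(perSite$event == "loss" & perSite$simplified == b), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  sp <- speciesNames(etree)
  speciesTotals <- data.frame(
    species = sp,
    gains = vapply(sp, function(s)
      sum(perSite$event == "gain" & perSite$simplified == s), 0L),
    losses = vapply(sp, function(s)
      sum(perSite$event == "loss" & perSite$simplified == s), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  lossCount <- table(perSite$site_id[perSite$event == "loss"])
  new("EventMap", branches = branches, perSite = perSite,
      speciesTotals = speciesTotals,
      multiLossSites = sort(names(lossCount)[lossCount > 1]),
      skippedSites = sort(assignResult$skipped %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname accessors
#' @export
setMethod("eventTable", "EventMap", function(x, ...) x@perSite)

#' @rdname accessors
#' @export
setMethod("branchTotals", "EventMap", function(x, ...) x@branches)

setMethod("show", "EventMap", function(object) {
  cat(sprintf("EventMap: %d gains, %d losses over %d branches; %d site(s) lost more than once, %d skipped\n",
              sum(object@branches$gains), sum(object@branches$losses),
              nrow(object@branches), length(object@multiLossSites),
              length(object@skippedSites)))
})
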