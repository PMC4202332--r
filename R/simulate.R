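# Dollo-style intron evolution along a yeast species tree with a WGD.
# Per gene, locus retention after the WGD is drawn first (at least one
# locus survives); the intron character then evolves on the observable
# locus tree: presence at the root (or a single gain on a random branch),
# irreversible per-branch loss, each realized loss carrying a type drawn
# from the perfect/imperfect/unknown mixture.  Branch events are recorded
# both raw and in canonical (minimal Dollo) form, because sibling losses
# merge and gains slide to the MRCA of the surviving tips in any
# reconstruction from tip states.

#' Create a SimConfig
#'
#' Defaults describe a Saccharomycetaceae-like regime: introns almost all
#' ancestral, gains rare, per-branch loss around 5\%, loss types mixed
#' 71\% perfect / 3\% imperfect / 26\% unknown, roughly half of the
#' duplicated loci retained (at least one per gene), a quarter of families
#' ribosomal protein genes whose introns are longer and lost less often,
#' and eight snoRNA-carrying introns.
#'
#' @param nGenes,intronsPerGene,pRootPresent,perBranchLossProb,lossTypeProbs
#'   see \linkS4class{SimConfig}.
#' @param gainRate,pLocusRetained,rpgFraction,rpgLossMultiplier see
#'   \linkS4class{SimConfig}.
#' @param intronLenMeanlog,intronLenSdlog,rpgLenMeanlog,rpgLenSdlog
#'   log-normal intron length parameters (nt), RPG component longer.
#' @param s2Mean,s2Sd,snornaSites,pDeintronized,utrFraction,exonNoise see
#'   \linkS4class{SimConfig}.
#' @param flankExonCodons,junctionMeanLog,junctionSdLog,dispersion,seed see
#'   \linkS4class{SimConfig}.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nGenes = 60L, intronsPerGene = c("1" = 0.9, "2" = 0.1),
                      pRootPresent = 0.97, perBranchLossProb = 0.05,
                      lossTypeProbs = c(perfect = 0.71, imperfect = 0.03,
                                        unknown = 0.26),
                      gainRate = 0.01, pLocusRetained = 0.5,
                      rpgFraction = 0.25, rpgLossMultiplier = 0.35,
                      intronLenMeanlog = log(120), intronLenSdlog = 0.35,
                      rpgLenMeanlog = log(420), rpgLenSdlog = 0.25,
                      s2Mean = 30, s2Sd = 6, snornaSites = 8L,
                      pDeintronized = 0.4, utrFraction = 0.1,
                      exonNoise = 0.05, flankExonCodons = 52L,
                      junctionMeanLog = log(60), junctionSdLog = 1,
                      dispersion = 0.3, seed = 1L) {
  new("SimConfig", nGenes = as.integer(nGenes),
      intronsPerGene = intronsPerGene, pRootPresent = pRootPresent,
      perBranchLossProb = perBranchLossProb, lossTypeProbs = lossTypeProbs,
      gainRate = gainRate, pLocusRetained = pLocusRetained,
      rpgFraction = rpgFraction, rpgLossMultiplier = rpgLossMultiplier,
      intronLenMeanlog = intronLenMeanlog, intronLenSdlog = intronLenSdlog,
      rpgLenMeanlog = rpgLenMeanlog, rpgLenSdlog = rpgLenSdlog,
      s2Mean = s2Mean, s2Sd = s2Sd, snornaSites = as.integer(snornaSites),
      pDeintronized = pDeintronized, utrFraction = utrFraction,
      exonNoise = exonNoise, flankExonCodons = as.integer(flankExonCodons),
      junctionMeanLog = junctionMeanLog, junctionSdLog = junctionSdLog,
      dispersion = dispersion, seed = as.integer(seed))
}

#' The 20-taxon Saccharomycetaceae fixture tree
#'
#' YGOB-style topology for the 20 Saccharomycetaceae used throughout:
#' 12 post-WGD species (Vpol, Tpha, Tbla, Ndai, Ncas, Knag, Kafr, Cgla,
#' Suva, Skud, Smik, Scer) under the tagged WGD node, the
#' Zygosaccharomyces/Torulaspora pair as its sister group, and the
#' Kluyveromyces/Eremothecium/Lachancea species outside.
#'
#' @return a \linkS4class{SpeciesTree} with 20 tips and a tagged WGD node.
#' @export
makeDefaultTree <- function() {
  path <- system.file("extdata", "saccharomycetaceae_20taxa.nwk",
                      package = "IntronDollo")
  readNewickTree(path)
}

# Rewrite raw generative events into the canonical minimal Dollo form:
# merge complete sets of sibling losses into one loss on the parent branch,
# and slide the gain down while all but one of its child lineages are lost.
.canonicalizeEvents <- function(phy, gain, lossNodes) {
  kids <- .childrenList(phy)
  nt <- .nTips(phy)
  L <- lossNodes
  repeat {
    changed <- FALSE
    for (v in (nt + 1):(nt + phy$Nnode)) {
      kv <- kids[[v]]
      if (v != gain && !(v %in% L) && length(kv) > 0 && all(kv %in% L)) {
        L <- c(setdiff(L, kv), v)
        changed <- TRUE
      }
    }
    if (gain > nt) {
      kg <- kids[[gain]]
      lost <- intersect(kg, L)
      if (length(lost) >= 1 && length(kg) - length(lost) == 1) {
        L <- setdiff(L, lost)
        gain <- setdiff(kg, lost)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(gain = gain, lossNodes = sort(L))
}

# Simulate one site on its observable tree; returns tip presence, raw and
# canonical events.  `p` is the per-branch loss probability.
.simulateSite <- function(phy, p, pRootPresent, gainRate) {
  nt <- .nTips(phy)
  root <- .rootNode(phy)
  labels <- .nodeLabels(phy)
  if (runif(1) < pRootPresent) {
    gain <- root
  } else if (runif(1) < gainRate) {
    gain <- sample(setdiff(seq_len(nt + phy$Nnode), root), 1)
  } else {
    return(NULL)                        # no intron ever existed at this site
  }
  kids <- .childrenList(phy)
  rawLoss <- integer(0)
  presentTips <- logical(nt)
  walk <- function(v) {
    if (v <= nt) { presentTips[v] <<- TRUE; return(invisible()) }
    for (ch in kids[[v]]) {
      if (runif(1) < p) rawLoss[length(rawLoss) + 1] <<- ch
      else walk(ch)
    }
  }
  if (gain <= nt) presentTips[gain] <- TRUE else walk(gain)
  out <- list(observable = any(presentTips),
              present = setNames(presentTips, phy$tip.label),
              gain = gain, rawLoss = rawLoss,
              gainLabel = if (gain != root) labels[gain] else NA_character_,
              rawLossLabels = labels[rawLoss])
  if (out$observable) {
    canon <- .canonicalizeEvents(phy, gain, rawLoss)
    out$canonGain <- canon$gain
    out$canonLoss <- canon$lossNodes
    out$canonGainLabel <- if (canon$gain != root) labels[canon$gain]
                          else NA_character_
    out$canonLossLabels <- labels[canon$lossNodes]
  }
  out
}

.sampleLossType <- function(probs) {
  sample(c("perfect", "imperfect", "unknown"), 1, prob = probs)
}

# Codon / nucleotide indel for a loss event.  Perfect: |k| <= 2 codons;
# imperfect: 3..40 codons, random sign; unknown: a frameshifting insertion
# of 4..20 nt (not a multiple of 3).
.sampleIndel <- function(type) {
  if (type == "perfect") {
    k <- sample(-2:2, 1)
    list(k = k, kNt = 3L * k)
  } else if (type == "imperfect") {
    k <- sample(3:40, 1) * sample(c(-1L, 1L), 1)
    list(k = k, kNt = 3L * k)
  } else {
    nt <- sample(setdiff(4:20, seq(6, 18, by = 3)), 1)
    list(k = NA_integer_, kNt = as.integer(nt))
  }
}

#' Simulate intron evolution with ground truth
#'
#' @param tree a \linkS4class{SpeciesTree} with a tagged WGD node.
#' @param config a \linkS4class{SimConfig}.
#' @param spliceCfg a \linkS4class{SpliceConfig}; bounds intron lengths and
#'   S2 draws.
#' @return a \linkS4class{TruthTable}.
#' @export
simulateIntronEvolution <- function(tree, config = simConfig(),
                                    spliceCfg = spliceConfig()) {
  methods::validObject(config)
  set.seed(config@seed)
  etree <- locusTree(tree)
  ephy <- etree@phy
  cols <- .lociForTree(tree)
  colInfo <- .splitRowName(cols)
  post <- postWgdSpecies(tree)

  tipsA <- grep("\\|A$", ephy$tip.label, value = TRUE)
  tipsB <- grep("\\|B$", ephy$tip.label, value = TRUE)
  phyBoth <- ephy
  phyA <- if (length(tipsB) > 0)
    ape::drop.tip(ephy, tipsB, collapse.singles = TRUE) else ephy
  phyB <- if (length(tipsA) > 0)
    ape::drop.tip(ephy, tipsA, collapse.singles = TRUE) else ephy

  nG <- config@nGenes
  genes <- data.frame(
    family = sprintf("fam%04d", seq_len(nG)),
    rpg = runif(nG) < config@rpgFraction,
    nIntrons = as.integer(sample(names(config@intronsPerGene), nG,
                                 replace = TRUE,
                                 prob = config@intronsPerGene)),
    retA = runif(nG) < config@pLocusRetained,
    retB = runif(nG) < config@pLocusRetained,
    stringsAsFactors = FALSE)
  neither <- !genes$retA & !genes$retB
  if (any(neither)) {                   # force at least one surviving locus
    pickA <- runif(sum(neither)) < 0.5
    genes$retA[neither] <- pickA
    genes$retB[neither] <- !pickA
  }

  siteRows <- list()
  for (g in seq_len(nG)) {
    for (j in seq_len(genes$nIntrons[g])) {
      siteRows[[length(siteRows) + 1]] <- data.frame(
        site_id = sprintf("%s_i%d", genes$family[g], j),
        family = genes$family[g], intron_index = j,
        rpg = genes$rpg[g], stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, siteRows)
  sites$utr5 <- sites$intron_index == 1 & runif(nrow(sites)) < config@utrFraction

  nS <- nrow(sites)
  mk <- function(x) matrix(x, nrow = nS, ncol = length(cols),
                           dimnames = list(sites$site_id, cols))
  states <- mk(NA_character_)
  kMat <- mk(NA_integer_)
  kNtMat <- mk(NA_integer_)
  lenMat <- mk(NA_real_)
  s2Mat <- mk(NA_real_)
  bpMat <- mk(NA_real_)
  snoMat <- mk(FALSE)
  observable <- logical(nS)
  events <- list(); rawEvents <- list()

  s2MeanOf <- function(sp) {
    if (length(config@s2Mean) == 1) unname(config@s2Mean)
    else unname(config@s2Mean[sp])
  }

  for (i in seq_len(nS)) {
    g <- match(sites$family[i], genes$family)
    retA <- genes$retA[g]; retB <- genes$retB[g]
    phy <- if (retA && retB) phyBoth else if (retA) phyA else phyB
    # fill gene-absent loci
    for (ci in seq_along(cols)) {
      loc <- colInfo$locus[ci]
      if ((loc == "A" && !retA) || (loc == "B" && !retB))
        states[i, ci] <- .STATE_GENE_ABSENT
    }
    p <- config@perBranchLossProb *
      if (sites$rpg[i]) config@rpgLossMultiplier else 1
    sim <- .simulateSite(phy, p, config@pRootPresent, config@gainRate)
    if (is.null(sim)) {                # never gained: not an intron site
      observable[i] <- FALSE
      next
    }
    # raw generative events are recorded even when every carrier was
    # subsequently lost (the site is then unobservable downstream)
    if (!is.na(sim$gainLabel))
      rawEvents[[length(rawEvents) + 1]] <- data.frame(
        site_id = sites$site_id[i], branch = sim$gainLabel, event = "gain",
        stringsAsFactors = FALSE)
    for (b in sim$rawLossLabels)
      rawEvents[[length(rawEvents) + 1]] <- data.frame(
        site_id = sites$site_id[i], branch = b, event = "loss",
        stringsAsFactors = FALSE)
    if (!sim$observable) {
      observable[i] <- FALSE
      next
    }
    observable[i] <- TRUE
    # states from raw events: tips under a loss event share its signature
    lossInfo <- lapply(sim$rawLoss, function(nd) {
      type <- .sampleLossType(config@lossTypeProbs)
      c(list(node = nd, type = type,
             tips = .cladeTips(phy, nd)), .sampleIndel(type))
    })
    for (tip in names(sim$present)) {
      ci <- match(.columnForTip(tip), cols)
      states[i, ci] <- if (sim$present[tip]) .STATE_PRESENT else NA_character_
    }
    for (li in lossInfo) {
      for (tip in li$tips) {
        ci <- match(.columnForTip(tip), cols)
        states[i, ci] <- paste0("lost_", li$type)
        kMat[i, ci] <- li$k
        kNtMat[i, ci] <- li$kNt
      }
    }
    # unobservable-but-not-simulated cells (tip absent from this gene tree
    # without a gene_absent mark) arise when the gain clade excludes them:
    # those lineages never carried the intron; downstream they are losses
    # only if inside the gain clade, otherwise simply "no intron" tips.
    missing <- is.na(states[i, ])
    if (any(missing)) {
      # tips outside the gain clade: intron never present there; the
      # alignment shows an intact exon junction -> perfect-loss signature
      # is wrong, so mark them lost_unknown?  No: a site gained on one
      # lineage shows, at all other loci, an uninterrupted exon: net indel
      # zero.  The classifier will call that lost_perfect (k = 0); the
      # truth therefore records the same, with k = 0.
      states[i, missing] <- .STATE_LOST_PERFECT
      kMat[i, missing] <- 0L
      kNtMat[i, missing] <- 0L
    }
    # intron measurements for present cells
    for (ci in which(states[i, ] == .STATE_PRESENT)) {
      sp <- colInfo$species[ci]
      s2 <- round(rnorm(1, s2MeanOf(sp), config@s2Sd))
      s2 <- max(max(spliceCfg@minS2, 4), min(s2, 120))
      len <- if (sites$rpg[i])
        rlnorm(1, config@rpgLenMeanlog, config@rpgLenSdlog)
      else rlnorm(1, config@intronLenMeanlog, config@intronLenSdlog)
      len <- round(min(max(len, spliceCfg@minIntronLen),
                       spliceCfg@maxIntronLen))
      len <- max(len, 13 + s2 + 2)
      lenMat[i, ci] <- len
      s2Mat[i, ci] <- s2
      bpMat[i, ci] <- len - 7 - s2
    }
    # events
    if (!is.na(sim$canonGainLabel))
      events[[length(events) + 1]] <- data.frame(
        site_id = sites$site_id[i], branch = sim$canonGainLabel,
        event = "gain", stringsAsFactors = FALSE)
    for (b in sim$canonLossLabels)
      events[[length(events) + 1]] <- data.frame(
        site_id = sites$site_id[i], branch = b, event = "loss",
        stringsAsFactors = FALSE)
  }

  # snoRNA-carrying introns: pick among observable sites; override their
  # intron lengths so a 90-nt snoRNA fits between 5'ss and branch point
  snoIds <- character(0)
  obsIdx <- which(observable)
  if (config@snornaSites > 0 && length(obsIdx) > 0) {
    pick <- sample(obsIdx, min(config@snornaSites, length(obsIdx)))
    snoIds <- sites$site_id[pick]
    for (i in pick) {
      for (ci in which(states[i, ] == .STATE_PRESENT)) {
        s2 <- s2Mat[i, ci]
        lenMat[i, ci] <- 13 + s2 + 120   # fixed 120-nt 5' spacer
        bpMat[i, ci] <- lenMat[i, ci] - 7 - s2
        snoMat[i, ci] <- TRUE
      }
      # deintronized survival where the host gene is absent
      for (ci in which(states[i, ] == .STATE_GENE_ABSENT))
        snoMat[i, ci] <- runif(1) < config@pDeintronized
    }
  }
  sites$snorna <- ifelse(sites$site_id %in% snoIds,
                         sprintf("sno%02d", match(sites$site_id, snoIds)),
                         NA_character_)
  sites$observable <- observable

  evDf <- if (length(events) > 0) do.call(rbind, events)
          else data.frame(site_id = character(0), branch = character(0),
                          event = character(0), stringsAsFactors = FALSE)
  rawDf <- if (length(rawEvents) > 0) do.call(rbind, rawEvents)
           else evDf[0, ]

  si <- sites[, c("site_id", "family", "utr5", "rpg", "snorna", "observable")]
  rownames(si) <- NULL
  tt <- new("TruthTable", states = states, k = kMat, kNt = kNtMat,
            siteInfo = si, events = evDf, rawEvents = rawDf,
            intronLen = lenMat, s2 = s2Mat, bpPos = bpMat,
            snoPresence = snoMat, tree = tree, etree = etree,
            config = config, genes = genes)
  tt
}

#' Truth states in the observed vocabulary
#'
#' Maps \code{gene_absent} (and cells of unobservable sites) to
#' \code{no_data}, i.e. what a perfect classifier sees.
#'
#' @param truth a \linkS4class{TruthTable}.
#' @param observableOnly drop sites with no present tip (default TRUE).
#' @return character matrix of pipeline-vocabulary states.
#' @export
truthObservedStates <- function(truth, observableOnly = TRUE) {
  s <- truth@states
  s[s == .STATE_GENE_ABSENT | is.na(s)] <- .STATE_NO_DATA
  if (observableOnly) s <- s[truth@siteInfo$observable, , drop = FALSE]
  s
}

#' @rdname accessors
#' @export
setMethod("states", "TruthTable", function(x, ...) x@states)

#' @rdname accessors
#' @export
setMethod("siteInfo", "TruthTable", function(x, ...) x@siteInfo)

#' @rdname accessors
#' @export
setMethod("eventTable", "TruthTable", function(x, ...) x@events)

setMethod("show", "TruthTable", function(object) {
  cat(sprintf("TruthTable: %d sites (%d observable) x %d species|locus columns; %d canonical events\n",
              nrow(object@states), sum(object@siteInfo$observable),
              ncol(object@states), nrow(object@events)))
})
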