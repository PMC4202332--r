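# Shared fixtures: small trees and a cached noise-free simulation on the
# 20-taxon tree so several test files can reuse one pipeline run.

fixtureTree <- function() makeDefaultTree()

cherryTree <- function() speciesTree(ape::read.tree(text = "(A,B)root;"))

fiveTipTree <- function() {
  speciesTree(ape::read.tree(text = "((A,B)n1,(C,(D,E)n3)n2)root;"),
              wgdLabel = NA)
}

# A perfect yeast intron of given length and S2 under the default grammar.
makeIntronSeq <- function(len = 80, s2 = 27) {
  sp1 <- len - 13 - s2
  paste0("GTATGT", strrep("T", sp1), "TACTAAC", strrep("T", s2 - 2), "AG")
}

.simCache <- new.env(parent = emptyenv())

# Noise-free 60-gene simulation + emission + classification on the fixture
# tree, computed once per test run.
cachedRun <- function() {
  if (!is.null(.simCache$run)) return(.simCache$run)
  tree <- fixtureTree()
  et <- expandWgdTree(tree)
  cfg <- simConfig(nGenes = 60, exonNoise = 0, dispersion = 0, seed = 19)
  tt <- simulateIntronEvolution(tree, cfg)
  alns <- emitGeneAlignments(tt)
  pil <- truthPillar(tt)
  sm <- buildStateMatrix(alns, pil)
  ar <- assignEvents(sm, et)
  em <- summarizeEvents(ar, et)
  .simCache$run <- list(tree = tree, et = et, cfg = cfg, tt = tt,
                        alns = alns, pil = pil, sm = sm, ar = ar, em = em)
  .simCache$run
}

eventKey <- function(d) sort(paste(d$site_id, d$branch, d$event))
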