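test_that("expandWgdTree duplicates the post-WGD clade into A/B loci", {
  tr <- fixtureTree()
  et <- expandWgdTree(tr)
  phy <- treePhylo(et)
  expect_length(phy$tip.label, 32)       # 8 pre-WGD + 2 x 12 post-WGD
  expect_setequal(grep("\\|A$", phy$tip.label, value = TRUE),
                  paste0(postWgdSpecies(tr), "|A"))
  bm <- branchMap(et)
  # collapsing through the branch map recovers the original branch set
  orig <- setdiff(c(treePhylo(tr)$tip.label, treePhylo(tr)$node.label),
                  "n1")
  expect_setequal(unique(bm$simplified), orig)
  # every post-WGD branch appears once per locus, pre-WGD branches once;
  # the WGD branch itself gathers three (its own plus both copy roots)
  tab <- table(bm$simplified)
  expect_true(all(tab[names(tab) != "WGD"] %in% c(1, 2)))
  expect_equal(unname(tab["WGD"]), 3)
  expect_equal(unname(tab["Scer"]), 2)
  expect_equal(unname(tab["Zrou"]), 1)
  # the copy-root branches fold onto the branch subtending the WGD node
  expect_setequal(bm$simplified[bm$branch %in% c("WGD|A", "WGD|B")], "WGD")

  # WGD at a cherry: 2 post-WGD tips become 4 locus tips
  small <- speciesTree(ape::read.tree(text = "((A,B)WGD,C)r;"))
  expect_length(treePhylo(expandWgdTree(small))$tip.label, 5)
  expect_error(expandWgdTree(speciesTree(ape::read.tree(text = "(A,(B,C));"))),
               class = "input_error")
})

test_that("dolloAssign places the gain at the MRCA and one loss per absent clade", {
  tr <- fiveTipTree()
  phy <- treePhylo(tr)
  pres <- function(x) setNames(phy$tip.label %in% x, phy$tip.label)
  # all present: root presence, no events
  a <- dolloAssign(phy, pres(c("A", "B", "C", "D", "E")))
  expect_false(a$gainIsEvent)
  expect_length(a$lossBranches, 0)
  # single present tip: terminal gain, no losses (the MCR1/MTR2 pattern)
  a1 <- dolloAssign(phy, pres("D"))
  expect_true(a1$gainIsEvent)
  expect_equal(a1$gainBranch, "D")
  expect_length(a1$lossBranches, 0)
  # A,B,D present; C,E absent: root presence, losses on C and E
  a2 <- dolloAssign(phy, pres(c("A", "B", "D")))
  expect_false(a2$gainIsEvent)
  expect_equal(a2$lossBranches, c("C", "E"))
  expect_equal(a2$nEvents, dolloOracle(phy, pres(c("A", "B", "D"))))
  # losses lie strictly inside the gain clade
  a3 <- dolloAssign(phy, pres(c("D", "E")))
  expect_true(a3$gainIsEvent)
  expect_equal(a3$gainBranch, "n3")
  expect_length(a3$lossBranches, 0)
  expect_error(dolloAssign(phy, pres(character(0))), class = "input_error")
})

test_that("dolloAssign equals the exhaustive oracle on random instances", {
  set.seed(4711)
  for (i in 1:300) {
    n <- sample(4:14, 1)
    phy <- treePhylo(speciesTree(ape::rtree(n), wgdLabel = NA))
    pres <- setNames(runif(n) < runif(1, 0.2, 0.8), phy$tip.label)
    if (!any(pres)) pres[sample(n, 1)] <- TRUE
    a <- dolloAssign(phy, pres)
    expect_equal(a$nEvents, dolloOracle(phy, pres))
    # minimality certificate: every loss branch subtends an absent clade
    # whose parent lineage is present-implied (removing it would imply a
    # present tip below it)
    for (b in a$lossBranches) {
      node <- match(b, c(phy$tip.label, phy$node.label))
      below <- if (node <= n) b else IntronDollo:::.cladeTips(phy, node)
      expect_false(any(pres[below]))
    }
  }
  # hand-countable: alternating pattern on a 6-tip caterpillar
  cat6 <- treePhylo(speciesTree(
    ape::read.tree(text = "(((((t1,t2),t3),t4),t5),t6);"), wgdLabel = NA))
  pres <- setNames(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                   paste0("t", 1:6))
  a <- dolloAssign(cat6, pres)
  expect_equal(a$nEvents, 3)
  expect_equal(dolloOracle(cat6, pres), 3)
  expect_error(dolloOracle(treePhylo(speciesTree(ape::rtree(15),
                                                 wgdLabel = NA)),
                           setNames(rep(TRUE, 15), ape::rtree(15)$tip.label)),
               class = "input_error")
})

test_that("pruneForSite removes no-data tips and keeps branch labels", {
  tr <- fixtureTree()
  et <- expandWgdTree(tr)
  cols <- colnames(states(cachedRun()$sm))
  st <- setNames(rep("present", length(cols)), cols)
  pr <- pruneForSite(et, st)
  expect_length(pr$phy$tip.label, 32)    # all data: identity
  st2 <- st; st2["Scer|A"] <- "no_data"
  pr2 <- pruneForSite(et, st2)
  expect_length(pr2$phy$tip.label, 31)
  expect_false("Scer|A" %in% pr2$phy$tip.label)
  st3 <- st; st3[] <- "lost_perfect"
  expect_warning(expect_null(pruneForSite(et, st3)), "no present tip")
  # simulator gene-absent loci prune to exactly the retained tips
  run <- cachedRun()
  tt <- run$tt
  halfGene <- run$tt@genes$family[!run$tt@genes$retB][1]
  site <- tt@siteInfo$site_id[tt@siteInfo$family == halfGene &
                              tt@siteInfo$observable][1]
  if (!is.na(site)) {
    pr3 <- pruneForSite(et, truthObservedStates(tt, FALSE)[site, ])
    expect_false(any(grepl("\\|B$", pr3$phy$tip.label)))
  }
})

test_that("gain overrides convert gains into alternative losses and invert", {
  tr <- speciesTree(ape::read.tree(text = "((A,B)n1,(C,D)n2)r;"),
                    wgdLabel = NA)
  phy <- treePhylo(tr)
  pres <- setNames(c(TRUE, FALSE, FALSE, FALSE), c("A", "B", "C", "D"))
  a <- dolloAssign(phy, pres)
  expect_true(a$gainIsEvent)
  b <- dolloAssign(phy, pres, assumeRootPresence = TRUE)
  expect_false(b$gainIsEvent)
  expect_setequal(b$lossBranches, c("B", "n2"))   # covers 3 tips, <= 2 losses
  expect_lte(length(b$lossBranches), 2)

  # via the assignment pipeline on simulated data
  run <- cachedRun()
  gains <- run$em@perSite[run$em@perSite$event == "gain", ]
  ar2 <- applyOverrides(run$ar, gains$site_id)
  em2 <- summarizeEvents(ar2, run$et)
  expect_equal(sum(em2@branches$gains), 0)
  expect_gte(sum(em2@branches$losses), sum(run$em@branches$losses))
  # empty override list is the identity
  ar3 <- applyOverrides(run$ar, character(0))
  expect_identical(summarizeEvents(ar3, run$et)@perSite, run$em@perSite)
  # re-running the assignment undoes the override
  ar4 <- assignEvents(run$sm, run$et)
  expect_identical(summarizeEvents(ar4, run$et)@perSite, run$em@perSite)
  # overriding a root-presence site warns and is a no-op
  rootSites <- names(run$ar$assignments)[!vapply(run$ar$assignments,
                                                 `[[`, TRUE, "gainIsEvent")]
  expect_warning(applyOverrides(run$ar, rootSites[1]), "no-op")
})

test_that("summarizeEvents folds A/B locus branches onto the simplified tree", {
  run <- cachedRun()
  em <- run$em
  ps <- eventTable(em)
  # summation conservation
  expect_equal(sum(branchTotals(em)$losses), sum(ps$event == "loss"))
  expect_equal(sum(branchTotals(em)$gains), sum(ps$event == "gain"))
  # locus branches project to their species branch
  onScer <- ps[ps$simplified == "Scer" & ps$event == "loss", ]
  st <- em@speciesTotals
  expect_equal(st$losses[st$species == "Scer"], nrow(onScer))
  if (nrow(onScer) > 0)
    expect_true(all(onScer$branch %in% c("Scer|A", "Scer|B", "Scer")))
  # multi-loss bookkeeping
  lossPerSite <- table(ps$site_id[ps$event == "loss"])
  expect_setequal(em@multiLossSites, names(lossPerSite)[lossPerSite > 1])
})

test_that("a full chain at loss probability 0.1 recovers the loss totals", {
  tr <- fixtureTree()
  et <- expandWgdTree(tr)
  cfg <- simConfig(nGenes = 250, intronsPerGene = c("1" = 1),
                   pRootPresent = 1, gainRate = 0, perBranchLossProb = 0.1,
                   rpgFraction = 0, snornaSites = 0, utrFraction = 0,
                   exonNoise = 0, seed = 55)
  tt <- simulateIntronEvolution(tr, cfg)
  sm <- buildStateMatrix(emitGeneAlignments(tt), truthPillar(tt))
  em <- summarizeEvents(assignEvents(sm, et), et)
  recovered <- sum(branchTotals(em)$losses)
  # exact agreement with the canonical truth
  expect_equal(recovered, sum(eventTable(tt)$event == "loss"))
  # and within 3 SD of the analytic expectation of raw losses: presence
  # probability recursion down the observable tree, summed over branches
  expectedPerTree <- function(phy) {
    parent <- IntronDollo:::.parentVec(phy)
    root <- IntronDollo:::.rootNode(phy)
    n <- length(phy$tip.label) + phy$Nnode
    pPres <- numeric(n); pPres[root] <- 1
    mu <- 0; v <- 0
    for (e in rev(ape::postorder(phy))) {
      ch <- phy$edge[e, 2]
      pLoss <- pPres[phy$edge[e, 1]] * 0.1
      mu <- mu + pLoss
      v <- v + pLoss * (1 - pLoss)
      pPres[ch] <- pPres[phy$edge[e, 1]] * 0.9
    }
    c(mu, v)
  }
  g <- tt@genes
  phys <- list(both = treePhylo(et),
               A = ape::drop.tip(treePhylo(et),
                                 grep("\\|B$", treePhylo(et)$tip.label,
                                      value = TRUE)),
               B = ape::drop.tip(treePhylo(et),
                                 grep("\\|A$", treePhylo(et)$tip.label,
                                      value = TRUE)))
  ev <- vapply(seq_len(nrow(g)), function(i) {
    key <- if (g$retA[i] && g$retB[i]) "both" else if (g$retA[i]) "A" else "B"
    expectedPerTree(phys[[key]])
  }, c(0, 0))
  rawTotal <- sum(tt@rawEvents$event == "loss")
  expect_lt(abs(rawTotal - sum(ev[1, ])), 3 * sqrt(sum(ev[2, ])))
})
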