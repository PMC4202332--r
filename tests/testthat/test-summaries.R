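test_that("speciesLossTable proportions hit the 0% and 100% bounds", {
  mk <- function(states) {
    dn <- list(c("s1", "s2"), c("X|0", "Y|0"))
    new("StateMatrix",
        states = matrix(states, 2, 2, dimnames = dn),
        k = matrix(NA_integer_, 2, 2, dimnames = dn),
        notes = matrix("", 2, 2, dimnames = dn),
        siteInfo = data.frame(site_id = c("s1", "s2"),
                              family = c("f1", "f2"), utr5 = FALSE,
                              rpg = FALSE, snorna = NA_character_))
  }
  emEmpty <- new("EventMap",
                 branches = data.frame(branch = c("X", "Y"), gains = 0L,
                                       losses = 0L),
                 perSite = data.frame(site_id = character(0),
                                      branch = character(0),
                                      simplified = character(0),
                                      locus = character(0),
                                      event = character(0)),
                 speciesTotals = data.frame(species = c("X", "Y"),
                                            gains = 0L, losses = 0L),
                 multiLossSites = character(0), skippedSites = character(0))
  allPresent <- mk(rep("present", 4))
  tab <- speciesLossTable(allPresent, emEmpty)
  expect_equal(tab$prop_genes_with_loss, c(0, 0))
  lossy <- mk(c("present", "present", "lost_perfect", "lost_unknown"))
  tab2 <- speciesLossTable(lossy, emEmpty)
  expect_equal(tab2$prop_genes_with_loss[tab2$species == "Y"], 1)
  expect_equal(tab2$introns_found[tab2$species == "X"], 2)
})

test_that("speciesLossTable agrees with truth-derived values and ignores site order", {
  run <- cachedRun()
  tab <- speciesLossTable(run$sm, run$em)
  # truth-derived proportions
  ts <- truthObservedStates(run$tt)
  fam <- run$tt@siteInfo$family[run$tt@siteInfo$observable]
  for (sp in c("Scer", "Cgla", "Zrou")) {
    sub <- ts[, grep(paste0("^", sp, "\\|"), colnames(ts)), drop = FALSE]
    def <- tapply(seq_len(nrow(sub)), fam,
                  function(ix) any(sub[ix, ] != "no_data"))
    lost <- tapply(seq_len(nrow(sub)), fam, function(ix)
      any(sub[ix, ] %in% c("lost_perfect", "lost_imperfect",
                           "lost_unknown")))
    expect_equal(tab$prop_genes_with_loss[tab$species == sp],
                 sum(def & lost) / sum(def))
  }
  # invariance to site order
  perm <- sample(nrow(states(run$sm)))
  smPerm <- new("StateMatrix", states = states(run$sm)[perm, ],
                k = codonIndels(run$sm)[perm, ],
                notes = run$sm@notes[perm, ],
                siteInfo = siteInfo(run$sm)[perm, ])
  tabPerm <- speciesLossTable(smPerm, run$em)
  expect_equal(tabPerm[order(tabPerm$species), ],
               tab[order(tab$species), ], ignore_attr = TRUE)
})

test_that("snoRNA fate categories are exhaustive, exclusive, and match the flag rules", {
  cats <- c("BOTH_RETAINED", "ONE_COPY_RETAINED_WITH_SNORNA",
            "INTRON_LOST_SNORNA_IN_PARALOG_INTRON", "DEINTRONIZED",
            "SNORNA_REMOVED")
  grid <- expand.grid(gA = c(TRUE, FALSE), iA = c(TRUE, FALSE),
                      sA = c(TRUE, FALSE), gB = c(TRUE, FALSE),
                      iB = c(TRUE, FALSE), sB = c(TRUE, FALSE))
  got <- apply(grid, 1, function(r)
    IntronDollo:::.snoFateCategory(r["gA"], r["iA"], r["sA"],
                                   r["gB"], r["iB"], r["sB"]))
  expect_true(all(got %in% cats))        # exhaustive over all 2^6 combos
  expect_length(got, 64)
  # the three canonical post-duplication outcomes
  expect_equal(IntronDollo:::.snoFateCategory(TRUE, TRUE, TRUE,
                                              FALSE, FALSE, FALSE),
               "ONE_COPY_RETAINED_WITH_SNORNA")
  expect_equal(IntronDollo:::.snoFateCategory(TRUE, FALSE, FALSE,
                                              TRUE, TRUE, TRUE),
               "INTRON_LOST_SNORNA_IN_PARALOG_INTRON")
  expect_equal(IntronDollo:::.snoFateCategory(TRUE, FALSE, FALSE,
                                              FALSE, FALSE, TRUE),
               "DEINTRONIZED")
  expect_equal(IntronDollo:::.snoFateCategory(TRUE, TRUE, TRUE,
                                              TRUE, TRUE, TRUE),
               "BOTH_RETAINED")
  expect_equal(IntronDollo:::.snoFateCategory(TRUE, FALSE, FALSE,
                                              TRUE, FALSE, FALSE),
               "SNORNA_REMOVED")
})

test_that("snornaFates classifies simulated sites from alignment flags", {
  run <- cachedRun()
  sno <- snoPresenceFromAlignments(run$alns, run$sm)
  res <- snornaFates(run$sm, sno, run$pil, run$tree)
  post <- postWgdSpecies(run$tree)
  snoSites <- siteInfo(run$sm)$site_id[!is.na(siteInfo(run$sm)$snorna)]
  expect_equal(nrow(res$fates), length(snoSites) * length(post))
  expect_equal(sum(res$counts), nrow(res$fates))
  # cross-check one deintronized cell against truth flags
  tt <- run$tt
  dei <- which(tt@snoPresence & tt@states == "gene_absent", arr.ind = TRUE)
  dei <- dei[rownames(tt@states)[dei[, 1]] %in% snoSites, , drop = FALSE]
  if (nrow(dei) > 0) {
    site <- rownames(tt@states)[dei[1, 1]]
    sp <- IntronDollo:::.splitRowName(colnames(tt@states)[dei[1, 2]])$species
    expect_equal(res$fates$category[res$fates$site_id == site &
                                    res$fates$species == sp],
                 "DEINTRONIZED")
  }
})

test_that("rpgStats separates loss rates and calls bimodality correctly", {
  run <- cachedRun()
  lens <- intronLengthsFromAlignments(run$alns, run$sm)
  # lengths measured from alignments equal the simulated truth
  ts <- truthObservedStates(run$tt)
  common <- rownames(ts)
  expect_equal(lens[common, ], run$tt@intronLen[common, ])
  st <- rpgStats(run$sm, run$em, lens)
  expect_equal(st$ancestralRpgIntrons, sum(siteInfo(run$sm)$rpg))
  # RPG sites lose introns at a reduced rate (rpgLossMultiplier < 1)
  expect_lt(st$rpgLossRate, st$otherLossRate)
  expect_true(all(st$lengths$length > 0))

  # bimodality verdicts on constructed samples
  dn <- list("s1", paste0("sp", 1, "|0"))
  smTiny <- new("StateMatrix",
                states = matrix("present", 1, 1, dimnames = dn),
                k = matrix(NA_integer_, 1, 1, dimnames = dn),
                notes = matrix("", 1, 1, dimnames = dn),
                siteInfo = data.frame(site_id = "s1", family = "f",
                                      utr5 = FALSE, rpg = TRUE,
                                      snorna = NA_character_))
  emTiny <- new("EventMap",
                branches = data.frame(branch = "sp1", gains = 0L,
                                      losses = 0L),
                perSite = data.frame(site_id = character(0),
                                     branch = character(0),
                                     simplified = character(0),
                                     locus = character(0),
                                     event = character(0)),
                speciesTotals = data.frame(species = "sp1", gains = 0L,
                                           losses = 0L),
                multiLossSites = character(0), skippedSites = character(0))
  set.seed(8)
  uni <- matrix(rlnorm(200, log(120), 0.3), 200, 1,
                dimnames = list(paste0("s", 1:200), "sp1|0"))
  bi <- matrix(c(rlnorm(100, log(90), 0.2), rlnorm(100, log(500), 0.2)),
               200, 1, dimnames = dimnames(uni))
  mkSm <- function() {
    dn2 <- dimnames(uni)
    new("StateMatrix",
        states = matrix("present", 200, 1, dimnames = dn2),
        k = matrix(NA_integer_, 200, 1, dimnames = dn2),
        notes = matrix("", 200, 1, dimnames = dn2),
        siteInfo = data.frame(site_id = rownames(uni), family = "f",
                              utr5 = FALSE,
                              rpg = rep(c(TRUE, FALSE), 100),
                              snorna = NA_character_))
  }
  stUni <- rpgStats(mkSm(), emTiny, uni)
  expect_false(stUni$bimodality$bimodal[1])     # the Z. rouxii pattern
  stBi <- rpgStats(mkSm(), emTiny, bi)
  expect_true(stBi$bimodality$bimodal[1])
  # deterministic verdicts
  expect_identical(rpgStats(mkSm(), emTiny, bi)$bimodality,
                   stBi$bimodality)
  noRpg <- mkSm(); noRpg@siteInfo$rpg <- FALSE
  expect_error(rpgStats(noRpg, emTiny, bi), class = "input_error")
})

test_that("heatmap export orders rows by tree with A/B sub-rows and round-trips", {
  run <- cachedRun()
  hm <- heatmapMatrix(run$sm, run$tree)
  expect_equal(sum(grepl("\\|A$|\\|B$", hm$row)),
               2 * length(postWgdSpecies(run$tree)))
  expect_true(all(unlist(hm[, -1]) %in%
                  c("present", "loss_cdna", "loss_indel", "unknown")))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeHeatmap(hm, p)
  expect_equal(readHeatmap(p), hm)
  # tiny all-present example
  dn <- list(c("s1", "s2", "s3"), c("A|0", "B|0"))
  smT <- new("StateMatrix",
             states = matrix("present", 3, 2, dimnames = dn),
             k = matrix(NA_integer_, 3, 2, dimnames = dn),
             notes = matrix("", 3, 2, dimnames = dn),
             siteInfo = data.frame(site_id = dn[[1]], family = "f",
                                   utr5 = FALSE, rpg = FALSE,
                                   snorna = NA_character_))
  trT <- speciesTree(ape::read.tree(text = "(A,B)r;"), wgdLabel = NA)
  hmT <- heatmapMatrix(smT, trT)
  expect_true(all(unlist(hmT[, -1]) == "present"))
})
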