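# Hand-built three-row alignment with one annotated intron site.
# rowP1/rowP2 carry the intron; the third row's state is configurable:
# "perfect" (gapped span, zero net indel), "insert" (k-codon insertion
# block before the intron), "delete" (gaps over the exon tail), "frame"
# (non-multiple-of-3 insertion), or "slid" (valid intron 3 codons into
# the downstream exon instead of at the annotated span).
makeClassifyFixture <- function(third = "perfect", k = 0) {
  set.seed(99)
  # G-free exon sequence: no spurious GTATGT or AG can arise in exons,
  # so sliding detection can only fire on a real displaced intron
  exonL <- paste(sample(c("A", "C", "T"), 90, replace = TRUE),
                 collapse = "")
  exonR <- paste(sample(c("A", "C", "T"), 90, replace = TRUE),
                 collapse = "")
  intron <- makeIntronSeq(60, s2 = 27)
  w <- nchar(intron)
  gap <- function(n) strrep("-", n)
  insBlock <- if (third %in% c("insert", "frame")) {
    nIns <- if (third == "insert") 3 * k else k
    paste(sample(c("A", "C", "G", "T"), nIns, replace = TRUE), collapse = "")
  } else ""
  nIns <- nchar(insBlock)
  rows <- c(
    "sp1|0" = paste0(exonL, gap(nIns), intron, exonR),
    "sp2|0" = paste0(exonL, gap(nIns), intron, exonR))
  third_row <- switch(third,
    perfect = paste0(exonL, gap(nIns), gap(w), exonR),
    insert = paste0(exonL, insBlock, gap(w), exonR),
    frame = paste0(exonL, insBlock, gap(w), exonR),
    delete = paste0(substr(exonL, 1, 90 - 3 * k), gap(3 * k), gap(nIns),
                    gap(w), exonR),
    slid = paste0(exonL, gap(nIns), gap(w), substr(exonR, 1, 9)))
  if (third == "slid") {
    # the slid row resumes exonR after its displaced intron; give the
    # displaced intron its own columns (gaps in the other rows)
    intron2 <- makeIntronSeq(60, s2 = 20)
    rows <- c(rows["sp1|0"], rows["sp2|0"],
              "sp3|0" = paste0(third_row, intron2,
                               substr(exonR, 10, 90)))
    pad <- function(s, at) paste0(substr(s, 1, at), strrep("-", 60),
                                  substr(s, at + 1, nchar(s)))
    at <- 90 + nIns + w + 9
    rows["sp1|0"] <- pad(rows["sp1|0"], at)
    rows["sp2|0"] <- pad(rows["sp2|0"], at)
  } else {
    rows <- c(rows, "sp3|0" = third_row)
  }
  feats <- data.frame(
    site_id = c("s1", "s1", "sc"),
    type = c("intron", "branch_point", "start_codon"),
    start = c(90 + nIns, 90 + nIns + 26, 0),
    end = c(90 + nIns + w, 90 + nIns + 33, 3),
    utr5 = FALSE, rpg = FALSE, snorna = NA_character_,
    present_in = NA_character_, stringsAsFactors = FALSE)
  new("AnnotatedAlignment", family = "famX", seqs = rows, features = feats,
      rpg = FALSE)
}

test_that("intact signals classify as PRESENT, empty spans by net indel", {
  aln <- makeClassifyFixture("perfect")
  expect_equal(classifySiteState(aln, "s1", "sp1|0")$state, "present")
  res <- classifySiteState(aln, "s1", "sp3|0")
  expect_equal(res$state, "lost_perfect")   # the ERD2-style zero-indel loss
  expect_equal(res$k, 0L)
})

test_that("insertions and deletions are classified by codon count", {
  res5 <- classifySiteState(makeClassifyFixture("insert", 5), "s1", "sp3|0")
  expect_equal(res5$state, "lost_imperfect")
  expect_equal(res5$k, 5L)
  res2 <- classifySiteState(makeClassifyFixture("insert", 2), "s1", "sp3|0")
  expect_equal(res2$state, "lost_perfect")
  expect_equal(res2$k, 2L)
  resD <- classifySiteState(makeClassifyFixture("delete", 4), "s1", "sp3|0")
  expect_equal(resD$state, "lost_imperfect")
  expect_equal(resD$k, -4L)
  # beyond the imperfect range
  res50 <- classifySiteState(makeClassifyFixture("insert", 50), "s1", "sp3|0")
  expect_equal(res50$state, "lost_unknown")
})

test_that("frameshifting indels are unknown-mechanism losses", {
  res <- classifySiteState(makeClassifyFixture("frame", 7), "s1", "sp3|0")
  expect_equal(res$state, "lost_unknown")
  expect_match(res$note, "frameshift")
})

test_that("classification is independent of row order and matches truth on simulated data", {
  run <- cachedRun()
  fam <- names(run$alns)[2]
  aln <- run$alns[[fam]]
  perm <- new("AnnotatedAlignment", family = aln@family,
              seqs = rev(aln@seqs), features = aln@features, rpg = aln@rpg)
  site <- aln@features$site_id[aln@features$type == "intron"][1]
  for (r in names(aln@seqs))
    expect_identical(classifySiteState(aln, site, r),
                     classifySiteState(perm, site, r))
  # simulator-emitted imperfect instance round-trips with its known k
  tt <- run$tt
  idx <- which(states(tt) == "lost_imperfect", arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  i <- idx[1, ]
  site <- rownames(states(tt))[i[1]]; cell <- colnames(states(tt))[i[2]]
  fam <- tt@siteInfo$family[tt@siteInfo$site_id == site]
  res <- classifySiteState(run$alns[[fam]], site, cell)
  expect_equal(res$state, "lost_imperfect")
  expect_equal(res$k, tt@k[site, cell])
})

test_that("detectSliding finds a +3-codon slide as a +9 column offset", {
  aln <- makeClassifyFixture("slid")
  rep <- detectSliding(aln, "s1")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$row, "sp3|0")
  expect_equal(rep$offset_cols, 9)
  expect_false(rep$crosses_start_codon)
  # all rows present at the annotated span: empty report
  ok <- makeClassifyFixture("perfect")
  ok@seqs["sp3|0"] <- ok@seqs["sp1|0"]
  expect_equal(nrow(detectSliding(ok, "s1")), 0)
  # a shifted 5'ss motif without a branch point is not a valid intron
  broken <- makeClassifyFixture("slid")
  broken@seqs["sp3|0"] <- gsub("TACTAAC", "TTTTTTT", broken@seqs["sp3|0"])
  expect_equal(nrow(detectSliding(broken, "s1")), 0)
})

test_that("buildStateMatrix lays out sites by pillar columns", {
  run <- cachedRun()
  sm <- run$sm
  expect_true(all(colnames(states(sm)) == colnames(pillarEntries(run$pil))))
  # post-WGD species contribute two columns
  expect_true(all(c("Scer|A", "Scer|B") %in% colnames(states(sm))))
  expect_true("Zrou|0" %in% colnames(states(sm)))
  # every cell filled; sites all carry at least one present call
  expect_false(any(is.na(states(sm))))
  expect_true(all(rowSums(states(sm) == "present") >= 1))
  # pillar/alignment inconsistency is an error naming the family
  pil2 <- pillarEntries(run$pil)
  fam <- siteInfo(sm)$family[1]
  pil2[fam, "Scer|A"] <- "ghost_gene"
  badPil <- new("PillarTable", entries = pil2)
  if (!"Scer|A" %in% names(alignmentRows(run$alns[[fam]])))
    expect_error(buildStateMatrix(run$alns[fam], badPil),
                 class = "validation_error")
})

test_that("noise-free recovery confusion matrix is diagonal", {
  run <- cachedRun()
  ts <- truthObservedStates(run$tt)
  called <- states(run$sm)[rownames(ts), colnames(ts)]
  expect_identical(called, ts)
  kTruth <- run$tt@k[rownames(ts), colnames(ts)]
  kCalled <- codonIndels(run$sm)[rownames(ts), colnames(ts)]
  lost <- ts %in% c("lost_perfect", "lost_imperfect")
  expect_identical(kCalled[lost], kTruth[lost])
})

test_that("tallyStates counts, rates and conservation", {
  run <- cachedRun()
  tl <- tallyStates(run$sm)
  expect_equal(sum(tl$counts), length(states(run$sm)))
  expect_equal(tl$definedCells + tl$counts[["no_data"]],
               length(states(run$sm)))
  expect_equal(tl$missingRate, tl$absentCells / tl$definedCells)
  # constructed example: 10 defined cells, 2 absent
  s <- matrix("present", 2, 5,
              dimnames = list(c("s1", "s2"), paste0("sp", 1:5, "|0")))
  s[1, 1] <- "lost_perfect"; s[2, 2] <- "lost_unknown"
  sm <- new("StateMatrix", states = s,
            k = matrix(NA_integer_, 2, 5, dimnames = dimnames(s)),
            notes = matrix("", 2, 5, dimnames = dimnames(s)),
            siteInfo = data.frame(site_id = c("s1", "s2"), family = "f",
                                  utr5 = FALSE, rpg = FALSE,
                                  snorna = NA_character_))
  tl2 <- tallyStates(sm)
  expect_equal(tl2$missingRate, 0.2)
  expect_equal(tl2$perfectFraction, 0.5)
  # all present: rate 0, perfect fraction undefined
  s[] <- "present"
  sm2 <- new("StateMatrix", states = s, k = sm@k, notes = sm@notes,
             siteInfo = sm@siteInfo)
  tl3 <- tallyStates(sm2)
  expect_equal(tl3$missingRate, 0)
  expect_true(is.na(tl3$perfectFraction))
})
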