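test_that("column classification follows the gap/flank/conservation rules", {
  aln <- Biostrings::AAStringSet(setNames(
    c("AAC", "AAC", "AAC", "AAC", "AAC",
      "AAC", "ACC", "ACC", "ACC", "AC-"), paste0("s", 1:10)))
  cls <- classifyColumns(aln)
  # col 1: unanimous A -> highly conserved; col 2: 6A/4C -> conserved
  # (0.6 > 0.5 but < 0.85); col 3: one gap -> gap
  expect_identical(cls, c("highly_conserved", "conserved", "gap"))

  # 50/50 split is nonconserved under the strict "more than half" rule
  aln2 <- Biostrings::AAStringSet(setNames(rep(c("A", "C"), 5),
                                           paste0("s", 1:10)))
  expect_identical(classifyColumns(aln2), "nonconserved")
})

test_that("block selection reproduces the worked examples", {
  # 20 unanimous columns: everything kept as one block
  aln <- Biostrings::AAStringSet(setNames(rep(strrep("A", 20), 4),
                                          paste0("s", 1:4)))
  mask <- selectBlocks(classifyColumns(aln))
  expect_identical(keptColumns(mask), 0:19)
  expect_identical(unname(as.matrix(blockRanges(mask))[1, ]), c(0L, 20L))

  # a gap column inserted between two runs of 10 unanimous columns:
  # both flanking blocks survive (each exactly the minimum length)
  s <- paste0(strrep("A", 10), "-", strrep("C", 10))
  aln <- Biostrings::AAStringSet(setNames(
    c(s, sub("-", "G", s), sub("-", "G", s), sub("-", "G", s)),
    paste0("s", 1:4)))
  mask <- selectBlocks(classifyColumns(aln))
  expect_identical(keptColumns(mask), c(0:9, 11:20))
  expect_identical(blockRanges(mask)$start, c(0L, 11L))
  expect_identical(blockRanges(mask)$end, c(10L, 21L))

  # a run of 9 nonconserved columns inside a conserved alignment is
  # rejected (> 8 contiguous nonconserved)
  set.seed(60)
  left <- strrep("A", 15); right <- strrep("C", 15)
  mid <- vapply(1:4, function(i) randomProtein(9), character(1))
  aln <- Biostrings::AAStringSet(setNames(paste0(left, mid, right),
                                          paste0("s", 1:4)))
  cls <- classifyColumns(aln)
  if (all(cls[16:24] == "nonconserved")) {
    mask <- selectBlocks(cls)
    expect_identical(keptColumns(mask), c(0:14, 24:38))
  }
})

test_that("block selection agrees with the rule-by-rule oracle", {
  set.seed(314)
  for (i in seq_len(100)) {
    aln <- randomTestAlignment(nSeq = sample(4:15, 1),
                               nCol = sample(20:60, 1))
    params <- blockFilterParams(minBlockLen = sample(c(5L, 10L), 1),
                                maxContigNonconserved = sample(c(4L, 8L), 1))
    cls <- classifyColumns(aln, params)
    got <- keptColumns(selectBlocks(cls, params))
    want <- oracleSelect(cls, params$minBlockLen,
                         params$maxContigNonconserved)
    expect_identical(got, as.integer(want), info = paste("case", i))
  }
})

test_that("filtering a filtered alignment changes nothing", {
  set.seed(2718)
  done <- 0L
  for (i in seq_len(60)) {
    aln <- randomTestAlignment(nSeq = sample(5:12, 1),
                               nCol = sample(30:60, 1))
    f1 <- filterAlignment(aln)
    if (is.null(f1$curated)) next
    done <- done + 1L
    f2 <- filterAlignment(f1$curated)
    expect_identical(as.character(f2$curated), as.character(f1$curated),
                     info = paste("case", i))
  }
  expect_gte(done, 20L)  # enough non-degenerate cases exercised
})

test_that("kept columns shrink as the parameters tighten", {
  set.seed(31415)
  for (i in seq_len(20)) {
    aln <- randomTestAlignment(nSeq = 8, nCol = 50)
    loose <- length(keptColumns(selectBlocks(
      classifyColumns(aln), blockFilterParams(minBlockLen = 5,
                                              maxContigNonconserved = 8))))
    tightNoncons <- length(keptColumns(selectBlocks(
      classifyColumns(aln), blockFilterParams(minBlockLen = 5,
                                              maxContigNonconserved = 4))))
    tightBlock <- length(keptColumns(selectBlocks(
      classifyColumns(aln), blockFilterParams(minBlockLen = 10,
                                              maxContigNonconserved = 8))))
    expect_lte(tightNoncons, loose)
    expect_lte(tightBlock, loose)
  }
})

test_that("mask application subsets columns and rejects degenerate masks", {
  aln <- Biostrings::AAStringSet(c(a = "ACDE", b = "ACDF"))
  full <- methods::new("BlockMask", kept = 0:3,
                       blocks = IRanges::IRanges(1, 4), nColumns = 4L)
  expect_identical(as.character(applyMask(aln, full)),
                   c(a = "ACDE", b = "ACDF"))
  two <- methods::new("BlockMask", kept = 0:1,
                      blocks = IRanges::IRanges(1, 2), nColumns = 4L)
  expect_identical(unname(as.character(applyMask(aln, two))), c("AC", "AC"))
  empty <- methods::new("BlockMask", kept = integer(0),
                        blocks = IRanges::IRanges(), nColumns = 4L)
  expect_error(applyMask(aln, empty), "empty curated alignment")
  oob <- methods::new("BlockMask", kept = c(0L, 7L),
                      blocks = IRanges::IRanges(1, 8), nColumns = 8L)
  expect_error(applyMask(aln, oob), "out of range")
})
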