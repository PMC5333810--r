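test_that("profile construction normalises with pseudocounts", {
  aln <- Biostrings::AAStringSet(c(a = "A", b = "A", c = "C"))
  p <- buildProfile(aln, pseudocount = 1)
  expect_equal(unname(profileFrequencies(p)["A", 1]), (2 + 1) / (3 + 20))
  expect_equal(unname(profileFrequencies(p)["C", 1]), (1 + 1) / (3 + 20))
  expect_equal(unname(profileFrequencies(p)["W", 1]), 1 / 23)

  # identical sequences: modal frequency maximal given the pseudocount
  aln2 <- Biostrings::AAStringSet(c(a = "MD", b = "MD"))
  p2 <- buildProfile(aln2)
  expect_equal(unname(profileFrequencies(p2)["M", 1]), 3 / 22)
  expect_true(all(apply(profileFrequencies(p2), 2, max) == 3 / 22))

  expect_error(buildProfile(Biostrings::AAStringSet(c(a = "-A", b = "-C"))),
               "gap-only")
})

test_that("the bundled paired-domain model is 128 columns, homeodomain 60", {
  pr <- paxProfiles()
  expect_identical(length(pr$PRD), 128L)
  expect_identical(length(pr$HD), 60L)
  expect_identical(Biostrings::width(referencePRDAlignment())[1], 128L)
})

test_that("profile scanning finds self, truncations and planted copies", {
  pr <- paxProfiles()
  cons <- profileConsensus(pr$PRD)

  h <- detectDomain(cons, pr$PRD, pr$minScore[["PRD"]])
  expect_identical(nrow(h), 1L)
  expect_identical(c(h$start, h$end), c(0L, 128L))
  expect_true(h$complete)
  # the consensus is the best possible ungapped match
  expect_gte(h$score, lophopax:::placementScore(paxReferencePRD("Pax4/6"),
                                                pr$PRD))

  trunc <- substr(cons, 1, 80)
  h <- detectDomain(trunc, pr$PRD, pr$minScore[["PRD"]])
  expect_identical(nrow(h), 1L)
  expect_false(h$complete)
  expect_identical(c(h$start, h$end), c(0L, 80L))

  # score is invariant under padding outside the hit window
  set.seed(10)
  padded <- paste0(randomProtein(37), cons, randomProtein(22))
  hp <- detectDomain(padded, pr$PRD, pr$minScore[["PRD"]])
  hp <- hp[hp$complete, ]
  expect_identical(hp$start, 37L)
  expect_equal(hp$score, h0 <- detectDomain(cons, pr$PRD,
                                            pr$minScore[["PRD"]])$score)
})

test_that("planted paired domains are recovered within +-2 at 5% mutation", {
  d <- generateDataset(syntheticConfig(nPerFamily = 9, mutationRate = 0.05,
                                       fragmentProb = 0, seed = 21))
  ann <- annotateAll(d$sequences)
  prdTruth <- d$truth[d$truth$kind == "PRD", ]
  err <- vapply(names(ann), function(id) {
    h <- domainHits(ann[[id]])
    h <- h[h$kind == "PRD" & h$complete, , drop = FALSE]
    if (!nrow(h)) return(Inf)
    abs(h$start[which.max(h$score)] -
          prdTruth$start[prdTruth$recordId == id])
  }, numeric(1))
  expect_gte(mean(err <= 2), 0.95)
})

test_that("percent identity follows the stated column conventions", {
  expect_identical(percentIdentity("MDKL", "MDKL"), 100)
  expect_identical(percentIdentity("AAAA", "AAAT"), 75)
  # symmetry
  set.seed(3)
  for (i in 1:10) {
    a <- randomProtein(40); b <- randomProtein(40)
    expect_identical(percentIdentity(a, b), percentIdentity(b, a))
  }
  # both-gap columns excluded; single-gap columns count as mismatches
  expect_identical(percentIdentity("A-C-", "A-G-"), 50)
  expect_identical(percentIdentity("A-CD", "AACD"), 75)
  # X never matches
  expect_identical(percentIdentity("AX", "AX"), 50)
  # unaligned inputs are globally aligned first
  expect_identical(percentIdentity("MDKLACDEFG", "MDKLCDEFG"), 90)
  expect_error(percentIdentity("", "A"), "empty")
})

test_that("architecture annotation reflects the planted layout", {
  # canonical Pax4/6: paired domain + MDKL + homeodomain, no octapeptide
  d <- generateDataset(syntheticConfig(families = "Pax4/6", nPerFamily = 1,
                                       mutationRate = 0, fragmentProb = 0,
                                       seed = 5))
  a <- annotateDomains(as.character(d$sequences[[1]]), "pax46")
  kinds <- domainHits(a)$kind
  expect_true("PRD" %in% kinds)
  expect_true("HD" %in% kinds)
  expect_false(any(domainHits(a)$kind == "OM"))
  expect_true("mdkl_linker" %in% domainHits(a)$name)
  expect_false(a@fragment)

  # Pax2/5/8: octapeptide + signal, no homeodomain
  d <- generateDataset(syntheticConfig(families = "Pax2/5/8", nPerFamily = 1,
                                       mutationRate = 0, fragmentProb = 0,
                                       seed = 6))
  a <- annotateDomains(as.character(d$sequences[[1]]), "pax258")
  expect_true("OM" %in% domainHits(a)$kind)
  expect_false(any(domainHits(a)$kind %in% c("HD", "HD_partial")))
  expect_true("basic_diacid" %in% domainHits(a)$name)

  # a short half paired domain is a fragment
  half <- substr(paxReferencePRD("Pax4/6"), 1, 70)
  a <- annotateDomains(half, "halfprd")
  expect_true(a@fragment)
  expect_false(any(domainHits(a)$complete & domainHits(a)$kind == "PRD"))
})

test_that("zero-noise annotation recovers every planted architecture", {
  d <- generateDataset(syntheticConfig(nPerFamily = 2, mutationRate = 0,
                                       fragmentProb = 0, seed = 77))
  ann <- annotateAll(d$sequences)
  for (id in names(ann)) {
    truth <- d$truth[d$truth$recordId == id, ]
    hits <- domainHits(ann[[id]])
    prd <- truth[truth$kind == "PRD", ]
    got <- hits[hits$kind == "PRD" & hits$complete, ]
    expect_identical(got$start[which.max(got$score)], prd$start)
    if (any(truth$kind == "HD"))
      expect_identical(hits$start[hits$kind == "HD"],
                       truth$start[truth$kind == "HD"])
    if (any(truth$kind == "OM"))
      expect_identical(hits$start[hits$kind == "OM"],
                       truth$start[truth$kind == "OM"])
  }
})
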