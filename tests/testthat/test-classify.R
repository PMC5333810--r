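beta <- "Paxβ"

test_that("the rule set encodes the lophotrochozoan architectures", {
  rules <- paxRuleSet()
  expect_identical(sum(rules$family != "eyg"), 6L)
  expect_setequal(rules$family,
                  c("Pax1/9", "Pax2/5/8", "Pax3/7", "Pax4/6", beta,
                    "PoxNeuro", "eyg"))
  p46 <- rules[rules$family == "Pax4/6", ]
  expect_true(all(c("OM_H", "OM_Y") %in% p46$forbidden[[1]]))
  p258 <- rules[rules$family == "Pax2/5/8", ]
  expect_true("HD" %in% p258$forbidden[[1]])
  expect_false(rules$autoAssign[rules$family == "eyg"])
})

test_that("classification follows domain composition and diagnostics", {
  prd <- paxReferencePRD("Pax2/5/8")
  # paired domain + Y-type octapeptide + quadribasic/diacid, no homeodomain
  s <- paste0("MSTA", prd, "GSTPLE", "YSIADILG", "AGT", "KRKRDEDE",
              strrep("GS", 15))
  call <- classifyFamily(annotateDomains(s, "syn258"))
  expect_identical(callFamily(call), "Pax2/5/8")
  expect_identical(call@confidence, "strong")

  # paired domain + MDKL + homeodomain, no octapeptide
  s <- paste0("MA", paxReferencePRD("Pax4/6"), "GSA", "MDKL", "PSTA",
              paxReferenceHD("Pax4/6"), strrep("AG", 12))
  call <- classifyFamily(annotateDomains(s, "syn46"))
  expect_identical(callFamily(call), "Pax4/6")
  expect_identical(call@confidence, "strong")
  expect_false(call@questionable)

  # truncated record: incomplete paired domain, nothing downstream
  s <- substr(paxReferencePRD("Pax1/9"), 1, 75)
  call <- classifyFamily(annotateDomains(s, "frag"))
  expect_identical(callFamily(call), "Pax")
  expect_identical(call@confidence, "indeterminate")
  expect_true(call@fragment)

  # no paired domain at all
  set.seed(8)
  call <- classifyFamily(annotateDomains(randomProtein(200), "rand"))
  expect_identical(call@status, "no-PRD")
  expect_true(is.na(callFamily(call)))
})

test_that("Pax-beta calls need two of the three motifs; beta-like needs none of the PRD", {
  prd <- paxReferencePRD(beta)
  m1 <- "YDYNLPDRGL"; m2 <- "PLDLS"
  set.seed(12)
  filler <- function(n) randomProtein(n)
  s <- paste0("MA", prd, filler(60), m1, filler(40), m2, filler(60))
  call <- classifyFamily(annotateDomains(s, "beta2of3"))
  expect_identical(callFamily(call), beta)

  # only one motif: not enough for the beta call
  s1 <- paste0("MA", prd, filler(60), m1, filler(100))
  call1 <- classifyFamily(annotateDomains(s1, "beta1of3"))
  expect_false(identical(callFamily(call1), beta))

  # motifs without a paired domain: the beta-like verdict
  s2 <- paste0(filler(50), m1, filler(40), m2, filler(50))
  call2 <- classifyFamily(annotateDomains(s2, "betalike"))
  expect_identical(callFamily(call2), paste0(beta, "like"))
})

test_that("strong calls are stable under unrelated downstream motifs", {
  prd <- paxReferencePRD("Pax1/9")
  s <- paste0("MA", prd, "GSTA", "HTVTDILG", strrep("AG", 20))
  base <- classifyFamily(annotateDomains(s, "p19"))
  expect_identical(callFamily(base), "Pax1/9")
  # append a Pax-beta motif: not forbidden for Pax1/9, call unchanged
  s2 <- paste0(s, "PLDLS", strrep("GA", 10))
  call2 <- classifyFamily(annotateDomains(s2, "p19b"))
  expect_identical(callFamily(call2), "Pax1/9")
})

test_that("octapeptide type separates the two homeodomain-less families", {
  d <- generateDataset(syntheticConfig(families = c("Pax1/9", "Pax2/5/8"),
                                       nPerFamily = 10, mutationRate = 0,
                                       fragmentProb = 0, seed = 17))
  calls <- classifyAll(annotateAll(d$sequences))
  got <- vapply(calls, callFamily, character(1))
  truth <- S4Vectors::mcols(d$sequences)$family
  expect_false(any(got == "Pax2/5/8" & truth == "Pax1/9"))
  expect_false(any(got == "Pax1/9" & truth == "Pax2/5/8"))
  expect_identical(unname(got), truth)
})

test_that("duplicated paired domains raise the eyg flag but never the label", {
  d <- generateDataset(syntheticConfig(families = "eyg", nPerFamily = 3,
                                       mutationRate = 0, fragmentProb = 0,
                                       seed = 23))
  calls <- classifyAll(annotateAll(d$sequences))
  for (call in calls) {
    expect_true(call@eygCandidate)
    expect_false(identical(callFamily(call), "eyg"))
  }
})

test_that("classification is deterministic", {
  d <- generateDataset(syntheticConfig(nPerFamily = 1, mutationRate = 0.05,
                                       fragmentProb = 0, seed = 3))
  a <- annotateDomains(as.character(d$sequences[[1]]), "x")
  c1 <- classifyFamily(a); c2 <- classifyFamily(a)
  expect_identical(proposedName(c1), proposedName(c2))
  expect_identical(c1@evidence, c2@evidence)
})

test_that("batch reports follow the five-column table format", {
  path <- tempfile(fileext = ".tsv")
  rep0 <- batchReport(list(), path = path)
  expect_identical(nrow(rep0), 0L)
  lines <- readLines(path)
  expect_identical(length(lines), 1L)
  expect_match(lines[1], "^Accession\tSubmitted name\tProposed name")

  # a strong fragment call gets the "(f)" decoration
  s <- paste0("MA", paxReferencePRD("Pax4/6"), "GSA", "MDKL", "PSTA",
              substr(paxReferenceHD("Pax4/6"), 1, 40))
  call <- classifyFamily(annotateDomains(s, "fragcall"))
  rep1 <- batchReport(list(call))
  expect_match(rep1$`Proposed name`[1], "\\(f\\)$")

  # zero-noise synthetic dataset: proposed = planted family for all
  d <- generateDataset(syntheticConfig(nPerFamily = 5, mutationRate = 0,
                                       fragmentProb = 0, seed = 41))
  calls <- classifyAll(annotateAll(d$sequences))
  rep <- batchReport(calls)
  expect_identical(nrow(rep), 30L)
  expect_identical(rep$`Proposed name`,
                   S4Vectors::mcols(d$sequences)$family)
})
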