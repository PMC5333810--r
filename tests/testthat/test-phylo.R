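test_that("p and gamma distances follow their closed forms", {
  aln <- Biostrings::AAStringSet(c(a = "AAAA", b = "AATT", c = "AAAA"))
  d <- distanceMatrix(aln, "p")
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_true(isSymmetric(d))
  expect_identical(unname(diag(d)), rep(0, 3))

  # gamma correction at p = 0.4 with the reference shape 0.716
  aln <- Biostrings::AAStringSet(c(a = strrep("A", 10),
                                   b = paste0(strrep("C", 4), strrep("A", 6)),
                                   c = strrep("A", 10)))
  dg <- distanceMatrix(aln, "gamma")
  alpha <- 0.716
  expect_equal(dg["a", "b"], alpha * ((1 - 0.4)^(-1 / alpha) - 1))

  # pairwise deletion: gaps and X are excluded from shared columns
  aln <- Biostrings::AAStringSet(c(a = "AA-C", b = "AAGC", c = "AXGC"))
  dp <- distanceMatrix(aln, "p")
  expect_equal(dp["a", "b"], 0)
  expect_equal(dp["a", "c"], 0)

  # saturation under the gamma correction is an error naming the pair
  sat <- Biostrings::AAStringSet(c(a = "AAAA", b = "CCCC", c = "AAAA"))
  expect_error(distanceMatrix(sat, "gamma"), "saturation.*a.*b")
  expect_error(distanceMatrix(Biostrings::AAStringSet(c(a = "A", b = "A"))),
               "at least 3")
})

test_that("three-taxon neighbor joining solves the three-point formulas", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tree <- neighborJoining(d)
  bl <- setNames(tree$edge.length,
                 tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
  expect_error(neighborJoining(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers additive topologies", {
  set.seed(404)
  for (i in seq_len(50)) {
    n <- sample(4:12, 1)
    case <- randomAdditiveMatrix(n)
    tree <- neighborJoining(case$d)
    expect_true(unrootedTopologyEqual(tree, case$tree),
                info = paste("case", i, "n", n))
  }
})

test_that("an all-zero matrix yields a star tree", {
  d <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  tree <- neighborJoining(d)
  expect_identical(tree$Nnode, 1L)
  expect_true(all(tree$edge.length == 0))
})

test_that("bootstrap supports are seeded, collapsible and sane", {
  set.seed(112)
  base <- vapply(1:4, function(i) randomProtein(60), character(1))
  aln <- Biostrings::AAStringSet(setNames(rep(base, each = 2),
                                          paste0("t", 1:8)))
  # identical duplicate pairs: the pairing splits get full support
  tree <- bootstrapTree(aln, nBootstrap = 25, collapseThreshold = 50,
                        seed = 9)
  rep <- monophylyReport(tree, data.frame(recordId = paste0("t", 1:8),
                                          family = rep(letters[1:4],
                                                       each = 2)))
  expect_true(all(rep$isMonophyletic))
  expect_true(all(rep$support == 100))

  # determinism: identical seed, identical newick bytes
  n1 <- ape::write.tree(bootstrapTree(aln, nBootstrap = 10, seed = 4))
  n2 <- ape::write.tree(bootstrapTree(aln, nBootstrap = 10, seed = 4))
  expect_identical(n1, n2)

  # collapse threshold 0 never removes edges; collapsing at 50 can only
  # reduce the internal node count
  set.seed(113)
  aln2 <- Biostrings::AAStringSet(setNames(
    vapply(1:6, function(i) randomProtein(40), character(1)),
    paste0("u", 1:6)))
  t0 <- bootstrapTree(aln2, nBootstrap = 10, collapseThreshold = 0, seed = 2)
  t50 <- bootstrapTree(aln2, nBootstrap = 10, collapseThreshold = 50, seed = 2)
  expect_gte(t0$Nnode, t50$Nnode)
  expect_identical(t0$tip.label, t50$tip.label)

  # a single replicate can only give supports 0 or 100
  t1 <- bootstrapTree(aln2, nBootstrap = 1, collapseThreshold = 0, seed = 2)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("monophyly reporting finds intruders and skips singletons", {
  tree <- ape::read.tree(text =
    "((p6a:1,(b1:1,(p6b:1,b2:1)x:1)y:1)z:1,(o1:1,o2:1)w:1,o3:1);")
  tree$node.label <- c("", "90", "80", "70", "60")
  calls <- data.frame(
    recordId = c("p6a", "p6b", "b1", "b2", "o1", "o2", "o3"),
    family = c("Pax6", "Pax6", "B", "B", "Out", "Out", "Single"))
  rep <- monophylyReport(tree, calls)
  expect_false(rep$isMonophyletic[rep$family == "Pax6"])
  expect_false(rep$isMonophyletic[rep$family == "B"])
  expect_true(rep$isMonophyletic[rep$family == "Out"])
  intr <- strsplit(rep$intruders[rep$family == "B"], ",")[[1]]
  expect_true("p6b" %in% intr)
  expect_false("Single" %in% rep$family)  # singleton excluded

  expect_error(monophylyReport(tree, calls[-1, ]), "without family call")
})

test_that("written distance and tree files are readable round-trips", {
  set.seed(77)
  aln <- Biostrings::AAStringSet(setNames(
    vapply(1:5, function(i) randomProtein(30), character(1)),
    paste0("q", 1:5)))
  d <- distanceMatrix(aln)
  f <- tempfile(fileext = ".phy")
  writePhylipDistances(d, f)
  lines <- readLines(f)
  expect_identical(as.integer(trimws(lines[1])), 5L)
  expect_identical(length(lines), 6L)

  tree <- neighborJoining(d)
  tf <- tempfile(fileext = ".nwk")
  writeSupportTree(tree, tf)
  back <- ape::read.tree(tf)
  expect_setequal(back$tip.label, names(aln))
})
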