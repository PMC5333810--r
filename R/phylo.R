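## Distance trees on curated paired-domain alignments. The tree stage is a
## neighbor-joining + bootstrap pipeline; supports are reported as
## "bootstrap (NJ)" percentages. Reference constants from maximum-likelihood
## analyses of comparable data are carried for the gamma distance
## correction: shape 0.716 (and an invariant-site proportion of 0.088,
## documented but not used by the distance machinery).

GAMMA_SHAPE_REFERENCE <- 0.716
PINV_REFERENCE <- 0.088

#' Pairwise distance matrix from a protein alignment
#'
#' Pairwise-deletion p-distances (mismatches over shared non-gap, non-`X`
#' columns), optionally gamma-corrected as
#' `d = alpha * ((1 - p)^(-1/alpha) - 1)` with the reference shape
#' `alpha = 0.716`.
#'
#' @param alignment equal-width [Biostrings::AAStringSet], >= 3 sequences.
#' @param correction `"p"` (uncorrected) or `"gamma"`.
#' @param gammaShape shape parameter for the gamma correction.
#' @return symmetric numeric matrix with zero diagonal, labelled by record
#'   ids.
#' @export
distanceMatrix <- function(alignment, correction = c("p", "gamma"),
                           gammaShape = GAMMA_SHAPE_REFERENCE) {
  correction <- match.arg(correction)
  alignment <- asAlignment(alignment)
  if (length(alignment) < 3L)
    stop("distance matrix needs at least 3 sequences", call. = FALSE)
  m <- alignmentMatrix(alignment)
  n <- nrow(m)
  usable <- m != "-" & m != "X"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- usable[i, ] & usable[j, ]
      ns <- sum(shared)
      if (ns == 0L)
        stop("no shared columns between ", rownames(m)[i], " and ",
             rownames(m)[j], call. = FALSE)
      p <- sum(m[i, shared] != m[j, shared]) / ns
      dij <- if (correction == "p") p else {
        if (p >= 1)
          stop("saturation error: p >= 1 for pair ", rownames(m)[i], " / ",
               rownames(m)[j], call. = FALSE)
        gammaShape * ((1 - p)^(-1 / gammaShape) - 1)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (via [ape::nj()]) with two post-conditions:
#' negative branch lengths are clamped to zero with the deficit transferred
#' to the sister edge, and zero-length internal edges are collapsed into
#' polytomies (so an all-zero matrix yields a star tree). Deterministic
#' given the input label order.
#'
#' @param d symmetric distance matrix with >= 3 labels (see
#'   [distanceMatrix()]).
#' @return an unrooted [ape] `phylo` tree.
#' @export
neighborJoining <- function(d) {
  if (is.matrix(d) && nrow(d) < 3L)
    stop("neighbor joining needs at least 3 labels", call. = FALSE)
  tree <- ape::nj(stats::as.dist(d))
  tree <- clampNegativeEdges(tree)
  ape::di2multi(tree, tol = 1e-10)
}

clampNegativeEdges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    siblings <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(siblings))
      tree$edge.length[siblings[1]] <-
        tree$edge.length[siblings[1]] + deficit
  }
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement `nBootstrap` times (seeded),
#' rebuilds the NJ tree per replicate, attaches the percentage of replicates
#' containing each internal bipartition as node labels, and collapses
#' internal branches with support below `collapseThreshold` into polytomies.
#'
#' @param alignment curated equal-width [Biostrings::AAStringSet].
#' @param nBootstrap number of bootstrap replicates (default 100).
#' @param collapseThreshold support percentage below which branches are
#'   collapsed (default 50; 0 disables collapsing).
#' @param correction,gammaShape passed to [distanceMatrix()].
#' @param seed integer seed for the column resampling.
#' @return a `phylo` tree with bootstrap percentages as `node.label`.
#' @export
bootstrapTree <- function(alignment, nBootstrap = 100L,
                          collapseThreshold = 50,
                          correction = c("p", "gamma"),
                          gammaShape = GAMMA_SHAPE_REFERENCE,
                          seed = 1L) {
  correction <- match.arg(correction)
  alignment <- asAlignment(alignment)
  stopifnot(nBootstrap >= 1L)
  m <- alignmentMatrix(alignment)
  buildTree <- function(cols) {
    sub <- Biostrings::AAStringSet(apply(m[, cols, drop = FALSE], 1L,
                                         paste, collapse = ""))
    names(sub) <- rownames(m)
    neighborJoining(distanceMatrix(sub, correction, gammaShape))
  }
  main <- buildTree(seq_len(ncol(m)))
  reps <- withSeed(seed, lapply(seq_len(nBootstrap), function(b) {
    buildTree(sample.int(ncol(m), replace = TRUE))
  }))
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  support <- round(100 * counts / nBootstrap)
  labels <- ifelse(is.na(support), "", as.character(support))
  main$node.label <- labels
  if (collapseThreshold > 0)
    main <- collapseWeakBranches(main, collapseThreshold)
  main
}

# collapse internal edges whose child-node support is below the threshold
collapseWeakBranches <- function(tree, threshold) {
  phangorn::pruneTree(tree, threshold)
}

#' Family monophyly report for a support-annotated tree
#'
#' For each family with at least two members among the leaves, tests whether
#' the members form a clade on some rooting of the unrooted tree (split
#' test: the tree is rooted at a leaf outside the family), and reports the
#' defining edge's bootstrap support, intruding taxa (non-members inside the
#' smallest clade spanning the members) and members missing from the tree.
#' Leaves with indeterminate calls are excluded; any other leaf without a
#' call is an error.
#'
#' @param tree a `phylo` tree with bootstrap percentages as `node.label`
#'   (see [bootstrapTree()]).
#' @param calls either a named list of [FamilyCall-class] or a data.frame
#'   with columns `recordId`, `family`.
#' @return data.frame with columns `family`, `n`, `isMonophyletic`,
#'   `support`, `intruders`, `missing`.
#' @export
monophylyReport <- function(tree, calls) {
  if (is.list(calls) && !is.data.frame(calls))
    calls <- data.frame(
      recordId = vapply(calls, function(x) x@recordId, character(1)),
      family = vapply(calls, function(x) x@family, character(1)),
      stringsAsFactors = FALSE)
  missingCalls <- setdiff(tree$tip.label, calls$recordId)
  if (length(missingCalls))
    stop("leaf without family call: ", paste(missingCalls, collapse = ", "),
         call. = FALSE)
  # leaves with indeterminate calls are excluded from the split tests
  calls <- calls[!is.na(calls$family) & calls$family != "Pax", , drop = FALSE]
  indeterminate <- setdiff(tree$tip.label, calls$recordId)
  if (length(indeterminate)) {
    if (length(tree$tip.label) - length(indeterminate) < 3L)
      stop("fewer than 3 determinate leaves", call. = FALSE)
    tree <- ape::drop.tip(tree, indeterminate)
  }
  families <- unique(calls$family)
  ntip <- ape::Ntip(tree)
  nodes <- seq.int(ntip + 1L, ntip + tree$Nnode)
  descSets <- lapply(nodes, function(nd) tree$tip.label[descendantTips(tree, nd)])
  rows <- lapply(families, function(fam) {
    members <- intersect(calls$recordId[calls$family == fam], tree$tip.label)
    missing <- setdiff(calls$recordId[calls$family == fam], tree$tip.label)
    if (length(members) < 2L) return(NULL)
    if (!length(setdiff(tree$tip.label, members))) {
      return(data.frame(family = fam, n = length(members),
                        isMonophyletic = TRUE, support = NA_real_,
                        intruders = "", missing = paste(missing, collapse = ","),
                        stringsAsFactors = FALSE))
    }
    # split test: members form a clade on some rooting iff some internal
    # node's descendant tip set equals the members or their complement
    same <- vapply(descSets, function(s) setequal(s, members), logical(1))
    compl <- vapply(descSets, function(s)
      setequal(s, setdiff(tree$tip.label, members)), logical(1))
    mono <- any(same) || any(compl)
    support <- NA_real_
    if (mono && !is.null(tree$node.label)) {
      nd <- if (any(same)) which(same)[1] else which(compl)[1]
      lab <- tree$node.label[nd]
      if (!is.na(lab) && nzchar(lab)) support <- as.numeric(lab)
    }
    intruders <- character()
    if (!mono) {
      # smallest clade (on this arbitrary rooting) spanning the members
      spans <- vapply(descSets, function(s) all(members %in% s), logical(1))
      if (any(spans)) {
        sizes <- lengths(descSets)
        best <- which(spans)[which.min(sizes[spans])]
        intruders <- setdiff(descSets[[best]], members)
      } else {
        intruders <- setdiff(tree$tip.label, members)
      }
    }
    data.frame(family = fam, n = length(members), isMonophyletic = mono,
               support = support,
               intruders = paste(intruders, collapse = ","),
               missing = paste(missing, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(family = character(), n = integer(),
                      isMonophyletic = logical(), support = numeric(),
                      intruders = character(), missing = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

descendantTips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  children <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(children, descendantTips, tree = tree))
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d labelled symmetric matrix from [distanceMatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhylipDistances <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Write a support-annotated tree in newick format
#'
#' Supports are written as internal node labels; labels containing newick
#' metacharacters are quoted by [ape::write.tree()].
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSupportTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
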