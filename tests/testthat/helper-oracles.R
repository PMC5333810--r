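# Independent brute-force oracles, written against the stated semantics and
# kept deliberately simple (position-by-position loops, no shared code with
# the package internals).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n, withX = FALSE) {
  pool <- if (withX) c(AA20, "X") else AA20
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# expand a pattern string into a list of per-element residue sets by a
# second, independent parse (regex-token based, unlike the package's
# character walker)
oracleParse <- function(text) {
  tokens <- regmatches(text, gregexpr("\\[[A-Z]+\\]|X(_[0-9]+_|[0-9]+)?|[A-Z]",
                                      text))[[1]]
  stopifnot(nchar(paste(tokens, collapse = "")) == nchar(text))
  lapply(tokens, function(tk) {
    if (startsWith(tk, "[")) {
      list(set = strsplit(substr(tk, 2, nchar(tk) - 1), "")[[1]], rep = 1L)
    } else if (startsWith(tk, "X")) {
      num <- gsub("[X_]", "", tk)
      list(set = NULL, rep = if (nzchar(num)) as.integer(num) else 1L)
    } else list(set = tk, rep = 1L)
  })
}

# all windows with <= maxMismatch failed elements; returns 0-based starts
# and mismatch counts
oracleScan <- function(sequence, text, maxMismatch) {
  elems <- oracleParse(text)
  s <- strsplit(sequence, "")[[1]]
  L <- sum(vapply(elems, `[[`, integer(1), "rep"))
  if (length(s) < L) return(data.frame(start = integer(), mm = integer()))
  starts <- integer(); mms <- integer()
  for (st in 0:(length(s) - L)) {
    pos <- st
    mm <- 0L
    for (el in elems) {
      failed <- FALSE
      for (r in seq_len(el$rep)) {
        ch <- s[pos + 1L]
        if (!is.null(el$set) && !(ch %in% el$set)) failed <- TRUE
        pos <- pos + 1L
      }
      if (failed) mm <- mm + 1L
    }
    if (mm <= maxMismatch) { starts <- c(starts, st); mms <- c(mms, mm) }
  }
  data.frame(start = starts, mm = mms)
}

# leftmost 4-residue run with >= minBasic K/R inside the window, or NA
oracleBasicRun <- function(sequence, windowStart, windowLen, minBasic) {
  s <- strsplit(sequence, "")[[1]]
  if (windowLen < 4) return(NA_integer_)
  for (st in windowStart:(windowStart + windowLen - 4)) {
    run <- s[(st + 1):(st + 4)]
    if (sum(run %in% c("K", "R")) >= minBasic) return(st)
  }
  NA_integer_
}

# rule-by-rule reimplementation of the block selection on column classes;
# returns kept 0-based indices
oracleSelect <- function(classes, minBlockLen = 10, maxNoncons = 8) {
  nc <- length(classes)
  dropped <- rep(FALSE, nc)
  # (i) gaps and adjacent nonconserved
  for (j in seq_len(nc)) {
    if (classes[j] == "gap") {
      dropped[j] <- TRUE
      if (j > 1 && classes[j - 1] == "nonconserved") dropped[j - 1] <- TRUE
      if (j < nc && classes[j + 1] == "nonconserved") dropped[j + 1] <- TRUE
    }
  }
  # (ii) runs of > maxNoncons nonconserved columns
  j <- 1
  while (j <= nc) {
    if (classes[j] == "nonconserved") {
      k <- j
      while (k < nc && classes[k + 1] == "nonconserved") k <- k + 1
      if (k - j + 1 > maxNoncons) dropped[j:k] <- TRUE
      j <- k + 1
    } else j <- j + 1
  }
  # (iii) blocks = maximal surviving runs, trimmed to highly conserved ends;
  # (iv) minimum length
  kept <- integer()
  j <- 1
  while (j <= nc) {
    if (!dropped[j]) {
      k <- j
      while (k < nc && !dropped[k + 1]) k <- k + 1
      block <- j:k
      hc <- which(classes[block] == "highly_conserved")
      if (length(hc)) {
        block <- block[hc[1]:hc[length(hc)]]
        if (length(block) >= minBlockLen) kept <- c(kept, block)
      }
      j <- k + 1
    } else j <- j + 1
  }
  kept - 1L
}

# random small alignment whose columns exercise all class labels
randomTestAlignment <- function(nSeq, nCol, gapProb = 0.05) {
  cols <- vapply(seq_len(nCol), function(j) {
    type <- sample(c("uni", "mix", "rand", "gap"), 1,
                   prob = c(0.35, 0.3, 0.25, gapProb * 4))
    if (type == "uni") rep(sample(AA20, 1), nSeq)
    else if (type == "mix") {
      base <- sample(AA20, 2)
      sample(base, nSeq, replace = TRUE, prob = c(0.7, 0.3))
    } else if (type == "rand") sample(AA20, nSeq, replace = TRUE)
    else { col <- sample(AA20, nSeq, replace = TRUE)
           col[sample(nSeq, 1)] <- "-"; col }
  }, character(nSeq))
  seqs <- apply(cols, 1, paste, collapse = "")
  names(seqs) <- sprintf("s%02d", seq_len(nSeq))
  Biostrings::AAStringSet(seqs)
}

# additive distance matrix from a random topology with positive branches
randomAdditiveMatrix <- function(nLeaves) {
  tree <- ape::rtree(nLeaves, br = function(n) runif(n, 0.1, 1))
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

unrootedTopologyEqual <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
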