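#' Build a position-specific frequency profile from a reference alignment
#'
#' Counts residues per column (gaps and `X` are ignored in the counts), adds
#' a pseudocount to every cell and normalises each column by
#' `nonGapResidues + 20 * pseudocount`, so with a single-column alignment
#' `A,A,C` and pseudocount 1 the frequency of A is `(2+1)/(3+20)`.
#'
#' @param reference equal-width [Biostrings::AAStringSet] (>= 2 sequences);
#'   its width defines the model length (128 for the paired domain, 60 for
#'   the homeodomain).
#' @param pseudocount positive real (default 1).
#' @param kind model label stored in the profile.
#' @return a [PositionProfile-class].
#' @export
buildProfile <- function(reference, pseudocount = 1, kind = "custom") {
  reference <- asAlignment(reference)
  assertScalarNumber(pseudocount, "pseudocount")
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  m <- alignmentMatrix(reference)
  counts <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col %in% AA_LETTERS]
    tab <- table(factor(col, levels = AA_LETTERS))
    as.integer(tab)
  }, integer(length(AA_LETTERS)))
  rownames(counts) <- AA_LETTERS
  nres <- colSums(counts)
  if (any(nres == 0L))
    stop("profile error: gap-only column(s) at 0-based index ",
         paste(which(nres == 0L) - 1L, collapse = ", "), call. = FALSE)
  freq <- sweep(counts + pseudocount, 2L, nres + 20 * pseudocount, "/")
  methods::new("PositionProfile", freq = freq, pseudocount = pseudocount,
               kind = kind)
}

#' Modal (consensus) sequence of a profile
#'
#' @param profile a [PositionProfile-class].
#' @return amino-acid string of the per-column modal residues.
#' @export
profileConsensus <- function(profile) {
  paste(AA_LETTERS[apply(profile@freq, 2L, which.max)], collapse = "")
}

# log-odds matrix against a uniform background of 1/20
logOddsMatrix <- function(profile) log(profile@freq * 20)

#' Score of a full-length ungapped placement of a profile
#'
#' Mean log-odds per column of placing the profile at 0-based offset
#' `offset` of the sequence; used for self-score calibration.
#' @param sequence amino-acid string.
#' @param profile a [PositionProfile-class].
#' @param offset 0-based placement offset.
#' @return numeric mean log-odds.
#' @keywords internal
placementScore <- function(sequence, profile, offset = 0L) {
  s <- seqChars(as.character(sequence))
  L <- length(profile)
  stopifnot(offset >= 0L, offset + L <= length(s))
  M <- logOddsMatrix(profile)
  idx <- match(s[(offset + 1L):(offset + L)], AA_LETTERS)
  vals <- ifelse(is.na(idx), 0, M[cbind(idx, seq_len(L))])
  mean(vals)
}

#' Data-driven default acceptance score for a profile
#'
#' Mean self-score of the (ungapped) reference sequences against the profile
#' minus three standard deviations. Avoids a hand-picked constant: the
#' threshold widens automatically with the divergence represented in the
#' reference set.
#'
#' @param profile a [PositionProfile-class].
#' @param reference the alignment the profile was built from.
#' @return numeric score threshold.
#' @export
defaultMinScore <- function(profile, reference) {
  reference <- asAlignment(reference)
  selfScores <- vapply(as.character(reference), function(x) {
    placementScore(gsub("-", "", x, fixed = TRUE), profile, 0L)
  }, numeric(1))
  mean(selfScores) - 3 * sd(selfScores)
}

#' Detect occurrences of a domain profile in a protein sequence
#'
#' Ungapped profile scanning: the profile is slid along the sequence
#' (including placements that run off either terminus, to catch database
#' fragments) and each placement is scored as the mean log-odds per covered
#' column against a uniform background. A placement must cover at least 25%
#' of the model to be considered; placements covering the full model are
#' `complete`. Hits with score >= `minScore` are accepted greedily
#' best-first, discarding overlaps, and reported sorted by start.
#'
#' @param sequence amino-acid string (or [Biostrings::AAString]).
#' @param profile a [PositionProfile-class].
#' @param minScore acceptance threshold (mean log-odds per column).
#' @return hits data.frame (columns as in [scanPattern()], `kind` = profile
#'   kind); zero rows when nothing scores above threshold.
#' @export
detectDomain <- function(sequence, profile, minScore) {
  assertScalarNumber(minScore, "minScore", min = -Inf)
  s <- seqChars(as.character(sequence))
  n <- length(s)
  if (n == 0L) return(emptyHits())
  L <- length(profile)
  minCov <- max(1L, ceiling(0.25 * L))
  M <- logOddsMatrix(profile)
  idx <- match(s, AA_LETTERS)
  offsets <- seq.int(-(L - minCov), n - minCov)
  res <- lapply(offsets, function(o) {
    j1 <- max(1L, 1L - o)           # first covered model column
    j2 <- min(L, n - o)             # last covered model column
    cols <- j1:j2
    pos <- o + cols
    ii <- idx[pos]
    vals <- ifelse(is.na(ii), 0, M[cbind(ii, cols)])
    c(score = mean(vals), start = pos[1] - 1L, end = pos[length(pos)],
      covered = length(cols))
  })
  res <- do.call(rbind, res)
  cand <- res[res[, "score"] >= minScore, , drop = FALSE]
  if (!nrow(cand)) return(emptyHits())
  cand <- cand[order(-cand[, "score"], cand[, "start"]), , drop = FALSE]
  taken <- logical(n)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    span <- (cand[i, "start"] + 1L):cand[i, "end"]
    if (any(taken[span])) next
    taken[span] <- TRUE
    out[[length(out) + 1L]] <- cand[i, ]
  }
  out <- do.call(rbind, out)
  hits <- data.frame(kind = profile@kind, name = profile@kind,
                     start = as.integer(out[, "start"]),
                     end = as.integer(out[, "end"]),
                     score = out[, "score"], mismatches = NA_integer_,
                     complete = out[, "covered"] == L,
                     stringsAsFactors = FALSE)
  hits$coverage <- out[, "covered"] / L
  hits[order(hits$start), , drop = FALSE]
}

#' Percent identity of two amino-acid sequences
#'
#' For equal-length inputs the strings are treated as aligned columns; for
#' unequal lengths a global pairwise alignment is computed first
#' (BLOSUM62, gap opening 10, gap extension 0.5 — the defaults used
#' throughout the package). Identity is `100 * matches / columns`, where
#' columns with a gap in both sequences are excluded, a gap in one sequence
#' counts as a mismatch, and the unknown residue `X` never matches. The
#' result is rounded half-up to the nearest integer for reporting.
#'
#' @param a,b amino-acid strings (gaps `-` allowed in aligned input).
#' @param align `"auto"` (align only when lengths differ), `"never"` or
#'   `"always"`.
#' @return integer percentage in `[0, 100]`.
#' @examples
#' percentIdentity("AAAA", "AAAT")  # 75
#' @export
percentIdentity <- function(a, b, align = c("auto", "never", "always")) {
  align <- match.arg(align)
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence", call. = FALSE)
  needAlign <- switch(align,
                      auto = nchar(a) != nchar(b),
                      never = FALSE,
                      always = TRUE)
  if (needAlign) {
    da <- gsub("-", "", a, fixed = TRUE)
    db <- gsub("-", "", b, fixed = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(da), Biostrings::AAString(db),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    a <- as.character(Biostrings::alignedPattern(pa))
    b <- as.character(Biostrings::alignedSubject(pa))
  }
  if (nchar(a) != nchar(b))
    stop("aligned inputs must have equal length", call. = FALSE)
  ca <- seqChars(a); cb <- seqChars(b)
  keep <- !(ca == "-" & cb == "-")
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) stop("no alignable columns", call. = FALSE)
  matches <- sum(ca == cb & ca != "-" & ca != "X")
  floor(100 * matches / length(ca) + 0.5)
}
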