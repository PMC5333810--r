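#' Parse a bracket-notation consensus motif
#'
#' The pattern language is the one used for Pax diagnostic motifs: uppercase
#' residue literals, residue classes in square brackets (`[ST]`), and the
#' wildcard `X`, optionally followed by an integer repeat count written
#' plainly (`X2`) or with subscript underscores (`X_2_`). A wildcard matches
#' any residue including the unknown residue `X`; `X` in a scanned sequence
#' never matches a literal or a class.
#'
#' @param text pattern string, e.g. `"Y[TS]IX2ILG"`.
#' @return a [MotifPattern-class].
#' @examples
#' p <- parsePattern("Y[TS]IX2ILG")
#' patternLength(p)  # 8
#' @export
parsePattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("pattern syntax error: empty pattern", call. = FALSE)
  chars <- seqChars(text)
  elements <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "[") {
      close <- NULL
      j <- i + 1L
      while (j <= n) {
        if (chars[[j]] == "]") { close <- j; break }
        j <- j + 1L
      }
      if (is.null(close))
        stop("pattern syntax error: unbalanced '[' in ", text, call. = FALSE)
      members <- chars[seq.int(i + 1L, length.out = close - i - 1L)]
      if (length(members) == 0L)
        stop("pattern syntax error: empty class in ", text, call. = FALSE)
      if (length(members) < 2L)
        stop("pattern syntax error: class with fewer than 2 residues in ",
             text, call. = FALSE)
      if (!all(members %in% AA_LETTERS))
        stop("pattern syntax error: illegal class residue in ", text,
             call. = FALSE)
      elements[[length(elements) + 1L]] <-
        list(kind = "class", residues = members, repeats = 1L)
      i <- close + 1L
    } else if (ch == "X") {
      i <- i + 1L
      repeats <- 1L
      if (i <= n && chars[[i]] == "_") {
        # subscript form X_2_
        j <- i + 1L
        digits <- character()
        while (j <= n && grepl("[0-9]", chars[[j]])) {
          digits <- c(digits, chars[[j]]); j <- j + 1L
        }
        if (length(digits) == 0L || j > n || chars[[j]] != "_")
          stop("pattern syntax error: malformed subscript repeat in ", text,
               call. = FALSE)
        repeats <- as.integer(paste(digits, collapse = ""))
        i <- j + 1L
      } else if (i <= n && grepl("[0-9]", chars[[i]])) {
        digits <- character()
        while (i <= n && grepl("[0-9]", chars[[i]])) {
          digits <- c(digits, chars[[i]]); i <- i + 1L
        }
        repeats <- as.integer(paste(digits, collapse = ""))
      }
      if (repeats < 1L)
        stop("pattern syntax error: zero repeat in ", text, call. = FALSE)
      elements[[length(elements) + 1L]] <-
        list(kind = "wildcard", residues = character(), repeats = repeats)
    } else if (ch %in% AA_LETTERS) {
      elements[[length(elements) + 1L]] <-
        list(kind = "literal", residues = ch, repeats = 1L)
      i <- i + 1L
    } else {
      stop("pattern syntax error: unexpected character '", ch, "' in ", text,
           call. = FALSE)
    }
  }
  methods::new("MotifPattern", elements = elements, text = text)
}

#' Expanded length of a pattern
#'
#' @param pattern a [MotifPattern-class].
#' @return integer: sum of element repeat counts.
#' @export
patternLength <- function(pattern) {
  sum(vapply(pattern@elements, function(e) e$repeats, integer(1)))
}

#' Serialize a pattern to its canonical string form
#'
#' Canonical form writes classes in their original residue order and counted
#' wildcards plainly (`X2`, never `X_2_`). `parsePattern()` composed with
#' `serializePattern()` is the identity on canonical strings.
#'
#' @param pattern a [MotifPattern-class].
#' @return character pattern string.
#' @export
serializePattern <- function(pattern) {
  paste(vapply(pattern@elements, function(e) {
    body <- switch(e$kind,
                   literal = e$residues,
                   class = paste0("[", paste(e$residues, collapse = ""), "]"),
                   wildcard = "X")
    if (e$kind == "wildcard" && e$repeats > 1L)
      paste0(body, e$repeats)
    else if (e$repeats > 1L)
      paste(rep(body, e$repeats), collapse = "")
    else body
  }, character(1)), collapse = "")
}

# per expanded position: list of residue sets (NULL = wildcard) and the
# element index covering that position
expandElements <- function(pattern) {
  sets <- list(); elem <- integer()
  for (k in seq_along(pattern@elements)) {
    e <- pattern@elements[[k]]
    for (r in seq_len(e$repeats)) {
      # list assignment keeps NULL (wildcard) entries as real elements
      sets[length(sets) + 1L] <-
        list(if (e$kind == "wildcard") NULL else e$residues)
      elem <- c(elem, k)
    }
  }
  list(sets = sets, elem = elem)
}

#' Scan a sequence for a consensus motif
#'
#' Slides the pattern along the sequence and reports every window whose
#' number of failed pattern elements is at most `maxMismatch`. Mismatches
#' are counted per element (a failed class counts 1 regardless of repeat);
#' wildcard elements never fail; an `X` residue in the sequence fails
#' literals and classes but matches wildcards. Overlapping hits are all
#' reported, sorted by start.
#'
#' @param sequence amino-acid string (or an [Biostrings::AAString]).
#' @param pattern a [MotifPattern-class] or pattern string.
#' @param maxMismatch maximum number of failed elements (default 0).
#' @return data.frame with columns `kind`, `name`, `start`, `end` (0-based
#'   half-open), `score`, `mismatches`, `complete`; zero rows when no hit.
#' @examples
#' scanPattern("AAMDKLAA", "MDKL")  # one hit at [2,6)
#' @export
scanPattern <- function(sequence, pattern, maxMismatch = 0L) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  stopifnot(is(pattern, "MotifPattern"))
  assertScalarNumber(maxMismatch, "maxMismatch", min = 0)
  s <- seqChars(as.character(sequence))
  L <- patternLength(pattern)
  n <- length(s)
  if (n < L) return(emptyHits())
  ex <- expandElements(pattern)
  nel <- length(pattern@elements)
  starts <- seq_len(n - L + 1L)
  # position-level failure per window start, folded to element level
  elemFail <- matrix(FALSE, nrow = length(starts), ncol = nel)
  for (j in seq_len(L)) {
    set <- ex$sets[[j]]
    if (is.null(set)) next
    bad <- !(s[starts + j - 1L] %in% set)
    k <- ex$elem[[j]]
    elemFail[, k] <- elemFail[, k] | bad
  }
  mm <- rowSums(elemFail)
  keep <- which(mm <= maxMismatch)
  if (!length(keep)) return(emptyHits())
  data.frame(kind = "MOTIF", name = pattern@text,
             start = keep - 1L, end = keep - 1L + L,
             score = NA_real_, mismatches = as.integer(mm[keep]),
             complete = TRUE, stringsAsFactors = FALSE)
}

#' Find a basic-residue signal in a sequence window
#'
#' Reports the leftmost run of 4 consecutive residues containing at least
#' `minBasic` basic residues (K/R) inside the given window. With
#' `minBasic = 4` this is the quadribasic signal of Pax2/5/8-type sequences;
#' `minBasic = 3` matches the tribasic variant found in the first
#' paired-domain helix of PoxNeuro and accepts the KRKH-type run.
#'
#' @param sequence amino-acid string.
#' @param windowStart 0-based start of the search window.
#' @param windowLen window length in residues.
#' @param minBasic minimum number of K/R residues in a 4-residue run.
#' @return one-row hits data.frame (see [scanPattern()]) or a zero-row
#'   data.frame when no run qualifies.
#' @examples
#' findBasicSignal("KRKHEDED", 0, 8, minBasic = 3)  # hit at [0,4)
#' @export
findBasicSignal <- function(sequence, windowStart, windowLen, minBasic = 4L) {
  s <- seqChars(as.character(sequence))
  n <- length(s)
  if (windowStart < 0 || windowLen < 0 || windowStart + windowLen > n)
    stop("range error: window [", windowStart, ",", windowStart + windowLen,
         ") outside sequence of length ", n, call. = FALSE)
  if (windowLen < 4L) return(emptyHits())
  isBasic <- s %in% BASIC_RESIDUES
  for (st in seq.int(windowStart, windowStart + windowLen - 4L)) {
    cnt <- sum(isBasic[(st + 1L):(st + 4L)])
    if (cnt >= minBasic) {
      return(data.frame(kind = "SIGNAL", name = "basic_run",
                        start = st, end = st + 4L,
                        score = as.numeric(cnt), mismatches = 0L,
                        complete = TRUE, stringsAsFactors = FALSE))
    }
  }
  emptyHits()
}

#' Expand a pattern into a concrete instance
#'
#' Chooses one member of each class uniformly at random (wildcards get a
#' uniform canonical residue). Used by the synthetic generator to plant
#' motifs; by construction the instance always yields a 0-mismatch hit.
#'
#' @param pattern a [MotifPattern-class] or pattern string.
#' @return amino-acid string of the expanded length.
#' @export
expandPattern <- function(pattern) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  ex <- expandElements(pattern)
  paste(vapply(ex$sets, function(set) {
    if (is.null(set)) sample(AA_LETTERS, 1L)
    else if (length(set) == 1L) set
    else sample(set, 1L)
  }, character(1)), collapse = "")
}

#' The bundled Pax diagnostic motif registry
#'
#' Loads the registry of family-diagnostic consensus motifs (octapeptides of
#' Pax1/9 and Pax2/5/8, the PoxNeuro junction and post-domain motifs, the
#' Pax4/6 MDKL linker, and the three Pax-beta motifs) together with their
#' associated family, search zone and default mismatch allowance. The
#' 31-element Pax-beta motif carries a default allowance of 2; all short
#' motifs default to 0.
#'
#' @param path optional path to an alternative registry TSV with columns
#'   `name`, `pattern`, `family`, `zone`, `maxMismatch`.
#' @return data.frame with those columns plus a `parsed` list-column of
#'   [MotifPattern-class] objects.
#' @export
paxMotifRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pax_motifs.tsv", package = "lophopax",
                        mustWork = TRUE)
  reg <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stopifnot(all(c("name", "pattern", "family", "zone", "maxMismatch") %in%
                  names(reg)))
  reg$family <- canonicalPaxName(reg$family)
  reg$parsed <- lapply(reg$pattern, parsePattern)
  reg
}
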