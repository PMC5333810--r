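#' Read unaligned protein sequences from FASTA
#'
#' Wraps [Biostrings::readAAStringSet()] and enforces the package's record
#' contract: ids are the header up to the first whitespace, sequences are
#' uppercased, `*` stop symbols are stripped, and the residue alphabet is
#' restricted to the 20 canonical letters plus `X`.
#'
#' @param path path to a FASTA file.
#' @return an [Biostrings::AAStringSet] with unique names; per-record
#'   metadata (`species`, `sourceAnnotation`, `isFragment`) lives in
#'   `S4Vectors::mcols()` and is initialised to `NA`.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read as BStringSet first so alphabet violations raise our parse error,
  # not a low-level lookup failure
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) return(emptyProteinSet())
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chr <- toupper(gsub("*", "", as.character(seqs), fixed = TRUE))
  validateProteinSequences(chr, names(seqs))
  out <- Biostrings::AAStringSet(chr)
  names(out) <- names(seqs)
  initMcols(out)
}

emptyProteinSet <- function() {
  initMcols(Biostrings::AAStringSet())
}

initMcols <- function(seqs) {
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    species = rep(NA_character_, length(seqs)),
    sourceAnnotation = rep(NA_character_, length(seqs)),
    isFragment = rep(NA, length(seqs)))
  seqs
}

validateProteinSequences <- function(chr, ids, gapped = FALSE) {
  if (anyDuplicated(ids))
    stop("duplicated sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  alphabet <- if (gapped) c(AA_WITH_X, "-") else AA_WITH_X
  for (i in seq_along(chr)) {
    if (!nzchar(chr[[i]]))
      stop(sprintf("parse error: empty sequence for record '%s'", ids[[i]]),
           call. = FALSE)
    bad <- setdiff(unique(seqChars(chr[[i]])), alphabet)
    if (length(bad))
      stop(sprintf("parse error: illegal residue(s) %s in record '%s'",
                   paste(sQuote(bad), collapse = ", "), ids[[i]]),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Write protein sequences to FASTA
#'
#' @param seqs an [Biostrings::AAStringSet].
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(seqs, path, width = 60L) {
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read an aligned protein FASTA (gap character '-')
#'
#' @param path path to an aligned FASTA file.
#' @return an [Biostrings::AAStringSet] whose members all have the same
#'   width (the alignment matrix); at least two records are required.
#' @export
readProteinAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chr <- toupper(gsub("*", "", as.character(seqs), fixed = TRUE))
  validateProteinSequences(chr, names(seqs), gapped = TRUE)
  out <- Biostrings::AAStringSet(chr)
  names(out) <- names(seqs)
  asAlignment(out)
}

#' Assemble and validate an alignment from equal-length sequences
#'
#' @param seqs a named [Biostrings::AAStringSet] or named character vector of
#'   aligned sequences (gaps as `-`).
#' @return the validated [Biostrings::AAStringSet].
#' @export
asAlignment <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  if (length(seqs) < 2L)
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    offending <- names(seqs)[w != max(w)]
    stop("alignment error: unequal sequence lengths for: ",
         paste(offending, collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Alignment as a character matrix
#'
#' @param alignment an equal-width [Biostrings::AAStringSet].
#' @return character matrix (rows = sequences, columns = alignment columns).
#' @export
alignmentMatrix <- function(alignment) {
  m <- do.call(rbind, lapply(as.character(alignment), seqChars))
  rownames(m) <- names(alignment)
  m
}

#' Write an alignment to FASTA
#'
#' @inheritParams writeProteinFasta
#' @export
writeProteinAlignment <- function(seqs, path, width = 60L) {
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

## ---- reclassification fixture (Table-1-style TSV) -------------------------

RECLASS_HEADER <- c("Accession", "Submitted name", "Proposed name",
                    "Species", "Classification")

# base names allowed in the proposed-name column, before "(f)"/"(?)"/"?"
# decorations; Greek beta is canonical, ASCII aliases are accepted on input
ALLOWED_PROPOSED <- c("Pax", "Pax1/9", "Pax2/5/8", "Pax3/7", "Pax3/7A",
                      "Pax3/7B", "Pax6", "Pax6A", "Pax6B", "Pax9",
                      PAX_BETA, paste0(PAX_BETA, "1"), paste0(PAX_BETA, "2"),
                      paste0(PAX_BETA, "like"), "PoxN", "eyg")

#' Canonicalise a Pax family name
#'
#' Accepts the ASCII aliases `PaxB`/`Paxbeta`/`Paxb` for the Greek-lettered
#' beta subfamily and returns the canonical UTF-8 spelling.
#'
#' @param x character vector of names.
#' @return character vector with canonical spellings.
#' @export
canonicalPaxName <- function(x) {
  x <- sub("^PaxB(?![a-z])", PAX_BETA, x, perl = TRUE)
  x <- sub("^Paxbeta", PAX_BETA, x)
  sub("^Paxb(?=like|[0-9]|$|\\(|\\?)", PAX_BETA, x, perl = TRUE)
}

#' Strip decorations from a proposed name
#'
#' Removes the fragment `"(f)"`, uncertainty `"(?)"`/`"?"` marks and isoform
#' letters/digits, returning the base family label (e.g. `"Pax2/5/8?(f)"`
#' becomes `"Pax2/5/8"`, `"Paxβ1(f)"` becomes `"Paxβ"`).
#'
#' @param x character vector of proposed names.
#' @return character vector of base family labels.
#' @export
paxBaseFamily <- function(x) {
  x <- canonicalPaxName(x)
  x <- gsub("\\(f\\)|\\(\\?\\)|\\?", "", x)
  x <- sub(paste0("^(", PAX_BETA, ")[12]$"), "\\1", x)
  x <- sub("^(Pax3/7)[AB]$", "\\1", x)
  x <- sub("^(Pax6)[AB]$", "\\1", x)
  x
}

#' Load the bundled reclassification fixture
#'
#' Reads the tab-separated table of previously non- or mis-identified
#' lophotrochozoan Pax proteins bundled with the package (56 entries:
#' accession, submitted name, proposed name, species, taxonomic
#' classification). The fragment flag is derived from the `"(f)"` suffix of
#' the proposed name.
#'
#' @param path path to the TSV; defaults to the bundled fixture.
#' @return data.frame with columns `accession`, `submittedName`,
#'   `proposedName`, `species`, `classification`, `fragmentFlag`,
#'   `baseFamily`.
#' @examples
#' tab <- loadReclassificationTable()
#' nrow(tab)  # 56
#' @export
loadReclassificationTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_reclassified.tsv",
                        package = "lophopax", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 5L))
    stop(sprintf("parse error: expected 5 tab-separated columns, got %d on line %d",
                 ncols[which(ncols != 5L)[1]], which(ncols != 5L)[1]),
         call. = FALSE)
  hdr <- fields[[1]]
  if (!identical(hdr, RECLASS_HEADER))
    stop("parse error: unexpected header row", call. = FALSE)
  body <- fields[-1]
  out <- data.frame(
    accession = vapply(body, `[[`, "", 1L),
    submittedName = vapply(body, `[[`, "", 2L),
    proposedName = canonicalPaxName(vapply(body, `[[`, "", 3L)),
    species = vapply(body, `[[`, "", 4L),
    classification = vapply(body, `[[`, "", 5L),
    stringsAsFactors = FALSE)
  out$fragmentFlag <- grepl("(f)", out$proposedName, fixed = TRUE)
  out$baseFamily <- paxBaseFamily(out$proposedName)
  bad <- setdiff(unique(gsub("\\(f\\)|\\(\\?\\)|\\?", "", out$proposedName)),
                 ALLOWED_PROPOSED)
  if (length(bad))
    stop("parse error: unknown proposed name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out
}
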