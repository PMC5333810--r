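#' MotifPattern: a parsed bracket-notation consensus motif
#'
#' A consensus motif in the bracket notation used throughout the Pax
#' literature: uppercase literals (`M`), residue classes (`[ST]`) and counted
#' wildcards (`X2`, also written `X_2_`). Objects are created with
#' [parsePattern()].
#'
#' @slot elements list of pattern elements; each element is a list with
#'   fields `kind` (`"literal"`, `"class"` or `"wildcard"`), `residues`
#'   (character vector, empty for wildcards) and `repeats` (positive integer).
#' @slot text the original pattern string.
#' @seealso [parsePattern()], [scanPattern()], [patternLength()]
#' @export
setClass("MotifPattern",
         representation(elements = "list", text = "character"))

setValidity("MotifPattern", function(object) {
  if (length(object@elements) < 1L) return("pattern needs at least one element")
  for (el in object@elements) {
    if (!el$kind %in% c("literal", "class", "wildcard"))
      return(sprintf("unknown element kind '%s'", el$kind))
    if (el$repeats < 1L) return("element repeat count must be positive")
    if (el$kind == "literal" && length(el$residues) != 1L)
      return("literal element must have exactly one residue")
    if (el$kind == "class" && length(el$residues) < 2L)
      return("class element must have at least two residues")
    if (el$kind == "wildcard" && length(el$residues) != 0L)
      return("wildcard element carries no residues")
  }
  TRUE
})

#' @describeIn MotifPattern pretty printer
#' @param object a `MotifPattern`.
#' @export
setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern \"%s\" (%d elements, expanded length %d)\n",
              object@text, length(object@elements), patternLength(object)))
})

#' PositionProfile: per-column residue frequencies of a domain model
#'
#' A position-specific frequency profile over the 20 canonical residues,
#' built from a gap-capable reference alignment with [buildProfile()]. The
#' paired-domain model is 128 columns (PAI columns `[0,64)`, RED `[64,128)`);
#' the paired-type homeodomain model is 60 columns.
#'
#' @slot freq 20 x L matrix of pseudocount-normalised frequencies; rows are
#'   residues, columns are model positions. Columns sum to
#'   (residues + 20 * pseudocount) / (residues + 20 * pseudocount) = 1 only
#'   when the alignment is gap-free in that column; with gaps the non-gap
#'   count is used.
#' @slot pseudocount positive real added to every cell before normalisation.
#' @slot kind free-text model label, e.g. `"PRD"` or `"HD"`.
#' @seealso [buildProfile()], [detectDomain()]
#' @export
setClass("PositionProfile",
         representation(freq = "matrix", pseudocount = "numeric",
                        kind = "character"))

setValidity("PositionProfile", function(object) {
  if (!identical(rownames(object@freq), AA_LETTERS))
    return("frequency matrix rows must be the 20 canonical residues")
  if (ncol(object@freq) < 1L) return("profile needs at least one column")
  if (object@pseudocount <= 0) return("pseudocount must be positive")
  if (any(object@freq <= 0)) return("frequencies must be strictly positive")
  TRUE
})

#' @describeIn PositionProfile number of model columns
#' @param x a `PositionProfile`.
#' @export
setMethod("length", "PositionProfile", function(x) ncol(x@freq))

#' @describeIn PositionProfile pretty printer
#' @param object a `PositionProfile`.
#' @export
setMethod("show", "PositionProfile", function(object) {
  cat(sprintf("PositionProfile '%s': %d columns, pseudocount %g\n",
              object@kind, ncol(object@freq), object@pseudocount))
})

#' BlockMask: alignment columns retained by the block filter
#'
#' The result of Gblocks-style curation ([selectBlocks()]): the ordered
#' 0-based indices of retained columns and the maximal contiguous blocks
#' they form in the original alignment coordinates.
#'
#' @slot kept integer vector of retained 0-based column indices (ordered).
#' @slot blocks an [IRanges::IRanges] of retained blocks; `start` is stored
#'   1-based (IRanges convention), use [blockRanges()] for the 0-based
#'   half-open view.
#' @slot nColumns total number of columns of the source alignment.
#' @seealso [selectBlocks()], [applyMask()]
#' @export
setClass("BlockMask",
         representation(kept = "integer", blocks = "ANY", nColumns = "integer"))

setValidity("BlockMask", function(object) {
  if (length(object@kept) && (min(object@kept) < 0L ||
                              max(object@kept) >= object@nColumns))
    return("kept indices out of range")
  if (is.unsorted(object@kept, strictly = TRUE) && length(object@kept) > 1L)
    return("kept indices must be strictly increasing")
  TRUE
})

#' @describeIn BlockMask pretty printer
#' @param object a `BlockMask`.
#' @export
setMethod("show", "BlockMask", function(object) {
  cat(sprintf("BlockMask: %d/%d columns kept in %d block(s)\n",
              length(object@kept), object@nColumns,
              length(object@blocks)))
})

#' DomainAnnotation: located domains and motifs of one protein
#'
#' Produced by [annotateDomains()]; holds every accepted domain/motif hit for
#' a record plus the extracted paired-domain subsequence and fragment status.
#'
#' @slot recordId sequence identifier.
#' @slot hits data.frame with columns `kind`, `name`, `start`, `end`
#'   (0-based half-open), `score`, `mismatches`, `complete`.
#' @slot prdSubsequence character; the matched paired-domain subsequence, or
#'   `NA` if no paired domain was accepted.
#' @slot fragment logical; `TRUE` when the paired domain is incomplete or the
#'   sequence ends inside a required domain.
#' @seealso [annotateDomains()], [classifyFamily()]
#' @export
setClass("DomainAnnotation",
         representation(recordId = "character", hits = "data.frame",
                        prdSubsequence = "character", fragment = "logical"))

#' @describeIn DomainAnnotation pretty printer
#' @param object a `DomainAnnotation`.
#' @export
setMethod("show", "DomainAnnotation", function(object) {
  cat(sprintf("DomainAnnotation for '%s': %d hit(s)%s\n", object@recordId,
              nrow(object@hits), if (object@fragment) " [fragment]" else ""))
  if (nrow(object@hits)) print(object@hits, row.names = FALSE)
})

#' FamilyCall: the classifier's verdict for one protein
#'
#' @slot recordId sequence identifier.
#' @slot family family label (`"Pax1/9"`, `"Pax2/5/8"`, `"Pax3/7"`,
#'   `"Pax4/6"`, `"Paxβ"`, `"PoxNeuro"`, `"Paxβlike"`) or `"Pax"` for an
#'   indeterminate call; `NA` when no paired domain was found.
#' @slot confidence one of `"strong"`, `"weak"`, `"indeterminate"`.
#' @slot fragment logical fragment status (from the annotation).
#' @slot questionable logical; `TRUE` when contradictory full-required
#'   families were resolved by score only (reported with a `"?"`).
#' @slot eygCandidate logical; `TRUE` when a divergent/duplicated
#'   paired-domain configuration suggests eyegone (never auto-confirmed).
#' @slot status `"ok"` or `"no-PRD"`.
#' @slot evidence data.frame with columns `key`, `satisfied`, `location`.
#' @slot score integer diagnostic score of the winning family.
#' @seealso [classifyFamily()], [batchReport()]
#' @export
setClass("FamilyCall",
         representation(recordId = "character", family = "character",
                        confidence = "character", fragment = "logical",
                        questionable = "logical", eygCandidate = "logical",
                        status = "character", evidence = "data.frame",
                        score = "integer"))

#' @describeIn FamilyCall pretty printer
#' @param object a `FamilyCall`.
#' @export
setMethod("show", "FamilyCall", function(object) {
  cat(sprintf("FamilyCall '%s': %s (%s)%s%s\n", object@recordId,
              proposedName(object), object@confidence,
              if (object@eygCandidate) " [eyg?]" else "",
              if (object@status != "ok") paste0(" status=", object@status) else ""))
})

#' Accessors for lophopax S4 objects
#'
#' Small read-only accessors so downstream code never touches slots.
#'
#' @param x an object of the documented class.
#' @return `patternText` and `patternElements` return the pattern string and
#'   element list of a [MotifPattern-class]; `profileFrequencies` the
#'   frequency matrix of a [PositionProfile-class]; `keptColumns` the 0-based
#'   retained columns and `blockRanges` a data.frame of 0-based half-open
#'   blocks of a [BlockMask-class]; `domainHits` the hits table and
#'   `prdSequence` the paired-domain subsequence of a
#'   [DomainAnnotation-class]; `callFamily` the family label of a
#'   [FamilyCall-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
patternText <- function(x) x@text

#' @rdname accessors
#' @export
patternElements <- function(x) x@elements

#' @rdname accessors
#' @export
profileFrequencies <- function(x) x@freq

#' @rdname accessors
#' @export
keptColumns <- function(x) x@kept

#' @rdname accessors
#' @export
blockRanges <- function(x) {
  data.frame(start = IRanges::start(x@blocks) - 1L,
             end = IRanges::end(x@blocks))
}

#' @rdname accessors
#' @export
domainHits <- function(x) x@hits

#' @rdname accessors
#' @export
prdSequence <- function(x) x@prdSubsequence

#' @rdname accessors
#' @export
callFamily <- function(x) x@family

#' Decorated proposed name of a family call
#'
#' Composes the reporting name the way the reclassification table prints it:
#' the family label, a `"?"` for questionable calls and `"(f)"` for
#' fragments, e.g. `"Pax2/5/8?(f)"`.
#'
#' @param call a [FamilyCall-class].
#' @return character proposed name.
#' @export
proposedName <- function(call) {
  if (is.na(call@family)) return(NA_character_)
  paste0(call@family,
         if (call@questionable) "?" else "",
         if (call@fragment) "(f)" else "")
}
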