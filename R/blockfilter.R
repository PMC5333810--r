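#' Parameters for Gblocks-style block filtering
#'
#' Defaults are the published curation settings used for paired-domain
#' alignments: minimum block length 10 after gap cleaning, no gap positions
#' in the final alignment, rejection of segments with more than 8 contiguous
#' non-conserved positions, and an 85% flank threshold. The conservation
#' threshold follows the canonical "more than half" rule: a column is
#' conserved when its modal residue frequency strictly exceeds
#' `conservedFraction` (default 0.5, i.e. modal count >= floor(n/2)+1).
#'
#' @param minBlockLen minimum retained block length (columns).
#' @param allowGaps whether gap-containing columns may be kept (the
#'   published setting is `FALSE`; `TRUE` is provided for experimentation).
#' @param maxContigNonconserved maximal run of non-conserved columns kept.
#' @param flankFraction modal-residue frequency required for a
#'   highly-conserved (flank) column.
#' @param conservedFraction modal-residue frequency that must be exceeded
#'   for a conserved column.
#' @return list of class `blockFilterParams`.
#' @export
blockFilterParams <- function(minBlockLen = 10L, allowGaps = FALSE,
                              maxContigNonconserved = 8L,
                              flankFraction = 0.85,
                              conservedFraction = 0.5) {
  stopifnot(minBlockLen >= 1L, maxContigNonconserved >= 0L,
            flankFraction > 0, flankFraction <= 1,
            conservedFraction >= 0, conservedFraction < 1)
  structure(list(minBlockLen = as.integer(minBlockLen),
                 allowGaps = isTRUE(allowGaps),
                 maxContigNonconserved = as.integer(maxContigNonconserved),
                 flankFraction = flankFraction,
                 conservedFraction = conservedFraction),
            class = "blockFilterParams")
}

#' Classify alignment columns for block filtering
#'
#' Per column: `gap` if any sequence has `-` (when gaps are disallowed);
#' otherwise `highly_conserved` if the modal residue frequency is at least
#' `flankFraction`, `conserved` if it strictly exceeds
#' `conservedFraction`, else `nonconserved`.
#'
#' @param alignment equal-width [Biostrings::AAStringSet].
#' @param params a [blockFilterParams()] list.
#' @return character vector of column labels.
#' @export
classifyColumns <- function(alignment, params = blockFilterParams()) {
  alignment <- asAlignment(alignment)
  m <- alignmentMatrix(alignment)
  n <- nrow(m)
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (!params$allowGaps && any(col == "-")) return("gap")
    res <- col[col != "-"]
    if (!length(res)) return("gap")
    modal <- max(table(res)) / n
    if (modal >= params$flankFraction) "highly_conserved"
    else if (modal > params$conservedFraction) "conserved"
    else "nonconserved"
  }, character(1))
}

#' Select retained blocks from column classes
#'
#' Applies the curation rules in fixed order: (i) drop gap columns and any
#' non-conserved column adjacent to a gap column; (ii) reject every maximal
#' run of more than `maxContigNonconserved` consecutive non-conserved
#' columns; (iii) trim each candidate block (maximal run of surviving
#' columns, contiguous in original coordinates) so it starts and ends on
#' highly-conserved flank columns; (iv) discard blocks shorter than
#' `minBlockLen`. Deterministic; the result is idempotent under
#' re-filtering of the curated alignment.
#'
#' @param classes column labels from [classifyColumns()].
#' @param params a [blockFilterParams()] list.
#' @return a [BlockMask-class].
#' @export
selectBlocks <- function(classes, params = blockFilterParams()) {
  nc <- length(classes)
  keep <- rep(TRUE, nc)

  # (i) gap columns and adjacent non-conserved columns
  gaps <- which(classes == "gap")
  keep[gaps] <- FALSE
  for (g in gaps) {
    for (j in c(g - 1L, g + 1L)) {
      if (j >= 1L && j <= nc && classes[j] == "nonconserved")
        keep[j] <- FALSE
    }
  }

  # (ii) long runs of non-conserved columns
  if (nc > 0L) {
    r <- rle(classes == "nonconserved")
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] > params$maxContigNonconserved)
        keep[startIdx[k]:endIdx[k]] <- FALSE
    }
  }

  # (iii) flank trimming of candidate blocks, (iv) minimum block length
  kept <- integer()
  blocksStart <- integer(); blocksEnd <- integer()
  idx <- which(keep)
  if (length(idx)) {
    runBreak <- c(0L, which(diff(idx) > 1L), length(idx))
    for (k in seq_len(length(runBreak) - 1L)) {
      block <- idx[(runBreak[k] + 1L):runBreak[k + 1L]]
      hc <- classes[block] == "highly_conserved"
      if (!any(hc)) next
      block <- block[min(which(hc)):max(which(hc))]
      if (length(block) < params$minBlockLen) next
      kept <- c(kept, block)
      blocksStart <- c(blocksStart, block[1])
      blocksEnd <- c(blocksEnd, block[length(block)])
    }
  }
  methods::new("BlockMask", kept = as.integer(kept - 1L),
               blocks = IRanges::IRanges(start = blocksStart,
                                         end = blocksEnd),
               nColumns = as.integer(nc))
}

#' Apply a block mask to an alignment
#'
#' @param alignment equal-width [Biostrings::AAStringSet].
#' @param mask a [BlockMask-class].
#' @return column-subset alignment (order preserved).
#' @export
applyMask <- function(alignment, mask) {
  alignment <- asAlignment(alignment)
  nc <- Biostrings::width(alignment)[1]
  if (length(mask@kept) == 0L)
    stop("empty curated alignment", call. = FALSE)
  if (max(mask@kept) >= nc)
    stop("mask index out of range: ", max(mask@kept), " >= ", nc,
         call. = FALSE)
  m <- alignmentMatrix(alignment)[, mask@kept + 1L, drop = FALSE]
  out <- Biostrings::AAStringSet(apply(m, 1L, paste, collapse = ""))
  names(out) <- names(alignment)
  out
}

#' One-call alignment curation
#'
#' @inheritParams classifyColumns
#' @return list with `mask` (a [BlockMask-class]), `curated` (the
#'   column-subset alignment) and `classes` (the column labels).
#' @export
filterAlignment <- function(alignment, params = blockFilterParams()) {
  alignment <- asAlignment(alignment)
  classes <- classifyColumns(alignment, params)
  mask <- selectBlocks(classes, params)
  curated <- if (length(mask@kept)) applyMask(alignment, mask) else NULL
  list(mask = mask, curated = curated, classes = classes)
}

#' Write a block report
#'
#' Human-readable per-block report (1-based inclusive coordinates, the
#' customary display convention of curation reports).
#'
#' @param mask a [BlockMask-class].
#' @param path optional output path.
#' @return data.frame with columns `block`, `start`, `end`, `length`.
#' @export
blockReport <- function(mask, path = NULL) {
  out <- data.frame(block = seq_along(mask@blocks),
                    start = IRanges::start(mask@blocks),
                    end = IRanges::end(mask@blocks),
                    length = IRanges::width(mask@blocks))
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
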