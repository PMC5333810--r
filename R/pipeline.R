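## Orchestration: single-call pipeline stages mirrored by the command-line
## front end in inst/scripts/pax-pipeline.R. Every stage is a pure function
## of (inputs, parameters, seed); re-runs are byte-identical.

#' Run the classification stage
#'
#' Reads a protein FASTA, annotates domain architectures, classifies every
#' record and writes the annotation and reclassification tables.
#'
#' @param fastaIn path to an unaligned protein FASTA.
#' @param outDir output directory (created if needed).
#' @param profiles,registry see [annotateDomains()].
#' @param verbose log per-family counts with `message()`.
#' @return invisibly, a list with `annotations`, `calls`, `report` and the
#'   written `paths`.
#' @export
runClassify <- function(fastaIn, outDir, profiles = paxProfiles(),
                        registry = paxMotifRegistry(), verbose = TRUE) {
  seqs <- readProteinFasta(fastaIn)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  annPath <- file.path(outDir, "annotation.tsv")
  repPath <- file.path(outDir, "reclassification.tsv")
  if (length(seqs) == 0L) {
    writeAnnotationTable(list(), annPath)
    report <- batchReport(list(), path = repPath)
    if (verbose) message("no sequences in input; wrote header-only tables")
    return(invisible(list(annotations = list(), calls = list(),
                          report = report,
                          paths = c(annotation = annPath,
                                    reclassification = repPath))))
  }
  annotations <- annotateAll(seqs, profiles, registry)
  calls <- classifyAll(annotations)
  writeAnnotationTable(annotations, annPath)
  report <- batchReport(calls, path = repPath)
  if (verbose) {
    fams <- vapply(calls, function(x)
      if (is.na(x@family)) "no-PRD" else x@family, character(1))
    tab <- table(fams)
    message("classified ", length(calls), " record(s): ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  invisible(list(annotations = annotations, calls = calls, report = report,
                 paths = c(annotation = annPath, reclassification = repPath)))
}

writeAnnotationTable <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    if (!nrow(a@hits))
      return(data.frame(record = a@recordId, kind = "none",
                        name = NA_character_, start = NA_integer_,
                        end = NA_integer_, score = NA_real_,
                        complete = NA, stringsAsFactors = FALSE))
    data.frame(record = a@recordId, kind = a@hits$kind, name = a@hits$name,
               start = a@hits$start, end = a@hits$end,
               score = round(a@hits$score, 4), complete = a@hits$complete,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record = character(), kind = character(), name = character(),
               start = integer(), end = integer(), score = numeric(),
               complete = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Run the tree stage
#'
#' Curates an aligned FASTA with the block filter, builds the bootstrap NJ
#' tree, collapses weak branches and writes all intermediates (curated
#' alignment, kept-column mask, distances in square PHYLIP format, newick
#' tree and — when family calls are supplied — the monophyly report).
#'
#' @param alignedIn path to an aligned protein FASTA.
#' @param outDir output directory.
#' @param params a [blockFilterParams()] list.
#' @param nBootstrap,collapseThreshold,correction,gammaShape,seed see
#'   [bootstrapTree()].
#' @param calls optional family calls for [monophylyReport()] (named list of
#'   [FamilyCall-class] or data.frame `recordId`/`family`).
#' @return invisibly, list with `mask`, `curated`, `tree`, `monophyly` and
#'   `paths`.
#' @export
runTree <- function(alignedIn, outDir, params = blockFilterParams(),
                    nBootstrap = 100L, collapseThreshold = 50,
                    correction = "p", gammaShape = GAMMA_SHAPE_REFERENCE,
                    seed = 1L, calls = NULL) {
  alignment <- readProteinAlignment(alignedIn)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  filtered <- filterAlignment(alignment, params)
  if (is.null(filtered$curated))
    stop("empty curated alignment: no block survived filtering",
         call. = FALSE)
  paths <- c(curated = file.path(outDir, "curated.fasta"),
             mask = file.path(outDir, "mask.txt"),
             distances = file.path(outDir, "distances.phy"),
             tree = file.path(outDir, "tree.nwk"))
  writeProteinAlignment(filtered$curated, paths[["curated"]])
  writeLines(as.character(filtered$mask@kept), paths[["mask"]])
  d <- distanceMatrix(filtered$curated, correction, gammaShape)
  writePhylipDistances(d, paths[["distances"]])
  tree <- bootstrapTree(filtered$curated, nBootstrap = nBootstrap,
                        collapseThreshold = collapseThreshold,
                        correction = correction, gammaShape = gammaShape,
                        seed = seed)
  writeSupportTree(tree, paths[["tree"]])
  monophyly <- NULL
  if (!is.null(calls)) {
    monophyly <- monophylyReport(tree, calls)
    paths[["monophyly"]] <- file.path(outDir, "monophyly.tsv")
    write.table(monophyly, paths[["monophyly"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(mask = filtered$mask, curated = filtered$curated,
                 tree = tree, monophyly = monophyly, paths = paths))
}

#' Run the simulation stage
#'
#' @param outDir output directory.
#' @param config a [syntheticConfig()] list.
#' @return invisibly, list with `dataset` and `paths`.
#' @export
runSimulate <- function(outDir, config = syntheticConfig()) {
  dataset <- generateDataset(config)
  paths <- writeDataset(dataset, outDir)
  cfgPath <- file.path(outDir, "config.txt")
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, function(v) paste(v, collapse = ","),
                            character(1))), cfgPath)
  invisible(list(dataset = dataset,
                 paths = c(paths, config = cfgPath)))
}

#' Extract paired-domain subsequences as an alignment
#'
#' Convenience for the tree stage on synthetic or curated data: collects
#' the paired-domain subsequence of every annotation with a complete
#' paired-domain hit. Because paired-domain detection is ungapped against a
#' fixed-length model, the extracted subsequences are positionally
#' comparable and form a 128-column alignment directly.
#'
#' @param annotations list of [DomainAnnotation-class].
#' @return equal-width [Biostrings::AAStringSet] of complete paired
#'   domains.
#' @export
prdAlignmentFromAnnotations <- function(annotations) {
  keep <- Filter(function(a) {
    !is.na(a@prdSubsequence) &&
      any(a@hits$kind == "PRD" & a@hits$complete)
  }, annotations)
  if (length(keep) < 2L)
    stop("fewer than 2 complete paired domains found", call. = FALSE)
  seqs <- Biostrings::AAStringSet(
    setNames(vapply(keep, function(a) a@prdSubsequence, character(1)),
             vapply(keep, function(a) a@recordId, character(1))))
  asAlignment(seqs)
}
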