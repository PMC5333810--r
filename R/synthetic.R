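## Synthetic Pax-like proteins with planted architectures.
##
## The bundled per-family paired-domain consensus sequences are generated
## once from fixed internal seeds (so the package needs no downloads); they
## are synthetic stand-ins for real reference paired domains and are
## documented as such. Real references can be substituted via the profile
## arguments of the detection functions.

PAX_FAMILIES <- c("Pax1/9", "Pax2/5/8", "Pax3/7", "Pax4/6", "Paxβ", "PoxNeuro")
PAX_FAMILIES_ALL <- c(PAX_FAMILIES, "eyg")

PRD_LENGTH <- 128L
PAI_END <- 64L       # PAI = columns [0,64), RED = [64,128)
HD_LENGTH <- 60L

.lophopaxCache <- new.env(parent = emptyenv())

familyToken <- function(family) {
  map <- c("Pax1/9" = "Pax1-9", "Pax2/5/8" = "Pax2-5-8",
           "Pax3/7" = "Pax3-7", "Pax4/6" = "Pax4-6",
           "PoxNeuro" = "PoxN", "eyg" = "eyg")
  map[PAX_BETA] <- "PaxB"
  unname(map[family])
}

randomResidues <- function(n) sample(AA_LETTERS, n, replace = TRUE)

mutateResidues <- function(chars, positions) {
  for (p in positions) {
    chars[p] <- sample(setdiff(AA_LETTERS, chars[p]), 1L)
  }
  chars
}

#' Synthetic reference paired-domain consensus for a Pax family
#'
#' Deterministic, seeded 128-residue consensus sequences: one shared master
#' sequence diverged independently per family (about 8% substitutions each,
#' hence roughly 15% pairwise divergence between families; the eyegone
#' stand-in is diverged 25%). The PoxNeuro consensus carries the two
#' synthetic landmarks of that family: a tribasic KRK run inside the first
#' 20 columns (first PAI helix) and the KPKQVAT junction heptapeptide
#' written across the PAI/RED boundary (columns 61-68, 0-based).
#'
#' @param family one of the six lophotrochozoan families or `"eyg"`.
#' @return 128-residue amino-acid string.
#' @export
paxReferencePRD <- function(family) {
  if (!family %in% PAX_FAMILIES_ALL)
    stop("unknown family: ", family, call. = FALSE)
  key <- paste0("prd_", family)
  if (!is.null(.lophopaxCache[[key]])) return(.lophopaxCache[[key]])
  master <- withSeed(1009L, randomResidues(PRD_LENGTH))
  i <- match(family, PAX_FAMILIES_ALL)
  nMut <- if (family == "eyg") 32L else 10L
  cons <- withSeed(2000L + i, {
    pos <- sample.int(PRD_LENGTH, nMut)
    mutateResidues(master, pos)
  })
  if (family == "PoxNeuro") {
    cons[3:5] <- c("K", "R", "K")                 # tribasic, first helix
    cons[62:68] <- seqChars("KPKQVAT")            # PAI/RED junction zone
  }
  res <- paste(cons, collapse = "")
  .lophopaxCache[[key]] <- res
  res
}

#' Synthetic reference homeodomain consensus
#'
#' A 60-residue paired-type homeodomain stand-in: a seeded master with small
#' family-specific variants for Pax3/7 and Pax4/6.
#'
#' @param family `"generic"`, `"Pax3/7"` or `"Pax4/6"`.
#' @return 60-residue amino-acid string.
#' @export
paxReferenceHD <- function(family = "generic") {
  key <- paste0("hd_", family)
  if (!is.null(.lophopaxCache[[key]])) return(.lophopaxCache[[key]])
  master <- withSeed(1013L, randomResidues(HD_LENGTH))
  cons <- switch(family,
                 generic = master,
                 "Pax3/7" = withSeed(3001L,
                   mutateResidues(master, sample.int(HD_LENGTH, 2L))),
                 "Pax4/6" = withSeed(3002L,
                   mutateResidues(master, sample.int(HD_LENGTH, 2L))),
                 stop("unknown homeodomain variant: ", family, call. = FALSE))
  res <- paste(cons, collapse = "")
  .lophopaxCache[[key]] <- res
  res
}

# reference alignment: per-family consensus plus seeded diverged variants.
# The variant divergence (8%) sets the self-score spread that defaultMinScore
# turns into an acceptance threshold, so it must cover the within-family
# divergence the detector is expected to accept.
referenceVariants <- function(cons, nVariants, divergence, seedBase) {
  chars <- seqChars(cons)
  out <- list(cons)
  for (v in seq_len(nVariants)) {
    out[[v + 1L]] <- withSeed(seedBase + v, {
      nMut <- max(1L, round(divergence * length(chars)))
      paste(mutateResidues(chars, sample.int(length(chars), nMut)),
            collapse = "")
    })
  }
  unlist(out)
}

#' Bundled synthetic reference alignments
#'
#' `referencePRDAlignment()` returns a 128-column alignment of the seven
#' per-family paired-domain consensus sequences (six families plus the
#' divergent eyegone stand-in), each with three seeded 8%-diverged variants;
#' `referenceHDAlignment()` the analogous 60-column homeodomain set.
#'
#' @return equal-width [Biostrings::AAStringSet].
#' @export
referencePRDAlignment <- function() {
  if (!is.null(.lophopaxCache[["prd_aln"]])) return(.lophopaxCache[["prd_aln"]])
  seqs <- character(); ids <- character()
  for (i in seq_along(PAX_FAMILIES_ALL)) {
    fam <- PAX_FAMILIES_ALL[i]
    vs <- referenceVariants(paxReferencePRD(fam), 3L, 0.08, 4000L + 10L * i)
    seqs <- c(seqs, vs)
    ids <- c(ids, paste0(familyToken(fam), "_ref", seq_along(vs) - 1L))
  }
  aln <- Biostrings::AAStringSet(setNames(seqs, ids))
  .lophopaxCache[["prd_aln"]] <- aln
  aln
}

#' @rdname referencePRDAlignment
#' @export
referenceHDAlignment <- function() {
  if (!is.null(.lophopaxCache[["hd_aln"]])) return(.lophopaxCache[["hd_aln"]])
  seqs <- character(); ids <- character()
  fams <- c("generic", "Pax3/7", "Pax4/6")
  for (i in seq_along(fams)) {
    vs <- referenceVariants(paxReferenceHD(fams[i]), 3L, 0.08, 5000L + 10L * i)
    seqs <- c(seqs, vs)
    ids <- c(ids, paste0("HD_", gsub("/", "-", fams[i]), "_ref",
                         seq_along(vs) - 1L))
  }
  aln <- Biostrings::AAStringSet(setNames(seqs, ids))
  .lophopaxCache[["hd_aln"]] <- aln
  aln
}

#' Default domain profiles and acceptance thresholds
#'
#' Builds (and caches) the paired-domain and homeodomain
#' [PositionProfile-class] objects from the bundled synthetic reference
#' alignments, with data-driven acceptance thresholds from
#' [defaultMinScore()].
#'
#' @return list with elements `PRD`, `HD` (profiles) and `minScore` (named
#'   numeric vector).
#' @export
paxProfiles <- function() {
  if (!is.null(.lophopaxCache[["profiles"]])) return(.lophopaxCache[["profiles"]])
  prdAln <- referencePRDAlignment()
  hdAln <- referenceHDAlignment()
  prd <- buildProfile(prdAln, kind = "PRD")
  hd <- buildProfile(hdAln, kind = "HD")
  res <- list(PRD = prd, HD = hd,
              minScore = c(PRD = defaultMinScore(prd, prdAln),
                           HD = defaultMinScore(hd, hdAln)))
  .lophopaxCache[["profiles"]] <- res
  res
}

#' Architecture blueprint for a Pax family
#'
#' The ordered element list a synthetic protein of the given family is built
#' from: terminal extensions and linkers (length ranges, uniform residues),
#' the family paired-domain consensus, and the family's diagnostic motifs
#' (planted as seeded expansions of their consensus patterns). The Pax-beta
#' blueprint places its three conserved motifs in a long variable region
#' (>= 150 residues after the paired domain); the eyegone blueprint carries
#' a divergent paired domain plus a duplicated partial copy.
#'
#' @param family one of the six families or `"eyg"`.
#' @param linkerRange integer length-2 vector: default range for internal
#'   linkers.
#' @return list of element descriptors (fields `kind`, `label`, and one of
#'   `sequence`, `pattern`, `lenRange`, plus optional `prob`).
#' @export
familyTemplate <- function(family, linkerRange = c(10L, 40L)) {
  lnk <- function(lo, hi, label = "linker")
    list(kind = "linker", label = label, lenRange = c(lo, hi))
  prd <- function(fam) list(kind = "PRD", label = "PRD",
                            sequence = paxReferencePRD(fam))
  om <- function(pattern, prob = 1)
    list(kind = "OM", label = "OM", pattern = pattern, prob = prob)
  hd <- function(fam) list(kind = "HD", label = "HD",
                           sequence = paxReferenceHD(fam))
  motif <- function(name, pattern) list(kind = "MOTIF", label = name,
                                        pattern = pattern)
  nExt <- lnk(5L, 30L, "n_ext")
  cExt <- lnk(20L, 80L, "c_ext")
  lo <- linkerRange[1]; hi <- linkerRange[2]
  if (family == "Pax1/9") {
    list(nExt, prd(family), lnk(lo, hi), om("H[ST]V[ST][DN][IL]LG"), cExt)
  } else if (family == "Pax2/5/8") {
    list(nExt, prd(family), lnk(lo, hi), om("Y[TS]IX2ILG"), lnk(3L, 10L),
         list(kind = "SIGNAL", label = "basic_diacid", sequence = "KRKRDE"),
         cExt)
  } else if (family == "Pax3/7") {
    list(nExt, prd(family), lnk(lo, hi),
         om("H[ST]V[ST][DN][IL]LG", prob = 0.5),
         lnk(5L, 20L), hd(family), cExt)
  } else if (family == "Pax4/6") {
    list(nExt, prd(family), lnk(5L, 20L), motif("mdkl_linker", "MDKL"),
         lnk(5L, 20L), hd(family), cExt)
  } else if (family == PAX_BETA) {
    list(nExt, prd(family), lnk(40L, 80L),
         motif("paxbeta_m1", "YDY[NS]LPDRGL"), lnk(30L, 60L),
         motif("paxbeta_m2", "PLDLS"), lnk(30L, 60L),
         motif("paxbeta_m3",
               "Y[ED][RK]N[LVM]L[LI]FGD[SNQ]E[IVL]EI[MI]SVGKX[KR]W[IV][VI]RNEX[DE]L"),
         lnk(20L, 60L), cExt)
  } else if (family == "PoxNeuro") {
    list(nExt, prd(family), lnk(5L, 20L),
         motif("poxn_post_prd", "[VI]PGLSYP[KR][IL]V"), cExt)
  } else if (family == "eyg") {
    # duplicated configuration: a C-terminal partial copy of the divergent
    # paired domain (terminal, so truncated-domain scanning can see it)
    list(nExt, prd(family), lnk(10L, 30L),
         list(kind = "PRD_PARTIAL", label = "PRD_partial",
              sequence = substr(paxReferencePRD("eyg"), 1L, 80L)))
  } else stop("unknown family: ", family, call. = FALSE)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the conditions of a curated lophotrochozoan protein
#' collection: all six families, moderate within-family divergence (5%
#' point substitutions) and a substantial fraction of database fragments
#' (20% of records truncated inside the paired domain).
#'
#' @param families character vector of families to generate.
#' @param nPerFamily records per family.
#' @param mutationRate i.i.d. point-substitution probability in `[0,1)`.
#' @param fragmentProb probability that a record is truncated at a uniform
#'   position inside the paired domain.
#' @param linkerRange default internal linker length range.
#' @param seed integer seed; identical configurations produce byte-identical
#'   output.
#' @return list of class `paxSynthConfig`.
#' @export
syntheticConfig <- function(families = PAX_FAMILIES, nPerFamily = 5L,
                            mutationRate = 0.05, fragmentProb = 0.2,
                            linkerRange = c(10L, 40L), seed = 1L) {
  if (mutationRate < 0 || mutationRate >= 1)
    stop("mutationRate must be in [0,1)", call. = FALSE)
  if (fragmentProb < 0 || fragmentProb > 1)
    stop("fragmentProb must be in [0,1]", call. = FALSE)
  stopifnot(all(families %in% PAX_FAMILIES_ALL), nPerFamily >= 1L)
  structure(list(families = families, nPerFamily = as.integer(nPerFamily),
                 mutationRate = mutationRate, fragmentProb = fragmentProb,
                 linkerRange = as.integer(linkerRange),
                 seed = as.integer(seed)),
            class = "paxSynthConfig")
}

#' Generate a labeled synthetic Pax-like protein dataset
#'
#' Instantiates each family blueprint (class members of planted motifs
#' sampled uniformly, seeded), applies i.i.d. point substitutions at
#' `mutationRate` everywhere except a 2-residue guard at the ends of each
#' planted element, and truncates records to fragments with probability
#' `fragmentProb` at a uniform position inside the paired domain. Truth
#' rows (planted coordinates, 0-based half-open) are emitted in lockstep.
#'
#' @param config a [syntheticConfig()] list.
#' @return list with `sequences` (an [Biostrings::AAStringSet]; per-record
#'   `family` and `isFragment` in `mcols()`) and `truth` (data.frame with
#'   columns `recordId`, `family`, `kind`, `label`, `start`, `end`,
#'   `isFragment`).
#' @examples
#' d <- generateDataset(syntheticConfig(nPerFamily = 2, seed = 7))
#' length(d$sequences)  # 12
#' @export
generateDataset <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "paxSynthConfig"))
  set.seed(config$seed)
  seqs <- character(); ids <- character()
  fams <- character(); frags <- logical()
  truthRows <- list()
  for (family in config$families) {
    tpl <- familyTemplate(family, config$linkerRange)
    for (k in seq_len(config$nPerFamily)) {
      id <- sprintf("%s_%02d", familyToken(family), k)
      inst <- instantiateTemplate(tpl)
      chars <- inst$chars
      # guard: first/last 2 positions of each planted element stay unmutated
      guarded <- logical(length(chars))
      for (el in inst$elements) {
        if (el$kind == "linker") next
        lo <- el$start + 1L; hi <- el$end
        guarded[lo:min(lo + 1L, hi)] <- TRUE
        guarded[max(hi - 1L, lo):hi] <- TRUE
      }
      if (config$mutationRate > 0) {
        hitPos <- which(runif(length(chars)) < config$mutationRate & !guarded)
        chars <- mutateResidues(chars, hitPos)
      }
      isFrag <- runif(1) < config$fragmentProb
      elements <- inst$elements
      if (isFrag) {
        prdEl <- Filter(function(e) e$kind == "PRD", elements)[[1]]
        cut <- prdEl$start + sample.int(PRD_LENGTH - 1L, 1L)  # inside PRD
        chars <- chars[seq_len(cut)]
        elements <- lapply(Filter(function(e) e$start < cut, elements),
                           function(e) { e$end <- min(e$end, cut); e })
      }
      seqs <- c(seqs, paste(chars, collapse = ""))
      ids <- c(ids, id)
      fams <- c(fams, family)
      frags <- c(frags, isFrag)
      planted <- Filter(function(e) e$kind != "linker", elements)
      if (length(planted))
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          recordId = id, family = family,
          kind = vapply(planted, `[[`, "", "kind"),
          label = vapply(planted, `[[`, "", "label"),
          start = vapply(planted, function(e) e$start, integer(1)),
          end = vapply(planted, function(e) e$end, integer(1)),
          isFragment = isFrag, stringsAsFactors = FALSE)
    }
  }
  sequences <- Biostrings::AAStringSet(setNames(seqs, ids))
  S4Vectors::mcols(sequences) <- S4Vectors::DataFrame(
    species = rep("synthetic", length(sequences)),
    sourceAnnotation = fams, isFragment = frags, family = fams)
  list(sequences = sequences,
       truth = do.call(rbind, truthRows))
}

# sample one concrete protein from a blueprint; returns residue vector and
# realised element coordinates (0-based half-open)
instantiateTemplate <- function(tpl) {
  chars <- character()
  elements <- list()
  for (el in tpl) {
    if (!is.null(el$prob) && el$prob < 1 && runif(1) >= el$prob) next
    piece <- if (!is.null(el$sequence)) seqChars(el$sequence)
             else if (!is.null(el$pattern)) seqChars(expandPattern(el$pattern))
             else randomResidues(sample(seq(el$lenRange[1], el$lenRange[2]), 1L))
    start <- length(chars)
    chars <- c(chars, piece)
    elements[[length(elements) + 1L]] <-
      list(kind = el$kind, label = el$label,
           start = start, end = start + length(piece))
  }
  list(chars = chars, elements = elements)
}

#' Write a synthetic dataset to disk
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "sequences.fasta")
  tr <- file.path(dir, "truth.tsv")
  writeProteinFasta(dataset$sequences, fa)
  write.table(dataset$truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, truth = tr))
}
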