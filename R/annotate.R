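## Domain architecture annotation: paired domain first, then octapeptide and
## homeodomain downstream, then the family-diagnostic motifs and signals.

# search-zone constants (0-based paired-domain columns)
TRIBASIC_ZONE_LEN <- 20L      # first PAI helix lies in the PRD N-terminus
JUNCTION_SLACK <- 10L         # KPKQVAT searched +/- 10 columns around col 64
HD_PARTIAL_COVERAGE <- 0.5    # below this coverage an HD hit is "partial"
SIGNAL_ACID_SPAN <- 8L        # acid residues sought within 8 aa of run start

#' Annotate the Pax domain architecture of a protein
#'
#' Locates domains in the order the visual procedure uses them: the paired
#' domain first (best profile hit), then the octapeptide motif strictly
#' downstream of the paired domain, then the homeodomain downstream of the
#' octapeptide (or paired domain when no octapeptide is found). The
#' family-diagnostic motifs and basic-residue signals are scanned in their
#' respective zones and recorded as additional hits. A record is flagged as
#' a fragment when its paired-domain hit is incomplete or the sequence ends
#' inside a required domain.
#'
#' @param sequence amino-acid string, [Biostrings::AAString], or a named
#'   length-1 subset of an [Biostrings::AAStringSet].
#' @param recordId identifier used in the annotation (defaults to the
#'   sequence name, or `"seq"`).
#' @param profiles list with `PRD`, `HD` profiles and `minScore` vector, as
#'   returned by [paxProfiles()].
#' @param registry motif registry data.frame from [paxMotifRegistry()].
#' @return a [DomainAnnotation-class].
#' @export
annotateDomains <- function(sequence, recordId = NULL,
                            profiles = paxProfiles(),
                            registry = paxMotifRegistry()) {
  if (is(sequence, "AAStringSet")) {
    if (is.null(recordId)) recordId <- names(sequence)[1]
    sequence <- as.character(sequence[[1]])
  }
  sequence <- as.character(sequence)
  if (is.null(recordId)) recordId <- "seq"
  n <- nchar(sequence)
  hits <- emptyHits(); hits$coverage <- numeric()

  prdHits <- detectDomain(sequence, profiles$PRD, profiles$minScore[["PRD"]])
  prdHit <- NULL
  if (nrow(prdHits)) {
    best <- which.max(prdHits$score)
    prdHit <- prdHits[best, , drop = FALSE]
    hits <- rbind(hits, prdHits)   # keep secondary hits: eyg-style evidence
  }

  fragment <- FALSE
  prdSub <- NA_character_
  if (!is.null(prdHit)) {
    prdSub <- substr(sequence, prdHit$start + 1L, prdHit$end)
    if (!prdHit$complete) fragment <- TRUE
    downstream <- prdHit$end
  } else {
    downstream <- 0L
  }

  getPattern <- function(name) {
    row <- registry[registry$name == name, , drop = FALSE]
    if (!nrow(row)) stop("pattern not in registry: ", name, call. = FALSE)
    row
  }
  scanZone <- function(name, from, to = n, kindLabel = "MOTIF") {
    row <- getPattern(name)
    if (to - from < patternLength(row$parsed[[1]])) return(NULL)
    sub <- substr(sequence, from + 1L, to)
    h <- scanPattern(sub, row$parsed[[1]], row$maxMismatch)
    if (!nrow(h)) return(NULL)
    h$start <- h$start + from
    h$end <- h$end + from
    h$kind <- kindLabel
    h$name <- name
    h$coverage <- 1
    h
  }

  omHit <- NULL
  if (!is.null(prdHit)) {
    # octapeptide strictly downstream of the paired domain
    for (nm in c("octapeptide_pax19", "octapeptide_pax258")) {
      h <- scanZone(nm, downstream, kindLabel = "OM")
      if (!is.null(h)) {
        h <- h[1, , drop = FALSE]
        hits <- rbind(hits, h)
        if (is.null(omHit) || h$start < omHit$start) omHit <- h
      }
    }
  }

  hdHit <- NULL
  if (!is.null(prdHit)) {
    hdFrom <- if (!is.null(omHit)) omHit$end else downstream
    if (n - hdFrom >= ceiling(0.25 * length(profiles$HD))) {
      sub <- substr(sequence, hdFrom + 1L, n)
      hh <- detectDomain(sub, profiles$HD, profiles$minScore[["HD"]])
      if (nrow(hh)) {
        hh$start <- hh$start + hdFrom
        hh$end <- hh$end + hdFrom
        best <- which.max(hh$score)
        hdHit <- hh[best, , drop = FALSE]
        if (hdHit$coverage < HD_PARTIAL_COVERAGE) hdHit$kind <- "HD_partial"
        hits <- rbind(hits, hdHit)
        if (!hdHit$complete) fragment <- TRUE
      }
    }
  }

  if (!is.null(prdHit)) {
    # Pax4/6 linker: MDKL between the paired domain and the homeodomain
    mdklTo <- if (!is.null(hdHit)) hdHit$start else n
    h <- scanZone("mdkl_linker", downstream, mdklTo)
    if (!is.null(h)) hits <- rbind(hits, h[1, , drop = FALSE])
    # PoxNeuro post-domain motif
    h <- scanZone("poxn_post_prd", downstream)
    if (!is.null(h)) hits <- rbind(hits, h[1, , drop = FALSE])
    # PoxNeuro junction heptapeptide around the PAI/RED boundary
    jCentre <- prdHit$start + PAI_END
    jFrom <- max(prdHit$start, jCentre - JUNCTION_SLACK - 7L)
    jTo <- min(n, jCentre + JUNCTION_SLACK + 7L)
    h <- scanZone("poxn_junction", jFrom, jTo)
    if (!is.null(h)) {
      h <- h[abs(h$start - jCentre) <= JUNCTION_SLACK + 7L, , drop = FALSE]
      if (nrow(h)) hits <- rbind(hits, h[1, , drop = FALSE])
    }
    # tribasic signal in the first paired-domain helix
    triLen <- min(TRIBASIC_ZONE_LEN, n - prdHit$start)
    h <- findBasicSignal(sequence, prdHit$start, triLen, minBasic = 3L)
    if (nrow(h)) {
      h$name <- "tribasic_helix1"; h$coverage <- 1
      hits <- rbind(hits, h)
    }
    # quadribasic/diacid signal downstream (Pax2/5/8 after the octapeptide,
    # Pax-beta anywhere after the paired domain): the first basic run that
    # is followed by at least two acidic residues within a short span; basic
    # runs without the acidic tail (chance runs in linkers) are skipped
    sigFrom <- if (!is.null(omHit)) omHit$end else downstream
    while (n - sigFrom >= 4L) {
      h <- findBasicSignal(sequence, sigFrom, n - sigFrom, minBasic = 3L)
      if (!nrow(h)) break
      acidTo <- min(n, h$start + SIGNAL_ACID_SPAN)
      acids <- sum(seqChars(substr(sequence, h$start + 1L, acidTo)) %in%
                     ACIDIC_RESIDUES)
      if (acids >= 2L) {
        h$name <- "basic_diacid"; h$coverage <- 1
        hits <- rbind(hits, h)
        break
      }
      sigFrom <- h$start + 1L
    }
  }

  # Pax-beta motifs searched even without a paired domain (beta-like case)
  for (nm in c("paxbeta_m1", "paxbeta_m2", "paxbeta_m3")) {
    h <- scanZone(nm, downstream)
    if (!is.null(h)) hits <- rbind(hits, h[1, , drop = FALSE])
  }

  rownames(hits) <- NULL
  methods::new("DomainAnnotation", recordId = as.character(recordId),
               hits = hits, prdSubsequence = prdSub, fragment = fragment)
}

#' Annotate every record of a protein set
#'
#' @param sequences an [Biostrings::AAStringSet].
#' @inheritParams annotateDomains
#' @return list of [DomainAnnotation-class], named by record id.
#' @export
annotateAll <- function(sequences, profiles = paxProfiles(),
                        registry = paxMotifRegistry()) {
  out <- lapply(seq_along(sequences), function(i) {
    annotateDomains(as.character(sequences[[i]]), names(sequences)[i],
                    profiles, registry)
  })
  names(out) <- names(sequences)
  out
}
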