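## Family assignment from domain composition and diagnostic motifs.
##
## Evidence keys derived from a DomainAnnotation:
##   PRD            accepted paired-domain hit
##   HD             homeodomain hit covering >= 50% of the model
##   HD_PARTIAL     homeodomain hit below 50% coverage
##   OM_H / OM_Y    octapeptide of the Pax1/9 (H-) or Pax2/5/8 (Y-) type
##   MDKL           MDKL linker between paired domain and homeodomain
##   BETA1..BETA3   the three conserved Pax-beta motifs
##   POXN_JUNCTION  KPKQVAT in the PAI/RED junction zone
##   POXN_POST      [VI]PGLSYP[KR][IL]V after the paired domain
##   TRIBASIC_H1    tribasic run in the first paired-domain helix
##   BASIC_DIACID   basic run followed by acidic residues, downstream

#' The lophotrochozoan Pax architecture rule set
#'
#' Returns the deterministic family profiles used by [classifyFamily()]: the
#' six lophotrochozoan families plus the eyegone entry (which is never
#' auto-assigned; divergent/duplicated paired-domain candidates are only
#' flagged `"eyg?"`).
#'
#' * Pax1/9: paired domain + H-type octapeptide; homeodomain forbidden.
#' * Pax2/5/8: paired domain + Y-type octapeptide + basic/diacid signal;
#'   homeodomain forbidden (lophotrochozoan architecture).
#' * Pax3/7: paired domain + homeodomain; octapeptide optional.
#' * Pax4/6: paired domain + homeodomain + MDKL linker; octapeptide
#'   forbidden.
#' * Pax-beta: paired domain + at least 2 of the three conserved motifs;
#'   basic/quadriacid signal optional.
#' * PoxNeuro: paired domain with tribasic first-helix signal and junction
#'   insertion + post-domain motif; octapeptide and homeodomain forbidden.
#'
#' @return data.frame with list-columns `required`, `forbidden`, `optional`
#'   and fields `family`, `minRequired` (`NA` = all required keys;
#'   Pax-beta uses 2-of-3 for its motif group), `autoAssign`.
#' @export
paxRuleSet <- function() {
  rule <- function(family, required, forbidden = character(),
                   optional = character(), betaGroup = FALSE,
                   autoAssign = TRUE) {
    data.frame(family = family, autoAssign = autoAssign,
               betaGroup = betaGroup,
               required = I(list(required)), forbidden = I(list(forbidden)),
               optional = I(list(optional)), stringsAsFactors = FALSE)
  }
  rbind(
    rule("Pax1/9", c("PRD", "OM_H"), forbidden = "HD"),
    rule("Pax2/5/8", c("PRD", "OM_Y", "BASIC_DIACID"), forbidden = "HD"),
    rule("Pax3/7", c("PRD", "HD"), optional = c("OM_H", "OM_Y")),
    rule("Pax4/6", c("PRD", "HD", "MDKL"), forbidden = c("OM_H", "OM_Y")),
    rule(PAX_BETA, "PRD", optional = "BASIC_DIACID", betaGroup = TRUE),
    rule("PoxNeuro",
         c("PRD", "TRIBASIC_H1", "POXN_JUNCTION", "POXN_POST"),
         forbidden = c("OM_H", "OM_Y", "HD")),
    rule("eyg", "PRD", autoAssign = FALSE)
  )
}

# evidence table from an annotation's hits
deriveEvidence <- function(annotation) {
  h <- annotation@hits
  loc <- function(rows) {
    if (!nrow(rows)) return(NA_character_)
    sprintf("[%d,%d)", rows$start[1], rows$end[1])
  }
  key <- function(name, rows) data.frame(
    key = name, satisfied = nrow(rows) > 0L, location = loc(rows),
    stringsAsFactors = FALSE)
  prd <- h[h$kind == "PRD", , drop = FALSE]
  hd <- h[h$kind == "HD", , drop = FALSE]
  hdp <- h[h$kind == "HD_partial", , drop = FALSE]
  byName <- function(nm, kind = NULL) {
    rows <- h[h$name == nm, , drop = FALSE]
    if (!is.null(kind)) rows <- rows[rows$kind == kind, , drop = FALSE]
    rows
  }
  rbind(
    key("PRD", prd),
    key("HD", hd),
    key("HD_PARTIAL", hdp),
    key("OM_H", byName("octapeptide_pax19", "OM")),
    key("OM_Y", byName("octapeptide_pax258", "OM")),
    key("MDKL", byName("mdkl_linker")),
    key("BETA1", byName("paxbeta_m1")),
    key("BETA2", byName("paxbeta_m2")),
    key("BETA3", byName("paxbeta_m3")),
    key("POXN_JUNCTION", byName("poxn_junction")),
    key("POXN_POST", byName("poxn_post_prd")),
    key("TRIBASIC_H1", byName("tribasic_helix1")),
    key("BASIC_DIACID", byName("basic_diacid")))
}

#' Classify an annotated protein into a Pax family
#'
#' Applies the architecture rule set: the family whose required evidence is
#' fully satisfied with no forbidden evidence present wins; several fully
#' satisfied families are resolved by diagnostic score (number of satisfied
#' diagnostic keys), cleanly when the winner's evidence contains the
#' runner-up's and with a `"?"` decoration otherwise. With a paired domain
#' but no winning family the verdict is the indeterminate `"Pax"`. Without
#' any paired domain the call carries status `"no-PRD"` — unless at least
#' two Pax-beta motifs are present, which yields the `"Paxβlike"` call. A
#' winner on a fragment is reported with confidence `"weak"`. A duplicated
#' paired-domain configuration raises the `eygCandidate` flag (`"eyg?"`);
#' eyegone is never auto-assigned.
#'
#' @param annotation a [DomainAnnotation-class].
#' @param rules rule set from [paxRuleSet()].
#' @return a [FamilyCall-class].
#' @export
classifyFamily <- function(annotation, rules = paxRuleSet()) {
  stopifnot(is(annotation, "DomainAnnotation"))
  ev <- deriveEvidence(annotation)
  sat <- setNames(ev$satisfied, ev$key)
  betaCount <- sum(sat[c("BETA1", "BETA2", "BETA3")])
  hdForbidden <- sat[["HD"]] || sat[["HD_PARTIAL"]]
  satisfiedKey <- function(k) {
    if (k == "HD") return(sat[["HD"]] || sat[["HD_PARTIAL"]])
    sat[[k]]
  }
  eyg <- sum(annotation@hits$kind == "PRD") >= 2L

  newCall <- function(family, confidence, questionable = FALSE,
                      status = "ok", score = 0L) {
    methods::new("FamilyCall", recordId = annotation@recordId,
                 family = family, confidence = confidence,
                 fragment = annotation@fragment, questionable = questionable,
                 eygCandidate = eyg, status = status, evidence = ev,
                 score = as.integer(score))
  }

  if (!sat[["PRD"]]) {
    if (betaCount >= 2L)
      return(newCall(paste0(PAX_BETA, "like"), "weak", score = betaCount))
    return(newCall(NA_character_, "indeterminate", status = "no-PRD"))
  }

  candidates <- list()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (!r$autoAssign) next
    req <- r$required[[1]]; forb <- r$forbidden[[1]]; opt <- r$optional[[1]]
    forbHit <- any(vapply(forb, function(k) {
      if (k == "HD") hdForbidden else sat[[k]]
    }, logical(1)))
    if (forbHit) next
    reqOk <- all(vapply(req, satisfiedKey, logical(1)))
    if (r$betaGroup) reqOk <- reqOk && betaCount >= 2L
    if (!reqOk) next
    satKeys <- c(req[vapply(req, satisfiedKey, logical(1))],
                 opt[vapply(opt, function(k) sat[[k]], logical(1))])
    if (r$betaGroup)
      satKeys <- c(satKeys,
                   c("BETA1", "BETA2", "BETA3")[sat[c("BETA1", "BETA2", "BETA3")]])
    candidates[[length(candidates) + 1L]] <-
      list(family = r$family, keys = unique(satKeys),
           score = length(unique(satKeys)))
  }

  if (!length(candidates))
    return(newCall("Pax", "indeterminate"))

  scores <- vapply(candidates, `[[`, numeric(1), "score")
  best <- candidates[[which.max(scores)]]
  questionable <- FALSE
  if (length(candidates) > 1L) {
    others <- candidates[-which.max(scores)]
    contained <- vapply(others, function(c2)
      all(c2$keys %in% best$keys), logical(1))
    tied <- vapply(others, function(c2) c2$score >= best$score, logical(1))
    questionable <- any(!contained) || any(tied)
  }
  confidence <- if (annotation@fragment || questionable) "weak" else "strong"
  newCall(best$family, confidence, questionable = questionable,
          score = best$score)
}

#' Classify every annotation in a list
#'
#' @param annotations list of [DomainAnnotation-class] (from
#'   [annotateAll()]).
#' @inheritParams classifyFamily
#' @return named list of [FamilyCall-class].
#' @export
classifyAll <- function(annotations, rules = paxRuleSet()) {
  out <- lapply(annotations, classifyFamily, rules = rules)
  names(out) <- vapply(annotations, function(a) a@recordId, character(1))
  out
}

#' Reclassification report from family calls
#'
#' Produces (and optionally writes) the five-column reclassification table:
#' accession, submitted name, proposed name (with `"?"` and `"(f)"`
#' decorations), species and classification. Submitted names, species and
#' classification default to metadata columns if provided.
#'
#' @param calls list of [FamilyCall-class].
#' @param metadata optional data.frame keyed by `accession` with columns
#'   among `submittedName`, `species`, `classification`.
#' @param path optional output TSV path; the header is written even for an
#'   empty call list.
#' @return data.frame with the five reporting columns.
#' @export
batchReport <- function(calls, metadata = NULL, path = NULL) {
  rows <- lapply(calls, function(call) {
    data.frame(Accession = call@recordId,
               `Submitted name` = call@recordId,
               `Proposed name` = if (is.na(call@family)) "no-PRD"
                                 else proposedName(call),
               Species = NA_character_,
               Classification = NA_character_,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    setNames(data.frame(matrix(character(), ncol = 5L),
                        stringsAsFactors = FALSE), RECLASS_HEADER)
  if (!is.null(metadata) && nrow(out)) {
    m <- match(out$Accession, metadata$accession)
    for (col in c("submittedName", "species", "classification")) {
      if (col %in% names(metadata)) {
        target <- c(submittedName = "Submitted name", species = "Species",
                    classification = "Classification")[[col]]
        ok <- !is.na(m)
        out[[target]][ok] <- metadata[[col]][m[ok]]
      }
    }
  }
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
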