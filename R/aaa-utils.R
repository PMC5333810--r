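#' @import methods
#' @importFrom stats sd setNames runif rbinom
#' @importFrom utils read.delim write.table head tail
NULL

# canonical residue alphabet; 'X' (unknown) is legal in sequences but is not
# part of profile/identity scoring
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_WITH_X <- c(AA_LETTERS, "X")
BASIC_RESIDUES <- c("K", "R")
ACIDIC_RESIDUES <- c("D", "E")

PAX_BETA <- "Paxβ"

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so deterministic internals (reference sequence
#' generation, bootstrap resampling) never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# split a sequence string into a character vector of residues
seqChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

assertScalarNumber <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single number >= %s", name, min), call. = FALSE)
  invisible(x)
}

# empty hits table shared by the scanners and the domain detector
emptyHits <- function() {
  data.frame(kind = character(), name = character(),
             start = integer(), end = integer(),
             score = numeric(), mismatches = integer(),
             complete = logical(), stringsAsFactors = FALSE)
}
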