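#' @useDynLib transfree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qchisq rbinom runif
#' @importFrom utils write.table read.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `code`, and
#' restores the state so generator calls are pure functions of their
#' arguments and never perturb the session RNG.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' @noRd
assert_dna <- function(x, what = "sequence") {
  if (grepl("[^ACGT]", x)) {
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  }
  invisible(x)
}

#' @noRd
seq_substr <- function(seq, start, end) substring(seq, start, end)
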