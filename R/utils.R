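# Internal helpers shared across modules.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement matchPattern
#'   vcountPattern pairwiseAlignment nucleotideSubstitutionMatrix pattern subject
#'   alignedPattern alignedSubject nmatch oligonucleotideFrequency writeXStringSet
#'   readDNAStringSet IUPAC_CODE_MAP
#' @importFrom BiocGenerics start end width score
#' @importMethodsFrom Biostrings nchar
#' @importFrom stats prcomp hclust cutree dist binom.test chisq.test rnorm runif
#'   predict
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run code with a private RNG state so simulations are reproducible without
# clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# IUPAC-aware per-position mismatch count between a degenerate pattern and a
# plain DNA window of the same length.
iupac_mismatch <- function(pattern_chars, window_chars) {
  stopifnot(length(pattern_chars) == length(window_chars))
  sets <- strsplit(IUPAC_CODE_MAP[pattern_chars], "", fixed = TRUE)
  sum(!mapply(function(s, b) b %in% s, sets, window_chars))
}

# 0-based half-open interval formatting used across digestion outputs.
check_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
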