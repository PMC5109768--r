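# In-silico XmnI digestion and the four-stage read filter cascade.

#' Filter cascade configuration
#'
#' @param reference Reference alpha satellite sequence (DNA string) used by
#'   the similarity filter and for reorientation. Required.
#' @param min_mean_quality Minimum mean Phred score.
#' @param monomer_len,dimer_len Inclusive length windows per band.
#' @param min_hit_len_monomer,min_hit_len_dimer Minimum local-alignment
#'   read-span against the reference.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(reference, min_mean_quality = 25,
                          monomer_len = c(162, 182), dimer_len = c(324, 364),
                          min_hit_len_monomer = 80, min_hit_len_dimer = 160) {
  check_scalar_string(reference, "reference")
  stopifnot(length(monomer_len) == 2L, length(dimer_len) == 2L,
            monomer_len[1] <= monomer_len[2], dimer_len[1] <= dimer_len[2],
            min_hit_len_monomer <= monomer_len[2],
            min_hit_len_dimer <= dimer_len[2])
  structure(list(reference = toupper(reference),
                 min_mean_quality = min_mean_quality,
                 monomer_len = monomer_len, dimer_len = dimer_len,
                 min_hit_len_monomer = min_hit_len_monomer,
                 min_hit_len_dimer = min_hit_len_dimer),
            class = "filter_config")
}

#' In-silico restriction digestion
#'
#' Cuts a sequence at every occurrence of the (degenerate) site pattern,
#' bluntly at the pattern midpoint (`GAANN^NNTTC` for XmnI). The pattern is
#' matched on the given strand only; the XmnI site is palindromic by
#' degeneracy so a single-strand scan suffices. A sequence without a site
#' yields a single fragment.
#'
#' @param genome DNA string.
#' @param site_pattern IUPAC site pattern.
#' @param cut_offset Cut position within the pattern (bases from its start).
#' @return data.frame of fragments with 0-based half-open `start`, `end`
#'   and `bases`, in 5' to 3' order.
#' @export
restriction_digest <- function(genome, site_pattern = XMNI_SITE,
                               cut_offset = XMNI_CUT_OFFSET) {
  check_scalar_string(genome, "genome")
  g <- DNAString(genome)
  m <- matchPattern(DNAString(site_pattern), g, fixed = FALSE)
  cuts <- sort(unique(start(m) - 1L + cut_offset))
  cuts <- cuts[cuts > 0 & cuts < length(g)]
  bounds <- c(0L, cuts, length(g))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  data.frame(start = starts, end = ends,
             bases = substring(genome, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

# Merge adjacent fragments where the internal cut is dropped
# (keep_cut[i] = FALSE merges fragments i and i+1).
.merge_fragments <- function(frags, keep_cut) {
  grp <- cumsum(c(TRUE, keep_cut))
  starts <- tapply(frags$start, grp, min)
  ends <- tapply(frags$end, grp, max)
  bases <- tapply(frags$bases, grp, paste, collapse = "")
  data.frame(start = as.integer(starts), end = as.integer(ends),
             bases = as.character(bases), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Quality filter
#'
#' Pass iff the mean Phred score is at least the threshold. Reads without
#' qualities (FASTA input) pass with a notice; empty reads fail.
#'
#' @param reads data.frame with `bases` and a `quals` list-column (or NULL
#'   entries).
#' @param min_mean_quality Threshold (default 25).
#' @return Logical vector.
#' @export
quality_filter <- function(reads, min_mean_quality = 25) {
  n <- nrow(reads)
  if (is.null(reads$quals)) {
    message("reads carry no qualities; quality filter passes all")
    return(nchar(reads$bases) > 0L)
  }
  vapply(seq_len(n), function(i) {
    q <- reads$quals[[i]]
    if (nchar(reads$bases[i]) == 0L) return(FALSE)
    if (is.null(q) || length(q) == 0L) return(TRUE)
    mean(q) >= min_mean_quality
  }, FALSE)
}

#' Extremity filter
#'
#' Pass iff the read carries the XmnI digested half-sites at both ends:
#' `TTC` at positions 3-5 and `GAA` at positions (n-4)-(n-2)
#' (`5'-NNTTC ... GAANN-3'`). The check is orientation-symmetric because
#' the reverse complement of `NNTTC...GAANN` has the same shape. Reads
#' shorter than 10 bases fail.
#'
#' @param reads data.frame with `bases` (or a character vector).
#' @return Logical vector.
#' @export
extremity_filter <- function(reads) {
  bases <- if (is.data.frame(reads)) reads$bases else reads
  n <- nchar(bases)
  n >= 10L &
    substr(bases, 3L, 5L) == "TTC" &
    substr(bases, n - 4L, n - 2L) == "GAA"
}

#' Length filter
#'
#' Pass iff the read length lies in the inclusive band window.
#'
#' @param reads data.frame with `bases` (or a character vector).
#' @param band `"monomer"` or `"dimer"`.
#' @param config A [filter_config()] (only the windows are used).
#' @return Logical vector.
#' @export
length_filter <- function(reads, band = c("monomer", "dimer"),
                          config = NULL) {
  band <- match.arg(band)
  win <- if (band == "monomer") {
    if (is.null(config)) c(162, 182) else config$monomer_len
  } else {
    if (is.null(config)) c(324, 364) else config$dimer_len
  }
  bases <- if (is.data.frame(reads)) reads$bases else reads
  nchar(bases) >= win[1] & nchar(bases) <= win[2]
}

# Local alignment of a set of reads against a subject; returns per-read
# score and aligned read-span (number of read positions inside the local
# alignment). BLASTN-like scoring: match +2, mismatch -3, open -5, extend -2.
.local_span <- function(reads, subject) {
  if (length(reads) == 0L) {
    return(list(score = numeric(0), span = integer(0)))
  }
  mat <- nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  pa <- pairwiseAlignment(DNAStringSet(reads), DNAString(subject),
                          type = "local", substitutionMatrix = mat,
                          gapOpening = 5, gapExtension = 2)
  ap <- pattern(pa)
  list(score = Biostrings::score(pa),
       span = Biostrings::end(ap) - Biostrings::start(ap) + 1L)
}

#' Similarity filter and reorientation
#'
#' Locally aligns each read and its reverse complement against the
#' reference (against two concatenated reference copies for the dimer
#' band). A read passes iff the best alignment covers at least
#' `min_hit_len` read bases; passing reads are returned in the reference
#' orientation with their original orientation recorded.
#'
#' @param reads data.frame with `bases` (or a character vector).
#' @param config A [filter_config()].
#' @param band `"monomer"` or `"dimer"`.
#' @return data.frame: `pass`, `bases` (oriented), `orientation_observed`.
#' @export
similarity_filter_and_orient <- function(reads, config,
                                         band = c("monomer", "dimer")) {
  band <- match.arg(band)
  bases <- if (is.data.frame(reads)) reads$bases else reads
  subject <- if (band == "dimer") {
    paste0(config$reference, config$reference)
  } else config$reference
  min_hit <- if (band == "dimer") config$min_hit_len_dimer else
    config$min_hit_len_monomer
  fwd <- .local_span(bases, subject)
  rev_bases <- if (length(bases)) revcomp(bases) else character(0)
  rev <- .local_span(rev_bases, subject)
  use_rev <- rev$score > fwd$score
  span <- ifelse(use_rev, rev$span, fwd$span)
  data.frame(
    pass = span >= min_hit,
    bases = ifelse(use_rev, rev_bases, bases),
    orientation_observed = ifelse(use_rev, "reverse", "forward"),
    stringsAsFactors = FALSE)
}

#' Run the four-stage filter cascade
#'
#' Applies quality, extremity, length and similarity filters in that order
#' and reports the survivor count after each stage.
#'
#' @param reads data.frame with `id`, `bases` and optionally `quals`.
#' @param config A [filter_config()].
#' @param band `"monomer"` or `"dimer"`.
#' @return List of class `filter_result`: `records` (data.frame id, bases
#'   oriented to the reference, orientation_observed, source) and `report`
#'   (data.frame stage, count).
#' @export
run_filter_cascade <- function(reads, config, band = c("monomer", "dimer")) {
  band <- match.arg(band)
  stopifnot(inherits(config, "filter_config"))
  if (is.null(reads$id)) reads$id <- sprintf("read%05d", seq_len(nrow(reads)))
  counts <- c(input = nrow(reads))
  reads <- reads[quality_filter(reads, config$min_mean_quality), ,
                 drop = FALSE]
  counts["quality"] <- nrow(reads)
  reads <- reads[extremity_filter(reads), , drop = FALSE]
  counts["extremity"] <- nrow(reads)
  reads <- reads[length_filter(reads, band, config), , drop = FALSE]
  counts["length"] <- nrow(reads)
  sim <- similarity_filter_and_orient(reads, config, band)
  records <- data.frame(
    id = reads$id[sim$pass],
    bases = sim$bases[sim$pass],
    orientation_observed = sim$orientation_observed[sim$pass],
    source = if (band == "monomer") "monomer_band" else "dimer",
    stringsAsFactors = FALSE)
  counts["similarity"] <- nrow(records)
  structure(list(records = records,
                 report = data.frame(stage = names(counts),
                                     count = as.integer(counts),
                                     stringsAsFactors = FALSE)),
            class = "filter_result")
}
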