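# Splitting dimer-band sequences into paired left and right monomers.

#' Find the internal XmnI site of a dimer
#'
#' Scans an oriented dimer for XmnI sites whose blunt-cut midpoint lies
#' within `window_halfwidth` bases of the sequence center and returns the
#' cut position closest to the center (leftmost on ties, with a notice),
#' or `NA` when no such site exists.
#'
#' @param bases Oriented dimer sequence.
#' @param window_halfwidth Half-width of the central window (default 30).
#' @return Integer split position (number of bases in the left monomer) or
#'   `NA_integer_`.
#' @export
find_internal_site <- function(bases, window_halfwidth = 30) {
  check_scalar_string(bases, "bases")
  L <- nchar(bases)
  m <- matchPattern(DNAString(XMNI_SITE), DNAString(bases), fixed = FALSE)
  if (length(m) == 0L) return(NA_integer_)
  mid <- start(m) - 1L + XMNI_CUT_OFFSET  # 0-based cut boundary
  d <- abs(mid - L / 2)
  ok <- d <= window_halfwidth
  if (!any(ok)) return(NA_integer_)
  mid <- mid[ok]; d <- d[ok]
  best <- which(d == min(d))
  if (length(best) > 1L) {
    message("multiple equally central XmnI sites; keeping the leftmost")
  }
  as.integer(mid[min(best)])
}

# Needleman-Wunsch of a read against a subject with +1/-1 match/mismatch and
# linear gap -2; returns the alignment object.
.nw_align <- function(read, subject) {
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pairwiseAlignment(DNAStringSet(read), DNAString(subject), type = "global",
                    substitutionMatrix = mat, gapOpening = 0,
                    gapExtension = 2)
}

#' Split a site-less dimer by alignment to a doubled reference
#'
#' Globally aligns the dimer against two concatenated copies of the
#' reference and splits it at the read position aligned to the reference
#' junction. If the junction falls inside a read gap, the split is placed
#' at the first read base aligned at or after the junction (so deletions
#' accrue to the left monomer).
#'
#' @param bases Oriented dimer sequence without a central XmnI site.
#' @param reference Monomer reference sequence (single copy).
#' @return Integer split position, or `NA_integer_` if the alignment is
#'   degenerate.
#' @export
split_by_alignment <- function(bases, reference) {
  check_scalar_string(bases, "bases")
  check_scalar_string(reference, "reference")
  L <- nchar(reference)
  pa <- .nw_align(bases, paste0(reference, reference))
  ap <- seq_chars(as.character(alignedPattern(pa)[[1]]))
  as_ <- seq_chars(as.character(alignedSubject(pa)[[1]]))
  if (all(ap == "-") || all(as_ == "-")) return(NA_integer_)
  sub_done <- cumsum(as_ != "-")
  pat_done <- cumsum(ap != "-")
  cols <- which(sub_done >= L)
  if (length(cols) == 0L) return(NA_integer_)
  j <- cols[1]  # column holding the last base of the first reference copy
  # advance past read-gap columns so the split lands on a read base boundary
  split <- pat_done[j]
  if (split <= 0L || split >= nchar(bases)) return(NA_integer_)
  as.integer(split)
}

#' Split dimers into paired left/right monomers
#'
#' Partitions oriented dimers into the X dataset (intact central XmnI site,
#' split at the site) and the noX dataset (split by alignment against a
#' doubled reference). Pairs where either monomer falls outside the length
#' range are discarded but reported.
#'
#' @param dimers data.frame with `id` and oriented `bases` (and optionally
#'   `orientation_observed`).
#' @param reference Monomer reference sequence.
#' @param len_range Inclusive monomer length window (default 162-182).
#' @param window_halfwidth Passed to [find_internal_site()].
#' @return List of class `dimer_pairs`: `pairs` (data.frame dimer_id,
#'   dataset, split_pos, left_len, right_len, kept), and `monomers`
#'   (data.frame of retained monomer records: id, bases, source, partner_id,
#'   dataset, orientation_observed).
#' @export
build_pairs <- function(dimers, reference, len_range = c(162, 182),
                        window_halfwidth = 30) {
  n <- nrow(dimers)
  if (is.null(n) || n == 0L) {
    empty <- data.frame(dimer_id = character(0), dataset = character(0),
                        split_pos = integer(0), left_len = integer(0),
                        right_len = integer(0), kept = logical(0),
                        stringsAsFactors = FALSE)
    return(structure(list(pairs = empty,
                          monomers = data.frame(id = character(0),
                                                bases = character(0),
                                                source = character(0),
                                                partner_id = character(0),
                                                dataset = character(0),
                                                orientation_observed = character(0),
                                                stringsAsFactors = FALSE)),
                     class = "dimer_pairs"))
  }
  oo <- if (!is.null(dimers$orientation_observed)) {
    dimers$orientation_observed
  } else rep("unset", n)
  pairs <- vector("list", n)
  mono <- vector("list", n)
  for (i in seq_len(n)) {
    b <- dimers$bases[i]
    split <- find_internal_site(b, window_halfwidth)
    dataset <- if (!is.na(split)) "X" else "noX"
    if (is.na(split)) split <- split_by_alignment(b, reference)
    if (is.na(split)) {
      pairs[[i]] <- data.frame(dimer_id = dimers$id[i], dataset = "unsplit",
                               split_pos = NA_integer_, left_len = NA_integer_,
                               right_len = NA_integer_, kept = FALSE,
                               stringsAsFactors = FALSE)
      next
    }
    left <- substr(b, 1L, split)
    right <- substr(b, split + 1L, nchar(b))
    ll <- nchar(left); rl <- nchar(right)
    kept <- ll >= len_range[1] && ll <= len_range[2] &&
      rl >= len_range[1] && rl <= len_range[2]
    pairs[[i]] <- data.frame(dimer_id = dimers$id[i], dataset = dataset,
                             split_pos = split, left_len = ll,
                             right_len = rl, kept = kept,
                             stringsAsFactors = FALSE)
    if (kept) {
      lid <- paste0(dimers$id[i], "_L")
      rid <- paste0(dimers$id[i], "_R")
      mono[[i]] <- data.frame(
        id = c(lid, rid), bases = c(left, right),
        source = c("dimer_left", "dimer_right"),
        partner_id = c(rid, lid), dataset = dataset,
        orientation_observed = oo[i], stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = do.call(rbind, pairs),
                 monomers = do.call(rbind, mono[!vapply(mono, is.null, TRUE)])),
            class = "dimer_pairs")
}
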