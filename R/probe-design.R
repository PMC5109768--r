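# Family-discriminating oligonucleotide probe selection by exact and
# one-mismatch binding frequencies.

#' Probe design configuration
#'
#' Selection thresholds: a probe is specific when strictly more than
#' `min_target_freq` of the target family's members and strictly fewer
#' than `max_offtarget_freq` of every other family's members carry its
#' hybridization target, optionally at both 0 and 1 mismatches.
#'
#' @param min_target_freq Strict lower bound on target binding (default 0.20).
#' @param max_offtarget_freq Strict upper bound off-target (default 0.03).
#' @param min_gc Minimum number of G/C pairs the probe forms (default 7).
#' @param apply_criteria_to_1mm Apply the thresholds at 1 mismatch too.
#' @return An object of class `probe_design_config`.
#' @export
probe_design_config <- function(min_target_freq = 0.20,
                                max_offtarget_freq = 0.03, min_gc = 7,
                                apply_criteria_to_1mm = TRUE) {
  check_probability(min_target_freq, "min_target_freq")
  check_probability(max_offtarget_freq, "max_offtarget_freq")
  structure(list(min_target_freq = min_target_freq,
                 max_offtarget_freq = max_offtarget_freq,
                 min_gc = min_gc,
                 apply_criteria_to_1mm = isTRUE(apply_criteria_to_1mm)),
            class = "probe_design_config")
}

#' Predicted binding frequency of a probe against a family
#'
#' Fraction of members that contain, on either strand, a window within
#' Hamming distance `max_mismatch` of the probe's hybridization target
#' (the probe's reverse complement). No indels are allowed in the window
#' comparison.
#'
#' @param probe Probe sequence (DNA string, written 5' to 3').
#' @param members Character vector of family member sequences.
#' @param max_mismatch 0 or 1.
#' @return Fraction in [0, 1].
#' @export
binding_frequency <- function(probe, members, max_mismatch = 0) {
  if (length(members) == 0L) stop("empty member set", call. = FALSE)
  check_scalar_string(probe, "probe")
  target <- revcomp(toupper(probe))
  ss <- DNAStringSet(members)
  fwd <- vcountPattern(target, ss, max.mismatch = max_mismatch,
                       with.indels = FALSE, fixed = TRUE)
  rev <- vcountPattern(target, reverseComplement(ss),
                       max.mismatch = max_mismatch, with.indels = FALSE,
                       fixed = TRUE)
  mean(fwd + rev > 0)
}

.gc_count <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) sum(ch %in% c("G", "C")), 0L)
}

#' Enumerate and score family-discriminating probe candidates
#'
#' Candidate windows are all N-free 18-mers of the target family's
#' consensus. A window forming fewer than `min_gc` G/C pairs is re-derived
#' as a 19-mer by extending one base into the consensus, preferring the
#' direction that adds a G/C pair (the 3' direction on ties). Each
#' candidate is scored by [binding_frequency()] against every family at 0
#' and 1 mismatches and marked specific per the configuration thresholds
#' (strict inequalities).
#'
#' @param consensus Consensus string of the target family.
#' @param members_by_family Named list of character vectors of member
#'   sequences (must include `target_family`).
#' @param target_family Name of the family the probes should target.
#' @param config A [probe_design_config()].
#' @return data.frame of class `probe_candidates`: `probe`, `start`
#'   (1-based position on the consensus), `length`, `gc_pairs`,
#'   `freq_exact_*` and `freq_1mm_*` per family, `specific`, `lna`.
#' @export
enumerate_candidates <- function(consensus, members_by_family, target_family,
                                 config = probe_design_config()) {
  stopifnot(target_family %in% names(members_by_family))
  L <- nchar(consensus)
  if (L < 18L) stop("consensus shorter than 18 bases", call. = FALSE)
  cand <- list()
  seen <- character(0)
  for (s in seq_len(L - 17L)) {
    w <- substr(consensus, s, s + 17L)
    if (grepl("[^ACGT]", w)) next
    start <- s
    if (.gc_count(w) < config$min_gc) {
      leftb <- if (s > 1L) substr(consensus, s - 1L, s - 1L) else ""
      rightb <- if (s + 18L <= L) substr(consensus, s + 18L, s + 18L) else ""
      left_ok <- leftb %in% DNA_BASES
      right_ok <- rightb %in% DNA_BASES
      pick_left <- left_ok && leftb %in% c("G", "C") &&
        !(right_ok && rightb %in% c("G", "C"))
      if (pick_left) {
        w <- paste0(leftb, w); start <- s - 1L
      } else if (right_ok) {
        w <- paste0(w, rightb)
      } else if (left_ok) {
        w <- paste0(leftb, w); start <- s - 1L
      } else next
    }
    if (w %in% seen) next
    seen <- c(seen, w)
    cand[[length(cand) + 1L]] <- list(window = w, start = start)
  }
  if (length(cand) == 0L) {
    message("no probe candidate could be derived from the consensus")
    return(structure(data.frame(), class = c("probe_candidates",
                                             "data.frame")))
  }
  fams <- names(members_by_family)
  rows <- lapply(cand, function(cd) {
    # the probe is the reverse complement of the consensus window, so that
    # its hybridization target IS the window
    probe <- revcomp(cd$window)
    f0 <- vapply(fams, function(f)
      binding_frequency(probe, members_by_family[[f]], 0), 0)
    f1 <- vapply(fams, function(f)
      binding_frequency(probe, members_by_family[[f]], 1), 0)
    others <- setdiff(fams, target_family)
    ok <- .gc_count(probe) >= config$min_gc &&
      f0[target_family] > config$min_target_freq &&
      all(f0[others] < config$max_offtarget_freq)
    if (ok && config$apply_criteria_to_1mm) {
      ok <- f1[target_family] > config$min_target_freq &&
        all(f1[others] < config$max_offtarget_freq)
    }
    row <- data.frame(probe = probe, start = cd$start,
                      length = nchar(probe),
                      gc_pairs = .gc_count(probe),
                      stringsAsFactors = FALSE)
    for (f in fams) row[[paste0("freq_exact_", f)]] <- unname(f0[f])
    for (f in fams) row[[paste0("freq_1mm_", f)]] <- unname(f1[f])
    row$specific <- ok
    row$lna <- lna_annotate(probe)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("probe_candidates", "data.frame")
  out
}

#' Annotate LNA positions in a probe
#'
#' Marks every second position starting at position 2 from the 5' end as a
#' locked nucleic acid (lowercase), the package's default alternating
#' placement convention. The annotation is presentation metadata only and
#' has no effect on binding computations.
#'
#' @param probe Probe sequence, 18 or 19 nt.
#' @return Mixed-case string (lowercase = LNA).
#' @export
lna_annotate <- function(probe) {
  check_scalar_string(probe, "probe")
  if (!nchar(probe) %in% c(18L, 19L)) {
    stop("probe must be 18 or 19 nt", call. = FALSE)
  }
  ch <- seq_chars(toupper(probe))
  idx <- seq(2L, length(ch), by = 2L)
  ch[idx] <- tolower(ch[idx])
  paste(ch, collapse = "")
}

#' Positions of LNA modifications in an annotated probe string
#'
#' @param annotated Mixed-case probe string (lowercase = LNA).
#' @return Integer vector of 1-based LNA positions.
#' @export
lna_positions <- function(annotated) {
  check_scalar_string(annotated, "annotated")
  which(seq_chars(annotated) %in% letters)
}
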