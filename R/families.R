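# Built-in synthetic alpha satellite family consensuses and motif constants.

#' XmnI recognition site
#'
#' Degenerate recognition pattern of the XmnI restriction endonuclease,
#' `GAANNNNTTC`, which cuts bluntly between the two central N positions
#' (`GAANN^NNTTC`).
#' @export
XMNI_SITE <- "GAANNNNTTC"

# Offset (in bases from the pattern start) of the blunt cut.
XMNI_CUT_OFFSET <- 5L

#' Centromere protein binding motifs
#'
#' Degenerate IUPAC patterns for the CENP-B box and the pJalpha box, the two
#' protein-binding motifs classically searched for in alpha satellite
#' monomers (with up to 2 mismatches allowed).
#' @export
CENPB_BOX <- "TTCGTTGGAARCGGGA"

#' @rdname CENPB_BOX
#' @export
PJALPHA_BOX <- "TTCCTTTTYCACCRTAG"

# Synthetic 172-bp family consensuses. These are generated sequences (not
# biological accessions): AT-rich, with exactly one XmnI site occupying
# positions 1-10 so that tandem arrays digest into phase-rotated monomers,
# and a pJalpha box at positions 121-137 (disrupted in the third family).
# The second family differs from the first at exactly 9 positions; the third
# and fourth differ from the first at 25 positions each.
SYNTHETIC_CONSENSUS <- c(
  C1 = "GAACATTTTCAAAGATGTTTCAAGTAGACCGTTCTAGATAAGGAGTTAAATCGAAGCTCATTCGCACATATTAAACTCTCTTTTGTTGATTTTCTCTAGGCCGGTCGGTTAACGCACCATTTCCTTTTTCACCATAGTTAATCCTGGCAGGCGCTTATTACAAAACTTAATT",
  C2 = "GAACATTTTCAAAGATGTTTCAAGTAGACCGTTCTAGATAAGGAGTTAAATCGAAGCTCATTCGCATAGAGTAAACTCTCTTATGTTGATTTTCTCTAGGCCGGGCGGATAACGCACCATTTCCTTTTTCACCATAGTTAATCCTGGCAGGCGCGTAATACAAAACTTAGTT",
  C3 = "GAACATTTTCAAAGATGATTCCAGTAGACCGTTATCGCTAACGTGTTAGATGGAATCTCATTCGCACATAGTAATCTCTCTTTTGTCGCTTTCCTCTAGGCTGGTCGCTTAAAGCACCGTATCCAGTTTCAACATAGTTAATCCTGGCAGGCGCTTATTACCAAACGTAATT",
  C4 = "GAACATTTTCAAAGATGTTTCGAGTAGACCGTTATAGTTAATATGTTACATGGAAACTCATTCGCACATACTATACTCTCTTTTGTCGATTTGCTCTAGGCGAATCGTTTAAAGCACCGTTTCCTTTTTCACCATAGCTAATCCTTGCCGGCGCTTATTACAAAACAAAATC"
)

#' Specify a satellite monomer family
#'
#' A family is defined by its consensus sequence, the per-base substitution
#' probability applied independently to every simulated copy
#' (`within_divergence`; e.g. 0.025 yields about 95% mean pairwise identity
#' between copies), and the probability that a copy's XmnI site is
#' inactivated by a point substitution (`site_kill_rate`).
#'
#' @param name Family label.
#' @param consensus DNA string of roughly 171-172 bp containing exactly one
#'   XmnI site (`GAANNNNTTC`).
#' @param within_divergence Per-base substitution probability per copy.
#' @param site_kill_rate Probability that a copy's XmnI site is mutated.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(name, consensus, within_divergence = 0.025,
                        site_kill_rate = 0) {
  check_scalar_string(name, "name")
  check_scalar_string(consensus, "consensus")
  consensus <- toupper(consensus)
  if (!all(seq_chars(consensus) %in% DNA_BASES)) {
    stop("consensus must contain only A/C/G/T", call. = FALSE)
  }
  check_probability(within_divergence, "within_divergence")
  check_probability(site_kill_rate, "site_kill_rate")
  m <- matchPattern(DNAString(XMNI_SITE), DNAString(consensus), fixed = FALSE)
  if (length(m) != 1L) {
    stop("consensus must contain exactly one XmnI site (found ",
         length(m), ")", call. = FALSE)
  }
  structure(
    list(name = name, consensus = consensus,
         within_divergence = within_divergence,
         site_kill_rate = site_kill_rate,
         site_start = start(m)[1]),
    class = "family_spec"
  )
}

#' Default synthetic family set
#'
#' Four built-in synthetic families shaped like the C1-C4 alpha satellite
#' families of an Old World monkey genome: C1 is abundant and homogeneous
#' (about 95% within-family identity), C2 is rarer and divergent (about 85%),
#' and C3/C4 form a dimeric higher-order repeat (86%/83% within-family
#' identity; C4 copies always lack a functional XmnI site so the C3-C4 unit
#' is released as a dimer). C2's consensus differs from C1's at exactly 9
#' positions; the pJalpha box is present in C1, C2 and C4 and absent from C3.
#'
#' @param within_divergence Named numeric vector of per-base substitution
#'   rates, calibrated by default so mean pairwise identities are about
#'   95/85/86/83%. With substitutions applied to the 162 positions outside
#'   the protected XmnI site and two copies matching at an unprotected
#'   position with probability (1-d)^2 + d^2/3, the expected identity is
#'   (162 ((1-d)^2 + d^2/3) + 10) / 172; the defaults solve that for the
#'   target identities.
#' @param site_kill_rate Named numeric vector of XmnI site inactivation
#'   probabilities per family.
#' @return Named list of [family_spec()] objects.
#' @export
solatus_families <- function(
    within_divergence = c(C1 = 0.0270, C2 = 0.0844, C3 = 0.0784, C4 = 0.0964),
    site_kill_rate = c(C1 = 0.002, C2 = 0.05, C3 = 0, C4 = 1)) {
  fams <- lapply(names(SYNTHETIC_CONSENSUS), function(nm) {
    family_spec(nm, SYNTHETIC_CONSENSUS[[nm]],
                within_divergence = unname(within_divergence[nm]),
                site_kill_rate = unname(site_kill_rate[nm]))
  })
  names(fams) <- names(SYNTHETIC_CONSENSUS)
  fams
}

#' Phase-rotate a monomer consensus to the XmnI cut frame
#'
#' Monomer reads released by XmnI digestion run from one blunt cut to the
#' next, so they are rotations of the biological consensus starting right
#' after the cut (`NNTTC...GAANN`). This helper rotates a consensus with an
#' internal XmnI site into that frame, which is the natural reference frame
#' for read filtering and consensus comparison.
#'
#' @param consensus DNA string with exactly one XmnI site.
#' @return The rotated string (same length).
#' @export
phase_rotate <- function(consensus) {
  m <- matchPattern(DNAString(XMNI_SITE), DNAString(consensus), fixed = FALSE)
  if (length(m) != 1L) stop("consensus must contain exactly one XmnI site")
  cut <- start(m)[1] + XMNI_CUT_OFFSET - 1L  # last base before the cut
  rotate_at(consensus, cut)
}

#' Rotate a circularly-viewed sequence at a cut position
#'
#' @param bases DNA string.
#' @param cut Number of leading bases moved to the end.
#' @export
rotate_at <- function(bases, cut) {
  paste0(substr(bases, cut + 1L, nchar(bases)), substr(bases, 1L, cut))
}

#' Default filtering reference sequence
#'
#' The reference used by the similarity filter and for reorientation: the
#' phase-rotated consensus of the most abundant synthetic family.
#' @param families Named list of [family_spec()] objects.
#' @return A DNA string.
#' @export
default_reference <- function(families = solatus_families()) {
  phase_rotate(families[[1]]$consensus)
}
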