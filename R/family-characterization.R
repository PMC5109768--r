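# Per-family consensus, identity statistics, motif search, duplicate census
# with orientation-bias artifact test, and left-right association analysis.

# Project members onto a template coordinate system: global NW of each
# member against the template; returns a character matrix
# (members x nchar(template)) where member insertions are dropped and
# deletions appear as "-".
.project_onto <- function(members, template) {
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- pairwiseAlignment(DNAStringSet(members), DNAString(template),
                          type = "global", substitutionMatrix = mat,
                          gapOpening = 0, gapExtension = 2)
  L <- nchar(template)
  out <- matrix("-", nrow = length(members), ncol = L)
  ap <- as.character(alignedPattern(pa))
  as_ <- as.character(alignedSubject(pa))
  for (i in seq_along(members)) {
    p <- seq_chars(ap[i]); s <- seq_chars(as_[i])
    keep <- s != "-"
    out[i, ] <- p[keep]
  }
  out
}

#' Build a family consensus (>60% rule)
#'
#' Aligns a seeded random subset of members onto the family's majority
#' template in two passes (global alignment projection; first pass onto the
#' most frequent member, second onto the first-pass plurality string).
#' Columns that are gaps in more than half of the members are dropped. A
#' column's consensus base is the base carried by strictly more than 60% of
#' its non-gap members; otherwise the column is `N`.
#'
#' @param members Character vector of oriented sequences (>= 2).
#' @param subset_size Members used (default 500; all when fewer).
#' @param seed Integer seed for the subset draw.
#' @param threshold Unambiguity threshold (strict, default 0.60).
#' @param gap_drop Drop columns with a gap fraction above this (default 0.5).
#' @return Object of class `consensus_profile`: `counts` (5 x columns
#'   matrix over A,C,G,T,-), `consensus` string, `n_members`.
#' @export
build_consensus <- function(members, subset_size = 500, seed = NULL,
                            threshold = 0.60, gap_drop = 0.50) {
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  sub <- if (length(members) > subset_size) {
    with_seed(seed, sample(members, subset_size))
  } else members
  tab <- table(sub)
  top <- names(tab)[tab == max(tab)]
  template <- sub[sub %in% top][1]  # most frequent; first occurrence on ties
  plurality <- function(M) {
    apply(M, 2, function(col) {
      col <- col[col != "-"]
      if (length(col) == 0L) return("A")
      names(sort(table(col), decreasing = TRUE))[1]
    })
  }
  M1 <- .project_onto(sub, template)
  t2 <- paste(plurality(M1), collapse = "")
  M2 <- .project_onto(sub, t2)
  counts <- apply(M2, 2, function(col) {
    tabulate(factor(col, levels = c(DNA_BASES, "-")), 5L)
  })
  rownames(counts) <- c(DNA_BASES, "-")
  keep <- counts["-", ] / length(sub) <= gap_drop
  counts <- counts[, keep, drop = FALSE]
  cons <- apply(counts, 2, function(ct) {
    nongap <- sum(ct[DNA_BASES])
    if (nongap == 0L) return("N")
    frac <- ct[DNA_BASES] / nongap
    if (max(frac) > threshold) DNA_BASES[which.max(frac)] else "N"
  })
  structure(list(counts = counts,
                 consensus = paste(cons, collapse = ""),
                 n_members = length(sub)),
            class = "consensus_profile")
}

#' Mean pairwise sequence identity within a family
#'
#' Mean over all pairs of a seeded random subset of
#' `matches / aligned columns` (columns counted over the full pairwise
#' global alignment; a pairwise alignment has no dual-gap columns), as a
#' percentage. `method = "positional"` compares equal-length sequences
#' position-wise without alignment.
#'
#' @param members Character vector of sequences (>= 2).
#' @param subset_size Subset used (default 500).
#' @param seed Integer seed.
#' @param method `"alignment"` (default) or `"positional"`.
#' @return Percentage in [0, 100].
#' @export
mean_pairwise_identity <- function(members, subset_size = 500, seed = NULL,
                                   method = c("alignment", "positional")) {
  method <- match.arg(method)
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  sub <- if (length(members) > subset_size) {
    with_seed(seed, sample(members, subset_size))
  } else members
  n <- length(sub)
  if (method == "positional") {
    if (length(unique(nchar(sub))) != 1L) {
      stop("positional identity requires equal-length sequences",
           call. = FALSE)
    }
    M <- do.call(rbind, strsplit(sub, "", fixed = TRUE))
    tot <- 0; np <- 0L
    for (i in seq_len(n - 1L)) {
      eq <- rowMeans(M[(i + 1L):n, , drop = FALSE] ==
                       matrix(M[i, ], n - i, ncol(M), byrow = TRUE))
      tot <- tot + sum(eq); np <- np + length(eq)
    }
    return(100 * tot / np)
  }
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  tot <- 0; np <- 0L
  ss <- DNAStringSet(sub)
  for (i in seq_len(n - 1L)) {
    pa <- pairwiseAlignment(ss[(i + 1L):n], ss[[i]], type = "global",
                            substitutionMatrix = mat, gapOpening = 0,
                            gapExtension = 2)
    tot <- tot + sum(nmatch(pa) / nchar(pa))
    np <- np + length(pa)
  }
  100 * tot / np
}

#' Fuzzy motif search (IUPAC-aware, both strands)
#'
#' Finds all positions on both strands where the Hamming distance between
#' the degenerate pattern and the sequence window is at most
#' `max_mismatches` (`N` matches anything, `R` matches A/G, `Y` matches
#' C/T, etc.). Minus-strand hits are reported with plus-strand start
#' coordinates.
#'
#' @param bases DNA string to search.
#' @param pattern IUPAC pattern (shorter than `bases`).
#' @param max_mismatches Mismatch budget (default 2).
#' @return data.frame: `position` (1-based start on the plus strand),
#'   `mismatches`, `strand` (`+`/`-`).
#' @export
motif_search <- function(bases, pattern, max_mismatches = 2) {
  check_scalar_string(bases, "bases")
  w <- nchar(pattern)
  if (w >= nchar(bases)) stop("pattern must be shorter than the sequence",
                              call. = FALSE)
  pat_chars <- seq_chars(toupper(pattern))
  scan <- function(subject) {
    m <- matchPattern(DNAString(pattern), DNAString(subject),
                      max.mismatch = max_mismatches, fixed = "subject")
    if (length(m) == 0L) {
      return(data.frame(position = integer(0), mismatches = integer(0)))
    }
    data.frame(
      position = start(m),
      mismatches = vapply(seq_along(m), function(i) {
        iupac_mismatch(pat_chars,
                       seq_chars(substr(subject, start(m)[i], end(m)[i])))
      }, 0L))
  }
  plus <- scan(bases)
  plus$strand <- rep("+", nrow(plus))
  minus <- scan(revcomp(bases))
  if (nrow(minus) > 0L) {
    minus$position <- nchar(bases) - (minus$position + w - 1L) + 1L
  }
  minus$strand <- rep("-", nrow(minus))
  out <- rbind(plus, minus)
  out[order(out$position), , drop = FALSE]
}

#' Fraction of members carrying a motif
#'
#' @param members Character vector of sequences.
#' @param pattern IUPAC pattern.
#' @param max_mismatches Mismatch budget (default 2).
#' @return Fraction in [0, 1].
#' @export
motif_frequency <- function(members, pattern, max_mismatches = 2) {
  if (length(members) == 0L) stop("empty member set", call. = FALSE)
  ss <- DNAStringSet(members)
  fwd <- vcountPattern(pattern, ss, max.mismatch = max_mismatches,
                       fixed = "subject")
  rev <- vcountPattern(pattern, reverseComplement(ss),
                       max.mismatch = max_mismatches, fixed = "subject")
  mean(fwd + rev > 0)
}

#' Census of identical sequences
#'
#' Groups byte-identical oriented sequences, counting copies and reads in
#' the reference (forward) orientation. All groups, including singletons,
#' are returned, ordered by decreasing copy number (first appearance on
#' ties).
#'
#' @param records data.frame with `bases` and `orientation_observed`.
#' @return data.frame of class `duplicate_census`: `bases`, `copy_number`,
#'   `forward_count`, `forward_fraction`.
#' @export
duplicate_census <- function(records) {
  stopifnot(!is.null(records$bases), !is.null(records$orientation_observed))
  f <- factor(records$bases, levels = unique(records$bases))
  copy_number <- as.integer(table(f))
  forward_count <- as.integer(tapply(
    records$orientation_observed == "forward", f, sum))
  out <- data.frame(bases = levels(f), copy_number = copy_number,
                    forward_count = forward_count,
                    forward_fraction = forward_count / copy_number,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$copy_number), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("duplicate_census", "data.frame")
  out
}

#' Orientation-bias artifact test
#'
#' Two-sided exact binomial test of each group's forward count against
#' p = 0.5, Bonferroni-corrected over the tested groups (copy number >= 2).
#' A group is flagged as a sequencing artifact when its adjusted p-value is
#' below `alpha` AND its forward fraction deviates from 0.5 by at least
#' `min_effect` (i.e. at least a 3:1 orientation imbalance by default): a
#' strong bias is both statistically reliable and large. With thousands of
#' copies, a small imbalance reaches significance without indicating a
#' strand-specific artifact, which is why the magnitude condition exists.
#'
#' @param groups A [duplicate_census()] data.frame (or any data.frame with
#'   `copy_number` and `forward_count`).
#' @param alpha Significance level (default 0.05).
#' @param min_effect Minimum `|forward_fraction - 0.5|` (default 0.25).
#' @return `groups` with `bias_p`, `bias_p_adjusted` and `artifact_flag`
#'   columns (NA for untested singletons).
#' @export
orientation_bias_test <- function(groups, alpha = 0.05, min_effect = 0.25) {
  tested <- which(groups$copy_number >= 2L)
  p <- rep(NA_real_, nrow(groups))
  p[tested] <- vapply(tested, function(i) {
    binom.test(groups$forward_count[i], groups$copy_number[i],
               p = 0.5)$p.value
  }, 0)
  padj <- pmin(p * length(tested), 1)
  ff <- groups$forward_count / groups$copy_number
  groups$bias_p <- p
  groups$bias_p_adjusted <- padj
  groups$artifact_flag <- !is.na(padj) & padj < alpha &
    abs(ff - 0.5) >= min_effect
  groups
}

#' Left-right family association test
#'
#' Contingency table of left x right family assignments with a Pearson
#' chi-square test of independence and standardized Pearson residuals.
#' Cells with a residual above `residual_threshold` are reported as
#' preferential associations. When any expected count is below 5 the
#' p-value is replaced by a seeded Monte-Carlo estimate.
#'
#' @param left,right Family labels of the paired left and right monomers.
#' @param residual_threshold Residual cutoff (default 2).
#' @param n_sim Monte-Carlo replicates (default 10000).
#' @param seed Integer seed for the Monte-Carlo p-value.
#' @return List of class `association_table`: `table`, `statistic`,
#'   `p.value`, `method`, `stdres`, `preferential` (logical matrix), or a
#'   degenerate note when fewer than 2 levels per margin are present.
#' @export
association_test <- function(left, right, residual_threshold = 2,
                             n_sim = 10000, seed = NULL) {
  stopifnot(length(left) == length(right), length(left) >= 1L)
  tab <- table(left = left, right = right)
  drop_r <- rowSums(tab) == 0; drop_c <- colSums(tab) == 0
  if (any(drop_r) || any(drop_c)) {
    message("families with zero margin excluded from the association table")
    tab <- tab[!drop_r, !drop_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L || sum(tab) < 2) {
    message("association test skipped: degenerate table")
    return(structure(list(table = tab, statistic = NA_real_,
                          p.value = NA_real_, method = "skipped",
                          stdres = NULL, preferential = NULL),
                     class = "association_table"))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  method <- "pearson"
  pval <- ct$p.value
  if (any(ct$expected < 5)) {
    method <- "monte-carlo"
    pval <- with_seed(seed, suppressWarnings(
      chisq.test(tab, simulate.p.value = TRUE, B = n_sim)$p.value))
  }
  structure(list(table = tab, statistic = unname(ct$statistic),
                 p.value = pval, method = method, stdres = ct$stdres,
                 preferential = ct$stdres > residual_threshold),
            class = "association_table")
}
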