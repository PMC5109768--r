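# Synthetic satellite genome and read simulator with ground-truth labels.

#' Specify a tandem array
#'
#' @param family_names Character vector of family names: length 1 for a
#'   monomeric array, length 2 for a dimeric higher-order repeat unit.
#' @param n_units Number of repeat units in the array.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(family_names, n_units) {
  if (!is.character(family_names) || length(family_names) < 1L) {
    stop("family_names must be a non-empty character vector", call. = FALSE)
  }
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 1) {
    stop("n_units must be >= 1", call. = FALSE)
  }
  structure(list(family_names = family_names, n_units = as.integer(n_units)),
            class = "array_spec")
}

#' Default synthetic genome organization
#'
#' Monomeric arrays of C1 and C2 in an 82:18 ratio plus a C3-C4 dimeric
#' higher-order repeat array. Unit counts are large relative to the
#' simulated read depths so that most genomic copies are sequenced at most
#' once and duplicate reads predominantly reflect identical genomic copies,
#' as in a real satellite sequencing experiment.
#' @param n_c1,n_c2,n_hor Unit counts for the three arrays.
#' @return List of [array_spec()] objects.
#' @export
default_arrays <- function(n_c1 = 2050, n_c2 = 450, n_hor = 300) {
  specs <- list()
  if (n_c1 > 0) specs <- c(specs, list(array_spec("C1", n_c1)))
  if (n_c2 > 0) specs <- c(specs, list(array_spec("C2", n_c2)))
  if (n_hor > 0) specs <- c(specs, list(array_spec(c("C3", "C4"), n_hor)))
  specs
}

#' Sequencing error model
#'
#' Error model emulating single-molecule semiconductor sequencing of
#' satellite fragments: uniform per-base substitutions, deletions within
#' homopolymer tracts (runs of length >= 2), and an orientation bias by
#' which a given homopolymer-deletion artifact class (a specific run in a
#' specific fragment) may occur on one read orientation only. Per-base
#' qualities are drawn from a normal distribution truncated to [0, 40].
#'
#' @param sub_rate Per-base substitution probability.
#' @param homopolymer_del_rate Per-run deletion probability per read.
#' @param orientation_bias Probability that an artifact class is
#'   orientation-restricted.
#' @param quality_mean,quality_sd Phred quality distribution parameters.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.005, homopolymer_del_rate = 0.01,
                        orientation_bias = 0.5, quality_mean = 30,
                        quality_sd = 4) {
  check_probability(sub_rate, "sub_rate")
  check_probability(homopolymer_del_rate, "homopolymer_del_rate")
  check_probability(orientation_bias, "orientation_bias")
  if (quality_mean < 0 || quality_mean > 40) {
    stop("quality_mean must be in [0, 40]", call. = FALSE)
  }
  structure(list(sub_rate = sub_rate,
                 homopolymer_del_rate = homopolymer_del_rate,
                 orientation_bias = orientation_bias,
                 quality_mean = quality_mean, quality_sd = quality_sd),
            class = "error_model")
}

#' Mutate a consensus at an exact number of positions
#'
#' Substitutes bases at exactly `n_positions` distinct positions, chosen
#' uniformly outside the XmnI site (so the digestion phenotype is controlled
#' separately) unless `avoid_xmni = FALSE`. Deterministic given `seed`.
#'
#' @param base DNA string.
#' @param n_positions Number of positions to substitute.
#' @param seed Integer seed.
#' @param avoid_xmni Exclude the 10-bp XmnI site from mutable positions.
#' @return DNA string at Hamming distance exactly `n_positions` from `base`.
#' @export
mutate_consensus <- function(base, n_positions, seed = NULL,
                             avoid_xmni = TRUE) {
  check_scalar_string(base, "base")
  chars <- seq_chars(base)
  allowed <- seq_along(chars)
  if (avoid_xmni) {
    m <- matchPattern(DNAString(XMNI_SITE), DNAString(base), fixed = FALSE)
    if (length(m) > 0) {
      site <- unlist(lapply(seq_along(m),
                            function(i) start(m)[i]:end(m)[i]))
      allowed <- setdiff(allowed, site)
    }
  }
  if (n_positions > length(allowed)) {
    stop("n_positions exceeds the number of mutable positions", call. = FALSE)
  }
  if (n_positions == 0L) return(base)
  with_seed(seed, {
    pos <- sample(allowed, n_positions)
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  })
  paste(chars, collapse = "")
}

# Substitute one copy of a consensus: Bernoulli(divergence) per base outside
# the XmnI site, plus an optional site-killing substitution (first site base
# G -> T). Assumes the ambient RNG stream is already seeded.
.mutate_copy <- function(chars, divergence, site_idx, kill_site) {
  n <- length(chars)
  if (divergence > 0) {
    hit <- which(runif(n) < divergence)
    hit <- setdiff(hit, site_idx)
    for (p in hit) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  if (kill_site) chars[site_idx[1]] <- "T"
  chars
}

#' Simulate a satellite genome with truth labels
#'
#' Concatenates the given arrays; every monomer copy is independently
#' mutated at the family's `within_divergence` rate (outside its XmnI site)
#' and its site is inactivated with probability `site_kill_rate`. Truth
#' labels map every copy to its array, unit and family with 0-based
#' half-open genome coordinates.
#'
#' @param families Named list of [family_spec()] objects.
#' @param arrays List of [array_spec()] objects; every referenced family
#'   name must resolve.
#' @param seed Integer seed.
#' @return An object of class `sat_genome`: list with `genome` (DNA string)
#'   and `copies` (data.frame of truth labels: array, unit, slot, family,
#'   start, end, site_killed, cut_pos).
#' @export
simulate_genome <- function(families, arrays, seed = NULL) {
  if (length(arrays) == 0L) stop("arrays must be non-empty", call. = FALSE)
  fam_names <- unlist(lapply(arrays, function(a) a$family_names))
  missing <- setdiff(fam_names, names(families))
  if (length(missing)) {
    stop("unknown families in arrays: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    pieces <- character(0)
    rows <- list()
    offset <- 0L
    for (ai in seq_along(arrays)) {
      a <- arrays[[ai]]
      for (u in seq_len(a$n_units)) {
        for (si in seq_along(a$family_names)) {
          f <- families[[a$family_names[si]]]
          site_idx <- f$site_start:(f$site_start + 9L)
          kill <- runif(1) < f$site_kill_rate
          chars <- .mutate_copy(seq_chars(f$consensus), f$within_divergence,
                                site_idx, kill)
          len <- length(chars)
          pieces[[length(pieces) + 1L]] <- paste(chars, collapse = "")
          rows[[length(rows) + 1L]] <- data.frame(
            array = ai, unit = u, slot = si, family = f$name,
            start = offset, end = offset + len,
            site_killed = kill,
            cut_pos = offset + f$site_start - 1L + XMNI_CUT_OFFSET,
            stringsAsFactors = FALSE)
          offset <- offset + len
        }
      }
    }
    structure(list(genome = paste(pieces, collapse = ""),
                   copies = do.call(rbind, rows)),
              class = "sat_genome")
  })
}

# Majority family over a 0-based half-open genome interval.
.interval_family <- function(copies, start, end) {
  ov <- copies[copies$end > start & copies$start < end, , drop = FALSE]
  if (nrow(ov) == 0L) return(NA_character_)
  w <- pmin(ov$end, end) - pmax(ov$start, start)
  tapply_sum <- tapply(w, ov$family, sum)
  names(tapply_sum)[which.max(tapply_sum)]
}

# Homopolymer runs (length >= 2) in a fragment: data.frame(start, length)
# in 1-based fragment coordinates.
.homopolymer_runs <- function(bases) {
  r <- rle(seq_chars(bases))
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= 2L
  data.frame(start = (ends - r$lengths + 1L)[keep],
             length = r$lengths[keep])
}

#' Simulate digestion-targeted reads from a genome
#'
#' Digests the genome in silico (optionally skipping each internal cut with
#' probability `cut_skip_prob`, emulating partial digestion), restricts
#' fragments to the gel-band length window, then samples reads uniformly
#' over the band's fragments. Each read takes a random true orientation
#' (p = 0.5), suffers homopolymer deletions (per artifact class: a specific
#' run in a specific fragment, which with probability `orientation_bias` is
#' restricted to one designated orientation) and uniform substitutions, and
#' receives truncated-normal per-base qualities.
#'
#' @param genome A [simulate_genome()] result (or plain DNA string).
#' @param error_model An [error_model()].
#' @param band `"monomer"` or `"dimer"`.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param cut_skip_prob Probability that an internal cut is skipped.
#' @param band_windows Named list of inclusive length windows per band.
#' @return A data.frame of reads with truth columns: id, bases, quals
#'   (list of integer Phred scores), orientation (truth), frag_start,
#'   frag_end, family_left, family_right, n_hp_del, hp_del_biased,
#'   hp_del_runs (comma-joined 1-based fragment positions of deleted
#'   homopolymer runs).
#' @export
simulate_reads <- function(genome, error_model, band = c("monomer", "dimer"),
                           n_reads, seed = NULL, cut_skip_prob = 0,
                           band_windows = list(monomer = c(162, 182),
                                               dimer = c(324, 364))) {
  band <- match.arg(band)
  gseq <- if (inherits(genome, "sat_genome")) genome$genome else genome
  copies <- if (inherits(genome, "sat_genome")) genome$copies else NULL
  with_seed(seed, {
    frags <- restriction_digest(gseq)
    if (cut_skip_prob > 0 && nrow(frags) > 1L) {
      keep_cut <- runif(nrow(frags) - 1L) >= cut_skip_prob
      frags <- .merge_fragments(frags, keep_cut)
    }
    win <- band_windows[[band]]
    lens <- frags$end - frags$start
    frags <- frags[lens >= win[1] & lens <= win[2], , drop = FALSE]
    if (nrow(frags) == 0L) {
      stop("no fragment falls in the ", band, " band window", call. = FALSE)
    }
    # artifact classes: homopolymer runs per eligible fragment
    classes <- lapply(seq_len(nrow(frags)), function(i) {
      runs <- .homopolymer_runs(frags$bases[i])
      if (nrow(runs) == 0L) return(runs)
      runs$biased <- runif(nrow(runs)) < error_model$orientation_bias
      runs$designated <- sample(c("forward", "reverse"), nrow(runs),
                                replace = TRUE)
      runs
    })
    idx <- sample.int(nrow(frags), n_reads, replace = TRUE)
    orient <- sample(c("forward", "reverse"), n_reads, replace = TRUE)
    out <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      fi <- idx[r]
      chars <- seq_chars(frags$bases[fi])
      cl <- classes[[fi]]
      n_del <- 0L
      del_biased <- FALSE
      del_runs <- ""
      if (nrow(cl) > 0L && error_model$homopolymer_del_rate > 0) {
        fire <- runif(nrow(cl)) < error_model$homopolymer_del_rate
        fire <- fire & (!cl$biased | cl$designated == orient[r])
        if (any(fire)) {
          del_pos <- sort(cl$start[fire], decreasing = TRUE)
          for (p in del_pos) chars <- chars[-p]
          n_del <- length(del_pos)
          del_biased <- any(cl$biased[fire])
          del_runs <- paste(sort(cl$start[fire]), collapse = ",")
        }
      }
      if (error_model$sub_rate > 0) {
        hit <- which(runif(length(chars)) < error_model$sub_rate)
        for (p in hit) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      }
      bases <- paste(chars, collapse = "")
      if (orient[r] == "reverse") bases <- revcomp(bases)
      quals <- as.integer(pmin(40, pmax(0, round(
        rnorm(nchar(bases), error_model$quality_mean,
              error_model$quality_sd)))))
      out[[r]] <- list(bases = bases, quals = quals, n_del = n_del,
                       del_biased = del_biased, del_runs = del_runs)
    }
    mid <- (frags$start[idx] + frags$end[idx]) / 2
    fam_left <- fam_right <- rep(NA_character_, n_reads)
    if (!is.null(copies)) {
      for (r in seq_len(n_reads)) {
        fam_left[r] <- .interval_family(copies, frags$start[idx[r]], mid[r])
        fam_right[r] <- .interval_family(copies, mid[r], frags$end[idx[r]])
      }
    }
    data.frame(
      id = sprintf("read%05d", seq_len(n_reads)),
      bases = vapply(out, `[[`, "", "bases"),
      quals = I(lapply(out, `[[`, "quals")),
      orientation = orient,
      frag_start = frags$start[idx],
      frag_end = frags$end[idx],
      family_left = fam_left,
      family_right = fam_right,
      n_hp_del = vapply(out, `[[`, 0L, "n_del"),
      hp_del_biased = vapply(out, `[[`, FALSE, "del_biased"),
      hp_del_runs = vapply(out, `[[`, "", "del_runs"),
      stringsAsFactors = FALSE)
  })
}

#' Simulate site-less (noX) dimer sequences with indels
#'
#' Builds dimeric sequences in the XmnI cut frame from two family
#' consensuses: each half is an independently substituted copy, the XmnI
#' site straddling the internal junction is inactivated, and up to
#' `max_indels` random 1-bp indels are applied per monomer. The true
#' junction position (number of bases in the left monomer) is recorded.
#'
#' @param families Named list of [family_spec()] objects.
#' @param left,right Family names for the left and right monomers.
#' @param n Number of dimers.
#' @param seed Integer seed.
#' @param max_indels Maximum number of 1-bp indels per monomer.
#' @return data.frame: id, bases, true_junction, left_family, right_family.
#' @export
simulate_noX_dimers <- function(families, left, right, n, seed = NULL,
                                max_indels = 3) {
  fl <- families[[left]]; fr <- families[[right]]
  if (is.null(fl) || is.null(fr)) stop("unknown family name", call. = FALSE)
  with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      half <- function(f) {
        site_idx <- f$site_start:(f$site_start + 9L)
        ch <- .mutate_copy(seq_chars(f$consensus), f$within_divergence,
                           site_idx, kill_site = FALSE)
        # rotate at the family's own cut point (a mutated copy may carry a
        # spurious degenerate site elsewhere)
        rotate_at(paste(ch, collapse = ""),
                  f$site_start + XMNI_CUT_OFFSET - 1L)
      }
      lm <- seq_chars(half(fl))
      rm_ <- seq_chars(half(fr))
      # kill the junction site: the G five bases before the junction
      lm[length(lm) - 4L] <- "T"
      indel <- function(ch, k) {
        for (j in seq_len(k)) {
          p <- sample.int(length(ch), 1L)
          if (runif(1) < 0.5 && length(ch) > 1L) {
            ch <- ch[-p]
          } else {
            ch <- append(ch, sample(DNA_BASES, 1L), after = p)
          }
        }
        ch
      }
      lm <- indel(lm, sample.int(max_indels + 1L, 1L) - 1L)
      rm_ <- indel(rm_, sample.int(max_indels + 1L, 1L) - 1L)
      rows[[i]] <- data.frame(
        id = sprintf("dimer%04d", i),
        bases = paste(c(lm, rm_), collapse = ""),
        true_junction = length(lm),
        left_family = fl$name, right_family = fr$name,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
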