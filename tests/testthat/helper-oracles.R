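# Shared fixtures and independent oracles used across the test files.

# Phase-rotated mutated copies of a family, as they appear in reads.
make_copies <- function(fam, n, seed) {
  set.seed(seed)
  site_idx <- fam$site_start:(fam$site_start + 9L)
  vapply(seq_len(n), function(i) {
    ch <- alphasat:::.mutate_copy(alphasat:::seq_chars(fam$consensus),
                                  fam$within_divergence, site_idx, FALSE)
    rotate_at(paste(ch, collapse = ""), fam$site_start + 4L)
  }, "")
}

# Brute-force Hamming distance.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Naive IUPAC-aware fuzzy scan on one strand: start positions with
# Hamming distance <= k between pattern and window.
naive_motif_scan <- function(seq, pattern, k) {
  map <- Biostrings::IUPAC_CODE_MAP
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  w <- length(p)
  hits <- integer(0)
  for (i in seq_len(length(s) - w + 1L)) {
    win <- s[i:(i + w - 1L)]
    mm <- sum(!mapply(function(code, base) {
      grepl(base, map[[code]], fixed = TRUE)
    }, p, win))
    if (mm <= k) hits <- c(hits, i)
  }
  hits
}

# Naive probe-binding oracle: fraction of members with a window within
# Hamming distance k of the probe's reverse complement, on either strand.
naive_binding <- function(probe, members, k) {
  target <- revcomp_chr(probe)
  tc <- strsplit(target, "")[[1]]
  w <- length(tc)
  bound <- vapply(members, function(m) {
    for (s in c(m, revcomp_chr(m))) {
      sc <- strsplit(s, "")[[1]]
      if (length(sc) < w) next
      for (i in seq_len(length(sc) - w + 1L)) {
        if (sum(sc[i:(i + w - 1L)] != tc) <= k) return(TRUE)
      }
    }
    FALSE
  }, FALSE)
  mean(bound)
}

# Exhaustive affine-gap Smith-Waterman returning the best score and the
# read-span (aligned read bases) of the best local alignment. Scoring:
# match +2, mismatch -3, gap open -5, gap extend -2 (open+first extend
# costs 7, matching the implementation's gapOpening=5/gapExtension=2).
naive_sw <- function(read, subject) {
  a <- strsplit(read, "")[[1]]; b <- strsplit(subject, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  # start-of-path read index propagated per state
  Hs <- matrix(0L, n + 1, m + 1); Es <- matrix(0L, n + 1, m + 1)
  Fs <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0L; bs <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # E: gap in read (consumes subject)
      e_open <- H[i + 1, j] - 7; e_ext <- E[i + 1, j] - 2
      if (e_open >= e_ext) { E[i + 1, j + 1] <- e_open
        Es[i + 1, j + 1] <- Hs[i + 1, j]
      } else { E[i + 1, j + 1] <- e_ext; Es[i + 1, j + 1] <- Es[i + 1, j] }
      # F: gap in subject (consumes read)
      f_open <- H[i, j + 1] - 7; f_ext <- F[i, j + 1] - 2
      if (f_open >= f_ext) { F[i + 1, j + 1] <- f_open
        Fs[i + 1, j + 1] <- Hs[i, j + 1]
      } else { F[i + 1, j + 1] <- f_ext; Fs[i + 1, j + 1] <- Fs[i, j + 1] }
      diag <- H[i, j] + if (a[i] == b[j]) 2 else -3
      ds <- if (H[i, j] == 0 && Hs[i, j] == 0L) i else Hs[i, j]
      h <- max(0, diag, E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      Hs[i + 1, j + 1] <- if (h == 0) 0L else if (h == diag) ds else
        if (h == E[i + 1, j + 1]) Es[i + 1, j + 1] else Fs[i + 1, j + 1]
      if (h > best) { best <- h; bi <- i; bs <- Hs[i + 1, j + 1] }
    }
  }
  list(score = best, span = if (best > 0) bi - bs + 1L else 0L)
}

default_fc <- function() filter_config(reference = default_reference())
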