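fams <- solatus_families()

test_that("mutate_consensus hits exactly the requested Hamming distance", {
  base <- fams$C1$consensus
  expect_identical(mutate_consensus(base, 0, seed = 3), base)
  for (n in c(1, 9, 25)) {
    mut <- mutate_consensus(base, n, seed = 1)
    expect_equal(nchar(mut), nchar(base))
    expect_equal(hamming(base, mut), n)
  }
  # deterministic given seed; avoids the XmnI site
  expect_identical(mutate_consensus(base, 9, seed = 1),
                   mutate_consensus(base, 9, seed = 1))
  mut <- mutate_consensus(base, 50, seed = 2)
  expect_identical(substr(mut, fams$C1$site_start, fams$C1$site_start + 9),
                   substr(base, fams$C1$site_start, fams$C1$site_start + 9))
  expect_error(mutate_consensus(base, nchar(base) + 1), "mutable")
})

test_that("simulate_genome concatenates labeled mutated copies", {
  f0 <- family_spec("F", fams$C1$consensus, within_divergence = 0,
                    site_kill_rate = 0)
  g1 <- simulate_genome(list(F = f0), list(array_spec("F", 1)), seed = 1)
  expect_identical(g1$genome, f0$consensus)
  g10 <- simulate_genome(list(F = f0), list(array_spec("F", 10)), seed = 1)
  expect_equal(nchar(g10$genome), 10 * nchar(f0$consensus))
  expect_equal(nrow(g10$copies), 10)
  # labels map every copy back onto the genome
  g <- simulate_genome(fams, default_arrays(n_c1 = 20, n_c2 = 10, n_hor = 5),
                       seed = 2)
  expect_equal(max(g$copies$end), nchar(g$genome))
  expect_true(all(g$copies$start == c(0, head(g$copies$end, -1))))
  # site-kill flags correspond to a broken site in the copy
  killed <- g$copies[g$copies$site_killed, ][1, ]
  copy <- substr(g$genome, killed$start + 1, killed$end)
  expect_equal(length(Biostrings::matchPattern(
    "GAANNNNTTC", Biostrings::DNAString(copy), fixed = FALSE)), 0)
})

test_that("within-family divergence is calibrated", {
  f <- family_spec("F", fams$C1$consensus, within_divergence = 0.05)
  g <- simulate_genome(list(F = f), list(array_spec("F", 1000)), seed = 7)
  cons <- alphasat:::seq_chars(f$consensus)
  mutable <- setdiff(seq_along(cons), f$site_start:(f$site_start + 9))
  n_sub <- vapply(seq_len(nrow(g$copies)), function(i) {
    copy <- alphasat:::seq_chars(
      substr(g$genome, g$copies$start[i] + 1, g$copies$end[i]))
    sum(copy[mutable] != cons[mutable])
  }, 0L)
  rate <- sum(n_sub) / (1000 * length(mutable))
  se <- sqrt(0.05 * 0.95 / (1000 * length(mutable)))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("simulate_reads is seeded, truth-labeled and band-checked", {
  g <- simulate_genome(fams, default_arrays(n_c1 = 30, n_c2 = 10, n_hor = 5),
                       seed = 3)
  clean <- error_model(sub_rate = 0, homopolymer_del_rate = 0,
                       quality_sd = 0)
  r1 <- simulate_reads(g, clean, "monomer", 50, seed = 4)
  r2 <- simulate_reads(g, clean, "monomer", 50, seed = 4)
  expect_identical(r1, r2)
  # error-free reads are exact fragment copies or reverse complements
  for (i in seq_len(nrow(r1))) {
    frag <- substr(g$genome, r1$frag_start[i] + 1, r1$frag_end[i])
    expected <- if (r1$orientation[i] == "reverse") revcomp_chr(frag) else frag
    expect_identical(r1$bases[i], expected)
  }
  expect_error(
    simulate_reads(g, clean, "dimer", 5, seed = 5,
                   band_windows = list(dimer = c(1000, 1001))),
    "band window")
})

test_that("fully biased homopolymer deletions are strand-exclusive", {
  g <- simulate_genome(fams, list(array_spec("C1", 30)), seed = 6)
  em <- error_model(sub_rate = 0, homopolymer_del_rate = 0.9,
                    orientation_bias = 1)
  rd <- simulate_reads(g, em, "monomer", 400, seed = 7)
  withdel <- rd[rd$n_hp_del > 0, ]
  expect_gt(nrow(withdel), 50)
  # every (fragment, run) artifact class appears in one orientation only
  cls <- do.call(rbind, lapply(seq_len(nrow(withdel)), function(i) {
    runs <- strsplit(withdel$hp_del_runs[i], ",")[[1]]
    data.frame(frag = withdel$frag_start[i], run = runs,
               orientation = withdel$orientation[i])
  }))
  per_class <- tapply(cls$orientation, paste(cls$frag, cls$run),
                      function(o) length(unique(o)))
  expect_true(all(per_class == 1))
})

test_that("noX dimer simulator kills the junction site and records truth", {
  nx <- simulate_noX_dimers(fams, "C3", "C4", 20, seed = 8, max_indels = 0)
  expect_equal(nx$true_junction, rep(172L, 20))
  expect_identical(simulate_noX_dimers(fams, "C3", "C4", 20, seed = 8,
                                       max_indels = 0), nx)
  # no intact site anywhere near the middle
  expect_true(all(is.na(vapply(nx$bases, find_internal_site, 0L))))
})
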