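fams <- solatus_families()

test_that("binding frequency equals the naive sliding-window oracle", {
  members <- make_copies(fams$C1, 10, seed = 61)
  window <- substr(members[1], 30, 47)
  probe <- revcomp_chr(window)  # hybridization target = the window
  expect_equal(binding_frequency(probe, members, 0),
               naive_binding(probe, members, 0))
  expect_equal(binding_frequency(probe, members, 1),
               naive_binding(probe, members, 1))

  # planted target in 7 of 10 members
  base <- strrep("AT", 86)
  target <- "GGCCAATTGGCCAATTGG"
  mem <- c(vapply(1:7, function(i) {
    paste0(substr(base, 1, 40), target, substr(base, 59, 172))
  }, ""), rep(base, 3))
  pr <- revcomp_chr(target)
  expect_equal(binding_frequency(pr, mem, 0), 0.7)
  expect_equal(binding_frequency(pr, mem, 0), naive_binding(pr, mem, 0))

  # a probe >=2 mismatches from every window binds nothing at 0 or 1
  away <- "GGCCGGCCGGCCGGCCGG"
  expect_equal(binding_frequency(away, rep(strrep("AT", 86), 4), 0), 0)
  expect_equal(binding_frequency(away, rep(strrep("AT", 86), 4), 1), 0)
  expect_error(binding_frequency(pr, character(0)), "empty")
})

test_that("binding frequency is monotone in mismatches and strand-symmetric", {
  members <- make_copies(fams$C2, 15, seed = 62)
  set.seed(63)
  for (i in 1:8) {
    s <- sample.int(150, 1)
    probe <- revcomp_chr(substr(members[sample.int(15, 1)], s, s + 17))
    f0 <- binding_frequency(probe, members, 0)
    f1 <- binding_frequency(probe, members, 1)
    expect_gte(f1, f0)
    expect_equal(binding_frequency(revcomp_chr(probe), members, 0), f0)
    expect_equal(binding_frequency(revcomp_chr(probe), members, 1), f1)
  }
})

test_that("a single discriminating window yields the unique specific probe", {
  # two otherwise-identical families differing at two positions exactly 18 bp
  # apart: only the one window covering both carries 2 mismatches to the
  # off-target family, so it alone survives the 1-mismatch criterion
  base <- fams$C1$consensus
  alt <- base
  substr(alt, 41, 41) <- "G"
  substr(alt, 58, 58) <- "G"
  fam_a <- rep(base, 30)
  fam_b <- rep(alt, 30)
  cands <- enumerate_candidates(base, list(A = fam_a, B = fam_b), "A")
  spec <- cands[cands$specific, ]
  expect_equal(nrow(spec), 1)
  expect_equal(spec$start, 41)
  expect_identical(spec$probe, revcomp_chr(substr(base, 41, 58)))
  # frequencies equal the oracle exactly, for every candidate
  set.seed(64)
  for (r in sample(seq_len(nrow(cands)), 12)) {
    expect_equal(cands$freq_exact_A[r],
                 naive_binding(cands$probe[r], fam_a, 0))
    expect_equal(cands$freq_1mm_B[r],
                 naive_binding(cands$probe[r], fam_b, 1))
  }
  # identical families admit no specific probe
  same <- enumerate_candidates(base, list(A = fam_a, B = fam_a), "A")
  expect_false(any(same$specific))
})

test_that("GC-poor windows are extended to 19-mers or rejected", {
  atcons <- strrep("AT", 30)
  cands <- enumerate_candidates(atcons, list(A = rep(atcons, 5)), "A")
  if (nrow(cands) > 0) {
    expect_true(all(cands$length == 19 | !cands$specific))
    expect_false(any(cands$specific))  # 19-mer of AT still has 0 GC
  }
  expect_error(enumerate_candidates("ACGT", list(A = "ACGT"), "A"),
               "shorter")
})

test_that("specificity thresholds are strict", {
  base <- strrep("AT", 86)
  target <- "GGCCAATTGGCCAATTGG"
  with_t <- paste0(substr(base, 1, 40), target, substr(base, 59, 172))
  # exactly 20% of the target family carries the site: not specific
  fam_a <- c(with_t, rep(base, 4))
  probe <- revcomp_chr(target)
  expect_equal(binding_frequency(probe, fam_a, 0), 0.2)
  cfg <- probe_design_config(apply_criteria_to_1mm = FALSE)
  cands <- enumerate_candidates(with_t, list(A = fam_a), "A", cfg)
  row <- cands[cands$probe == probe, ]
  expect_equal(nrow(row), 1)
  expect_false(row$specific)
})

test_that("LNA annotation alternates and round-trips the printed probes", {
  p18 <- strrep("ACG", 6)
  ann <- lna_annotate(p18)
  expect_equal(length(lna_positions(ann)), 9)
  expect_equal(lna_positions(ann), seq(2, 18, by = 2))
  expect_identical(toupper(ann), p18)
  expect_error(lna_annotate("ACGT"), "18 or 19")

  printed <- read.delim(system.file("extdata", "printed_probes.tsv",
                                    package = "alphasat"))
  t39g <- printed$annotated[printed$name == "T39G"]
  expect_equal(lna_positions(t39g), c(2, 4, 6, 8, 11, 13, 15, 17, 19))
  expect_identical(nchar(t39g), 19L)
  # strip-case recovers plain bases for every printed probe
  expect_true(all(grepl("^[ACGT]+$", toupper(printed$annotated))))
})
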