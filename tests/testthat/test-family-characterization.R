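fams <- solatus_families()

test_that("consensus follows the strict >60% rule", {
  ten <- rep(fams$C1$consensus, 10)
  cp <- build_consensus(ten)
  expect_identical(cp$consensus, fams$C1$consensus)
  expect_false(grepl("N", cp$consensus))
  expect_equal(cp$n_members, 10)

  # constructed 6/10 column: 60% is not "more than 60%"
  base <- strrep("ACGT", 10)
  members <- c(rep(paste0("A", substr(base, 2, 40)), 6),
               rep(paste0("C", substr(base, 2, 40)), 4))
  cp6 <- build_consensus(members)
  expect_identical(substr(cp6$consensus, 1, 1), "N")
  members7 <- c(members, paste0("A", substr(base, 2, 40)))
  cp7 <- build_consensus(members7)  # 7/11 = 63.6% > 60%
  expect_identical(substr(cp7$consensus, 1, 1), "A")

  # a single 1-bp-deleted member does not change the consensus length
  del <- paste0(substr(fams$C1$consensus, 1, 99),
                substr(fams$C1$consensus, 101, 172))
  cpd <- build_consensus(c(rep(fams$C1$consensus, 9), del))
  expect_equal(nchar(cpd$consensus), 172)
  expect_identical(cpd$consensus, fams$C1$consensus)

  # idempotence
  cc <- build_consensus(rep(cp$consensus, 5))
  expect_identical(cc$consensus, cp$consensus)
  expect_error(build_consensus("ACGT"), "at least 2")
})

test_that("mean pairwise identity matches hand-computed values", {
  expect_equal(mean_pairwise_identity(rep(fams$C1$consensus, 5)), 100)
  # two 172-bp sequences differing at 9 positions: 163/172
  a <- fams$C1$consensus
  b <- mutate_consensus(a, 9, seed = 51)
  expect_equal(mean_pairwise_identity(c(a, b)), 100 * 163 / 172,
               tolerance = 1e-9)
  expect_equal(mean_pairwise_identity(c(a, b), method = "positional"),
               100 * 163 / 172, tolerance = 1e-9)
  # calibrated family divergence gives ~95% identity
  copies <- make_copies(fams$C1, 80, seed = 52)
  est <- mean_pairwise_identity(copies, subset_size = 80, seed = 53)
  expect_lt(abs(est - 95), 1)
})

test_that("fuzzy motif search is IUPAC-aware and strand-mirrored", {
  seq <- paste0(strrep("ACGT", 20), "TTCCTTTTTCACCATAG", strrep("TGCA", 20))
  h <- motif_search(seq, PJALPHA_BOX)
  expect_equal(nrow(h[h$mismatches == 0, ]), 1)
  expect_equal(h$position[h$mismatches == 0], 81)

  # three planted mismatches kill the hit
  bad <- seq
  substr(bad, 81, 83) <- "GGG"
  expect_equal(nrow(motif_search(bad, PJALPHA_BOX)), 0)

  # reverse complement mirrors coordinates
  hr <- motif_search(revcomp_chr(seq), PJALPHA_BOX)
  expect_equal(nrow(hr), nrow(h))
  expect_equal(sort(nchar(seq) - (h$position + nchar(PJALPHA_BOX) - 1) + 1),
               sort(hr$position))
  expect_setequal(hr$strand, "-")

  # random sequences: hit count equals the naive sliding-window oracle
  set.seed(54)
  for (i in 1:5) {
    rnd <- paste(sample(c("A", "C", "G", "T"), 172, TRUE), collapse = "")
    got <- motif_search(rnd, PJALPHA_BOX, max_mismatches = 4)
    plus <- naive_motif_scan(rnd, PJALPHA_BOX, 4)
    minus <- naive_motif_scan(revcomp_chr(rnd), PJALPHA_BOX, 4)
    expect_equal(sum(got$strand == "+"), length(plus))
    expect_equal(sum(got$strand == "-"), length(minus))
    if (length(plus)) expect_setequal(got$position[got$strand == "+"], plus)
  }
})

test_that("duplicate census equals a hash-count oracle and conserves reads", {
  set.seed(55)
  pool <- c(strrep("ACGT", 43), strrep("TGCA", 43), strrep("GATC", 43))
  idx <- c(rep(1, 40), rep(2, 7), 3)
  rec <- data.frame(bases = pool[idx],
                    orientation_observed = sample(c("forward", "reverse"),
                                                  48, TRUE))
  cen <- duplicate_census(rec)
  expect_equal(sum(cen$copy_number), nrow(rec))
  expect_equal(cen$copy_number, c(40, 7, 1))
  oracle <- table(rec$bases)
  expect_equal(cen$copy_number[match(names(oracle), cen$bases)],
               as.integer(oracle))
  fwd <- tapply(rec$orientation_observed == "forward", rec$bases, sum)
  expect_equal(cen$forward_count[match(names(fwd), cen$bases)],
               as.integer(fwd))
  # all-unique input has no groups above 1
  uniq <- data.frame(bases = c("AAAA", "CCCC"),
                     orientation_observed = "forward")
  expect_true(all(duplicate_census(uniq)$copy_number == 1))
})

test_that("orientation-bias test reproduces the published artifact set", {
  tab <- read.delim(system.file("extdata", "monomer_duplicate_counts.tsv",
                                package = "alphasat"))
  tab$forward_count <- round(tab$forward_pct / 100 * tab$copy_number)
  res <- orientation_bias_test(tab)
  expect_identical(which(res$artifact_flag), c(2L, 3L, 8L, 15L, 20L))
  expect_identical(tab$variant[res$artifact_flag],
                   c("C114Del", "T101Del", "T80Del", "T39G-C114Del",
                     "T39G-T101Del"))
  # the abundant consensus row is significantly imbalanced but not strongly
  expect_lt(res$bias_p_adjusted[1], 0.05)
  expect_false(res$artifact_flag[1])
  # binomial symmetry: k and n-k give identical p-values
  sym <- data.frame(copy_number = c(100, 100), forward_count = c(30, 70))
  rs <- orientation_bias_test(sym)
  expect_equal(rs$bias_p[1], rs$bias_p[2])
})

test_that("association test flags planted pairings and skips degenerate input", {
  # pure C3->C4 pairing against a C2-C2 background
  left <- c(rep("C3", 40), rep("C2", 60))
  right <- c(rep("C4", 40), rep("C2", 60))
  res <- association_test(left, right)
  expect_gt(res$stdres["C3", "C4"], 2)
  # closed-form chi-square on the 2x2 table: X2 = n (ad - bc)^2 / products
  n <- 100; a <- 60; b <- 0; c <- 0; d <- 40
  x2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$statistic, x2)

  # independent pairs: no residual above 2 (seeded)
  set.seed(56)
  li <- sample(c("C1", "C2"), 1000, TRUE)
  ri <- sample(c("C1", "C2"), 1000, TRUE)
  ri2 <- association_test(li, ri)
  expect_true(all(ri2$stdres < 2.6))

  expect_message(s <- association_test("C1", "C1"), "degenerate")
  expect_identical(s$method, "skipped")
})
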