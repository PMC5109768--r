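fams <- solatus_families()
ref <- default_reference()

test_that("restriction digest cuts at GAANN^NNTTC with exact coordinates", {
  nosite <- paste(rep("ACGT", 30), collapse = "")
  d <- restriction_digest(nosite)
  expect_equal(nrow(d), 1)
  expect_identical(d$bases, nosite)

  # perfect tandem of 10 copies with the site at positions 1-10 of each:
  # cuts at 172k+5 give a 5-bp partial, nine 172-bp internal fragments and
  # a 167-bp terminal partial
  arr <- strrep(fams$C1$consensus, 10)
  d <- restriction_digest(arr)
  expect_equal(nrow(d), 11)
  expect_equal(d$start, c(0, seq(5, by = 172, length.out = 10)))
  expect_equal(d$end - d$start, c(5, rep(172, 9), 167))
  # conservation
  expect_equal(sum(d$end - d$start), nchar(arr))
  expect_identical(paste(d$bases, collapse = ""), arr)

  # one site-killed copy fuses two fragments into a 344-mer
  killed <- fams$C1$consensus
  substr(killed, 1, 1) <- "T"
  arr2 <- paste0(strrep(fams$C1$consensus, 3), killed,
                 strrep(fams$C1$consensus, 3))
  d2 <- restriction_digest(arr2)
  expect_true(344 %in% (d2$end - d2$start))
})

test_that("quality filter thresholds the mean Phred score", {
  reads <- data.frame(bases = rep(strrep("A", 20), 3))
  reads$quals <- list(rep(40L, 20), rep(24L, 20), rep(25L, 20))
  expect_equal(quality_filter(reads), c(TRUE, FALSE, TRUE))
  # toy set: survivor count equals per-read arithmetic
  set.seed(1)
  toy <- data.frame(bases = rep(strrep("A", 30), 10))
  toy$quals <- lapply(1:10, function(i) sample(15:40, 30, replace = TRUE))
  expect_equal(sum(quality_filter(toy)),
               sum(vapply(toy$quals, function(q) mean(q) >= 25, FALSE)))
  empty <- data.frame(bases = "")
  empty$quals <- list(integer(0))
  expect_false(quality_filter(empty))
})

test_that("extremity filter demands digested half-sites at both ends", {
  mid <- strrep("ACGT", 40)
  good <- paste0("AATTC", mid, "GAATT")
  expect_true(extremity_filter(good))
  expect_true(extremity_filter(revcomp_chr(good)))  # orientation-symmetric
  expect_false(extremity_filter(paste0("TTCAA", mid, "GAATT")))
  expect_false(extremity_filter(paste0("AATTC", mid, "TTCAA")))
  expect_false(extremity_filter("AATTC"))  # too short
})

test_that("length filter windows are inclusive", {
  expect_true(length_filter(strrep("A", 172), "monomer"))
  expect_true(length_filter(strrep("A", 162), "monomer"))
  expect_true(length_filter(strrep("A", 182), "monomer"))
  expect_false(length_filter(strrep("A", 161), "monomer"))
  expect_false(length_filter(strrep("A", 183), "monomer"))
  expect_true(length_filter(strrep("A", 324), "dimer"))
  expect_false(length_filter(strrep("A", 323), "dimer"))
})

test_that("similarity filter orients reads and agrees with a SW oracle", {
  fc <- default_fc()
  res <- similarity_filter_and_orient(ref, fc, "monomer")
  expect_true(res$pass)
  expect_identical(res$bases, ref)
  expect_identical(res$orientation_observed, "forward")

  rc <- revcomp_chr(ref)
  res2 <- similarity_filter_and_orient(rc, fc, "monomer")
  expect_true(res2$pass)
  expect_identical(res2$orientation_observed, "reverse")
  expect_identical(res2$bases, ref)  # returned in reference orientation

  set.seed(42)
  rnd <- paste(sample(c("A", "C", "G", "T"), 172, replace = TRUE),
               collapse = "")
  res3 <- similarity_filter_and_orient(rnd, fc, "monomer")
  expect_false(res3$pass)
  # oracle: exhaustive affine SW span below the 80-bp hit threshold on
  # both strands
  expect_lt(max(naive_sw(rnd, ref)$span, naive_sw(revcomp_chr(rnd), ref)$span),
            80)
  # and the oracle reproduces the package span on a true fragment
  sw <- naive_sw(ref, ref)
  expect_equal(sw$span, 172)
})

test_that("cascade counts match planted per-predicate truth", {
  fc <- default_fc()
  g <- simulate_genome(fams, default_arrays(n_c1 = 50, n_c2 = 15, n_hor = 0),
                       seed = 11)
  clean <- error_model(sub_rate = 0.003, homopolymer_del_rate = 0,
                       quality_mean = 33, quality_sd = 3)
  rd <- simulate_reads(g, clean, "monomer", 120, seed = 12)
  rd$fails <- "none"
  plant <- function(rd, n, what, mutate) {
    extra <- rd[sample.int(nrow(rd), n), ]
    extra <- mutate(extra)
    extra$fails <- what
    extra$id <- paste0(extra$id, "_", what)
    rbind(rd, extra)
  }
  set.seed(13)
  rd <- plant(rd, 20, "quality", function(x) {
    x$quals <- lapply(x$quals, function(q) pmax(0L, q - 20L)); x })
  rd <- plant(rd, 20, "extremity", function(x) {
    substr(x$bases, 3, 5) <- "AAA"; x })
  rd <- plant(rd, 20, "length", function(x) {
    # excise an internal block so both extremities survive
    n <- nchar(x$bases)
    x$bases <- paste0(substr(x$bases, 1, 50), substr(x$bases, 101, n))
    x$quals <- lapply(x$quals, function(q) q[-(51:100)]); x })
  rd <- plant(rd, 20, "similarity", function(x) {
    x$bases <- vapply(seq_len(nrow(x)), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 162, replace = TRUE),
                 collapse = "")
      paste0("AATTC", substr(s, 6, nchar(s) - 5), "GAATT")
    }, ""); x })
  rd <- rd[sample.int(nrow(rd)), ]

  res <- run_filter_cascade(rd, fc, "monomer")
  # independent per-predicate oracle from the planted truth
  q_ok <- vapply(rd$quals, function(q) mean(q) >= 25, FALSE)
  b <- rd$bases; n <- nchar(b)
  e_ok <- n >= 10 & substr(b, 3, 5) == "TTC" & substr(b, n - 4, n - 2) == "GAA"
  l_ok <- n >= 162 & n <= 182
  s_ok <- rd$fails != "similarity"  # planted random cores cannot reach 80 bp
  expected <- c(nrow(rd), sum(q_ok), sum(q_ok & e_ok), sum(q_ok & e_ok & l_ok),
                sum(q_ok & e_ok & l_ok & s_ok))
  expect_equal(res$report$count, expected)
  expect_true(all(diff(res$report$count) <= 0))

  # no planted failure may reach the survivor set
  expect_false(any(grepl("_length$|_extremity$|_quality$|_similarity$",
                         res$records$id)))
})

test_that("reorientation is involutive", {
  fc <- default_fc()
  g <- simulate_genome(fams, list(array_spec("C1", 30)), seed = 14)
  rd <- simulate_reads(g, error_model(sub_rate = 0.01,
                                      homopolymer_del_rate = 0),
                       "monomer", 40, seed = 15)
  once <- similarity_filter_and_orient(rd$bases, fc, "monomer")
  twice <- similarity_filter_and_orient(once$bases, fc, "monomer")
  expect_identical(twice$bases, once$bases)
  expect_true(all(twice$orientation_observed[once$pass] == "forward"))
})
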