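test_that("a perfect GC stem folds to a full ladder with the documented energies", {
  f <- fold_hairpin(paste0(strrep("G", 20), "AAAA", strrep("C", 20)))
  expect_equal(f$n_pairs, 20L)
  expect_equal(f$loop_length, 4L)
  expect_equal(f$largest_bulge, 0L)
  ## 19 G:C stacks plus the terminal loop closure
  expect_equal(f$energy, 19 * -3.0 + 4.0)
  expect_valid_hairpin_structure(f)
  ## the explicit structure scorer agrees with the DP on its own optimum
  expect_equal(hairpin_structure_energy(f$sequence, f$structure), f$energy)
})

test_that("sequences without complementarity stay unfolded at energy 0", {
  f <- fold_hairpin(strrep("A", 60))
  expect_equal(f$n_pairs, 0L)
  expect_equal(f$energy, 0)
  expect_equal(f$structure, strrep(".", 60))
})

test_that("an invalid alphabet is rejected", {
  expect_error(fold_hairpin(paste0(strrep("G", 30), "NN", strrep("C", 30))),
               "invalid alphabet")
})

test_that("DP energies equal exhaustive enumeration over all short sequences
           and random sequences up to 24 nt", {
  ## every sequence up to 7 nt (the full-depth sweep runs in the
  ## acceptance suite); enumeration here is the independent recursion
  chk <- goosemir:::.fold_check_exhaustive(7L, unclass(hairpin_energy_params()))
  expect_equal(chk$n_mismatch, 0)
  expect_equal(chk$n_checked, sum(4^(1:7)))
  set.seed(42)
  for (i in 1:60) {
    s <- rand_dna(sample(8:24, 1))
    f <- fold_hairpin(s)
    e <- goosemir:::.fold_enum_core(s, unclass(hairpin_energy_params()))
    expect_equal(f$energy, e$energy, tolerance = 1e-9)
    expect_valid_hairpin_structure(f)
    if (f$n_pairs > 0)
      expect_equal(hairpin_structure_energy(f$sequence, f$structure),
                   f$energy, tolerance = 1e-9)
  }
})

test_that("ties break toward more base pairs", {
  ## G:U-only stems never beat the empty structure (stack -1.2 cannot pay
  ## the +4 loop), so check pair maximisation on an energy-degenerate stem:
  ## extending a perfect stem monotonically lowers energy and adds pairs
  e_prev <- 0; p_prev <- 0
  for (k in c(5, 8, 12)) {
    f <- fold_hairpin(paste0(strrep("G", k), "AAAA", strrep("C", k)))
    expect_lt(f$energy, e_prev)
    expect_gt(f$n_pairs, p_prev)
    e_prev <- f$energy; p_prev <- f$n_pairs
  }
})

make_stem_hairpin <- function(arm, loop) paste0(arm, loop, rc_chr(arm))

test_that("each criterion is evaluated independently with inclusive/strict
           boundaries", {
  th <- hairpin_criteria_thresholds()
  ## a compliant construct: 20-pair mixed stem, loop 17, mature = arm 1..20
  arm <- strrep("GACU", 5)
  hp <- make_stem_hairpin(arm, strrep("A", 17))
  f <- fold_hairpin(hp)
  crit <- evaluate_hairpin_criteria(f, 1, 20, th)
  expect_true(all(crit))

  ## energy boundary: strictly below -20 passes, exactly -20 fails
  fake <- list(sequence = f$sequence, structure = f$structure, energy = -20.0)
  expect_false(evaluate_hairpin_criteria(fake, 1, 20, th)[["energy"]])
  fake$energy <- -20.1
  expect_true(evaluate_hairpin_criteria(fake, 1, 20, th)[["energy"]])

  ## A+U content: 29% and 71% fail, 30% and 70% pass (inclusive)
  au_mature <- function(n_au) {
    m <- c(rep("A", n_au), rep("G", 24 - n_au))
    paste(m, collapse = "")
  }
  for (cse in list(c(7, FALSE), c(8, TRUE))) {   # 7/24 = 29.2%, 8/24 = 33%
    arm2 <- paste0(au_mature(cse[1]), "GGGGGG")
    f2 <- fold_hairpin(make_stem_hairpin(arm2, strrep("A", 17)))
    expect_equal(evaluate_hairpin_criteria(f2, 1, 24, th)[["mature_au"]],
                 as.logical(cse[2]))
  }
})

test_that("tags below the support threshold are never reported", {
  fx <- test_fixture()
  nv <- fx$ref$truth$novel
  tags <- data.frame(sequence = nv$mature, count1 = 2L, count2 = 2L)
  out <- discover_novel_mirnas(tags, fx$ref$transcriptome, min_support = 5L)
  expect_equal(nrow(out), 0L)
  out2 <- discover_novel_mirnas(tags, fx$ref$transcriptome, min_support = 4L)
  expect_equal(nrow(out2), nrow(nv))
})

test_that("identical precursors planted in two transcripts merge into one
           candidate listing both loci", {
  fx <- test_fixture()
  nv <- fx$ref$truth$novel[1, ]
  pre <- gsub("U", "T", nv$precursor)
  flank <- function() rand_dna(80)
  set.seed(5)
  txs <- c(txA = paste0(flank(), pre, flank()),
           txB = paste0(flank(), pre, flank()))
  tags <- data.frame(sequence = nv$mature, count1 = 6L, count2 = 6L)
  out <- discover_novel_mirnas(tags, txs, min_support = 5L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_loci, 2L)
  expect_true(grepl("txA", out$loci) && grepl("txB", out$loci))
})

test_that("the accepted candidate set does not depend on tag order", {
  fx <- test_fixture()
  nv <- fx$ref$truth$novel
  tags <- data.frame(sequence = nv$mature, count1 = 6L, count2 = 6L)
  a <- discover_novel_mirnas(tags, fx$ref$transcriptome)
  b <- discover_novel_mirnas(tags[rev(seq_len(nrow(tags))), ],
                             fx$ref$transcriptome)
  expect_equal(a, b)
})
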