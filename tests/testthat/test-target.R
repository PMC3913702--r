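test_that("a perfect complement scores 0 and passes every rule with ratio 1", {
  mir <- "UGGAAUGUAAAGAAGUAUGUAC"
  site <- rc_chr(mir)
  aln <- duplex_align_and_score(mir, site)
  expect_equal(aln$score, 0)
  expect_true(all(aln$rules))
  mfe <- duplex_mfe_ratio(aln)
  expect_equal(mfe$mfe_ratio, 1)
  expect_true(mfe$pass)
})

test_that("five G:U wobbles score 2.5 and fail the strict two-mismatch rule", {
  mir <- strrep("G", 22)
  site <- strsplit(rc_chr(mir), "")[[1]]
  ## wobble five Gs outside positions 10/11: G at p faces site position L-p+1
  L <- nchar(mir)
  for (p in c(1, 4, 7, 16, 19)) site[L - p + 1] <- "T"   # G:U wobble
  aln <- duplex_align_and_score(mir, paste(site, collapse = ""))
  expect_equal(aln$n_gu, 5L)
  expect_equal(aln$score, 2.5)
  expect_false(aln$rules[["strict"]])
  expect_true(aln$rules[["r1_max_mismatches"]])   # 2.5 <= 4
})

test_that("any mismatch at position 10 or 11 is rejected regardless of score", {
  mir <- "UGGAAUGUAAAGAAGUAUGUAC"
  L <- nchar(mir)
  for (p in c(10L, 11L)) {
    site <- strsplit(rc_chr(mir), "")[[1]]
    idx <- L - p + 1
    site[idx] <- setdiff(c("A", "C", "G", "T"),
                         c(site[idx], comp_base[[substr(mir, p, p)]]))[1]
    aln <- duplex_align_and_score(mir, paste(site, collapse = ""))
    expect_equal(aln$score, 1)
    expect_false(aln$rules[["r4_perfect_10_11"]])
  }
})

test_that("adjacency rules catch runs of non-matches and the seed-span score", {
  mir <- strrep("GA", 11)
  ## three consecutive mismatches at positions 15-17 violate rule 2 only
  site <- strsplit(rc_chr(mir), "")[[1]]
  L <- nchar(mir)
  for (p in 15:17) {
    idx <- L - p + 1
    site[idx] <- setdiff(c("A", "C", "G", "T"),
                         c(comp_base[[substr(mir, p, p)]],
                           ifelse(substr(mir, p, p) %in% c("G", "T"), "T", "x")))[1]
  }
  aln <- duplex_align_and_score(mir, paste(site, collapse = ""))
  expect_false(aln$rules[["r2_adjacent"]])
  ## two adjacent mismatches inside positions 2-12 violate rule 3
  site2 <- strsplit(rc_chr(mir), "")[[1]]
  for (p in 5:6) {
    idx <- L - p + 1
    site2[idx] <- setdiff(c("A", "C", "G", "T"),
                          c(comp_base[[substr(mir, p, p)]],
                            ifelse(substr(mir, p, p) %in% c("G", "T"), "T", "x")))[1]
  }
  aln2 <- duplex_align_and_score(mir, paste(site2, collapse = ""))
  expect_false(aln2$rules[["r3_no_adjacent_2_12"]])
  expect_true(aln2$rules[["r2_adjacent"]])
})

test_that("the MFE-ratio boundary is inclusive at 0.75", {
  mir <- strrep("G", 21)                 # perfect: 20 stacks x -3 = -60
  mk_site <- function(mis_pos) {
    site <- strsplit(rc_chr(mir), "")[[1]]
    site[22 - mis_pos] <- "A"            # G:A mismatch
    paste(site, collapse = "")
  }
  ## mismatches at 7,14,21 leave runs 6/6/6: 15 stacks -> ratio -45/-60 = 0.75
  aln <- duplex_align_and_score(mir, mk_site(c(7, 14, 21)),
                                rules = target_rules(strict_score = 4))
  mfe <- duplex_mfe_ratio(aln)
  expect_equal(mfe$mfe_ratio, 0.75)
  expect_true(mfe$pass)
  ## mismatches at 7,14,20 leave runs 6/6/5/1: 14 stacks -> 0.70, fail
  aln2 <- duplex_align_and_score(mir, mk_site(c(7, 14, 20)),
                                 rules = target_rules(strict_score = 4))
  mfe2 <- duplex_mfe_ratio(aln2)
  expect_equal(mfe2$mfe_ratio, 0.70)
  expect_false(mfe2$pass)
})

test_that("duplex energies match hand evaluation of the stacking table", {
  mir <- strrep("G", 22)
  site <- strsplit(rc_chr(mir), "")[[1]]
  site[c(11, 12)] <- "A"                 # central mismatches at pos 11,12
  aln <- duplex_align_and_score(mir, paste(site, collapse = ""),
                                rules = target_rules())
  mfe <- duplex_mfe_ratio(aln)
  ## runs of 9 and 10 matches: (9-1) + (10-1)... positions 1..10 and 13..22
  expect_equal(mfe$mfe_perfect, -63)
  expect_equal(mfe$mfe_duplex, (10 - 1 + 10 - 1) * -3)
  expect_equal(mfe$mfe_ratio, 54 / 63, tolerance = 1e-9)
})

test_that("an all-A miRNA has no stackable steps and no defined ratio", {
  ## A:U stacks do exist, so use alternating mismatch states instead: a
  ## miRNA of length 1 cannot stack
  aln <- duplex_align_and_score("A", "T")
  expect_error(duplex_mfe_ratio(aln), "undefined MFE ratio")
})

test_that("mismatched window length is an input error", {
  expect_error(duplex_align_and_score("ACGU", "ACGUA"), "identical length")
})

test_that("the exhaustive scan equals the brute-force oracle, and
           tightening the strict threshold never adds sites", {
  set.seed(9)
  mirs <- c(mirA = "UGGAAUGUAAAGAAGUAUGUAC", mirB = "ACCGAUUCGGAACUGAUCGGCA")
  txs <- setNames(lapply(1:4, function(i) rand_dna(400)), paste0("tx", 1:4))
  ## plant a perfect site for mirA and a 1-mismatch site for mirB
  siteA <- rc_chr(mirs[["mirA"]])
  sB <- strsplit(rc_chr(mirs[["mirB"]]), "")[[1]]; sB[3] <- "A"
  txs$tx1 <- paste0(substr(txs$tx1, 1, 100), siteA, substr(txs$tx1, 123, 400))
  txs$tx2 <- paste0(substr(txs$tx2, 1, 200), paste(sB, collapse = ""),
                    substr(txs$tx2, 223, 400))
  txs <- vapply(txs, identity, character(1))
  got <- predict_targets(mirs, txs)
  for (id in names(mirs)) {
    oracle <- merge_sites_oracle(target_scan_oracle(mirs[[id]], txs))
    sub <- got[got$mirna == id, c("transcript", "start", "end", "score")]
    rownames(sub) <- NULL; rownames(oracle) <- NULL
    expect_equal(sub, oracle, info = id)
  }
  ## the planted perfect site is recovered
  expect_true(any(got$mirna == "mirA" & got$transcript == "tx1" &
                    got$start == 101 & got$score == 0))
  ## anti-monotone strict filter
  loose <- predict_targets(mirs, txs, rules = target_rules(strict_score = 4))
  expect_true(nrow(got) <= nrow(loose))
  key <- function(d) paste(d$mirna, d$transcript, d$start)
  expect_true(all(key(got) %in% key(loose)))
  ## empty miRNA list gives an empty table
  expect_equal(nrow(predict_targets(character(0), txs)), 0L)
})
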