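A3 <- "TGGAATTCTCGGGTGCCAAGG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

pad50 <- function(x) substr(paste0(x, strrep("G", 50)), 1, 50)

test_that("each filter class is detected and reported under its own key", {
  reads <- c(
    no_3p = paste(rep("A", 25), collapse = ""),             # 25 nt, no adapter
    p5    = pad50(paste0(substr(A5, 1, 10), strrep("CA", 10), A3)),
    dimer = pad50(A3),
    polyA = pad50(paste0(strrep("A", 20), "CC", A3)),
    short = pad50(paste0("ACGTACGTACGTACGT", A3)),          # 16 nt insert
    long  = pad50(paste0(strrep("ACG", 11), A3)),           # 33 nt insert
    clean = pad50(paste0("ACGTACGTACGTACGTACGTAC", A3)))    # 22 nt insert
  cl <- clean_reads(reads, A3, A5)
  expect_equal(as.character(cl$reasons),
               c("no_3p_adapter", "5p_contaminant", "no_insert", "polyA",
                 "too_short", "length_out_of_range", "clean"))
  expect_equal(unname(cl$discard), c(1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(unname(cl$clean), "ACGTACGTACGTACGTACGTAC")
})

test_that("multi-violation reads are counted once, in the documented order", {
  ## no 3' adapter wins over a 5' contaminant prefix
  r1 <- paste0(substr(A5, 1, 10), strrep("CA", 20))
  ## 5' contaminant wins over a poly(A) insert
  r2 <- pad50(paste0(substr(A5, 1, 10), strrep("A", 20), A3))
  cl <- clean_reads(c(r1, r2), A3, A5)
  expect_equal(as.character(cl$reasons), c("no_3p_adapter", "5p_contaminant"))
})

test_that("adapter detection trims at the leftmost qualifying position and
           tolerates one mismatch in overlaps of 8+", {
  insert <- "ACGTACGTACGTACGTACGTAC"
  mm <- A3
  substr(mm, 5, 5) <- ifelse(substr(mm, 5, 5) == "A", "C", "A")
  cl <- clean_reads(pad50(paste0(insert, mm)), A3, A5)
  expect_equal(unname(cl$clean), insert)
  ## a 5 nt terminal overlap must be exact
  r_exact <- paste0(strrep("CA", 10), "ACT", substr(A3, 1, 5))
  r_mm <- paste0(strrep("CA", 10), "ACT", "TTTTT")
  cl2 <- clean_reads(c(r_exact, r_mm), A3, A5)
  expect_equal(as.character(cl2$reasons), c("clean", "no_3p_adapter"))
})

test_that("discard tally plus clean count equals the raw count on the fixture,
           and per-class counts match the simulator ledger exactly", {
  fx <- test_fixture()
  tg <- test_fixture_tags()
  for (lib in 1:2) {
    cl <- tg$clean[[lib]]
    expect_equal(length(cl$clean) + sum(cl$discard), cl$n_raw)
    ledger <- fx$sim$truth$class_counts
    ledger <- ledger[ledger$library == paste0("lib", lib), ]
    junk <- setNames(ledger$count[grepl("^junk_", ledger$class)],
                     sub("^junk_", "", ledger$class[grepl("^junk_", ledger$class)]))
    expect_equal(cl$discard[names(junk)], junk)
    expect_equal(length(cl$clean), fx$sim$truth$clean_total[lib])
  }
})

test_that("collapse_tags is an exact multiset collapse that conserves counts", {
  out <- collapse_tags(list(lib1 = c("ACGTACGTACGTACGTAA", "ACGTACGTACGTACGTAA",
                                     "TTTTACGTACGTACGTCC")))
  expect_equal(out$count1[out$sequence == "ACGTACGTACGTACGTAA"], 2L)
  expect_equal(out$count1[out$sequence == "TTTTACGTACGTACGTCC"], 1L)
  expect_equal(sum(out$count1), 3L)

  tg <- test_fixture_tags()
  expect_equal(sum(tg$tags$count1), length(tg$clean$cl1$clean))
  expect_equal(sum(tg$tags$count2), length(tg$clean$cl2$clean))
  ## collapse/expand round-trip preserves the multiset
  expanded <- rep(tg$tags$sequence, tg$tags$count1)
  expect_equal(sort(expanded), sort(unname(tg$clean$cl1$clean)))
})

test_that("common/specific partition equals the brute-force set oracle", {
  tg <- test_fixture_tags()
  s <- library_summary(tg$tags)
  set1 <- unique(unname(tg$clean$cl1$clean))
  set2 <- unique(unname(tg$clean$cl2$clean))
  common <- intersect(set1, set2)
  expect_equal(s$overlap$common_pct[2],
               100 * length(common) / length(union(set1, set2)))
  expect_equal(s$overlap$specific1_pct[2],
               100 * length(setdiff(set1, set2)) / length(union(set1, set2)))
  ## percentages sum to 100 within each partition
  expect_equal(sum(s$length_dist$pct_total), 100, tolerance = 1e-4)
  expect_equal(s$overlap$common_pct[1] + s$overlap$specific1_pct[1] +
                 s$overlap$specific2_pct[1], 100, tolerance = 1e-9)
})

test_that("degenerate summaries behave: single-length library and identical libraries", {
  tags <- collapse_tags(list(lib1 = rep(strrep("AC", 11), 10),
                             lib2 = rep(strrep("AC", 11), 4)))
  s <- library_summary(tags)
  expect_equal(s$length_dist$pct1[s$length_dist$length == 22], 100)
  expect_equal(s$overlap$common_pct, c(100, 100))
  expect_error(library_summary(collapse_tags(list(lib1 = "ACGTACGTACGTACGTAC",
                                                  lib2 = character()))),
               "empty library")
})

test_that("a malformed FASTQ is reported with its record index", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGT", "+", "III"), f)   # quality too short
  expect_error(clean_reads(f, A3, A5), "record 2")
})
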