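test_that("the priority rule assigns exactly one category per tag", {
  tags <- c("T1", "T2", "T3", "T4")
  cat <- assign_category(tags, list(
    rRNA_etc_GenBank = c("T1"),
    known_miRNA = c("T1", "T2"),
    exon = c("T3"),
    intron = c("T3")))
  expect_equal(as.character(cat),
               c("rRNA_etc_GenBank", "known_miRNA", "exon", "unannotated"))
  ## partition: every tag appears in exactly one category
  expect_equal(sum(table(cat)), length(tags))
})

test_that("tags are attributed to known miRNAs within offset and tolerance", {
  mat <- c(`mir-b` = "ACGTACGTACGTACGTACGTAC",
           `mir-a` = "TGCATGCATGCATGCATGCAT")
  pre <- setNames(paste0("GGGGGCCCCC", mat, "TTTTTGGGGG"), names(mat))
  tags <- data.frame(sequence = c(mat[["mir-b"]],                 # exact
                                  paste0("C", mat[["mir-a"]])),   # 5' shift -1
                     count1 = c(7L, 3L), count2 = c(1L, 0L))
  q <- quantify_known_mirnas(tags, mat, pre, tolerance = 0)
  expect_equal(q$counts$count1[q$counts$mirna == "mir-b"], 7L)
  expect_equal(q$counts$count1[q$counts$mirna == "mir-a"], 3L)
  expect_false(any(q$assignments$ambiguous))
})

test_that("equidistant tags go to the lexicographically smallest ID, flagged ambiguous", {
  base <- "ACGTACGTACGTACGTACGTAC"
  tag <- paste0(substr(base, 1, 21), "G")     # 1 mismatch from base (last nt)
  mat <- c(`mir-z` = base, `mir-a` = base)
  names(mat) <- c("mir-z", "mir-a")
  pre <- setNames(paste0("AAAAA", mat, "CCCCC"), names(mat))
  tags <- data.frame(sequence = tag, count1 = 5L, count2 = 2L)
  q <- quantify_known_mirnas(tags, mat, pre, tolerance = 1)
  expect_equal(q$assignments$mirna, "mir-a")
  expect_true(q$assignments$ambiguous)
  expect_equal(q$counts$mirna, "mir-a")
  expect_error(quantify_known_mirnas(tags, c(a = base, a = base),
                                     c(a = base, a = base)),
               "duplicate mature IDs")
})

test_that("raising the tolerance never decreases any miRNA count", {
  fx <- test_fixture()
  tg <- test_fixture_tags()
  prev <- NULL
  for (tol in 0:2) {
    q <- quantify_known_mirnas(tg$tags, fx$ref$matures, fx$ref$precursors,
                               tolerance = tol)
    cur <- setNames(q$counts$count1 + q$counts$count2, q$counts$mirna)
    if (!is.null(prev)) {
      shared <- names(prev)
      expect_true(all(cur[shared] >= prev[shared]))
    }
    prev <- cur
  }
})

test_that("with the fixture, zero-tolerance counts equal the planted ledger exactly", {
  cfg <- simulation_config(seed = 11L, n_reads_per_library = c(8000L, 8000L),
                           count_noise = 0)
  ref <- build_reference(cfg)
  sim <- simulate_libraries(cfg, ref)
  cl1 <- clean_reads(sim$reads$lib1, cfg$adapter_3p, cfg$adapter_5p)
  cl2 <- clean_reads(sim$reads$lib2, cfg$adapter_3p, cfg$adapter_5p)
  tags <- collapse_tags(list(unname(cl1$clean), unname(cl2$clean)))
  q <- quantify_known_mirnas(tags, ref$matures, ref$precursors, tolerance = 0)
  truth <- sim$truth$mirna_counts
  truth <- truth[truth$count1 + truth$count2 > 0, ]
  got <- q$counts[match(truth$id, q$counts$mirna), ]
  expect_equal(got$count1, truth$count1)
  expect_equal(got$count2, truth$count2)
})

test_that("annotate_tags partitions the fixture tags and honours priority", {
  fx <- test_fixture()
  tg <- test_fixture_tags()
  ann <- annotate_tags(tg$tags, fx$ref)
  expect_equal(sum(ann$summary$n_unique_tags), nrow(tg$tags))
  expect_equal(length(ann$category), nrow(tg$tags))
  ## contaminant tags must not be claimed by lower-priority categories
  contam <- match_contaminants(tg$tags$sequence, fx$ref$contaminants)
  expect_true(all(ann$category[contam$rRNA_etc_GenBank] == "rRNA_etc_GenBank"))
  ## families: members share identical seed (positions 2-8)
  seeds <- substr(fx$ref$matures[ann$known$counts$mirna], 2, 8)
  expect_equal(unname(ann$known$counts$family), paste0("fam-", unname(seeds)))
})
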