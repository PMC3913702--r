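test_that("invalid configurations are rejected up front", {
  expect_error(simulation_config(n_known_mirnas = 5, n_de = 6,
                                 planted_log2fc = rep(2, 6)),
               "n_de exceeds")
  expect_error(simulation_config(contaminant_fraction = 0.7,
                                 junk_fraction = 0.5), "sum <= 1")
  expect_error(simulation_config(count_noise = -1), "count_noise")
})

test_that("the reference carries the configured number of unique mature IDs
           and planted structures pass their own acceptance predicates", {
  cfg <- simulation_config(seed = 3L, n_reads_per_library = c(2000L, 2000L),
                           n_known_mirnas = 10L, n_de = 4L,
                           planted_log2fc = c(2, 2, -2, -2),
                           n_novel_hairpins = 1L, n_target_transcripts = 8L)
  ref <- build_reference(cfg)
  expect_equal(length(ref$matures), 10L)
  expect_equal(anyDuplicated(names(ref$matures)), 0L)
  expect_true(all(nchar(ref$matures) >= 20 & nchar(ref$matures) <= 24))

  ## planted hairpin: 7/7 criteria under the package's own fold
  nv <- ref$truth$novel
  f <- fold_hairpin(nv$precursor[1])
  crit <- evaluate_hairpin_criteria(f, 1, nchar(nv$mature[1]))
  expect_true(all(crit))
  ## and the precursor is really at the recorded transcript coordinates
  expect_equal(substr(ref$transcriptome[[nv$transcript[1]]], nv$start[1],
                      nv$end[1]),
               gsub("U", "T", nv$precursor[1]))

  ## planted target sites pass the target module's own scorer with <= 2
  ## mismatches
  tg <- ref$truth$targets
  for (i in seq_len(nrow(tg))) {
    mir <- ref$matures[[tg$mirna[i]]]
    win <- substr(ref$transcriptome[[tg$transcript[i]]], tg$start[i], tg$end[i])
    aln <- duplex_align_and_score(mir, win)
    expect_true(aln$rules[["accepted"]])
    expect_lte(aln$score, 2)
  }
})

test_that("a fixed seed reproduces the simulation byte for byte", {
  cfg <- simulation_config(seed = 5L, n_reads_per_library = c(1500L, 1500L),
                           n_known_mirnas = 15L, n_de = 4L,
                           n_novel_hairpins = 1L, n_target_transcripts = 6L)
  ref1 <- build_reference(cfg); sim1 <- simulate_libraries(cfg, ref1)
  ref2 <- build_reference(cfg); sim2 <- simulate_libraries(cfg, ref2)
  expect_identical(ref1$transcriptome, ref2$transcriptome)
  expect_identical(sim1$reads, sim2$reads)
  expect_identical(sim1$truth$mirna_counts, sim2$truth$mirna_counts)
})

test_that("per-provenance counts are conserved and sum to the library sizes", {
  fx <- test_fixture()
  prov <- fx$sim$truth$read_provenance
  for (lib in c("lib1", "lib2")) {
    p <- prov[prov$library == lib, ]
    expect_equal(nrow(p), length(fx$sim$reads[[lib]]))
    ## every read has exactly one label
    expect_equal(anyDuplicated(p$read_id), 0L)
    cc <- fx$sim$truth$class_counts
    cc <- cc[cc$library == lib, ]
    expect_equal(sum(cc$count),
                 fx$cfg$n_reads_per_library[as.integer(substr(lib, 4, 4))])
    expect_equal(setNames(cc$count, cc$class)[sort(unique(p$class))],
                 setNames(as.integer(table(p$class)[sort(unique(p$class))]),
                          sort(unique(p$class))))
  }
  ## miRNA ledger counts equal the per-read provenance recount
  p1 <- prov[prov$library == "lib1" & prov$class == "miRNA", ]
  recount <- table(p1$feature)
  mc <- fx$sim$truth$mirna_counts
  expect_equal(mc$count1[match(names(recount), mc$id)],
               as.integer(recount))
})

test_that("with no noise and no planted fold change, expected counts scale
           with library size", {
  cfg <- simulation_config(seed = 8L, n_reads_per_library = c(4000L, 2000L),
                           n_known_mirnas = 12L, n_de = 0L,
                           planted_log2fc = numeric(0), count_noise = 0,
                           n_novel_hairpins = 0L, n_target_transcripts = 5L)
  ref <- build_reference(cfg)
  sim <- simulate_libraries(cfg, ref)
  mc <- sim$truth$mirna_counts
  ## totals are fixed exactly by the allocation
  expect_equal(sum(mc$count1) / sum(mc$count2), 2, tolerance = 1e-12)
  ## per-feature counts stay near the 2:1 expectation
  big <- mc$count2 >= 50
  expect_true(all(abs(mc$count1[big] / mc$count2[big] - 2) < 0.75))
})

test_that("the fixture bundle writes 8 checksummed files and verification
           catches tampering", {
  fx <- test_fixture()
  out <- tempfile("bundle")
  man <- write_fixture_bundle(fx$sim, fx$ref, out)
  expect_equal(nrow(man), 8L)
  expect_equal(sum(grepl("\\.fastq$", man$file)), 2L)
  expect_equal(sum(grepl("\\.fa$", man$file)), 4L)
  expect_equal(sum(grepl("\\.tsv$", man$file)), 2L)
  v <- verify_fixture_bundle(out)
  expect_true(v$ok)
  ## same seed regenerates identical checksums
  out2 <- tempfile("bundle")
  man2 <- write_fixture_bundle(fx$sim, fx$ref, out2)
  expect_equal(man$md5, man2$md5)
  ## deleting a file is reported by name
  unlink(file.path(out, "matures.fa"))
  v2 <- verify_fixture_bundle(out)
  expect_false(v2$ok)
  expect_true(any(grepl("matures.fa", v2$problems)))
  unlink(c(out, out2), recursive = TRUE)
})
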