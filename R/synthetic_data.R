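## Synthetic two-library small-RNA experiment with full ground truth.
## Every planted structure is validated with the downstream modules' own
## acceptance predicates (the read classifier, the hairpin criteria, the
## target rules), never with private copies, so the ledger is exact by
## construction.

## Evaluate an expression with a temporary RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

.rand_seq <- function(len, alphabet = c("A", "C", "G", "T"),
                      prob = NULL) {
  paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
}

#' Configuration of a synthetic two-library experiment
#'
#' Defaults describe the emulated study conditions: two libraries of 1e5
#' reads with 19-24 nt inserts (mode 22 nt), standard small-RNA kit
#' adapters, ~15% contaminant small RNAs, ~12% junk reads spread over the
#' six filter classes, 60 known miRNAs of which 16 carry a planted
#' |log2 fold change| of 2, three novel hairpin precursors planted in
#' transcripts, and one perfect target site per differentially expressed
#' miRNA in a 3'UTR-like transcript tail.
#'
#' @param seed Integer; fully determines the simulated experiment.
#' @param n_reads_per_library Integer pair of raw library sizes.
#' @param adapter_3p,adapter_5p Adapter sequences.
#' @param n_known_mirnas Number of known mature miRNAs in the reference.
#' @param n_de Number of miRNAs with a planted fold change
#'   (`n_null = n_known_mirnas - n_de`).
#' @param planted_log2fc Planted log2 fold changes (library 2 over
#'   library 1), recycled to length `n_de`.
#' @param contaminant_fraction,junk_fraction Read fractions in `[0, 1]`
#'   (sum <= 1).
#' @param n_novel_hairpins Novel precursors planted in transcripts.
#' @param n_target_transcripts Transcripts in the synthetic transcriptome.
#' @param count_noise Overdispersion of feature counts (gamma-Poisson;
#'   0 = Poisson/deterministic weights).
#' @param read_length Sequencer read length (nt).
#' @param min_len,max_len Insert length range retained by cleaning.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_reads_per_library = c(100000L, 100000L),
                              adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                              adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                              n_known_mirnas = 60L,
                              n_de = 16L,
                              planted_log2fc = rep(c(2, -2), length.out = 16L),
                              contaminant_fraction = 0.15,
                              junk_fraction = 0.12,
                              n_novel_hairpins = 3L,
                              n_target_transcripts = 30L,
                              count_noise = 0.1,
                              read_length = 50L,
                              min_len = 18L, max_len = 30L) {
  cfg <- list(seed = as.integer(seed),
              n_reads_per_library = as.integer(rep_len(n_reads_per_library, 2)),
              adapter_3p = as_dna(adapter_3p), adapter_5p = as_dna(adapter_5p),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_de = as.integer(n_de),
              planted_log2fc = rep_len(as.numeric(planted_log2fc),
                                       as.integer(n_de)),
              n_null = as.integer(n_known_mirnas) - as.integer(n_de),
              contaminant_fraction = contaminant_fraction,
              junk_fraction = junk_fraction,
              n_novel_hairpins = as.integer(n_novel_hairpins),
              n_target_transcripts = as.integer(n_target_transcripts),
              count_noise = count_noise,
              read_length = as.integer(read_length),
              min_len = as.integer(min_len), max_len = as.integer(max_len))
  if (cfg$n_de > cfg$n_known_mirnas)
    stop("configuration error: n_de exceeds n_known_mirnas", call. = FALSE)
  if (cfg$contaminant_fraction < 0 || cfg$junk_fraction < 0 ||
      cfg$contaminant_fraction + cfg$junk_fraction > 1)
    stop("configuration error: read fractions must be in [0,1] and sum <= 1",
         call. = FALSE)
  if (cfg$count_noise < 0)
    stop("configuration error: count_noise must be >= 0", call. = FALSE)
  if (any(cfg$n_reads_per_library < 100))
    stop("configuration error: libraries must have >= 100 reads", call. = FALSE)
  if (cfg$n_target_transcripts < max(1, cfg$n_novel_hairpins))
    stop("configuration error: not enough transcripts to plant hairpins",
         call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

## One validated clean read: insert + 3' adapter, G-padded to read length.
.make_read <- function(insert, cfg) {
  substr(paste0(insert, cfg$adapter_3p, strrep("G", cfg$read_length)),
         1L, cfg$read_length)
}

## Classify candidate inserts with the preprocess module's own filter chain;
## returns TRUE where the read built from the insert survives cleaning and
## trims back to exactly the insert.
.insert_is_clean <- function(inserts, cfg) {
  reads <- vapply(inserts, .make_read, character(1), cfg = cfg,
                  USE.NAMES = FALSE)
  cl <- clean_reads(reads, cfg$adapter_3p, cfg$adapter_5p,
                    cfg$min_len, cfg$max_len)
  ok <- cl$reasons == "clean"
  ok[ok] <- unname(cl$clean) == inserts[ok]
  ok
}

## Draw a random mature-like sequence (validated clean, balanced A+U).
.draw_mature <- function(cfg, len = NULL) {
  repeat {
    L <- if (is.null(len)) sample(20:24, 1, prob = c(1, 2, 4, 2, 1)) else len
    s <- .rand_seq(L)
    au <- mean(strsplit(s, "")[[1]] %in% c("A", "T"))
    if (au < 0.35 || au > 0.65) next
    if (.insert_is_clean(s, cfg)) return(s)
  }
}

## Build one novel precursor passing all seven criteria under the package's
## own fold + criteria evaluation, with the mature on the 5' arm.
.draw_novel_precursor <- function(cfg, params, thresholds) {
  repeat {
    arm5 <- .draw_mature(cfg, len = 30L)
    loop <- .rand_seq(6L)
    pre <- paste0(arm5, loop, revcomp(arm5))
    mature <- substr(arm5, 1L, 22L)
    fold <- fold_hairpin(pre, params)
    crit <- evaluate_hairpin_criteria(fold, 1L, 22L, thresholds)
    if (!crit[["accepted"]]) next
    if (!.insert_is_clean(mature, cfg)) next
    return(list(precursor = pre, mature = mature, arm = "5p"))
  }
}

#' Build the synthetic reference bundle
#'
#' Generates known mature miRNAs and their precursors, contaminant small
#' RNAs (GenBank/Rfam tagged), a transcriptome with planted novel hairpin
#' precursors and planted miRNA target sites, and a gene-to-GO/KEGG
#' annotation map. Planted hairpins are accepted only if they pass all
#' seven stem-loop criteria (checked with [fold_hairpin()] and
#' [evaluate_hairpin_criteria()], including the windowed fold used by
#' discovery), and planted target sites only if they pass all target rules
#' (checked with [duplex_align_and_score()] and [duplex_mfe_ratio()]).
#'
#' @param config A [simulation_config()].
#' @param params,thresholds,rules Downstream acceptance predicates used for
#'   self-checks.
#' @return List of class `reference_bundle`: `matures`, `precursors`,
#'   `contaminants`, `transcriptome` (named character vectors), `ann_map`
#'   (data frame) and `truth` (planted features).
#' @export
build_reference <- function(config,
                            params = hairpin_energy_params(),
                            thresholds = hairpin_criteria_thresholds(),
                            rules = target_rules()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    ## known miRNAs and precursors
    n <- cfg$n_known_mirnas
    ids <- sprintf("gmir-%03d", seq_len(n))
    ids[seq_len(n) %% 9 == 0] <- paste0(ids[seq_len(n) %% 9 == 0], "*")
    matures <- setNames(vapply(seq_len(n), function(i) .draw_mature(cfg),
                               character(1)), ids)
    precursors <- setNames(vapply(matures, function(m)
      paste0(.rand_seq(15L), m, .rand_seq(20L)), character(1)), ids)

    ## contaminant small RNAs
    classes <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA"), each = 4)
    src <- rep_len(c("GenBank", "Rfam"), length(classes))
    contam <- vapply(seq_along(classes), function(i)
      .rand_seq(sample(80:150, 1)), character(1))
    names(contam) <- sprintf("contam%02d_%s source=%s class=%s",
                             seq_along(classes), classes, src, classes)

    ## transcriptome
    ntx <- cfg$n_target_transcripts
    tx <- setNames(vapply(seq_len(ntx), function(i)
      .rand_seq(sample(400:700, 1)), character(1)),
      sprintf("tx%03d", seq_len(ntx)))

    ## plant novel hairpin precursors (middle of distinct transcripts,
    ## clear of the 3'UTR-like tail used for target sites)
    novel <- NULL
    if (cfg$n_novel_hairpins > 0) {
      rows <- list()
      for (k in seq_len(cfg$n_novel_hairpins)) {
        txid <- names(tx)[k]
        repeat {
          hp <- .draw_novel_precursor(cfg, params, thresholds)
          len <- nchar(tx[[txid]])
          plen <- nchar(hp$precursor)
          pos <- sample(seq(40L, len - plen - 160L), 1)
          cand_tx <- paste0(substr(tx[[txid]], 1, pos - 1), hp$precursor,
                            substr(tx[[txid]], pos + plen, len))
          ## self-check with the discovery module's own windowed fold
          ok <- !is.null(.fold_tag_windows(cand_tx, pos, pos + 21L, 120L,
                                           params, thresholds))
          ## the mature tag must be unique in the transcriptome
          ok <- ok && sum(vapply(c(tx, cand_tx), function(s)
            lengths(regmatches(s, gregexpr(hp$mature, s, fixed = TRUE))),
            integer(1))) == 1
          if (ok) break
        }
        tx[[txid]] <- cand_tx
        rows[[k]] <- data.frame(id = sprintf("novel-%d", k),
                                transcript = txid, start = pos,
                                end = pos + nchar(hp$precursor) - 1L,
                                mature = hp$mature, arm = hp$arm,
                                precursor = hp$precursor,
                                stringsAsFactors = FALSE)
      }
      novel <- do.call(rbind, rows)
    }

    ## plant one perfect target site per DE miRNA in a transcript tail
    de_ids <- ids[seq_len(cfg$n_de)]
    targets <- NULL
    if (cfg$n_de > 0) {
      rows <- list()
      used <- list()
      for (i in seq_along(de_ids)) {
        mir <- matures[[de_ids[i]]]
        site <- revcomp(mir)
        L <- nchar(site)
        repeat {
          txid <- names(tx)[sample(ntx, 1)]
          len <- nchar(tx[[txid]])
          pos <- sample(seq(len - 140L, len - L - 5L), 1)
          iv <- used[[txid]]
          if (!is.null(iv) &&
              any(pos <= iv[, 2] + 2 & pos + L - 1 >= iv[, 1] - 2)) next
          cand_tx <- paste0(substr(tx[[txid]], 1, pos - 1), site,
                            substr(tx[[txid]], pos + L, len))
          aln <- duplex_align_and_score(mir, substr(cand_tx, pos, pos + L - 1),
                                        rules)
          mfe <- duplex_mfe_ratio(aln, rules, params)
          if (aln$rules[["accepted"]] && mfe$pass) break
        }
        used[[txid]] <- rbind(used[[txid]], c(pos, pos + L - 1))
        tx[[txid]] <- cand_tx
        rows[[i]] <- data.frame(mirna = de_ids[i], transcript = txid,
                                start = pos, end = pos + L - 1L,
                                score = aln$score, stringsAsFactors = FALSE)
      }
      targets <- do.call(rbind, rows)
    }

    ## GO / KEGG annotation map; one GO term concentrates on target-bearing
    ## transcripts so enrichment has signal
    go_terms <- sprintf("GO:%07d", 1:12)
    go_ns <- rep_len(c("biological_process", "molecular_function",
                       "cellular_component"), 12)
    kegg_terms <- sprintf("ko%05d", 1:5)
    ann <- list()
    target_txs <- if (is.null(targets)) character() else unique(targets$transcript)
    for (t in names(tx)) {
      gos <- sample(go_terms[-1], sample(2:4, 1))
      if (t %in% target_txs) gos <- unique(c(go_terms[1], gos))
      keg <- if (runif(1) < 0.7) sample(kegg_terms, sample(1:2, 1)) else character()
      lab_go <- sprintf("synthetic GO term %d", match(gos, go_terms))
      lab_kegg <- sprintf("synthetic pathway %d", match(keg, kegg_terms))
      ann[[t]] <- data.frame(
        gene_id = t, term_id = c(gos, keg),
        term_label = c(lab_go, lab_kegg),
        namespace = c(go_ns[match(gos, go_terms)],
                      rep("KEGG", length(keg))),
        stringsAsFactors = FALSE)
    }
    ann_map <- do.call(rbind, c(ann, list(make.row.names = FALSE)))

    ## expression programme
    base_mean <- exp(stats::rnorm(n, log(100), 0.8))
    true_lfc <- numeric(n)
    true_lfc[seq_len(cfg$n_de)] <- cfg$planted_log2fc
    mirna_truth <- data.frame(id = ids, base_mean = base_mean,
                              true_log2fc = true_lfc,
                              is_de = seq_len(n) <= cfg$n_de,
                              stringsAsFactors = FALSE)

    out <- list(matures = matures, precursors = precursors,
                contaminants = contam, transcriptome = tx, ann_map = ann_map,
                truth = list(mirna = mirna_truth, novel = novel,
                             targets = targets),
                config = cfg)
    class(out) <- "reference_bundle"
    out
  })
}

## Junk read generators, one per filter class; each batch is validated with
## the preprocess classifier and offenders are redrawn.
.junk_generators <- function(cfg) {
  a3 <- cfg$adapter_3p; a5 <- cfg$adapter_5p; RL <- cfg$read_length
  pad <- function(x) substr(paste0(x, strrep("G", RL)), 1, RL)
  list(
    no_3p_adapter = function(n) vapply(seq_len(n), function(i)
      .rand_seq(RL), character(1)),
    `5p_contaminant` = function(n) vapply(seq_len(n), function(i)
      pad(paste0(substr(a5, 1, 10), .rand_seq(15L), a3)), character(1)),
    no_insert = function(n) rep(pad(a3), n),
    polyA = function(n) vapply(seq_len(n), function(i) {
      ins <- strsplit(strrep("A", 22L), "")[[1]]
      ins[sample(22L, 2L)] <- sample(c("C", "G"), 2L, replace = TRUE)
      pad(paste0(paste(ins, collapse = ""), a3))
    }, character(1)),
    too_short = function(n) vapply(seq_len(n), function(i)
      pad(paste0(.rand_seq(sample(10:16, 1)), a3)), character(1)),
    length_out_of_range = function(n) vapply(seq_len(n), function(i)
      pad(paste0(.rand_seq(sample(31:38, 1)), a3)), character(1)))
}

.validated_batch <- function(gen, n, class, cfg) {
  reads <- gen(n)
  for (iter in 1:50) {
    cl <- clean_reads(reads, cfg$adapter_3p, cfg$adapter_5p,
                      cfg$min_len, cfg$max_len)
    bad <- which(as.character(cl$reasons) != class)
    if (!length(bad)) return(reads)
    reads[bad] <- gen(length(bad))
  }
  stop("could not generate reads of junk class ", class, call. = FALSE)
}

#' Simulate the two sequencing libraries
#'
#' Feature counts are gamma-Poisson weights (deterministic when
#' `count_noise = 0`) allocated by a single multinomial draw conditioned on
#' the configured library total, so provenance counts always sum exactly to
#' the library size. Junk reads are validated against the preprocess
#' module's own classifier so each violates exactly its intended filter.
#'
#' @param config A [simulation_config()].
#' @param reference Bundle from [build_reference()] (same config).
#' @return List of class `srna_simulation`: `reads` (per-library named
#'   character vectors), `truth` (provenance ledger: `read_provenance`,
#'   `mirna_counts`, `novel_counts`, `class_counts`, `clean_total`) and
#'   `config`.
#' @export
simulate_libraries <- function(config, reference) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(reference, "reference_bundle"))
  cfg <- config
  ref <- reference
  with_seed(cfg$seed + 1L, {
    gens <- .junk_generators(cfg)
    n_feat <- nrow(ref$truth$mirna)
    novel <- ref$truth$novel
    n_nov <- if (is.null(novel)) 0L else nrow(novel)

    ## pre-validated contaminant fragment pool
    contam_pool <- lapply(seq_along(ref$contaminants), function(ci) {
      seqs <- character(0)
      while (length(seqs) < 12) {
        L <- sample(19:24, 1)
        s0 <- sample(nchar(ref$contaminants[ci]) - L + 1, 1)
        frag <- substr(ref$contaminants[[ci]], s0, s0 + L - 1)
        if (.insert_is_clean(frag, cfg)) seqs <- c(seqs, frag)
      }
      unique(seqs)
    })

    libs <- list()
    prov <- list()
    mirna_counts <- matrix(0L, n_feat, 2,
                           dimnames = list(ref$truth$mirna$id, NULL))
    novel_counts <- matrix(0L, max(n_nov, 1), 2)
    class_rows <- list()
    clean_total <- integer(2)

    for (lib in 1:2) {
      N <- cfg$n_reads_per_library[lib]
      n_junk <- round(cfg$junk_fraction * N)
      junk_each <- rep(n_junk %/% 6L, 6L)
      extra <- n_junk - sum(junk_each)
      if (extra > 0) junk_each[seq_len(extra)] <- junk_each[seq_len(extra)] + 1L
      names(junk_each) <- names(gens)
      n_contam <- round(cfg$contaminant_fraction * N)
      n_main <- N - n_junk - n_contam

      w <- ref$truth$mirna$base_mean *
        ifelse(rep(lib == 2, n_feat), 2^ref$truth$mirna$true_log2fc, 1)
      w_nov <- rep(15, n_nov)
      w_all <- c(w, w_nov)
      if (cfg$count_noise > 0) {
        sh <- 1 / cfg$count_noise
        w_all <- rgamma(length(w_all), shape = sh, rate = sh / w_all)
        w_all[w_all <= 0] <- 1e-9
      }
      counts_main <- as.integer(rmultinom(1, n_main, w_all))
      counts_contam <- as.integer(rmultinom(1, n_contam,
                                            rep(1, length(ref$contaminants))))

      mirna_counts[, lib] <- counts_main[seq_len(n_feat)]
      if (n_nov > 0) novel_counts[, lib] <- counts_main[n_feat + seq_len(n_nov)]

      reads <- character(0); label <- character(0); feat <- character(0)
      add <- function(seqs, cls, ft) {
        reads <<- c(reads, seqs)
        label <<- c(label, rep(cls, length(seqs)))
        feat <<- c(feat, ft)
      }
      for (i in seq_len(n_feat)) {
        ci <- counts_main[i]
        if (ci > 0) add(rep(.make_read(ref$matures[[i]], cfg), ci), "miRNA",
                        rep(ref$truth$mirna$id[i], ci))
      }
      if (n_nov > 0) for (k in seq_len(n_nov)) {
        ck <- counts_main[n_feat + k]
        if (ck > 0) add(rep(.make_read(novel$mature[k], cfg), ck),
                        "novel_hairpin_arm", rep(novel$id[k], ck))
      }
      for (ci in seq_along(ref$contaminants)) {
        cc <- counts_contam[ci]
        if (cc > 0) {
          frags <- sample(contam_pool[[ci]], cc, replace = TRUE)
          add(vapply(frags, .make_read, character(1), cfg = cfg,
                     USE.NAMES = FALSE), "contaminant",
              rep(names(ref$contaminants)[ci], cc))
        }
      }
      for (cls in names(gens)) {
        nk <- junk_each[[cls]]
        if (nk > 0) add(.validated_batch(gens[[cls]], nk, cls, cfg),
                        paste0("junk_", cls), rep(cls, nk))
      }
      ord <- sample(length(reads))
      reads <- reads[ord]; label <- label[ord]; feat <- feat[ord]
      names(reads) <- sprintf("L%d_%06d", lib, seq_along(reads))
      libs[[paste0("lib", lib)]] <- reads
      prov[[lib]] <- data.frame(library = paste0("lib", lib),
                                read_id = names(reads), class = label,
                                feature = feat, stringsAsFactors = FALSE)
      tab <- table(label)
      class_rows[[lib]] <- data.frame(library = paste0("lib", lib),
                                      class = names(tab),
                                      count = as.integer(tab),
                                      stringsAsFactors = FALSE)
      clean_total[lib] <- sum(label %in% c("miRNA", "novel_hairpin_arm",
                                           "contaminant"))
    }

    truth <- list(
      read_provenance = do.call(rbind, prov),
      mirna_counts = data.frame(id = ref$truth$mirna$id,
                                count1 = mirna_counts[, 1],
                                count2 = mirna_counts[, 2],
                                true_log2fc = ref$truth$mirna$true_log2fc,
                                is_de = ref$truth$mirna$is_de,
                                stringsAsFactors = FALSE),
      novel_counts = if (n_nov > 0)
        data.frame(id = novel$id, count1 = novel_counts[, 1],
                   count2 = novel_counts[, 2], stringsAsFactors = FALSE)
        else NULL,
      class_counts = do.call(rbind, class_rows),
      clean_total = clean_total)
    out <- list(reads = libs, truth = truth, config = cfg)
    class(out) <- "srna_simulation"
    out
  })
}

#' Write the simulated experiment to disk
#'
#' Produces 2 FASTQ (libraries), 4 FASTA (matures, precursors,
#' contaminants, transcriptome), 2 TSV (annotation map, feature-level truth
#' ledger) plus `manifest.json` with an MD5 checksum per file.
#'
#' @param sim Output of [simulate_libraries()].
#' @param reference Matching [build_reference()] bundle.
#' @param outdir Output directory (created if needed).
#' @return Data frame manifest (file, md5, bytes), invisibly the same as
#'   written to `manifest.json`.
#' @export
write_fixture_bundle <- function(sim, reference, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir,
                                call. = FALSE)
  ref <- reference
  p <- function(f) file.path(outdir, f)
  write_fastq(sim$reads$lib1, p("lib1.fastq"))
  write_fastq(sim$reads$lib2, p("lib2.fastq"))
  write_fasta(ref$matures, p("matures.fa"))
  write_fasta(ref$precursors, p("precursors.fa"))
  write_fasta(ref$contaminants, p("contaminants.fa"))
  write_fasta(ref$transcriptome, p("transcriptome.fa"))
  write_tsv(ref$ann_map, p("annotation_map.tsv"))
  write_tsv(.truth_ledger(sim, ref), p("truth_features.tsv"))
  files <- c("lib1.fastq", "lib2.fastq", "matures.fa", "precursors.fa",
             "contaminants.fa", "transcriptome.fa", "annotation_map.tsv",
             "truth_features.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    bytes = unname(file.size(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = sim$config$seed, files = manifest),
                       p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

## Flatten all planted features into the single-TSV truth ledger
## (one row per feature).
.truth_ledger <- function(sim, ref) {
  blank <- function(n) rep(NA, n)
  mk <- function(type, n, ...) {
    d <- data.frame(type = rep(type, n), id = blank(n), library = blank(n),
                    class = blank(n), transcript = blank(n),
                    start = blank(n), end = blank(n), arm = blank(n),
                    count1 = blank(n), count2 = blank(n),
                    true_log2fc = blank(n), count = blank(n),
                    sequence = blank(n), stringsAsFactors = FALSE)
    args <- list(...)
    for (nm in names(args)) d[[nm]] <- args[[nm]]
    d
  }
  mc <- sim$truth$mirna_counts
  parts <- list(mk("mirna", nrow(mc), id = mc$id, count1 = mc$count1,
                   count2 = mc$count2, true_log2fc = mc$true_log2fc,
                   sequence = unname(ref$matures[mc$id])))
  nv <- ref$truth$novel
  if (!is.null(nv)) {
    nc <- sim$truth$novel_counts
    parts <- c(parts, list(mk("novel_hairpin", nrow(nv), id = nv$id,
                              transcript = nv$transcript, start = nv$start,
                              end = nv$end, arm = nv$arm,
                              count1 = nc$count1, count2 = nc$count2,
                              sequence = nv$mature)))
  }
  tg <- ref$truth$targets
  if (!is.null(tg)) {
    parts <- c(parts, list(mk("target_site", nrow(tg), id = tg$mirna,
                              transcript = tg$transcript, start = tg$start,
                              end = tg$end)))
  }
  cc <- sim$truth$class_counts
  parts <- c(parts, list(mk("class_count", nrow(cc), library = cc$library,
                            class = cc$class, count = cc$count)))
  do.call(rbind, parts)
}

#' Verify a fixture bundle against its manifest
#'
#' @param outdir Directory holding a bundle and its `manifest.json`.
#' @return List with `ok` (logical) and `problems` (character vector of
#'   messages naming each missing or altered file).
#' @export
verify_fixture_bundle <- function(outdir) {
  mpath <- file.path(outdir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", outdir, call. = FALSE)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)$files
  problems <- character(0)
  for (i in seq_len(nrow(man))) {
    f <- file.path(outdir, man$file[i])
    if (!file.exists(f)) {
      problems <- c(problems, paste0("missing file: ", man$file[i]))
    } else if (unname(tools::md5sum(f)) != man$md5[i]) {
      problems <- c(problems, paste0("checksum mismatch: ", man$file[i]))
    }
  }
  list(ok = length(problems) == 0, problems = problems)
}
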