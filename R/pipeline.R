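## End-to-end orchestration. Stages communicate through TSV/FASTA/FASTQ
## files in the run directory, so any stage can be resumed from cached
## outputs and reruns are byte-reproducible.

#' Default pipeline configuration
#'
#' A nested list with one section per stage, mirroring each module's
#' parameters; serialisable to/from YAML. All randomness flows from the
#' single root `seed`.
#'
#' @param seed Root seed.
#' @param ... Named overrides for stage sections (`simulate`, `preprocess`,
#'   `annotate`, `novel`, `diffexpr`, `targets`, `enrich`, `inputs`).
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(),
    preprocess = list(min_len = 18L, max_len = 30L),
    annotate = list(tolerance = 1L),
    novel = list(window = 120L, min_support = 5L),
    diffexpr = list(alpha = 0.01),
    targets = list(),
    enrich = list(go_method = "bonferroni", kegg_method = "bh",
                  threshold = 0.5),
    inputs = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_pipeline_config,
          c(list(seed = if (is.null(y$seed)) 1L else y$seed),
            y[setdiff(names(y), "seed")]))
}

.stage_done <- function(outdir, files, resume) {
  resume && all(file.exists(file.path(outdir, files)))
}

#' Run the full small-RNA pipeline
#'
#' Stage order: simulate (optional) -> preprocess -> annotate -> novel ->
#' diffexpr -> targets -> enrich. Each stage writes its outputs under
#' `outdir/<stage>/`; with `resume = TRUE` stages whose outputs already
#' exist are skipped. A JSON manifest with per-file MD5 checksums, record
#' counts, the seed and the config checksum is written to
#' `outdir/manifest.json`.
#'
#' @param outdir Run directory.
#' @param config Configuration list, see [default_pipeline_config()].
#' @param simulate Generate the synthetic fixture first (otherwise
#'   `config$inputs` must name fastq1, fastq2, matures, precursors,
#'   contaminants, transcriptome, ann_map files).
#' @param resume Reuse existing stage outputs.
#' @param quiet Suppress per-stage messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(outdir, config = default_pipeline_config(),
                         simulate = TRUE, resume = FALSE, quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(seed = config$seed,
                   config_md5 = .config_md5(config),
                   package_version = as.character(utils::packageVersion("goosemir")),
                   r_version = R.version.string,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  counts <- list()

  inputs <- config$inputs
  if (simulate) {
    fx <- file.path(outdir, "fixture")
    fx_files <- c("lib1.fastq", "lib2.fastq", "matures.fa", "precursors.fa",
                  "contaminants.fa", "transcriptome.fa", "annotation_map.tsv",
                  "truth_features.tsv", "manifest.json")
    if (!.stage_done(fx, fx_files, resume)) {
      sc <- do.call(simulation_config,
                    c(list(seed = config$seed), config$simulate))
      ref <- build_reference(sc)
      sim <- simulate_libraries(sc, ref)
      write_fixture_bundle(sim, ref, fx)
      say("simulate: ", sum(sc$n_reads_per_library), " reads in 2 libraries")
    } else say("simulate: reusing cached fixture")
    inputs <- list(fastq1 = file.path(fx, "lib1.fastq"),
                   fastq2 = file.path(fx, "lib2.fastq"),
                   matures = file.path(fx, "matures.fa"),
                   precursors = file.path(fx, "precursors.fa"),
                   contaminants = file.path(fx, "contaminants.fa"),
                   transcriptome = file.path(fx, "transcriptome.fa"),
                   ann_map = file.path(fx, "annotation_map.tsv"))
    manifest$stages <- c(manifest$stages,
                         list(.stage_record(fx, "simulate",
                                            setdiff(fx_files, "manifest.json"))))
  } else {
    need <- c("fastq1", "fastq2", "matures", "precursors", "contaminants",
              "transcriptome", "ann_map")
    miss <- need[!vapply(need, function(k)
      !is.null(inputs[[k]]) && file.exists(inputs[[k]]), logical(1))]
    if (length(miss))
      stop("missing input file(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }

  ## ---- preprocess -------------------------------------------------------
  pd <- file.path(outdir, "preprocess")
  pp_files <- c("tags.tsv", "tags.fa", "filter_tally.tsv", "length_dist.tsv",
                "overlap.tsv")
  if (!.stage_done(pd, pp_files, resume)) {
    dir.create(pd, showWarnings = FALSE)
    ad3 <- .fixture_adapter(config, "adapter_3p")
    ad5 <- .fixture_adapter(config, "adapter_5p")
    cl1 <- clean_reads(inputs$fastq1, ad3, ad5,
                       config$preprocess$min_len, config$preprocess$max_len)
    cl2 <- clean_reads(inputs$fastq2, ad3, ad5,
                       config$preprocess$min_len, config$preprocess$max_len)
    tags <- collapse_tags(list(lib1 = unname(cl1$clean),
                               lib2 = unname(cl2$clean)))
    summ <- library_summary(tags, config$preprocess$min_len,
                            config$preprocess$max_len)
    tally <- data.frame(library = c("lib1", "lib2"),
                        n_raw = c(cl1$n_raw, cl2$n_raw),
                        n_clean = c(length(cl1$clean), length(cl2$clean)),
                        rbind(cl1$discard, cl2$discard))
    write_tsv(tags, file.path(pd, "tags.tsv"))
    write_tag_fasta(tags, file.path(pd, "tags.fa"))
    write_tsv(tally, file.path(pd, "filter_tally.tsv"))
    write_tsv(summ$length_dist, file.path(pd, "length_dist.tsv"))
    write_tsv(summ$overlap, file.path(pd, "overlap.tsv"))
  }
  tags <- read_tsv(file.path(pd, "tags.tsv"))
  tally <- read_tsv(file.path(pd, "filter_tally.tsv"))
  counts$clean_reads <- sum(tally$n_clean)
  counts$unique_tags <- nrow(tags)
  say("preprocess: ", counts$clean_reads, " clean reads, ",
      counts$unique_tags, " unique tags")
  manifest$stages <- c(manifest$stages,
                       list(.stage_record(pd, "preprocess", pp_files)))

  ## ---- annotate ---------------------------------------------------------
  ref <- list(matures = read_fasta(inputs$matures),
              precursors = read_fasta(inputs$precursors),
              contaminants = read_fasta(inputs$contaminants),
              transcriptome = read_fasta(inputs$transcriptome))
  names(ref$transcriptome) <- sub("\\s.*$", "", names(ref$transcriptome))
  names(ref$matures) <- sub("\\s.*$", "", names(ref$matures))
  names(ref$precursors) <- sub("\\s.*$", "", names(ref$precursors))
  an <- file.path(outdir, "annotate")
  an_files <- c("category_summary.tsv", "known_counts.tsv", "categories.tsv")
  if (!.stage_done(an, an_files, resume)) {
    dir.create(an, showWarnings = FALSE)
    ann <- annotate_tags(tags, ref, tolerance = config$annotate$tolerance)
    write_tsv(ann$summary, file.path(an, "category_summary.tsv"))
    write_tsv(ann$known$counts, file.path(an, "known_counts.tsv"))
    write_tsv(data.frame(sequence = tags$sequence,
                         category = as.character(ann$category)),
              file.path(an, "categories.tsv"))
  }
  known_counts <- read_tsv(file.path(an, "known_counts.tsv"))
  categories <- read_tsv(file.path(an, "categories.tsv"))
  counts$known_mirnas <- nrow(known_counts)
  say("annotate: ", counts$known_mirnas, " known miRNAs detected")
  manifest$stages <- c(manifest$stages,
                       list(.stage_record(an, "annotate", an_files)))

  ## ---- novel ------------------------------------------------------------
  nv <- file.path(outdir, "novel")
  nv_files <- c("novel_candidates.tsv", "novel_precursors.fa",
                "novel_structures.txt")
  if (!.stage_done(nv, nv_files, resume)) {
    dir.create(nv, showWarnings = FALSE)
    unann <- tags[!categories$category %in%
                    c("rRNA_etc_GenBank", "rRNA_etc_Rfam", "known_miRNA"), ,
                  drop = FALSE]
    cands <- discover_novel_mirnas(unann, ref$transcriptome,
                                   window = config$novel$window,
                                   min_support = config$novel$min_support)
    write_tsv(cands, file.path(nv, "novel_candidates.tsv"))
    if (nrow(cands)) {
      write_fasta(setNames(cands$precursor, cands$id),
                  file.path(nv, "novel_precursors.fa"))
    } else {
      writeLines(character(0), file.path(nv, "novel_precursors.fa"))
    }
    write_vienna(cands, file.path(nv, "novel_structures.txt"))
  }
  cands <- read_tsv(file.path(nv, "novel_candidates.tsv"))
  counts$novel_candidates <- nrow(cands)
  say("novel: ", counts$novel_candidates, " hairpin candidates")
  manifest$stages <- c(manifest$stages,
                       list(.stage_record(nv, "novel", nv_files)))

  ## ---- diffexpr ---------------------------------------------------------
  de <- file.path(outdir, "diffexpr")
  de_files <- c("de_table.tsv", "de_summary.tsv")
  if (!.stage_done(de, de_files, resume)) {
    dir.create(de, showWarnings = FALSE)
    det <- de_table(data.frame(mirna = known_counts$mirna,
                               count1 = known_counts$count1,
                               count2 = known_counts$count2),
                    n1 = tally$n_clean[1], n2 = tally$n_clean[2],
                    alpha = config$diffexpr$alpha)
    write_tsv(det, file.path(de, "de_table.tsv"))
    s <- de_summary(det)
    write_tsv(data.frame(metric = names(s), value = as.integer(s)),
              file.path(de, "de_summary.tsv"))
  }
  det <- read_tsv(file.path(de, "de_table.tsv"))
  counts$de_up <- sum(det$call == "up")
  counts$de_down <- sum(det$call == "down")
  say("diffexpr: ", counts$de_up, " up, ", counts$de_down, " down")
  manifest$stages <- c(manifest$stages,
                       list(.stage_record(de, "diffexpr", de_files)))

  ## ---- targets ----------------------------------------------------------
  tg <- file.path(outdir, "targets")
  tg_files <- "targets.tsv"
  if (!.stage_done(tg, tg_files, resume)) {
    dir.create(tg, showWarnings = FALSE)
    de_ids <- det$mirna[det$call %in% c("up", "down")]
    mirnas <- ref$matures[names(ref$matures) %in% de_ids]
    targets <- predict_targets(mirnas, ref$transcriptome)
    write_tsv(targets, file.path(tg, "targets.tsv"))
  }
  targets <- read_tsv(file.path(tg, "targets.tsv"))
  counts$target_sites <- nrow(targets)
  say("targets: ", counts$target_sites, " sites")
  manifest$stages <- c(manifest$stages,
                       list(.stage_record(tg, "targets", tg_files)))

  ## ---- enrich -----------------------------------------------------------
  en <- file.path(outdir, "enrich")
  en_files <- c("enrichment_go.tsv", "enrichment_kegg.tsv")
  if (!.stage_done(en, en_files, resume)) {
    dir.create(en, showWarnings = FALSE)
    ann_map <- read_tsv(inputs$ann_map)
    gene_set <- unique(targets$transcript)
    go_map <- ann_map[ann_map$namespace != "KEGG", , drop = FALSE]
    kegg_map <- ann_map[ann_map$namespace == "KEGG", , drop = FALSE]
    go <- correct_pvalues(hypergeom_enrich(gene_set, go_map),
                          method = config$enrich$go_method,
                          threshold = config$enrich$threshold)
    write_tsv(go, file.path(en, "enrichment_go.tsv"))
    if (nrow(kegg_map)) {
      kegg <- correct_pvalues(hypergeom_enrich(gene_set, kegg_map),
                              method = config$enrich$kegg_method,
                              threshold = config$enrich$threshold)
      write_tsv(kegg, file.path(en, "enrichment_kegg.tsv"))
    } else {
      write_tsv(data.frame(), file.path(en, "enrichment_kegg.tsv"))
    }
  }
  go <- read_tsv(file.path(en, "enrichment_go.tsv"))
  counts$enriched_go_terms <- sum(go$significant)
  say("enrich: ", counts$enriched_go_terms, " significant GO terms")
  manifest$stages <- c(manifest$stages,
                       list(.stage_record(en, "enrich", en_files)))

  manifest$counts <- counts
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.stage_record <- function(dir, name, files) {
  list(stage = name, status = "completed",
       outputs = data.frame(
         file = file.path(basename(dir), files),
         md5 = unname(tools::md5sum(file.path(dir, files))),
         stringsAsFactors = FALSE))
}

.config_md5 <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}

## Adapters: an explicit preprocess setting wins, then the simulate section,
## then the simulator defaults.
.fixture_adapter <- function(config, which) {
  for (sec in c("preprocess", "simulate")) {
    v <- config[[sec]][[which]]
    if (!is.null(v)) return(v)
  }
  formals(simulation_config)[[which]]
}
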