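## Novel miRNA discovery: single-hairpin folding under a constant stacking
## table plus the seven stem-loop acceptance criteria.

#' Energy model parameters for hairpin and duplex folding
#'
#' A deliberately simple nearest-neighbour-flavoured model: each stack of two
#' adjacent base pairs contributes a constant depending on the pair classes,
#' the terminal loop costs a fixed closure penalty, and every bulged side
#' between consecutive stem pairs costs a fixed bulge penalty. All values in
#' kcal/mol.
#'
#' @param stack_gc_gc Stack of two G:C pairs (default -3.0).
#' @param stack_gc_au Stack of a G:C with an A:U pair (default -2.4).
#' @param stack_au_au Stack of two A:U pairs (default -1.8).
#' @param stack_gu Any stack involving a G:U wobble (default -1.2).
#' @param loop_penalty Terminal hairpin loop closure (default +4.0).
#' @param bulge_penalty Per bulged side between consecutive pairs (default +3.0).
#' @param min_loop Minimum unpaired nucleotides in the terminal loop (default 3).
#' @param max_gap Maximum unpaired nucleotides on one side between
#'   consecutive stem pairs considered by the fold (default 30).
#' @return A list of class `hairpin_energy_params`.
#' @export
hairpin_energy_params <- function(stack_gc_gc = -3.0, stack_gc_au = -2.4,
                                  stack_au_au = -1.8, stack_gu = -1.2,
                                  loop_penalty = 4.0, bulge_penalty = 3.0,
                                  min_loop = 3L, max_gap = 30L) {
  p <- list(stack_gc_gc = stack_gc_gc, stack_gc_au = stack_gc_au,
            stack_au_au = stack_au_au, stack_gu = stack_gu,
            loop_penalty = loop_penalty, bulge_penalty = bulge_penalty,
            min_loop = as.integer(min_loop), max_gap = as.integer(max_gap))
  stopifnot(p$min_loop >= 1, p$max_gap >= 0)
  class(p) <- "hairpin_energy_params"
  p
}

.check_rna_alphabet <- function(seq) {
  if (grepl("[^ACGUTacgut]", seq))
    stop("invalid alphabet: sequence may contain only A, C, G, U/T",
         call. = FALSE)
}

#' Fold a sequence into its minimum-energy single hairpin
#'
#' Dynamic programme over all single-hairpin structures (one terminal loop, a
#' chain of nested pairs with optional bulges/internal gaps; no multiloops,
#' no pseudoknots). Allowed pairs are A:U, G:C and the G:U wobble. Ties are
#' broken toward more base pairs, then toward the 5'-most terminal loop. A
#' structure is reported only when its energy beats the open chain (energy
#' 0), so the returned energy is always <= 0.
#'
#' @param seq Nucleotide string (ACGU; T accepted as U).
#' @param params Energy model, see [hairpin_energy_params()].
#' @return A list of class `fold_result`: `sequence` (RNA alphabet),
#'   `structure` (dot-bracket), `energy` (kcal/mol), `n_pairs`,
#'   `loop_length`, `largest_bulge`, `outer_start`/`outer_end` (1-based span
#'   of the outermost pair; NA when unfolded).
#' @examples
#' fold_hairpin(paste0(strrep("G", 20), "AAAA", strrep("C", 20)))$energy
#' @export
fold_hairpin <- function(seq, params = hairpin_energy_params()) {
  .check_rna_alphabet(seq)
  res <- .fold_core(as_dna(seq), unclass(params))
  out <- list(sequence = as_rna(seq),
              structure = res$structure,
              energy = res$energy,
              n_pairs = res$n_pairs,
              loop_length = res$loop_length,
              largest_bulge = res$largest_bulge,
              outer_start = res$outer_start,
              outer_end = res$outer_end,
              loop_start = res$loop_start,
              loop_end = res$loop_end,
              params = params)
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", sprintf("%.1f", x$energy), ")\n",
      sep = "")
  cat("pairs:", x$n_pairs, " loop:", x$loop_length,
      " largest bulge:", x$largest_bulge, "\n")
  invisible(x)
}

## Parse a single-hairpin dot-bracket string into its pair chain.
## Returns i/j index vectors (1-based, outermost first) or errors when the
## structure is not a single hairpin.
parse_hairpin_structure <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  open <- which(ch == "(")
  close <- which(ch == ")")
  if (length(open) != length(close))
    stop("unbalanced brackets in structure", call. = FALSE)
  if (length(open) > 0 && max(open) > min(close))
    stop("not a single hairpin: '(' found after ')'", call. = FALSE)
  list(i = open, j = rev(close), n_pairs = length(open))
}

#' Energy of a given single-hairpin structure
#'
#' Scores an explicit dot-bracket structure under the same energy model as
#' [fold_hairpin()]; used to audit constructed hairpins and by the
#' enumeration tests.
#'
#' @param seq Nucleotide string.
#' @param structure Dot-bracket string of the same length (single hairpin).
#' @param params Energy model.
#' @return Energy in kcal/mol (0 for the empty structure).
#' @export
hairpin_structure_energy <- function(seq, structure,
                                     params = hairpin_energy_params()) {
  .check_rna_alphabet(seq)
  s <- strsplit(as_rna(seq), "")[[1]]
  stopifnot(length(s) == nchar(structure))
  pr <- parse_hairpin_structure(structure)
  if (pr$n_pairs == 0) return(0)
  cls <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) return(0L)
    if (p %in% c("AU", "UA")) return(1L)
    if (p %in% c("GU", "UG")) return(2L)
    stop("position pair ", a, ":", b, " is not pairable", call. = FALSE)
  }
  k <- pr$n_pairs
  loop <- pr$j[k] - pr$i[k] - 1
  if (loop < params$min_loop)
    stop("terminal loop shorter than min_loop", call. = FALSE)
  e <- params$loop_penalty
  if (k > 1) {
    for (t in seq_len(k - 1)) {
      gapL <- pr$i[t + 1] - pr$i[t] - 1
      gapR <- pr$j[t] - pr$j[t + 1] - 1
      if (gapL == 0 && gapR == 0) {
        c1 <- cls(s[pr$i[t]], s[pr$j[t]])
        c2 <- cls(s[pr$i[t + 1]], s[pr$j[t + 1]])
        e <- e + if (c1 == 2L || c2 == 2L) params$stack_gu
          else if (c1 == 0L && c2 == 0L) params$stack_gc_gc
          else if (c1 == 1L && c2 == 1L) params$stack_au_au
          else params$stack_gc_au
      } else {
        e <- e + params$bulge_penalty * ((gapL > 0) + (gapR > 0))
      }
    }
  } else {
    cls(s[pr$i[1]], s[pr$j[1]])   # validate the lone pair
  }
  e
}

#' Thresholds for the seven stem-loop acceptance criteria
#'
#' Defaults follow the classic stem-loop screen: (1) >= 18 paired bases in
#' the stem; (2) largest one-sided bulge <= 18 nt; (3) folding energy
#' strictly below -20 kcal/mol; (4) >= 80% of the mature sequence inside the
#' stem; (5) hairpin span (both stems plus terminal loop) >= 53 nt;
#' (6) terminal loop <= 22 nt; (7) mature A+U content between 30% and 70%
#' inclusive.
#'
#' @param min_stem_pairs,max_bulge,max_energy,min_mature_in_stem,min_hairpin_length,max_loop,au_min,au_max
#'   Criterion thresholds.
#' @return A list of class `hairpin_criteria`.
#' @export
hairpin_criteria_thresholds <- function(min_stem_pairs = 18L, max_bulge = 18L,
                                        max_energy = -20, min_mature_in_stem = 0.80,
                                        min_hairpin_length = 53L, max_loop = 22L,
                                        au_min = 0.30, au_max = 0.70) {
  structure(list(min_stem_pairs = min_stem_pairs, max_bulge = max_bulge,
                 max_energy = max_energy,
                 min_mature_in_stem = min_mature_in_stem,
                 min_hairpin_length = min_hairpin_length, max_loop = max_loop,
                 au_min = au_min, au_max = au_max),
            class = "hairpin_criteria")
}

#' Evaluate the seven stem-loop criteria on a folded precursor
#'
#' @param fold A `fold_result` (or a list with `sequence`, `structure`,
#'   `energy`).
#' @param mature_start,mature_end 1-based inclusive position of the mature
#'   sequence within the folded window.
#' @param thresholds See [hairpin_criteria_thresholds()].
#' @return Named logical vector of the 7 criteria plus `accepted` (all
#'   seven true), with the measured quantities attached as attribute
#'   `measures`.
#' @export
evaluate_hairpin_criteria <- function(fold, mature_start, mature_end,
                                      thresholds = hairpin_criteria_thresholds()) {
  th <- thresholds
  s <- strsplit(fold$sequence, "")[[1]]
  pr <- parse_hairpin_structure(fold$structure)
  mature <- s[mature_start:mature_end]
  if (pr$n_pairs == 0) {
    stem_pairs <- 0L; bulge <- 0L; loop <- NA_integer_
    span <- 0L; in_stem <- 0
  } else {
    k <- pr$n_pairs
    stem_pairs <- k
    loop <- pr$j[k] - pr$i[k] - 1
    span <- pr$j[1] - pr$i[1] + 1
    gaps <- if (k > 1) c(diff(pr$i) - 1L, -diff(pr$j) - 1L) else integer()
    bulge <- if (length(gaps)) max(gaps) else 0L
    stem_pos <- c(seq(pr$i[1], pr$i[k]), seq(pr$j[k], pr$j[1]))
    in_stem <- mean(seq(mature_start, mature_end) %in% stem_pos)
  }
  au <- mean(mature %in% c("A", "U", "T"))
  crit <- c(
    stem_pairs = stem_pairs >= th$min_stem_pairs,
    bulge = bulge <= th$max_bulge,
    energy = fold$energy < th$max_energy - 1e-6,   # strict, float-safe
    mature_in_stem = in_stem >= th$min_mature_in_stem,
    hairpin_length = !is.na(span) && span >= th$min_hairpin_length,
    loop_length = !is.na(loop) && loop <= th$max_loop,
    mature_au = au >= th$au_min && au <= th$au_max)
  out <- c(crit, accepted = all(crit))
  attr(out, "measures") <- list(stem_pairs = stem_pairs, largest_bulge = bulge,
                                energy = fold$energy, mature_in_stem = in_stem,
                                hairpin_length = span, loop_length = loop,
                                mature_au = au)
  out
}

## Fold both candidate precursor windows around a tag occurrence and return
## the best window passing all criteria, or NULL.
.fold_tag_windows <- function(tx_seq, tag_start, tag_end, window, params,
                              thresholds) {
  len <- nchar(tx_seq)
  wins <- list(
    `5p` = c(tag_start, min(len, tag_end + window)),
    `3p` = c(max(1L, tag_start - window), tag_end))
  best <- NULL
  for (arm in names(wins)) {
    w <- wins[[arm]]
    if (w[2] - w[1] + 1 < thresholds$min_hairpin_length) next
    sub <- substr(tx_seq, w[1], w[2])
    fold <- fold_hairpin(sub, params)
    if (fold$n_pairs == 0) next
    crit <- evaluate_hairpin_criteria(fold, tag_start - w[1] + 1,
                                      tag_end - w[1] + 1, thresholds)
    if (!crit[["accepted"]]) next
    if (is.null(best) || fold$energy < best$fold$energy) {
      best <- list(arm = arm, window = w, fold = fold, criteria = crit)
    }
  }
  best
}

#' Discover novel miRNA candidates from unannotated tags
#'
#' Each unannotated tag with pooled read support >= `min_support` and an
#' exact hit in the transcriptome seeds two candidate precursor windows (tag
#' on the 5' arm extending downstream, and on the 3' arm extending
#' upstream). Both windows are folded; the lowest-energy window passing all
#' seven criteria is reported. Candidates sharing an identical precursor
#' sequence are merged into one record listing every locus.
#'
#' @param tags Data frame with columns `sequence` and per-library counts
#'   (any columns matching `^count`), as produced by [collapse_tags()].
#' @param transcriptome Named character vector of transcript sequences.
#' @param window Flank length in nt added beyond the tag (default 120).
#' @param min_support Minimum pooled read count (default 5).
#' @param params,thresholds Energy model and criteria thresholds.
#' @return Data frame with one row per merged candidate: id, mature tag,
#'   support, arm, locus fields (1-based inclusive), precursor sequence,
#'   dot-bracket structure, energy, stem/loop measures, and `n_loci` plus a
#'   semicolon-separated `loci` column for merged duplicates.
#' @export
discover_novel_mirnas <- function(tags, transcriptome, window = 120L,
                                  min_support = 5L,
                                  params = hairpin_energy_params(),
                                  thresholds = hairpin_criteria_thresholds()) {
  count_cols <- grep("^count", names(tags), value = TRUE)
  support <- rowSums(tags[, count_cols, drop = FALSE])
  keep <- which(support >= min_support)
  txs <- as_dna(transcriptome)
  rows <- list()
  for (t in keep[order(tags$sequence[keep])]) {
    tag <- as_dna(tags$sequence[t])
    for (tx in names(txs)) {
      hits <- gregexpr(tag, txs[[tx]], fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      for (h in as.integer(hits)) {
        cand <- .fold_tag_windows(txs[[tx]], h, h + nchar(tag) - 1L, window,
                                  params, thresholds)
        if (is.null(cand)) next
        m <- attr(cand$criteria, "measures")
        ## trim the reported precursor to the folded hairpin (outer pair
        ## span, extended to cover the mature tag) so identical planted
        ## loci in different flanking contexts merge cleanly
        p1 <- cand$window[1] + min(cand$fold$outer_start, h - cand$window[1] + 1) - 1L
        p2 <- cand$window[1] + max(cand$fold$outer_end,
                                   h + nchar(tag) - cand$window[1]) - 1L
        rows[[length(rows) + 1]] <- data.frame(
          mature = as_rna(tag), support = support[t], arm = cand$arm,
          transcript = tx, start = p1, end = p2,
          precursor = as_rna(substr(txs[[tx]], p1, p2)),
          structure = substr(cand$fold$structure, p1 - cand$window[1] + 1,
                             p2 - cand$window[1] + 1),
          energy = cand$fold$energy,
          stem_pairs = m$stem_pairs, loop_length = m$loop_length,
          largest_bulge = m$largest_bulge,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(), mature = character(),
                      support = numeric(), arm = character(),
                      transcript = character(), start = integer(),
                      end = integer(), precursor = character(),
                      structure = character(), energy = numeric(),
                      stem_pairs = integer(), loop_length = integer(),
                      largest_bulge = integer(), n_loci = integer(),
                      loci = character(), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, rows)
  ## merge candidates with identical precursor sequence (same locus planted
  ## in several transcripts)
  grp <- split(seq_len(nrow(all)), all$precursor)
  merged <- do.call(rbind, lapply(grp, function(idx) {
    first <- all[idx[1], , drop = FALSE]
    first$n_loci <- length(idx)
    first$loci <- paste(sprintf("%s:%d-%d", all$transcript[idx],
                                all$start[idx], all$end[idx]),
                        collapse = ";")
    first
  }))
  merged <- merged[order(merged$energy, merged$mature), , drop = FALSE]
  merged <- cbind(id = sprintf("novel-mir-%03d", seq_len(nrow(merged))),
                  merged, stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  merged
}

#' Write folded precursors in Vienna dot-bracket format
#'
#' @param candidates Candidate table from [discover_novel_mirnas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(candidates))) {
    writeLines(c(paste0(">", candidates$id[r]),
                 candidates$precursor[r],
                 sprintf("%s (%.2f)", candidates$structure[r],
                         candidates$energy[r])), con)
  }
  invisible(path)
}
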