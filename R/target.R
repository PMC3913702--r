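## miRNA target prediction with plant-style mismatch rules and the
## minimum-free-energy ratio filter.

#' Rule thresholds for target-site scoring
#'
#' @param max_score Rule 1: maximum total mismatch score (default 4).
#' @param max_adjacent Rule 2: maximum run of consecutive non-match states
#'   (default 2).
#' @param strict_score Strict criterion: maximum total mismatch score
#'   (default 2); supersedes rule 1 when applied.
#' @param max_score_1_12 Rule 5: maximum mismatch score within miRNA
#'   positions 1-12 (default 2.5).
#' @param min_mfe_ratio Rule 6: minimum duplex/perfect MFE ratio
#'   (default 0.75, inclusive).
#' @return List of class `target_rules`.
#' @export
target_rules <- function(max_score = 4, max_adjacent = 2, strict_score = 2,
                         max_score_1_12 = 2.5, min_mfe_ratio = 0.75) {
  structure(list(max_score = max_score, max_adjacent = max_adjacent,
                 strict_score = strict_score,
                 max_score_1_12 = max_score_1_12,
                 min_mfe_ratio = min_mfe_ratio), class = "target_rules")
}

.duplex_states <- function(mirna, window) {
  m <- strsplit(as_dna(mirna), "")[[1]]
  w <- strsplit(as_dna(window), "")[[1]]
  L <- length(m)
  t <- rev(w)                       # antisense: position p pairs L - p + 1
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  state <- ifelse(t == comp[m], "match",
                  ifelse((m == "G" & t == "T") | (m == "T" & t == "G"),
                         "GU", "mismatch"))
  unname(state)
}

#' Align a miRNA against a candidate target window and score mismatches
#'
#' The window (same length as the miRNA, transcript 5'->3') is paired
#' antisense so that miRNA position p (numbered 1..L from the miRNA 5' end)
#' faces window position L - p + 1. G:U wobbles count 0.5 toward the
#' mismatch score and count as non-match states for adjacency rules.
#' Evaluated rules: (1) score <= 4; (2) no more than 2 consecutive
#' non-match states; (3) no adjacent non-matches within positions 2-12;
#' (4) perfect Watson-Crick match at positions 10 and 11; (5) score within
#' positions 1-12 <= 2.5; strict: score <= 2.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param window Transcript window of identical length, 5'->3'.
#' @param rules See [target_rules()].
#' @return List of class `duplex_alignment`: `states` (per miRNA position),
#'   `score`, `n_gu`, `n_mismatch`, and `rules` (named logical vector with
#'   `accepted` = all rules true).
#' @export
duplex_align_and_score <- function(mirna, window, rules = target_rules()) {
  if (nchar(mirna) != nchar(window))
    stop("miRNA and target window must have identical length", call. = FALSE)
  st <- .duplex_states(mirna, window)
  L <- length(st)
  non <- st != "match"
  score <- sum(st == "mismatch") + 0.5 * sum(st == "GU")
  runs <- rle(non)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  span212 <- seq(2L, min(12L, L))
  adj212 <- any(non[span212][-1] & non[span212][-length(span212)])
  span112 <- seq_len(min(12L, L))
  score112 <- sum(st[span112] == "mismatch") + 0.5 * sum(st[span112] == "GU")
  pos1011 <- intersect(c(10L, 11L), seq_len(L))
  rl <- c(
    r1_max_mismatches = score <= rules$max_score,
    r2_adjacent = max_run <= rules$max_adjacent,
    r3_no_adjacent_2_12 = !adj212,
    r4_perfect_10_11 = all(st[pos1011] == "match"),
    r5_score_1_12 = score112 <= rules$max_score_1_12,
    strict = score <= rules$strict_score)
  out <- list(mirna = as_rna(mirna), window = as_rna(window), states = st,
              score = score, n_gu = sum(st == "GU"),
              n_mismatch = sum(st == "mismatch"),
              rules = c(rl, accepted = all(rl)))
  class(out) <- "duplex_alignment"
  out
}

## Intermolecular duplex energy: stacks form only between adjacent
## Watson-Crick matched positions (mismatches and G:U wobbles break the
## helix); no initiation term, so it cancels in the MFE ratio.
.duplex_energy <- function(mirna, states, params) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  cls <- ifelse(m %in% c("G", "C"), 0L, 1L)   # pair class when matched
  e <- 0
  for (p in seq_len(length(m) - 1)) {
    if (states[p] == "match" && states[p + 1] == "match") {
      e <- e + if (cls[p] == 0L && cls[p + 1] == 0L) params$stack_gc_gc
        else if (cls[p] == 1L && cls[p + 1] == 1L) params$stack_au_au
        else params$stack_gc_au
    }
  }
  e
}

#' MFE ratio of a duplex relative to the perfect complement
#'
#' Both energies use the intermolecular variant of the hairpin stacking
#' table. The site passes when `duplex MFE / perfect MFE >= min_mfe_ratio`
#' (0.75 by default, inclusive).
#'
#' @param alignment A `duplex_alignment` from [duplex_align_and_score()].
#' @param rules See [target_rules()].
#' @param params Energy model, see [hairpin_energy_params()].
#' @return List with `mfe_duplex`, `mfe_perfect`, `mfe_ratio` and `pass`.
#' @export
duplex_mfe_ratio <- function(alignment, rules = target_rules(),
                             params = hairpin_energy_params()) {
  perfect <- .duplex_energy(alignment$mirna,
                            rep("match", length(alignment$states)), params)
  if (perfect == 0)
    stop("undefined MFE ratio: miRNA has no stackable steps", call. = FALSE)
  duplex <- .duplex_energy(alignment$mirna, alignment$states, params)
  ratio <- duplex / perfect
  list(mfe_duplex = duplex, mfe_perfect = perfect, mfe_ratio = ratio,
       pass = ratio >= rules$min_mfe_ratio)
}

#' Predict target sites of miRNAs on a transcriptome
#'
#' Every length-L window of every transcript is scanned (exhaustively, no
#' seed heuristic). A site is reported when all mismatch rules, the strict
#' score criterion, and the MFE-ratio filter pass. Overlapping accepted
#' sites of the same miRNA on the same transcript are merged to the
#' best-scoring one (ties: lowest start).
#'
#' @param mirnas Named character vector of (differentially expressed)
#'   mature miRNA sequences.
#' @param transcriptome Named character vector of transcript sequences.
#' @param rules,params Rule thresholds and energy model.
#' @return Data frame: mirna, transcript, start, end (1-based inclusive),
#'   score, n_gu, mfe_ratio.
#' @export
predict_targets <- function(mirnas, transcriptome, rules = target_rules(),
                            params = hairpin_energy_params()) {
  out <- list()
  scan_cap <- min(rules$max_score, rules$strict_score)
  for (id in names(mirnas)) {
    mir <- as_dna(mirnas[[id]])
    L <- nchar(mir)
    for (tx in names(transcriptome)) {
      txseq <- as_dna(transcriptome[[tx]])
      cand <- .scan_duplex(mir, txseq, scan_cap)
      if (!nrow(cand)) next
      acc <- list()
      for (k in seq_len(nrow(cand))) {
        s <- cand$start[k]
        aln <- duplex_align_and_score(mir, substr(txseq, s, s + L - 1L), rules)
        if (!aln$rules[["accepted"]]) next
        mfe <- duplex_mfe_ratio(aln, rules, params)
        if (!mfe$pass) next
        acc[[length(acc) + 1]] <- data.frame(
          mirna = id, transcript = tx, start = s, end = s + L - 1L,
          score = aln$score, n_gu = aln$n_gu, mfe_ratio = mfe$mfe_ratio,
          stringsAsFactors = FALSE)
      }
      if (!length(acc)) next
      sites <- do.call(rbind, acc)
      out[[length(out) + 1]] <- .merge_overlapping_sites(sites)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(), score = numeric(),
                      n_gu = integer(), mfe_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mirna, res$transcript, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Merge overlapping windows (same miRNA and transcript): keep the best
## score, ties resolved toward the lowest start.
.merge_overlapping_sites <- function(sites) {
  sites <- sites[order(sites$start), , drop = FALSE]
  grp <- integer(nrow(sites))
  g <- 1L; grp[1] <- g; hi <- sites$end[1]
  for (k in seq_len(nrow(sites))[-1]) {
    if (sites$start[k] > hi) g <- g + 1L
    grp[k] <- g
    hi <- max(hi, sites$end[k])
  }
  do.call(rbind, lapply(split(sites, grp), function(d) {
    d[order(d$score, d$start), , drop = FALSE][1, , drop = FALSE]
  }))
}
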