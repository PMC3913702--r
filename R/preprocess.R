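## Read cleaning with the five classic small-RNA filter classes (plus the
## over-length sibling), tag collapsing, and library summary statistics.

.DISCARD_KEYS <- c("no_3p_adapter", "5p_contaminant", "no_insert", "polyA",
                   "too_short", "length_out_of_range")

#' Clean raw small-RNA reads
#'
#' Applies, in a fixed reporting order, the filters: missing 3' adapter,
#' 5' adapter contamination, empty insert (adapter dimer), poly(A) insert
#' (>= 80% adenine), insert shorter than `min_len`, and insert longer than
#' `max_len`. The 3' adapter is located as the leftmost position where the
#' full overlap with the adapter (at least 5 nt) matches with at most one
#' mismatch for overlaps of 8 nt or more (exact for shorter overlaps);
#' retained reads are trimmed to their insert.
#'
#' @param reads Character vector of read sequences, or a path to a FASTQ
#'   file (parsed with an error naming the record index when malformed).
#' @param adapter_3p,adapter_5p Adapter sequences (non-empty).
#' @param min_len,max_len Retained insert length range (defaults 18-30 nt).
#' @return List with `clean` (named character vector of trimmed inserts),
#'   `discard` (named tally over all six filter keys), `reasons`
#'   (per-read factor, `"clean"` for survivors) and `n_raw`.
#' @export
clean_reads <- function(reads, adapter_3p, adapter_5p,
                        min_len = 18L, max_len = 30L) {
  stopifnot(nzchar(adapter_3p), nzchar(adapter_5p))
  if (length(reads) == 1 && file.exists(reads)) reads <- read_fastq_reads(reads)
  reads <- toupper(reads)
  n <- length(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%d", seq_len(n))
  a3 <- as_dna(adapter_3p); a5 <- as_dna(adapter_5p)
  pos <- .find_adapter(unname(as_dna(reads)), a3)
  insert <- substr(reads, 1L, pmax(pos - 1L, 0L))
  ilen <- nchar(insert)
  p5 <- substr(a5, 1L, 8L)
  frac_a <- ifelse(ilen > 0, (ilen - nchar(gsub("A", "", insert))) / pmax(ilen, 1L), 0)
  reason <- rep("clean", n)
  reason[ilen > max_len] <- "length_out_of_range"
  reason[ilen < min_len] <- "too_short"
  reason[frac_a >= 0.8 & ilen > 0] <- "polyA"
  reason[ilen == 0] <- "no_insert"
  reason[nchar(a5) >= 8 & startsWith(as_dna(reads), p5)] <- "5p_contaminant"
  reason[pos == 0] <- "no_3p_adapter"
  keep <- reason == "clean"
  tally <- vapply(.DISCARD_KEYS, function(k) sum(reason == k), integer(1))
  list(clean = insert[keep],
       discard = tally,
       reasons = factor(reason, levels = c("clean", .DISCARD_KEYS)),
       n_raw = n)
}

#' Collapse clean reads to unique tags with per-library counts
#'
#' @param libraries Named list of character vectors of clean insert
#'   sequences, one element per library (typically two).
#' @return Data frame with `sequence`, one `count<i>` column per library,
#'   and `total`, sorted by descending pooled count with lexicographic
#'   tie-break.
#' @export
collapse_tags <- function(libraries) {
  stopifnot(is.list(libraries), length(libraries) >= 1)
  if (is.null(names(libraries)))
    names(libraries) <- paste0("lib", seq_along(libraries))
  all_seq <- sort(unique(toupper(unlist(libraries, use.names = FALSE))))
  counts <- lapply(libraries, function(lib) {
    tab <- table(factor(toupper(lib), levels = all_seq))
    as.integer(tab)
  })
  out <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
  for (i in seq_along(counts)) out[[paste0("count", i)]] <- counts[[i]]
  out$total <- rowSums(out[, paste0("count", seq_along(counts)), drop = FALSE])
  out <- out[order(-out$total, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length distribution and two-library overlap summary
#'
#' @param tags Tag table from [collapse_tags()] with two count columns.
#' @param min_len,max_len Histogram range (defaults 18-30 nt).
#' @return List with `length_dist` (per library and pooled, counts and
#'   percentages per length bin; percentages sum to 100 within each
#'   partition) and `overlap` (total-read and unique-tag common/specific
#'   percentages across the two libraries).
#' @export
library_summary <- function(tags, min_len = 18L, max_len = 30L) {
  stopifnot(all(c("count1", "count2") %in% names(tags)))
  n1 <- sum(tags$count1); n2 <- sum(tags$count2)
  if (n1 == 0 || n2 == 0) stop("empty library", call. = FALSE)
  len <- nchar(tags$sequence)
  bins <- seq(min_len, max_len)
  hist_of <- function(w) vapply(bins, function(L) sum(w[len == L]), numeric(1))
  ld <- data.frame(length = bins,
                   count1 = hist_of(tags$count1),
                   count2 = hist_of(tags$count2))
  ld$count_total <- ld$count1 + ld$count2
  ld$pct1 <- 100 * ld$count1 / n1
  ld$pct2 <- 100 * ld$count2 / n2
  ld$pct_total <- 100 * ld$count_total / (n1 + n2)
  common <- tags$count1 > 0 & tags$count2 > 0
  ov <- data.frame(
    partition = c("total_reads", "unique_tags"),
    common_pct = c(100 * sum(tags$total[common]) / sum(tags$total),
                   100 * mean(common)),
    specific1_pct = c(100 * sum(tags$count1[!common]) / sum(tags$total),
                      100 * mean(tags$count1 > 0 & tags$count2 == 0)),
    specific2_pct = c(100 * sum(tags$count2[!common]) / sum(tags$total),
                      100 * mean(tags$count2 > 0 & tags$count1 == 0)))
  list(length_dist = ld, overlap = ov, n1 = n1, n2 = n2)
}

#' Write collapsed tags as count-embedded-ID FASTA
#'
#' Headers follow the `tagN_xCOUNT` convention (pooled count).
#'
#' @param tags Tag table from [collapse_tags()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  ids <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$total)
  write_fasta(setNames(tags$sequence, ids), path)
}
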