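## Priority-rule annotation of unique tags and known-miRNA quantification.

#' Annotation categories in priority order
#'
#' Highest priority first; a tag receives the first category with a match,
#' or `"unannotated"`.
#' @export
ANNOTATION_PRIORITY <- c("rRNA_etc_GenBank", "rRNA_etc_Rfam", "known_miRNA",
                         "repeat", "exon", "intron")

#' Assign each tag to exactly one annotation category
#'
#' @param tags Character vector of tag sequences (order preserved).
#' @param match_sets Named list of logical vectors (same length as `tags`)
#'   or character vectors of matching tag sequences; names must be a subset
#'   of [ANNOTATION_PRIORITY]. Missing categories count as no match.
#' @return Factor of categories (levels: the priority order plus
#'   `"unannotated"`).
#' @export
assign_category <- function(tags, match_sets) {
  stopifnot(all(names(match_sets) %in% ANNOTATION_PRIORITY))
  out <- rep("unannotated", length(tags))
  for (cat in rev(ANNOTATION_PRIORITY)) {        # low priority first
    ms <- match_sets[[cat]]
    if (is.null(ms)) next
    hit <- if (is.logical(ms)) ms else tags %in% ms
    out[hit] <- cat
  }
  factor(out, levels = c(ANNOTATION_PRIORITY, "unannotated"))
}

## Substring matches of tags against contaminant references, split by the
## `source=GenBank|Rfam` tag carried in the FASTA headers.
match_contaminants <- function(tags, contaminants) {
  headers <- names(contaminants)
  src <- ifelse(grepl("source=Rfam", headers), "Rfam",
                ifelse(grepl("source=GenBank", headers), "GenBank", "GenBank"))
  tags <- as_dna(tags)
  seqs <- as_dna(unname(contaminants))
  hit_in <- function(subset) {
    if (!length(subset)) return(rep(FALSE, length(tags)))
    blob <- seqs[subset]
    vapply(tags, function(t) any(grepl(t, blob, fixed = TRUE)), logical(1),
           USE.NAMES = FALSE)
  }
  list(rRNA_etc_GenBank = hit_in(which(src == "GenBank")),
       rRNA_etc_Rfam = hit_in(which(src == "Rfam")))
}

## Ungapped mismatch count between two equal-length DNA strings.
.mismatches <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Quantify known (conserved) miRNAs from collapsed tags
#'
#' A tag is attributed to a mature miRNA when it aligns, without gaps, to
#' the precursor at a start within +/- `offset` nt of the annotated mature
#' start, ends within +/- `offset` nt of the mature end, and carries at
#' most `tolerance` mismatches. A tag matching several matures equally is
#' attributed to the lexicographically smallest ID and flagged ambiguous.
#' miRNAs with zero attributed counts in both libraries are omitted.
#'
#' @param tags Tag table from [collapse_tags()] (columns `sequence`,
#'   `count1`, `count2`).
#' @param matures Named character vector of mature miRNA sequences
#'   (IDs must be unique).
#' @param precursors Named character vector of precursor sequences; each
#'   mature ID must have a precursor of the same ID containing it.
#' @param tolerance Maximum mismatches (default 1).
#' @param offset Maximum 5'/3' shift against the precursor context
#'   (default 2).
#' @return List with `counts` (data frame: mirna, family, count1, count2)
#'   and `assignments` (data frame: tag sequence, mirna, ambiguous).
#' @export
quantify_known_mirnas <- function(tags, matures, precursors, tolerance = 1L,
                                  offset = 2L) {
  if (anyDuplicated(names(matures)))
    stop("duplicate mature IDs in reference", call. = FALSE)
  matures <- setNames(as_dna(matures), names(matures))
  precursors <- setNames(as_dna(precursors), names(precursors))
  miss <- setdiff(names(matures), names(precursors))
  if (length(miss))
    stop("matures without precursor: ", paste(miss, collapse = ", "),
         call. = FALSE)
  mat_ids <- sort(names(matures))
  mstart <- vapply(mat_ids, function(id)
    regexpr(matures[[id]], precursors[[id]], fixed = TRUE)[1], integer(1))
  if (any(mstart < 0))
    stop("mature not found in its precursor: ",
         paste(mat_ids[mstart < 0], collapse = ", "), call. = FALSE)
  mlen <- nchar(matures[mat_ids])
  tag_seq <- as_dna(tags$sequence)
  tlen <- nchar(tag_seq)
  hits <- vector("list", length(tag_seq))
  for (mi in seq_along(mat_ids)) {
    id <- mat_ids[mi]
    pre <- precursors[[id]]
    plen <- nchar(pre)
    m_end <- mstart[mi] + mlen[mi] - 1L
    cand <- which(abs(tlen - mlen[mi]) <= 2L * offset)
    for (t in cand) {
      L <- tlen[t]
      for (s in seq(max(1L, mstart[mi] - offset),
                    min(mstart[mi] + offset, plen - L + 1L))) {
        if (abs((s + L - 1L) - m_end) > offset) next
        if (.mismatches(tag_seq[t], substr(pre, s, s + L - 1L)) <= tolerance) {
          hits[[t]] <- c(hits[[t]], id)
          break
        }
      }
    }
  }
  n_hit <- lengths(hits)
  assigned <- which(n_hit > 0)
  assignments <- data.frame(
    sequence = tags$sequence[assigned],
    mirna = vapply(hits[assigned], function(h) sort(h)[1], character(1)),
    ambiguous = n_hit[assigned] > 1,
    stringsAsFactors = FALSE)
  counts <- data.frame(mirna = mat_ids,
                       family = paste0("fam-", substr(matures[mat_ids], 2, 8)),
                       count1 = 0L, count2 = 0L, stringsAsFactors = FALSE)
  if (nrow(assignments)) {
    for (col in c("count1", "count2")) {
      agg <- tapply(tags[[col]][assigned], assignments$mirna, sum)
      counts[[col]][match(names(agg), counts$mirna)] <- as.integer(agg)
    }
  }
  counts <- counts[counts$count1 + counts$count2 > 0, , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, assignments = assignments)
}

#' Annotate collapsed tags against a reference bundle
#'
#' Builds the per-category match sets (GenBank/Rfam contaminants by
#' substring match, known miRNAs via [quantify_known_mirnas()], exon via
#' exact transcript substring match; no repeat or intron references are
#' modelled) and applies the priority rule.
#'
#' @param tags Tag table from [collapse_tags()].
#' @param reference A `reference_bundle` (see [build_reference()]) or a
#'   list with `matures`, `precursors`, `contaminants`, `transcriptome`.
#' @param tolerance Mismatch tolerance for known-miRNA attribution.
#' @return List with `category` (per-tag factor), `summary` (category
#'   count/percentage table over unique tags), `known` (the
#'   [quantify_known_mirnas()] result).
#' @export
annotate_tags <- function(tags, reference, tolerance = 1L) {
  contam <- match_contaminants(tags$sequence, reference$contaminants)
  known <- quantify_known_mirnas(tags, reference$matures,
                                 reference$precursors, tolerance = tolerance)
  tx <- as_dna(unname(reference$transcriptome))
  exon <- vapply(as_dna(tags$sequence),
                 function(t) any(grepl(t, tx, fixed = TRUE)), logical(1),
                 USE.NAMES = FALSE)
  category <- assign_category(tags$sequence, list(
    rRNA_etc_GenBank = contam$rRNA_etc_GenBank,
    rRNA_etc_Rfam = contam$rRNA_etc_Rfam,
    known_miRNA = tags$sequence %in% known$assignments$sequence,
    exon = exon))
  tab <- table(category)
  summary <- data.frame(category = names(tab),
                        n_unique_tags = as.integer(tab),
                        pct_unique_tags = 100 * as.integer(tab) / nrow(tags),
                        stringsAsFactors = FALSE)
  list(category = category, summary = summary, known = known)
}
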