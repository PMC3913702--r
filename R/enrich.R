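## Hypergeometric enrichment of annotation terms among predicted target
## genes, with Bonferroni and Benjamini-Hochberg corrections.

#' Hypergeometric term enrichment
#'
#' For each term: N = genes with at least one annotation in the map,
#' n = target candidates among them, M = genes annotated to the term,
#' m = target candidates annotated to the term. The raw p-value is the
#' upper tail P(X >= m) of the hypergeometric distribution (enrichment,
#' not depletion).
#'
#' @param targets Character vector of candidate target gene IDs
#'   (deduplicated internally).
#' @param ann_map Data frame with columns `gene_id`, `term_id` and
#'   optionally `term_label`, `namespace`; one row per gene-term pair.
#' @return Data frame of class `enrichment_result`: term_id, term_label,
#'   namespace, N, n, M, m, p_raw, ordered by p_raw.
#' @export
hypergeom_enrich <- function(targets, ann_map) {
  stopifnot(all(c("gene_id", "term_id") %in% names(ann_map)))
  if (!nrow(ann_map)) stop("annotation map is empty", call. = FALSE)
  if (is.null(ann_map$term_label)) ann_map$term_label <- ann_map$term_id
  if (is.null(ann_map$namespace)) ann_map$namespace <- NA_character_
  universe <- unique(ann_map$gene_id)
  N <- length(universe)
  cand <- unique(intersect(targets, universe))
  n <- length(cand)
  terms <- unique(ann_map[, c("term_id", "term_label", "namespace")])
  res <- do.call(rbind, lapply(seq_len(nrow(terms)), function(i) {
    genes <- unique(ann_map$gene_id[ann_map$term_id == terms$term_id[i]])
    M <- length(genes)
    m <- length(intersect(cand, genes))
    if (m > min(n, M))
      stop("internal consistency error: m > min(n, M)", call. = FALSE)
    data.frame(term_id = terms$term_id[i], term_label = terms$term_label[i],
               namespace = terms$namespace[i], N = N, n = n, M = M, m = m,
               p_raw = phyper(m - 1, M, N - M, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res <- res[res$M > 0, , drop = FALSE]
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Multiple-testing correction and significance flags
#'
#' Adds a Bonferroni-corrected p-value (`min(1, k * p)`) and a BH q-value;
#' the `significant` flag uses the chosen method at `threshold`
#' (inclusive; the classic screen used the lenient 0.5 for both).
#'
#' @param results Output of [hypergeom_enrich()].
#' @param method `"bonferroni"` or `"bh"`.
#' @param threshold Significance cut-off on the corrected value
#'   (default 0.5).
#' @return `results` with `p_bonferroni`, `q_bh` and `significant` columns.
#' @export
correct_pvalues <- function(results, method = c("bonferroni", "bh"),
                            threshold = 0.5) {
  if (!is.character(method) || !all(method %in% c("bonferroni", "bh")))
    stop("unknown correction method: must be 'bonferroni' or 'bh'",
         call. = FALSE)
  method <- match.arg(method)
  results$p_bonferroni <- p.adjust(results$p_raw, method = "bonferroni")
  results$q_bh <- p.adjust(results$p_raw, method = "BH")
  corrected <- if (method == "bonferroni") results$p_bonferroni else results$q_bh
  results$significant <- corrected <= threshold
  results
}
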