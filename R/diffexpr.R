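## Two-library differential expression: transcripts-per-million
## normalisation with the 0.01 zero-floor, log2 fold change, and the
## Audic-Claverie exact count statistic.

#' Normalized expression (reads per million clean reads)
#'
#' `NE = count / N * 1e6`. A zero NE is floored to 0.01 so fold changes stay
#' defined; features with NE < 1 in both libraries are excluded from
#' differential testing downstream.
#'
#' @param count Non-negative raw count (vectorized).
#' @param total_reads Total clean reads N of the library.
#' @return Numeric vector of floored NE values.
#' @examples
#' normalize_ne(50, 1e6)   # 50
#' normalize_ne(0, 1e6)    # 0.01
#' @export
normalize_ne <- function(count, total_reads) {
  if (any(total_reads <= 0)) stop("total clean reads must be positive", call. = FALSE)
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  ne <- count / total_reads * 1e6
  ne[ne == 0] <- 0.01
  ne
}

#' Log2 fold change of normalized expression
#'
#' `log2(NE_broody / NE_laying)`; both NE values must be positive (the 0.01
#' floor guarantees this after [normalize_ne()]).
#'
#' @param ne_broody,ne_laying Floored NE values (vectorized).
#' @return log2 fold change.
#' @export
log2_fold_change <- function(ne_broody, ne_laying) {
  stopifnot(all(ne_broody > 0), all(ne_laying > 0))
  log2(ne_broody / ne_laying)
}

## Scalar core of the Audic-Claverie two-sided p-value.  The orientation is
## canonicalised (smaller library first; at equal depth, smaller count
## first) so the statistic is exactly symmetric under exchanging the two
## libraries.  The doubled tail of the posterior-predictive mass
##   p(y | x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1)),  r = N2/N1
## is accumulated in log space; the upper tail terminates once a term falls
## 40 nats below the running maximum.
.ac_pvalue1 <- function(x, y, n1, n2) {
  if (n1 > n2 || (n1 == n2 && x > y)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  r <- n2 / n1
  lr <- log(r); l1r <- log1p(r)
  lterm <- function(yy) yy * lr + lgamma(x + yy + 1) - lgamma(x + 1) -
    lgamma(yy + 1) - (x + yy + 1) * l1r
  if (y >= x * r) {
    ## upper tail from y
    lt <- lterm(y)
    lmax <- lt
    lsum <- lt
    yy <- y
    repeat {
      yy <- yy + 1
      lt <- lterm(yy)
      lsum <- max(lsum, lt) + log1p(exp(-abs(lsum - lt)))
      if (lt > lmax) lmax <- lt else if (lt < lmax - 40) break
      if (yy > y + 1e6) break
    }
    tail <- exp(lsum)
  } else {
    lts <- lterm(0:y)
    m <- max(lts)
    tail <- exp(m) * sum(exp(lts - m))
  }
  min(1, 2 * tail)
}

#' Audic-Claverie two-library count p-value
#'
#' Exact two-sided probability that a feature with `x` reads out of `n1`
#' clean reads in one library and `y` reads out of `n2` in the other
#' deviates at least as much as observed under equal expression. The
#' observed-direction tail of the Audic-Claverie posterior-predictive
#' distribution is doubled and capped at 1. Computation is in log space and
#' the two libraries are ordered canonically first, making the result
#' symmetric under `(x, n1) <-> (y, n2)`.
#'
#' @param x,y Raw counts in library 1 and 2 (vectorized).
#' @param n1,n2 Total clean reads in library 1 and 2.
#' @return p-values in `[0, 1]`.
#' @examples
#' ac_pvalue(0, 0, 1e6, 1e6)   # 1
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) .ac_pvalue1(x[i], y[i], n1[i], n2[i]),
         numeric(1))
}

#' Build the differential-expression table for known miRNAs
#'
#' Computes floored NE values, the log2 fold change (library 2 over
#' library 1, i.e. broody over laying), the Audic-Claverie p-value on the
#' raw counts, a Benjamini-Hochberg q-value (informational), and the
#' regulation call. Features with NE < 1 in both libraries are excluded
#' from testing.
#'
#' @param counts Data frame with columns `mirna`, `count1`, `count2`.
#' @param n1,n2 Total clean reads of library 1 (laying) and 2 (broody).
#' @param alpha Significance threshold on the raw p-value (default 0.01).
#' @return Data frame of class `de_table` with columns mirna, count1,
#'   count2, n1, n2, ne1, ne2, log2fc, p_value, q_bh, call.
#' @export
de_table <- function(counts, n1, n2, alpha = 0.01) {
  stopifnot(all(c("mirna", "count1", "count2") %in% names(counts)))
  ne1 <- normalize_ne(counts$count1, n1)
  ne2 <- normalize_ne(counts$count2, n2)
  excluded <- ne1 < 1 & ne2 < 1
  out <- data.frame(mirna = counts$mirna,
                    count1 = counts$count1, count2 = counts$count2,
                    n1 = n1, n2 = n2, ne1 = ne1, ne2 = ne2,
                    log2fc = log2_fold_change(ne2, ne1),
                    p_value = NA_real_, q_bh = NA_real_,
                    call = ifelse(excluded, "excluded", "ns"),
                    stringsAsFactors = FALSE)
  idx <- which(!excluded)
  if (length(idx)) {
    out$p_value[idx] <- ac_pvalue(out$count1[idx], out$count2[idx], n1, n2)
    out$q_bh[idx] <- p.adjust(out$p_value[idx], method = "BH")
  }
  de_classify(out, alpha = alpha)
}

#' Call differential expression at a p-value threshold
#'
#' `up` means significantly higher in library 2 (broody), `down` lower;
#' the boundary `p == alpha` is inclusive. Excluded records are untouched.
#'
#' @param records Data frame with `p_value`, `log2fc` and `call` columns
#'   (rows with call `"excluded"` are skipped).
#' @param alpha Threshold on the raw p-value (default 0.01).
#' @return `records` with updated `call`; the summary counts
#'   `(n_up, n_down, n_ns, n_excluded)` are attached as attribute `summary`
#'   and available via [de_summary()].
#' @export
de_classify <- function(records, alpha = 0.01) {
  idx <- which(records$call != "excluded" | is.na(records$call))
  call <- rep("ns", length(idx))
  p <- records$p_value[idx]; fc <- records$log2fc[idx]
  call[p <= alpha & fc > 0] <- "up"
  call[p <= alpha & fc < 0] <- "down"
  records$call[idx] <- call
  attr(records, "summary") <- c(n_up = sum(records$call == "up"),
                                n_down = sum(records$call == "down"),
                                n_ns = sum(records$call == "ns"),
                                n_excluded = sum(records$call == "excluded"))
  class(records) <- unique(c("de_table", class(records)))
  records
}

#' @rdname de_classify
#' @export
de_summary <- function(records) {
  s <- attr(records, "summary")
  if (is.null(s)) s <- c(n_up = sum(records$call == "up"),
                         n_down = sum(records$call == "down"),
                         n_ns = sum(records$call == "ns"),
                         n_excluded = sum(records$call == "excluded"))
  s
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_ref)_B - (Ct_target - Ct_ref)_A`; the returned
#' value `2^-ddCt` is the expression of the target in condition B relative
#' to condition A, normalised to the reference gene.
#'
#' @param ct_target_a,ct_ref_a Mean Ct of target and reference gene in
#'   condition A.
#' @param ct_target_b,ct_ref_b Mean Ct of target and reference gene in
#'   condition B.
#' @return Relative expression (vectorized).
#' @examples
#' ddct_relative_expression(25, 20, 24, 21)   # 4
#' @export
ddct_relative_expression <- function(ct_target_a, ct_ref_a,
                                     ct_target_b, ct_ref_b) {
  stopifnot(all(c(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) > 0))
  ddct <- (ct_target_b - ct_ref_b) - (ct_target_a - ct_ref_a)
  2^(-ddct)
}
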