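## Independent oracles used across the suite. These deliberately avoid the
## package's own computational paths: direct summation instead of log-space
## recursions, explicit enumeration instead of dynamic programming, plain
## double loops instead of the compiled scanners.

## Audic-Claverie doubled tail by direct finite summation of
## p(y'|x) = r^y' (x+y')!/(x! y'! (1+r)^(x+y'+1)), with the same canonical
## orientation rule the package documents (smaller library first, then
## smaller count).
ac_oracle <- function(x, y, n1, n2, ymax = 5000) {
  if (n1 > n2 || (n1 == n2 && x > y)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  r <- n2 / n1
  pmass <- function(yy) exp(yy * log(r) + lchoose(x + yy, yy) -
                              (x + yy + 1) * log1p(r))
  tail <- if (y >= x * r) sum(pmass(y:ymax)) else sum(pmass(0:y))
  min(1, 2 * tail)
}

## Upper-tail hypergeometric probability by explicit combinatorial
## enumeration.
hyper_oracle <- function(N, M, n, m) {
  ks <- m:min(n, M)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

## Hypergeometric pmf by enumeration (for sums-to-one checks).
hyper_pmf_oracle <- function(N, M, n) {
  ks <- max(0, n - (N - M)):min(n, M)
  choose(M, ks) * choose(N - M, n - ks) / choose(N, n)
}

## Plain nucleotide complement in DNA letters.
comp_base <- c(A = "T", C = "G", G = "C", T = "A")

rc_chr <- function(s) {
  paste(rev(comp_base[strsplit(gsub("U", "T", toupper(s)), "")[[1]]]),
        collapse = "")
}

rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

## Brute-force target scan: double loop over transcripts/windows evaluating
## every rule from first principles (G:U = 0.5, non-match adjacency, the
## 2-12 / 1-12 spans, positions 10-11, strict score, stack-run MFE ratio).
target_scan_oracle <- function(mirna, transcriptome, min_ratio = 0.75,
                               strict = 2) {
  mirna <- gsub("U", "T", toupper(mirna))
  m <- strsplit(mirna, "")[[1]]
  L <- length(m)
  stack_e <- function(c1, c2) {
    if (c1 == "S" && c2 == "S") -3.0
    else if (c1 == "W" && c2 == "W") -1.8
    else -2.4
  }
  cls <- ifelse(m %in% c("G", "C"), "S", "W")
  perfect <- sum(vapply(seq_len(L - 1), function(p)
    stack_e(cls[p], cls[p + 1]), numeric(1)))
  hits <- list()
  for (tx in names(transcriptome)) {
    txs <- strsplit(gsub("U", "T", toupper(transcriptome[[tx]])), "")[[1]]
    for (w in seq_len(length(txs) - L + 1)) {
      win <- txs[w:(w + L - 1)]
      st <- character(L)
      for (p in seq_len(L)) {
        t <- win[L - p + 1]
        st[p] <- if (t == comp_base[m[p]]) "match"
          else if ((m[p] == "G" && t == "T") || (m[p] == "T" && t == "G")) "GU"
          else "mismatch"
      }
      score <- sum(st == "mismatch") + 0.5 * sum(st == "GU")
      if (score > 4 || score > strict) next
      non <- st != "match"
      runs <- rle(non)
      if (any(runs$lengths[runs$values] > 2)) next
      sp <- 2:min(12, L)
      if (any(non[sp][-1] & non[sp][-length(sp)])) next
      if (any(st[intersect(c(10, 11), 1:L)] != "match")) next
      sp2 <- 1:min(12, L)
      if (sum(st[sp2] == "mismatch") + 0.5 * sum(st[sp2] == "GU") > 2.5) next
      dup <- 0
      for (p in seq_len(L - 1)) {
        if (st[p] == "match" && st[p + 1] == "match")
          dup <- dup + stack_e(cls[p], cls[p + 1])
      }
      if (dup / perfect < min_ratio) next
      hits[[length(hits) + 1]] <- data.frame(
        transcript = tx, start = w, end = w + L - 1, score = score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(transcript = character(),
                                       start = integer(), end = integer(),
                                       score = numeric()))
  do.call(rbind, hits)
}

## Merge the oracle's overlapping windows the same documented way (best
## score, then lowest start).
merge_sites_oracle <- function(sites) {
  if (!nrow(sites)) return(sites)
  out <- list()
  for (tx in unique(sites$transcript)) {
    d <- sites[sites$transcript == tx, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    hi <- d$end[1]; g <- 1; grp <- integer(nrow(d)); grp[1] <- 1
    if (nrow(d) > 1) for (k in 2:nrow(d)) {
      if (d$start[k] > hi) g <- g + 1
      grp[k] <- g
      hi <- max(hi, d$end[k])
    }
    for (gg in unique(grp)) {
      dd <- d[grp == gg, , drop = FALSE]
      dd <- dd[order(dd$score, dd$start), , drop = FALSE]
      out[[length(out) + 1]] <- dd[1, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  res[order(res$transcript, res$start), , drop = FALSE]
}

## Dot-bracket validity check for fold results.
expect_valid_hairpin_structure <- function(fold) {
  ch <- strsplit(fold$structure, "")[[1]]
  expect_equal(length(ch), nchar(fold$sequence))
  no <- sum(ch == "(")
  nc <- sum(ch == ")")
  expect_equal(no, nc)
  if (no > 0) expect_true(max(which(ch == "(")) < min(which(ch == ")")))
  s <- strsplit(fold$sequence, "")[[1]]
  i <- which(ch == "("); j <- rev(which(ch == ")"))
  ok_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  if (no > 0) expect_true(all(paste0(s[i], s[j]) %in% ok_pairs))
  invisible(fold)
}
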