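## File format helpers. FASTA/FASTQ go through Biostrings; tables are plain
## TSV with headers so every pipeline artefact is diffable.

#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (full header line as name).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA/RNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(gsub("U", "T", toupper(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file as a character vector of read sequences
#'
#' Reads are returned as uppercase DNA strings named by their FASTQ ids.
#' A structurally invalid file produces an error naming the first
#' offending record index.
#'
#' @param path Path to a FASTQ file (uncompressed or gzip).
#' @return Named character vector of read sequences.
#' @export
read_fastq_reads <- function(path) {
  bad <- .first_bad_fastq_record(path)
  if (!is.na(bad))
    stop("malformed FASTQ record at record ", bad, " in '", path, "'",
         call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

## Vectorised scan for the first structurally broken 4-line FASTQ record
## (Biostrings is lenient about quality-line lengths, so the structural
## contract is checked up front).
.first_bad_fastq_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(NA_integer_)
  if (length(lines) %% 4 != 0) return(length(lines) %/% 4 + 1L)
  i1 <- seq(1L, length(lines), 4L)
  ok <- startsWith(lines[i1], "@") & startsWith(lines[i1 + 2], "+") &
    nchar(lines[i1 + 1]) == nchar(lines[i1 + 3]) &
    !grepl("[^ACGTUNacgtun]", lines[i1 + 1])
  if (all(ok)) NA_integer_ else which(!ok)[1]
}

#' Write reads to FASTQ with uniform qualities
#'
#' Quality strings are constant "I" (Phred 40): the simulator does not model
#' per-base quality beyond a dedicated low-quality junk class.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(!is.null(names(reads)))
  x <- Biostrings::DNAStringSet(toupper(reads))
  names(x) <- names(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read/write tab-delimited tables with headers
#'
#' @param x Data frame.
#' @param path File path.
#' @return For `read_tsv`, a data frame; for `write_tsv`, `path` invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Reverse complement for plain character vectors (DNA alphabet).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(gsub("U", "T", toupper(x)))))
}

## RNA/DNA alphabet normalisation used across modules.
as_dna <- function(x) gsub("U", "T", toupper(x))
as_rna <- function(x) gsub("T", "U", toupper(x))
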