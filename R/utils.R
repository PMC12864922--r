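#' @noRd
dna_complement <- function(x) {
  chartr("ACGTUacgtu", "TGCAAtgcaa", x)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over character input; kept in plain character space because the
#' read simulator and matcher work on raw strings.
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as named character
#' vectors, the representation used throughout the pipeline.
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read and write FASTQ
#'
#' Standard 4-line FASTQ. `write_fastq()` emits a uniform high base quality
#' ("I", Q40) unless per-read qualities are given.
#' @param ids,seqs,quals character vectors (recycled quality allowed).
#' @param path file path.
#' @return `read_fastq()` returns a data.frame with columns id, seq, qual.
#' @export
write_fastq <- function(ids, seqs, path, quals = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  }
  n <- length(ids)
  out <- character(4L * n)
  if (n > 0) {
    idx <- seq_len(n)
    out[4L * idx - 3L] <- paste0("@", ids)
    out[4L * idx - 2L] <- seqs
    out[4L * idx - 1L] <- "+"
    out[4L * idx] <- quals
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  }
  n <- length(lines) %/% 4L
  if (n == 0) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  idx <- seq_len(n)
  ids <- sub("^@", "", lines[4L * idx - 3L])
  ids <- sub("[ \t].*$", "", ids)
  data.frame(id = ids, seq = lines[4L * idx - 2L], qual = lines[4L * idx],
             stringsAsFactors = FALSE)
}

#' Write and read the pipeline's TSV tables
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "")
}

#' BED6 interval I/O (0-based half-open)
#'
#' @param df data.frame with columns chrom, start, end and optionally name,
#'   score, strand.
#' @param path file path.
#' @return `read_bed()` returns a data.frame with BED6 columns.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0 && any(df$end <= df$start)) {
    stop("BED intervals must satisfy start < end")
  }
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0,
                    strand = if ("strand" %in% names(df)) df$strand else "+")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    stop("malformed BED at line ", bad[1], ": fewer than 3 fields")
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0) {
    stop("malformed BED at line ", bad[1], ": bad interval")
  }
  data.frame(chrom = get(1, NA), start = start, end = end,
             name = get(4, "."),
             score = suppressWarnings(as.numeric(get(5, "0"))),
             strand = get(6, "+"), stringsAsFactors = FALSE)
}

#' @noRd
random_dna <- function(n, len, alphabet = c("A", "C", "G", "T"),
                       prob = NULL) {
  if (n == 0) return(character(0))
  m <- matrix(sample(alphabet, n * len, replace = TRUE, prob = prob),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
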