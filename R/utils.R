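#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive values (the convention used by most printed summary tables),
#' unlike [base::round()]'s round-half-to-even. A tiny guard absorbs
#' floating-point dust so that values such as `1.535` stored as
#' `1.53499999...` still round up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(1.525, 0.015, 2.345), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(round(x * scale + 0.5, 9)) / scale
}

#' Percentage of a total, rounded half-up
#'
#' @param count numeric vector of counts.
#' @param total denominator (scalar or vector).
#' @param digits decimal places (default 2, matching printed tables).
#' @return percentages on the 0-100 scale.
#' @export
percent_of <- function(count, total, digits = 2) {
  stopifnot(all(total > 0))
  round_half_up(count / total * 100, digits)
}

# Reverse complement on plain character vectors (DNA alphabet, U tolerated).
revcomp <- function(x) {
  chartr("ACGTU", "TGCAA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Random DNA strings of the given lengths.
random_dna <- function(lengths, letters = c("A", "C", "G", "T")) {
  vapply(lengths, function(n) {
    paste(sample(letters, n, replace = TRUE), collapse = "")
  }, character(1))
}

# Apply k random substitutions to a sequence, guaranteed to change the base.
mutate_seq <- function(seq, k) {
  mutate_seq_at(seq, k, seq_len(nchar(seq)))
}

# As mutate_seq, but positions are drawn from an allowed set only.
mutate_seq_at <- function(seq, k, allowed) {
  if (k == 0 || !length(allowed)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- allowed[sample.int(length(allowed), min(k, length(allowed)))]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Hamming distance between two equal-length strings (fast byte compare).
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' character sequences keyed by record name.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Write reads + Phred+33 quality strings as FASTQ.
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ids)) {
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  }
  invisible(path)
}

# Validate FASTQ framing cheaply so parse errors name the offending record.
validate_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4 (record ",
         length(lines) %/% 4 + 1, " truncated)")
  }
  heads <- lines[seq(1, length(lines), by = 4)]
  seps <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "': record ", bad[1],
         " lacks '@'/'+' framing")
  }
  invisible(TRUE)
}

# Read FASTQ into a list(seq = character, qual = character).
read_fastq <- function(path) {
  validate_fastq(path)
  lines <- readLines(path)
  n <- length(lines) %/% 4
  list(
    id = sub("^@", "", lines[seq(1, length(lines), by = 4)]),
    seq = toupper(lines[seq(2, length(lines), by = 4)]),
    qual = lines[seq(4, length(lines), by = 4)]
  )
}

# Mean Phred score (+33 offset) per quality string, vectorised.
mean_phred <- function(quals) {
  vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}
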