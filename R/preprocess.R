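#' Clean and length-select raw small-RNA reads
#'
#' Applies the standard sRNA-seq cleaning cascade to a FASTQ file:
#' \enumerate{
#'   \item quality: reads with mean Phred below `quality_floor` are
#'     removed ("low-quality"); survivors are the high-quality reads;
#'   \item adapter: the leftmost occurrence of the 3' adapter (allowing
#'     `adapter_mm` substitutions, minimum overlap `min_overlap` nt when
#'     the read ends inside the adapter) is trimmed; untrimmed reads are
#'     kept only if already no longer than `max_len`;
#'   \item ambiguity: reads containing N are removed;
#'   \item poly(A): reads with a run of >= 8 consecutive A or >= 80% A
#'     content are removed;
#'   \item length: surviving inserts must be within `[min_len, max_len]`.
#' }
#'
#' @param fastq path to a FASTQ file (Phred+33).
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len insert length window (nt).
#' @param quality_floor minimum mean Phred score of a high-quality read.
#' @param adapter_mm substitutions tolerated in the adapter match.
#' @param min_overlap minimum adapter overlap at the read 3' end.
#' @return list of class `cleaning_result` with `reads` (clean insert
#'   sequences) and `stats` (a `cleaning_stats` list: `raw_reads`,
#'   `high_quality_reads`, `clean_reads`, per-reason removal counts and
#'   the clean-read `length_histogram`).
#' @export
clean_reads <- function(fastq, adapter, min_len = 18, max_len = 30,
                        quality_floor = 20, adapter_mm = 1, min_overlap = 6) {
  stopifnot(nchar(adapter) > 0, min_len <= max_len)
  fq <- read_fastq(fastq)
  raw <- length(fq$seq)

  mq <- mean_phred(fq$qual)
  hq <- mq >= quality_floor
  n_lowq <- sum(!hq)
  seqs <- fq$seq[hq]

  pos <- .adapter_scan(seqs, toupper(adapter), as.integer(adapter_mm),
                       as.integer(min_overlap))
  trimmed <- ifelse(pos >= 0, substr(seqs, 1, pos), seqs)
  no_adapter <- pos < 0 & nchar(seqs) > max_len
  n_no_adapter <- sum(no_adapter)
  trimmed <- trimmed[!no_adapter]

  has_n <- grepl("N", trimmed, fixed = TRUE)
  n_ambig <- sum(has_n)
  trimmed <- trimmed[!has_n]

  a_frac <- nchar(gsub("[^A]", "", trimmed)) / pmax(1, nchar(trimmed))
  polya <- grepl("AAAAAAAA", trimmed, fixed = TRUE) | a_frac >= 0.8
  n_polya <- sum(polya)
  trimmed <- trimmed[!polya]

  len <- nchar(trimmed)
  n_short <- sum(len < min_len)
  n_long <- sum(len > max_len)
  clean <- trimmed[len >= min_len & len <= max_len]

  hist <- table(factor(nchar(clean), levels = min_len:max_len))
  stats <- structure(list(
    raw_reads = raw,
    high_quality_reads = raw - n_lowq,
    clean_reads = length(clean),
    removed = c(low_quality = n_lowq, no_adapter = n_no_adapter,
                ambiguous = n_ambig, poly_a = n_polya,
                too_short = n_short, too_long = n_long),
    length_histogram = as.integer(hist),
    length_bins = min_len:max_len
  ), class = "cleaning_stats")
  structure(list(reads = clean, stats = stats), class = "cleaning_result")
}

#' @export
print.cleaning_stats <- function(x, ...) {
  cat(sprintf("raw reads:          %d\n", x$raw_reads))
  cat(sprintf("high-quality reads: %d\n", x$high_quality_reads))
  cat(sprintf("clean reads:        %d (%.2f%% of high-quality)\n",
              x$clean_reads, clean_rate(x$high_quality_reads, x$clean_reads)))
  cat("removed:", paste(names(x$removed), x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Clean-read rate as a percentage of high-quality reads
#'
#' @param high_quality,clean read counts.
#' @param digits decimal places (half-up).
#' @return percentage on the 0-100 scale.
#' @export
#' @examples
#' clean_rate(23168277, 23040002)  # 99.45
clean_rate <- function(high_quality, clean, digits = 2) {
  percent_of(clean, high_quality, digits)
}

#' Collapse clean reads from both libraries into unique tags
#'
#' @param control,treated character vectors of clean insert sequences
#'   (one element per read).
#' @return data.frame with one row per distinct sequence: `sequence`,
#'   `count_control`, `count_treated`, ordered by decreasing pooled count.
#' @export
collapse_tags <- function(control, treated) {
  tc <- table(control)
  tt <- table(treated)
  seqs <- union(names(tc), names(tt))
  out <- data.frame(
    sequence = seqs,
    count_control = as.integer(tc[seqs]),
    count_treated = as.integer(tt[seqs]),
    stringsAsFactors = FALSE
  )
  out$count_control[is.na(out$count_control)] <- 0L
  out$count_treated[is.na(out$count_treated)] <- 0L
  out <- out[order(-(out$count_control + out$count_treated), out$sequence), ]
  rownames(out) <- NULL
  out
}

#' Length distribution of unique tags
#'
#' @param tags a [collapse_tags()] data.frame.
#' @param min_len,max_len histogram bin range (nt).
#' @return data.frame with one row per length bin and, per library,
#'   total-read and unique-tag counts with percentages.
#' @export
length_distribution <- function(tags, min_len = 18, max_len = 30) {
  if (nrow(tags) == 0) stop("no tags: empty library")
  len <- factor(nchar(tags$sequence), levels = min_len:max_len)
  out <- data.frame(length = min_len:max_len)
  for (lib in c("control", "treated")) {
    cnt <- tags[[paste0("count_", lib)]]
    tot <- as.integer(tapply(cnt, len, sum, default = 0L))
    uni <- as.integer(tapply(as.integer(cnt > 0), len, sum, default = 0L))
    out[[paste0("total_", lib)]] <- tot
    out[[paste0("total_", lib, "_pct")]] <- percent_of(tot, max(1, sum(tot)))
    out[[paste0("unique_", lib)]] <- uni
    out[[paste0("unique_", lib, "_pct")]] <- percent_of(uni, max(1, sum(uni)))
  }
  out
}

#' Write collapsed tags as FASTA with count-bearing headers
#'
#' Headers follow the `>tagN_x<control>_y<treated>` convention.
#'
#' @param tags a [collapse_tags()] data.frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  ids <- sprintf("tag%d_x%d_y%d", seq_len(nrow(tags)),
                 tags$count_control, tags$count_treated)
  seqs <- tags$sequence
  names(seqs) <- ids
  write_fasta(seqs, path)
}
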