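# Shared fixtures: a small but complete synthetic experiment and a few
# hand-built micro-inputs.

TEST_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

small_config <- function(seed = 101, ...) {
  simulation_config(depth_per_library = 8000, n_transcripts = 30,
                    n_conserved_mirnas = 6, n_novel_mirnas = 6,
                    seed = seed, ...)
}

# Write a FASTQ from inserts: insert + adapter + fill, fixed quality.
write_test_fastq <- function(inserts, path, adapter = TEST_ADAPTER,
                             read_len = 50, phred = 35) {
  reads <- substr(paste0(inserts, adapter,
                         strrep("G", read_len)), 1, read_len)
  quals <- strrep(intToUtf8(phred + 33), nchar(reads))
  con <- file(path, "w")
  writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n", quals), con)
  close(con)
  path
}

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
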