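test_that("configuration is validated", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(depth_per_library = 0), "positive count")
  expect_error(simulation_config(mature_len_range = c(16, 24)), "18-30")
  expect_error(simulation_config(de_fraction = 1.5), "de_fraction")
  expect_error(simulation_config(n_transcripts = 10), "n_transcripts")
})

test_that("reference bundle is deterministic and bookkeeps miRNA classes", {
  cfg <- small_config(seed = 7)
  ref1 <- make_reference(cfg)
  ref2 <- make_reference(cfg)
  expect_identical(ref1$transcripts, ref2$transcripts)
  expect_identical(ref1$truth, ref2$truth)

  expect_equal(nrow(ref1$truth), 12)  # 6 conserved + 6 novel
  expect_equal(sum(ref1$truth$class == "conserved"), 6)
  expect_equal(length(ref1$known_matures), 6)

  # no novel class => known matures cover all planted matures
  cfg0 <- simulation_config(n_conserved_mirnas = 5, n_novel_mirnas = 0,
                            n_transcripts = 12, seed = 3)
  ref0 <- make_reference(cfg0)
  expect_equal(length(ref0$known_matures), 5)
  expect_true(all(ref0$truth$class == "conserved"))
})

test_that("planted structures respect their own invariants", {
  ref <- make_reference(small_config(seed = 11))
  t <- ref$truth
  for (i in seq_len(nrow(t))) {
    # each precursor occurs in exactly one host transcript
    hits <- vapply(ref$transcripts, grepl, logical(1), pattern = t$precursor[i],
                   fixed = TRUE)
    expect_equal(sum(hits), 1)
    expect_equal(names(ref$transcripts)[hits], t$host_transcript[i])
    # mature inside precursor, on the recorded arm side
    expect_true(grepl(t$mature[i], t$precursor[i], fixed = TRUE))
  }
  # cleavage positions lie within their transcript
  for (k in seq_len(nrow(ref$targets))) {
    len <- nchar(ref$transcripts[[ref$targets$transcript[k]]])
    expect_gte(ref$targets$cleavage_pos[k], 0)
    expect_lt(ref$targets$cleavage_pos[k] + 20, len)
  }
  # DE labels consistent with true lfc at the |lfc| >= 1 threshold
  expect_equal(t$is_de, abs(t$true_lfc) >= 1)
})

test_that("read simulation is deterministic and respects depth", {
  cfg <- small_config(seed = 5)
  ref <- make_reference(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- simulate_sra_reads(ref, d1)
  r2 <- simulate_sra_reads(ref, d2)
  expect_identical(readLines(r1$fastq[["control"]]),
                   readLines(r2$fastq[["control"]]))
  expect_identical(r1$truth_counts, r2$truth_counts)
  # per-library planted miRNA reads never exceed the configured depth
  expect_lte(sum(r1$truth_counts$count_control), cfg$depth_per_library)
  expect_lte(sum(r1$truth_counts$count_treated), cfg$depth_per_library)
  # library sizes equal the configured depth
  expect_equal(length(readLines(r1$fastq[["control"]])) / 4,
               cfg$depth_per_library)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero-dispersion count model matches a Poisson oracle", {
  set.seed(1)
  mu <- 40
  sim <- simulate_counts(rep(mu, 10000), lfc = 0, dispersion = 0)
  x <- sim$count_control
  set.seed(1)
  # Poisson oracle at the same mean
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(var(x), mu, tolerance = 0.05)
  # chi-square GOF against the Poisson pmf over a central range
  rng <- (mu - 15):(mu + 15)
  obs <- tabulate(factor(x[x %in% rng], levels = rng), nbins = length(rng))
  expct <- dpois(rng, mu) * length(x)
  chi <- sum((obs - expct)^2 / expct)
  expect_lt(chi, qchisq(0.999, df = length(rng) - 1))
})

test_that("overdispersed counts exceed Poisson variance", {
  set.seed(2)
  sim <- simulate_counts(rep(100, 20000), lfc = 0, dispersion = 0.1)
  expect_gt(var(sim$count_control) / mean(sim$count_control), 5)
  # treated mean scales with 2^lfc
  sim2 <- simulate_counts(rep(100, 20000), lfc = 2, dispersion = 0.02)
  expect_equal(mean(sim2$count_treated) / mean(sim2$count_control), 4,
               tolerance = 0.05)
})

test_that("degradome simulation plants dominant tags at true sites", {
  cfg <- small_config(seed = 9)
  ref <- make_reference(cfg)
  d <- tempfile()
  deg <- simulate_degradome(ref, d, background_per_transcript = 0)
  tags <- read_fasta(deg$fasta[["control"]])
  # with zero background every planted site is the unique per-transcript
  # maximum: check via the package mapper
  ann <- classify_degradome_tags(unname(tags), ref$transcripts,
                                 ref$noncoding, ref$noncoding_family)
  sense <- ann$tags[ann$tags$annotation == "cDNA_sense", ]
  for (k in seq_len(nrow(ref$targets))) {
    prof <- sense[sense$transcript == ref$targets$transcript[k], ]
    agg <- tapply(prof$count, prof$pos, sum)
    expect_equal(as.integer(names(agg)[which.max(agg)]),
                 ref$targets$cleavage_pos[k])
  }
  unlink(d, recursive = TRUE)
})

test_that("config round-trips through the key=value file", {
  cfg <- small_config(seed = 77)
  f <- tempfile()
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$depth_per_library, cfg$depth_per_library)
  expect_equal(cfg2$adapter_seq, cfg$adapter_seq)
  expect_equal(cfg2$true_lfc_values, cfg$true_lfc_values)
})
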