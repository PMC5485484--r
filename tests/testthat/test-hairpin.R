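test_that("precursor windows are clipped and cover planted hairpins", {
  set.seed(15)
  tx <- setNames(rand_seq(1, 400), "t1")
  tag <- substr(tx, 1, 21)  # maps at transcript start
  tags <- data.frame(sequence = tag, count_control = 10L, count_treated = 0L)
  w <- extract_precursors(tags, tx, flank = 150)
  expect_equal(nrow(w), 2)
  expect_equal(w$win_start[1], 0)          # upstream window clipped
  expect_equal(w$win_end[1], 21)
  expect_equal(nchar(w$window[1]), 21)     # length collapses to tag length
  expect_equal(w$win_end[2], 171)  # tag_end (21) + flank

  # a tag mapping to two transcripts yields windows from both
  tx2 <- c(tx, t2 = paste0(rand_seq(1, 50), tag, rand_seq(1, 50)))
  w2 <- extract_precursors(tags, tx2, flank = 150)
  expect_setequal(unique(w2$transcript), c("t1", "t2"))

  # unmapped tags are skipped
  w3 <- extract_precursors(
    data.frame(sequence = rand_seq(1, 22), count_control = 9L,
               count_treated = 0L), tx)
  expect_equal(nrow(w3), 0)
})

test_that("planted hairpin fixture yields exactly one call per mature", {
  cfg <- simulation_config(n_conserved_mirnas = 1, n_novel_mirnas = 8,
                           n_transcripts = 30, depth_per_library = 5000,
                           star_fraction = 3 / 9, seed = 23)
  ref <- make_reference(cfg)
  dir <- tempfile()
  reads <- simulate_sra_reads(ref, dir)
  cl <- lapply(reads$fastq, clean_reads, adapter = cfg$adapter_seq)
  tags <- collapse_tags(cl$control$reads, cl$treated$reads)
  ann <- annotate_tags(tags, ref$known_matures, ref$noncoding,
                       ref$noncoding_family)
  unann <- unannotated_tags(ann)
  w <- extract_precursors(unann, ref$transcripts)
  novel <- call_novel(w, unann, known_matures = ann$conserved$sequence)
  nov_truth <- ref$truth[ref$truth$class == "novel", ]
  m <- match(nov_truth$mature, novel$mature)
  expect_true(all(!is.na(m)))
  expect_equal(novel$arm[m], nov_truth$arm)
  expect_equal(nrow(novel), nrow(nov_truth))  # stars never double-called
  # star flags match the planted star reads
  expect_equal(sort(novel$mature[novel$has_star]),
               sort(nov_truth$mature[nov_truth$has_star_reads]))
  unlink(dir, recursive = TRUE)
})

test_that("a mature spanning the terminal loop is rejected", {
  # hairpin whose only qualifying placement covers the loop
  stem <- "GCGCGGCAGUCCUAUGCGGCAGU"
  loop <- "ACACACACACAC"
  prec <- paste0(stem, loop, srnadeg:::revcomp(chartr("U", "T", stem)))
  f <- fold_rna(prec)
  # position the candidate across the loop centre
  m1 <- nchar(stem) - 4
  m2 <- m1 + 20
  ev <- srnadeg:::evaluate_hairpin(f, m1, m2, -18, 4, 2)
  expect_null(ev)
})

test_that("calls below the count floor are dropped", {
  cfg <- simulation_config(n_conserved_mirnas = 1, n_novel_mirnas = 4,
                           n_transcripts = 12, depth_per_library = 4000,
                           seed = 29)
  ref <- make_reference(cfg)
  nov <- ref$truth[ref$truth$class == "novel", ]
  tags <- data.frame(sequence = nov$mature,
                     count_control = c(10L, 3L, 3L, 1L),
                     count_treated = c(10L, 3L, 1L, 1L))
  w <- extract_precursors(tags, ref$transcripts)
  calls <- call_novel(w, tags)
  expect_setequal(calls$mature, nov$mature[c(1, 2)])  # pooled >= 5 only
})

test_that("star detection is reverse-complement aware", {
  set.seed(33)
  m <- rand_seq(1, 21)
  star <- srnadeg:::revcomp(m)
  expect_true(is_star_like(m, star))
  expect_false(is_star_like(m, rand_seq(1, 21)))
  expect_true(flag_star_support(m, c(star, rand_seq(5, 21))))
  # singleton support can be filtered by count
  expect_false(flag_star_support(m, c(star, rand_seq(5, 21)),
                                 tag_counts = c(1L, rep(5L, 5))))
})
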