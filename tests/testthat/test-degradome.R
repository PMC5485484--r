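deg_fixture <- function(seed = 41) {
  set.seed(seed)
  tx <- setNames(c(rand_seq(1, 300), rand_seq(1, 300)), c("t1", "t2"))
  nc <- setNames(rand_seq(2, 90), c("r1", "tr1"))
  fam <- c("rRNA", "tRNA")
  list(tx = tx, nc = nc, fam = fam)
}

test_that("degradome tags classify with the documented precedence", {
  fx <- deg_fixture()
  tag_sense <- substr(fx$tx[["t1"]], 51, 70)
  tag_anti <- srnadeg:::revcomp(substr(fx$tx[["t2"]], 101, 120))
  tag_r <- substr(fx$nc[["r1"]], 11, 30)
  tag_polyn <- paste0("ACGT", strrep("N", 6), "ACGTACGTAC")
  tag_other <- rand_seq(1, 20)
  ann <- classify_degradome_tags(
    c(tag_sense, tag_sense, tag_anti, tag_r, tag_polyn, tag_other),
    fx$tx, fx$nc, fx$fam)
  got <- setNames(ann$tags$annotation, ann$tags$sequence)
  expect_equal(unname(got[tag_sense]), "cDNA_sense")
  expect_equal(unname(got[substr(tag_anti, 1, 20)]), "cDNA_antisense")
  expect_equal(unname(got[tag_r]), "rRNA")
  expect_equal(unname(got[substr(tag_polyn, 1, 20)]), "polyN")
  expect_equal(unname(got[tag_other]), "other")
  # counts: duplicated sense tag collapses to count 2
  expect_equal(ann$tags$count[ann$tags$sequence == tag_sense], 2)
  # summary partitions and percentages
  s <- ann$summary
  expect_equal(s$total_tags[s$category == "Total"], 6)
  expect_equal(sum(s$unique_tags[s$category != "Total"]),
               s$unique_tags[s$category == "Total"])
  # printed-table worked example
  expect_equal(percent_of(8086336, 22803097), 35.46)
  expect_equal(percent_of(2926724, 9096818), 32.17)
})

test_that("target alignment scores follow the penalty scheme", {
  set.seed(43)
  mir <- c(m1 = rand_seq(1, 21))
  site <- srnadeg:::revcomp(mir)
  tx <- setNames(paste0(rand_seq(1, 80), site, rand_seq(1, 80)), "t1")
  hits <- align_mirna_targets(mir, tx)
  perfect <- hits[hits$score == 0, ]
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$pos, 80)
  expect_equal(perfect$cleavage_pos, 80 + 21 - 10)

  # single G:U at miRNA position 5 scores 0.5 x 2 (core doubling)
  ch <- strsplit(site, "")[[1]]
  # miRNA position 5 pairs transcript site offset L - 5 (0-based 16)
  pos_in_site <- 21 - 5 + 1
  base <- ch[pos_in_site]
  mir_base <- substr(mir, 5, 5)
  wob <- if (mir_base == "G") "T" else if (mir_base == "T") "G" else NA
  if (!is.na(wob)) {
    ch[pos_in_site] <- wob
    tx2 <- setNames(paste0(rand_seq(1, 80), paste(ch, collapse = ""),
                           rand_seq(1, 80)), "t1")
    h2 <- align_mirna_targets(mir, tx2)
    expect_true(any(abs(h2$score - 1.0) < 1e-9 & h2$pos == 80))
  }
  expect_error(align_mirna_targets(c(bad = "ACGT"), tx), "18-30")
})

test_that("t-plot categories follow the five-class protocol", {
  # direct category arithmetic on profiles
  expect_equal(srnadeg:::tplot_category(1, c(1, 1, 1)), 4L)
  expect_equal(srnadeg:::tplot_category(50, c(50, 1, 1, 1)), 0L)
  expect_equal(srnadeg:::tplot_category(50, c(50, 50, 1)), 1L)
  expect_equal(srnadeg:::tplot_category(5, c(50, 5, 2, 1, 1)), 2L)
  expect_equal(srnadeg:::tplot_category(2, c(50, 40, 30, 2, 2)), 3L)
})

test_that("cleavage calling recovers planted sites and drops empty ones", {
  set.seed(47)
  mir <- c(m1 = rand_seq(1, 21))
  site <- srnadeg:::revcomp(mir)
  tx <- setNames(paste0(rand_seq(1, 100), site, rand_seq(1, 100)), "t1")
  cpos <- 100 + 21 - 10
  site_tags <- rep(substr(tx, cpos + 1, cpos + 20), 50)
  bg_pos <- c(10, 40, 170)
  bg_tags <- substring(tx, bg_pos + 1, bg_pos + 20)
  ann <- classify_degradome_tags(c(site_tags, bg_tags), tx,
                                 character(0), character(0))
  dup <- align_mirna_targets(mir, tx)
  hits <- call_cleavage(dup, ann)
  planted <- hits[hits$cleavage_pos == cpos, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$site_count, 50)
  expect_equal(planted$category, 0L)
  # duplexes with no tag support are dropped
  expect_true(all(hits$site_count > 0))

  # t-plot table conserves abundance and flags the site
  tp <- tplot_table(planted, ann, tx)
  expect_equal(sum(tp$abundance), 53)
  expect_equal(tp$position[tp$is_cleavage_site], cpos)
  expect_equal(tp$abundance[tp$is_cleavage_site], 50)
})

test_that("end-to-end planted degradome recovery is category 0", {
  cfg <- small_config(seed = 51)
  ref <- make_reference(cfg)
  d <- tempfile()
  deg <- simulate_degradome(ref, d)
  ann <- classify_degradome_tags(deg$fasta[["control"]], ref$transcripts,
                                 ref$noncoding, ref$noncoding_family)
  mir <- setNames(ref$truth$mature, ref$truth$mirna_id)
  dup <- align_mirna_targets(mir, ref$transcripts)
  hits <- call_cleavage(dup, ann)
  key <- paste(hits$transcript, hits$cleavage_pos)
  tkey <- paste(ref$targets$transcript, ref$targets$cleavage_pos)
  expect_true(all(tkey %in% key))
  rec <- hits[key %in% tkey, ]
  expect_true(all(rec$category == 0))
  unlink(d, recursive = TRUE)
})
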