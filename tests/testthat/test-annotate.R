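mk_tags <- function(seqs, ctl = NULL, trt = NULL) {
  n <- length(seqs)
  data.frame(sequence = seqs,
             count_control = if (is.null(ctl)) rep(1L, n) else ctl,
             count_treated = if (is.null(trt)) rep(0L, n) else trt,
             stringsAsFactors = FALSE)
}

test_that("conserved matching applies the two-mismatch rule and tie-breaks", {
  set.seed(5)
  ref <- rand_seq(1, 21)
  known <- c(mirA = ref, mirB = ref)
  tags <- mk_tags(ref)
  calls <- match_known_mirnas(tags, known)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$mismatches, 0)
  expect_equal(calls$known_id, "mirA")  # lexicographic tie-break

  tag2 <- srnadeg:::mutate_seq(ref, 2)
  tag3 <- srnadeg:::mutate_seq(ref, 3)
  calls2 <- match_known_mirnas(mk_tags(c(tag2, tag3)), c(mir = ref))
  expect_equal(calls2$sequence, tag2)
  expect_equal(calls2$mismatches, 2)

  # length tolerance: flush 5' end, up to 2 nt shorter/longer
  short2 <- substr(ref, 1, 19)
  long2 <- paste0(ref, "GG")
  too_short <- substr(ref, 1, 18)
  calls3 <- match_known_mirnas(mk_tags(c(short2, long2, too_short)),
                               c(mir = ref))
  expect_setequal(calls3$sequence, c(short2, long2))
})

test_that("conserved calls agree with a brute-force alignment oracle", {
  set.seed(6)
  refs <- setNames(rand_seq(8, 21), paste0("mir", 1:8))
  pool <- c(
    vapply(refs[1:5], function(r) srnadeg:::mutate_seq(r, sample(0:2, 1)),
           character(1)),
    rand_seq(60, 21)
  )
  tags <- mk_tags(unique(pool))
  calls <- match_known_mirnas(tags, refs)
  # oracle: enumerate all (tag, ref) pairs independently
  oracle_hit <- vapply(tags$sequence, function(tg) {
    any(vapply(refs, function(r) {
      lt <- nchar(tg); lr <- nchar(r)
      if (abs(lt - lr) > 2) return(FALSE)
      ov <- min(lt, lr)
      sum(charToRaw(substr(tg, 1, ov)) != charToRaw(substr(r, 1, ov))) <= 2
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  expect_setequal(calls$sequence, tags$sequence[oracle_hit])
  # the 5 planted mutated matures are all recovered
  expect_true(all(pool[1:5] %in% calls$sequence))
})

test_that("noncoding classification is exact-substring with precedence", {
  set.seed(7)
  rrna <- rand_seq(1, 80)
  trna <- rand_seq(1, 80)
  tag_r <- substr(rrna, 10, 30)
  tag_both <- substr(rrna, 40, 60)
  trna2 <- paste0(substr(trna, 1, 30), tag_both, substr(trna, 31, 80))
  tag_none <- rand_seq(1, 24)
  nc <- c(rrna, trna2)
  fam <- c("rRNA", "tRNA")
  got <- classify_noncoding(mk_tags(c(tag_r, tag_both, tag_none)), nc, fam)
  expect_equal(got, c("rRNA", "rRNA", NA))  # rRNA beats tRNA
})

test_that("category table partitions tags and reproduces printed cells", {
  set.seed(8)
  known <- setNames(rand_seq(2, 21), c("mirA", "mirB"))
  nc <- rand_seq(2, 90)
  fam <- c("rRNA", "tRNA")
  tags <- mk_tags(
    c(known[[1]], substr(nc[1], 5, 26), substr(nc[2], 5, 26), rand_seq(3, 22)),
    ctl = c(5L, 3L, 2L, 1L, 1L, 0L), trt = c(2L, 0L, 1L, 0L, 1L, 4L))
  ann <- annotate_tags(tags, known, nc, fam)
  tab <- category_table(ann)
  for (lib in c("control", "treated")) {
    for (kind in c("unique", "total")) {
      col <- paste0(kind, "_", lib)
      expect_equal(sum(tab[[col]][tab$category != "Total"]),
                   tab[[col]][tab$category == "Total"])
    }
  }
  # single-category edge: all tags in one bucket carry 100%
  solo <- annotate_tags(mk_tags(rand_seq(3, 20), ctl = c(1L, 1L, 1L)),
                        known, nc, fam)
  stab <- category_table(solo)
  expect_equal(stab$unique_control_pct[stab$category == "unann"], 100)

  # printed-table worked example: percentage cells from integer counts
  expect_equal(percent_of(49384, 3221622), 1.53)
  expect_equal(percent_of(4086959, 11777552), 34.70)
})

test_that("unannotated pool is exactly the unann records", {
  set.seed(9)
  known <- setNames(rand_seq(1, 21), "mirA")
  nc <- rand_seq(1, 90)
  tags <- mk_tags(c(known[[1]], substr(nc, 3, 24), rand_seq(4, 21)))
  ann <- annotate_tags(tags, known, nc, "rRNA")
  pool <- unannotated_tags(ann)
  expect_setequal(pool$sequence,
                  ann$records$sequence[ann$records$category == "unann"])
})
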