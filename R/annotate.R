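# Mismatches between a tag and a known mature aligned flush at the 5'
# end; lengths may differ by at most len_tol, the 3' overhang is ignored.
# Returns NA when the pair is not alignable.
mature_mismatches <- function(tag, ref, max_mismatch = 2, len_tol = 2) {
  lt <- nchar(tag)
  lr <- nchar(ref)
  if (abs(lt - lr) > len_tol) return(NA_integer_)
  ov <- min(lt, lr)
  mm <- hamming(substr(tag, 1, ov), substr(ref, 1, ov))
  if (mm > max_mismatch) NA_integer_ else mm
}

#' Identify conserved miRNAs among unique tags
#'
#' A tag is called conserved when an ungapped alignment to some known
#' mature miRNA - flush at the 5' end, length difference of at most 2 nt
#' with the 3' overhang tolerated - has at most `max_mismatch`
#' substitutions. Ties are broken by fewest mismatches, then by the
#' lexicographically smallest reference id.
#'
#' @param tags a [collapse_tags()] data.frame.
#' @param known named character vector of known mature sequences (or a
#'   FASTA path).
#' @param max_mismatch maximum substitutions (default 2).
#' @return data.frame of calls: `sequence`, `known_id`, `mismatches`,
#'   `count_control`, `count_treated`. Zero rows when nothing matches.
#' @export
match_known_mirnas <- function(tags, known, max_mismatch = 2) {
  if (is.character(known) && length(known) == 1 && file.exists(known)) {
    known <- read_fasta(known)
  }
  stopifnot(length(known) > 0, !is.null(names(known)))
  known <- toupper(chartr("U", "T", known))
  empty <- data.frame(sequence = character(0), known_id = character(0),
                      mismatches = integer(0), count_control = integer(0),
                      count_treated = integer(0), stringsAsFactors = FALSE)
  if (nrow(tags) == 0) return(empty)

  ord <- order(names(known))
  known <- known[ord]
  calls <- lapply(seq_len(nrow(tags)), function(i) {
    tg <- tags$sequence[i]
    mm <- vapply(known, mature_mismatches, integer(1), tag = tg,
                 max_mismatch = max_mismatch)
    if (all(is.na(mm))) return(NULL)
    best <- which(mm == min(mm, na.rm = TRUE))[1]  # refs are id-sorted
    data.frame(sequence = tg, known_id = names(known)[best],
               mismatches = mm[[best]],
               count_control = tags$count_control[i],
               count_treated = tags$count_treated[i],
               stringsAsFactors = FALSE)
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Classify tags against noncoding RNA families
#'
#' A tag matches a family when it is an exact substring of any sequence
#' in that family's database. When several families match, precedence is
#' rRNA > tRNA > snRNA > snoRNA.
#'
#' @param tags a [collapse_tags()] data.frame.
#' @param noncoding named character vector of family sequences.
#' @param family family label per noncoding sequence (values among
#'   rRNA, tRNA, snRNA, snoRNA; scRNA entries are folded into snRNA).
#' @return character vector: the matched family per tag, or `NA`.
#' @export
classify_noncoding <- function(tags, noncoding, family) {
  stopifnot(length(noncoding) == length(family))
  family[family == "scRNA"] <- "snRNA"
  prec <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  out <- rep(NA_character_, nrow(tags))
  for (fam in prec) {
    seqs <- noncoding[family == fam]
    if (!length(seqs)) next
    haystack <- paste(seqs, collapse = "|")
    todo <- which(is.na(out))
    if (!length(todo)) break
    hit <- vapply(tags$sequence[todo], grepl, logical(1), x = haystack,
                  fixed = TRUE, USE.NAMES = FALSE)
    out[todo[hit]] <- fam
  }
  out
}

#' Hierarchically annotate unique tags
#'
#' Assigns each tag exactly one category with precedence
#' miRNA > rRNA > tRNA > snRNA > snoRNA > unann. miRNA calls come from
#' [match_known_mirnas()]; noncoding matches are exact-substring.
#'
#' @param tags a [collapse_tags()] data.frame.
#' @param known known mature miRNAs (named vector or FASTA path).
#' @param noncoding named character vector of noncoding sequences.
#' @param family family label per noncoding sequence.
#' @param max_mismatch miRNA mismatch tolerance.
#' @return list of class `annotation` with `records` (tags + `category`,
#'   `matched_reference`, `mismatches`) and `conserved` (the miRNA calls).
#' @export
annotate_tags <- function(tags, known, noncoding, family, max_mismatch = 2) {
  conserved <- match_known_mirnas(tags, known, max_mismatch)
  records <- tags
  records$category <- "unann"
  records$matched_reference <- NA_character_
  records$mismatches <- NA_integer_

  is_mir <- records$sequence %in% conserved$sequence
  idx <- match(records$sequence[is_mir], conserved$sequence)
  records$category[is_mir] <- "miRNA"
  records$matched_reference[is_mir] <- conserved$known_id[idx]
  records$mismatches[is_mir] <- conserved$mismatches[idx]

  rest <- !is_mir
  fam <- classify_noncoding(records[rest, , drop = FALSE], noncoding, family)
  records$category[rest][!is.na(fam)] <- fam[!is.na(fam)]

  structure(list(records = records, conserved = conserved),
            class = "annotation")
}

#' Per-library category table with unique/total counts and percentages
#'
#' Reproduces the layout of a categories-and-statistics summary table:
#' one row per category plus a Total row; per library, unique-tag and
#' total-read counts, each with a percentage of the library total rounded
#' half-up to two decimals.
#'
#' @param annotation an [annotate_tags()] result (or its `records`).
#' @return data.frame rows Total, miRNA, rRNA, snRNA, snoRNA, tRNA,
#'   unann; columns `<unique|total>_<control|treated>` and `_pct`.
#' @export
category_table <- function(annotation) {
  records <- if (inherits(annotation, "annotation")) annotation$records else
    annotation
  stopifnot(all(c("category", "count_control", "count_treated") %in%
                names(records)))
  cats <- c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "unann")
  stopifnot(all(records$category %in% cats))
  f <- factor(records$category, levels = cats)
  out <- data.frame(category = c("Total", cats), stringsAsFactors = FALSE)
  for (lib in c("control", "treated")) {
    cnt <- records[[paste0("count_", lib)]]
    uni <- as.integer(tapply(as.integer(cnt > 0), f, sum, default = 0L))
    tot <- as.integer(tapply(cnt, f, sum, default = 0L))
    out[[paste0("unique_", lib)]] <- c(sum(uni), uni)
    out[[paste0("unique_", lib, "_pct")]] <-
      percent_of(c(sum(uni), uni), max(1, sum(uni)))
    out[[paste0("total_", lib)]] <- c(sum(tot), tot)
    out[[paste0("total_", lib, "_pct")]] <-
      percent_of(c(sum(tot), tot), max(1, sum(tot)))
  }
  out
}

#' Unannotated tags to feed novel-miRNA prediction
#'
#' @param annotation an [annotate_tags()] result.
#' @return the subset of tag rows with category `unann`.
#' @export
unannotated_tags <- function(annotation) {
  stopifnot(inherits(annotation, "annotation"))
  out <- annotation$records[annotation$records$category == "unann",
                            c("sequence", "count_control", "count_treated")]
  rownames(out) <- NULL
  out
}
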