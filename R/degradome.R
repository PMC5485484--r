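# Collapse raw degradome tag reads (character vector) to unique tags with
# counts, truncating to the first trunc_len nt for mapping determinism.
collapse_degradome <- function(tags, trunc_len = 20) {
  tags <- toupper(tags)
  tags <- substr(tags, 1, trunc_len)
  tb <- table(tags)
  data.frame(sequence = names(tb), count = as.integer(tb),
             stringsAsFactors = FALSE)
}

# Map unique equal-length tags to transcripts (exact, forward strand).
# Returns data.frame(tag_index, transcript, pos) with 0-based 5' position.
map_tags_sense <- function(seqs, transcripts) {
  stopifnot(length(unique(nchar(seqs))) <= 1)
  if (!length(seqs)) {
    return(data.frame(tag_index = integer(0), transcript = character(0),
                      pos = integer(0), stringsAsFactors = FALSE))
  }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
  txset <- Biostrings::DNAStringSet(transcripts)
  hits <- lapply(seq_along(txset), function(t) {
    m <- Biostrings::matchPDict(pd, txset[[t]])
    idx <- which(lengths(m) > 0)
    if (!length(idx)) return(NULL)
    do.call(rbind, lapply(idx, function(i) {
      data.frame(tag_index = i, transcript = names(transcripts)[t],
                 pos = IRanges::start(m[[i]]) - 1L, stringsAsFactors = FALSE)
    }))
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(tag_index = integer(0), transcript = character(0),
                      pos = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Classify degradome tags and build the category summary
#'
#' Each unique tag (truncated to its first `trunc_len` nt) receives
#' exactly one annotation with precedence rRNA > tRNA > snRNA > snoRNA >
#' poly(N) (>= 10% N or any run of >= 5 N) > cDNA_sense (exact forward
#' match to a transcript) > cDNA_antisense (exact reverse-complement
#' match) > other. Noncoding matching is exact-substring.
#'
#' @param tags character vector of raw degradome tag reads, or a FASTA
#'   path.
#' @param transcripts named character vector of reference transcripts.
#' @param noncoding named character vector of noncoding sequences.
#' @param family family label per noncoding sequence.
#' @param trunc_len tag truncation length for mapping (default 20).
#' @return list of class `degradome_annotation`: `tags` (unique tags with
#'   `count`, `annotation`, and `transcript`/`pos` for sense-mapped tags)
#'   and `summary` (per-category unique/total counts and percentages in
#'   the degradome summary-table layout).
#' @export
classify_degradome_tags <- function(tags, transcripts, noncoding, family,
                                    trunc_len = 20) {
  if (length(tags) == 1 && file.exists(tags)) tags <- read_fasta(tags)
  uq <- collapse_degradome(tags, trunc_len)
  n <- nrow(uq)
  ann <- rep(NA_character_, n)

  fam <- classify_noncoding(data.frame(sequence = uq$sequence), noncoding,
                            family)
  ann[!is.na(fam)] <- fam[!is.na(fam)]

  n_count <- nchar(gsub("[^N]", "", uq$sequence))
  polyn <- is.na(ann) & (n_count / nchar(uq$sequence) >= 0.10 |
                           grepl("NNNNN", uq$sequence, fixed = TRUE))
  ann[polyn] <- "polyN"

  uq$transcript <- NA_character_
  uq$pos <- NA_integer_
  todo <- which(is.na(ann) & !grepl("N", uq$sequence, fixed = TRUE))
  if (length(todo)) {
    sm <- map_tags_sense(uq$sequence[todo], transcripts)
    if (nrow(sm)) {
      first <- sm[!duplicated(sm$tag_index), ]
      hit <- todo[first$tag_index]
      ann[hit] <- "cDNA_sense"
      uq$transcript[hit] <- first$transcript
      uq$pos[hit] <- first$pos
    }
    left <- todo[is.na(ann[todo])]
    if (length(left)) {
      am <- map_tags_sense(revcomp(uq$sequence[left]), transcripts)
      if (nrow(am)) ann[left[unique(am$tag_index)]] <- "cDNA_antisense"
    }
  }
  ann[is.na(ann)] <- "other"
  uq$annotation <- ann

  cats <- c("rRNA", "tRNA", "snRNA", "snoRNA", "polyN", "cDNA_sense",
            "cDNA_antisense", "other")
  f <- factor(ann, levels = cats)
  uni <- as.integer(tapply(rep(1L, n), f, sum, default = 0L))
  tot <- as.integer(tapply(uq$count, f, sum, default = 0L))
  summary <- data.frame(
    category = c(cats, "Total"),
    unique_tags = c(uni, sum(uni)),
    unique_pct = percent_of(c(uni, sum(uni)), max(1, sum(uni))),
    total_tags = c(tot, sum(tot)),
    total_pct = percent_of(c(tot, sum(tot)), max(1, sum(tot))),
    stringsAsFactors = FALSE
  )
  structure(list(tags = uq, summary = summary),
            class = "degradome_annotation")
}

#' Align miRNAs antisense to transcripts with the plant target-penalty
#' scheme
#'
#' Ungapped sliding-window alignment of each miRNA against every
#' transcript: mismatch 1, G:U wobble 0.5, doubled at miRNA positions
#' 2-13 (1-based from the 5' end); windows scoring at most `max_score`
#' are candidate duplexes. The cleavage position of a candidate is the
#' transcript coordinate opposite miRNA positions 10-11.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcripts.
#' @param max_score score cutoff (default 4.5).
#' @param core core interval of doubled penalties (default 2-13).
#' @return data.frame: `mirna_id`, `transcript`, `pos` (0-based window
#'   start), `score`, `cleavage_pos` (0-based transcript coordinate of
#'   the degradome tag 5' end expected from cleavage).
#' @export
align_mirna_targets <- function(mirnas, transcripts, max_score = 4.5,
                                core = c(2, 13)) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  lens <- nchar(mirnas)
  if (any(lens < 18 | lens > 30)) {
    stop("miRNA lengths must be within 18-30 nt")
  }
  hits <- .target_scan(unname(toupper(mirnas)), unname(toupper(transcripts)),
                       max_score, as.integer(core[1]), as.integer(core[2]))
  if (!nrow(hits)) {
    return(data.frame(mirna_id = character(0), transcript = character(0),
                      pos = integer(0), score = numeric(0),
                      cleavage_pos = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(
    mirna_id = names(mirnas)[hits$mirna],
    transcript = names(transcripts)[hits$transcript],
    pos = hits$pos, score = hits$score,
    cleavage_pos = hits$pos + lens[hits$mirna] - 10L,
    stringsAsFactors = FALSE
  )
}

# t-plot category from a per-position abundance profile.
#   0: site is the unique maximum; 1: site at a tied maximum;
#   2: below the maximum but above the median of occupied positions;
#   3: at or below that median, more than one read; 4: exactly one read.
tplot_category <- function(site_count, profile_counts) {
  occupied <- profile_counts[profile_counts >= 1]
  mx <- max(occupied)
  if (site_count == 1) return(4L)
  if (site_count == mx) {
    if (sum(occupied == mx) == 1) return(0L) else return(1L)
  }
  med <- median(occupied)
  if (site_count > med) return(2L) else return(3L)
}

#' Call cleavage sites from candidate duplexes and degradome tags
#'
#' For every candidate duplex, the site abundance is the summed count of
#' sense-mapped degradome tags whose 5' end sits exactly at the position
#' opposite miRNA positions 10-11. Sites with zero reads are dropped;
#' retained sites are assigned a t-plot category 0-4 from the
#' per-transcript abundance profile (see details in the vignette).
#'
#' @param duplexes an [align_mirna_targets()] data.frame.
#' @param deg_annotation a [classify_degradome_tags()] result.
#' @return data.frame of target hits: `mirna_id`, `transcript`, `pos`,
#'   `score`, `cleavage_pos`, `site_count`, `category`.
#' @export
call_cleavage <- function(duplexes, deg_annotation) {
  stopifnot(inherits(deg_annotation, "degradome_annotation"))
  sense <- deg_annotation$tags[
    deg_annotation$tags$annotation == "cDNA_sense", , drop = FALSE]
  out <- duplexes
  out$site_count <- 0L
  out$category <- NA_integer_
  for (i in seq_len(nrow(out))) {
    prof <- sense[sense$transcript == out$transcript[i], , drop = FALSE]
    if (!nrow(prof)) next
    counts <- tapply(prof$count, prof$pos, sum)
    site <- counts[as.character(out$cleavage_pos[i])]
    if (is.na(site) || site == 0) next
    out$site_count[i] <- as.integer(site)
    out$category[i] <- tplot_category(site, as.numeric(counts))
  }
  out <- out[out$site_count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position abundance table for a t-plot
#'
#' @param hit one row of a [call_cleavage()] result.
#' @param deg_annotation the [classify_degradome_tags()] result.
#' @param transcripts named character vector of transcripts (for length).
#' @return data.frame of `position` (0-based), `abundance`,
#'   `is_cleavage_site` covering the transcript.
#' @export
tplot_table <- function(hit, deg_annotation, transcripts) {
  stopifnot(nrow(hit) == 1)
  sense <- deg_annotation$tags[
    deg_annotation$tags$annotation == "cDNA_sense" &
      deg_annotation$tags$transcript == hit$transcript, , drop = FALSE]
  if (!nrow(sense)) stop("no sense-mapped tags on ", hit$transcript)
  len <- nchar(transcripts[[hit$transcript]])
  ab <- integer(len)
  agg <- tapply(sense$count, sense$pos, sum)
  ab[as.integer(names(agg)) + 1L] <- as.integer(agg)
  data.frame(
    position = 0:(len - 1L),
    abundance = ab,
    is_cleavage_site = 0:(len - 1L) == hit$cleavage_pos
  )
}
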