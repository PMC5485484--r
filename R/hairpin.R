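# Exact (0-mismatch) mapping of variable-length tags to transcripts,
# using one PDict per tag length. Returns 0-based start positions.
map_tags_exact <- function(seqs, transcripts) {
  empty <- data.frame(tag_index = integer(0), transcript = character(0),
                      pos = integer(0), stringsAsFactors = FALSE)
  if (!length(seqs)) return(empty)
  out <- lapply(split(seq_along(seqs), nchar(seqs)), function(idx) {
    m <- map_tags_sense(seqs[idx], transcripts)
    if (!nrow(m)) return(NULL)
    m$tag_index <- idx[m$tag_index]
    m
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract candidate precursor windows around transcript-mapped tags
#'
#' Maps each unannotated tag to the transcripts (exact, ungapped); for
#' every mapping, emits two windows - `[tag_start - flank, tag_end]` and
#' `[tag_start, tag_end + flank]` - clipped to the transcript bounds
#' (0-based half-open coordinates). Tags mapping nowhere are skipped.
#'
#' @param tags a data.frame of unannotated tags (from
#'   [unannotated_tags()]).
#' @param transcripts named character vector of transcripts.
#' @param flank window extension on either side (nt).
#' @return data.frame: `sequence`, counts, `transcript`, `tag_start`
#'   (0-based), `win_start`, `win_end` (0-based half-open), `window`
#'   (the window sequence) and `mat_offset` (1-based mature position
#'   within the window).
#' @export
extract_precursors <- function(tags, transcripts, flank = 150) {
  maps <- map_tags_exact(tags$sequence, transcripts)
  if (!nrow(maps)) {
    return(data.frame(sequence = character(0), count_control = integer(0),
                      count_treated = integer(0), transcript = character(0),
                      tag_start = integer(0), win_start = integer(0),
                      win_end = integer(0), window = character(0),
                      mat_offset = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(maps)), function(k) {
    i <- maps$tag_index[k]
    tx <- transcripts[[maps$transcript[k]]]
    L <- nchar(tags$sequence[i])
    s <- maps$pos[k]
    e <- s + L
    win <- rbind(c(max(0L, s - flank), e), c(s, min(nchar(tx), e + flank)))
    data.frame(
      sequence = tags$sequence[i],
      count_control = tags$count_control[i],
      count_treated = tags$count_treated[i],
      transcript = maps$transcript[k], tag_start = s,
      win_start = win[, 1], win_end = win[, 2],
      window = substring(tx, win[, 1] + 1, win[, 2]),
      mat_offset = s - win[, 1] + 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Minimum mismatches of tag reverse-complement-aligned to mature over
# shifts -max_shift..max_shift (overlap >= 15 nt required). A small value
# means the tag is the duplex (star) partner of the mature.
rc_align_mismatch <- function(mature, tag, max_shift = 4) {
  brc <- revcomp(tag)
  best <- Inf
  for (sh in -max_shift:max_shift) {
    i1 <- max(1, 1 + sh)
    i2 <- min(nchar(mature), nchar(brc) + sh)
    if (i2 - i1 + 1 < 15) next
    mm <- hamming(substr(mature, i1, i2), substr(brc, i1 - sh, i2 - sh))
    if (mm < best) best <- mm
  }
  best
}

#' Is a tag the likely duplex (star) partner of a mature miRNA?
#'
#' True when the tag's reverse complement aligns to the mature with at
#' most `max_mm` mismatches at some shift within +/- 4 nt (the canonical
#' 2-nt duplex overhang plus slack), over an overlap of at least 15 nt.
#'
#' @param mature mature miRNA sequence.
#' @param tag candidate star sequence.
#' @param max_mm maximum mismatches in the duplex alignment.
#' @return logical.
#' @export
is_star_like <- function(mature, tag, max_mm = 4) {
  rc_align_mismatch(mature, tag) <= max_mm
}

#' Flag star-sequence support for mature miRNAs in a tag set
#'
#' For each mature, reports whether any distinct tag in the set is its
#' duplex partner per [is_star_like()]. A fast exact 7-mer seed screen
#' against the mature's reverse complement preselects candidates.
#'
#' @param matures character vector of mature sequences.
#' @param tag_seqs character vector of all tag sequences.
#' @param tag_counts optional pooled read counts along `tag_seqs`;
#'   candidate stars below `min_count` reads are ignored.
#' @param max_mm maximum mismatches in the duplex alignment; the default
#'   (2) keeps chance reverse-complement matches from random background
#'   tags negligible.
#' @param min_count minimum pooled reads of a supporting star tag.
#' @return logical vector along `matures`.
#' @export
flag_star_support <- function(matures, tag_seqs, tag_counts = NULL,
                              max_mm = 2, min_count = 2) {
  if (!is.null(tag_counts)) {
    keep <- tag_counts >= min_count
    tag_seqs <- tag_seqs[keep]
  }
  vapply(matures, function(m) {
    rc <- revcomp(m)
    seeds <- unique(substring(rc, 1:(nchar(rc) - 6), 7:nchar(rc)))
    cand <- tag_seqs[grepl(paste(seeds, collapse = "|"), tag_seqs)]
    cand <- setdiff(cand, m)
    any(vapply(cand, function(tg) is_star_like(m, tg, max_mm), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

# Direct children of pair (i, j=pairs[i]): the base pairs immediately
# nested inside it. Returns a 2-column matrix.
pair_children <- function(pairs, i, j) {
  kids <- NULL
  pos <- i + 1
  while (pos < j) {
    p <- pairs[pos]
    if (!is.na(p) && p > pos) {
      kids <- rbind(kids, c(pos, p))
      pos <- p + 1
    } else {
      pos <- pos + 1
    }
  }
  kids
}

# Walk from the minimal pair enclosing the mature's core toward the
# terminal loop. A few mature edge bases (up to `edge_slack`) may stick
# out of the anchored stem - they are accounted for by the unpaired-base
# criterion instead. Fails (NULL) when no stem covers the core or when
# the path opens into a multiloop before reaching a single terminal loop.
mature_stem_walk <- function(pairs, m1, m2, edge_slack = 3) {
  n <- length(pairs)
  c1 <- min(max(1, m1 + edge_slack), n)
  c2 <- max(1, min(n, m2 - edge_slack))
  best <- NULL
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (is.na(j) || j <= i) next
    if (i <= c1 && j >= c2) {
      if (is.null(best) || (j - i) < (best[2] - best[1])) best <- c(i, j)
    }
  }
  if (is.null(best)) return(NULL)
  cur <- best
  repeat {
    kids <- pair_children(pairs, cur[1], cur[2])
    if (is.null(kids)) {
      return(list(anchor = best, loop = c(cur[1] + 1, cur[2] - 1)))
    }
    if (nrow(kids) > 1) {
      # the path branches: if the mature core sits wholly inside one
      # branch, follow it; otherwise the mature faces a multiloop
      inside <- which(kids[, 1] <= c1 & kids[, 2] >= c2)
      if (length(inside) == 1) {
        cur <- kids[inside, ]
      } else {
        return(NULL)
      }
    } else {
      cur <- kids[1, ]
    }
  }
}

# Top-level structural component (outermost pair in the forest) covering
# the mature. The component must contain all but at most `max_outside`
# mature bases; the best-overlapping component wins.
component_span <- function(pairs, m1, m2, max_outside = 4) {
  n <- length(pairs)
  L <- m2 - m1 + 1
  best <- NULL
  best_ov <- -1L
  pos <- 1
  while (pos <= n) {
    j <- pairs[pos]
    if (!is.na(j) && j > pos) {
      ov <- max(0L, min(j, m2) - max(pos, m1) + 1L)
      if (ov > best_ov) {
        best_ov <- ov
        best <- c(pos, j)
      }
      pos <- j + 1
    } else {
      pos <- pos + 1
    }
  }
  if (is.null(best) || best_ov < L - max_outside) return(NULL)
  best
}

# Apply the novel-miRNA hairpin criteria to a folded precursor.
# Returns NULL on rejection, else the call descriptors.
evaluate_hairpin <- function(fold, m1, m2, mfe_max, max_unpaired,
                             max_bulge) {
  n <- length(fold$pairs)
  L <- m2 - m1 + 1
  c1 <- max(1, m1)                 # mature bases beyond the excised
  c2 <- min(n, m2)                 # component count as unpaired below
  if (c2 - c1 + 1 < L - max_unpaired) return(NULL)
  walk <- mature_stem_walk(fold$pairs, m1, m2)
  if (is.null(walk)) return(NULL)                       # criterion (i)
  loop <- walk$loop
  on5 <- c2 <= loop[1] - 2
  on3 <- c1 >= loop[2] + 2
  if (!on5 && !on3) return(NULL)                        # criterion (ii)
  partners <- fold$pairs[c1:c2]
  unpaired <- L - sum(!is.na(partners))
  if (unpaired > max_unpaired) return(NULL)             # criterion (iii)
  ps <- partners[!is.na(partners)]
  star_span <- max(ps) - min(ps) + 1
  # asymmetric bulge within the duplex: compare the spans of the two
  # strands between their outermost paired bases (unpaired edge bases
  # are governed by the unpaired-count criterion, not this one)
  paired_idx <- which(!is.na(partners))
  mature_span <- max(paired_idx) - min(paired_idx) + 1
  if (abs(mature_span - star_span) > max_bulge) return(NULL)
  if (fold$mfe > mfe_max) return(NULL)                  # criterion (iv)
  arm <- if ((m1 + m2) / 2 < loop[1]) "5p" else "3p"
  list(arm = arm, loop = loop, mfe = fold$mfe, unpaired = unpaired,
       star_region = c(min(ps), max(ps)))
}

#' Predict novel miRNAs from candidate precursor windows
#'
#' Each window is folded; the top-level structural component covering the
#' mapped tag is excised and refolded, and the hairpin criteria applied:
#' (i) the tag's stem runs into exactly one terminal loop (no multiloop
#' on the path), (ii) the tag lies wholly on one arm, at least 2 nt from
#' the loop, (iii) at most `max_unpaired` tag bases are unpaired against
#' the star region and the duplex asymmetry is at most `max_bulge` nt,
#' (iv) precursor MFE at most `mfe_max` kcal/mol, (v) tag count summed
#' over libraries at least `min_count`. Star support is flagged when
#' another tag matches the star region (2-nt tolerance). Calls from
#' overlapping windows are deduplicated by mature sequence.
#'
#' @param windows an [extract_precursors()] data.frame.
#' @param tags all unannotated tags (for star detection).
#' @param params folding parameters from [fold_params()].
#' @param mfe_max maximum precursor MFE (kcal/mol).
#' @param min_count minimum pooled read count of the mature.
#' @param max_unpaired maximum unpaired mature bases in the duplex.
#' @param max_bulge maximum asymmetric bulge (nt) within the duplex.
#' @param known_matures optional character vector of already-identified
#'   (conserved) mature sequences; candidates whose precursor contains
#'   one of them are duplex partners of a known miRNA, not novel calls.
#' @return data.frame of novel calls: `mature`, `star`, `has_star`,
#'   `arm`, `precursor`, `structure`, `mfe`, `precursor_length`,
#'   `count_control`, `count_treated`.
#' @export
call_novel <- function(windows, tags, params = fold_params(),
                       mfe_max = -18, min_count = 5, max_unpaired = 4,
                       max_bulge = 2, known_matures = NULL) {
  empty <- data.frame(
    mature = character(0), star = character(0), has_star = logical(0),
    arm = character(0), precursor = character(0), structure = character(0),
    mfe = numeric(0), precursor_length = integer(0),
    count_control = integer(0), count_treated = integer(0),
    stringsAsFactors = FALSE
  )
  if (!nrow(windows)) return(empty)

  # pass 1: evaluate every window independently
  cands <- list()
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    if (w$count_control + w$count_treated < min_count) next  # criterion (v)
    if (!is.null(known_matures) &&
        any(vapply(known_matures, is_star_like, logical(1),
                   tag = w$sequence, USE.NAMES = FALSE))) {
      next  # duplex partner of an already-identified miRNA
    }
    L <- nchar(w$sequence)
    if (nchar(w$window) < L + 20) next
    f1 <- fold_rna(w$window, params)
    span <- component_span(f1$pairs, w$mat_offset, w$mat_offset + L - 1)
    if (is.null(span)) next
    precursor <- substr(w$window, span[1], span[2])
    if (nchar(precursor) < L + 12) next
    if (!is.null(known_matures) &&
        any(vapply(known_matures, grepl, logical(1), x = precursor,
                   fixed = TRUE, USE.NAMES = FALSE))) {
      next  # hairpin of an already-identified miRNA: candidate is its star
    }
    f2 <- fold_rna(precursor, params)
    m1 <- w$mat_offset - span[1] + 1
    m2 <- m1 + L - 1
    ev <- evaluate_hairpin(f2, m1, m2, mfe_max, max_unpaired, max_bulge)
    if (is.null(ev)) next
    sr <- span[1] + ev$star_region - 1  # star span in window coordinates
    cands[[length(cands) + 1]] <- list(
      mature = w$sequence,
      star_window = substr(w$window, max(1, sr[1] - 4),
                           min(nchar(w$window), sr[2] + 6)),
      arm = ev$arm, precursor = precursor, structure = f2$structure,
      mfe = f2$mfe, precursor_length = nchar(precursor),
      count_control = w$count_control, count_treated = w$count_treated
    )
  }
  if (!length(cands)) return(empty)

  # pass 2: per mature keep the most stable precursor; accept abundant
  # matures first so the (lower-count) star tag of an accepted hairpin is
  # reported as its duplex partner, not as a second miRNA
  counts <- vapply(cands, function(x) x$count_control + x$count_treated,
                   numeric(1))
  mfes <- vapply(cands, function(x) x$mfe, numeric(1))
  cands <- cands[order(-counts, mfes)]
  accepted <- list()
  seen <- character(0)
  for (x in cands) {
    if (x$mature %in% seen) next
    if (any(vapply(seen, is_star_like, logical(1), tag = x$mature,
                   USE.NAMES = FALSE))) {
      next  # duplex partner of an accepted call
    }
    accepted[[length(accepted) + 1]] <- x
    seen <- c(seen, x$mature)
  }
  out <- do.call(rbind, lapply(accepted, function(x) {
    data.frame(x, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL

  # star support: a distinct tag sitting at the star position (exact
  # substring of the star arm window, i.e. the duplex span +/- 2 nt)
  out$star <- NA_character_
  out$has_star <- FALSE
  for (i in seq_len(nrow(out))) {
    sw <- out$star_window[i]
    wl <- nchar(sw)
    subs <- unlist(lapply(18:wl, function(sl) {
      if (sl > wl) return(character(0))
      substring(sw, 1:(wl - sl + 1), sl:wl)
    }))
    hit <- setdiff(intersect(subs, tags$sequence), out$mature[i])
    if (length(hit)) {
      out$star[i] <- hit[which.max(nchar(hit))]
      out$has_star[i] <- TRUE
    }
  }
  out[, c("mature", "star", "has_star", "arm", "precursor", "structure",
          "mfe", "precursor_length", "count_control", "count_treated")]
}
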