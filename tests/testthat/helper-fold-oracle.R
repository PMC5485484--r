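# Exhaustive enumeration oracle for RNA folding: generates every nested
# secondary structure (minimum loop 3, Watson-Crick + G:U pairs) of a
# short sequence and scores each with an independent loop-decomposition
# energy evaluator over the same parameter table. Integer tenth-kcal
# arithmetic makes the comparison with the dynamic program exact.

PAIR_LEVELS <- c("AU", "CG", "GC", "UA", "GU", "UG")

seq_codes <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ch[ch == "T"] <- "U"
  ch
}

can_pair_chr <- function(a, b) paste0(a, b) %in% PAIR_LEVELS

# All nested structures of `seq` as a list of 2-column pair matrices
# (NULL = open structure).
enum_structures <- function(seq, min_loop = 3) {
  ch <- seq_codes(seq)
  n <- length(ch)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (j - i < min_loop) return(list(NULL))
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1, j)                       # i unpaired
    ks <- if (i + min_loop + 1 <= j) (i + min_loop + 1):j else integer(0)
    for (k in ks) {
      if (!can_pair_chr(ch[i], ch[k])) next
      left <- rec(i + 1, k - 1)
      right <- if (k + 1 <= j) rec(k + 1, j) else list(NULL)
      for (ls in left) {
        for (rs in right) {
          out[[length(out) + 1]] <- rbind(c(i, k), ls, rs)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

to_tenth <- function(x) {
  out <- round(x * 10)
  out[!is.finite(out)] <- NA_real_
  as.integer(out)
}

# Loop-decomposition energy of one structure, in integer tenths;
# NA if the structure uses a loop outside the tabulated sizes.
eval_energy <- function(seq, pairs_mat, params) {
  ch <- seq_codes(seq)
  n <- length(ch)
  pmap <- rep(NA_integer_, n)
  if (!is.null(pairs_mat)) {
    for (r in seq_len(nrow(pairs_mat))) {
      pmap[pairs_mat[r, 1]] <- pairs_mat[r, 2]
      pmap[pairs_mat[r, 2]] <- pairs_mat[r, 1]
    }
  } else {
    return(0L)
  }
  stack10 <- round(params$stack * 10)
  hp10 <- to_tenth(params$hairpin)
  bu10 <- to_tenth(params$bulge)
  il10 <- to_tenth(params$internal)
  a10 <- to_tenth(params$ml_close)
  b10 <- to_tenth(params$ml_branch)
  c10 <- to_tenth(params$ml_unpaired)
  asymc <- to_tenth(params$asym_coef)
  asymm <- to_tenth(params$asym_max)
  pair_name <- function(i, j) paste0(ch[i], ch[j])

  total <- 0L
  for (r in seq_len(nrow(pairs_mat))) {
    i <- pairs_mat[r, 1]
    j <- pairs_mat[r, 2]
    # direct children
    kids <- NULL
    unp <- 0L
    pos <- i + 1
    while (pos < j) {
      if (!is.na(pmap[pos]) && pmap[pos] > pos) {
        kids <- rbind(kids, c(pos, pmap[pos]))
        pos <- pmap[pos] + 1
      } else {
        unp <- unp + 1L
        pos <- pos + 1
      }
    }
    if (is.null(kids)) {
      e <- hp10[j - i - 1]
      if (is.na(e)) return(NA_integer_)
      total <- total + e
    } else if (nrow(kids) == 1) {
      k <- kids[1, 1]
      l <- kids[1, 2]
      n1 <- k - i - 1
      n2 <- j - l - 1
      if (n1 == 0 && n2 == 0) {
        total <- total + stack10[pair_name(i, j), pair_name(k, l)]
      } else if (n1 == 0 || n2 == 0) {
        e <- bu10[n1 + n2]
        if (is.na(e)) return(NA_integer_)
        total <- total + e
      } else {
        e <- il10[n1 + n2]
        if (is.na(e)) return(NA_integer_)
        total <- total + e + min(asymm, asymc * abs(n1 - n2))
      }
    } else {
      total <- total + a10 + b10 * (nrow(kids) + 1L) + c10 * unp
    }
  }
  as.integer(total)
}

# Oracle MFE in tenths (0 for the open structure at minimum).
oracle_mfe <- function(seq, params) {
  structs <- enum_structures(seq)
  best <- 0L
  for (s in structs) {
    e <- eval_energy(seq, s, params)
    if (!is.na(e) && e < best) best <- e
  }
  best
}
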