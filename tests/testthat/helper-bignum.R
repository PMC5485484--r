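# Exact big-integer arithmetic (base 1e7 limbs, little-endian numeric
# vectors) used to evaluate the tag-count exact test in rational
# arithmetic, independently of the package's log-gamma implementation.
# All quantities of the test with library ratio r = p/q are ratios of
# integers: P(y|x) = C(x+y, y) p^y q^(x+1) / (p+q)^(x+y+1).

BIG_BASE <- 1e7

big_norm <- function(x) {
  repeat {
    carry <- floor(x / BIG_BASE)
    if (!any(carry != 0)) break
    x <- x - carry * BIG_BASE
    x <- c(x, 0)
    x[seq_along(carry) + 1] <- x[seq_along(carry) + 1] + carry
  }
  n <- if (any(x != 0)) max(which(x != 0)) else 1
  x[seq_len(n)]
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

big_smul <- function(a, k) big_norm(a * k)  # k a small integer

big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    res[idx] <- res[idx] + a[i] * b
  }
  big_norm(res)
}

big_sub <- function(a, b) {  # requires a >= b
  n <- max(length(a), length(b))
  x <- c(a, numeric(n - length(a))) - c(b, numeric(n - length(b)))
  for (i in seq_len(max(n - 1, 1))) {
    if (i < n && x[i] < 0) {
      k <- ceiling(-x[i] / BIG_BASE)
      x[i] <- x[i] + k * BIG_BASE
      x[i + 1] <- x[i + 1] - k
    }
  }
  stopifnot(x[n] >= 0)
  m <- if (any(x != 0)) max(which(x != 0)) else 1
  x[seq_len(m)]
}

# Natural log of a bignum, accurate to ~1e-15 relative.
big_ln <- function(a) {
  n <- length(a)
  if (n <= 2) return(log(sum(a * BIG_BASE^(seq_len(n) - 1))))
  top <- a[n] * BIG_BASE^2 + a[n - 1] * BIG_BASE + a[n - 2]
  log(top) + (n - 3) * log(BIG_BASE)
}

# All Pascal rows 0..nmax as limb matrices (column k+1 holds C(n, k)).
# Built by exact addition only.
pascal_rows <- function(nmax, limbs = 30) {
  norm_mat <- function(M) {
    repeat {
      carry <- floor(M / BIG_BASE)
      if (!any(carry != 0)) return(M)
      M <- M - carry * BIG_BASE
      M[2:nrow(M), ] <- M[2:nrow(M), ] + carry[1:(nrow(M) - 1), , drop = FALSE]
    }
  }
  rows <- vector("list", nmax + 1)
  M <- matrix(0, limbs, 1)
  M[1, 1] <- 1
  rows[[1]] <- M
  for (n in seq_len(nmax)) {
    M <- norm_mat(cbind(M, 0) + cbind(0, M))
    rows[[n + 1]] <- M
  }
  rows
}

big_from_col <- function(M, k) {
  v <- M[, k]
  n <- if (any(v != 0)) max(which(v != 0)) else 1
  v[seq_len(n)]
}

# Exact-oracle evaluation of the tag-count test over the full grid
# x, y in 0..nmax for one library ratio r in {0.5, 1, 2}. Returns
# matrices pmf, C, D, p (two-sided) indexed [x+1, y+1].
ac_oracle_grid <- function(nmax, r, rows = pascal_rows(2 * nmax)) {
  stopifnot(r %in% c(0.5, 1, 2))
  ln2 <- log(2)
  ln3 <- log(3)
  pmf <- Cm <- Dm <- matrix(NA_real_, nmax + 1, nmax + 1)
  # powers of the denominator base (2 for r=1, else 3) and of 2
  pow2 <- vector("list", 2 * nmax + 2)
  pow3 <- vector("list", 2 * nmax + 2)
  pw <- 1
  for (k in 0:(2 * nmax + 1)) {
    pow2[[k + 1]] <- pw
    pw <- big_smul(pw, 2)
  }
  pw <- 1
  for (k in 0:(2 * nmax + 1)) {
    pow3[[k + 1]] <- pw
    pw <- big_smul(pw, 3)
  }
  for (x in 0:nmax) {
    num <- NULL  # numerator of the cumulative sum S_y
    for (y in 0:nmax) {
      Cxy <- big_from_col(rows[[x + y + 1]], y + 1)
      if (r == 1) {
        ln_pmf <- big_ln(Cxy) - (x + y + 1) * ln2
        term <- Cxy
        num <- if (is.null(num)) term else big_add(big_smul(num, 2), term)
        ln_C <- big_ln(num) - (x + y + 1) * ln2
        if (y == 0) {
          Dm[x + 1, y + 1] <- 1
        } else {
          dnum <- big_sub(pow2[[x + y + 1]], num_prev)
          Dm[x + 1, y + 1] <- exp(big_ln(dnum) - (x + y) * ln2)
        }
      } else {
        term <- if (r == 2) big_mul(pow2[[y + 1]], Cxy) else
          big_mul(pow2[[x + 2]], Cxy)
        ln_pmf <- big_ln(term) - (x + y + 1) * ln3
        num <- if (is.null(num)) term else big_add(big_smul(num, 3), term)
        ln_C <- big_ln(num) - (x + y + 1) * ln3
        if (y == 0) {
          Dm[x + 1, y + 1] <- 1
        } else {
          dnum <- big_sub(pow3[[x + y + 1]], num_prev)
          Dm[x + 1, y + 1] <- exp(big_ln(dnum) - (x + y) * ln3)
        }
      }
      pmf[x + 1, y + 1] <- exp(ln_pmf)
      Cm[x + 1, y + 1] <- min(exp(ln_C), 1)
      num_prev <- num
    }
  }
  p <- pmin(2 * pmin(Cm, Dm), 1)  # first arg keeps the dim attributes
  list(pmf = pmf, C = Cm, D = pmin(Dm, 1), p = p)
}
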