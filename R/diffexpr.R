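#' Reads-per-million normalisation
#'
#' `RPM = count / library_total * 1e6`. Zero counts stay zero here; the
#' pseudo-value used for fold changes is applied only in
#' [log2_fold_change()].
#'
#' @param count raw tag count(s).
#' @param library_total total clean reads of the library.
#' @return normalised expression in reads per million.
#' @export
#' @examples
#' rpm(100, 1e6)  # 100
rpm <- function(count, library_total) {
  if (length(library_total) != 1 || library_total <= 0) {
    stop("library_total must be a single positive count")
  }
  stopifnot(all(count >= 0))
  count / library_total * 1e6
}

#' Log2 fold change of normalised expression
#'
#' `log2(max(rpm_treated, eps) / max(rpm_control, eps))`; the pseudo-value
#' `eps` (default 0.01 RPM) keeps zero-count miRNAs finite and is never
#' reported as an expression value. Antisymmetric under swapping the
#' libraries.
#'
#' @param rpm_treated,rpm_control normalised expression values.
#' @param eps pseudo-value in RPM for zero expression.
#' @return log2 fold change (treated over control).
#' @export
log2_fold_change <- function(rpm_treated, rpm_control, eps = 0.01) {
  stopifnot(all(rpm_treated >= 0), all(rpm_control >= 0))
  log2(pmax(rpm_treated, eps) / pmax(rpm_control, eps))
}

#' Exact tag-count probability (Audic-Claverie-type conditional law)
#'
#' Probability of observing `y` tags in the second library given `x` in
#' the first, for library sizes `N1` and `N2`:
#' `P(y | x) = (N2/N1)^y * (x+y)! / (x! y!) / (1 + N2/N1)^(x+y+1)`.
#' Evaluated in log space via `lgamma` so real library depths cannot
#' overflow. Vectorised over `y`.
#'
#' @param x count in the first library (scalar).
#' @param y count(s) in the second library.
#' @param N1,N2 total clean reads of the first and second library.
#' @return probabilities.
#' @export
#' @examples
#' ac_pmf(0, 0, 1e6, 1e6)  # 0.5
#' ac_pmf(1, 1, 1e6, 1e6)  # 0.25
ac_pmf <- function(x, y, N1, N2) {
  stopifnot(length(x) == 1, x >= 0, all(y >= 0), N1 > 0, N2 > 0)
  r <- N2 / N1
  lp <- y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
  exp(lp)
}

# Upper tail sum_{k >= y} P(k | x), summed directly in blocks until the
# running tail increment is negligible. Used when the complement would
# lose precision.
ac_upper_tail <- function(x, y, N1, N2, block = 256L, rel_tol = 1e-16) {
  total <- 0
  k0 <- y
  repeat {
    ks <- k0:(k0 + block - 1L)
    inc <- sum(ac_pmf(x, ks, N1, N2))
    total <- total + inc
    if (inc < rel_tol * max(total, .Machine$double.xmin) || k0 > y + 1e6) {
      break
    }
    k0 <- k0 + block
  }
  min(total, 1)
}

#' Exact-test tail probabilities and two-sided p-value
#'
#' Computes the lower tail `C = sum_{k=0}^{y} P(k | x)`, the upper tail
#' `D = sum_{k=y}^{Inf} P(k | x)` (evaluated as a complement, or by
#' direct summation when the complement would cancel), and the p-value
#' `p = min(1, 2 * min(C, D))` (or `min(C, D)` one-sided). The identity
#' `C + D - P(y | x) = 1` holds to at least ten digits.
#'
#' @param x count in the first (treated) library; scalar.
#' @param y count in the second (control) library; scalar or vector.
#' @param N1,N2 library totals for `x` and `y` respectively.
#' @param two_sided double the smaller tail (default) or report it as is.
#' @return data.frame with columns `C`, `D`, `p_value` (one row per `y`).
#' @export
ac_pvalue <- function(x, y, N1, N2, two_sided = TRUE) {
  stopifnot(length(x) == 1, x >= 0, all(y >= 0), N1 > 0, N2 > 0)
  ymax <- max(y)
  pmf <- ac_pmf(x, 0:ymax, N1, N2)
  cum <- cumsum(pmf)
  C <- cum[y + 1]
  below <- ifelse(y == 0, 0, cum[pmax(y, 1)])  # sum_{k < y}
  D <- 1 - below
  # refine D by direct summation where the complement cancels badly
  # (the complement's absolute error ~1e-14 must stay small relative to D)
  for (i in which(D < 1e-2)) {
    D[i] <- ac_upper_tail(x, y[i], N1, N2)
  }
  C <- pmin(C, 1)
  D <- pmin(pmax(D, 0), 1)
  p <- if (two_sided) pmin(1, 2 * pmin(C, D)) else pmin(C, D)
  data.frame(C = C, D = D, p_value = p)
}

#' Differential-expression table for a set of miRNAs
#'
#' Assembles the full expression result per miRNA: raw counts, RPM,
#' log2 fold change, exact-test tails and p-value.
#'
#' @param mirna_id identifiers.
#' @param count_treated,count_control raw counts per library.
#' @param n_treated,n_control total clean reads per library (`N1`, `N2`).
#' @param two_sided p-value sidedness (see [ac_pvalue()]).
#' @param eps pseudo-RPM for zero counts in the fold change.
#' @return data.frame with `mirna_id`, `x`, `y`, `N1`, `N2`,
#'   `rpm_treated`, `rpm_control`, `log2fc`, `C`, `D`, `p_value`, and a
#'   Benjamini-Hochberg `p_adj` column (informational; never used by the
#'   threshold-based flags).
#' @export
ac_test <- function(mirna_id, count_treated, count_control,
                    n_treated, n_control, two_sided = TRUE, eps = 0.01) {
  n <- length(mirna_id)
  stopifnot(length(count_treated) == n, length(count_control) == n)
  rpm_t <- rpm(count_treated, n_treated)
  rpm_c <- rpm(count_control, n_control)
  tails <- do.call(rbind, lapply(seq_len(n), function(i) {
    ac_pvalue(count_treated[i], count_control[i], n_treated, n_control,
              two_sided = two_sided)
  }))
  data.frame(
    mirna_id = mirna_id, x = count_treated, y = count_control,
    N1 = n_treated, N2 = n_control,
    rpm_treated = rpm_t, rpm_control = rpm_c,
    log2fc = log2_fold_change(rpm_t, rpm_c, eps),
    C = tails$C, D = tails$D, p_value = tails$p_value,
    p_adj = stats::p.adjust(tails$p_value, method = "BH"),
    stringsAsFactors = FALSE
  )
}

#' Flag differentially expressed miRNAs at fixed thresholds
#'
#' A miRNA is differentially expressed when `p <= p_de` and
#' `|log2fc| >= lfc_min`; significantly so when `p <= p_sig` with the
#' same fold-change gate. Raw p-values gate the flags (no multiplicity
#' correction), mirroring threshold-based sRNA-seq practice.
#'
#' @param results an [ac_test()] data.frame.
#' @param p_de,p_sig p-value thresholds for DE and significant DE.
#' @param lfc_min minimum absolute log2 fold change.
#' @return list of class `de_calls`: `results` (input plus `de_flag`,
#'   `sig_flag`, `direction`) and `tally`
#'   (n_de, n_up, n_down, n_sig, n_sig_up, n_sig_down).
#' @export
call_de <- function(results, p_de = 0.05, p_sig = 0.01, lfc_min = 1) {
  stopifnot(all(c("p_value", "log2fc") %in% names(results)))
  up <- results$log2fc >= lfc_min
  down <- results$log2fc <= -lfc_min
  de <- results$p_value <= p_de & (up | down)
  sig <- results$p_value <= p_sig & (up | down)
  results$de_flag <- de
  results$sig_flag <- sig
  results$direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  tally <- c(
    n_de = sum(de), n_up = sum(de & up), n_down = sum(de & down),
    n_sig = sum(sig), n_sig_up = sum(sig & up), n_sig_down = sum(sig & down)
  )
  structure(list(results = results, tally = tally), class = "de_calls")
}

#' @export
print.de_calls <- function(x, ...) {
  t <- x$tally
  cat(sprintf("DE miRNAs: %d (%d up, %d down); significant: %d (%d up, %d down)\n",
              t["n_de"], t["n_up"], t["n_down"],
              t["n_sig"], t["n_sig_up"], t["n_sig_down"]))
  invisible(x)
}
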