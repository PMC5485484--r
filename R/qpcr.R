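#' Read a qPCR Ct table from TSV
#'
#' Expected columns: `gene`, `role` (`target`/`reference`), `condition`
#' (`control`/`treated`), `replicate`, `ct`.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(ct)
  ct
}

validate_ct_table <- function(ct) {
  need <- c("gene", "role", "condition", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(ct$role %in% c("target", "reference")),
            all(ct$condition %in% c("control", "treated")),
            all(ct$ct > 0))
  invisible(ct)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per condition, `dCt = Ct_gene - Ct_reference` with replicates paired
#' by index (same RNA preparation); `ddCt = dCt - mean(dCt_control)`;
#' `fold = 2^-ddCt`. Folds in both groups are rescaled by the mean
#' control fold so that the control mean is exactly 1.
#'
#' @param ct a Ct table (see [read_ct_table()]).
#' @param gene assayed gene id.
#' @param reference endogenous control gene id.
#' @return list of class `relative_expression`: `gene`, `dct_control`,
#'   `dct_treated`, `ddct_treated` (per replicate), `fold_control`,
#'   `fold_treated`, per-group means and SDs, and `p_value` from
#'   [replicate_ttest()].
#' @export
#' @examples
#' ct <- simulate_ct_table("g1", lfc = 2, noise_sd = 0)
#' ddct(ct, "g1", "U6")$fold_mean_treated  # 4
ddct <- function(ct, gene, reference) {
  validate_ct_table(ct)
  pick <- function(g, cond) {
    x <- ct[ct$gene == g & ct$condition == cond, , drop = FALSE]
    if (!nrow(x)) stop("no Ct rows for '", g, "' in condition '", cond, "'")
    setNames(x$ct, x$replicate)
  }
  dct <- list()
  for (cond in c("control", "treated")) {
    g <- pick(gene, cond)
    r <- pick(reference, cond)
    reps <- intersect(names(g), names(r))
    orphan <- setdiff(union(names(g), names(r)), reps)
    if (length(orphan)) {
      stop("unpaired replicates for '", gene, "' (", cond, "): ",
           paste(orphan, collapse = ", "))
    }
    if (length(reps) < 2) stop("need >= 2 paired replicates per condition")
    dct[[cond]] <- g[reps] - r[reps]
  }
  ddct_ctl <- dct$control - mean(dct$control)
  ddct_trt <- dct$treated - mean(dct$control)
  fold_ctl <- 2^-ddct_ctl
  fold_trt <- 2^-ddct_trt
  scale <- mean(fold_ctl)           # control mean pinned to 1
  fold_ctl <- fold_ctl / scale
  fold_trt <- fold_trt / scale
  structure(list(
    gene = gene, reference = reference,
    dct_control = dct$control, dct_treated = dct$treated,
    ddct_treated = ddct_trt,
    fold_control = fold_ctl, fold_treated = fold_trt,
    fold_mean_control = mean(fold_ctl), fold_mean_treated = mean(fold_trt),
    fold_sd_control = stats::sd(fold_ctl), fold_sd_treated = stats::sd(fold_trt),
    p_value = replicate_ttest(fold_ctl, fold_trt)
  ), class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("%s (vs %s): fold %.3f +/- %.3f (control 1 +/- %.3f), p = %.4g\n",
              x$gene, x$reference, x$fold_mean_treated, x$fold_sd_treated,
              x$fold_sd_control, x$p_value))
  invisible(x)
}

#' Two-sample replicate t-test (Welch)
#'
#' Two-sided Welch t-test between control and treated replicate values.
#' Degenerate input (zero variance in both groups) yields p = 1 for
#' equal means and p ~ 0 otherwise.
#'
#' @param control,treated numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance (Student) test instead of Welch.
#' @return two-sided p-value.
#' @export
replicate_ttest <- function(control, treated, pooled = FALSE) {
  if (length(control) < 2 || length(treated) < 2) {
    stop("need >= 2 replicates per group")
  }
  if (stats::sd(control) == 0 && stats::sd(treated) == 0) {
    return(if (isTRUE(all.equal(mean(control), mean(treated)))) 1 else 0)
  }
  stats::t.test(control, treated, var.equal = pooled)$p.value
}
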